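# Small fixtures built in code.

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a toy descriptor tibble with two well-separated classes
toy_two_class <- function(n_per_class = 20, d = 81, shift = 6, seed = 42) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(2 * n_per_class * d), 2 * n_per_class, d)
    x[seq_len(n_per_class), 1] <- x[seq_len(n_per_class), 1] + shift
    colnames(x) <- sprintf("hog%02d", seq_len(d))
    dplyr::bind_cols(
      tibble::tibble(id = sprintf("t%03d", seq_len(2 * n_per_class)),
                     class = rep(c("normal", "EGFR_deletion"),
                                 each = n_per_class)),
      tibble::as_tibble(x)
    )
  })
}

# a miniature synthetic corpus (short genes, few samples) for fast pipeline
# tests
tiny_corpus_config <- function(seed = 7, counts = 6L) {
  corpus_config(
    gene_lengths = c(EGFR = 120L, KRAS = 60L, TP53 = 90L),
    class_counts = setNames(rep(as.integer(counts), 5), class_labels()$class[-1]),
    deletion_length_range = c(2L, 8L),
    seed = seed
  )
}

tiny_pipeline_config <- function(seed = 1L) {
  cfg <- pipeline_config(seed = seed)
  cfg$ann$hidden <- c(12L, 12L)
  cfg$ann$max_epochs <- 120L
  cfg$bagging$n_base <- 6L
  cfg$bagging$n_selected <- 3L
  cfg
}
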