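#' Scale the benchmark's per-class acquired counts
#'
#' Reproduces the five mutation-class count ratios 2640 : 975 : 2472 : 42 :
#' 277 at any scale factor, rounded to the nearest integer with a floor so
#' no class disappears.
#'
#' @param scale Positive scale factor (1 reproduces the acquired counts).
#' @param min_count Per-class floor (default 3, so every class survives a
#'   stratified three-way split).
#' @return A named integer vector over the five mutation classes.
#' @export
#' @examples
#' scaled_class_counts(0.047)
scaled_class_counts <- function(scale = 1, min_count = 3L) {
  if (scale <= 0) abort("scale must be > 0")
  ref <- reference_class_counts()
  setNames(pmax(as.integer(round(scale * ref$acquired)),
                as.integer(min_count)),
           ref$class)
}

#' Configuration of the synthetic six-class corpus
#'
#' The generator emulates the structure of the NSCLC mutation benchmark:
#' three uniform-random reference "genes" with the benchmark's coding-
#' sequence lengths, and five mutation classes whose sample counts follow
#' the benchmark's acquired-count ratios. A single mutation event per
#' sample: a substitution draws a uniform position and a uniformly chosen
#' different base; a deletion removes a uniform-length contiguous run (3-24
#' bases by default, spanning typical in-frame deletion sizes in these
#' genes). The normal class is the three unmutated references.
#'
#' @param gene_lengths Named lengths of the three references (defaults
#'   [reference_gene_lengths()]).
#' @param class_counts Named counts for the five mutation classes (default
#'   `scaled_class_counts(scale)`).
#' @param scale Scale factor applied to the benchmark's acquired counts when
#'   `class_counts` is not given (default 0.047, about 300 samples).
#' @param n_normal Number of normal samples (default 3, one per reference;
#'   with `unique_only` there are only three distinct normals).
#' @param unique_only Forbid duplicate (class, sequence) pairs (default
#'   TRUE).
#' @param deletion_length_range Inclusive bounds of deletion lengths.
#' @param seed Integer seed; the whole corpus is a pure function of this
#'   configuration.
#' @return A `corpus_config` list.
#' @export
corpus_config <- function(gene_lengths = reference_gene_lengths(),
                          class_counts = NULL, scale = 0.047,
                          n_normal = 3L, unique_only = TRUE,
                          deletion_length_range = c(3L, 24L), seed = 1L) {
  if (is.null(class_counts)) class_counts <- scaled_class_counts(scale)
  stopifnot(length(gene_lengths) == 3L, !is.null(names(gene_lengths)))
  if (!all(names(class_counts) %in% CLASS_LEVELS[-1])) {
    abort("class_counts must be named by the five mutation classes")
  }
  if (any(class_counts < 1L)) abort("class counts must be >= 1")
  if (any(gene_lengths < 10L)) {
    abort("gene lengths must be at least the minimum descriptor width (10)")
  }
  if (deletion_length_range[1] < 1L ||
      deletion_length_range[2] < deletion_length_range[1] ||
      deletion_length_range[2] >= min(gene_lengths)) {
    abort("deletion_length_range must be within [1, min gene length)")
  }
  structure(list(gene_lengths = gene_lengths,
                 class_counts = class_counts[CLASS_LEVELS[-1]],
                 n_normal = as.integer(n_normal),
                 unique_only = unique_only,
                 deletion_length_range = as.integer(deletion_length_range),
                 seed = as.integer(seed)),
            class = "corpus_config")
}

#' Generate the three reference sequences
#'
#' Seeded uniform-random A/C/G/T strings at the configured lengths.
#'
#' @param cfg A [corpus_config()].
#' @return A tibble with columns `gene`, `id`, `bases`.
#' @export
generate_references <- function(cfg = corpus_config()) {
  genes <- names(cfg$gene_lengths)
  withr_seed(derive_seed(cfg$seed, 101L), {
    tibble::tibble(
      gene = genes,
      id = paste0("ref_", genes),
      bases = vapply(cfg$gene_lengths, function(n) {
        paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
      }, character(1), USE.NAMES = FALSE)
    )
  })
}

# gene of origin for each mutation class
class_gene <- c(EGFR_deletion = "EGFR", EGFR_substitution = "EGFR",
                KRAS_substitution = "KRAS", TP53_deletion = "TP53",
                TP53_substitution = "TP53")

#' Generate the labelled synthetic corpus
#'
#' Draws seeded mutation events per class, applies them to the matching
#' reference and returns samples, references and a per-sample manifest of
#' the generating events. With `unique_only` a class count exceeding the
#' number of attainable distinct mutants is a capacity error.
#'
#' @param cfg A [corpus_config()].
#' @return A `synthetic_corpus` list: `references` and `samples` tibbles
#'   (`id`, `gene`, `class`, `bases`) plus a `manifest` tibble recording
#'   each sample's mutation (`kind`, `position`, `alt_base`, `del_length`).
#' @export
#' @examples
#' corp <- generate_corpus(corpus_config(
#'   gene_lengths = c(EGFR = 60, KRAS = 40, TP53 = 50),
#'   class_counts = setNames(rep(5L, 5), class_labels()$class[-1]),
#'   deletion_length_range = c(2, 6), seed = 7))
#' nrow(corp$samples)
generate_corpus <- function(cfg = corpus_config()) {
  refs <- generate_references(cfg)
  ref_of <- setNames(refs$bases, refs$gene)
  samples <- list()
  manifest <- list()
  # normal class: the unmutated references, cycled
  genes <- refs$gene[((seq_len(cfg$n_normal) - 1L) %% 3L) + 1L]
  if (cfg$unique_only && cfg$n_normal > 3L) {
    abort("capacity error: at most 3 unique normal samples exist")
  }
  samples[["normal"]] <- tibble::tibble(
    id = sprintf("normal_%03d", seq_len(cfg$n_normal)),
    gene = genes, class = "normal", bases = unname(ref_of[genes])
  )
  manifest[["normal"]] <- tibble::tibble(
    id = samples[["normal"]]$id, gene = genes, kind = "none",
    position = NA_integer_, alt_base = NA_character_,
    del_length = NA_integer_
  )
  withr_seed(derive_seed(cfg$seed, 202L), {
    for (cls in names(cfg$class_counts)) {
      gene <- class_gene[[cls]]
      ref <- ref_of[[gene]]
      n_ref <- nchar(ref)
      kind <- if (grepl("deletion", cls)) "deletion" else "substitution"
      count <- cfg$class_counts[[cls]]
      capacity <- if (kind == "substitution") {
        3 * n_ref
      } else {
        dl <- cfg$deletion_length_range
        sum(vapply(dl[1]:dl[2], function(l) n_ref - l + 1, numeric(1)))
      }
      if (cfg$unique_only && count > capacity) {
        abort(paste0("capacity error: ", cls, " allows at most ", capacity,
                     " distinct mutants, requested ", count))
      }
      seen <- character(0)
      rows <- vector("list", count)
      made <- 0L
      while (made < count) {
        if (kind == "substitution") {
          pos <- sample.int(n_ref, 1L) - 1L  # 0-based
          ref_base <- substr(ref, pos + 1L, pos + 1L)
          alt <- sample(setdiff(c("A", "C", "G", "T"), ref_base), 1L)
          spec <- mutation_spec("substitution", pos, alt_base = alt)
          key <- paste0("s", pos, alt)
        } else {
          dl <- cfg$deletion_length_range
          len <- sample(seq.int(dl[1], dl[2]), 1L)
          pos <- sample.int(n_ref - len + 1L, 1L) - 1L
          spec <- mutation_spec("deletion", pos, del_length = len)
          key <- paste0("d", pos, "_", len)
        }
        if (cfg$unique_only && key %in% seen) next
        seen <- c(seen, key)
        made <- made + 1L
        rows[[made]] <- tibble::tibble(
          id = sprintf("%s_%03d", cls, made), gene = gene, class = cls,
          bases = apply_mutation(ref, spec), kind = spec$kind,
          position = spec$position,
          alt_base = spec$alt_base %||% NA_character_,
          del_length = spec$del_length %||% NA_integer_
        )
      }
      all_rows <- dplyr::bind_rows(rows)
      samples[[cls]] <- all_rows[c("id", "gene", "class", "bases")]
      manifest[[cls]] <- all_rows[c("id", "gene", "kind", "position",
                                    "alt_base", "del_length")]
    }
  })
  structure(list(references = refs,
                 samples = dplyr::bind_rows(samples),
                 manifest = dplyr::bind_rows(manifest),
                 config = cfg),
            class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat("Synthetic six-class mutation corpus\n")
  cat(sprintf("  %d samples over %d classes; references: %s\n",
              nrow(x$samples), length(unique(x$samples$class)),
              paste(sprintf("%s (%d nt)", x$references$gene,
                            nchar(x$references$bases)), collapse = ", ")))
  print(table(x$samples$class))
  invisible(x)
}

#' Write a corpus to FASTA + label/manifest tables
#'
#' Writes `samples.fasta`, `references.fasta`, a two-column tab-separated
#' label table `labels.tsv` (`id`, `class`) and the full `manifest.tsv` into
#' `dir`. The FASTA round-trips through [read_fasta()].
#'
#' @param corpus A `synthetic_corpus`.
#' @param dir Output directory (created if missing).
#' @return The paths, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    samples = file.path(dir, "samples.fasta"),
    references = file.path(dir, "references.fasta"),
    labels = file.path(dir, "labels.tsv"),
    manifest = file.path(dir, "manifest.tsv")
  )
  write_fasta(corpus$samples, paths$samples)
  write_fasta(corpus$references, paths$references)
  readr::write_tsv(corpus$samples[c("id", "class")], paths$labels)
  readr::write_tsv(corpus$manifest, paths$manifest)
  invisible(paths)
}

#' Read a sequence table plus labels written by [write_corpus()]
#'
#' @param fasta Path to a samples FASTA.
#' @param labels Path to the tab-separated `id`/`class` table.
#' @return A tibble with columns `id`, `class`, `bases`.
#' @export
read_labelled_fasta <- function(fasta, labels) {
  seqs <- read_fasta(fasta)
  lab <- readr::read_tsv(labels, show_col_types = FALSE)
  if (!all(c("id", "class") %in% names(lab))) {
    abort("label table must have columns 'id' and 'class'")
  }
  out <- dplyr::inner_join(lab, seqs, by = "id")
  if (nrow(out) < nrow(seqs)) {
    warn(paste0(nrow(seqs) - nrow(out), " FASTA record(s) without a label"))
  }
  out
}
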