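test_that("reference generation honours lengths, seed and near-uniform composition", {
  cfg <- corpus_config(seed = 3)
  refs <- generate_references(cfg)
  expect_equal(nchar(refs$bases), unname(reference_gene_lengths()))
  expect_identical(refs, generate_references(corpus_config(seed = 3)))
  expect_false(identical(refs$bases,
                         generate_references(corpus_config(seed = 4))$bases))
  # composition close to uniform at these lengths
  for (b in refs$bases) {
    comp <- table(strsplit(b, "")[[1]]) / nchar(b)
    expect_true(all(abs(comp - 0.25) < 0.03))
  }
})

test_that("scaled class counts keep the benchmark ratios and totals", {
  expect_equal(unname(scaled_class_counts(1, min_count = 1)),
               c(2640L, 975L, 2472L, 42L, 277L))
  expect_equal(sum(scaled_class_counts(1, min_count = 1)), 6406L)
  expect_equal(sum(reference_class_counts()$acquired), 6406)
  expect_equal(sum(reference_class_counts()$unique), 157)
  for (s in c(0.01, 0.047, 0.3, 2)) {
    expect_equal(unname(scaled_class_counts(s, min_count = 1)),
                 pmax(as.integer(round(s * c(2640, 975, 2472, 42, 277))), 1L))
  }
})

test_that("corpus generation books the requested samples per class", {
  cfg <- corpus_config(
    gene_lengths = c(EGFR = 80L, KRAS = 50L, TP53 = 60L),
    class_counts = setNames(rep(5L, 5), class_labels()$class[-1]),
    n_normal = 3L, deletion_length_range = c(2L, 6L), seed = 12)
  corp <- generate_corpus(cfg)
  expect_equal(nrow(corp$samples), 28)  # 3 normals + 5 classes x 5
  expect_equal(unname(table(corp$samples$class)[class_labels()$class[-1]]),
               rep(5L, 5), ignore_attr = TRUE)
  # deletions are shorter than their reference; substitutions same length
  ref_len <- setNames(nchar(corp$references$bases), corp$references$gene)
  del <- corp$samples[grepl("deletion", corp$samples$class), ]
  expect_true(all(nchar(del$bases) < ref_len[del$gene]))
  sub <- corp$samples[grepl("substitution", corp$samples$class), ]
  expect_true(all(nchar(sub$bases) == ref_len[sub$gene]))
  # substitution samples differ from their reference at exactly one site
  ref_of <- setNames(corp$references$bases, corp$references$gene)
  for (i in seq_len(nrow(sub))) {
    a <- strsplit(ref_of[[sub$gene[i]]], "")[[1]]
    b <- strsplit(sub$bases[i], "")[[1]]
    expect_equal(sum(a != b), 1)
  }
  # manifest is consistent: positions within bounds, labels match kinds
  man <- dplyr::inner_join(corp$manifest, corp$samples[c("id", "class")],
                           by = "id")
  mut <- man[man$kind != "none", ]
  expect_true(all(mut$position >= 0 & mut$position < ref_len[mut$gene]))
  expect_true(all(grepl("deletion", mut$class) == (mut$kind == "deletion")))
  # full determinism of the corpus as a function of its configuration
  expect_identical(corp$samples, generate_corpus(cfg)$samples)
})

test_that("unique-only mode dedupes and enforces capacity", {
  cfg <- tiny_corpus_config()
  corp <- generate_corpus(cfg)
  expect_equal(anyDuplicated(corp$samples[c("class", "bases")]), 0)
  over <- corpus_config(
    gene_lengths = c(EGFR = 20L, KRAS = 20L, TP53 = 20L),
    class_counts = setNames(c(100L, 3L, 3L, 3L, 3L),
                            class_labels()$class[-1]),
    deletion_length_range = c(2L, 3L), seed = 1)
  expect_error(generate_corpus(over), "capacity")
  expect_error(corpus_config(n_normal = 4L, seed = 1) |> generate_corpus(),
               "at most 3 unique normal")
})

test_that("a corpus round-trips through its on-disk fixture files", {
  corp <- generate_corpus(tiny_corpus_config())
  dir <- withr::local_tempdir()
  paths <- write_corpus(corp, dir)
  back <- read_labelled_fasta(paths$samples, paths$labels)
  expect_setequal(back$id, corp$samples$id)
  merged <- dplyr::inner_join(back, corp$samples[c("id", "bases")], by = "id",
                              suffix = c("", ".orig"))
  expect_equal(merged$bases, merged$bases.orig)
  expect_equal(merged$class[match(corp$samples$id, merged$id)],
               corp$samples$class)
  man <- readr::read_tsv(paths$manifest, show_col_types = FALSE)
  expect_equal(nrow(man), nrow(corp$samples))
})

test_that("the six classes are learnable well above chance on held-out data", {
  # non-degeneracy of the generator: a linear machine on HOG descriptors
  # beats the 1/6 chance rate by a wide margin
  corp <- generate_corpus(corpus_config(
    gene_lengths = c(EGFR = 300L, KRAS = 150L, TP53 = 200L),
    class_counts = setNames(rep(12L, 5), class_labels()$class[-1]),
    deletion_length_range = c(3L, 12L), seed = 31))
  feats <- hog_features(corp$samples)
  ev <- repeated_holdout(feats, kernel_spec("linear"), n_rounds = 3, seed = 5)
  expect_gt(ev$mean_accuracy, 3 * 100 / 6)
})
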