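test_that("read_fasta parses records in order and validates the alphabet", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s first", "ACGT"), fa)
  out <- read_fasta(fa)
  expect_equal(out$id, "s")
  expect_equal(out$bases, "ACGT")

  writeLines(c(">a", "acgt", ">b", "TTAA", "CCGG"), fa)
  out <- read_fasta(fa)
  expect_equal(out$id, c("a", "b"))
  expect_equal(out$bases, c("ACGT", "TTAACCGG"))  # upper-cased, joined

  writeLines(c(">bad", "ACGN"), fa)
  expect_error(read_fasta(fa), "bad.*position 4")
  expect_error(read_fasta(file.path(tempdir(), "nope.fa")), "not found")
})

test_that("write_fasta round-trips through read_fasta", {
  withr::with_seed(1, {
    tbl <- tibble::tibble(id = sprintf("r%d", 1:5),
                          bases = vapply(sample(50:200, 5), random_bases,
                                         character(1)))
  })
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(tbl, fa)
  expect_equal(read_fasta(fa), tbl)
})

test_that("Voss encoding reproduces the three published 10-mer mappings", {
  expected_egfr <- rbind(
    A = c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0),
    C = c(0, 0, 0, 1, 0, 0, 1, 1, 1, 0),
    G = c(0, 0, 1, 0, 1, 0, 0, 0, 0, 0),
    T = c(0, 1, 0, 0, 0, 0, 0, 0, 0, 1))
  expected_kras <- rbind(
    A = c(1, 0, 0, 1, 0, 0, 0, 1, 1, 0),
    C = c(0, 0, 0, 0, 1, 0, 0, 0, 0, 0),
    G = c(0, 0, 1, 0, 0, 0, 1, 0, 0, 0),
    T = c(0, 1, 0, 0, 0, 1, 0, 0, 0, 1))
  expected_tp53 <- rbind(
    A = c(1, 0, 0, 0, 1, 0, 0, 1, 0, 0),
    C = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 1),
    G = c(0, 0, 1, 1, 0, 1, 1, 0, 1, 0),
    T = c(0, 1, 0, 0, 0, 0, 0, 0, 0, 0))
  expect_identical(voss_encode("ATGCGACCCT") * 1, expected_egfr)
  expect_identical(voss_encode("ATGACTGAAT") * 1, expected_kras)
  expect_identical(voss_encode("ATGGAGGAGC") * 1, expected_tp53)
  expect_identical(voss_encode("A")[, 1], c(A = 1L, C = 0L, G = 0L, T = 0L))
})

test_that("Voss matrices are column-stochastic with row sums matching base composition", {
  withr::with_seed(11, {
    for (i in 1:25) {
      b <- random_bases(sample(1:80, 1))
      m <- voss_encode(b)
      expect_true(all(colSums(m) == 1))
      comp <- table(factor(strsplit(b, "")[[1]], levels = c("A", "C", "G", "T")))
      expect_equal(unname(rowSums(m)), as.vector(comp))
    }
  })
})

test_that("voss_decode inverts voss_encode and rejects broken matrices", {
  withr::with_seed(2, {
    for (i in 1:50) {
      b <- random_bases(sample(1:100, 1))
      expect_identical(voss_decode(voss_encode(b)), b)
    }
  })
  m <- voss_encode("ACGT")
  m[, 3] <- 0L
  expect_error(voss_decode(m), "column 3")
  m2 <- voss_encode("ACGT")
  m2[2, 1] <- 1L
  expect_error(voss_decode(m2), "column 1")
  expect_error(voss_decode(matrix(1L, 3, 4)), "4 rows")
})

test_that("apply_mutation implements substitution and deletion semantics", {
  expect_identical(
    apply_mutation("ACGT", mutation_spec("substitution", 1, alt_base = "T")),
    "ATGT")
  expect_identical(
    apply_mutation("ACGT", mutation_spec("deletion", 1, del_length = 2)),
    "AT")
  # no-op substitutions are spec errors
  expect_error(
    apply_mutation("ACGT", mutation_spec("substitution", 0, alt_base = "A")),
    "equals the reference")
  expect_error(
    apply_mutation("ACGT", mutation_spec("substitution", 9, alt_base = "A")),
    "out of range")
  expect_error(
    apply_mutation("ACGT", mutation_spec("deletion", 3, del_length = 2)),
    "exceeds")
  # purity: same spec, same reference, same result; reference untouched
  ref <- "ACGTACGT"
  spec <- mutation_spec("deletion", 2, del_length = 3)
  out1 <- apply_mutation(ref, spec)
  out2 <- apply_mutation(ref, spec)
  expect_identical(out1, out2)
  expect_identical(ref, "ACGTACGT")
})

test_that("substitutions change exactly one position, deletions shorten by del_length", {
  withr::with_seed(5, {
    for (i in 1:30) {
      ref <- random_bases(60)
      pos <- sample(0:59, 1)
      rb <- substr(ref, pos + 1, pos + 1)
      alt <- sample(setdiff(c("A", "C", "G", "T"), rb), 1)
      mut <- apply_mutation(ref, mutation_spec("substitution", pos, alt_base = alt))
      diffs <- which(strsplit(ref, "")[[1]] != strsplit(mut, "")[[1]])
      expect_equal(diffs, pos + 1)
      len <- sample(1:10, 1)
      dpos <- sample(0:(60 - len), 1)
      del <- apply_mutation(ref, mutation_spec("deletion", dpos, del_length = len))
      expect_equal(nchar(del), 60 - len)
      expect_identical(del, paste0(substr(ref, 1, dpos),
                                   substr(ref, dpos + len + 1, 60)))
    }
  })
})

test_that("class target encoding is one-hot and consistent across representations", {
  tbl <- class_labels()
  expect_equal(nrow(tbl), 6)
  expect_equal(tbl$class_index, 1:6)
  # the 1's index equals the integer label
  for (i in 1:6) {
    bits <- as.integer(strsplit(tbl$target[i], "")[[1]])
    expect_equal(sum(bits), 1)
    expect_equal(which(bits == 1), i)
  }
  tm <- encode_targets(c("KRAS_substitution", "normal"))
  expect_equal(dim(tm), c(2, 6))
  expect_equal(unname(tm[1, ]), c(0, 0, 0, 1, 0, 0))
  # argmax decoding round-trips, ties go to the lowest class index
  expect_equal(as.character(decode_outputs(tm)),
               c("KRAS_substitution", "normal"))
  expect_equal(as.character(decode_outputs(matrix(0.5, 1, 6))), "normal")
  expect_error(encode_targets("EGFR"), "unknown class")
})
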