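# Bundled reference tables from the published NSCLC six-class mutation
# benchmark that this pipeline targets. They serve as regression fixtures for
# the evaluation arithmetic and as worked-example inputs; no sequence data is
# included.

#' Reference per-class sample counts of the mutation benchmark
#'
#' Acquired and unique sample counts for the five mutation classes of the
#' NSCLC benchmark corpus (the normal class is the three reference genes and
#' carries no row). The acquired-count ratios drive
#' [scaled_class_counts()].
#'
#' @return A tibble with columns `class`, `acquired`, `unique`.
#' @export
#' @examples
#' sum(reference_class_counts()$acquired)
reference_class_counts <- function() {
  tibble::tibble(
    class = CLASS_LEVELS[-1],
    acquired = c(2640L, 975L, 2472L, 42L, 277L),
    unique = c(35L, 27L, 28L, 32L, 35L)
  )
}

#' Reference gene lengths of the benchmark's three genes
#'
#' Coding-sequence lengths (in bases) of the EGFR, KRAS and TP53 references
#' used as defaults by the synthetic corpus generator.
#'
#' @return A named integer vector.
#' @export
reference_gene_lengths <- function() {
  c(EGFR = 3633L, KRAS = 567L, TP53 = 1182L)
}

#' Reference per-member metrics of the benchmark's bagged network ensembles
#'
#' MSE and accuracy of the 12 selected base networks of the bagged ensemble,
#' for HOG and for LBP features. Used as a regression fixture for
#' [member_average()].
#'
#' @param features `"hog"` or `"lbp"`.
#' @return A 12-row tibble with columns `member`, `mse`, `accuracy`.
#' @export
#' @examples
#' member_average(reference_member_metrics("hog"))
reference_member_metrics <- function(features = c("hog", "lbp")) {
  features <- match.arg(features)
  if (features == "hog") {
    tibble::tibble(
      member = 1:12,
      mse = c(0.0170, 0.0118, 0.0232, 0.0107, 0.0088, 0.0193,
              0.0215, 0.0206, 0.0157, 0.0197, 0.0165, 0.0222),
      accuracy = c(95.9, 97.9, 94.8, 97.9, 97.9, 94.8,
                   95.3, 94.8, 95.9, 94.8, 95.9, 94.8)
    )
  } else {
    tibble::tibble(
      member = 1:12,
      mse = c(0.0479, 0.0464, 0.0513, 0.0450, 0.0446, 0.0496,
              0.0462, 0.0522, 0.0449, 0.0501, 0.0491, 0.0476),
      accuracy = c(87.0, 81.3, 81.3, 82.9, 79.8, 80.3,
                   81.3, 80.8, 82.9, 79.8, 83.9, 87.6)
    )
  }
}

#' Reference confusion matrices of the benchmark's single SVM
#'
#' The published 6 x 6 confusion matrices (rows true, columns predicted,
#' canonical class order) of the polynomial-kernel one-against-all SVM on
#' HOG and on LBP features; regression fixtures for [accuracy()].
#'
#' @param features `"hog"` or `"lbp"`.
#' @return A `confusion_matrix`.
#' @export
#' @examples
#' accuracy(reference_confusion("hog"))
reference_confusion <- function(features = c("hog", "lbp")) {
  features <- match.arg(features)
  m <- if (features == "hog") {
    matrix(c(
      7, 0, 0, 0, 0, 0,
      0, 7, 0, 0, 0, 0,
      1, 0, 4, 0, 0, 0,
      1, 0, 0, 4, 0, 0,
      1, 0, 0, 0, 5, 0,
      2, 0, 0, 0, 0, 5
    ), nrow = 6, byrow = TRUE)
  } else {
    matrix(c(
      5, 0, 0, 0, 2, 0,
      0, 7, 0, 0, 0, 0,
      0, 0, 5, 0, 0, 0,
      0, 0, 0, 5, 0, 0,
      0, 0, 0, 0, 6, 0,
      0, 0, 0, 0, 7, 0
    ), nrow = 6, byrow = TRUE)
  }
  as_confusion_matrix(m)
}
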