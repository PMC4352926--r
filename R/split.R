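# Largest-remainder apportionment of n samples into the given fractions.
# Guarantees the counts sum to n; ties go to the earlier fraction.
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Split labelled data into train / validation / test sets
#'
#' Seeded random partition, stratified by `class` so every class appears in
#' every split in proportion. Within each class, counts come from
#' largest-remainder rounding, so the splits are disjoint and exhaustive.
#' When any class has fewer samples than splits, stratification is abandoned
#' with a warning and the whole table is apportioned at once.
#'
#' @param data A tibble with a `class` column.
#' @param fractions Named positive fractions summing to 1
#'   (default `c(train = .70, validation = .15, test = .15)`).
#' @param seed Integer seed for the shuffle.
#' @param stratify Stratify by `class` (default TRUE).
#' @return A named list of tibbles, one per fraction.
#' @export
#' @examples
#' d <- tibble::tibble(class = rep(c("normal", "EGFR_deletion"), each = 50))
#' sapply(split_dataset(d, seed = 1), nrow)
split_dataset <- function(data,
                          fractions = c(train = 0.70, validation = 0.15,
                                        test = 0.15),
                          seed = 1L, stratify = TRUE) {
  if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-8) {
    abort("fractions must be positive and sum to 1")
  }
  n <- nrow(data)
  if (n == 0L) abort("cannot split an empty dataset")
  if (stratify && !"class" %in% names(data)) stratify <- FALSE
  if (stratify) {
    counts <- table(data$class)
    if (any(counts < length(fractions))) {
      warn(paste0(
        "class(es) with fewer samples than splits (",
        paste(names(counts)[counts < length(fractions)], collapse = ", "),
        "); falling back to unstratified splitting"
      ))
      stratify <- FALSE
    }
  }
  group <- character(n)
  withr_seed(seed, {
    if (stratify) {
      for (cls in unique(data$class)) {
        idx <- sample(which(data$class == cls))
        sizes <- apportion(length(idx), fractions)
        group[idx] <- rep(names(fractions), times = sizes)
      }
    } else {
      idx <- sample.int(n)
      sizes <- apportion(n, fractions)
      group[idx] <- rep(names(fractions), times = sizes)
    }
  })
  out <- lapply(setNames(names(fractions), names(fractions)),
                function(g) data[group == g, , drop = FALSE])
  attr(out, "assignment") <- group
  out
}

#' Bootstrap resample of a data table
#'
#' Draws `nrow(data)` rows with replacement (seeded). The out-of-bag rows —
#' those never drawn — are attached as attribute `"oob"` for ensemble member
#' selection.
#'
#' @param data A tibble.
#' @param seed Integer seed.
#' @return A tibble of the same size as `data`, with attribute `oob` holding
#'   the unsampled rows.
#' @export
bootstrap_resample <- function(data, seed = 1L) {
  n <- nrow(data)
  if (n == 0L) abort("cannot bootstrap an empty dataset")
  idx <- withr_seed(seed, sample.int(n, n, replace = TRUE))
  out <- data[idx, , drop = FALSE]
  attr(out, "oob") <- data[setdiff(seq_len(n), unique(idx)), , drop = FALSE]
  out
}

# Evaluate expr under a temporary RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
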