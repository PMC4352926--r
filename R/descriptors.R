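#' HOG descriptor configuration
#'
#' Geometry and normalisation settings for the histogram-of-oriented-
#' gradients descriptor on 4 x N indicator images. Defaults give the
#' 9 bins x 9 blocks = 81-dimensional descriptor: unsigned orientations over
#' [0, 180) degrees in 20-degree bins, nine half-overlapping block windows
#' along the sequence axis, and L2 block normalisation.
#'
#' @param n_bins Number of orientation channels (default 9).
#' @param angular_range Degrees spanned by the orientation axis: 180
#'   (unsigned) or 360 (signed).
#' @param n_blocks Number of block windows along the width (default 9).
#' @param block_overlap Fraction of a block shared with its neighbour
#'   (default 1/2).
#' @param norm Block normalisation scheme: `"L2"`, `"L1"` or `"L1-sqrt"`.
#' @param epsilon Small positive constant added in the normalisation factor.
#' @return A `hog_config` list.
#' @export
hog_config <- function(n_bins = 9L, angular_range = 180, n_blocks = 9L,
                       block_overlap = 0.5, norm = c("L2", "L1", "L1-sqrt"),
                       epsilon = 1e-5) {
  norm <- match.arg(norm)
  if (n_bins < 1L) abort("n_bins must be >= 1")
  if (!angular_range %in% c(180, 360)) {
    abort("angular_range must be 180 (unsigned) or 360 (signed)")
  }
  if (block_overlap < 0 || block_overlap >= 1) {
    abort("block_overlap must be in [0, 1)")
  }
  if (epsilon <= 0) abort("epsilon must be > 0")
  structure(
    list(n_bins = as.integer(n_bins), angular_range = angular_range,
         n_blocks = as.integer(n_blocks), block_overlap = block_overlap,
         norm = norm, epsilon = epsilon),
    class = "hog_config"
  )
}

#' Image gradients with 1-D centred derivative masks
#'
#' Correlates the image with the centred masks `[-1, 0, 1]` horizontally and
#' vertically using replicate-edge padding, so the derivative images keep the
#' input shape. Magnitude is the Euclidean norm of the two derivatives;
#' orientation is the two-argument arctangent in degrees folded into
#' [0, `angular_range`), with zero-gradient pixels assigned orientation 0
#' (they carry zero magnitude, so they cast no vote).
#'
#' @param image A numeric matrix (rows x columns).
#' @param angular_range 180 for unsigned orientations (default) or 360.
#' @return A list with matrices `ix`, `iy`, `magnitude`, `orientation`.
#' @export
compute_gradients <- function(image, angular_range = 180) {
  if (!is.matrix(image) || ncol(image) < 3L || nrow(image) < 1L) {
    abort("image must be a matrix with >= 1 row and >= 3 columns")
  }
  storage.mode(image) <- "double"
  nr <- nrow(image)
  nc <- ncol(image)
  # replicate-edge padding: neighbour indices clamped to the image
  right <- image[, pmin(seq_len(nc) + 1L, nc), drop = FALSE]
  left <- image[, pmax(seq_len(nc) - 1L, 1L), drop = FALSE]
  below <- image[pmin(seq_len(nr) + 1L, nr), , drop = FALSE]
  above <- image[pmax(seq_len(nr) - 1L, 1L), , drop = FALSE]
  ix <- right - left
  iy <- below - above
  g <- sqrt(ix^2 + iy^2)
  theta <- atan2(iy, ix) * 180 / pi          # (-180, 180]
  if (angular_range == 180) {
    theta <- theta %% 180                    # fold opposite directions
  } else {
    theta <- theta %% 360
  }
  theta[theta >= angular_range] <- 0         # exact wrap to bin 0
  theta[g == 0] <- 0
  list(ix = ix, iy = iy, magnitude = g, orientation = theta)
}

#' Magnitude-weighted orientation histogram of a pixel window
#'
#' Each pixel in the window casts its full gradient magnitude into the single
#' bin containing its orientation (hard assignment, half-open bins
#' `[lo, hi)`), so the histogram mass equals the sum of magnitudes over the
#' window.
#'
#' @param field A gradient field from [compute_gradients()].
#' @param rows,cols Integer index vectors selecting the window (defaults:
#'   all rows / all columns).
#' @param cfg A [hog_config()].
#' @return A numeric vector of length `cfg$n_bins`.
#' @export
orientation_binning <- function(field, rows = NULL, cols = NULL,
                                cfg = hog_config()) {
  if (is.null(rows)) rows <- seq_len(nrow(field$magnitude))
  if (is.null(cols)) cols <- seq_len(ncol(field$magnitude))
  if (length(rows) == 0L || length(cols) == 0L) {
    abort("orientation_binning: empty pixel window")
  }
  g <- field$magnitude[rows, cols, drop = FALSE]
  th <- field$orientation[rows, cols, drop = FALSE]
  bin_width <- cfg$angular_range / cfg$n_bins
  bin <- pmin(floor(th / bin_width), cfg$n_bins - 1L) + 1L
  as.numeric(tapply(as.vector(g), factor(bin, levels = seq_len(cfg$n_bins)),
                    sum, default = 0))
}

#' Normalise a block histogram vector
#'
#' The three supported factors for a raw block vector v are
#' `L2`: v / sqrt(||v||_2^2 + e^2); `L1`: v / (||v||_1 + e);
#' `L1-sqrt`: sqrt(v / (||v||_1 + e)). With e > 0 the L2-normalised vector
#' always has Euclidean norm <= 1.
#'
#' @param v Raw non-negative histogram vector.
#' @param norm `"L2"`, `"L1"` or `"L1-sqrt"`.
#' @param epsilon Stabilising constant e; e = 0 is permitted only for
#'   non-zero `v`.
#' @return The normalised vector.
#' @export
block_normalize <- function(v, norm = c("L2", "L1", "L1-sqrt"),
                            epsilon = 1e-5) {
  norm <- match.arg(norm)
  if (!all(is.finite(v))) abort("block vector must be finite")
  if (epsilon < 0) abort("epsilon must be >= 0")
  if (epsilon == 0 && sum(abs(v)) == 0) {
    abort("epsilon = 0 requires a non-zero vector")
  }
  switch(norm,
    "L2" = v / sqrt(sum(v^2) + epsilon^2),
    "L1" = v / (sum(abs(v)) + epsilon),
    "L1-sqrt" = sqrt(v / (sum(abs(v)) + epsilon))
  )
}

# Column spans of the n_blocks half-overlapping block windows over width n.
# Continuous block width w = n / (1 + (B-1)(1-o)); block j spans columns
# floor((j-1)(1-o)w)+1 .. floor(((j-1)(1-o)+1)w). With the default B = 9,
# o = 1/2 this is the half-overlapping pairing of ten equal strips and needs
# n >= 10.
block_windows <- function(n, cfg) {
  b <- cfg$n_blocks
  o <- cfg$block_overlap
  w <- n / (1 + (b - 1) * (1 - o))
  lapply(seq_len(b), function(j) {
    lo <- floor((j - 1) * (1 - o) * w) + 1
    hi <- floor(((j - 1) * (1 - o) + 1) * w)
    if (hi < lo) return(integer(0))
    seq.int(lo, hi)
  })
}

min_hog_width <- function(cfg) {
  n <- 3L
  repeat {
    if (!any(lengths(block_windows(n, cfg)) == 0L)) return(n)
    n <- n + 1L
  }
}

#' HOG descriptor of a Voss indicator image
#'
#' Computes gradients over the full 4 x N image, lays `n_blocks`
#' half-overlapping block windows along the sequence axis (the full 4-row
#' height acts as a single cell row), accumulates one magnitude-weighted
#' orientation histogram per block and normalises each block independently.
#' The concatenated result has fixed length `n_blocks * n_bins` (81 with
#' defaults) for every sequence length at or above the minimum width, which
#' is what makes variable-length genes comparable.
#'
#' @param m A 4 x N Voss matrix from [voss_encode()] (any numeric image with
#'   >= 1 row is accepted).
#' @param cfg A [hog_config()].
#' @return A numeric vector of length `n_blocks * n_bins`.
#' @export
#' @examples
#' length(hog_descriptor(voss_encode(strrep("ACGT", 10))))
hog_descriptor <- function(m, cfg = hog_config()) {
  if (!is.matrix(m)) abort("m must be a matrix")
  need <- min_hog_width(cfg)
  if (ncol(m) < need) {
    abort(paste0("sequence too short for the block layout: width ", ncol(m),
                 " < minimum ", need))
  }
  field <- compute_gradients(m, angular_range = cfg$angular_range)
  wins <- block_windows(ncol(m), cfg)
  out <- lapply(wins, function(cols) {
    h <- orientation_binning(field, cols = cols, cfg = cfg)
    block_normalize(h, norm = cfg$norm, epsilon = cfg$epsilon)
  })
  unlist(out, use.names = FALSE)
}

#' Basic LBP descriptor of a Voss indicator image
#'
#' Classic 8-neighbour, radius-1 local binary patterns: each interior pixel
#' is coded by thresholding its 8 neighbours against the centre (neighbour >=
#' centre scores 1), reading the bits clockwise from the top-left corner as
#' an 8-bit code. The descriptor is the raw 256-bin histogram of codes over
#' the (rows-2) x (cols-2) interior pixels.
#'
#' @param m A matrix with at least 3 rows and 3 columns.
#' @return A numeric vector of 256 counts (codes 0..255).
#' @export
lbp_descriptor <- function(m) {
  if (!is.matrix(m) || nrow(m) < 3L || ncol(m) < 3L) {
    abort("LBP requires a matrix of at least 3 x 3")
  }
  storage.mode(m) <- "double"
  nr <- nrow(m)
  nc <- ncol(m)
  ri <- 2:(nr - 1L)
  ci <- 2:(nc - 1L)
  centre <- m[ri, ci, drop = FALSE]
  # clockwise from top-left, bit weights 2^0 .. 2^7
  offs <- list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, 1L),
               c(1L, 1L), c(1L, 0L), c(1L, -1L), c(0L, -1L))
  code <- matrix(0, nrow = length(ri), ncol = length(ci))
  for (k in seq_along(offs)) {
    nb <- m[ri + offs[[k]][1], ci + offs[[k]][2], drop = FALSE]
    code <- code + 2^(k - 1) * (nb >= centre)
  }
  as.numeric(tabulate(as.vector(code) + 1L, nbins = 256L))
}

#' Descriptor tables for a sequence tibble
#'
#' Encode every sequence with the Voss mapping and summarise it with the HOG
#' or LBP descriptor, returning one row per record with the descriptor in
#' numeric columns (`hog01..hog81` or `lbp001..lbp256`). Non-sequence columns
#' such as `class` are carried through, so the result feeds directly into the
#' classifiers.
#'
#' @param seqs A tibble with columns `id`, `bases` and optionally `class`.
#' @param cfg A [hog_config()] (HOG only).
#' @return A tibble of descriptors keyed by `id`.
#' @export
#' @examples
#' seqs <- tibble::tibble(id = "s1", bases = strrep("ACGT", 5))
#' dim(hog_features(seqs))
hog_features <- function(seqs, cfg = hog_config()) {
  descriptor_table(seqs, function(b) hog_descriptor(voss_encode(b), cfg),
                   cfg$n_blocks * cfg$n_bins, "hog")
}

#' @rdname hog_features
#' @export
lbp_features <- function(seqs) {
  descriptor_table(seqs, function(b) lbp_descriptor(voss_encode(b)),
                   256L, "lbp")
}

descriptor_table <- function(seqs, fun, len, prefix) {
  stopifnot(all(c("id", "bases") %in% names(seqs)))
  vals <- vapply(seqs$bases, fun, numeric(len), USE.NAMES = FALSE)
  mat <- t(vals)
  colnames(mat) <- sprintf(paste0(prefix, "%0", nchar(as.character(len)), "d"),
                           seq_len(len))
  keep <- seqs[setdiff(names(seqs), "bases")]
  dplyr::bind_cols(keep, tibble::as_tibble(mat))
}

#' Extract the descriptor value matrix from a feature table
#'
#' @param data A tibble from [hog_features()] or [lbp_features()].
#' @return A numeric matrix of the `hog*`/`lbp*` columns, rows named by `id`
#'   when present.
#' @export
feature_matrix <- function(data) {
  cols <- grep("^(hog|lbp)[0-9]+$", names(data), value = TRUE)
  if (length(cols) == 0L) {
    abort("no descriptor columns (hog*/lbp*) found")
  }
  m <- as.matrix(data[cols])
  if ("id" %in% names(data)) rownames(m) <- data$id
  m
}
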