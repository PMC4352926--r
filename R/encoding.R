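#' Read nucleotide sequences from a FASTA file
#'
#' Reads a FASTA file into a tibble of validated A/C/G/T sequences. Bases are
#' upper-cased before validation; any character outside the strict
#' \{A, C, G, T\} alphabet is an error naming the offending record and
#' position, because the Voss indicator mapping is defined only on the four
#' unambiguous bases.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (record identifier, first word of the
#'   header) and `bases` (upper-case sequence string), one row per record in
#'   file order.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "ACGT", ">s2", "TTGA"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort(paste0("malformed FASTA in ", path, ": ", conditionMessage(e)))
    }
  )
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, character(1), 1L)
  bases <- toupper(as.character(set))
  for (i in seq_along(bases)) {
    validate_bases(bases[[i]], ids[[i]])
  }
  tibble::tibble(id = unname(ids), bases = unname(bases))
}

#' Write a sequence table to FASTA
#'
#' @param seqs A tibble with columns `id` and `bases`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(all(c("id", "bases") %in% names(seqs)))
  set <- Biostrings::DNAStringSet(seqs$bases)
  names(set) <- seqs$id
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

validate_bases <- function(bases, id = "<sequence>") {
  if (!is.character(bases) || length(bases) != 1L || !nzchar(bases)) {
    abort(paste0("record '", id, "': sequence must be a non-empty string"))
  }
  bad <- regexpr("[^ACGT]", bases)
  if (bad > 0L) {
    abort(paste0(
      "record '", id, "': invalid base '", substr(bases, bad, bad),
      "' at position ", bad, " (alphabet is A/C/G/T)"
    ))
  }
  invisible(bases)
}

#' Voss indicator-sequence encoding
#'
#' Maps a DNA string onto four binary indicator rows (order A, C, G, T): row
#' r has a 1 at position k exactly when base k equals the row's nucleotide.
#' Stacked, the rows form a 4 x N binary image in which every column sums
#' to 1.
#'
#' @param bases A single A/C/G/T string (upper case).
#' @return An integer 4 x N matrix with rownames `c("A","C","G","T")`.
#' @export
#' @examples
#' voss_encode("ATGCGACCCT")
voss_encode <- function(bases) {
  validate_bases(bases)
  chars <- strsplit(bases, "", fixed = TRUE)[[1]]
  n <- length(chars)
  m <- matrix(0L, nrow = 4L, ncol = n,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  m[cbind(match(chars, rownames(m)), seq_len(n))] <- 1L
  m
}

#' Decode a Voss indicator matrix back to a DNA string
#'
#' Inverse of [voss_encode()]: requires every column of the 4 x N matrix to
#' contain exactly one 1 and errors with the first offending position
#' otherwise.
#'
#' @param m A 4 x N binary matrix with row order A, C, G, T.
#' @return The decoded sequence string.
#' @export
voss_decode <- function(m) {
  if (!is.matrix(m) || nrow(m) != 4L) {
    abort("Voss matrix must have exactly 4 rows (A, C, G, T)")
  }
  if (!all(m %in% c(0L, 1L))) {
    abort("Voss matrix entries must be 0 or 1")
  }
  sums <- colSums(m)
  bad <- which(sums != 1L)
  if (length(bad) > 0L) {
    abort(paste0(
      "invalid Voss matrix: column ", bad[[1]], " sums to ", sums[bad[[1]]],
      " (every column must sum to exactly 1)"
    ))
  }
  paste(c("A", "C", "G", "T")[max.col(t(m))], collapse = "")
}

#' Describe a single substitution or deletion event
#'
#' Positions are 0-based offsets into the reference, matching matrix column
#' indexing minus one. A substitution replaces one base (the replacement must
#' differ from the reference base); a deletion removes a contiguous run of
#' `del_length` bases starting at `position`.
#'
#' @param kind `"substitution"` or `"deletion"`.
#' @param position 0-based offset into the reference.
#' @param alt_base Replacement base (substitution only).
#' @param del_length Number of bases removed (deletion only, >= 1).
#' @return A `mutation_spec` list.
#' @export
mutation_spec <- function(kind, position, alt_base = NULL, del_length = NULL) {
  kind <- match.arg(kind, c("substitution", "deletion"))
  if (!is.numeric(position) || length(position) != 1L || position < 0 ||
      position != floor(position)) {
    abort("mutation position must be a single non-negative integer (0-based)")
  }
  if (kind == "substitution") {
    if (is.null(alt_base) || !alt_base %in% c("A", "C", "G", "T")) {
      abort("substitution requires alt_base in {A, C, G, T}")
    }
    del_length <- NULL
  } else {
    if (is.null(del_length) || del_length < 1 ||
        del_length != floor(del_length)) {
      abort("deletion requires del_length >= 1")
    }
    alt_base <- NULL
  }
  structure(
    list(kind = kind, position = as.integer(position),
         alt_base = alt_base,
         del_length = if (!is.null(del_length)) as.integer(del_length)),
    class = "mutation_spec"
  )
}

#' Apply a mutation event to a reference sequence
#'
#' Pure function: the reference string is never modified. A substitution
#' yields a same-length sequence differing at exactly one position; a
#' deletion yields a sequence shorter by `del_length` with the specified run
#' removed.
#'
#' @param bases Reference A/C/G/T string.
#' @param spec A [mutation_spec()].
#' @return The mutated sequence string.
#' @export
#' @examples
#' apply_mutation("ACGT", mutation_spec("substitution", 1, alt_base = "T"))
#' apply_mutation("ACGT", mutation_spec("deletion", 1, del_length = 2))
apply_mutation <- function(bases, spec) {
  validate_bases(bases)
  if (!inherits(spec, "mutation_spec")) {
    abort("spec must be created with mutation_spec()")
  }
  n <- nchar(bases)
  pos1 <- spec$position + 1L  # 1-based
  if (spec$kind == "substitution") {
    if (pos1 > n) {
      abort(paste0("substitution position ", spec$position,
                   " out of range for reference of length ", n))
    }
    ref_base <- substr(bases, pos1, pos1)
    if (ref_base == spec$alt_base) {
      abort(paste0("alt_base '", spec$alt_base,
                   "' equals the reference base at position ", spec$position))
    }
    paste0(substr(bases, 1L, pos1 - 1L), spec$alt_base,
           substr(bases, pos1 + 1L, n))
  } else {
    if (pos1 + spec$del_length - 1L > n) {
      abort(paste0("deletion of length ", spec$del_length, " at position ",
                   spec$position, " exceeds reference of length ", n))
    }
    paste0(substr(bases, 1L, pos1 - 1L),
           substr(bases, pos1 + spec$del_length, n))
  }
}

#' The six-class label scheme and its target encodings
#'
#' Returns the fixed class table: class name, 1-based class index (the SVM
#' target), and the 6-element one-hot network target as a string of bits.
#' The normal class pools unmutated EGFR, KRAS and TP53 sequences under one
#' label.
#'
#' @return A tibble with columns `class`, `class_index`, `target`.
#' @export
#' @examples
#' class_labels()
class_labels <- function() {
  tibble::tibble(
    class = CLASS_LEVELS,
    class_index = seq_along(CLASS_LEVELS),
    target = vapply(seq_along(CLASS_LEVELS), function(i) {
      paste(as.integer(seq_along(CLASS_LEVELS) == i), collapse = "")
    }, character(1))
  )
}

#' One-hot target matrix for a vector of class labels
#'
#' @param labels Character vector or factor of class names.
#' @return An n x 6 0/1 matrix, columns in canonical class order.
#' @export
encode_targets <- function(labels) {
  idx <- class_index(labels)
  t6 <- diag(6L)
  out <- t6[idx, , drop = FALSE]
  colnames(out) <- CLASS_LEVELS
  out
}

#' Decode network outputs to class labels by argmax
#'
#' Ties resolve to the lowest class index, the tie-break used throughout the
#' package.
#'
#' @param outputs An n x 6 numeric matrix of network outputs.
#' @return A factor of class names with the canonical six levels.
#' @export
decode_outputs <- function(outputs) {
  stopifnot(is.matrix(outputs), ncol(outputs) == 6L)
  factor(CLASS_LEVELS[max.col(outputs, ties.method = "first")],
         levels = CLASS_LEVELS)
}

class_index <- function(labels) {
  idx <- match(as.character(labels), CLASS_LEVELS)
  if (anyNA(idx)) {
    abort(paste0("unknown class label(s): ",
                 paste(unique(as.character(labels)[is.na(idx)]),
                       collapse = ", ")))
  }
  idx
}

class_factor <- function(labels) {
  factor(CLASS_LEVELS[class_index(labels)], levels = CLASS_LEVELS)
}
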