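# Well addressing: rows A-H x columns 1-12, zero-padded labels ("A01").
# Zero-padding makes lexicographic order equal plate reading order.

WELL_ROLES <- c("sample", "vector", "mock", "empty")

#' All 96 well labels of a plate in reading order
#'
#' @return Character vector `c("A01", ..., "A12", "B01", ..., "H12")`.
#' @export
well_labels <- function() {
  as.vector(t(outer(LETTERS[1:8], sprintf("%02d", 1:12), paste0)))
}

#' Validate well labels
#'
#' @param x character vector of candidate labels.
#' @return Logical vector, `TRUE` where `x` is a valid label "A01".."H12".
#' @export
is_well_label <- function(x) {
  grepl("^[A-H](0[1-9]|1[0-2])$", x)
}

#' Convert between well labels and (row, column) indices
#'
#' `well_row`/`well_col` extract 1-based indices from labels; `well_label`
#' builds labels from indices.
#'
#' @param x character vector of well labels.
#' @param row,col integer indices, rows 1-8 (A-H), columns 1-12.
#' @return Integer indices, or character labels for `well_label`.
#' @export
well_row <- function(x) match(substr(x, 1L, 1L), LETTERS[1:8])

#' @rdname well_row
#' @export
well_col <- function(x) as.integer(substr(x, 2L, 3L))

#' @rdname well_row
#' @export
well_label <- function(row, col) sprintf("%s%02d", LETTERS[row], col)
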