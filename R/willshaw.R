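#' Binary Willshaw associative memory primitives
#'
#' Synapses are clipped binary weights: a single co-occurrence of pre- and
#' postsynaptic activity sets w_ij from 0 to 1, and further co-activations
#' change nothing. Recall is one synchronous thresholded pass with the
#' classical Willshaw threshold, the number of active cells in the cue. A
#' cell fires when its dendritic sum reaches the threshold (H(x) = 1 for
#' x >= 0), so recall of a stored pattern from its full cue is exact up to
#' crosstalk.
#'
#' @name willshaw
NULL

#' Create a zeroed clipped weight matrix
#'
#' @param rows,cols input and output layer sizes.
#' @return Integer `rows x cols` matrix of zeros.
#' @export
weight_matrix <- function(rows, cols = rows) {
  matrix(0L, nrow = rows, ncol = cols)
}

#' Store a pattern autoassociatively
#'
#' Sets `W[i, j] <- 1` for every pair of co-active cells `i`, `j` of `a`,
#' the diagonal included. Storage is monotone (weights never decrease) and
#' idempotent (re-storing a pattern changes nothing).
#'
#' @param W square clipped weight matrix.
#' @param a binary pattern with `length(a) == nrow(W)`.
#' @return Updated weight matrix.
#' @export
store_auto <- function(W, a) {
  if (nrow(W) != ncol(W) || length(a) != nrow(W))
    stop("autoassociative storage needs a square matrix matching the pattern",
         call. = FALSE)
  idx <- which(a == 1L)
  W[idx, idx] <- 1L
  W
}

#' Store an input/output pair heteroassociatively
#'
#' Sets `W[i, j] <- 1` wherever `x[i] == 1` and `y[j] == 1`.
#'
#' @param W clipped weight matrix, `length(x)` rows by `length(y)` columns.
#' @param x presynaptic (input-layer) binary pattern.
#' @param y postsynaptic (output-layer) binary pattern.
#' @return Updated weight matrix.
#' @export
store_hetero <- function(W, x, y) {
  if (length(x) != nrow(W) || length(y) != ncol(W))
    stop("pattern lengths do not match the weight matrix", call. = FALSE)
  W[which(x == 1L), which(y == 1L)] <- 1L
  W
}

#' Threshold recall from a cue
#'
#' Output cell `j` fires iff its dendritic sum `sum_i W[i, j] * cue[i]`
#' reaches the threshold `theta = sum(cue)`. An all-zero cue returns an
#' all-zero output: the printed rule would otherwise fire every cell at
#' `theta = 0`, and "no input, no recall" is the only behaviour consistent
#' with how recalled activity is used downstream.
#'
#' @param W clipped weight matrix.
#' @param cue binary cue with `length(cue) == nrow(W)`.
#' @return Binary output pattern of length `ncol(W)`.
#' @export
willshaw_recall <- function(W, cue) {
  if (length(cue) != nrow(W))
    stop("cue length does not match the weight matrix", call. = FALSE)
  theta <- sum(cue)
  if (theta == 0L) return(integer(ncol(W)))
  as.integer(as.vector(cue %*% W) >= theta)
}
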