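#' Synthetic binary activity patterns
#'
#' Patterns are plain integer vectors of 0s and 1s. Exteroceptive patterns
#' model entorhinal input: `n` binary cells of which exactly `k` are active
#' (defaults 300 and 8, a sparse coding level at which the Willshaw memory
#' recalls reliably). Interoceptive patterns are length-3 one-hot valence
#' codes. Cell indices are 1-based throughout.
#'
#' @name patterns
NULL

#' Valence labels in their fixed cell order
#'
#' The three labels map, in order, to cells 1-3 of the interoceptive code:
#' positive = (1 0 0), negative = (0 1 0), neutral = (0 0 1).
#' @export
VALENCE_LABELS <- c("positive", "negative", "neutral")

assert_pattern <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) < 1L || anyNA(x) || !all(x == 0L | x == 1L))
    stop(sprintf("'%s' must be a binary (0/1) vector", name), call. = FALSE)
  invisible(x)
}

#' Hamming distance between two equal-length binary patterns
#'
#' Number of positions at which the patterns differ. This is the error
#' metric used everywhere in the model: completion error on exteroceptive
#' patterns and prediction error on valence codes are both Hamming
#' distances between the recalled and the true pattern.
#'
#' @param x,y binary vectors of equal length.
#' @return Non-negative integer count of differing positions.
#' @examples
#' hamming_distance(c(0, 1, 1, 1, 0), c(1, 1, 0, 1, 0)) # 2
#' @export
hamming_distance <- function(x, y) {
  if (length(x) != length(y))
    stop("patterns have incompatible lengths (", length(x), " vs ",
         length(y), ")", call. = FALSE)
  sum(x != y)
}

#' Generate a sparse exteroceptive pattern
#'
#' Draws a binary pattern of `n` cells with exactly `k` active cells chosen
#' uniformly at random without replacement, using the current RNG state.
#'
#' @param n number of cells (default 300).
#' @param k number of active cells (default 8).
#' @return Integer 0/1 vector of length `n` with `sum == k`.
#' @export
random_sparse_pattern <- function(n = 300L, k = 8L) {
  if (k > n || k < 0L) stop("'k' must lie in [0, n]", call. = FALSE)
  p <- integer(n)
  if (k > 0L) p[sample.int(n, k)] <- 1L
  p
}

#' One-hot interoceptive valence code for a label
#'
#' @param label one of `"positive"`, `"negative"`, `"neutral"`.
#' @return Length-3 integer one-hot vector.
#' @export
valence_pattern <- function(label) {
  i <- match(label, VALENCE_LABELS)
  if (is.na(i)) stop("unknown valence label: ", label, call. = FALSE)
  v <- integer(3L)
  v[i] <- 1L
  v
}

#' Silence active cells of a cue
#'
#' Returns a copy of `p` with `d` uniformly chosen active cells set to 0,
#' modelling partial retrieval cues in which part of the original stimulus
#' is unavailable.
#'
#' @param p binary pattern.
#' @param d number of active cells to silence; must not exceed `sum(p)`.
#' @return Degraded pattern with `sum(p) - d` active cells.
#' @export
degrade_cue <- function(p, d) {
  act <- which(p == 1L)
  if (d < 0L || d > length(act))
    stop("'d' must lie in [0, number of active cells]", call. = FALSE)
  if (d > 0L) p[act[sample.int(length(act), d)]] <- 0L
  p
}

#' Construct an exteroceptive/interoceptive stimulus pair
#'
#' @param extero binary exteroceptive pattern.
#' @param valence_label valence label, see [VALENCE_LABELS].
#' @return A `stimulus_pair`: list with `extero`, `valence_label`, `intero`.
#' @export
stimulus_pair <- function(extero, valence_label) {
  assert_pattern(extero)
  structure(list(extero = as.integer(extero),
                 valence_label = valence_label,
                 intero = valence_pattern(valence_label)),
            class = "stimulus_pair")
}

#' Generate a random stimulus set
#'
#' `N` independent exteroceptive patterns, each assigned a valence label
#' drawn uniformly from the three labels.
#'
#' @param N number of stimulus pairs.
#' @param n,k exteroceptive pattern size and density.
#' @return List of `N` [stimulus_pair] objects.
#' @export
stimulus_set <- function(N, n = 300L, k = 8L) {
  if (N < 1L) stop("'N' must be >= 1", call. = FALSE)
  labels <- sample(VALENCE_LABELS, N, replace = TRUE)
  lapply(seq_len(N), function(i)
    stimulus_pair(random_sparse_pattern(n, k), labels[i]))
}

#' Generate the cue/context reversal-learning task
#'
#' Builds the 12-pattern discrimination/reversal design: 8 cues (one cell
#' each) and 8 contexts (seven cells each) occupy 64 pairwise-disjoint
#' cells; every pattern is one cue cell plus one full context block, 8
#' active cells in total. Group 1 is the original discrimination set
#' (A1+, B2+, C3-, D4-); group 2 reverses the cue (new cues E-H in the old
#' contexts 1-4, opposite valence); group 3 reverses the context (old cues
#' A-D in new contexts 5-8, opposite valence).
#'
#' @param n total number of exteroceptive cells; must be at least 64.
#' @return A `reversal_task`: list with `group1`, `group2`, `group3` (each
#'   4 [stimulus_pair]s named e.g. "A1"), `cue_cells` (named length-8
#'   vector), `context_cells` (list of 8 length-7 index vectors).
#' @export
reversal_task <- function(n = 300L) {
  if (n < 64L) stop("'n' must be >= 64 to allocate disjoint cue/context cells",
                    call. = FALSE)
  cells <- sample.int(n, 64L)
  cue_cells <- cells[1:8]
  names(cue_cells) <- LETTERS[1:8]
  context_cells <- split(cells[9:64], rep(1:8, each = 7L))

  make <- function(cue, ctx, label) {
    p <- integer(n)
    p[c(cue_cells[[cue]], context_cells[[ctx]])] <- 1L
    sp <- stimulus_pair(p, label)
    sp$cue <- cue
    sp$context <- ctx
    sp
  }
  pos <- "positive"; neg <- "negative"
  g1 <- list(A1 = make("A", 1L, pos), B2 = make("B", 2L, pos),
             C3 = make("C", 3L, neg), D4 = make("D", 4L, neg))
  g2 <- list(E1 = make("E", 1L, neg), F2 = make("F", 2L, neg),
             G3 = make("G", 3L, pos), H4 = make("H", 4L, pos))
  g3 <- list(A5 = make("A", 5L, neg), B6 = make("B", 6L, neg),
             C7 = make("C", 7L, pos), D8 = make("D", 8L, pos))
  structure(list(group1 = g1, group2 = g2, group3 = g3,
                 cue_cells = cue_cells, context_cells = context_cells),
            class = "reversal_task")
}
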