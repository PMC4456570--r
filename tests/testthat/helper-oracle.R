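# Brute-force Willshaw oracle: builds clipped weights and dendritic sums
# with explicit loops, independent of the package's matrix-based recall
# path. Used to cross-check recall on small instances.

oracle_weights_auto <- function(patterns, n) {
  w <- matrix(0L, n, n)
  for (p in patterns)
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (p[i] == 1L && p[j] == 1L) w[i, j] <- 1L
  w
}

oracle_weights_hetero <- function(pairs, n, m) {
  w <- matrix(0L, n, m)
  for (pr in pairs)
    for (i in seq_len(n))
      for (j in seq_len(m))
        if (pr$x[i] == 1L && pr$y[j] == 1L) w[i, j] <- 1L
  w
}

oracle_recall <- function(w, cue) {
  theta <- 0L
  for (i in seq_along(cue)) theta <- theta + cue[i]
  out <- integer(ncol(w))
  if (theta == 0L) return(out)
  for (j in seq_len(ncol(w))) {
    s <- 0L
    for (i in seq_along(cue)) s <- s + w[i, j] * cue[i]
    if (s - theta >= 0L) out[j] <- 1L
  }
  out
}

# random sparse pattern without using the package generator
oracle_pattern <- function(n, k) {
  p <- integer(n)
  p[sample.int(n, k)] <- 1L
  p
}
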