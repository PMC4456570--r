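#' Plain-text pattern and snapshot formats
#'
#' Fixtures and checkpoints use text-only formats: pattern files with one
#' 0/1 string per line, JSON manifests for stimulus sets (valence label
#' plus 1-based active cell indices) and JSON model snapshots (sizes,
#' thresholds and the plastic weight matrices as row strings). The
#' prewired inhibition and projection matrices are reconstructed from the
#' sizes on load, never serialised.
#'
#' @name io
NULL

#' Write binary patterns to a text file, one 0/1 string per line
#'
#' @param patterns list of binary vectors (or a single vector).
#' @param path file path.
#' @export
write_patterns <- function(patterns, path) {
  if (!is.list(patterns)) patterns <- list(patterns)
  writeLines(vapply(patterns, function(p) paste0(p, collapse = ""),
                    character(1)), path)
}

#' Read binary patterns from a text file written by [write_patterns()]
#'
#' @param path file path.
#' @return List of integer 0/1 vectors.
#' @export
read_patterns <- function(path) {
  lapply(readLines(path), function(l) {
    p <- as.integer(strsplit(l, "", fixed = TRUE)[[1]])
    assert_pattern(p, "pattern file line")
    p
  })
}

#' Write a stimulus set as a JSON manifest
#'
#' Stores each pair as its valence label plus the 1-based indices of
#' active exteroceptive cells, together with the pattern length.
#'
#' @param stimuli list of [stimulus_pair]s.
#' @param path file path.
#' @export
write_stimulus_manifest <- function(stimuli, path) {
  n <- length(stimuli[[1]]$extero)
  obj <- list(n = n, stimuli = lapply(stimuli, function(s)
    list(valence = s$valence_label, active = which(s$extero == 1L))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
}

#' Read a stimulus set from a JSON manifest
#'
#' @param path file path.
#' @return List of [stimulus_pair]s.
#' @export
read_stimulus_manifest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- obj$n
  lapply(seq_len(nrow(obj$stimuli)), function(i) {
    p <- integer(n)
    p[unlist(obj$stimuli$active[i])] <- 1L
    stimulus_pair(p, obj$stimuli$valence[i])
  })
}

matrix_to_rows <- function(W) {
  apply(W, 1L, paste0, collapse = "")
}

rows_to_matrix <- function(rows) {
  do.call(rbind, lapply(rows, function(l)
    as.integer(strsplit(l, "", fixed = TRUE)[[1]])))
}

#' Snapshot a model to JSON
#'
#' @param model a [hippo_model] or [standard_model].
#' @param path file path.
#' @export
save_model_state <- function(model, path) {
  obj <- if (inherits(model, "hippo_model")) {
    list(kind = "hippo_model", n = model$n, m = model$m,
         assoc_groups = model$p - 1L, e = model$e, v = model$v,
         W_e = matrix_to_rows(model$W_e), W_i = matrix_to_rows(model$W_i),
         W_ev = matrix_to_rows(model$W_ev))
  } else if (inherits(model, "standard_model")) {
    list(kind = "standard_model", n = model$n, m = model$m,
         e = model$e, v = model$v, W = matrix_to_rows(model$W))
  } else stop("unknown model class", call. = FALSE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
}

#' Restore a model from a JSON snapshot
#'
#' @param path file path written by [save_model_state()].
#' @return The reconstructed model object.
#' @export
load_model_state <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (obj$kind == "hippo_model") {
    model <- hippo_model(obj$n, obj$m, obj$assoc_groups, obj$e, obj$v)
    model$W_e <- rows_to_matrix(obj$W_e)
    model$W_i <- rows_to_matrix(obj$W_i)
    model$W_ev <- rows_to_matrix(obj$W_ev)
  } else {
    model <- standard_model(obj$n, obj$m, obj$e, obj$v)
    model$W <- rows_to_matrix(obj$W)
  }
  model
}
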