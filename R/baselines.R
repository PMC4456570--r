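#' Comparison models
#'
#' Two reference models frame the binding model's behaviour. The standard
#' autoassociative model binds "flat": each stimulus is the concatenation
#' of its exteroceptive and interoceptive patterns, stored in one square
#' Willshaw memory, so pattern completion and valence prediction happen
#' concurrently in a single recall pass. The simple heteroassociative
#' model is the binding model reduced to its primary valence group alone
#' (no associated groups, hence no interference escalation): completion
#' happens first, valence prediction second.
#'
#' @name baselines
NULL

#' Build the flat concatenated autoassociative model
#'
#' @param n exteroceptive cells (default 300).
#' @param m interoceptive cells (default 3).
#' @param e,v novelty / valence-error thresholds on the two pattern
#'   segments (defaults 0), used only to gate storage during trials.
#' @return A `standard_model` object with a single `(n+m) x (n+m)` clipped
#'   weight matrix.
#' @export
standard_model <- function(n = 300L, m = 3L, e = 0L, v = 0L) {
  structure(list(n = as.integer(n), m = as.integer(m),
                 e = as.integer(e), v = as.integer(v),
                 W = weight_matrix(n + m)),
            class = "standard_model")
}

#' @export
print.standard_model <- function(x, ...) {
  cat(sprintf("<standard_model> flat %d-cell autoassociative memory (%d extero + %d intero)\n",
              x$n + x$m, x$n, x$m))
  invisible(x)
}

#' Store an extero-interoceptive pair as one concatenated pattern
#'
#' @param model a [standard_model].
#' @param a_e,a_i the two pattern segments.
#' @return Updated model.
#' @export
standard_store <- function(model, a_e, a_i) {
  model$W <- store_auto(model$W, c(a_e, a_i))
  model
}

#' Concurrent completion and prediction from an exteroceptive cue
#'
#' The cue is the exteroceptive pattern padded with zeros on the
#' interoceptive segment, and the threshold counts only the exteroceptive
#' active cells — the only reading under which full-cue recall of stored
#' pairs is exact. The single recalled pattern is split back into its two
#' segments.
#'
#' @param model a [standard_model].
#' @param cue_e exteroceptive cue of length `model$n`.
#' @return List with `completed` (length `n`) and `predicted` (length `m`).
#' @export
standard_recall <- function(model, cue_e) {
  if (length(cue_e) != model$n)
    stop("cue length does not match the model", call. = FALSE)
  out <- willshaw_recall(model$W, c(cue_e, integer(model$m)))
  list(completed = out[seq_len(model$n)],
       predicted = out[model$n + seq_len(model$m)])
}

#' @export
process_trial.standard_model <- function(model, a_e, a_i, learning = TRUE,
                                         target_e = a_e, ...) {
  rec <- standard_recall(model, a_e)
  completion_hd <- hamming_distance(rec$completed, target_e)
  prediction_hd <- hamming_distance(rec$predicted, a_i)
  extero_novel <- completion_hd > model$e
  valence_error <- prediction_hd > model$v
  learned <- FALSE
  if (learning && (extero_novel || valence_error)) {
    model <- standard_store(model, a_e, a_i)
    learned <- TRUE
  }
  list(model = model,
       record = new_trial_record(completion_hd, prediction_hd, extero_novel,
                                 valence_error, FALSE, learned,
                                 NA_integer_, FALSE))
}

#' Build the simple heteroassociative model
#'
#' The binding model without associated valence groups (`p = 1`): its
#' trial-by-trial behaviour is by construction that of [hippo_model] with
#' `assoc_groups = 0`. Interference can be detected at the primary group
#' but there is no group to escalate to, so conflicting associations
#' accumulate (clipped weights cannot unlearn).
#'
#' @param n,m,e,v as in [hippo_model].
#' @return A [hippo_model] with a single (primary) valence group.
#' @export
simple_hetero_model <- function(n = 300L, m = 3L, e = 0L, v = 0L) {
  hippo_model(n = n, m = m, assoc_groups = 0L, e = e, v = v)
}

#' Construct a model by kind
#'
#' Convenience dispatcher used by the experiment drivers and the command
#' line: `"proposed"` (full binding model), `"simple_hetero"`, or
#' `"standard_auto"`.
#'
#' @param kind model kind string.
#' @param n,m,e,v shared size and threshold parameters.
#' @param assoc_groups associated groups for the proposed model.
#' @return A model object supporting [process_trial()].
#' @export
build_model <- function(kind = c("proposed", "simple_hetero", "standard_auto"),
                        n = 300L, m = 3L, assoc_groups = 4L, e = 0L, v = 0L) {
  switch(match.arg(kind),
         proposed = hippo_model(n, m, assoc_groups, e, v),
         simple_hetero = simple_hetero_model(n, m, e, v),
         standard_auto = standard_model(n, m, e, v))
}
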