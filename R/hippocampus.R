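#' The extero-interoceptive binding model
#'
#' Two Willshaw autoassociative memories — an exteroceptive network of `n`
#' cells and an interoceptive network of `m` valence cells — are linked
#' through plastic heteroassociative synapses onto a layer of intermediate
#' valence cells. That layer holds `p` ordered groups of `m` cells: one
#' primary group plus `assoc_groups` associated groups. Later groups carry
#' prewired inhibitory connections onto all earlier groups, so at most one
#' group can be active at a time, and each valence cell projects (prewired,
#' one-to-one by valence identity) into the interoceptive network.
#'
#' A trial has three phases. (1) Recall: an exteroceptive cue is completed
#' through the recurrent weights, drives the intermediate valence cells
#' through the plastic heteroassociative weights, and the surviving group
#' triggers recall of a predicted valence. (2) Matching: the completed
#' pattern is compared to the actual input (novelty, threshold `e`) and
#' the predicted valence to the actual valence (prediction error,
#' threshold `v`); a group that is active but mismatches the actual
#' valence raises an interference signal that gates the next group.
#' (3) Learning: if either mismatch exceeds its threshold the model stores
#' the trial with clipped Hebbian updates — autoassociatively in both
#' memories, and heteroassociatively from the exteroceptive pattern onto
#' the highest-indexed gated group, which is the primary group unless
#' interference escalated the write.
#'
#' Groups are numbered from 1 (primary); associated groups are 2..p.
#'
#' @name hippocampus
NULL

valence_group_of <- function(i, m) ((i - 1L) %/% m) + 1L
valence_position_of <- function(i, m) ((i - 1L) %% m) + 1L

#' Prewired inhibition among intermediate valence cells
#'
#' `I[i, j] = 1` iff cell `i` belongs to a later group than cell `j`:
#' every associated group shunts all groups that precede it, and there is
#' no inhibition within a group.
#'
#' @param p number of groups.
#' @param m cells per group.
#' @return Binary `(p*m) x (p*m)` matrix.
#' @export
inhibition_matrix <- function(p, m) {
  g <- valence_group_of(seq_len(p * m), m)
  1L * outer(g, g, ">")
}

#' Prewired projection from valence cells to the interoceptive network
#'
#' `P[i, k] = 1` iff valence cell `i` and interoceptive cell `k` code the
#' same valence, i.e. `i`'s within-group position is `k`. Each valence
#' cell has exactly one outgoing projection.
#'
#' @param p number of groups.
#' @param m cells per group (= interoceptive cells).
#' @return Binary `(p*m) x m` matrix.
#' @export
projection_matrix <- function(p, m) {
  pos <- valence_position_of(seq_len(p * m), m)
  1L * outer(pos, seq_len(m), "==")
}

#' Build the binding model
#'
#' All plastic weight matrices start at zero; the inhibition and
#' projection wiring is fixed and non-plastic.
#'
#' @param n exteroceptive cells (default 300).
#' @param m interoceptive / valence cells (default 3).
#' @param assoc_groups associated valence-cell groups beyond the primary
#'   group (default 4, i.e. `p = 5` groups in total).
#' @param e exteroceptive novelty threshold: the input counts as novel
#'   when the completion Hamming distance exceeds `e` (default 0).
#' @param v valence mismatch threshold: a prediction counts as erroneous,
#'   and an active group as interfering, when the Hamming distance to the
#'   actual valence exceeds `v` (default 0).
#' @return A `hippo_model` object.
#' @export
hippo_model <- function(n = 300L, m = 3L, assoc_groups = 4L, e = 0L, v = 0L) {
  stopifnot(n >= 1L, m >= 1L, assoc_groups >= 0L, e >= 0L, v >= 0L)
  p <- assoc_groups + 1L
  structure(list(
    n = as.integer(n), m = as.integer(m), p = p,
    e = as.integer(e), v = as.integer(v),
    W_e  = weight_matrix(n),
    W_i  = weight_matrix(m),
    W_ev = weight_matrix(n, p * m),
    inhibition = inhibition_matrix(p, m),
    projection = projection_matrix(p, m)
  ), class = "hippo_model")
}

#' @export
print.hippo_model <- function(x, ...) {
  cat(sprintf(
    "<hippo_model> %d exteroceptive cells, %d valence cells, %d group(s) (1 primary + %d associated)\n",
    x$n, x$m, x$p, x$p - 1L))
  cat(sprintf("  stored synapses: W_e %d, W_i %d, W_ev %d; thresholds e=%d v=%d\n",
              sum(x$W_e), sum(x$W_i), sum(x$W_ev), x$e, x$v))
  invisible(x)
}

#' Complete an exteroceptive cue through the recurrent network
#'
#' @param model a [hippo_model].
#' @param a_e binary cue of length `model$n`.
#' @return Completed binary pattern of length `n`.
#' @export
recall_extero <- function(model, a_e) {
  willshaw_recall(model$W_e, a_e)
}

#' Drive the intermediate valence cells and resolve inhibition
#'
#' Excitation: valence cell `l` is excited iff its dendritic sum over the
#' heteroassociative weights reaches the cue threshold (the number of
#' active cells in `completed`). Inhibition: because every excited cell in
#' a later group shunts all earlier groups, only the highest-indexed group
#' containing any excited cell keeps its activity; this closed form is the
#' fixed point the prewired inhibition settles to.
#'
#' @param model a [hippo_model].
#' @param completed completed exteroceptive pattern (length `n`).
#' @return List with `excitation` and post-inhibition `activity`, both
#'   binary vectors of length `p*m`.
#' @export
activate_valence <- function(model, completed) {
  exc <- willshaw_recall(model$W_ev, completed)
  act <- integer(length(exc))
  on <- which(exc == 1L)
  if (length(on)) {
    winner <- max(valence_group_of(on, model$m))
    slice <- ((winner - 1L) * model$m + 1L):(winner * model$m)
    act[slice] <- exc[slice]
  }
  list(excitation = exc, activity = act)
}

#' Predict the valence from intermediate valence-cell activity
#'
#' The surviving valence cells project one-to-one (by valence identity)
#' into the interoceptive network: interoceptive cell `k` receives input
#' iff any valence cell in position `k` is active. The projected input
#' then triggers recall through the interoceptive recurrent weights.
#'
#' @param model a [hippo_model].
#' @param activity post-inhibition valence activity (length `p*m`).
#' @return List with `intero_input` (projected input) and `predicted`
#'   (recalled valence), both binary vectors of length `m`.
#' @export
predict_intero <- function(model, activity) {
  intero_input <- as.integer(as.vector(activity %*% model$projection) > 0L)
  list(intero_input = intero_input,
       predicted = willshaw_recall(model$W_i, intero_input))
}

#' Detect valence-overload interference and gate the next group
#'
#' Group `k` raises the interference signal `xi[k]` when it has at least
#' one active cell (post-inhibition) whose pattern mismatches the actual
#' valence by more than `v`. Gating: the primary group is always enabled
#' (`gate[1] = 1`); associated group `k` is enabled for this trial's
#' learning exactly when the preceding group flagged interference. Since
#' inhibition leaves at most one group active, at most one `xi` can be
#' set per trial, so escalation proceeds one group per trial.
#'
#' @param model a [hippo_model].
#' @param activity post-inhibition valence activity (length `p*m`).
#' @param a_i actual interoceptive valence pattern (length `m`).
#' @return List with binary vectors `xi` and `gate`, both of length `p`.
#' @export
detect_interference <- function(model, activity, a_i) {
  p <- model$p; m <- model$m
  xi <- integer(p)
  for (k in seq_len(p)) {
    g <- activity[((k - 1L) * m + 1L):(k * m)]
    if (sum(g) > 0L && hamming_distance(g, a_i) > model$v) xi[k] <- 1L
  }
  gate <- integer(p)
  gate[1L] <- 1L
  if (p > 1L) gate[2:p] <- xi[1:(p - 1L)]
  list(xi = xi, gate = gate)
}

#' Store a trial's patterns (learning mode)
#'
#' In learning mode intrinsic transmission is suppressed and activity is
#' driven purely by the afferent patterns: both autoassociative memories
#' store their inputs, and the heteroassociative weights store the
#' exteroceptive pattern against the actual valence placed on the
#' highest-indexed gated group (the primary group when no interference
#' was flagged). If interference was flagged at the last group there is
#' no further group to recruit: the heteroassociative update is skipped
#' and the trial marked capacity-exhausted (the autoassociative stores
#' still proceed).
#'
#' @param model a [hippo_model].
#' @param a_e,a_i the afferent exteroceptive and interoceptive patterns.
#' @param gating gating state from [detect_interference()].
#' @return List with the updated `model`, `group_used` (integer group
#'   index, or `NA` when exhausted) and logical `capacity_exhausted`.
#' @export
learn_trial <- function(model, a_e, a_i, gating) {
  model$W_e <- store_auto(model$W_e, a_e)
  model$W_i <- store_auto(model$W_i, a_i)
  if (gating$xi[model$p] == 1L)
    return(list(model = model, group_used = NA_integer_,
                capacity_exhausted = TRUE))
  target <- max(which(gating$gate == 1L))
  h <- integer(model$p * model$m)
  h[((target - 1L) * model$m + 1L):(target * model$m)] <- a_i
  model$W_ev <- store_hetero(model$W_ev, a_e, h)
  list(model = model, group_used = target, capacity_exhausted = FALSE)
}

new_trial_record <- function(completion_hd, prediction_hd, extero_novel,
                             valence_error, interference_detected, learned,
                             group_used, capacity_exhausted) {
  list(completion_hd = completion_hd, prediction_hd = prediction_hd,
       extero_novel = extero_novel, valence_error = valence_error,
       interference_detected = interference_detected, learned = learned,
       group_used = group_used, capacity_exhausted = capacity_exhausted)
}

#' Run one trial of a model
#'
#' Generic over model kinds; see [hippocampus] for the three-phase trial
#' structure. With `learning = FALSE` (a test trial) the model is
#' returned untouched.
#'
#' @param model a model object ([hippo_model] or [standard_model]).
#' @param a_e exteroceptive cue pattern.
#' @param a_i actual interoceptive valence pattern.
#' @param learning whether storage may occur on mismatch.
#' @param ... passed to methods; both methods accept `target_e`, the
#'   pattern against which completion error is measured (defaults to the
#'   cue itself; set to the originally stored pattern when testing with
#'   degraded cues).
#' @return List with the (possibly updated) `model` and a `record` list
#'   holding `completion_hd`, `prediction_hd`, `extero_novel`,
#'   `valence_error`, `interference_detected`, `learned`, `group_used`
#'   and `capacity_exhausted`.
#' @export
process_trial <- function(model, a_e, a_i, learning = TRUE, ...) {
  UseMethod("process_trial")
}

#' @export
process_trial.hippo_model <- function(model, a_e, a_i, learning = TRUE,
                                      target_e = a_e, ...) {
  completed <- recall_extero(model, a_e)
  val <- activate_valence(model, completed)
  pred <- predict_intero(model, val$activity)

  completion_hd <- hamming_distance(completed, target_e)
  prediction_hd <- hamming_distance(pred$predicted, a_i)
  extero_novel <- completion_hd > model$e
  valence_error <- prediction_hd > model$v
  gating <- detect_interference(model, val$activity, a_i)

  learned <- FALSE
  group_used <- NA_integer_
  capacity_exhausted <- FALSE
  if (learning && (extero_novel || valence_error)) {
    upd <- learn_trial(model, a_e, a_i, gating)
    model <- upd$model
    learned <- TRUE
    group_used <- upd$group_used
    capacity_exhausted <- upd$capacity_exhausted
  }
  list(model = model,
       record = new_trial_record(completion_hd, prediction_hd, extero_novel,
                                 valence_error, any(gating$xi == 1L), learned,
                                 group_used, capacity_exhausted))
}

#' Count associated groups holding any stored association
#'
#' Structural measure of how many associated (non-primary) groups were
#' recruited: the number of associated groups owning at least one nonzero
#' heteroassociative column. Independent of any transient activity.
#'
#' @param model a [hippo_model].
#' @return Integer count in `0..(p-1)`.
#' @export
assoc_groups_in_use <- function(model) {
  if (model$p == 1L) return(0L)
  colsum <- colSums(model$W_ev)
  used <- unique(valence_group_of(which(colsum > 0L), model$m))
  sum(used > 1L)
}
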