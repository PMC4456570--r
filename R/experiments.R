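#' Block/trial experiment drivers
#'
#' Experiments are organised as blocks of trials: one block is a single
#' pass through a stimulus set, randomly reordered when learning is
#' enabled. Errors are scored per trial from the recall made before any
#' storage: a prediction error is a nonzero Hamming distance between
#' predicted and actual valence, a completion error a nonzero distance
#' between completed and stored exteroceptive pattern. Results are
#' averaged over independent replicate runs and reported with Student-t
#' 95% confidence intervals.
#'
#' All drivers derive one sub-seed per run from the master `seed`, so any
#' single run can be reproduced on its own.
#'
#' @name experiments
NULL

run_seeds <- function(seed, runs) {
  set.seed(seed)
  sample.int(.Machine$integer.max, runs)
}

#' Run one block of trials
#'
#' @param model a model object supporting [process_trial()].
#' @param stimuli list of [stimulus_pair]s.
#' @param learning whether storage may occur (training block) or not
#'   (test block; the model is returned bit-identical).
#' @param shuffle randomise trial order (default: only when learning).
#' @param deletions number of active cue cells to silence per trial
#'   (partial-cue testing); completion error is still measured against
#'   the full stored pattern.
#' @return List with `model`, `records` (one list per trial, in
#'   presentation order) and `stats` from [block_stats()].
#' @export
run_block <- function(model, stimuli, learning = TRUE, shuffle = learning,
                      deletions = 0L) {
  stopifnot(length(stimuli) >= 1L)
  ord <- if (shuffle) sample.int(length(stimuli)) else seq_along(stimuli)
  records <- vector("list", length(ord))
  for (i in seq_along(ord)) {
    s <- stimuli[[ord[i]]]
    cue <- if (deletions > 0L) degrade_cue(s$extero, deletions) else s$extero
    out <- process_trial(model, cue, s$intero, learning = learning,
                         target_e = s$extero)
    model <- out$model
    records[[i]] <- out$record
  }
  list(model = model, records = records, stats = block_stats(records))
}

#' Aggregate trial records of one block
#'
#' @param records list of trial records as returned by [process_trial()].
#' @return List with `n_trials`, `error_pct` (% of trials with prediction
#'   Hamming distance > 0), `completion_error_pct` (% with completion
#'   distance >= 1), `mean_completion_hd`, `interference_count` and
#'   `capacity_exhausted_count`.
#' @export
block_stats <- function(records) {
  pred <- vapply(records, `[[`, numeric(1), "prediction_hd")
  comp <- vapply(records, `[[`, numeric(1), "completion_hd")
  intf <- vapply(records, `[[`, logical(1), "interference_detected")
  capx <- vapply(records, `[[`, logical(1), "capacity_exhausted")
  list(n_trials = length(records),
       error_pct = 100 * mean(pred > 0),
       completion_error_pct = 100 * mean(comp >= 1),
       mean_completion_hd = mean(comp),
       interference_count = sum(intf),
       capacity_exhausted_count = sum(capx))
}

model_groups_in_use <- function(model) {
  if (inherits(model, "hippo_model")) assoc_groups_in_use(model) else NA_integer_
}

#' Capacity experiment: valence prediction vs. number of stored patterns
#'
#' For each run and each set size `N`, a fresh stimulus set (uniform
#' 3-way valences) is generated and every requested model kind is trained
#' on it for `blocks` passes; after each training block a full-cue test
#' block (learning disabled) scores prediction errors. The proposed
#' model's interference detections during each training block and the
#' number of associated groups recruited are recorded alongside.
#'
#' @param kinds model kinds, see [build_model()].
#' @param N vector of stimulus-set sizes.
#' @param blocks training passes per set.
#' @param runs independent replicates.
#' @param seed master seed.
#' @param n,k exteroceptive pattern size and density.
#' @param assoc_groups,e,v model parameters, see [hippo_model()].
#' @return Tidy data.frame: one row per run x kind x N x block with
#'   columns `run`, `seed`, `model`, `N`, `block`, `error_pct`,
#'   `completion_error_pct`, `interference_count`, `groups_in_use`,
#'   `capacity_exhausted_count`.
#' @export
capacity_experiment <- function(kinds = c("proposed", "simple_hetero",
                                          "standard_auto"),
                                N = seq(10L, 100L, 10L), blocks = 1L,
                                runs = 20L, seed = 1L, n = 300L, k = 8L,
                                assoc_groups = 4L, e = 0L, v = 0L) {
  seeds <- run_seeds(seed, runs)
  rows <- list()
  for (r in seq_len(runs)) {
    set.seed(seeds[r])
    for (N_i in N) {
      stimuli <- stimulus_set(N_i, n, k)
      for (kind in kinds) {
        model <- build_model(kind, n = n, m = 3L,
                             assoc_groups = assoc_groups, e = e, v = v)
        for (b in seq_len(blocks)) {
          tr <- run_block(model, stimuli, learning = TRUE)
          model <- tr$model
          te <- run_block(model, stimuli, learning = FALSE)
          rows[[length(rows) + 1L]] <- data.frame(
            run = r, seed = seeds[r], model = kind, N = N_i, block = b,
            error_pct = te$stats$error_pct,
            completion_error_pct = te$stats$completion_error_pct,
            interference_count = tr$stats$interference_count,
            groups_in_use = model_groups_in_use(model),
            capacity_exhausted_count = tr$stats$capacity_exhausted_count)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Partial-cue experiment: recall from degraded exteroceptive cues
#'
#' Models are trained on `N` random stimuli for `blocks` passes; then, for
#' every deletion level `d`, each stored cue is presented with `d` of its
#' active cells silenced and both completion and prediction performance
#' are scored (learning disabled).
#'
#' @param deletions vector of deletion levels (0 = full cue).
#' @inheritParams capacity_experiment
#' @return Tidy data.frame: one row per run x kind x deletion level with
#'   prediction `error_pct`, `completion_error_pct` and
#'   `mean_completion_hd`.
#' @export
partial_cue_experiment <- function(kinds = c("simple_hetero", "standard_auto"),
                                   N = 100L, deletions = 0:7, blocks = 1L,
                                   runs = 20L, seed = 1L, n = 300L, k = 8L,
                                   assoc_groups = 4L, e = 0L, v = 0L) {
  seeds <- run_seeds(seed, runs)
  rows <- list()
  for (r in seq_len(runs)) {
    set.seed(seeds[r])
    stimuli <- stimulus_set(N, n, k)
    for (kind in kinds) {
      model <- build_model(kind, n = n, m = 3L,
                           assoc_groups = assoc_groups, e = e, v = v)
      for (b in seq_len(blocks))
        model <- run_block(model, stimuli, learning = TRUE)$model
      for (d in deletions) {
        te <- run_block(model, stimuli, learning = FALSE, deletions = d)
        rows[[length(rows) + 1L]] <- data.frame(
          run = r, seed = seeds[r], model = kind, N = N, deletions = d,
          error_pct = te$stats$error_pct,
          completion_error_pct = te$stats$completion_error_pct,
          mean_completion_hd = te$stats$mean_completion_hd)
      }
    }
  }
  do.call(rbind, rows)
}

#' Novelty-threshold experiment: tolerance to valence change
#'
#' The binding model is trained on `N` neutral stimuli, after which each
#' stimulus is reassigned a valence drawn uniformly from the three labels
#' (so about two thirds change). The model is retrained for one block
#' under each `(e, v)` threshold pair and then tested. With a permissive
#' valence threshold (`v = 2`) the exteroceptive patterns are recognised
#' (completion distance 0 <= e) and the changed valences are within
#' tolerance, so no relearning occurs and errors persist on the changed
#' stimuli; with `v = 0` every change is detected and relearned.
#'
#' @param threshold_pairs list of `c(e, v)` pairs.
#' @inheritParams capacity_experiment
#' @return Tidy data.frame: one row per run x threshold pair with test
#'   `error_pct` and the retraining-block mismatch components
#'   `retrain_mean_hd_extero` and `retrain_mean_hd_valence`.
#' @export
threshold_experiment <- function(threshold_pairs = list(c(0L, 0L), c(2L, 2L),
                                                        c(2L, 0L)),
                                 N = 10L, runs = 20L, seed = 1L,
                                 n = 300L, k = 8L, assoc_groups = 4L) {
  seeds <- run_seeds(seed, runs)
  rows <- list()
  for (r in seq_len(runs)) {
    set.seed(seeds[r])
    base <- stimulus_set(N, n, k)
    neutral <- lapply(base, function(s) stimulus_pair(s$extero, "neutral"))
    relabel <- sample(VALENCE_LABELS, N, replace = TRUE)
    changed <- lapply(seq_len(N), function(i)
      stimulus_pair(base[[i]]$extero, relabel[i]))
    for (pair in threshold_pairs) {
      model <- hippo_model(n = n, m = 3L, assoc_groups = assoc_groups,
                           e = pair[1], v = pair[2])
      model <- run_block(model, neutral, learning = TRUE)$model
      retrain <- run_block(model, changed, learning = TRUE)
      model <- retrain$model
      rec <- retrain$records
      te <- run_block(model, changed, learning = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        run = r, seed = seeds[r], e = pair[1], v = pair[2], N = N,
        error_pct = te$stats$error_pct,
        retrain_mean_hd_extero =
          mean(vapply(rec, `[[`, numeric(1), "completion_hd")),
        retrain_mean_hd_valence =
          mean(vapply(rec, `[[`, numeric(1), "prediction_hd")))
    }
  }
  do.call(rbind, rows)
}

#' Cue/context reversal-learning experiment
#'
#' Phase 1 (acquisition): four blocks over the four original patterns;
#' prediction errors are scored on each trial's recall before storage, so
#' block 1 reflects first exposure and later blocks retention. Phase 2
#' (retention and reversal): four blocks over all 12 patterns (originals
#' plus cue-reversed and context-reversed sets), with errors additionally
#' split into old (group 1) and new (groups 2-3) patterns, and the
#' proposed model's interference detections and recruited associated
#' groups recorded.
#'
#' @inheritParams capacity_experiment
#' @return Tidy data.frame: one row per run x kind x phase x block with
#'   `error_pct`, `error_pct_old`, `error_pct_new` (NA in phase 1),
#'   `interference_count` and `groups_in_use`.
#' @export
reversal_experiment <- function(kinds = c("proposed", "simple_hetero",
                                          "standard_auto"),
                                runs = 20L, seed = 1L, n = 300L,
                                assoc_groups = 4L, e = 0L, v = 0L) {
  seeds <- run_seeds(seed, runs)
  rows <- list()
  for (r in seq_len(runs)) {
    set.seed(seeds[r])
    task <- reversal_task(n)
    old <- unname(task$group1)
    all12 <- unname(c(task$group1, task$group2, task$group3))
    is_old <- c(rep(TRUE, 4L), rep(FALSE, 8L))
    for (kind in kinds) {
      model <- build_model(kind, n = n, m = 3L,
                           assoc_groups = assoc_groups, e = e, v = v)
      for (b in 1:4) {
        tr <- run_block(model, old, learning = TRUE)
        model <- tr$model
        rows[[length(rows) + 1L]] <- data.frame(
          run = r, seed = seeds[r], model = kind, phase = "acquisition",
          block = b, error_pct = tr$stats$error_pct,
          error_pct_old = NA_real_, error_pct_new = NA_real_,
          interference_count = tr$stats$interference_count,
          groups_in_use = model_groups_in_use(model))
      }
      for (b in 1:4) {
        ord <- sample.int(length(all12))
        recs <- vector("list", length(ord))
        for (i in seq_along(ord)) {
          s <- all12[[ord[i]]]
          out <- process_trial(model, s$extero, s$intero, learning = TRUE)
          model <- out$model
          recs[[i]] <- out$record
        }
        pred <- vapply(recs, `[[`, numeric(1), "prediction_hd")
        oldness <- is_old[ord]
        rows[[length(rows) + 1L]] <- data.frame(
          run = r, seed = seeds[r], model = kind, phase = "reversal",
          block = b, error_pct = 100 * mean(pred > 0),
          error_pct_old = 100 * mean(pred[oldness] > 0),
          error_pct_new = 100 * mean(pred[!oldness] > 0),
          interference_count = sum(vapply(recs, `[[`, logical(1),
                                          "interference_detected")),
          groups_in_use = model_groups_in_use(model))
      }
    }
  }
  do.call(rbind, rows)
}

#' Mean and Student-t 95% confidence interval
#'
#' Symmetric t-interval with `length(x) - 1` degrees of freedom; a single
#' value yields a degenerate interval equal to the point.
#'
#' @param x numeric vector of per-run values.
#' @param conf confidence level (default 0.95).
#' @return data.frame with `mean`, `ci_low`, `ci_high`, `n_runs`.
#' @export
summarize_ci <- function(x, conf = 0.95) {
  if (length(x) < 1L) stop("need at least one value", call. = FALSE)
  m <- mean(x)
  if (length(x) == 1L) return(data.frame(mean = m, ci_low = m, ci_high = m,
                                         n_runs = 1L))
  hw <- stats::qt(1 - (1 - conf) / 2, df = length(x) - 1L) *
    stats::sd(x) / sqrt(length(x))
  data.frame(mean = m, ci_low = m - hw, ci_high = m + hw, n_runs = length(x))
}

#' Summarise an experiment data.frame over runs
#'
#' Groups `df` by the given columns and applies [summarize_ci()] to one
#' value column, giving per-condition means and confidence bounds.
#'
#' @param df tidy per-run data.frame from an experiment driver.
#' @param value name of the value column.
#' @param by character vector of grouping column names.
#' @return data.frame with grouping columns plus `mean`, `ci_low`,
#'   `ci_high`, `n_runs`.
#' @export
summarize_experiment <- function(df, value = "error_pct",
                                 by = intersect(c("model", "N", "block",
                                                  "deletions", "e", "v",
                                                  "phase"), names(df))) {
  idx <- split(seq_len(nrow(df)), df[by], drop = TRUE)
  rows <- lapply(idx, function(i)
    cbind(df[i[1L], by, drop = FALSE], summarize_ci(df[[value]][i])))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[do.call(order, out[by]), , drop = FALSE]
}
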