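test_that("model wiring: shapes, inhibition ordering and projection alignment", {
  m <- hippo_model()
  expect_equal(dim(m$W_e), c(300, 300))
  expect_equal(dim(m$W_i), c(3, 3))
  expect_equal(dim(m$W_ev), c(300, 15))
  expect_true(all(m$W_e == 0L) && all(m$W_i == 0L) && all(m$W_ev == 0L))

  I <- m$inhibition
  g <- rep(1:5, each = 3)
  expect_equal(I, 1L * outer(g, g, ">"))              # later groups inhibit earlier
  expect_true(all(diag(I) == 0L))
  expect_true(all(inhibition_matrix(1, 3) == 0L))     # p = 1: nobody to inhibit

  P <- m$projection
  expect_true(all(rowSums(P) == 1))                   # one projection per cell
  expect_equal(which(P[(3 - 1) * 3 + 2, ] == 1L), 2L) # group 3 position 2 -> cell 2
})

test_that("inhibition resolution keeps only the highest-indexed excited group", {
  m <- hippo_model(n = 10, m = 3, assoc_groups = 2)
  # wire cue cell 1 to a group-1 and a group-2 cell
  m$W_ev <- store_hetero(m$W_ev, c(1L, rep(0L, 9)),
                         c(1L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L))
  res <- activate_valence(m, c(1L, rep(0L, 9)))
  expect_equal(which(res$excitation == 1L), c(1L, 5L))
  expect_equal(which(res$activity == 1L), 5L)         # only group 2 survives
  expect_true(all(res$activity <= res$excitation))

  none <- activate_valence(m, integer(10))
  expect_equal(none$excitation, integer(9))
  expect_equal(none$activity, integer(9))

  m2 <- hippo_model(n = 10, m = 3, assoc_groups = 2)
  m2$W_ev <- store_hetero(m2$W_ev, c(1L, rep(0L, 9)),
                          c(0L, 1L, 0L, rep(0L, 6)))
  only1 <- activate_valence(m2, c(1L, rep(0L, 9)))
  expect_equal(only1$activity, only1$excitation)      # no inhibitor fired
})

test_that("valence activity projects one-to-one and predicts through the interoceptive net", {
  m <- hippo_model(n = 10, m = 3, assoc_groups = 4)
  m$W_i <- store_auto(m$W_i, c(1L, 0L, 0L))
  y <- integer(15); y[(4 - 1) * 3 + 1] <- 1L          # positive cell, group 4
  pr <- predict_intero(m, y)
  expect_equal(pr$intero_input, c(1L, 0L, 0L))
  expect_equal(pr$predicted, c(1L, 0L, 0L))

  m$W_i <- store_auto(m$W_i, c(0L, 1L, 0L))
  y2 <- integer(15); y2[1:2] <- 1L                    # pos AND neg in group 1
  pr2 <- predict_intero(m, y2)
  expect_equal(sum(pr2$intero_input), 2)
  expect_equal(pr2$predicted, integer(3))             # theta=2 beats diagonal sums

  expect_equal(predict_intero(m, integer(15))$predicted, integer(3))
})

test_that("interference is flagged by an active mismatching group and gates its successor", {
  m <- hippo_model(n = 10, m = 3, assoc_groups = 4)
  a_i <- c(1L, 0L, 0L)
  y <- integer(15); y[1:2] <- 1L                      # group 1 active (1 1 0)
  g <- detect_interference(m, y, a_i)
  expect_equal(g$xi, c(1L, 0L, 0L, 0L, 0L))
  expect_equal(g$gate, c(1L, 1L, 0L, 0L, 0L))

  g0 <- detect_interference(m, integer(15), a_i)      # silence: no interference
  expect_equal(g0$xi, integer(5))
  expect_equal(g0$gate, c(1L, 0L, 0L, 0L, 0L))

  ym <- integer(15); ym[1] <- 1L                      # matching activity
  expect_equal(detect_interference(m, ym, a_i)$xi, integer(5))
})

test_that("learning writes the gated group and skips the hetero store when exhausted", {
  m <- hippo_model(n = 6, m = 3, assoc_groups = 1)    # p = 2
  a_e <- c(1L, 1L, 0L, 0L, 0L, 0L); a_i <- c(1L, 0L, 0L)

  up <- learn_trial(m, a_e, a_i, list(xi = c(0L, 0L), gate = c(1L, 0L)))
  expect_equal(up$group_used, 1L)
  expect_equal(which(colSums(up$model$W_ev) > 0), 1L) # primary positive column

  up2 <- learn_trial(m, a_e, a_i, list(xi = c(1L, 0L), gate = c(1L, 1L)))
  expect_equal(up2$group_used, 2L)
  expect_equal(which(colSums(up2$model$W_ev) > 0), 4L) # group-2 positive column

  up3 <- learn_trial(m, a_e, a_i, list(xi = c(0L, 1L), gate = c(1L, 0L)))
  expect_true(up3$capacity_exhausted)                 # interference at last group
  expect_true(all(up3$model$W_ev == 0L))              # hetero store skipped
  expect_equal(sum(up3$model$W_e), 4)                 # auto stores still proceed

  again <- learn_trial(up$model, a_e, a_i, list(xi = c(0L, 0L), gate = c(1L, 0L)))
  expect_identical(again$model$W_ev, up$model$W_ev)   # clipped learning idempotent
})

test_that("the AB+/AC-/BD- conflict is detected and resolved through group 2", {
  feat <- function(i) { p <- integer(16L); p[i] <- 1L; p }
  AB <- feat(c(1:4, 5:8)); AC <- feat(c(1:4, 9:12)); BD <- feat(c(5:8, 13:16))
  m <- hippo_model(n = 16, m = 3, assoc_groups = 4)
  for (s in list(list(AB, "positive"), list(AC, "negative"),
                 list(BD, "negative")))
    m <- process_trial(m, s[[1]], valence_pattern(s[[2]]))$model

  exc <- activate_valence(m, recall_extero(m, AB))$excitation
  expect_equal(which(exc == 1L), c(1L, 2L))           # both primary valences excited

  t1 <- process_trial(m, AB, valence_pattern("positive"))
  expect_true(t1$record$valence_error)
  expect_true(t1$record$interference_detected)
  expect_equal(t1$record$group_used, 2L)
  m <- t1$model

  t2 <- process_trial(m, AB, valence_pattern("positive"), learning = FALSE)
  expect_equal(t2$record$prediction_hd, 0)
  # AC- and BD- remain intact
  for (s in list(list(AC, "negative"), list(BD, "negative"))) {
    tt <- process_trial(m, s[[1]], valence_pattern(s[[2]]), learning = FALSE)
    expect_equal(tt$record$prediction_hd, 0)
  }
})

test_that("a fresh model treats its first trial as novel and acquires it in one shot", {
  set.seed(31)
  m <- hippo_model(n = 40, m = 3, assoc_groups = 4)
  a_e <- random_sparse_pattern(40, 6); a_i <- valence_pattern("negative")
  t1 <- process_trial(m, a_e, a_i)
  expect_true(t1$record$extero_novel)
  expect_true(t1$record$learned)
  expect_equal(t1$record$group_used, 1L)

  t2 <- process_trial(t1$model, a_e, a_i)
  expect_equal(t2$record$completion_hd, 0)
  expect_equal(t2$record$prediction_hd, 0)
  expect_false(t2$record$learned)
  expect_identical(t2$model, t1$model)                # nothing to store
})

test_that("trial invariants hold over random trial sequences", {
  set.seed(32)
  m <- hippo_model(n = 30, m = 3, assoc_groups = 2)
  wsum <- function(mm) sum(mm$W_e) + sum(mm$W_i) + sum(mm$W_ev)
  prev <- wsum(m)
  for (i in 1:60) {
    a_e <- random_sparse_pattern(30, 4)
    a_i <- valence_pattern(sample(VALENCE_LABELS, 1))
    out <- process_trial(m, a_e, a_i)
    rec <- out$record

    # learning happens iff novelty or prediction error
    expect_equal(rec$learned, rec$extero_novel || rec$valence_error)
    # weights only grow
    expect_gte(wsum(out$model), prev)
    # post-inhibition activity never spans two groups
    act <- activate_valence(out$model, recall_extero(out$model, a_e))$activity
    groups <- unique((which(act == 1L) - 1L) %/% 3L)
    expect_lte(length(groups), 1)
    # predictions are one-hot or empty when only one-hot valences are stored
    pred <- predict_intero(out$model,
                           activate_valence(out$model,
                                            recall_extero(out$model, a_e))$activity)
    expect_true(sum(pred$predicted) <= 1)
    # a detected interference either recruits a group or exhausts capacity
    if (rec$interference_detected && rec$learned)
      expect_true(rec$capacity_exhausted || rec$group_used > 1L)
    m <- out$model
    prev <- wsum(m)
  }
})

test_that("the p=1 model reproduces the simple heteroassociative baseline trial by trial", {
  set.seed(33)
  full <- hippo_model(n = 50, m = 3, assoc_groups = 0)
  base <- simple_hetero_model(n = 50, m = 3)
  for (i in 1:40) {
    a_e <- random_sparse_pattern(50, 5)
    a_i <- valence_pattern(sample(VALENCE_LABELS, 1))
    o1 <- process_trial(full, a_e, a_i)
    o2 <- process_trial(base, a_e, a_i)
    expect_identical(o1$record, o2$record)
    full <- o1$model; base <- o2$model
  }
  expect_identical(full$W_ev, base$W_ev)
})

test_that("interference in the reduced model persists: clipped weights cannot unlearn", {
  feat <- function(i) { p <- integer(16L); p[i] <- 1L; p }
  AB <- feat(c(1:4, 5:8)); AC <- feat(c(1:4, 9:12)); BD <- feat(c(5:8, 13:16))
  m <- simple_hetero_model(n = 16, m = 3)
  stim <- list(list(AB, "positive"), list(AC, "negative"), list(BD, "negative"))
  for (pass in 1:3)
    for (s in stim)
      m <- process_trial(m, s[[1]], valence_pattern(s[[2]]))$model
  t_ab <- process_trial(m, AB, valence_pattern("positive"), learning = FALSE)
  expect_gt(t_ab$record$prediction_hd, 0)
})
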