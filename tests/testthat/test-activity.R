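# toy fingerprints used across the scorer tests
toy_model <- function() {
  actives <- rbind(
    c(1, 1, 1, 0, 0, 0, 0, 0),
    c(1, 1, 0, 1, 0, 0, 0, 0),
    c(1, 0, 1, 1, 0, 0, 0, 0))
  # pad to the 10-active floor with near-duplicates
  actives <- rbind(actives, actives, actives, actives[1:3, , drop = FALSE])
  decoys <- matrix(0L, 200, 8)
  decoys[, 7] <- 1L
  decoys[seq(1, 200, by = 2), 8] <- 1L
  fit_activity_model(actives, decoys)
}

test_that("bit weights follow the log frequency-ratio formula with clipping", {
  actives <- matrix(0L, 10, 4); actives[, 1] <- 1L   # bit 1 in all actives
  actives[1:5, 2] <- 1L                              # bit 2 in half
  decoys <- matrix(0L, 200, 4); decoys[1:100, 2] <- 1L  # bit 2 in half
  decoys[, 3] <- 1L                                  # bit 3 decoy-only
  m <- fit_activity_model(actives, decoys)
  expect_equal(m$bit_weights[1], log((1 + 0.01) / 0.01))  # ~4.615, under the clip
  expect_equal(m$bit_weights[2], 0)                       # equal frequency
  expect_equal(m$bit_weights[3], -log((1 + 0.01) / 0.01))
  expect_equal(m$bit_weights[4], 0)
  expect_false(is.unsorted(m$null_scores))
  expect_error(fit_activity_model(actives[1:5, ], decoys), "at least 10")
  expect_error(fit_activity_model(actives, decoys[1:50, ]), "at least 200")
})

test_that("hybrid score equals a brute-force evaluation on a toy model", {
  m <- toy_model()
  queries <- rbind(
    c(1, 1, 1, 0, 0, 0, 0, 0),   # identical to an active
    c(0, 0, 0, 0, 0, 1, 0, 0),   # shares no bits with any active
    c(1, 0, 0, 1, 1, 0, 1, 0))
  got <- score_compound(m, queries)
  # independent brute force: loop over bits and references
  w_pos <- exp(m$bit_weights)
  brute_one <- function(q) {
    wtc <- apply(m$active_fps, 1, function(a) {
      num <- den <- 0
      for (b in seq_along(q)) {
        if (q[b] == 1 && a[b] == 1) num <- num + w_pos[b]
        if (q[b] == 1 || a[b] == 1) den <- den + w_pos[b]
      }
      if (den == 0) 0 else num / den
    })
    top <- sort(wtc, decreasing = TRUE)[1:5]
    0.5 * top[1] + 0.5 * mean(top)
  }
  expect_equal(got, apply(queries, 1, brute_one))
  expect_gte(got[1], 0.5)  # identical query: max term is 1
  expect_equal(got[2], 0)  # disjoint query scores zero
})

test_that("empirical P follows the add-one tail estimator with conservative ties", {
  m <- toy_model()
  m$null_scores <- sort(seq_len(999) / 1000)
  expect_equal(empirical_pvalue(m, 2), 1 / 1000)   # above all nulls
  expect_equal(empirical_pvalue(m, 0), 1)          # at or below all nulls
  med <- m$null_scores[500]
  expect_equal(empirical_pvalue(m, med), (1 + sum(m$null_scores >= med)) / 1000)
  # never zero, never above one
  p <- empirical_pvalue(m, c(-Inf, 0.5, Inf))
  expect_true(all(p > 0 & p <= 1))
})

test_that("higher scores never get larger empirical P", {
  m <- toy_model()
  s <- sort(runif(50))
  p <- empirical_pvalue(m, s)
  expect_true(all(diff(p) <= 0))
  # agreement with the direct count definition on the model's own nulls
  direct <- vapply(s, function(x) (1 + sum(m$null_scores >= x)) /
                     (1 + length(m$null_scores)), numeric(1))
  expect_equal(p, direct)
})

test_that("predict_library calls actives at p < alpha and honours endpoints", {
  cfg <- small_config(seed = 2)
  lib <- generate_library(cfg)
  refs <- generate_reference_sets(cfg)
  model <- fit_activity_model(maccs_fingerprint(refs$actives$smiles),
                              maccs_fingerprint(refs$decoys$smiles))
  fps <- maccs_fingerprint(lib$compounds$smiles, lib$compounds$compound_id)
  calls <- predict_library(model, fps, alpha = 0.05)
  expect_identical(nrow(calls), nrow(lib$compounds))
  expect_identical(calls$is_active, calls$p_value < 0.05)
  # scoring the reference actives themselves recovers far more than 5%
  self <- predict_library(model, maccs_fingerprint(refs$actives$smiles,
                                                   refs$actives$compound_id))
  expect_gt(mean(self$is_active), 0.5)
  # alpha = 0 can call nothing active
  none <- predict_library(model, fps, alpha = 1e-12)
  expect_identical(sum(none$is_active), 0L)
})
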