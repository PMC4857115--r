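test_that("upper tail matches exhaustive subset enumeration on a small case", {
  # all C(10,5) = 252 draws of 5 from a library of 10 with 4 actives
  draws <- combn(10, 5)
  n_hits <- sum(apply(draws, 2, function(d) sum(d <= 4) >= 3))
  expect_identical(n_hits, 66L)
  expect_equal(hypergeom_upper_tail(10, 4, 5, 3), 66 / 252, tolerance = 1e-14)
  expect_equal(exact_upper_tail(10, 4, 5, 3), 66 / 252, tolerance = 1e-14)
})

test_that("upper tail handles boundary and degenerate arguments", {
  expect_equal(hypergeom_upper_tail(100, 30, 10, 0), 1)
  expect_equal(hypergeom_upper_tail(10, 10, 7, 7), 1)  # every compound active
  expect_error(hypergeom_upper_tail(10, 4, 5, 6), "k <= min")
  expect_error(hypergeom_upper_tail(10, 4, 12, 2), "m <= N")
  expect_error(hypergeom_upper_tail(10, 12, 5, 2), "n <= N")
})

test_that("upper tail agrees with phyper and is monotone in k", {
  cases <- expand.grid(N = c(8, 15, 22), n = c(2, 7, 12), m = c(3, 9, 14))
  cases <- cases[cases$n <= cases$N & cases$m <= cases$N, ]
  for (r in seq_len(nrow(cases))) {
    N <- cases$N[r]; n <- cases$n[r]; m <- cases$m[r]
    ks <- 0:min(n, m)
    p <- vapply(ks, function(k) hypergeom_upper_tail(N, n, m, k), numeric(1))
    ref <- vapply(ks, function(k)
      if (k == 0) 1 else phyper(k - 1, n, N - n, m, lower.tail = FALSE),
      numeric(1))
    expect_equal(p, ref, tolerance = 1e-12)
    expect_true(all(diff(p) <= 1e-14))  # non-increasing in k
  }
})

test_that("log-space evaluation stays accurate for extreme tails", {
  # a strongly enriched plant in a large library: tail ~ 1e-40 scale
  p <- hypergeom_upper_tail(21334, 5278, 36, 36)
  expect_gt(p, 0)
  expect_equal(log(p), 36 * log(5278 / 21334), tolerance = 0.05)
})

test_that("Bonferroni adjustment multiplies and caps at one", {
  expect_equal(bonferroni_adjust(1e-5, 2402), 0.02402)
  expect_equal(bonferroni_adjust(0.001, 2402), 1)
  expect_equal(bonferroni_adjust(0.37, 1), 0.37)
  expect_error(bonferroni_adjust(1.2, 10))
})

test_that("run_acea computes per-plant counts with database-level N and n", {
  calls <- data.frame(compound_id = sprintf("C%02d", 1:20),
                      is_active = rep(c(TRUE, FALSE), c(5, 15)))
  plants <- data.frame(plant_id = c("P1", "P2", "P3"),
                       plant_name = c("all active", "mixed", "empty"),
                       family = "F")
  plants$compound_ids <- list(c("C01", "C02", "C03", "C04", "C05"),
                              c("C01", "C06", "C07"),
                              character(0))
  res <- run_acea(plants, calls)
  expect_identical(res$N, rep(20L, 3))
  expect_identical(res$n, rep(5L, 3))
  r1 <- res[res$plant_id == "P1", ]
  expect_identical(c(r1$m, r1$k), c(5L, 5L))
  expect_equal(r1$p, exact_upper_tail(20, 5, 5, 5), tolerance = 1e-12)
  expect_equal(r1$p_adj, min(1, r1$p * 3))
  expect_true(r1$significant)
  # the m = 0 plant is untestable: p = 1, counted in the log
  expect_equal(res$p[res$plant_id == "P3"], 1)
  expect_identical(attr(res, "log")[["n_untestable"]], 1L)
})

test_that("plants sharing (m, k) tie on p and order by name", {
  calls <- data.frame(compound_id = sprintf("C%02d", 1:30),
                      is_active = rep(c(TRUE, FALSE), c(10, 20)))
  plants <- data.frame(plant_id = c("PA", "PB"),
                       plant_name = c("zeta", "alpha"), family = "F")
  plants$compound_ids <- list(c("C01", "C02", "C11"), c("C03", "C04", "C12"))
  res <- run_acea(plants, calls)
  expect_equal(res$p[1], res$p[2])
  expect_equal(res$p_adj[1], res$p_adj[2])
  expect_identical(res$plant_name, c("alpha", "zeta"))
})

test_that("a compound shared by two plants counts in both m but once in N", {
  calls <- data.frame(compound_id = c("C1", "C2", "C3"),
                      is_active = c(TRUE, FALSE, FALSE))
  plants <- data.frame(plant_id = c("P1", "P2"), plant_name = c("a", "b"),
                       family = "F")
  plants$compound_ids <- list(c("C1", "C2"), c("C1", "C3"))
  res <- run_acea(plants, calls)
  expect_identical(res$N, c(3L, 3L))
  expect_identical(res$m, c(2L, 2L))
  expect_identical(res$k, c(1L, 1L))
})
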