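# Activity enrichment analysis: for each plant, an upper-tail hypergeometric
# test of whether the plant holds more predicted-active compounds than chance
# would give, with Bonferroni control across plants.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` where X counts actives in a plant of `m` compounds drawn from
#' a library of `N` compounds of which `n` are active. Evaluated as a
#' log-space sum of hypergeometric point masses for numerical stability; the
#' tiny Bonferroni-significant tail probabilities (down to ~1e-48 on real
#' libraries) stay accurate. `k = 0` returns exactly 1.
#'
#' @param N library size; @param n actives in the library;
#' @param m compounds in the plant; @param k actives in the plant.
#' @return probability in (0, 1\].
#' @examples
#' hypergeom_upper_tail(10, 4, 5, 3)  # 66/252
#' @export
hypergeom_upper_tail <- function(N, n, m, k) {
  if (k < 0 || k > min(n, m)) {
    stop("need 0 <= k <= min(n, m): k=", k, ", n=", n, ", m=", m, call. = FALSE)
  }
  if (m > N) stop("need m <= N: m=", m, ", N=", N, call. = FALSE)
  if (n > N) stop("need n <= N: n=", n, ", N=", N, call. = FALSE)
  if (k == 0L) return(1)
  support <- k:min(n, m)
  min(1, exp(logsumexp(stats::dhyper(support, n, N - n, m, log = TRUE))))
}

#' Bonferroni adjustment
#'
#' Multiplies a P-value by the number of tests and caps at 1.
#'
#' @param p P-value(s) in \[0, 1\].
#' @param n_tests number of tests (here, plants), >= 1.
#' @return adjusted P-value(s).
#' @export
bonferroni_adjust <- function(p, n_tests) {
  stopifnot(all(p >= 0 & p <= 1), n_tests >= 1)
  pmin(1, p * n_tests)
}

#' Per-plant activity enrichment analysis
#'
#' For each plant computes (N, n, m, k): `N` distinct compounds in the
#' library, `n` predicted actives in the library, `m` compounds annotated to
#' the plant, `k` predicted actives among them. Compounds shared by several
#' plants count toward each plant's (m, k) but only once in (N, n). The
#' upper-tail hypergeometric P is Bonferroni-adjusted by the number of plants
#' tested; a plant is significant when `p_adj < alpha_adj`.
#'
#' @param plants plant table from [read_compound_library()] (`plant_id`,
#'   `plant_name`, `family`, list-column `compound_ids`).
#' @param calls activity calls from [predict_library()].
#' @param alpha_adj family-wise significance level on the adjusted P.
#' @param min_m optional minimum plant size; plants below it are excluded
#'   from testing (and from the Bonferroni count). Default 0 keeps every
#'   plant: small plants simply lack power.
#' @return data.frame, one row per tested plant, sorted by (`p_adj`,
#'   `plant_name`): `plant_id`, `plant_name`, `family`, `N`, `n`, `m`, `k`,
#'   `p`, `p_adj`, `significant`. Attribute `log` records `n_untestable`
#'   (plants with m = 0).
#' @export
run_acea <- function(plants, calls, alpha_adj = 0.05, min_m = 0L) {
  stopifnot(alpha_adj > 0, alpha_adj <= 1)
  N <- nrow(calls)
  active_ids <- calls$compound_id[calls$is_active]
  n <- length(active_ids)
  if (min_m > 0L) {
    plants <- plants[lengths(plants$compound_ids) >= min_m, , drop = FALSE]
  }
  n_tests <- nrow(plants)
  m <- integer(n_tests); k <- integer(n_tests); p <- numeric(n_tests)
  for (i in seq_len(n_tests)) {
    ids <- intersect(plants$compound_ids[[i]], calls$compound_id)
    m[i] <- length(ids)
    k[i] <- sum(ids %in% active_ids)
    p[i] <- if (m[i] == 0L) 1 else hypergeom_upper_tail(N, n, m[i], k[i])
  }
  res <- data.frame(
    plant_id = plants$plant_id, plant_name = plants$plant_name,
    family = plants$family, N = N, n = n, m = m, k = k, p = p,
    p_adj = bonferroni_adjust(p, max(1L, n_tests)),
    row.names = NULL)
  res$significant <- res$p_adj < alpha_adj
  res <- res[order(res$p_adj, res$plant_name), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "log") <- c(n_tested = n_tests, n_untestable = sum(m == 0L))
  res
}
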