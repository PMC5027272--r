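test_that("rate estimates are exact ratios with 3 d.p. display", {
  r1 <- estimate_rate(24, 232)
  r2 <- estimate_rate(107, 237)
  expect_identical(r1$rate, 24 / 232)
  expect_equal(round(r1$rate, 3), 0.103)
  expect_equal(round(r2$rate, 3), 0.451)
  expect_identical(estimate_rate(0, 100)$rate, 0)
  expect_error(estimate_rate(5, 0), "transferred")
  expect_error(estimate_rate(10, 5), "exceed")
})

test_that("concordance evidence is the closed-form power", {
  expect_identical(concordance_evidence(0, 0.7), 1)
  expect_identical(concordance_evidence(20, 0), 1)
  expect_equal(concordance_evidence(20, 0.1), 0.9^20)
  expect_identical(concordance_evidence(20, 1), 0)
  expect_error(concordance_evidence(20, 1.2), "rho")
  # log-space path stays finite for large k
  expect_equal(concordance_evidence(1e4, 0.5, log = TRUE), 1e4 * log(0.5))
})

test_that("term-origin pmf obeys degenerate limits and normalization", {
  q <- small_query()
  expect_equal(term_origin_pmf(q, rho = 0, n = 1), 0)
  expect_equal(term_origin_pmf(q, rho = 0, n = 0), 1)
  expect_equal(term_origin_pmf(q, rho = 1, n = q$T_total), 1)
  pmf <- vapply(0:q$T_total, function(n) term_origin_pmf(q, 0.25, n), numeric(1))
  expect_equal(sum(pmf), 1, tolerance = 1e-12)
  expect_error(term_origin_pmf(q, rho = -0.1), "rho")
  expect_error(term_origin_pmf(q, 0.2, n = q$T_total + 1), "n")
})

test_that("tail equals one minus the lower cumulative and is monotone in n", {
  q <- small_query()
  for (rho in c(0.05, 0.3, 0.8)) {
    pmf <- vapply(0:q$T_total, function(n) term_origin_pmf(q, rho, n), numeric(1))
    tails <- vapply(0:q$T_total, function(n) term_origin_tail(q, rho, n), numeric(1))
    expect_equal(tails, rev(cumsum(rev(pmf))), tolerance = 1e-12)
    expect_equal(tails[1], 1, tolerance = 1e-12)
    expect_true(all(diff(tails) <= 1e-14))
  }
  expect_equal(term_origin_tail(q, rho = 0, n = 1), 0)
})

test_that("pmf and tail match the Monte-Carlo cohort oracle", {
  q <- small_query()
  rho <- 0.25
  tal <- simulate_cohort_tallies(2e5, q$N, rho, q$q1, q$q2, seed = 99)
  sel <- tal[tal$term_total == q$T_total, ]
  expect_gt(nrow(sel), 5000)
  for (n in 2:10) {
    emp <- mean(sel$term_ii == n)
    theo <- term_origin_pmf(q, rho, n)
    se <- sqrt(theo * (1 - theo) / nrow(sel))
    expect_lt(abs(emp - theo), 3 * se + 1e-12)
  }
  emp_tail <- mean(sel$term_ii >= 6)
  theo_tail <- term_origin_tail(q, rho, n = 6)
  se <- sqrt(theo_tail * (1 - theo_tail) / nrow(sel))
  expect_lt(abs(emp_tail - theo_tail), 3 * se)
})

test_that("combined probability factorizes into tail and evidence", {
  q0 <- small_query(n = 4)
  expect_equal(combined_probability(q0, 0.3),
               term_origin_tail(q0, 0.3))
  qk <- mixture_query(60, 16, 0.2, 0.5, k = c(9, 20), n = 4)
  expect_equal(combined_probability(qk, 0.1),
               term_origin_tail(qk, 0.1, n = 4) * 0.9^29)
  q1 <- mixture_query(60, 16, 0.2, 0.5, k = 20, n = 4)
  expect_equal(combined_probability(q1, 1), 0)
})

test_that("rho profile brackets the refined worst case and is monotone in n", {
  q9 <- mixture_query(60, 16, 0.2, 0.5, k = 10, n = 6)
  prof <- rho_profile(q9, grid_size = 201)
  expect_equal(prof$p_values[1], 0)
  expect_equal(prof$p_values[length(prof$p_values)], 0)
  wc <- worst_case(q9, grid_size = 201)
  expect_gte(wc$p_max, max(prof$p_values) - 1e-12)
  expect_lt(wc$p_max, max(prof$p_values) * 1.01)
  q10 <- mixture_query(60, 16, 0.2, 0.5, k = 10, n = 7)
  prof10 <- rho_profile(q10, grid_size = 201)
  expect_true(all(prof10$p_values <= prof$p_values + 1e-14))
  expect_error(rho_profile(q9, grid_size = 1), "grid_size")
})

test_that("worst case is monotone in n and in every evidence count", {
  pmax_for <- function(n, k) worst_case(
    mixture_query(60, 16, 0.2, 0.5, k = k, n = n), grid_size = 401)$p_max
  p_by_n <- vapply(c(2, 5, 8, 12, 16), pmax_for, numeric(1), k = 10)
  expect_true(all(diff(p_by_n) <= 1e-12))
  p_by_k <- vapply(list(5, 10, c(10, 5)), function(k) pmax_for(6, k), numeric(1))
  expect_true(all(diff(p_by_k) <= 1e-12))
})

test_that("minimum excludable n decreases as alpha grows", {
  n_at <- function(alpha) min_excludable_n(
    mixture_query(60, 16, 0.2, 0.5, k = 10, alpha = alpha), grid_size = 401)
  ns <- vapply(c(0.01, 0.05, 0.2), n_at, integer(1))
  expect_true(all(diff(ns) <= 0))
  # exclusion verdict is consistent with the threshold
  n_star <- n_at(0.05)
  q_at <- function(n) worst_case(
    mixture_query(60, 16, 0.2, 0.5, k = 10, n = n, alpha = 0.05),
    grid_size = 401)
  expect_true(q_at(n_star)$excluded)
  expect_false(q_at(n_star - 1L)$excluded)
})

test_that("interpretation strategy is recorded and the literal variant runs in log space", {
  q <- mixture_query(232, 24, estimate_rate(24, 232), estimate_rate(107, 237),
                     k = 20, n = 9, strategy = "literal-prose")
  wc <- worst_case(q, grid_size = 201)
  expect_identical(wc$strategy, "literal-prose")
  # literal reading makes all N embryos develop: log-probabilities are far
  # below the conditioned ones but remain well-defined
  lp <- combined_probability(q, 0.5, log = TRUE)
  expect_true(is.finite(lp) || lp == -Inf)
  expect_lt(lp, combined_probability(
    mixture_query(232, 24, estimate_rate(24, 232), estimate_rate(107, 237),
                  k = 20, n = 9), 0.5, log = TRUE))
  expect_identical(worst_case(small_query(n = 2L), grid_size = 201)$strategy,
                   "total-conditioned")
})
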