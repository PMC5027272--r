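#' Term-development rate estimate
#'
#' Point estimate of the probability that a transferred embryo develops to
#' term, kept as the exact ratio `developed / transferred`. Rounding happens
#' only at display time (see [format()] method).
#'
#' @param developed Non-negative integer count of embryos developed to term.
#' @param transferred Positive integer count of embryos transferred.
#' @return An object of class `rate_estimate`: a list with elements
#'   `developed`, `transferred` and `rate` (the exact ratio).
#' @examples
#' estimate_rate(24, 232)   # ~0.103
#' estimate_rate(107, 237)  # ~0.451
#' @export
estimate_rate <- function(developed, transferred) {
  stopifnot(length(developed) == 1L, length(transferred) == 1L)
  if (!is.finite(transferred) || transferred <= 0 || transferred != round(transferred))
    stop("'transferred' must be a positive integer count", call. = FALSE)
  if (!is.finite(developed) || developed < 0 || developed != round(developed))
    stop("'developed' must be a non-negative integer count", call. = FALSE)
  if (developed > transferred)
    stop("'developed' cannot exceed 'transferred'", call. = FALSE)
  structure(
    list(developed = as.integer(developed),
         transferred = as.integer(transferred),
         rate = developed / transferred),
    class = "rate_estimate"
  )
}

#' @export
format.rate_estimate <- function(x, digits = 3, ...) {
  sprintf("%d/%d = %s", x$developed, x$transferred,
          formatC(round(x$rate, digits), format = "fg", digits = digits))
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat("Term-development rate:", format(x), "\n")
  invisible(x)
}

# Coerce a rate argument: accepts a rate_estimate or a bare probability.
as_rate <- function(q, what = "rate") {
  if (inherits(q, "rate_estimate")) return(q)
  if (is.numeric(q) && length(q) == 1L && q >= 0 && q <= 1)
    return(structure(list(developed = NA_integer_, transferred = NA_integer_,
                          rate = as.numeric(q)), class = "rate_estimate"))
  stop(sprintf("'%s' must be a rate_estimate or a probability in [0,1]", what),
       call. = FALSE)
}

#' Parameterize one exclusion computation
#'
#' Bundles everything a worst-case exclusion bound needs: the nominal
#' phenotype-I cohort (`N` embryos transferred, `T` developed to term), the
#' per-phenotype term rates, the concordant-assay evidence counts and the
#' candidate number `n` of phenotype-II-derived term offspring.
#'
#' @param N Cohort size (embryos transferred).
#' @param T_total Total number of embryos developed to term (0 <= T <= N).
#' @param q1 Phenotype-I term rate: a [estimate_rate()] object or probability.
#' @param q2 Phenotype-II term rate, likewise.
#' @param k Integer vector of concordant phenotype-I observation counts, one
#'   entry per independent line of evidence (e.g. `c(9, 20)` for two
#'   independently assayed DNA modifications). May be empty.
#' @param n Candidate count of phenotype-II-derived term offspring
#'   (0 <= n <= T).
#' @param alpha Significance level for exclusion (default 0.05).
#' @param strategy Interpretation of the development-allocation step:
#'   `"total-conditioned"` (default) conditions on the observed total `T`,
#'   so the probability is over how many of the `T` term offspring derive
#'   from phenotype-II; `"literal-prose"` uses the unconditioned product
#'   `p(n | m, q2) * p(N - n | N - m, q1)`, under which all `N` embryos
#'   develop. See the methods vignette for why total-conditioned is the
#'   default.
#' @return An object of class `mixture_query`.
#' @export
mixture_query <- function(N, T_total, q1, q2, k = integer(), n = 0L,
                          alpha = 0.05,
                          strategy = c("total-conditioned", "literal-prose")) {
  strategy <- match.arg(strategy)
  q1 <- as_rate(q1, "q1"); q2 <- as_rate(q2, "q2")
  stopifnot(length(N) == 1L, length(T_total) == 1L, length(n) == 1L)
  if (N < 1 || N != round(N)) stop("'N' must be a positive integer", call. = FALSE)
  if (T_total < 0 || T_total > N || T_total != round(T_total))
    stop("'T_total' must be an integer in [0, N]", call. = FALSE)
  if (n < 0 || n > T_total || n != round(n))
    stop("'n' must be an integer in [0, T_total]", call. = FALSE)
  if (length(k) && (any(k < 1) || any(k != round(k))))
    stop("every evidence count in 'k' must be a positive integer", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie strictly between 0 and 1", call. = FALSE)
  structure(
    list(N = as.integer(N), T_total = as.integer(T_total),
         q1 = q1, q2 = q2, k = as.integer(k), n = as.integer(n),
         alpha = alpha, strategy = strategy),
    class = "mixture_query"
  )
}

#' @export
print.mixture_query <- function(x, ...) {
  cat(sprintf(
    "Mixture query: N=%d, T=%d, q1=%.4g, q2=%.4g, k={%s}, n=%d, alpha=%g (%s)\n",
    x$N, x$T_total, x$q1$rate, x$q2$rate, paste(x$k, collapse = ","),
    x$n, x$alpha, x$strategy))
  invisible(x)
}

#' Concordant-assay evidence factor
#'
#' Probability of observing the phenotype-I modification state in all `k`
#' independently assayed embryos when a fraction `rho` of the nominal
#' phenotype-I population is actually phenotype-II: binomial
#' `p(k | k, 1 - rho) = (1 - rho)^k`, evaluated in log space.
#'
#' @param k Number of concordant observations (>= 0).
#' @param rho Admixture fraction in \[0, 1\].
#' @param log Return the log probability?
#' @return `(1 - rho)^k` (or its log).
#' @export
concordance_evidence <- function(k, rho, log = FALSE) {
  if (any(rho < 0 | rho > 1)) stop("'rho' must lie in [0,1]", call. = FALSE)
  if (any(k < 0)) stop("'k' must be non-negative", call. = FALSE)
  lp <- sum(k) * log1p(-rho)
  lp[rho == 1 & sum(k) > 0] <- -Inf  # log1p(-1) already -Inf; keep explicit
  if (log) lp else exp(lp)
}

logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Log joint probabilities, marginal over the unknown number m of phenotype-II
# embryos in the cohort, for every candidate n' = 0..T at one rho:
#   sum_m p(m | N, rho) * p(n' | m, q2) * p(T - n' | N - m, q1)
# (total-conditioned) or with p(N - n' | N - m, q1) (literal-prose).
# Infeasible binomial arguments contribute zero mass. Returns a vector of
# log values indexed by n' = 0..T.
term_origin_log_joint <- function(query, rho) {
  L <- query_dev_matrix(query)
  lpm <- stats::dbinom(0:query$N, query$N, rho, log = TRUE)
  M <- sweep(L, 2L, lpm, "+")
  apply(M, 1L, logsumexp)
}

# rho-independent part: log p(n' | m, q2) + log p(dev1(n') | N - m, q1),
# a (T+1) x (N+1) matrix indexed by n' = 0..T (rows) and m = 0..N (cols).
# Cached on the query object by reference-free memoization per call site.
query_dev_matrix <- function(query) {
  key <- paste(query$N, query$T_total, query$q1$rate, query$q2$rate,
               query$strategy)
  hit <- dev_matrix_cache[[key]]
  if (!is.null(hit)) return(hit)
  N <- query$N; Tt <- query$T_total
  q1 <- query$q1$rate; q2 <- query$q2$rate
  m <- 0:N
  dev1 <- if (query$strategy == "total-conditioned") Tt - (0:Tt) else N - (0:Tt)
  L <- matrix(-Inf, Tt + 1L, N + 1L)
  for (np in 0:Tt) {
    L[np + 1L, ] <- stats::dbinom(np, m, q2, log = TRUE) +  # -Inf where np > m
      stats::dbinom(dev1[np + 1L], N - m, q1, log = TRUE)
  }
  if (length(dev_matrix_cache) > 32L)
    rm(list = ls(dev_matrix_cache), envir = dev_matrix_cache)
  assign(key, L, envir = dev_matrix_cache)
  L
}

dev_matrix_cache <- new.env(hash = TRUE, parent = emptyenv())

# Normalized log pmf over n = 0..T (total-conditioned strategy normalizes to
# the conditional distribution given the observed total; literal-prose has no
# natural conditioning event and is left unnormalized).
term_origin_log_dist <- function(query, rho) {
  lj <- term_origin_log_joint(query, rho)
  if (query$strategy == "total-conditioned") {
    lz <- logsumexp(lj)
    if (is.finite(lz)) lj <- lj - lz else lj <- c(0, rep(-Inf, query$T_total))
  }
  lj
}

#' Probability that exactly n term offspring derive from phenotype-II
#'
#' Marginal over the unknown phenotype-II count `m ~ Binomial(N, rho)` in the
#' cohort. Under the default total-conditioned strategy this is the
#' conditional probability, given that `T` embryos developed to term in all,
#' that exactly `n` of them derive from phenotype-II; development is
#' independent Bernoulli at rate `q2` (phenotype-II) or `q1` (phenotype-I).
#' All arithmetic is done in log space.
#'
#' @param query A [mixture_query()].
#' @param rho Admixture fraction in \[0, 1\].
#' @param n Candidate count; defaults to `query$n`.
#' @param log Return log probability?
#' @return The probability (or log probability).
#' @export
term_origin_pmf <- function(query, rho, n = query$n, log = FALSE) {
  stopifnot(inherits(query, "mixture_query"))
  if (rho < 0 || rho > 1) stop("'rho' must lie in [0,1]", call. = FALSE)
  if (n < 0 || n > query$T_total)
    stop("'n' must lie in [0, T_total]", call. = FALSE)
  lp <- term_origin_log_dist(query, rho)[n + 1L]
  if (log) lp else exp(lp)
}

#' Cumulative probability of at least n phenotype-II-derived term offspring
#'
#' Tail sum of [term_origin_pmf()] from `n` to the support maximum `T`,
#' accumulated with log-sum-exp.
#'
#' @inheritParams term_origin_pmf
#' @export
term_origin_tail <- function(query, rho, n = query$n, log = FALSE) {
  stopifnot(inherits(query, "mixture_query"))
  if (rho < 0 || rho > 1) stop("'rho' must lie in [0,1]", call. = FALSE)
  if (n < 0 || n > query$T_total)
    stop("'n' must lie in [0, T_total]", call. = FALSE)
  ld <- term_origin_log_dist(query, rho)
  lp <- logsumexp(ld[(n + 1L):(query$T_total + 1L)])
  if (query$strategy == "total-conditioned") lp <- min(lp, 0)
  if (log) lp else exp(lp)
}

#' Combined probability of mixture tail and concordant-assay evidence
#'
#' Treats the assay evidence and the term-development record as independent
#' observations of the same cohort, with a common admixture fraction `rho`:
#' the product of [term_origin_tail()] and `(1 - rho)^k` for every evidence
#' count `k` in the query.
#'
#' @inheritParams term_origin_pmf
#' @export
combined_probability <- function(query, rho, n = query$n, log = FALSE) {
  lp <- term_origin_tail(query, rho, n = n, log = TRUE) +
    concordance_evidence(sum(query$k), rho, log = TRUE)
  if (log) lp else exp(lp)
}

# Golden-section maximization of f (log scale) on [lo, hi].
golden_max <- function(f, lo, hi, tol = 1e-6) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c_ <- b - gr * (b - a); d_ <- a + gr * (b - a)
  fc <- f(c_); fd <- f(d_)
  while (b - a > tol) {
    if (fc >= fd) { b <- d_; d_ <- c_; fd <- fc; c_ <- b - gr * (b - a); fc <- f(c_) }
    else          { a <- c_; c_ <- d_; fc <- fd; d_ <- a + gr * (b - a); fd <- f(d_) }
  }
  x <- if (fc >= fd) c_ else d_
  list(x = x, fx = max(fc, fd))
}

#' Profile of the combined probability over the admixture fraction
#'
#' Evaluates [combined_probability()] on an evenly spaced grid over
#' \[0, 1\] (endpoints included) and refines the maximum by golden-section
#' search around the grid argmax.
#'
#' @param query A [mixture_query()].
#' @param grid_size Number of grid points (>= 2; default 2001).
#' @param refine_tol Width tolerance of the golden-section refinement.
#' @return An object of class `rho_profile`: list with `rho_grid`,
#'   `p_values`, `log_p`, `p_max`, `log_p_max`, `rho_argmax`.
#' @export
rho_profile <- function(query, grid_size = 2001L, refine_tol = 1e-6) {
  stopifnot(inherits(query, "mixture_query"))
  if (grid_size < 2) stop("'grid_size' must be at least 2", call. = FALSE)
  grid <- seq(0, 1, length.out = grid_size)
  lp <- vapply(grid, function(r) combined_probability(query, r, log = TRUE),
               numeric(1))
  i <- which.max(lp)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(grid_size, i + 1L)]
  ref <- golden_max(function(r) combined_probability(query, r, log = TRUE),
                    lo, hi, tol = refine_tol)
  if (ref$fx >= lp[i]) {
    log_p_max <- ref$fx; rho_argmax <- ref$x
  } else {
    log_p_max <- lp[i]; rho_argmax <- grid[i]
  }
  structure(
    list(rho_grid = grid, p_values = exp(lp), log_p = lp,
         p_max = exp(log_p_max), log_p_max = log_p_max,
         rho_argmax = rho_argmax),
    class = "rho_profile"
  )
}

#' Worst-case exclusion bound over the admixture fraction
#'
#' Maximizes the combined probability over `rho` in \[0, 1\] (coarse grid
#' plus golden-section refinement) and compares the maximum against the
#' query's significance level. A maximum at or below `alpha` excludes the
#' scenario that `n` or more of the term offspring derive from the
#' phenotype-II subpopulation, whatever the true admixture fraction.
#'
#' @inheritParams rho_profile
#' @return An object of class `exclusion_result`: list with `query`,
#'   `profile` (a `rho_profile`), `p_max`, `log_p_max`, `rho_argmax`,
#'   `excluded` and `strategy`.
#' @export
worst_case <- function(query, grid_size = 2001L, refine_tol = 1e-6) {
  prof <- rho_profile(query, grid_size = grid_size, refine_tol = refine_tol)
  structure(
    list(query = query, profile = prof,
         p_max = prof$p_max, log_p_max = prof$log_p_max,
         rho_argmax = prof$rho_argmax,
         excluded = prof$p_max <= query$alpha,
         strategy = query$strategy),
    class = "exclusion_result"
  )
}

#' @export
print.exclusion_result <- function(x, ...) {
  cat(sprintf(
    "Worst-case bound: P(n>=%d | k={%s}) <= %.4g at rho=%.4f [%s]\n  %s at alpha=%g\n",
    x$query$n, paste(x$query$k, collapse = ","), x$p_max, x$rho_argmax,
    x$strategy,
    if (x$excluded) "EXCLUDED" else "not excluded", x$query$alpha))
  invisible(x)
}

#' Smallest excludable phenotype-II offspring count
#'
#' Scans `n = 0, 1, ..., T` and returns the smallest `n` whose worst-case
#' combined probability is at or below `alpha`. Monotonicity of the tail in
#' `n` makes the scan exact. Returns `NA_integer_` (with a warning) when not
#' even `n = T` is excludable -- a possible outcome, not an error.
#'
#' @inheritParams rho_profile
#' @export
min_excludable_n <- function(query, grid_size = 2001L, refine_tol = 1e-6) {
  stopifnot(inherits(query, "mixture_query"))
  # One grid pass gives a lower bound on p_max for every n simultaneously
  # (the refined maximum can only exceed the grid maximum, so any n whose
  # grid maximum already exceeds alpha is certainly not excludable).
  grid <- seq(0, 1, length.out = grid_size)
  Tt <- query$T_total
  grid_lmax <- rep(-Inf, Tt + 1L)
  lev <- sum(query$k)
  for (r in grid) {
    ld <- term_origin_log_dist(query, r)
    ltail <- rev(cumlogsumexp(rev(ld)))  # log tails for n = 0..T
    lc <- ltail + lev * log1p(-r)
    grid_lmax <- pmax(grid_lmax, lc)
  }
  la <- log(query$alpha)
  for (n in 0:Tt) {
    if (grid_lmax[n + 1L] > la) next
    q <- query; q$n <- as.integer(n)
    if (worst_case(q, grid_size, refine_tol)$p_max <= query$alpha)
      return(as.integer(n))
  }
  warning("no n in [0, T] achieves exclusion at alpha = ", query$alpha)
  NA_integer_
}

# Running log-sum-exp of a log-scale vector.
cumlogsumexp <- function(lx) {
  out <- numeric(length(lx))
  acc <- -Inf
  for (i in seq_along(lx)) {
    acc <- logsumexp(c(acc, lx[i]))
    out[i] <- acc
  }
  out
}
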