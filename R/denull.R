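#' Expression study container
#'
#' A probes-by-samples matrix with optional probe annotation, sibling-pair
#' map and group labels. Values may be raw intensities (before
#' [preprocess()]) or log2 intensities (after).
#'
#' @param values Numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids).
#' @param annotation Optional data.frame with columns `probe_id`,
#'   `gene_symbol`, `rep_group` (technical-replicate group, e.g. a shared
#'   platform id). Must cover every probe in `values`.
#' @param pairs Optional named character vector: sample id -> sibling-pair
#'   id. Every named pair must contain exactly two distinct samples.
#' @param groups Optional named character vector: sample id -> group label.
#' @param scale `"intensity"` or `"log2"`.
#' @return An object of class `expr_study`.
#' @export
expr_study <- function(values, annotation = NULL, pairs = NULL, groups = NULL,
                       scale = c("intensity", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must be a matrix with probe rownames and sample colnames",
         call. = FALSE)
  if (!is.null(annotation)) {
    need <- c("probe_id", "gene_symbol", "rep_group")
    if (!all(need %in% names(annotation)))
      stop("'annotation' needs columns ", paste(need, collapse = ", "),
           call. = FALSE)
    missing <- setdiff(rownames(values), annotation$probe_id)
    if (length(missing))
      stop("annotation missing for probes: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  if (!is.null(pairs)) {
    pairs <- pairs[names(pairs) %in% colnames(values)]
    sz <- table(pairs)
    if (any(sz != 2L))
      stop("every sibling pair must name exactly two samples", call. = FALSE)
  }
  structure(list(values = values, annotation = annotation,
                 pairs = pairs, groups = groups, scale = scale),
            class = "expr_study")
}

#' @export
print.expr_study <- function(x, ...) {
  cat(sprintf("expr_study: %d probes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  if (!is.null(x$pairs))
    cat(" ", length(unique(x$pairs)), "sibling pairs\n")
  if (!is.null(x$groups))
    cat("  groups:", paste(names(table(x$groups)), table(x$groups),
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Preprocess raw intensities
#'
#' Log2-transforms strictly positive intensities, quantile-normalizes all
#' columns to a common distribution (tied values receive the mean of the
#' reference values at their tied ranks), then collapses technical-replicate
#' probe groups to their per-sample median. Background correction is assumed
#' done upstream; non-positive intensities are refused with the offending
#' cell named.
#'
#' @param study An [expr_study()] on the intensity scale (or a bare matrix).
#' @param collapse_replicates Collapse technical-replicate groups? Requires
#'   annotation.
#' @return An `expr_study` on the log2 scale; after collapsing, rows are
#'   replicate groups and the annotation is collapsed accordingly.
#' @export
preprocess <- function(study, collapse_replicates = !is.null(study$annotation)) {
  if (is.matrix(study)) study <- expr_study(study)
  stopifnot(inherits(study, "expr_study"))
  x <- study$values
  bad <- which(!is.finite(x) | x <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-positive or non-finite intensity at probe '%s', sample '%s'",
                 rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]]), call. = FALSE)
  }
  x <- log2(x)
  x <- limma::normalizeQuantiles(x, ties = TRUE)
  ann <- study$annotation
  if (collapse_replicates) {
    if (is.null(ann)) stop("collapsing replicates requires annotation", call. = FALSE)
    grp <- ann$rep_group[match(rownames(x), ann$probe_id)]
    idx <- split(seq_len(nrow(x)), grp)
    collapsed <- t(vapply(idx, function(i) {
      if (length(i) == 1L) x[i, ] else apply(x[i, , drop = FALSE], 2, stats::median)
    }, numeric(ncol(x))))
    colnames(collapsed) <- colnames(x)
    x <- collapsed
    ann <- unique(data.frame(
      probe_id = names(idx),
      gene_symbol = vapply(idx, function(i)
        ann$gene_symbol[match(rownames(study$values)[i[1]], ann$probe_id)],
        character(1)),
      rep_group = names(idx),
      row.names = NULL))
  }
  expr_study(x, annotation = ann, pairs = study$pairs, groups = study$groups,
             scale = "log2")
}

#' Moderated two-group t-statistics with empirical-Bayes variance shrinkage
#'
#' Per gene, the two-sample statistic
#' `t = (mean1 - mean2) / sqrt(s2_post * (1/n1 + 1/n2))` with the posterior
#' variance `s2_post = (d0 * s0^2 + d_g * s_g^2) / (d0 + d_g)`, where `s_g^2`
#' is the pooled within-group variance on `d_g = n1 + n2 - 2` degrees of
#' freedom and the prior `(d0, s0^2)` is estimated by moment-matching a
#' scaled F distribution to the gene-wise variances (on the log scale, via
#' digamma/trigamma inversion). Two-sided p-values come from the t
#' distribution on `d0 + d_g` degrees of freedom. `d0 = 0` recovers the
#' ordinary pooled t exactly; `d0 = Inf` shrinks fully to `s0^2`.
#'
#' @param study An [expr_study()] on the log2 scale, or a bare matrix.
#' @param assignment A [group_assignment()]; both groups need >= 2 samples.
#' @param d0 Optional prior degrees of freedom override (numeric, may be 0
#'   or `Inf`). Estimated from the data when `NULL`.
#' @param s02 Optional prior variance override (used only with `d0`).
#' @return An object of class `gene_stats`: data.frame with columns `id`,
#'   `mean_diff`, `t`, `df`, `p`, `p_adj` (BH), plus attributes `d0`, `s02`.
#' @export
moderated_t <- function(study, assignment, d0 = NULL, s02 = NULL) {
  x <- if (inherits(study, "expr_study")) study$values else study
  g1 <- match(assignment$group1, colnames(x))
  g2 <- match(assignment$group2, colnames(x))
  if (anyNA(g1) || anyNA(g2))
    stop("assignment names samples absent from the matrix", call. = FALSE)
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 2 || n2 < 2)
    stop("each group needs at least 2 samples", call. = FALSE)
  m1 <- rowMeans(x[, g1, drop = FALSE])
  m2 <- rowMeans(x[, g2, drop = FALSE])
  ss1 <- rowSums((x[, g1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((x[, g2, drop = FALSE] - m2)^2)
  df <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / df
  if (is.null(d0)) {
    fit <- fit_f_moments(s2, df)
    d0 <- fit$df_prior; s02 <- fit$s2_prior
  } else if (is.null(s02)) {
    s02 <- if (d0 > 0) mean(s2) else 0
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + df * s2) / (d0 + df)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tt <- (m1 - m2) / se
  # degenerate genes: zero posterior variance
  deg <- se == 0
  tt[deg & (m1 - m2) == 0] <- 0
  # with all genes pooled the effective df cannot exceed the summed
  # residual df (matters only when the moment fit returns d0 = Inf)
  df_total <- min(d0 + df, df * length(s2))
  p <- 2 * stats::pt(-abs(tt), df = df_total)
  p[deg & (m1 - m2) == 0] <- 1
  p[deg & (m1 - m2) != 0] <- 0
  out <- data.frame(id = rownames(x), mean_diff = m1 - m2, t = tt,
                    df = df_total, p = p, p_adj = bh_adjust(p),
                    row.names = NULL)
  structure(out, class = c("gene_stats", "data.frame"),
            d0 = d0, s02 = s02, df_residual = df)
}

#' Moment-matching fit of a scaled F prior to gene-wise variances
#'
#' Smyth-style estimation of the prior degrees of freedom `d0` and prior
#' variance `s0^2` from pooled sample variances `s2` on `df` residual
#' degrees of freedom: moments of `log(s2)` are matched to the theoretical
#' digamma/trigamma moments of a scaled F, with `d0` recovered by Newton
#' inversion of the trigamma function. A non-positive excess variance of
#' `log(s2)` yields `d0 = Inf` (full shrinkage).
#'
#' @param s2 Vector of positive sample variances.
#' @param df Residual degrees of freedom (scalar).
#' @return List with `df_prior` (d0) and `s2_prior` (s0^2).
#' @export
fit_f_moments <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) return(list(df_prior = Inf, s2_prior = stats::median(s2)))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0)  # no excess dispersion: full shrinkage
    return(list(df_prior = Inf, s2_prior = mean(s2[ok])))
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  if (!is.finite(d0) || d0 <= 0) return(list(df_prior = Inf, s2_prior = mean(s2[ok])))
  list(df_prior = d0, s2_prior = s02)
}

# Solve trigamma(y) = x for y > 0 by Newton iteration on the reciprocal
# scale (trigamma is convex decreasing; 1/trigamma is nearly linear).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values in input order, via [stats::p.adjust()].
#'
#' @param pvals Vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order and length.
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals) | pvals < 0 | pvals > 1))
    stop("p-values must lie in [0,1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Collapse multi-probe genes to their best probe
#'
#' For genes targeted by several probes, retains only the probe with the
#' lowest raw p-value (ties broken by lexicographically smallest probe id,
#' then input order). By default BH adjustment is re-applied to the
#' gene-level p-values after collapsing; `readjust = FALSE` keeps each
#' retained probe's original adjusted p instead.
#'
#' @param stats A `gene_stats` table from [moderated_t()].
#' @param annotation Probe annotation covering all probes (columns
#'   `probe_id`, `gene_symbol`).
#' @param readjust Re-apply BH on the collapsed table?
#' @return A `gene_stats` table with one row per gene symbol; `id` becomes
#'   the gene symbol and `probe_id` records the retained probe.
#' @export
disambiguate_probes <- function(stats, annotation, readjust = TRUE) {
  sym <- annotation$gene_symbol[match(stats$id, annotation$probe_id)]
  if (anyNA(sym))
    stop("annotation missing for probes: ",
         paste(utils::head(stats$id[is.na(sym)], 5), collapse = ", "),
         call. = FALSE)
  ord <- order(sym, stats$p, stats$id)
  keep <- ord[!duplicated(sym[ord])]
  keep <- sort(keep)  # restore input order among winners
  out <- stats[keep, , drop = FALSE]
  out$probe_id <- out$id
  out$id <- sym[keep]
  if (readjust) out$p_adj <- bh_adjust(out$p)
  rownames(out) <- NULL
  structure(out, class = c("gene_stats", "data.frame"),
            d0 = attr(stats, "d0"), s02 = attr(stats, "s02"))
}

#' Ranked adjusted-p curve
#'
#' Orders a `gene_stats` table by ascending raw p and returns the curve of
#' FDR-adjusted p-values over gene rank.
#'
#' @param stats A `gene_stats` table.
#' @return data.frame with columns `rank`, `p`, `p_adj`.
#' @export
ranked_curve <- function(stats) {
  o <- order(stats$p, stats$id)
  data.frame(rank = seq_along(o), p = stats$p[o], p_adj = stats$p_adj[o])
}

#' Null ensemble of group assignments
#'
#' Runs the full ranking pipeline (moderated t, optional probe
#' disambiguation, BH adjustment, sort by ascending raw p) for every
#' assignment and collects the ranked curves.
#'
#' @param study A preprocessed [expr_study()] (log2 scale) or matrix.
#' @param assignments List of [group_assignment()]s (>= 1).
#' @param alpha Significance level used for significant-gene counts.
#' @param disambiguate Collapse probes to genes per assignment? Requires
#'   annotation on `study`.
#' @param ... Passed to [moderated_t()] (e.g. `d0`).
#' @return An object of class `null_ensemble`: list with `assignments`,
#'   `raw_p` and `adj_p` (rank-by-assignment matrices of the ranked curves),
#'   `n_sig` (significant genes per assignment at `alpha`) and `alpha`.
#' @export
ensemble_curves <- function(study, assignments, alpha = 0.05,
                            disambiguate = FALSE, ...) {
  if (!length(assignments)) stop("need at least one assignment", call. = FALSE)
  ann <- if (inherits(study, "expr_study")) study$annotation else NULL
  if (disambiguate && is.null(ann))
    stop("disambiguation requires probe annotation", call. = FALSE)
  one <- function(a) {
    st <- moderated_t(study, a, ...)
    if (disambiguate) st <- disambiguate_probes(st, ann)
    ranked_curve(st)
  }
  curves <- lapply(assignments, one)
  nr <- unique(vapply(curves, nrow, integer(1)))
  stopifnot(length(nr) == 1L)
  raw_p <- vapply(curves, function(cv) cv$p, numeric(nr))
  adj_p <- vapply(curves, function(cv) cv$p_adj, numeric(nr))
  structure(
    list(assignments = assignments,
         raw_p = matrix(raw_p, nrow = nr), adj_p = matrix(adj_p, nrow = nr),
         n_sig = colSums(matrix(adj_p, nrow = nr) < alpha), alpha = alpha),
    class = "null_ensemble"
  )
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("null_ensemble: %d assignments x %d ranked genes\n",
              length(x$assignments), nrow(x$adj_p)))
  cat(sprintf("  significant genes (adj p < %g): max %d, median %g\n",
              x$alpha, max(x$n_sig), stats::median(x$n_sig)))
  invisible(x)
}

#' Most extreme assignment of an ensemble
#'
#' The assignment with the most FDR-adjusted p-values below `alpha`; ties
#' broken by the smallest minimum adjusted p, then input order.
#'
#' @param ensemble A [ensemble_curves()] result.
#' @param alpha Significance level.
#' @return The winning [group_assignment()], with attributes `index` and
#'   `n_sig`.
#' @export
most_extreme_assignment <- function(ensemble, alpha = ensemble$alpha) {
  n_sig <- colSums(ensemble$adj_p < alpha)
  min_p <- apply(ensemble$adj_p, 2, min)
  best <- order(-n_sig, min_p, seq_along(n_sig))[1]
  structure(ensemble$assignments[[best]], index = best, n_sig = n_sig[best])
}

#' Smoothed rank-versus-p density of an ensemble
#'
#' Pools every assignment's ranked adjusted-p curve into points
#' `(log10(rank), p_adj)` and evaluates a two-dimensional Gaussian kernel
#' density on a fixed grid. Bandwidths default to Silverman's rule per axis;
#' the density is normalized so it integrates to exactly 1 over the grid.
#'
#' @param ensemble A [ensemble_curves()] result with >= 2 curves.
#' @param n_grid Grid resolution, length-2 integer (rank axis, p axis).
#' @param bandwidth Optional length-2 numeric bandwidth (log10-rank, p).
#' @param xlim,ylim Optional grid ranges; default covers the data padded by
#'   three bandwidths.
#' @return An object of class `rank_p_density`: list with grid vectors `x`
#'   (log10 rank), `y` (adjusted p), matrix `z`, and `bandwidth`.
#' @export
smooth_density <- function(ensemble, n_grid = c(64L, 64L), bandwidth = NULL,
                           xlim = NULL, ylim = NULL) {
  if (ncol(ensemble$adj_p) < 2) stop("need at least two curves", call. = FALSE)
  nr <- nrow(ensemble$adj_p)
  px <- rep(log10(seq_len(nr)), times = ncol(ensemble$adj_p))
  py <- as.vector(ensemble$adj_p)
  if (is.null(bandwidth)) {
    bw1 <- stats::bw.nrd0(px); bw2 <- stats::bw.nrd0(py)
    # degenerate (all-identical) curves collapse Silverman's rule to zero
    bandwidth <- c(max(bw1, 1e-3), max(bw2, 1e-3))
  }
  if (is.null(xlim)) xlim <- range(px) + c(-3, 3) * bandwidth[1]
  if (is.null(ylim)) ylim <- range(py) + c(-3, 3) * bandwidth[2]
  gx <- seq(xlim[1], xlim[2], length.out = n_grid[1])
  gy <- seq(ylim[1], ylim[2], length.out = n_grid[2])
  z <- matrix(0, n_grid[1], n_grid[2])
  blocks <- split(seq_along(px), ceiling(seq_along(px) / 5e4))
  for (b in blocks) {
    kx <- stats::dnorm(outer(gx, px[b], "-") / bandwidth[1]) / bandwidth[1]
    ky <- stats::dnorm(outer(gy, py[b], "-") / bandwidth[2]) / bandwidth[2]
    z <- z + kx %*% t(ky)
  }
  z <- z / length(px)
  cell <- diff(gx[1:2]) * diff(gy[1:2])
  z <- z / (sum(z) * cell)  # exact unit mass over the grid
  structure(list(x = gx, y = gy, z = z, bandwidth = bandwidth),
            class = "rank_p_density")
}
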