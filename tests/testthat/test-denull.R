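test_that("preprocessing quantile-normalizes and collapses replicates", {
  # two identical columns are untouched by quantile normalization
  m <- matrix(2^c(1, 3, 2, 1, 3, 2), 3, 2,
              dimnames = list(c("p1", "p2", "p3"), c("a", "b")))
  out <- preprocess(expr_study(m), collapse_replicates = FALSE)
  expect_equal(out$values, log2(m))
  # hand-computed reference distribution: sorted-column means
  m2 <- matrix(2^c(1, 2, 3, 4, 5, 6), 3, 2,
               dimnames = list(c("p1", "p2", "p3"), c("a", "b")))
  out2 <- preprocess(expr_study(m2), collapse_replicates = FALSE)
  expect_equal(unname(out2$values),
               matrix(c(2.5, 3.5, 4.5, 2.5, 3.5, 4.5), 3, 2))
  expect_identical(out2$scale, "log2")
  # replicate probes collapse to their per-sample median
  ann <- data.frame(probe_id = c("pA", "pB", "pC"),
                    gene_symbol = c("G1", "G1", "G2"),
                    rep_group = c("r1", "r1", "r2"))
  m3 <- matrix(2^c(1, 3, 5, 1, 3, 5), 3, 2,
               dimnames = list(c("pA", "pB", "pC"), c("a", "b")))
  out3 <- preprocess(expr_study(m3, annotation = ann))
  expect_equal(out3$values["r1", ], c(a = 2, b = 2))
  expect_equal(nrow(out3$values), 2)
  # non-positive intensities are refused with the cell named
  m4 <- m; m4[2, 2] <- -1
  expect_error(preprocess(expr_study(m4), collapse_replicates = FALSE),
               "p2.*b")
})

test_that("moderated t matches limma and collapses to the pooled t at d0 = 0", {
  x <- toy_matrix(n_genes = 1000, seed = 2)
  a <- halves_assignment(x)
  st <- moderated_t(x, a)
  design <- cbind(1, rep(c(1, 0), each = 8))
  fit <- limma::eBayes(limma::lmFit(x, design))
  expect_equal(attr(st, "d0"), fit$df.prior, tolerance = 1e-10)
  expect_equal(attr(st, "s02"), fit$s2.prior, tolerance = 1e-10)
  expect_equal(st$t, unname(fit$t[, 2]), tolerance = 1e-10)
  expect_equal(st$p, unname(fit$p.value[, 2]), tolerance = 1e-10)
  # shrinkage-free limit: ordinary pooled two-sample t
  st0 <- moderated_t(x, a, d0 = 0)
  g1 <- x[, 1:8]; g2 <- x[, 9:16]
  s2 <- (apply(g1, 1, var) * 7 + apply(g2, 1, var) * 7) / 14
  t_ref <- (rowMeans(g1) - rowMeans(g2)) / sqrt(s2 * (2 / 8))
  expect_equal(st0$t, unname(t_ref), tolerance = 1e-10)
  expect_error(moderated_t(x, group_assignment("s01", colnames(x)[-1])),
               "at least 2")
})

test_that("identical groups and degenerate genes follow the stated rules", {
  half <- toy_matrix(n_genes = 50, n_samples = 4, seed = 3)
  x <- cbind(half, half)
  colnames(x) <- sprintf("s%02d", 1:8)
  st <- moderated_t(x, halves_assignment(x))
  expect_true(all(st$t == 0))
  expect_true(all(st$p == 1))
  # zero variance everywhere, equal means -> t = 0, p = 1 (no 0/0)
  flat <- matrix(5, 4, 8, dimnames = list(paste0("g", 1:4), sprintf("s%02d", 1:8)))
  stf <- moderated_t(flat, halves_assignment(flat), d0 = 0)
  expect_true(all(stf$t == 0) && all(stf$p == 1))
})

test_that("BH adjustment equals the textbook step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.42), 0.42)
  set.seed(4)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_brute_force(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0,1")
  p <- runif(20)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("probe disambiguation keeps the lowest-p probe per gene", {
  x <- toy_matrix(n_genes = 250, seed = 5)
  genes <- sprintf("G%03d", sample(1:100, 250, replace = TRUE))
  rownames(x) <- sprintf("probe%03d", 1:250)
  ann <- data.frame(probe_id = rownames(x), gene_symbol = genes,
                    rep_group = rownames(x))
  st <- moderated_t(x, halves_assignment(x))
  dis <- disambiguate_probes(st, ann)
  # brute-force group-by-minimum oracle
  ref <- tapply(st$p, genes, min)
  expect_identical(sort(dis$id), sort(names(ref)))
  expect_equal(dis$p[match(names(ref), dis$id)], as.vector(ref))
  # BH re-applied on the gene-level p's by default
  expect_equal(dis$p_adj, bh_adjust(dis$p))
  dis2 <- disambiguate_probes(st, ann, readjust = FALSE)
  expect_equal(dis2$p_adj, st$p_adj[match(dis2$probe_id, st$id)])
  # deterministic tie-break: lexicographically smallest probe id
  st_tie <- st; st_tie$p[] <- 0.5
  dtie <- disambiguate_probes(st_tie, ann)
  first_probe <- tapply(ann$probe_id, ann$gene_symbol, min)
  expect_identical(dtie$probe_id, as.vector(first_probe[dtie$id]))
  expect_error(disambiguate_probes(st, ann[-1, ]), "missing")
})

test_that("a one-assignment ensemble reproduces the direct analysis", {
  x <- toy_matrix(n_genes = 300, seed = 6)
  a <- halves_assignment(x)
  ens <- ensemble_curves(x, list(a))
  direct <- ranked_curve(moderated_t(x, a))
  expect_equal(ens$raw_p[, 1], direct$p)
  expect_equal(ens$adj_p[, 1], direct$p_adj)
  expect_identical(ncol(ens$adj_p), 1L)
})

test_that("the most extreme assignment maximizes significant genes with stated tie-breaks", {
  fake <- function(adj) structure(
    list(assignments = as.list(seq_len(ncol(adj))), raw_p = adj, adj_p = adj,
         n_sig = colSums(adj < 0.05), alpha = 0.05),
    class = "null_ensemble")
  adj <- cbind(c(0.2, 0.3, 0.4), c(0.01, 0.3, 0.4), c(0.02, 0.03, 0.4))
  expect_identical(attr(most_extreme_assignment(fake(adj)), "index"), 3L)
  # tie on counts: smaller minimum adjusted p wins
  adj2 <- cbind(c(0.03, 0.5, 0.5), c(0.01, 0.5, 0.5))
  expect_identical(attr(most_extreme_assignment(fake(adj2)), "index"), 2L)
  # full tie: input order
  adj3 <- cbind(c(0.5, 0.6), c(0.5, 0.6))
  expect_identical(attr(most_extreme_assignment(fake(adj3)), "index"), 1L)
})

test_that("smoothed density integrates to one and flattens with bandwidth", {
  x <- toy_matrix(n_genes = 150, seed = 7)
  asn <- enumerate_assignments(colnames(x), 8)[1:20]
  ens <- ensemble_curves(x, asn)
  d <- smooth_density(ens, n_grid = c(50, 50))
  cell <- diff(d$x[1:2]) * diff(d$y[1:2])
  expect_equal(sum(d$z) * cell, 1, tolerance = 1e-6)
  expect_true(all(d$z >= 0))
  # doubling the bandwidth cannot sharpen the density (common wide grid)
  xl <- c(-2, 4); yl <- c(-3, 4)
  d1 <- smooth_density(ens, n_grid = c(50, 50), bandwidth = c(0.2, 0.1),
                       xlim = xl, ylim = yl)
  d2 <- smooth_density(ens, n_grid = c(50, 50), bandwidth = c(0.4, 0.2),
                       xlim = xl, ylim = yl)
  expect_lte(max(d2$z), max(d1$z) * (1 + 1e-9))
  # identical curves give a concentrated ridge, not an error
  ens2 <- ens; ens2$adj_p <- ens$adj_p[, c(1, 1)]; ens2$raw_p <- ens$raw_p[, c(1, 1)]
  ens2$assignments <- ens$assignments[c(1, 1)]
  expect_silent(smooth_density(ens2, n_grid = c(30, 30)))
  # MASS cross-check on the same bandwidth convention
  pts_x <- rep(log10(seq_len(nrow(ens$adj_p))), ncol(ens$adj_p))
  pts_y <- as.vector(ens$adj_p)
  mk <- MASS::kde2d(pts_x, pts_y, h = c(0.2, 0.1) * 4, n = 25,
                    lims = c(xl, yl))
  dk <- smooth_density(ens, n_grid = c(25, 25), bandwidth = c(0.2, 0.1),
                       xlim = xl, ylim = yl)
  ratio <- sum(mk$z) / sum(dk$z)
  expect_equal(mk$z / ratio, dk$z, tolerance = 1e-6)
})
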