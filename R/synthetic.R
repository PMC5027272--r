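# Run code under a locally seeded RNG, restoring global state afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()),
            add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Simulate one mixed embryo cohort
#'
#' `N` embryos, each phenotype-II with probability `rho`, developing to term
#' independently at rate `q2` (phenotype-II) or `q1` (phenotype-I). A
#' separate set of `k` embryos from the same nominal population is assayed;
#' by default the assayed modification state equals the phenotype (the
#' 100-percent-correlated-modifications assumption), with an optional
#' `state_flip_prob` to decorrelate for robustness checks.
#'
#' @param N Cohort size.
#' @param rho Phenotype-II admixture fraction.
#' @param q1,q2 Term rates (probabilities or [estimate_rate()] objects).
#' @param k Number of assayed embryos.
#' @param seed Integer seed (local to this call).
#' @param state_flip_prob Probability an assayed state disagrees with the
#'   embryo's phenotype (default 0).
#' @return An object of class `sim_cohort`: list with `embryos` (data.frame
#'   `phenotype`, `developed`), `assays` (data.frame `phenotype`, `state`)
#'   and the generating parameters.
#' @export
simulate_cohort <- function(N, rho, q1, q2, k = 0L, seed = NULL,
                            state_flip_prob = 0) {
  q1 <- as_rate(q1, "q1")$rate; q2 <- as_rate(q2, "q2")$rate
  if (rho < 0 || rho > 1 || q1 < 0 || q1 > 1 || q2 < 0 || q2 > 1 ||
      state_flip_prob < 0 || state_flip_prob > 1)
    stop("probabilities must lie in [0,1]", call. = FALSE)
  if (N < 1) stop("'N' must be at least 1", call. = FALSE)
  with_seed(seed, {
    phen <- ifelse(stats::runif(N) < rho, "II", "I")
    developed <- stats::runif(N) < ifelse(phen == "II", q2, q1)
    assays <- NULL
    if (k > 0) {
      aphen <- ifelse(stats::runif(k) < rho, "II", "I")
      flip <- stats::runif(k) < state_flip_prob
      state <- ifelse(xor(aphen == "II", flip), "II-like", "I-like")
      assays <- data.frame(phenotype = aphen, state = state)
    }
    structure(
      list(embryos = data.frame(phenotype = phen, developed = developed),
           assays = assays,
           params = list(N = N, rho = rho, q1 = q1, q2 = q2, k = k,
                         seed = seed, state_flip_prob = state_flip_prob)),
      class = "sim_cohort")
  })
}

#' Tally many simulated cohorts at once
#'
#' Vectorized replicate engine used as the Monte-Carlo oracle for the
#' mixture model: per replicate, the number `m` of phenotype-II embryos, and
#' the term-offspring counts by phenotype.
#'
#' @inheritParams simulate_cohort
#' @param reps Number of replicate cohorts.
#' @return data.frame with columns `m`, `term_ii`, `term_i`, `term_total`.
#' @export
simulate_cohort_tallies <- function(reps, N, rho, q1, q2, seed = NULL) {
  q1 <- as_rate(q1, "q1")$rate; q2 <- as_rate(q2, "q2")$rate
  with_seed(seed, {
    m <- stats::rbinom(reps, N, rho)
    term_ii <- stats::rbinom(reps, m, q2)
    term_i <- stats::rbinom(reps, N - m, q1)
    data.frame(m = m, term_ii = term_ii, term_i = term_i,
               term_total = term_ii + term_i)
  })
}

#' Simulate a sibling-paired expression study
#'
#' Emulates the design of a two-condition single-blastomere microarray
#' study: `2 * n_pairs` samples of the paired condition (two sibling
#' blastomeres per embryo) plus `n_extra_group` samples of the contrast
#' condition. Per gene, the log2 signal is
#' `baseline + embryo effect + group effect (DE genes only) + noise`;
#' baselines are lognormal on the intensity scale (normal on log2), sibling
#' samples share their embryo's latent effect, and a configurable subset of
#' genes carries a true group shift. A fraction of genes is measured by
#' multiple technical-replicate probes that share the sample signal but add
#' independent measurement noise. Values are returned on the intensity
#' scale, ready for [preprocess()].
#'
#' @param n_genes Number of genes.
#' @param n_pairs Number of sibling pairs in the paired condition.
#' @param n_extra_group Number of samples in the contrast condition.
#' @param n_de Number of truly differentially expressed genes between the
#'   conditions.
#' @param effect_size Group shift of DE genes, in units of the per-sample
#'   biological SD `sqrt(pair_sd^2 + noise_sd^2)`; signs alternate.
#' @param sibling_cor Target within-pair correlation of the biological
#'   signal; sets the embryo-effect SD via
#'   `pair_sd = noise_sd * sqrt(r / (1 - r))`. The default 0 emulates a
#'   study whose sibling blastomeres show no detectable embryo-level
#'   component (uniform null p-values under pairing-respecting splits); see
#'   the methods vignette for the conservatism that a positive correlation
#'   induces in unpaired two-group statistics.
#' @param noise_sd Per-sample biological noise SD (log2 units).
#' @param baseline_mean,baseline_sd Mean and SD of the log2 baselines
#'   (SD 1.5 spans roughly 6 log2 units of dynamic range).
#' @param rep_fraction Fraction of genes carrying technical-replicate
#'   probes.
#' @param rep_copies Probe copies for replicated genes.
#' @param tech_sd Technical (probe-level) noise SD (log2 units).
#' @param seed Integer seed (local to this call).
#' @return An object of class `sim_expr_study`, also an [expr_study()]
#'   (intensity scale), with extra elements `truth` (data.frame
#'   `gene_symbol`, `effect`) and `params`.
#' @export
simulate_expression <- function(n_genes = 20000L, n_pairs = 8L,
                                n_extra_group = 8L, n_de = 73L,
                                effect_size = 2, sibling_cor = 0,
                                noise_sd = 0.25, baseline_mean = 8,
                                baseline_sd = 1.5, rep_fraction = 0.1,
                                rep_copies = 2L, tech_sd = 0.1,
                                seed = NULL) {
  if (n_pairs < 2) stop("'n_pairs' must be at least 2", call. = FALSE)
  if (n_genes < 10) stop("'n_genes' must be at least 10", call. = FALSE)
  if (n_de < 0 || n_de > n_genes)
    stop("'n_de' must lie in [0, n_genes]", call. = FALSE)
  if (sibling_cor < 0 || sibling_cor >= 1)
    stop("'sibling_cor' must lie in [0, 1)", call. = FALSE)
  with_seed(seed, {
    genes <- sprintf("G%05d", seq_len(n_genes))
    paired <- sprintf("ICSI_p%02d_%s", rep(seq_len(n_pairs), each = 2),
                      rep(c("a", "b"), n_pairs))
    extra <- if (n_extra_group > 0) sprintf("phICSI_%02d", seq_len(n_extra_group))
             else character()
    samples <- c(paired, extra)
    n_s <- length(samples)
    pair_sd <- noise_sd * sqrt(sibling_cor / (1 - sibling_cor))
    # embryo index per sample: siblings share one, every other sample its own
    embryo <- c(rep(seq_len(n_pairs), each = 2),
                n_pairs + seq_len(n_extra_group))
    n_e <- n_pairs + n_extra_group
    baseline <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
    de_idx <- if (n_de > 0) sort(sample.int(n_genes, n_de)) else integer()
    sd_sample <- sqrt(pair_sd^2 + noise_sd^2)
    effect <- numeric(n_genes)
    effect[de_idx] <- effect_size * sd_sample *
      rep_len(c(1, -1), length(de_idx))
    in_extra <- samples %in% extra
    emb_eff <- matrix(stats::rnorm(n_genes * n_e, 0, pair_sd), n_genes, n_e)
    sig <- baseline + emb_eff[, embryo, drop = FALSE] +
      outer(effect, as.numeric(in_extra)) +
      matrix(stats::rnorm(n_genes * n_s, 0, noise_sd), n_genes, n_s)
    colnames(sig) <- samples
    # expand genes to probes (technical replicates)
    n_rep_genes <- round(rep_fraction * n_genes)
    rep_genes <- if (n_rep_genes > 0) sort(sample.int(n_genes, n_rep_genes))
                 else integer()
    copies <- rep(1L, n_genes); copies[rep_genes] <- as.integer(rep_copies)
    gene_of_probe <- rep(seq_len(n_genes), copies)
    probe_ids <- sprintf("%s_p%d", genes[gene_of_probe],
                         sequence(copies))
    vals <- sig[gene_of_probe, , drop = FALSE] +
      matrix(stats::rnorm(length(gene_of_probe) * n_s, 0, tech_sd),
             length(gene_of_probe), n_s)
    rownames(vals) <- probe_ids
    ann <- data.frame(probe_id = probe_ids,
                      gene_symbol = genes[gene_of_probe],
                      rep_group = genes[gene_of_probe])
    pairs <- stats::setNames(sprintf("pair%02d", rep(seq_len(n_pairs), each = 2)),
                             paired)
    groups <- stats::setNames(ifelse(in_extra, "phICSI", "ICSI"), samples)
    st <- expr_study(2^vals, annotation = ann, pairs = pairs, groups = groups,
                     scale = "intensity")
    st$truth <- data.frame(gene_symbol = genes[de_idx],
                           effect = effect[de_idx])
    st$params <- list(n_genes = n_genes, n_pairs = n_pairs,
                      n_extra_group = n_extra_group, n_de = n_de,
                      effect_size = effect_size, sibling_cor = sibling_cor,
                      noise_sd = noise_sd, pair_sd = pair_sd,
                      baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                      rep_fraction = rep_fraction, rep_copies = rep_copies,
                      tech_sd = tech_sd, seed = seed)
    class(st) <- c("sim_expr_study", class(st))
    st
  })
}

#' Write simulation fixtures as TSV files
#'
#' Emits the tab-separated files consumed by the readers in this package.
#' For an expression study: `expression.tsv` (probe_id + one column per
#' sample, intensity scale), `annotation.tsv`, `pairs.tsv` (sample_id,
#' pair_id, condition) and, when ground truth is present, `truth.tsv`. For a
#' cohort: `cohort.tsv` (one row per embryo) and `assays.tsv`. Numbers are
#' written with 10 significant digits so a write-read round trip reproduces
#' values to that precision; bytes are deterministic for a fixed input.
#'
#' @param x A `sim_expr_study` / [expr_study()] or [simulate_cohort()]
#'   result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_fixtures <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir, call. = FALSE)
  files <- character()
  tsv <- function(df, name) {
    path <- file.path(dir, name)
    tmp <- paste0(path, ".tmp")
    num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
    df[num] <- lapply(df[num], function(v) sprintf("%.10g", v))
    utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE,
                       eol = "\n", fileEncoding = "UTF-8")
    file.rename(tmp, path)
    files <<- c(files, path)
  }
  if (inherits(x, "expr_study")) {
    df <- data.frame(probe_id = rownames(x$values), x$values,
                     check.names = FALSE)
    tsv(df, "expression.tsv")
    if (!is.null(x$annotation)) tsv(x$annotation, "annotation.tsv")
    pr <- x$pairs %||% stats::setNames(character(), character())
    all_s <- colnames(x$values)
    tsv(data.frame(sample_id = all_s,
                   pair_id = ifelse(all_s %in% names(pr), pr[all_s], ""),
                   condition = if (!is.null(x$groups)) x$groups[all_s] else ""),
        "pairs.tsv")
    if (!is.null(x$truth)) tsv(x$truth, "truth.tsv")
  } else if (inherits(x, "sim_cohort")) {
    tsv(x$embryos, "cohort.tsv")
    if (!is.null(x$assays)) tsv(x$assays, "assays.tsv")
  } else stop("don't know how to write fixtures for this object", call. = FALSE)
  invisible(files)
}
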