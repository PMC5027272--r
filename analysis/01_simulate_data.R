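#!/usr/bin/env Rscript
# Generate the synthetic datasets used by the downstream analyses and write
# them as TSV fixtures under results/fixtures/. Everything later steps read
# is produced here, so the whole workflow runs without external downloads.

suppressPackageStartupMessages(library(embryomix))

seed <- 20160913L
out <- "results/fixtures"

# One mixed cohort matching the term-development experiment: 232 embryos of
# a nominal low-rate phenotype possibly hiding a 10% high-rate fraction,
# with 20 assayed embryos.
cohort <- simulate_cohort(N = 232, rho = 0.10,
                          q1 = estimate_rate(24, 232),
                          q2 = estimate_rate(107, 237),
                          k = 20, seed = seed)
write_fixtures(cohort, file.path(out, "cohort"))
cat(sprintf("cohort: %d embryos, %d phenotype-II, %d developed to term\n",
            nrow(cohort$embryos), sum(cohort$embryos$phenotype == "II"),
            sum(cohort$embryos$developed)))

# A sibling-paired expression study emulating the array design: 8 sibling
# pairs (16 arrays) of the control condition plus 8 arrays of the contrast
# condition, 73 genes truly shifted. 2,000 genes keep the fixture light;
# the generator scales to array-sized gene counts.
study <- simulate_expression(n_genes = 2000, n_pairs = 8, n_extra_group = 8,
                             n_de = 73, seed = seed)
write_fixtures(study, file.path(out, "expression"))
cat(sprintf("expression: %d probes x %d samples, %d true DE genes\n",
            nrow(study$values), ncol(study$values), nrow(study$truth)))

# A pure-null sibling study (no group, no DE) for the null-ensemble step.
null_study <- simulate_expression(n_genes = 2000, n_pairs = 8,
                                  n_extra_group = 0, n_de = 0,
                                  seed = seed + 1L)
write_fixtures(null_study, file.path(out, "null_siblings"))
cat("null sibling study written\n")

write_run_config(list(seed = seed, n_genes = 2000L, n_pairs = 8L,
                      n_extra_group = 8L, n_de = 73L),
                 file.path(out, "config.yaml"))
cat("fixtures under", out, "\n")
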