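#!/usr/bin/env Rscript
# Stage 4: spatial diagnostics and county composition models.
#
# Builds queen-contiguity weights, tests the county fluoride surface for
# global spatial autocorrelation (Moran's I with a permutation test) and for
# the form of spatial dependence (Lagrange multiplier lag/error
# diagnostics), then fits maximum-likelihood spatial error models of log
# county fluoride per 10 percentage-point higher composition for each
# racial/ethnic group (Model 1: + groundwater share, density, SVI; Model 2:
# + percent fluoridated), reported as geometric mean ratios.
#
# Usage: Rscript analysis/04_model.R [seed]
library(cwsfluoride)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

cty <- read.csv("results/county_estimates.csv", stringsAsFactors = FALSE)
counties <- read.csv("results/data/counties.csv", stringsAsFactors = FALSE)
adjacency <- read.csv("results/data/adjacency.csv", stringsAsFactors = FALSE)

merged <- merge(cty[cty$included, ], counties, by = "county_id")
w_all <- build_queen_weights(adjacency, counties$county_id)
w <- subset_weights(w_all, merged$county_id)
if (length(w$islands)) {
  merged <- merged[!merged$county_id %in% w$islands, ]
  w <- subset_weights(w_all, merged$county_id)
}

set.seed(seed)
moran <- morans_i(merged$weighted_mean, w, n_permutations = 999)
cat(sprintf("Moran's I = %.3f (E = %.4f), permutation p = %.3g\n",
            moran$I, moran$expected, moran$p_perm))

X <- cbind(intercept = 1, pct_hispanic = merged$pct_hispanic / 10,
           pct_groundwater = merged$pct_groundwater,
           density = merged$density / 1000, svi = merged$svi)
lm_d <- lm_diagnostics(log(merged$weighted_mean), X, w)
cat(sprintf("LM-error = %.1f (p = %.3g); LM-lag = %.1f (p = %.3g)\n",
            lm_d$lm_error$statistic, lm_d$lm_error$p_value,
            lm_d$lm_lag$statistic, lm_d$lm_lag$p_value))

report <- run_models(merged, w, outcome = "weighted_mean")
print(report)
write.csv(report$table, "results/table3.csv", row.names = FALSE)

t2 <- describe_analysis_sets(merged)
write.csv(t2, "results/table2.csv", row.names = FALSE)

jsonlite::write_json(
  list(moran_I = moran$I, moran_p_perm = moran$p_perm,
       lm_error = lm_d$lm_error, lm_lag = lm_d$lm_lag),
  "results/diagnostics.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/table2.csv, results/table3.csv, results/diagnostics.json\n")
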