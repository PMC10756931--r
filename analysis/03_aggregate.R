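#!/usr/bin/env Rscript
# Stage 3: population-weighted county estimates.
#
# Aggregates system estimates to county weighted mean / P90 / P95
# concentrations with population-served weights, applies the 50% coverage
# rule against the public-water-reliant population, and computes the
# weighted percent of each county served by fluoridated systems.
#
# Usage: Rscript analysis/03_aggregate.R
library(cwsfluoride)

est <- read.csv("results/cws_estimates.csv", stringsAsFactors = FALSE)
inventory <- read.csv("results/data/inventory.csv", stringsAsFactors = FALSE)
counties <- read.csv("results/data/counties.csv", stringsAsFactors = FALSE)

cty <- aggregate_counties(est, inventory,
                          counties[c("county_id", "public_water_population")])
write.csv(cty, "results/county_estimates.csv", row.names = FALSE)

tab <- table(cty$status)
cat(sprintf("counties: %d included, %d inadequate (<50%% coverage), %d no data\n",
            tab[["included"]], if ("inadequate" %in% names(tab))
              tab[["inadequate"]] else 0L,
            if ("no_data" %in% names(tab)) tab[["no_data"]] else 0L))
inc <- cty[cty$included, ]
cat(sprintf("included-county weighted mean fluoride: mean %.0f, P90 %.0f ug/L\n",
            mean(inc$weighted_mean), quantile(inc$weighted_mean, 0.9)))
cat(sprintf("population-weighted %% fluoridated (mean over counties): %.1f%%\n",
            mean(inc$pct_fluoridated)))
cat("wrote results/county_estimates.csv\n")
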