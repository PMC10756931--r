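#' @keywords internal
"_PACKAGE"

#' @import data.table
#' @importFrom stats setNames
#' @importFrom methods as
NULL

utils::globalVariables(c(".", ".N", "system_id", "year", "value", "treated",
                         "nondetect", "ymean", "treated_only", "n_nd"))

#' Run configuration for the end-to-end pipeline
#'
#' A flat configuration driving [run_pipeline()]: either paths to the four
#' input CSVs (records, inventory, counties, adjacency) or a `simulate`
#' block, plus the averaging window, exceedance thresholds, county outcome,
#' composition scale, model set, permutation count and seed.  Readable from
#' a YAML file via [read_run_config()].
#'
#' @param records,inventory,counties,adjacency Input CSV paths (ignored when
#'   `simulate = TRUE`).
#' @param simulate Logical; generate synthetic inputs instead of reading.
#' @param sim_config A [synthetic_config()] used when `simulate = TRUE`.
#' @param window Averaging years (default 2006:2011).
#' @param thresholds Strictly increasing ug/L reference levels.
#' @param outcome `"weighted_mean"` or `"weighted_p95"`.
#' @param scale Composition scale in percentage points: 10 or 60.
#' @param models Subset of `c(1, 2)`.
#' @param n_permutations Moran permutation count (default 999).
#' @param seed Integer seed for all stochastic stages.
#' @param out_dir Output directory (created if needed); `NULL` for no files.
#' @return List of class `run_config`.
#' @export
run_config <- function(records = NULL, inventory = NULL, counties = NULL,
                       adjacency = NULL, simulate = is.null(records),
                       sim_config = synthetic_config(),
                       window = 2006:2011,
                       thresholds = c(700, 1500, 4000),
                       outcome = c("weighted_mean", "weighted_p95"),
                       scale = 10, models = c(1, 2),
                       n_permutations = 999, seed = 1L, out_dir = NULL) {
  outcome <- match.arg(outcome)
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing", call. = FALSE)
  if (!scale %in% c(10, 60)) stop("scale must be 10 or 60", call. = FALSE)
  if (window[1] > window[length(window)])
    stop("window start must be <= end", call. = FALSE)
  structure(list(records = records, inventory = inventory,
                 counties = counties, adjacency = adjacency,
                 simulate = simulate, sim_config = sim_config,
                 window = as.integer(window), thresholds = thresholds,
                 outcome = outcome, scale = scale, models = models,
                 n_permutations = n_permutations, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Flat keys mirror the [run_config()] arguments; a `simulate:` block maps
#' onto [synthetic_config()] fields.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_cfg <- if (!is.null(y$simulate_config))
    do.call(synthetic_config, y$simulate_config) else synthetic_config()
  args <- y[setdiff(names(y), "simulate_config")]
  args$sim_config <- sim_cfg
  if (!is.null(args$window) && length(args$window) == 2)
    args$window <- args$window[1]:args$window[2]
  do.call(run_config, args)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> CWS estimation -> county aggregation ->
#' spatial diagnostics -> spatial error models, and writes the report bundle:
#' `table1.csv` (subgroup summaries with exceedances and Kruskal-Wallis
#' p-values), `table2.csv` (analysis-set descriptives), `table3.csv` (GMRs
#' per composition scale with percent changes), `diagnostics.json` (Moran's
#' I, LM statistics, lambda estimates) and `qc_log.txt` (record, system and
#' county accounting).
#'
#' @param config A [run_config()].
#' @return List with all intermediate tables, diagnostics, the model report
#'   and the QC log (invisibly written to `config$out_dir` when set).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  qc <- list()
  if (config$simulate) {
    sim <- config$sim_config
    sim$seed <- config$seed
    dat <- simulate_fluoride_data(sim)
    records <- dat$records; inventory <- dat$inventory
    counties <- dat$counties; adjacency <- dat$adjacency
    truth <- dat$truth
  } else {
    records <- utils::read.csv(config$records, stringsAsFactors = FALSE)
    inventory <- utils::read.csv(config$inventory, stringsAsFactors = FALSE)
    counties <- utils::read.csv(config$counties, stringsAsFactors = FALSE)
    adjacency <- utils::read.csv(config$adjacency, stringsAsFactors = FALSE)
    truth <- NULL
    check_schema(records, c("system_id", "sample_date", "value", "units",
                            "lod", "detected", "sample_type"), "records")
    check_schema(inventory, c("system_id", "county_id", "population_served"),
                 "inventory")
    check_schema(counties, c("county_id", "public_water_population"),
                 "counties")
  }
  if (!"size_category" %in% names(inventory))
    inventory$size_category <- population_size_category(inventory$population_served)

  # --- CWS estimates -------------------------------------------------------
  est <- cws_estimates(records, window = config$window)
  qc$records <- attr(est, "qc")
  qc$n_records <- nrow(records)
  qc$n_detected <- sum(records$detected)
  qc$pct_detected <- percent_of_total(sum(records$detected), nrow(records))
  qc$n_systems <- nrow(est)

  inv_unique <- inventory[!duplicated(inventory$system_id), , drop = FALSE]
  table1 <- list()
  kw <- list()
  for (grp in intersect(c("source_type", "size_category", "region", "cluster",
                          "correctional", "fluoridation_reported"),
                        names(inventory))) {
    dedupe <- grp != "cluster"
    s <- summarize_subgroups(est, inventory, grp,
                             thresholds = config$thresholds, dedupe = dedupe)
    s$grouping <- grp
    table1[[grp]] <- s
    mm <- merge(if (dedupe) inv_unique else inventory, est, by = "system_id")
    g <- mm[[grp]]
    if (length(unique(g[!is.na(g)])) >= 2)
      kw[[grp]] <- kruskal_wallis(mm$mean_6yr, g)
  }
  table1 <- do.call(rbind, table1)
  rownames(table1) <- NULL

  # --- county aggregation --------------------------------------------------
  cty <- aggregate_counties(est, inventory,
                            counties[c("county_id", "public_water_population")])
  qc$n_counties_total <- nrow(cty)
  qc$n_counties_no_data <- sum(cty$status == "no_data")
  qc$n_counties_inadequate <- sum(cty$status == "inadequate")
  qc$n_counties_included <- sum(cty$status == "included")

  merged <- merge(cty[cty$included, , drop = FALSE], counties,
                  by = "county_id")

  # --- spatial diagnostics -------------------------------------------------
  w_all <- build_queen_weights(adjacency, counties$county_id)
  w_inc <- subset_weights(w_all, merged$county_id)
  if (length(w_inc$islands) > 0) {
    qc$n_island_counties <- length(w_inc$islands)
    merged <- merged[!merged$county_id %in% w_inc$islands, , drop = FALSE]
    w_inc <- subset_weights(w_all, merged$county_id)
  } else qc$n_island_counties <- 0L
  set.seed(config$seed)
  moran <- morans_i(merged$weighted_mean, w_inc,
                    n_permutations = config$n_permutations)
  X_diag <- cbind(intercept = 1,
                  pct_hispanic = merged$pct_hispanic / config$scale,
                  pct_groundwater = merged$pct_groundwater,
                  density = merged$density / 1000,
                  svi = merged$svi)
  lmres <- lm_diagnostics(log(merged[[config$outcome]]), X_diag, w_inc)

  # --- models --------------------------------------------------------------
  report <- run_models(merged, w_inc, outcome = config$outcome,
                       models = config$models, scale = config$scale)
  table3 <- report$table

  groups <- default_groups()
  table2 <- describe_analysis_sets(merged, groups, min_count = 100)

  diagnostics <- list(
    moran_I = moran$I, moran_p_norm = moran$p_norm,
    moran_p_perm = moran$p_perm,
    lm_error = lmres$lm_error, lm_lag = lmres$lm_lag,
    lambda = stats::setNames(table3$lambda,
                             paste(table3$group, table3$model)))

  out <- list(records = records, inventory = inventory, counties = counties,
              adjacency = adjacency, truth = truth, estimates = est,
              county_estimates = cty, merged = merged,
              table1 = table1, table2 = table2, table3 = table3,
              kruskal_wallis = kw, moran = moran, lm = lmres,
              models = report, diagnostics = diagnostics, qc = qc,
              weights = w_inc, config = config)

  if (!is.null(config$out_dir)) write_report_bundle(out, config$out_dir)
  out
}

check_schema <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s input is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}

#' Descriptive statistics for the model analysis sets
#'
#' One row for all included counties and one per group-specific analysis set
#' (counties with at least `min_count` residents of the group): n, mean (SD)
#' county fluoride, population, density, percent groundwater, SVI, and
#' composition percentages.
#'
#' @param merged Included-county table with covariates and `weighted_mean`.
#' @param groups Group map as in [default_groups()].
#' @param min_count Minimum group residents (default 100).
#' @param complement Also return rows for the excluded counties per group.
#' @return `data.frame`, one row per analysis set.
#' @export
describe_analysis_sets <- function(merged, groups = default_groups(),
                                   min_count = 100, complement = FALSE) {
  one <- function(label, d) {
    ms <- function(x) sprintf("%.3g (%.3g)", mean(x), stats::sd(x))
    data.frame(analysis_set = label, n = nrow(d),
               fluoride_mean = mean(d$weighted_mean),
               fluoride_sd = stats::sd(d$weighted_mean),
               population = ms(d$population),
               density = ms(d$density),
               pct_groundwater = ms(d$pct_groundwater),
               svi = ms(d$svi),
               pct_hispanic = ms(d$pct_hispanic),
               pct_nh_black = ms(d$pct_nh_black),
               pct_aian = ms(d$pct_aian),
               pct_nh_white = ms(d$pct_nh_white),
               stringsAsFactors = FALSE)
  }
  rows <- list(one("All included counties", merged))
  for (g in names(groups)) {
    sub <- restrict_by_group_count(merged, groups[[g]][["count"]], min_count)
    rows[[length(rows) + 1L]] <- one(g, sub)
    if (complement && nrow(sub) < nrow(merged))
      rows[[length(rows) + 1L]] <-
        one(paste0(g, " (excluded)"),
            merged[!merged$county_id %in% sub$county_id, , drop = FALSE])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

write_report_bundle <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$table1, file.path(out_dir, "table1.csv"),
                   row.names = FALSE)
  utils::write.csv(run$table2, file.path(out_dir, "table2.csv"),
                   row.names = FALSE)
  utils::write.csv(run$table3, file.path(out_dir, "table3.csv"),
                   row.names = FALSE)
  utils::write.csv(run$county_estimates,
                   file.path(out_dir, "county_estimates.csv"),
                   row.names = FALSE)
  utils::write.csv(run$estimates, file.path(out_dir, "cws_estimates.csv"),
                   row.names = FALSE)
  jsonlite::write_json(run$diagnostics,
                       file.path(out_dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  qc <- run$qc
  lines <- c("QC log",
             sprintf("records total: %d", qc$n_records),
             sprintf("records detected: %d (%.1f%%)", qc$n_detected,
                     qc$pct_detected),
             sprintf("records outside window dropped: %d",
                     qc$records$n_records_outside_window),
             sprintf("nondetects rejected (bad LOD): %d",
                     qc$records$n_nondetect_rejected),
             sprintf("systems with estimates: %d", qc$n_systems),
             sprintf("counties total: %d", qc$n_counties_total),
             sprintf("counties included: %d", qc$n_counties_included),
             sprintf("counties inadequate (<50%% coverage): %d",
                     qc$n_counties_inadequate),
             sprintf("counties no data: %d", qc$n_counties_no_data),
             sprintf("island counties dropped from spatial fits: %d",
                     qc$n_island_counties))
  writeLines(lines, file.path(out_dir, "qc_log.txt"))
  invisible(out_dir)
}
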