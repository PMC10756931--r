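#' Population-served weights within a county
#'
#' Each system's weight is its population served divided by the total
#' population served by all systems serving the county.
#'
#' @param population_served Positive populations of the systems serving one
#'   county.
#' @return Numeric weights summing to 1.
#' @export
compute_population_weights <- function(population_served) {
  if (length(population_served) == 0) stop("no systems", call. = FALSE)
  tot <- sum(population_served)
  if (tot <= 0) stop("zero total population served", call. = FALSE)
  population_served / tot
}

#' Population-weighted mean concentration
#'
#' @param values Concentrations (ug/L).
#' @param weights Weights summing to 1 (see [compute_population_weights()]).
#' @return `sum(weights * values)`.
#' @export
weighted_mean_conc <- function(values, weights) {
  if (length(values) != length(weights))
    stop("values/weights length mismatch", call. = FALSE)
  sum(weights * values)
}

#' Weighted quantile (cumulative-weight rule)
#'
#' With values sorted ascending, returns the smallest value whose cumulative
#' weight reaches `q` — a deterministic left-continuous definition.  An
#' interpolating estimator (Harrell-Davis-style linear interpolation of the
#' cumulative weights) is available behind `method = "interpolate"`.
#'
#' @param values Concentrations.
#' @param weights Weights summing to 1.
#' @param q Quantile in (0, 1), e.g. 0.90 or 0.95.
#' @param method `"cumulative"` (default) or `"interpolate"`.
#' @return Quantile value.
#' @export
weighted_quantile <- function(values, weights, q, method = c("cumulative",
                                                             "interpolate")) {
  method <- match.arg(method)
  if (length(values) == 0) stop("empty input", call. = FALSE)
  if (length(values) != length(weights))
    stop("values/weights length mismatch", call. = FALSE)
  stopifnot(q > 0, q < 1)
  o <- order(values)
  v <- values[o]; cw <- cumsum(weights[o])
  if (method == "cumulative") {
    v[which(cw >= q - 1e-12)[1]]
  } else {
    stats::approx(x = cw, y = v, xout = q, rule = 2, ties = "ordered")$y
  }
}

#' Coverage filter for county estimates
#'
#' A county's estimate is retained only when the systems serving it
#' cumulatively report serving at least fifty percent of the county's
#' public-water-reliant population (the boundary case of exactly 50% is
#' kept; "less than fifty percent" is excluded).
#'
#' @param served_population Total population served by systems with data.
#' @param public_water_population County public-water-reliant population.
#' @return Logical: include the county.
#' @export
apply_coverage_filter <- function(served_population, public_water_population) {
  if (any(is.na(public_water_population)) || any(public_water_population <= 0))
    stop("public water population missing or non-positive", call. = FALSE)
  served_population / public_water_population >= 0.5
}

#' Population-weighted percent of county on fluoridated systems
#'
#' `100 * sum(w_i * fluoridated_i)`; systems with missing fluoridation flags
#' are treated as not fluoridated (voluntary reporting is incomplete), with
#' the count of missing flags tracked by the aggregator.
#'
#' @param fluoridated Logical per system (NA treated as FALSE).
#' @param weights Weights summing to 1.
#' @return Percent in \[0, 100\].
#' @export
percent_fluoridated <- function(fluoridated, weights) {
  fl <- !is.na(fluoridated) & fluoridated
  100 * sum(weights[fl])
}

#' Aggregate CWS estimates to population-weighted county estimates
#'
#' Joins system estimates to the inventory, computes population-served
#' weights per county, and produces the weighted mean, 90th and 95th
#' percentile county concentrations, the coverage fraction against the
#' public-water-reliant population, and the percent of the served population
#' on fluoridated systems.  Counties are labelled `included`
#' (coverage >= 50%), `inadequate` (coverage < 50%) or `no_data` (no systems
#' with estimates, or missing denominator).  Multi-county systems contribute
#' their full population served to every county they serve.
#'
#' @param estimates CWS estimate table (`system_id`, `mean_6yr`).
#' @param systems Inventory (`system_id`, `county_id`, `population_served`,
#'   `fluoridation_reported`); one row per system-county pair.
#' @param county_pop `data.frame` with `county_id` and
#'   `public_water_population`.
#' @return `data.frame`: `county_id`, `weighted_mean`, `weighted_p90`,
#'   `weighted_p95`, `n_systems`, `coverage_fraction`, `pct_fluoridated`,
#'   `n_fluoridation_missing`, `status`, `included`.
#' @export
aggregate_counties <- function(estimates, systems, county_pop) {
  m <- merge(systems, estimates, by = "system_id")
  per_county <- split(m, m$county_id)
  rows <- lapply(per_county, function(d) {
    wts <- compute_population_weights(d$population_served)
    data.frame(
      county_id = d$county_id[1],
      weighted_mean = weighted_mean_conc(d$mean_6yr, wts),
      weighted_p90 = weighted_quantile(d$mean_6yr, wts, 0.90),
      weighted_p95 = weighted_quantile(d$mean_6yr, wts, 0.95),
      n_systems = nrow(d),
      served_population = sum(d$population_served),
      pct_fluoridated = percent_fluoridated(d$fluoridation_reported, wts),
      n_fluoridation_missing = sum(is.na(d$fluoridation_reported)),
      stringsAsFactors = FALSE)
  })
  agg <- do.call(rbind, rows)
  out <- merge(county_pop, agg, by = "county_id", all.x = TRUE)
  has_data <- !is.na(out$weighted_mean) & !is.na(out$public_water_population) &
    out$public_water_population > 0
  out$coverage_fraction <- ifelse(has_data,
    out$served_population / out$public_water_population, NA_real_)
  out$included <- has_data & out$coverage_fraction >= 0.5
  out$status <- ifelse(!has_data, "no_data",
                       ifelse(out$included, "included", "inadequate"))
  out <- out[order(out$county_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict counties by minimum subgroup population
#'
#' Keeps counties with at least `min_count` residents of the group of
#' interest (positivity restriction for the composition models).
#'
#' @param counties County table containing the count column.
#' @param count_col Name of the residents-count column (e.g.
#'   `count_hispanic`).
#' @param min_count Minimum residents (default 100).
#' @return Subset of `counties`.
#' @export
restrict_by_group_count <- function(counties, count_col, min_count = 100) {
  if (!count_col %in% names(counties))
    stop("unknown group count column: ", count_col, call. = FALSE)
  counties[counties[[count_col]] >= min_count, , drop = FALSE]
}
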