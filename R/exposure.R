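#' Convert monitoring records to micrograms per litre
#'
#' Concentrations and LODs arrive in a mix of mg/L and ug/L; everything is
#' converted to ug/L (mg/L values multiplied by 1000) so estimates are
#' directly comparable to the 700 / 1500 / 4000 ug/L reference levels.
#'
#' @param records Monitoring-record `data.frame` with `value`, `lod`,
#'   `units` columns (`"mg/L"` or `"ug/L"`; the Unicode micro sign is
#'   accepted).
#' @return Records with `value` and `lod` in ug/L and `units = "ug/L"`.
#' @export
standardize_units <- function(records) {
  units <- as.character(records$units)
  units[units %in% c("µg/L", "μg/L", "ug/l", "UG/L")] <- "ug/L"
  units[units %in% c("mg/l", "MG/L")] <- "mg/L"
  bad <- !units %in% c("mg/L", "ug/L")
  if (any(bad))
    stop("unrecognized concentration unit in record(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  f <- ifelse(units == "mg/L", 1000, 1)
  records$value <- records$value * f
  records$lod <- records$lod * f
  records$units <- "ug/L"
  records
}

#' Substitute left-censored nondetects
#'
#' Records below the limit of detection are assigned the record-specific
#' LOD divided by the square root of two, the standard substitution for
#' left-censored compliance data; detected records are unchanged.
#' Nondetects with a missing or non-positive LOD cannot be imputed and are
#' dropped with a warning (count retained in `attr(, "n_rejected")`).
#'
#' @param records Monitoring records with `value`, `lod`, `detected`.
#' @return Records with all nondetect values imputed as `lod / sqrt(2)`.
#' @export
substitute_nondetects <- function(records) {
  nd <- !records$detected
  bad <- nd & (is.na(records$lod) | records$lod <= 0)
  if (any(bad)) {
    warning(sprintf("%d nondetect record(s) with missing/non-positive LOD dropped",
                    sum(bad)), call. = FALSE)
    records <- records[!bad, , drop = FALSE]
    nd <- !records$detected
  }
  records$value[nd] <- records$lod[nd] / sqrt(2)
  out <- records
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Yearly average for one system-year with the treated/raw rule
#'
#' The default yearly average is the arithmetic mean of all samples in the
#' calendar year.  When both treated (finished) and raw (untreated) samples
#' exist and the raw mean exceeds the treated mean, the average uses treated
#' samples only, reflecting the water actually distributed to consumers.  A
#' year with only raw samples uses the raw mean (there is no treated
#' comparator to override it).
#'
#' @param values Concentrations (ug/L) for one system and calendar year.
#' @param sample_type Character vector (`"treated"` / `"raw"`), same length.
#' @return List with `mean` (ug/L) and `treated_only` (logical flag).
#' @export
yearly_average <- function(values, sample_type) {
  if (length(values) == 0) stop("no records in system-year", call. = FALSE)
  stopifnot(length(values) == length(sample_type))
  tr <- sample_type == "treated"
  if (any(tr) && any(!tr)) {
    mt <- mean(values[tr]); mr <- mean(values[!tr])
    if (mr > mt) return(list(mean = mt, treated_only = TRUE))
  }
  list(mean = mean(values), treated_only = FALSE)
}

#' Chronic multi-year average from yearly means
#'
#' The unweighted arithmetic mean of the yearly averages falling inside the
#' window; a system with no yearly mean in the window is omitted upstream.
#'
#' @param yearly_means Named numeric vector (names = years) of yearly
#'   averages (ug/L).
#' @param window Integer vector of calendar years (default 2006:2011).
#' @return Mean concentration (ug/L) over the years present in the window.
#' @export
chronic_average <- function(yearly_means, window = 2006:2011) {
  keep <- as.integer(names(yearly_means)) %in% window
  if (!any(keep)) stop("no yearly means inside the averaging window", call. = FALSE)
  mean(yearly_means[keep])
}

#' CWS-level chronic fluoride estimates from monitoring records
#'
#' The full record-to-system pipeline: unit standardization, nondetect
#' substitution at LOD/sqrt(2), within-year averaging with the treated/raw
#' override, and the unweighted mean of yearly averages across the window.
#'
#' @param records Monitoring-record `data.frame` (`system_id`, `sample_date`,
#'   `value`, `units`, `lod`, `detected`, `sample_type`).
#' @param window Integer years to average over (default 2006:2011).
#' @return `data.frame` with one row per system: `system_id`, `mean_6yr`
#'   (ug/L), `n_records`, `n_nondetect`, `n_years`, `any_raw_override`.
#'   QC counts (records outside window, rejected nondetects, negative
#'   values dropped) are in `attr(, "qc")`.
#' @export
cws_estimates <- function(records, window = 2006:2011) {
  stopifnot(all(c("system_id", "sample_date", "value", "units", "lod",
                  "detected", "sample_type") %in% names(records)))
  records <- standardize_units(records)
  neg <- records$detected & !is.na(records$value) & records$value < 0
  if (any(neg)) records <- records[!neg, , drop = FALSE]
  n_rej <- 0L
  records <- withCallingHandlers(
    substitute_nondetects(records),
    warning = function(w) invokeRestart("muffleWarning"))
  n_rej <- attr(records, "n_rejected")

  yr <- as.integer(format(as.Date(records$sample_date), "%Y"))
  outside <- !yr %in% window
  n_outside <- sum(outside)
  records <- records[!outside, , drop = FALSE]
  yr <- yr[!outside]
  if (nrow(records) == 0) stop("no records inside the averaging window", call. = FALSE)

  dt <- data.table::data.table(system_id = records$system_id, year = yr,
                               value = records$value,
                               treated = records$sample_type == "treated",
                               nondetect = !records$detected)
  yearly <- dt[, {
    mt <- if (any(treated)) mean(value[treated]) else NA_real_
    mr <- if (any(!treated)) mean(value[!treated]) else NA_real_
    override <- !is.na(mt) && !is.na(mr) && mr > mt
    list(ymean = if (override) mt else mean(value),
         treated_only = override,
         n = .N, n_nd = sum(nondetect))
  }, by = .(system_id, year)]
  est <- yearly[, list(mean_6yr = mean(ymean),
                       n_records = sum(n),
                       n_nondetect = sum(n_nd),
                       n_years = .N,
                       any_raw_override = any(treated_only)),
                by = .(system_id)]
  out <- as.data.frame(est)
  out <- out[order(out$system_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "qc") <- list(n_records_outside_window = n_outside,
                          n_nondetect_rejected = n_rej,
                          n_negative_dropped = sum(neg))
  out
}

#' Percent of a total, reported at one decimal
#'
#' `100 * count / total`, rounded half-even to one decimal place — the
#' reporting convention behind all count/percent summaries.
#'
#' @param count,total Non-negative counts with `count <= total`, `total > 0`.
#' @return Percent rounded to one decimal.
#' @export
percent_of_total <- function(count, total) {
  if (any(total <= 0)) stop("total must be > 0", call. = FALSE)
  if (any(count < 0) || any(count > total))
    stop("count must lie in [0, total]", call. = FALSE)
  round(100 * count / total, 1)
}

#' Count systems exceeding reference concentrations
#'
#' For each threshold, the number of systems whose chronic average is
#' strictly above it, the percent of systems, and the total population
#' served by exceeding systems.  Default thresholds are the optimal
#' fluoridation level (700), the WHO guideline (1500) and the EPA MCL
#' (4000 ug/L).
#'
#' @param estimates CWS estimate table with `mean_6yr`.
#' @param thresholds Numeric vector of ug/L levels.
#' @param population_served Optional vector aligned with `estimates`.
#' @return `data.frame`: `threshold`, `n_exceed`, `pct_exceed`,
#'   `population_exceed`.
#' @export
count_exceedances <- function(estimates, thresholds = c(700, 1500, 4000),
                              population_served = NULL) {
  x <- estimates$mean_6yr
  n <- length(x)
  res <- lapply(thresholds, function(th) {
    ex <- x > th
    data.frame(threshold = th, n_exceed = sum(ex),
               pct_exceed = percent_of_total(sum(ex), n),
               population_exceed = if (is.null(population_served)) NA_real_
                                   else sum(population_served[ex]))
  })
  do.call(rbind, res)
}

#' Subgroup summaries of CWS fluoride (stratified reporting)
#'
#' Per level of the grouping variable: number of systems, mean with a 95%
#' normal-approximation CI (`mean +/- 1.96 sd/sqrt(n)`), empirical 90th and
#' 95th percentiles (linear interpolation between order statistics),
#' exceedance counts/percents at each threshold, and total population
#' served.  For cluster-based grouping, systems serving counties in several
#' clusters appear once per cluster (pass the inventory unduplicated by
#' system for other groupings via `dedupe = TRUE`).
#'
#' @param estimates CWS estimate table (`system_id`, `mean_6yr`).
#' @param systems Inventory table (one row per system-county pair).
#' @param grouping Column of `systems` to stratify by (e.g. `source_type`,
#'   `size_category`, `region`, `cluster`, `correctional`,
#'   `fluoridation_reported`).
#' @param thresholds ug/L reference levels (default 700/1500/4000).
#' @param dedupe Drop duplicate system rows before grouping (default TRUE;
#'   set FALSE for the cluster analysis so multi-county systems count once
#'   per cluster).
#' @return `data.frame`, one row per group, plus an `"All"` row.
#' @export
summarize_subgroups <- function(estimates, systems, grouping,
                                thresholds = c(700, 1500, 4000),
                                dedupe = TRUE) {
  stopifnot(grouping %in% names(systems))
  sys <- systems
  if (dedupe) {
    sys <- sys[!duplicated(sys$system_id), , drop = FALSE]
  } else {
    # one row per system x group level
    sys <- sys[!duplicated(sys[c("system_id", grouping)]), , drop = FALSE]
  }
  m <- merge(sys, estimates, by = "system_id")
  grp_row <- function(label, d) {
    n <- nrow(d)
    if (n == 0) {
      row <- data.frame(group = label, n_systems = 0L, mean = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        p90 = NA_real_, p95 = NA_real_,
                        population_total = 0)
      for (th in thresholds) {
        row[[paste0("n_exceed_", th)]] <- 0L
        row[[paste0("pct_exceed_", th)]] <- NA_real_
      }
      return(row)
    }
    x <- d$mean_6yr
    mu <- mean(x); sdev <- stats::sd(x)
    half <- if (n > 1) 1.96 * sdev / sqrt(n) else NA_real_
    row <- data.frame(group = label, n_systems = n, mean = mu,
                      ci_low = mu - half, ci_high = mu + half,
                      p90 = unname(stats::quantile(x, 0.90, type = 7)),
                      p95 = unname(stats::quantile(x, 0.95, type = 7)),
                      population_total = sum(d$population_served))
    for (th in thresholds) {
      row[[paste0("n_exceed_", th)]] <- sum(x > th)
      row[[paste0("pct_exceed_", th)]] <- percent_of_total(sum(x > th), n)
    }
    row
  }
  g <- m[[grouping]]
  levs <- if (is.factor(g)) levels(g) else sort(unique(g[!is.na(g)]))
  rows <- lapply(levs, function(lv) grp_row(as.character(lv),
                                            m[!is.na(g) & g == lv, , drop = FALSE]))
  all_row <- grp_row("All", m)
  out <- rbind(all_row, do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Kruskal-Wallis rank test across subgroups
#'
#' Rank-based H with the standard mid-rank ties correction, referred to
#' chi-square with (k - 1) degrees of freedom.  Degenerate input where every
#' observation is identical returns H = 0, p = 1 (no rank variation).
#'
#' @param values Numeric vector of system estimates.
#' @param groups Grouping vector, same length; at least two non-empty groups.
#' @return List with `statistic` (H), `p_value`, `df`.
#' @export
kruskal_wallis <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.factor(as.character(groups[keep]))
  if (nlevels(droplevels(groups)) < 2)
    stop("need at least two non-empty groups", call. = FALSE)
  groups <- droplevels(groups)
  if (length(unique(values)) == 1L)
    return(list(statistic = 0, p_value = 1, df = nlevels(groups) - 1L))
  kt <- stats::kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}
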