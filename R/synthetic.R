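#' Configuration for the synthetic drinking-water data generator
#'
#' Builds a validated configuration for [simulate_fluoride_data()].  The
#' generator emulates the four inputs of the exposure pipeline: compliance
#' monitoring records, a water-system inventory, county sociodemographic
#' covariates, and county adjacency.  Counties live on an
#' `n_county_rows` x `n_county_cols` rectangular grid with queen (8-neighbour)
#' contiguity, a stand-in for real county topology that reproduces the
#' contiguity-matrix machinery without shapefiles.
#'
#' The county latent log fluoride surface is `X beta + u`, where the
#' composition columns of `X` are scaled as percent/10 (so `exp(beta)` is a
#' geometric mean ratio per 10 percentage points), `% groundwater` is scaled
#' per 10 percentage points, density per 1000 persons/sq mi, SVI on its raw
#' 0-1 scale, and `u` follows a simultaneous autoregressive error process
#' `u = lambda_true W u + eps`, `eps ~ N(0, sigma_spatial^2)` on the
#' row-standardized queen weights.
#'
#' @param n_county_rows,n_county_cols Grid dimensions (each >= 2).
#' @param systems_per_county_mean Mean number of water systems per county;
#'   counts are `1 + Poisson(mean - 1)` so every county has at least one.
#' @param pop_served_range Relative log-uniform range of system sizes within
#'   a county; systems partition the covered share of the county's
#'   public-water-reliant population in these proportions.
#' @param frac_low_coverage Proportion of counties whose monitored systems
#'   cover less than half the public-water-reliant population (these fail
#'   the 50\% coverage filter downstream); remaining counties are covered at
#'   55-100\%.
#' @param frac_groundwater_systems Proportion of systems on groundwater.
#' @param beta Named numeric vector of generative coefficients on the log
#'   micrograms-per-litre scale.  Recognised names: `intercept`,
#'   `pct_hispanic`, `pct_nh_black`, `pct_aian`, `pct_groundwater`,
#'   `density`, `svi` (composition and groundwater per 10 percentage points).
#' @param lambda_true Spatial error parameter, strictly inside (-1, 1).
#' @param sigma_spatial,sigma_cws,sigma_record Positive standard deviations
#'   (log scale) of the county spatial innovation, the between-system effect,
#'   and record-level noise.
#' @param lod_ug_l Record limit of detection in micrograms/litre (scalar or a
#'   vector sampled per record).  The default of 410 puts roughly 30\% of
#'   generated records below the LOD under the default configuration.
#' @param frac_raw_samples Proportion of records flagged as raw (untreated).
#' @param raw_bias Multiplicative bias (>= 1 by default) applied to raw
#'   samples, so the treated/raw yearly reconciliation rule is exercised.
#' @param frac_mg_l Proportion of records reported in mg/L (others in ug/L).
#' @param frac_fluoridated Proportion of systems reporting manual
#'   fluoridation among those with fluoridation data.
#' @param frac_fluoridation_missing Proportion of systems with missing
#'   fluoridation data (voluntary reporting is incomplete).
#' @param fluoridation_setpoint_ug_l Fluoridated systems have their latent
#'   mean raised to at least `log(setpoint)` (the optimal-level target).
#' @param frac_multi_county Proportion of systems serving a second county
#'   (duplicated per county served, mirroring inventory conventions).
#' @param years Inclusive calendar-year range of monitoring records.
#' @param seed Integer seed; per-table sub-streams are derived from it
#'   deterministically (covariates seed+1, inventory seed+2, records seed+3).
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_county_rows = 20L,
                             n_county_cols = 20L,
                             systems_per_county_mean = 12,
                             pop_served_range = c(500, 5e4),
                             frac_low_coverage = 0.15,
                             frac_groundwater_systems = 0.8,
                             beta = c(intercept = log(300),
                                      pct_hispanic = log(1.15),
                                      pct_nh_black = 0,
                                      pct_aian = 0,
                                      pct_groundwater = log(1.03),
                                      density = 0,
                                      svi = 0.1),
                             lambda_true = 0.5,
                             sigma_spatial = 0.6,
                             sigma_cws = 0.15,
                             sigma_record = 0.15,
                             lod_ug_l = 410,
                             frac_raw_samples = 0.3,
                             raw_bias = 1.1,
                             frac_mg_l = 0.5,
                             frac_fluoridated = 0.24,
                             frac_fluoridation_missing = 0.21,
                             fluoridation_setpoint_ug_l = 700,
                             frac_multi_county = 0,
                             years = 2006:2011,
                             seed = 1L) {
  cfg <- list(n_county_rows = as.integer(n_county_rows),
              n_county_cols = as.integer(n_county_cols),
              systems_per_county_mean = systems_per_county_mean,
              pop_served_range = pop_served_range,
              frac_low_coverage = frac_low_coverage,
              frac_groundwater_systems = frac_groundwater_systems,
              beta = beta,
              lambda_true = lambda_true,
              sigma_spatial = sigma_spatial,
              sigma_cws = sigma_cws,
              sigma_record = sigma_record,
              lod_ug_l = lod_ug_l,
              frac_raw_samples = frac_raw_samples,
              raw_bias = raw_bias,
              frac_mg_l = frac_mg_l,
              frac_fluoridated = frac_fluoridated,
              frac_fluoridation_missing = frac_fluoridation_missing,
              fluoridation_setpoint_ug_l = fluoridation_setpoint_ug_l,
              frac_multi_county = frac_multi_county,
              years = as.integer(years),
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  stopifnot(cfg$n_county_rows >= 2L, cfg$n_county_cols >= 2L)
  if (!(cfg$sigma_spatial > 0 && cfg$sigma_cws >= 0 && cfg$sigma_record >= 0))
    stop("sigmas must be positive (sigma_spatial strictly)", call. = FALSE)
  if (abs(cfg$lambda_true) >= 1)
    stop("lambda_true must satisfy |lambda_true| < 1", call. = FALSE)
  if (any(cfg$lod_ug_l <= 0)) stop("lod_ug_l must be > 0", call. = FALSE)
  for (p in c("frac_groundwater_systems", "frac_low_coverage",
              "frac_raw_samples", "frac_mg_l",
              "frac_fluoridated", "frac_fluoridation_missing",
              "frac_multi_county")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop(sprintf("%s must lie in [0, 1]", p), call. = FALSE)
  }
  if (cfg$systems_per_county_mean < 1)
    stop("systems_per_county_mean must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' Queen-contiguity edge list for a rectangular county grid
#'
#' Two grid cells are neighbours iff their row and column indices each differ
#' by at most one (8-neighbourhood), the lattice analogue of queen contiguity
#' in which counties sharing any boundary point, including a corner, are
#' neighbours.
#'
#' @param n_rows,n_cols Positive grid dimensions.
#' @return A `data.frame` with columns `county_a`, `county_b` (county ids
#'   `"C<index>"`, row-major, each undirected pair listed once with a < b).
#' @examples
#' generate_grid_adjacency(2, 2)   # complete graph on four cells: 6 edges
#' @export
generate_grid_adjacency <- function(n_rows, n_cols) {
  if (n_rows < 1 || n_cols < 1) stop("grid dimensions must be >= 1", call. = FALSE)
  idx <- function(r, c) (r - 1L) * n_cols + c   # row-major 1-based
  from <- integer(0); to <- integer(0)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    r <- rep(seq_len(n_rows), each = n_cols)
    c <- rep(seq_len(n_cols), times = n_rows)
    r2 <- r + dr; c2 <- c + dc
    ok <- r2 >= 1 & r2 <= n_rows & c2 >= 1 & c2 <= n_cols
    from <- c(from, idx(r, c)[ok])
    to <- c(to, idx(r2, c2)[ok])
  }
  keep <- from < to            # each undirected edge once
  from <- from[keep]; to <- to[keep]
  o <- order(from, to)
  data.frame(county_a = paste0("C", from[o]),
             county_b = paste0("C", to[o]),
             stringsAsFactors = FALSE)
}

# Simultaneous-autoregressive Gaussian field: u = lambda W u + eps, solved as
# u = (I - lambda W)^{-1} eps with sparse row-standardized W.
sar_field <- function(W, lambda, sigma) {
  n <- nrow(W)
  eps <- stats::rnorm(n, 0, sigma)
  if (lambda == 0) return(eps)
  A <- Matrix::Diagonal(n) - lambda * W
  as.numeric(Matrix::solve(A, eps))
}

#' Generate county covariates and the latent fluoride surface
#'
#' Produces per-county racial/ethnic composition (Hispanic/Latino,
#' non-Hispanic Black, American Indian/Alaskan Native, non-Hispanic White),
#' population, density, socioeconomic vulnerability (SVI, 0-1), percent of
#' public water from groundwater, region and sociodemographic-cluster labels,
#' and the county latent log-mean fluoride
#' `X beta_true + u`, `u = lambda W u + eps` realized by solving
#' `(I - lambda W) u = eps` with the row-standardized queen weights.
#' Composition percentages are generated from spatially autocorrelated
#' logit-normal fields so that covariates themselves carry spatial structure,
#' as real county demographics do.
#'
#' @param config A [synthetic_config()].
#' @param adjacency Edge list from [generate_grid_adjacency()] covering all
#'   counties of the configured grid.
#' @return A list with `counties` (data.frame) and `truth` (list with
#'   `beta_true`, `lambda_true`, `gmr_true_per_10pct`,
#'   `county_latent_log_mean`).
#' @export
generate_county_covariates <- function(config, adjacency) {
  validate_synthetic_config(config)
  n <- config$n_county_rows * config$n_county_cols
  ids <- paste0("C", seq_len(n))
  w <- build_queen_weights(adjacency, ids)
  if (abs(config$lambda_true) >= 1)
    stop("lambda_true outside the invertibility range of (I - lambda W)",
         call. = FALSE)
  set.seed(config$seed + 1L)

  s_hisp <- sar_field(w$W, 0.4, 1); s_hisp <- s_hisp / stats::sd(s_hisp)
  s_blk <- sar_field(w$W, 0.4, 1); s_blk <- s_blk / stats::sd(s_blk)
  s_aian <- sar_field(w$W, 0.4, 1); s_aian <- s_aian / stats::sd(s_aian)
  s_gw <- sar_field(w$W, 0.4, 1); s_gw <- s_gw / stats::sd(s_gw)

  pct_hispanic <- 100 * stats::plogis(-2.2 + 1.3 * s_hisp)
  pct_nh_black <- 100 * stats::plogis(-3.0 + 1.4 * s_blk)
  pct_aian <- 100 * stats::plogis(-4.3 + 1.2 * s_aian)
  pct_other <- 100 * stats::plogis(-3.4 + 0.5 * stats::rnorm(n))
  # remaining share; rescale the minority shares in the rare case they exceed 100
  tot_min <- pct_hispanic + pct_nh_black + pct_aian + pct_other
  over <- tot_min > 100
  if (any(over)) {
    sc <- 100 / tot_min[over]
    pct_hispanic[over] <- pct_hispanic[over] * sc
    pct_nh_black[over] <- pct_nh_black[over] * sc
    pct_aian[over] <- pct_aian[over] * sc
    pct_other[over] <- pct_other[over] * sc
  }
  pct_nh_white <- pmax(0, 100 - (pct_hispanic + pct_nh_black + pct_aian +
                                   pct_other))

  population <- round(stats::rlnorm(n, meanlog = log(25000), sdlog = 1.4))
  population <- pmax(population, 1000)
  area_sqmi <- stats::rlnorm(n, meanlog = log(600), sdlog = 0.6)
  density <- population / area_sqmi
  svi <- stats::plogis(0.9 * (0.6 * s_hisp + 0.8 * stats::rnorm(n)))
  pct_groundwater <- 100 * stats::plogis(1.0 + 2.0 * s_gw)

  # region: 8 blocks of the grid (4 column-bands x 2 row-bands)
  row_i <- (seq_len(n) - 1L) %/% config$n_county_cols + 1L
  col_i <- (seq_len(n) - 1L) %% config$n_county_cols + 1L
  rb <- pmin(2L, 1L + (row_i - 1L) %/% max(1L, ceiling(config$n_county_rows / 2)))
  cb <- pmin(4L, 1L + (col_i - 1L) %/% max(1L, ceiling(config$n_county_cols / 4)))
  region_names <- c("Alaska/Hawaii", "Central Midwest", "Eastern Midwest",
                    "Mid-Atlantic", "New England", "Pacific Northwest",
                    "Southeast", "Southwest")
  region <- region_names[(rb - 1L) * 4L + cb]
  cluster_names <- c("Semi-Urban, High SES", "Semi-Urban, Mid/Low SES",
                     "Semi-Urban, Hispanic", "Mostly Rural, Mid-SES",
                     "Rural, Mid/Low SES", "Young, Urban, Mid/High SES",
                     "Rural, American Indian", "Rural, High SES")
  cluster <- sample(cluster_names, n, replace = TRUE,
                    prob = c(0.38, 0.04, 0.14, 0.24, 0.015, 0.03, 0.013, 0.14))

  X <- latent_design(pct_hispanic, pct_nh_black, pct_aian,
                     pct_groundwater, density, svi)
  beta <- config$beta[colnames(X)]
  beta[is.na(beta)] <- 0
  u <- sar_field(w$W, config$lambda_true, config$sigma_spatial)
  latent <- as.numeric(X %*% beta) + u

  counties <- data.frame(
    county_id = ids,
    pct_hispanic = pct_hispanic, pct_nh_black = pct_nh_black,
    pct_aian = pct_aian, pct_nh_white = pct_nh_white,
    population = population, density = density, svi = svi,
    pct_groundwater = pct_groundwater,
    count_hispanic = round(population * pct_hispanic / 100),
    count_nh_black = round(population * pct_nh_black / 100),
    count_aian = round(population * pct_aian / 100),
    count_nh_white = round(population * pct_nh_white / 100),
    region = region, cluster = cluster,
    public_water_population = round(population *
      stats::runif(n, 0.55, 0.95)),
    latent_log_mean = latent,
    stringsAsFactors = FALSE)

  comp <- intersect(names(config$beta),
                    c("pct_hispanic", "pct_nh_black", "pct_aian"))
  truth <- list(beta_true = beta,
                lambda_true = config$lambda_true,
                gmr_true_per_10pct = exp(config$beta[comp]),
                county_latent_log_mean = latent)
  list(counties = counties, truth = truth)
}

# Design matrix of the generative latent model; composition and groundwater
# per 10 percentage points, density per 1000 persons/sq mi, SVI raw.
latent_design <- function(pct_hispanic, pct_nh_black, pct_aian,
                          pct_groundwater, density, svi) {
  cbind(intercept = 1,
        pct_hispanic = pct_hispanic / 10,
        pct_nh_black = pct_nh_black / 10,
        pct_aian = pct_aian / 10,
        pct_groundwater = pct_groundwater / 10,
        density = density / 1000,
        svi = svi)
}

#' Generate a water-system inventory
#'
#' Each system serves one county (a configurable fraction serve a second,
#' appearing once per county served), with population served drawn
#' log-uniformly, source type (groundwater/surface), region and cluster
#' labels inherited from the county, tribal/correctional/fluoridation flags,
#' and the EPA population-served size category (cut-points 500, 3300,
#' 10,000 persons).
#'
#' @param config A [synthetic_config()].
#' @param counties County table from [generate_county_covariates()].
#' @return A `data.frame`, one row per system-county pair.
#' @export
generate_system_inventory <- function(config, counties) {
  validate_synthetic_config(config)
  set.seed(config$seed + 2L)
  n_cty <- nrow(counties)
  n_sys_cty <- 1L + stats::rpois(n_cty, config$systems_per_county_mean - 1)
  county_of <- rep(counties$county_id, n_sys_cty)
  n_sys <- length(county_of)
  # systems partition the covered share of the county public-water population
  # in log-uniform relative sizes; a configured fraction of counties are
  # covered below the 50% threshold used by the downstream coverage filter
  lo <- log(config$pop_served_range[1]); hi <- log(config$pop_served_range[2])
  size_raw <- exp(stats::runif(n_sys, lo, hi))
  coverage <- ifelse(stats::runif(n_cty) < config$frac_low_coverage,
                     stats::runif(n_cty, 0.15, 0.49),
                     stats::runif(n_cty, 0.55, 1.0))
  pwp <- counties$public_water_population[match(county_of, counties$county_id)]
  county_tot <- tapply(size_raw, county_of, sum)
  share <- size_raw / as.numeric(county_tot[as.character(county_of)])
  pop <- pmax(25, round(share * coverage[match(county_of, counties$county_id)] *
                          pwp))
  fl <- ifelse(stats::runif(n_sys) < config$frac_fluoridation_missing, NA,
               stats::runif(n_sys) < config$frac_fluoridated)
  inv <- data.frame(
    system_id = sprintf("S%05d", seq_len(n_sys)),
    county_id = county_of,
    population_served = pop,
    source_type = ifelse(stats::runif(n_sys) < config$frac_groundwater_systems,
                         "groundwater", "surface"),
    tribal = stats::runif(n_sys) < 0.02,
    correctional = stats::runif(n_sys) < 0.006,
    fluoridation_reported = as.logical(fl),
    stringsAsFactors = FALSE)
  if (config$frac_multi_county > 0) {
    pick <- which(stats::runif(n_sys) < config$frac_multi_county)
    if (length(pick)) {
      # duplicate the system under a random different county
      second <- vapply(inv$county_id[pick], function(cid)
        sample(setdiff(counties$county_id, cid), 1L), character(1))
      dup <- inv[pick, ]; dup$county_id <- second
      inv <- rbind(inv, dup)
    }
  }
  m <- match(inv$county_id, counties$county_id)
  inv$region <- counties$region[m]
  inv$cluster <- counties$cluster[m]
  inv$size_category <- population_size_category(inv$population_served)
  rownames(inv) <- NULL
  inv
}

#' EPA population-served size category
#'
#' Standard EPA categories: at most 500, 501-3300, 3301-10,000 and more than
#' 10,000 persons.
#'
#' @param population_served Numeric vector of persons (> 0).
#' @return Factor with levels `<=500`, `501-3300`, `3301-10000`, `>10000`.
#' @export
population_size_category <- function(population_served) {
  cut(population_served, breaks = c(0, 500, 3300, 10000, Inf),
      labels = c("<=500", "501-3300", "3301-10000", ">10000"),
      include.lowest = FALSE)
}

#' Generate compliance monitoring records
#'
#' Systems receive at least one record per three-year compliance window
#' (yearly for surface-water systems) across the configured years.  A record's
#' concentration is `exp(county latent log mean + system effect + noise)`,
#' with fluoridated systems' latent mean raised to at least the fluoridation
#' set-point.  Raw (untreated) samples receive a multiplicative bias; a
#' configured fraction of records are reported in mg/L; values below the
#' record LOD are flagged nondetect and blanked.
#'
#' @param config A [synthetic_config()].
#' @param inventory Inventory from [generate_system_inventory()].
#' @param county_latent Named numeric vector (or county table) of latent
#'   log-mean fluoride per county id.
#' @return `data.frame` with columns `system_id`, `sample_date`, `value`,
#'   `units`, `lod`, `detected`, `sample_type`.
#' @export
generate_monitoring_records <- function(config, inventory, county_latent) {
  validate_synthetic_config(config)
  if (is.data.frame(county_latent))
    county_latent <- stats::setNames(county_latent$latent_log_mean,
                                     county_latent$county_id)
  if (nrow(inventory) == 0) stop("empty inventory", call. = FALSE)
  set.seed(config$seed + 3L)
  # unique systems (multi-county systems monitored once)
  inv <- inventory[!duplicated(inventory$system_id), ]
  n_sys <- nrow(inv)
  sys_eff <- stats::rnorm(n_sys, 0, config$sigma_cws)
  latent_sys <- county_latent[inv$county_id] + sys_eff
  fl <- !is.na(inv$fluoridation_reported) & inv$fluoridation_reported
  latent_sys[fl] <- pmax(latent_sys[fl], log(config$fluoridation_setpoint_ug_l))

  years <- config$years
  # sampling years: surface systems yearly; groundwater one random year per
  # 3-year compliance window
  rec_sys <- list(); rec_year <- list()
  windows <- split(years, (seq_along(years) - 1L) %/% 3L)
  gw <- inv$source_type == "groundwater"
  if (any(!gw)) {
    rec_sys[["sw"]] <- rep(which(!gw), each = length(years))
    rec_year[["sw"]] <- rep(years, times = sum(!gw))
  }
  if (any(gw)) {
    for (wnd in windows) {
      rec_sys[[paste0("gw", wnd[1])]] <- which(gw)
      rec_year[[paste0("gw", wnd[1])]] <-
        sample(wnd, sum(gw), replace = TRUE)
    }
  }
  si <- unlist(rec_sys, use.names = FALSE)
  yr <- unlist(rec_year, use.names = FALSE)
  n_rec <- length(si)

  value_ugl <- exp(latent_sys[si] + stats::rnorm(n_rec, 0, config$sigma_record))
  sample_type <- ifelse(stats::runif(n_rec) < config$frac_raw_samples,
                        "raw", "treated")
  value_ugl[sample_type == "raw"] <- value_ugl[sample_type == "raw"] *
    config$raw_bias
  lod_ugl <- if (length(config$lod_ug_l) == 1L) rep(config$lod_ug_l, n_rec)
             else sample(config$lod_ug_l, n_rec, replace = TRUE)
  detected <- value_ugl >= lod_ugl
  units <- ifelse(stats::runif(n_rec) < config$frac_mg_l, "mg/L", "ug/L")
  value <- ifelse(units == "mg/L", value_ugl / 1000, value_ugl)
  lod <- ifelse(units == "mg/L", lod_ugl / 1000, lod_ugl)
  value[!detected] <- NA_real_

  day <- sample.int(364L, n_rec, replace = TRUE)
  rec <- data.frame(
    system_id = inv$system_id[si],
    sample_date = as.Date(paste0(yr, "-01-01")) + day,
    value = value, units = units, lod = lod,
    detected = detected, sample_type = sample_type,
    stringsAsFactors = FALSE)
  rec[order(rec$system_id, rec$sample_date), , drop = FALSE] -> rec
  rownames(rec) <- NULL
  rec
}

#' Simulate a complete synthetic study data set
#'
#' Runs the full generator: grid adjacency, county covariates with a latent
#' spatially autocorrelated fluoride surface, system inventory, and
#' monitoring records.  Identical `config` (including seed) yields identical
#' tables.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Optional directory; when given, writes `records.csv`,
#'   `inventory.csv`, `counties.csv`, `adjacency.csv` and `truth.json`.
#' @return List with `records`, `inventory`, `counties`, `adjacency`,
#'   `truth`, `config`.
#' @export
simulate_fluoride_data <- function(config = synthetic_config(),
                                   out_dir = NULL) {
  validate_synthetic_config(config)
  adjacency <- generate_grid_adjacency(config$n_county_rows,
                                       config$n_county_cols)
  cov <- generate_county_covariates(config, adjacency)
  inventory <- generate_system_inventory(config, cov$counties)
  records <- generate_monitoring_records(config, inventory, cov$counties)
  out <- list(records = records, inventory = inventory,
              counties = cov$counties, adjacency = adjacency,
              truth = cov$truth, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records, file.path(out_dir, "records.csv"),
                     row.names = FALSE)
    utils::write.csv(inventory, file.path(out_dir, "inventory.csv"),
                     row.names = FALSE)
    utils::write.csv(cov$counties, file.path(out_dir, "counties.csv"),
                     row.names = FALSE)
    utils::write.csv(adjacency, file.path(out_dir, "adjacency.csv"),
                     row.names = FALSE)
    jsonlite::write_json(cov$truth[c("beta_true", "lambda_true",
                                     "gmr_true_per_10pct")],
                         file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
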