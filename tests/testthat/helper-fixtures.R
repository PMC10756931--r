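# Shared fixtures built in code.

# Line-graph weights 1-2-...-n (rook/queen coincide on a path).
line_weights <- function(n, ids = paste0("C", seq_len(n))) {
  edges <- data.frame(county_a = ids[-n], county_b = ids[-1])
  build_queen_weights(edges, ids)
}

# Random connected-ish undirected graph weights on n nodes (seeded).
random_graph_weights <- function(n, p = 0.15, seed = 1) {
  set.seed(seed)
  ids <- paste0("C", seq_len(n))
  pairs <- t(utils::combn(n, 2))
  pick <- stats::runif(nrow(pairs)) < p
  # guarantee connectivity along the path so no islands
  edges <- rbind(pairs[pick, , drop = FALSE],
                 cbind(seq_len(n - 1), 2:n))
  edges <- unique(edges)
  build_queen_weights(data.frame(county_a = ids[edges[, 1]],
                                 county_b = ids[edges[, 2]]), ids)
}

# Dense brute-force Moran's I: (n/S0) z'Az / z'z with plain matrices.
dense_moran <- function(values, w) {
  A <- as.matrix(w$W)
  z <- values - mean(values)
  n <- length(values)
  (n / sum(A)) * as.numeric(t(z) %*% A %*% z) / sum(z^2)
}

# Dense brute-force LM statistics (Anselin forms).
dense_lm_stats <- function(y, X, w) {
  X <- as.matrix(X)
  W <- as.matrix(w$W)
  n <- length(y)
  b <- solve(t(X) %*% X, t(X) %*% y)
  e <- y - X %*% b
  s2 <- sum(e^2) / n
  T_ <- sum(diag(t(W) %*% W + W %*% W))
  lm_err <- (as.numeric(t(e) %*% W %*% e) / s2)^2 / T_
  M <- diag(n) - X %*% solve(t(X) %*% X) %*% t(X)
  WXb <- W %*% X %*% b
  D <- as.numeric(t(WXb) %*% M %*% WXb) / s2 + T_
  lm_lag <- (as.numeric(t(e) %*% W %*% y) / s2)^2 / D
  list(lm_error = lm_err, lm_lag = lm_lag)
}

# Ten hand-built monitoring records: two systems, nondetects, mixed units,
# treated/raw override, and one out-of-window record.
hand_fixture <- function() {
  rec <- data.frame(
    system_id = c("A", "A", "A", "A", "B", "B", "B", "B", "B", "B"),
    sample_date = as.Date(c("2006-03-01", "2006-06-01", "2006-09-01",
                            "2009-05-01",
                            "2007-04-01", "2008-02-01", "2008-07-01",
                            "2010-03-01", "2010-08-01",
                            "2005-01-15")),
    value = c(0.4, 600, 900,
              NA,
              800, 300, 250,
              NA, 129.2893218813452,
              999),
    units = c("mg/L", "ug/L", "ug/L",
              "mg/L",
              "ug/L", "ug/L", "ug/L",
              "ug/L", "ug/L",
              "ug/L"),
    lod = c(0.1, 100, 100,
            0.2,
            100, 100, 100,
            100, 100,
            100),
    detected = c(TRUE, TRUE, TRUE,
                 FALSE,
                 TRUE, TRUE, TRUE,
                 FALSE, TRUE,
                 TRUE),
    sample_type = c("treated", "treated", "raw",
                    "treated",
                    "raw", "treated", "raw",
                    "treated", "treated",
                    "treated"),
    stringsAsFactors = FALSE)
  systems <- data.frame(
    system_id = c("A", "B"),
    county_id = c("X", "X"),
    population_served = c(9000, 1000),
    source_type = c("groundwater", "groundwater"),
    fluoridation_reported = c(FALSE, TRUE),
    stringsAsFactors = FALSE)
  county_pop <- data.frame(county_id = "X", public_water_population = 15000)
  list(records = rec, systems = systems, county_pop = county_pop)
}

# Hand-computed expectations for the fixture above:
# System A: 2006 treated mean = (400 + 600)/2 = 500, raw 900 > 500 -> 500
#           (override); 2009 nondetect -> 200/sqrt(2); mean over 2 years.
# System B: 2007 raw-only 800; 2008 mean(300, 250) = 275 (raw not higher);
#           2010 mean(100/sqrt(2), 129.2893218813452) = 100.
hand_expected <- function() {
  a <- (500 + 200 / sqrt(2)) / 2
  b <- (800 + 275 + (100 / sqrt(2) + 129.2893218813452) / 2) / 3
  # ascending order is (A, B); cumulative weight 0.9 at A reaches q = 0.9,
  # so p90 = A and p95 = B under the cumulative-weight rule
  list(mean_A = a, mean_B = b,
       county_mean = 0.9 * a + 0.1 * b,
       county_p90 = a,
       county_p95 = b)
}

# Small benchmark configuration for recovery experiments: the planted
# composition effect is the estimand (no fluoridation intervention, light
# censoring, full county coverage).
recovery_config <- function(seed) {
  synthetic_config(seed = seed, frac_fluoridated = 0,
                   frac_fluoridation_missing = 0,
                   lod_ug_l = 150, frac_low_coverage = 0)
}
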