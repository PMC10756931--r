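make_rec <- function(value, units = "ug/L", lod = 100, detected = !is.na(value),
                     sample_type = "treated", system_id = "S1",
                     sample_date = as.Date("2008-06-01")) {
  data.frame(system_id = system_id, sample_date = sample_date, value = value,
             units = units, lod = lod, detected = detected,
             sample_type = sample_type, stringsAsFactors = FALSE)
}

test_that("nondetect substitution imputes LOD/sqrt(2) and leaves detects alone", {
  r <- rbind(make_rec(NA, "mg/L", lod = 0.2, detected = FALSE),
             make_rec(0.5, "mg/L", lod = 0.2),
             make_rec(NA, "ug/L", lod = 100, detected = FALSE))
  out <- substitute_nondetects(r)
  expect_equal(out$value[1], 0.2 / sqrt(2), tolerance = 1e-12)
  expect_equal(out$value[2], 0.5)
  expect_equal(out$value[3], 100 / sqrt(2), tolerance = 1e-12)
  expect_equal(round(out$value[3], 2), 70.71)

  # nondetect with unusable LOD is dropped with a warning and counted
  bad <- rbind(make_rec(NA, lod = NA, detected = FALSE), make_rec(500))
  expect_warning(out2 <- substitute_nondetects(bad), "dropped")
  expect_equal(nrow(out2), 1L)
  expect_equal(attr(out2, "n_rejected"), 1L)
})

test_that("unit standardization converts mg/L to ug/L and rejects unknown units", {
  r <- rbind(make_rec(0.7, "mg/L", lod = 0.1),
             make_rec(700, "ug/L"),
             make_rec(4, "mg/L", lod = 0.1))
  out <- standardize_units(r)
  expect_equal(out$value, c(700, 700, 4000))
  expect_equal(out$lod, c(100, 100, 100))
  expect_true(all(out$units == "ug/L"))
  expect_equal(standardize_units(make_rec(1, "µg/L"))$value, 1)

  expect_error(standardize_units(make_rec(1, "ppm")), "unrecognized")
})

test_that("yearly average applies the treated/raw override rule", {
  # raw mean higher -> treated-only average, flagged
  a <- yearly_average(c(400, 600, 900), c("treated", "treated", "raw"))
  expect_equal(a$mean, 500); expect_true(a$treated_only)
  # raw not higher -> plain mean of all samples
  b <- yearly_average(c(500, 300), c("treated", "raw"))
  expect_equal(b$mean, 400); expect_false(b$treated_only)
  # raw-only year: no treated comparator, raw mean stands
  c_ <- yearly_average(800, "raw")
  expect_equal(c_$mean, 800); expect_false(c_$treated_only)
  expect_error(yearly_average(numeric(0), character(0)), "no records")
})

test_that("treated-only override never increases the yearly mean", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(2:8, 1)
    v <- runif(n, 50, 2000)
    st <- sample(c("treated", "raw"), n, replace = TRUE)
    ya <- yearly_average(v, st)
    expect_lte(ya$mean, mean(v) + 1e-12)
  }
})

test_that("chronic average is the unweighted mean of in-window yearly means", {
  expect_equal(chronic_average(c("2006" = 400, "2009" = 600)), 500)
  expect_equal(chronic_average(c("2008" = 350)), 350)
  expect_equal(chronic_average(c("2006" = 400, "2010" = 800),
                               window = 2009:2011), 800)
  expect_error(chronic_average(c("2003" = 1), window = 2006:2011), "window")
})

test_that("cws_estimates equals a plain group-by mean when no special cases apply", {
  # oracle: with no nondetects and one treated record per system-year,
  # mean_6yr is the plain average of record values per system
  set.seed(21)
  sys <- sprintf("S%02d", 1:15)
  rows <- do.call(rbind, lapply(sys, function(s) {
    yrs <- sort(sample(2006:2011, sample(2:6, 1)))
    make_rec(runif(length(yrs), 100, 900), system_id = s,
             sample_date = as.Date(paste0(yrs, "-06-15")))
  }))
  est <- cws_estimates(rows)
  oracle <- tapply(rows$value, rows$system_id, mean)
  expect_equal(est$mean_6yr, as.numeric(oracle[est$system_id]),
               tolerance = 1e-12)
  expect_true(all(est$n_nondetect == 0))
  expect_true(all(est$mean_6yr > 0))
})

test_that("pipeline output is invariant to input units", {
  set.seed(22)
  r_ugl <- do.call(rbind, lapply(sprintf("S%d", 1:10), function(s) {
    make_rec(runif(6, 50, 3000), system_id = s,
             sample_date = as.Date(paste0(2006:2011, "-03-01")),
             sample_type = sample(c("treated", "raw"), 6, replace = TRUE))
  }))
  r_mgl <- r_ugl
  r_mgl$value <- r_mgl$value / 1000
  r_mgl$lod <- r_mgl$lod / 1000
  r_mgl$units <- "mg/L"
  e1 <- cws_estimates(r_ugl); e2 <- cws_estimates(r_mgl)
  expect_equal(e1$mean_6yr, e2$mean_6yr, tolerance = 1e-9)
})

test_that("exceedance counts are correct and monotone in the threshold", {
  est <- data.frame(mean_6yr = c(500, 800, 1600, 4200))
  ex <- count_exceedances(est, c(700, 1500, 4000),
                          population_served = c(10, 20, 30, 40))
  expect_equal(ex$n_exceed, c(3L, 2L, 1L))
  expect_equal(ex$population_exceed, c(90, 70, 40))
  # monotonicity property over random estimate sets
  set.seed(30)
  for (i in 1:20) {
    e <- data.frame(mean_6yr = rlnorm(50, 6, 1))
    cnt <- count_exceedances(e, c(200, 700, 1500, 4000))$n_exceed
    expect_true(all(diff(cnt) <= 0))
  }
})

test_that("percent reporting matches printed-precision conventions", {
  expect_equal(percent_of_total(1456, 32495), 4.5)
  expect_equal(percent_of_total(0, 100), 0)
  expect_equal(percent_of_total(4992, 32495), 15.4)
  expect_error(percent_of_total(1, 0), "total")
  expect_error(percent_of_total(5, 4), "count")
})

test_that("subgroup summaries stratify correctly and duplicate by cluster", {
  est <- data.frame(system_id = c("A", "B", "C"),
                    mean_6yr = c(100, 900, 900))
  sys <- data.frame(system_id = c("A", "B", "C"),
                    county_id = c("X", "Y", "Z"),
                    population_served = c(10, 20, 30),
                    source_type = c("groundwater", "surface", "surface"),
                    stringsAsFactors = FALSE)
  s <- summarize_subgroups(est, sys, "source_type")
  all_row <- s[s$group == "All", ]
  gw <- s[s$group == "groundwater", ]
  sw <- s[s$group == "surface", ]
  expect_equal(all_row$n_systems, 3L)
  expect_equal(gw$mean, 100); expect_equal(gw$p90, 100)
  expect_equal(sw$mean, 900); expect_equal(sw$p90, 900)
  expect_equal(sw$n_systems, 2L)

  # single group: group row equals overall row
  sys1 <- transform(sys, source_type = "groundwater")
  s1 <- summarize_subgroups(est, sys1, "source_type")
  expect_equal(s1[s1$group == "groundwater", -1], s1[s1$group == "All", -1],
               ignore_attr = TRUE)

  # a system serving counties in two clusters appears once per cluster
  sys2 <- rbind(
    data.frame(system_id = "A", county_id = "X", population_served = 10,
               cluster = "Semi-Urban, Hispanic"),
    data.frame(system_id = "A", county_id = "Y", population_served = 10,
               cluster = "Rural, High SES"),
    data.frame(system_id = "B", county_id = "Z", population_served = 20,
               cluster = "Rural, High SES"))
  est2 <- data.frame(system_id = c("A", "B"), mean_6yr = c(100, 200))
  s2 <- summarize_subgroups(est2, sys2, "cluster", dedupe = FALSE)
  expect_equal(s2[s2$group == "All", "n_systems"], 3L)  # 2 systems + 1 dup
})

test_that("Kruskal-Wallis matches the hand-computed rank statistic", {
  # groups [1,2,3] vs [4,5,6]: ranks 1..6, H = 12/(N(N+1)) sum n_i Rbar_i^2 - 3(N+1)
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(kw$statistic, 12 / (6 * 7) * (3 * 2^2 + 3 * 5^2) - 3 * 7,
               tolerance = 1e-10)
  expect_equal(kw$statistic, 27 / 7, tolerance = 1e-10)
  expect_equal(kw$df, 1)

  # all-identical observations: no rank variation, H = 0, p = 1
  flat <- kruskal_wallis(rep(5, 10), rep(c("a", "b"), 5))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  expect_error(kruskal_wallis(1:5, rep("a", 5)), "two")
})
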