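make_table <- function() {
  data.frame(
    site_id = c("A", "B", "C", "D"),
    x_km = c(10, 20, 30, 40), y_km = c(10, 20, 30, 40),
    state_id = "S01",
    lab_id_top5 = c("L1", "L2", "N.S.", "N.S."),
    lab_id_ahorizon = c("L5", "L6", "L7", "N.S."),
    conc_top5 = c(4, 0.05, 2, 1),
    conc_ahorizon = c(6, 3, 6, 1),
    below_lld_top5 = c(FALSE, TRUE, FALSE, FALSE),
    below_lld_ahorizon = FALSE,
    lld = 0.2, stringsAsFactors = FALSE)
}

test_that("below-detection values are replaced by half the detection limit", {
  tab <- make_table()
  out <- substitute_below_lld(tab)
  expect_equal(out$conc_top5[2], 0.1)                      # lld 0.2 -> 0.1
  expect_equal(out$conc_top5[-2], tab$conc_top5[-2])
  expect_equal(out$conc_ahorizon, tab$conc_ahorizon)       # no flags: unchanged
  log <- attr(out, "cleaning_log")
  expect_equal(log[[1]]$n_substituted, 1L)

  tab2 <- tab
  tab2$below_lld_top5 <- c(TRUE, TRUE, FALSE, FALSE)
  tab2$lld <- 1.0
  out2 <- substitute_below_lld(tab2)
  expect_equal(out2$conc_top5[1:2], c(0.5, 0.5))
  expect_equal(attr(out2, "cleaning_log")[[1]]$n_substituted, 2L)

  tab3 <- tab; tab3$lld[2] <- NA
  expect_error(substitute_below_lld(tab3), "lld is missing")
})

test_that("outlier masking blanks concentrations but keeps rows", {
  tab <- make_table()
  out <- mask_outliers(tab, "A")
  expect_equal(nrow(out), 4)
  expect_true(is.na(out$conc_top5[1]) && is.na(out$conc_ahorizon[1]))
  expect_equal(mask_outliers(tab, character(0))$conc_top5, tab$conc_top5)
  expect_warning(mask_outliers(tab, c("A", "ZZZ")), "ZZZ")
})

test_that("not-sampled horizons are blanked and fully-N.S. sites dropped", {
  tab <- make_table()
  out <- drop_not_sampled(tab)
  expect_equal(nrow(out), 3)                    # site D dropped
  expect_true(is.na(out$conc_top5[out$site_id == "C"]))
  expect_equal(out$conc_ahorizon[out$site_id == "C"], 6)
  no_ns <- make_table(); no_ns$lab_id_top5 <- "L"; no_ns$lab_id_ahorizon <- "L"
  expect_equal(nrow(drop_not_sampled(no_ns)), 4)
})

test_that("horizon averaging uses mean-of-available with coalesce semantics", {
  tab <- make_table()[1:3, ]
  tab$conc_top5 <- c(4, 3, NA); tab$conc_ahorizon <- c(6, 3, 6)
  out <- merge_horizons(tab)
  expect_equal(out$conc, c(5, 3, 6))            # mean, identity, coalesce
  expect_false(any(c("conc_top5", "conc_ahorizon") %in% names(out)))
  tab$conc_ahorizon[3] <- NA
  out2 <- merge_horizons(tab)
  expect_equal(nrow(out2), 2)                   # both-missing site dropped
})

test_that("masking an observation removes it from the model likelihood", {
  tab <- make_table()
  tab$below_lld_top5 <- FALSE
  cleaned <- merge_horizons(drop_not_sampled(tab))
  n0 <- nrow(cleaned)
  masked <- merge_horizons(drop_not_sampled(mask_outliers(tab, "A")))
  spec <- model_spec("m", "lognormal", include_spatial = FALSE, include_state = FALSE)
  f0 <- fit_spde(spec, cleaned, n_draws = 50)
  f1 <- fit_spde(spec, masked, n_draws = 50)
  expect_equal(f0$n_obs - f1$n_obs, 1L)
})

test_that("collinearity screen drops the later covariate above |r| = 0.7", {
  set.seed(2)
  n <- 60
  a <- rnorm(n); b <- rnorm(n); d <- rnorm(n)
  mix <- function(x, z, r) {
    xs <- (x - mean(x)) / sd(x)
    z <- z - mean(z); z <- z - xs * sum(z * xs) / sum(xs^2)
    r * xs + sqrt(1 - r^2) * z / sd(z)
  }
  covs <- data.frame(ph = a, precip = mix(a, b, 0.9), clay = d)
  res <- screen_collinear(covs)
  expect_equal(res$dropped, "precip")
  expect_equal(res$retained, c("ph", "clay"))
  expect_equal(dim(res$cor_matrix), c(3, 3))

  # all pairs at or below the threshold: identity, including exactly 0.70
  covs2 <- data.frame(ph = a, precip = mix(a, b, 0.70), clay = d)
  res2 <- screen_collinear(covs2)
  expect_equal(res2$retained, c("ph", "precip", "clay"))

  covs3 <- data.frame(ph = a, flat = rep(1, n))
  expect_warning(res3 <- screen_collinear(covs3), "zero-variance")
  expect_equal(res3$retained, "ph")
})

test_that("screen output is order-stable for a fixed covariate ordering", {
  set.seed(3)
  a <- rnorm(50)
  covs <- data.frame(x1 = a, x2 = a + rnorm(50, sd = 0.1), x3 = rnorm(50))
  expect_identical(screen_collinear(covs)$retained,
                   screen_collinear(covs)$retained)
  expect_equal(screen_collinear(covs)$retained, c("x1", "x3"))
})

test_that("standardization is exact and reapplies through the stored record", {
  covs <- data.frame(a = c(1, 2, 3), b = c(10, 20, 40))
  out <- standardize_covariates(covs)
  expect_equal(colMeans(out$data), c(a = 0, b = 0))
  expect_equal(vapply(out$data, sd, numeric(1)), c(a = 1, b = 1))
  new <- data.frame(a = 5, b = 10)
  scaled <- apply_scaling(new, out$record)
  expect_equal(scaled$a, (5 - 2) / 1)
  expect_equal(scaled$b, (10 - mean(c(10, 20, 40))) / sd(c(10, 20, 40)))
  expect_error(standardize_covariates(data.frame(a = c(1, 1, 1))), "zero-SD")
})

test_that("survey CSV and cleaning report round trip", {
  tab <- make_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_survey_csv(tab, path)
  back <- read_survey_csv(path)
  expect_equal(back$conc_top5, tab$conc_top5)
  expect_identical(back$below_lld_top5, tab$below_lld_top5)
  expect_identical(back$lab_id_top5, tab$lab_id_top5)

  cleaned <- merge_horizons(drop_not_sampled(substitute_below_lld(tab)))
  rp <- withr::local_tempfile(fileext = ".json")
  write_cleaning_report(cleaned, rp)
  log <- jsonlite::read_json(rp)
  expect_equal(vapply(log, `[[`, "", "step"),
               c("substitute_below_lld", "drop_not_sampled", "merge_horizons"))
})
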