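test_that("free Gaussian fit recovers exact generative parameters", {
  x <- seq(-20, 0, by = 1)
  tab <- cat_tbl(x, model = 100 * exp(-(x + 10)^2 / (2 * 3^2)))
  fit <- fit_gaussian_free(tab)
  expect_equal(fit$A, 100, tolerance = 1e-6)
  expect_equal(fit$mu, -10, tolerance = 1e-6)
  expect_equal(fit$sigma, 3, tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_true(fit$reliable)
})

test_that("free Gaussian fit flags degenerate and under-determined tables", {
  expect_warning(deg <- fit_gaussian_free(cat_tbl(1:6, model = 5)),
                 "degenerate")
  expect_true(deg$degenerate)
  expect_true(is.na(deg$A))
  expect_error(fit_gaussian_free(cat_tbl(1:3, model = c(1, 2, 1))),
               "at least 4")
})

test_that("binomial spike-in modeling aggregates fit a Gaussian with high R2", {
  tab <- cat_tbl(0:8, model = choose(8, 0:8) * 256, key = "gc")
  fit <- fit_gaussian_free(tab)
  expect_gt(fit$r2, 0.99)
  expect_equal(fit$mu, 4, tolerance = 0.05)  # symmetry of the design
})

test_that("closed-form amplitude equals the least-squares optimum", {
  # proportional case: y = 2 * g exactly -> A* = 2, zero residuals
  sg <- sqrt(1 / (2 * log(2)))        # so exp(-1/(2 sg^2)) = 0.5
  tab <- cat_tbl(c(-1, 0, 1), model = 1, obs = c(2, 4, 2))
  prop <- fit_amplitude_fixed(tab, mu = 0, sigma = sg)
  expect_equal(prop$amplitude, 4, tolerance = 1e-12)
  expect_equal(prop$data$residual, rep(0, 3), tolerance = 1e-12)

  # dip case against a brute-force 1-D minimiser
  dip <- fit_amplitude_fixed(cat_tbl(c(-1, 0, 1), model = 1,
                                     obs = c(1, 0, 1)), mu = 0, sigma = sg)
  g <- c(0.5, 1, 0.5)
  brute <- optimize(function(A) sum((c(1, 0, 1) - A * g)^2), c(0, 10),
                    tol = 1e-10)$minimum
  expect_equal(dip$amplitude, brute, tolerance = 1e-6)
  expect_equal(dip$amplitude, sum(c(1, 0, 1) * g) / sum(g^2),
               tolerance = 1e-12)

  zero <- fit_amplitude_fixed(cat_tbl(1:4, model = 1, obs = 0), 2.5, 1)
  expect_equal(zero$amplitude, 0)
  expect_equal(zero$data$predicted, rep(0, 4))

  expect_error(fit_amplitude_fixed(cat_tbl(1:4, model = 1), 2.5, -1),
               "sigma")
  expect_error(fit_amplitude_fixed(cat_tbl(1:4, model = 1), 1e6, 1e-3),
               "underflow")
})

test_that("closed-form amplitude matches a grid minimiser on random instances", {
  set.seed(431)
  for (i in 1:100) {
    m <- sample(4:30, 1)
    x <- sort(runif(m, -20, 0))
    mu <- runif(1, -20, 0)
    sigma <- runif(1, 0.5, 8)
    y <- pmax(rpois(m, 50) * runif(m, 0, 2), 0)
    g <- exp(-(x - mu)^2 / (2 * sigma^2))
    fit <- fit_amplitude_fixed(cat_tbl(x, model = 1, obs = y), mu, sigma)
    brute <- optimize(function(A) sum((y - A * g)^2),
                      c(0, 2 * max(y) / max(g)), tol = 1e-12)$minimum
    expect_equal(fit$amplitude, brute,
                 tolerance = 1e-6 * max(1, abs(brute)))
  }
})

test_that("calibration redistributes predictions and is idempotent", {
  km <- spikein_kmers()
  km <- simulate_counts(km, 100, bias_model(beta_mfe = 0, seed = 432))
  run <- gsb_calibrate(km, key = "gc")
  expect_true(all(run$kmers$count_cal >= 0))
  # biased GC simulation: calibration tightens the per-k-mer distribution
  expect_lt(run$cv_after, run$cv_before)
  # category means equal predicted / n by construction
  chk <- dplyr::summarise(dplyr::group_by(run$kmers, gc),
                          m = mean(count_cal), .groups = "drop")
  pred <- run$amp_fit$data$predicted / run$amp_fit$data$n_kmers
  expect_equal(chk$m, pred, tolerance = 1e-12)

  # idempotence: recalibrating the calibrated counts changes nothing
  again <- run$kmers
  again$count_obs <- again$count_cal
  run2 <- gsb_calibrate(again, key = "gc")
  expect_equal(run2$kmers$count_cal, run$kmers$count_cal,
               tolerance = 1e-9)
})

test_that("single-category tables split the predicted mass evenly", {
  km <- kmer_tbl(rep("ACGTT", 4), mfe_vals = -1, obs = c(2, 6, 2, 6))
  tab <- categorize(km, "mfe")
  fit <- fit_amplitude_fixed(tab, mu = -1, sigma = 1)
  cal <- calibrate_kmers(km, fit)
  expect_equal(cal$count_cal, rep(fit$data$predicted / 4, 4))
})

test_that("fixed-parameter CDF amplitude recovers exact and self-consistent totals", {
  # exact generative case under the fit's own edge convention
  x <- seq(-12, -2, by = 1)
  mu <- -7; sigma <- 2
  phi <- pnorm((x + 0.5 - mu) / sigma)
  tab <- cat_tbl(x, model = 1, obs = diff(c(0, 500 * phi)))
  fit <- fit_cdf_amplitude(tab, mu, sigma)
  expect_equal(fit$amplitude, 500, tolerance = 1e-9)

  expect_error(fit_cdf_amplitude(cat_tbl(c(2, 1, 3), model = 1), 0, 1),
               "ascending")
  expect_error(fit_cdf_amplitude(tab, mu, -2), "sigma")

  # modeling data as its own input: amplitude ~ total modeling count
  sp_tab <- categorize(spikein_kmers(), key = "gc")
  pf <- fit_gaussian_free(sp_tab)
  expect_gt(pf$r2, 0.99)
  sp_self <- sp_tab
  sp_self$agg_obs <- sp_self$agg_model
  self_fit <- fit_cdf_amplitude(sp_self, pf)
  expect_equal(self_fit$amplitude, sum(sp_tab$agg_model), tolerance = 0.01)
})

test_that("fixed-parameter CDF beats free fitting on biased data", {
  set.seed(433)
  tx <- random_transcript(2000, seed = 2433)
  km <- add_mfe(extract_kmers(tx, k = 50))
  km <- simulate_counts(km, 100, bias_model(seed = 433))
  truth <- 100 * nrow(km)
  tab <- categorize(km, "mfe")
  pf <- fit_gaussian_free(tab, "model")
  fixed <- fit_cdf_amplitude(tab, pf)$amplitude
  free <- fit_gaussian_cdf_free(tab, which = "obs")$A
  expect_false(isTRUE(all.equal(fixed, free)))
  expect_lt(abs(fixed - truth), abs(free - truth))
})

test_that("modeling self-fit residuals are no worse than the free fit's", {
  tab <- categorize(spikein_kmers(), key = "gc")
  pf <- fit_gaussian_free(tab, "model")
  tab$agg_obs <- tab$agg_model
  fixed <- fit_amplitude_fixed(tab, pf)
  rms <- function(r) sqrt(mean(r^2))
  expect_lte(rms(fixed$data$residual), rms(pf$data$residual) + 1e-6)
})

test_that("RPKM and TPM normalisations satisfy their identities", {
  out <- normalize_abundance(1000, 1000, 1e6)
  expect_equal(out$rpkm, 1000)

  eq <- normalize_abundance(rep(50, 4), rep(200, 4), 1e6)
  expect_equal(eq$tpm, rep(2.5e5, 4))

  set.seed(434)
  rnd <- normalize_abundance(runif(7, 10, 1000), sample(200:2000, 7), 5e5)
  expect_equal(sum(rnd$tpm), 1e6)
  expect_error(normalize_abundance(10, 0, 1e6), "region_length")
  expect_error(normalize_abundance(10, 100, 0), "library_total")
})
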