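test_that("spike-in enumeration is complete, ordered and deterministic", {
  d <- spikein_design()
  expect_equal(nchar(d$backbone), 50L)
  expect_equal(d$n_variable, 8L)

  sp <- enumerate_spikeins(d)
  expect_equal(nrow(sp), 65536L)
  expect_equal(length(unique(sp$core)), 65536L)
  # lexicographic A < C < G < T over the variable positions
  expect_equal(sp$variant[1:5],
               c("AAAAAAAA", "AAAAAAAC", "AAAAAAAG", "AAAAAAAT",
                 "AAAAAACA"))
  expect_false(is.unsorted(sp$variant, strictly = TRUE))
  expect_true(all(nchar(sp$core) == 50L))
  expect_true(all(startsWith(sp$sequence, "AAAAAAAA") &
                    endsWith(sp$sequence, "AAAAAAAA")))
  expect_identical(sp, enumerate_spikeins(d))

  # GC histogram of the variable positions is exactly binomial
  gc_var <- gc_count(sp$variant)
  expect_equal(as.integer(table(gc_var)), as.integer(choose(8, 0:8) * 2^8))

  one_n <- spikein_design(paste0(strrep("A", 49), "N"))
  expect_equal(nrow(enumerate_spikeins(one_n)), 4L)
  zero_n <- spikein_design(strrep("ACGTT", 10))
  expect_equal(nrow(enumerate_spikeins(zero_n)), 1L)
  expect_error(spikein_design(paste0(strrep("N", 13), strrep("A", 37))),
               "12")
})

test_that("random transcripts honour the seed and the GC target", {
  a <- random_transcript(200, seed = 451)
  b <- random_transcript(200, seed = 451)
  expect_identical(a$sequence, b$sequence)

  allgc <- random_transcript(100, gc_prob = 1, seed = 452)
  expect_equal(gc_count(allgc$sequence), 100L)

  big <- random_transcript(10000, gc_prob = 0.4, seed = 453)
  p_hat <- gc_count(big$sequence) / 10000
  expect_lt(abs(p_hat - 0.4), 3 * sqrt(0.4 * 0.6 / 10000))
  expect_error(random_transcript(0), ">= 1")
})

test_that("simulate_counts injects the specified biases with the chosen noise law", {
  set.seed(454)
  km <- kmer_tbl(replicate(600, rand_seq(50)))
  km$mfe <- as.numeric(mfe(km$kmer))

  # neutral model, Poisson noise: mean close to alpha
  neutral <- simulate_counts(km, 100,
                             bias_model(beta_gc = 0, beta_mfe = 0,
                                        seed = 454))
  expect_lt(abs(mean(neutral$count_obs) - 100), 3 * sqrt(100 / 600))

  # positive GC slope induces positive count-GC correlation
  gcpos <- simulate_counts(km, 100,
                           bias_model(beta_gc = 0.05, beta_mfe = 0,
                                      seed = 455))
  expect_gt(cor(gcpos$count_obs, gcpos$gc), 0)

  # deterministic expectations with noise = "none"
  det <- simulate_counts(km, 50, bias_model(noise = "none", seed = 1))
  expect_equal(det$count_obs, attr(det, "lambda"))

  expect_error(simulate_counts(km, 0), "abundance")
  expect_error(simulate_counts(km, 1, bias_model(beta_gc = 10, seed = 1)),
               "non-positive expected count")
  expect_identical(
    simulate_counts(km, 100, bias_model(seed = 456))$count_obs,
    simulate_counts(km, 100, bias_model(seed = 456))$count_obs
  )
})

test_that("simulate_fragments respects geometry, size law and hexamer preferences", {
  tx <- random_transcript(1500, seed = 457, id = "tx")
  expect_equal(nrow(simulate_fragments(tx, 0)), 0L)

  fr <- simulate_fragments(tx, 4000, bias_model(seed = 457))
  expect_equal(nrow(fr), 4000L)
  expect_true(all(fr$start0 >= 0 & fr$end0 <= 1500))
  expect_equal(fr$length, fr$end0 - fr$start0)
  expect_equal(fr$first6,
               substr(rep(tx$sequence, 4000), fr$start0 + 1, fr$start0 + 6))
  expect_lt(abs(mean(fr$length) - 300), 3 * 30 / sqrt(4000) + 1)
  expect_identical(fr, simulate_fragments(tx, 4000, bias_model(seed = 457)))

  expect_error(simulate_fragments(random_transcript(200, seed = 1), 10),
               "size_mu")

  # a strong preference shifts the start-hexamer composition: favour a
  # tenth of the start hexamers 4x and watch their share rise
  starts <- 0:(1500 - 6)
  h_all <- substr(rep(tx$sequence, length(starts)), starts + 1, starts + 6)
  set.seed(458)
  fav_set <- sample(unique(h_all), round(length(unique(h_all)) / 10))
  pref <- stats::setNames(rep(4, length(fav_set)), fav_set)
  fav <- simulate_fragments(tx, 4000,
                            bias_model(hexamer_pref = pref, seed = 458))
  u <- mean(h_all %in% fav_set)
  expect_gt(mean(fav$first6 %in% fav_set), 1.5 * u)
  expect_lt(abs(mean(fr$first6 %in% fav_set) - u), 0.05)
})

test_that("full loop: biased simulated counts return the true abundance within 5%", {
  tx <- random_transcript(2000, seed = 459)
  km <- add_mfe(extract_kmers(tx, k = 50))
  km <- simulate_counts(km, 100, bias_model(seed = 459))
  run <- gsb_calibrate(km, key = "mfe")
  amp <- fit_cdf_amplitude(run$categories, run$model_fit)
  truth <- 100 * nrow(km)
  expect_lt(abs(amp$amplitude - truth) / truth, 0.05)
})
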