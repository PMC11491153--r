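# transcript built from fixed-GC blocks so fragment GC bins are controlled:
# block i (100 nt) has GC count gcs[i], fragments are whole blocks
block_fragments <- function(gcs, reps = 1L) {
  blocks <- vapply(gcs, function(g) {
    paste0(strrep("G", g), strrep("A", 100 - g))
  }, "")
  tx <- tx_tbl(paste0(blocks, collapse = ""), ids = "blocks")
  frag1 <- tibble::tibble(transcript_id = "blocks",
                          start0 = (seq_along(gcs) - 1L) * 100L,
                          end0 = seq_along(gcs) * 100L)
  list(tx = tx, fragments = frag1[rep(seq_along(gcs), each = reps), ])
}

test_that("LOESS GC weights are 1 for flat bin counts and dip where counts bulge", {
  fx <- block_fragments(10:29, reps = 10L)
  wt <- loess_gc_weights(fx$fragments, fx$tx)
  expect_equal(nrow(wt), 20L)
  expect_equal(wt$weight, rep(1, 20), tolerance = 1e-9)

  # one bin at twice the global mean: weight < 1 there, and it matches a
  # manual tricube local-linear oracle at that bin
  reps <- rep(10L, 20); reps[10] <- 20L
  fx2 <- block_fragments(10:29)
  frag2 <- fx2$fragments[rep(1:20, times = reps), ]
  wt2 <- loess_gc_weights(frag2, fx2$tx)
  expect_lt(wt2$weight[10], 1)
  oracle <- tricube_local_linear(wt2$key, wt2$n, wt2$key[10], span = 0.3)
  expect_equal(wt2$weight[10], mean(wt2$n) / max(oracle, 0.5),
               tolerance = 1e-6)

  expect_error(loess_gc_weights(block_fragments(20)$fragments,
                                block_fragments(20)$tx),
               "GC bins")
})

test_that("apply_weights multiplies matched keys and round-trips via inverse weights", {
  wt <- loess_gc_weights(block_fragments(10:29, 5L)$fragments,
                         block_fragments(10:29, 5L)$tx)
  df <- tibble::tibble(key = wt$key, count = seq_along(wt$key))
  idy <- apply_weights(df, wt, key = "key")
  expect_equal(idy$count_corrected, df$count, tolerance = 1e-9)

  wt$weight[3] <- 2 * wt$weight[3]
  dbl <- apply_weights(df, wt, key = "key")
  expect_equal(dbl$count_corrected[3], 2 * df$count[3], tolerance = 1e-9)
  expect_equal(dbl$count_corrected[-3], df$count[-3], tolerance = 1e-9)

  set.seed(441)
  wt$weight <- runif(nrow(wt), 0.2, 5)
  fwd <- apply_weights(df, wt, key = "key")
  inv <- wt
  inv$weight <- 1 / wt$weight
  back <- apply_weights(dplyr::rename(fwd, count0 = count,
                                      count = count_corrected),
                        inv, key = "key")
  expect_equal(back$count_corrected, df$count, tolerance = 1e-9)

  expect_warning(apply_weights(tibble::tibble(key = "zz", count = 1), wt,
                               key = "key"), "absent")
})

test_that("fragment size model recovers the generating Gaussian", {
  tx <- random_transcript(1500, seed = 442, id = "tx")
  fr <- simulate_fragments(tx, 10000, bias_model(seed = 442))
  fit <- fragment_size_model(fr)
  expect_lt(abs(fit$mu - 300), 1)
  expect_lt(abs(fit$sigma - 30), 1)

  expect_error(fragment_size_model(fr[1:50, ]), "at least 100")
  same <- fr
  same$length <- 250L
  expect_error(fragment_size_model(same), "degenerate")
})

test_that("size calibration returns the total for library-shaped transcripts and flags truncation", {
  tx <- random_transcript(1500, seed = 443, id = "big")
  fr <- simulate_fragments(tx, 10000, bias_model(seed = 443))
  fit <- fragment_size_model(fr)
  cal <- calibrate_by_size(fr, fit)
  expect_equal(cal$amplitude, cal$n_fragments, tolerance = 0.02)

  # short transcript truncates the size law: amplitude departs from raw
  short <- random_transcript(340, seed = 444, id = "short")
  fr_s <- simulate_fragments(short, 2000, bias_model(seed = 444))
  cal2 <- calibrate_by_size(dplyr::bind_rows(fr, fr_s), fit)
  amp_s <- cal2$amplitude[cal2$transcript_id == "short"]
  expect_gt(abs(amp_s - 2000) / 2000, 0.005)

  cal_cdf <- calibrate_by_size(fr, fit, cdf = TRUE)
  expect_equal(cal_cdf$amplitude, cal_cdf$n_fragments, tolerance = 0.02)
})

test_that("hexamer weights form a complete table with count-weighted mean 1", {
  hexamers <- mfegsb:::all_hexamers()
  uniform <- tibble::tibble(first6 = rep(hexamers, 3L))
  wt <- hexamer_weights(uniform)
  expect_equal(nrow(wt), 4096L)
  expect_equal(wt$weight, rep(1, 4096), tolerance = 1e-12)

  # all mass on one hexamer: its weight collapses, absentees hit the ceiling
  one <- suppressWarnings(
    hexamer_weights(tibble::tibble(first6 = rep("ACGTAC", 4096L)))
  )
  expect_equal(nrow(one), 4096L)
  w_hit <- one$weight[one$key == "ACGTAC"]
  w_miss <- unique(one$weight[one$key != "ACGTAC"])
  expect_lt(w_hit, w_miss[1])
  expect_equal(w_hit * 4096, sum(one$n * one$weight), tolerance = 1e-9)

  # simulated 4x preference for AAAAAA is flattened by the weights
  set.seed(445)
  pref <- rep(1, 4096)
  pref[1] <- 4
  draws <- sample(hexamers, 2e5, replace = TRUE, prob = pref)
  wt2 <- hexamer_weights(tibble::tibble(first6 = draws))
  corrected <- wt2$n * wt2$weight
  baseline <- 2e5 / 4096
  expect_lt(abs(corrected[wt2$key == "AAAAAA"] - baseline),
            3 * sqrt(4 * baseline))
  expect_lt(cv(corrected[wt2$n > 0]), cv(wt2$n[wt2$n > 0]))
})

test_that("category smoothing tracks exact Gaussians, keeps flats flat, attenuates spikes", {
  x <- seq(-15, -1, by = 0.5)
  y <- 200 * exp(-(x + 8)^2 / (2 * 2.5^2))
  smo <- smooth_category_counts(cat_tbl(x, model = 1, obs = y))
  r2 <- 1 - sum((y - smo$data$predicted)^2) / sum((y - mean(y))^2)
  expect_gt(r2, 0.99)

  flat <- smooth_category_counts(cat_tbl(1:12, model = 1, obs = 7))
  expect_equal(flat$data$predicted, rep(7, 12), tolerance = 1e-9)

  spike_y <- c(rep(2, 6), 40, rep(2, 6))
  spike <- smooth_category_counts(cat_tbl(1:13, model = 1, obs = spike_y))
  expect_lt(max(spike$data$predicted), max(spike_y))
  expect_error(smooth_category_counts(cat_tbl(1:4, model = 1, obs = 1)),
               "at least 5")
})
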