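test_that("channel-wise normalizations match their definitions", {
  rec <- noise_recording(k = 4, dur = 8, seed = 3)
  z <- zscore_normalize(rec)
  expect_lt(max(abs(rowMeans(z$data))), 1e-10)
  expect_equal(apply(z$data, 1, sd), rep(1, 4), tolerance = 1e-9,
               ignore_attr = TRUE)
  l2 <- l2_normalize(rec)
  expect_equal(rowSums(l2$data^2), rep(1, 4), tolerance = 1e-9,
               ignore_attr = TRUE)
  # rank is invariant under both (positive per-channel rescalings)
  expect_equal(effective_rank(z), effective_rank(rec))
  expect_equal(effective_rank(l2), effective_rank(rec))

  flat <- rec
  flat$data[2, ] <- 7
  expect_error(zscore_normalize(flat), "EXG Channel 1")
})

test_that("spectral entropy spans its flat and concentrated limits", {
  fs <- fs_default
  white <- withr::with_seed(4, rnorm(16 * fs))
  n_bins <- floor(2 * fs / 2)        # 2-s windows, DC excluded
  expect_lt(abs(spectral_entropy(white, fs) - log2(n_bins)) / log2(n_bins),
            0.05)
  tone <- sin(2 * pi * 10 * (0:(16 * fs - 1)) / fs)
  expect_lt(spectral_entropy(tone, fs), 1)

  # 50/50 mix agrees with direct summation over the PSD mass
  mix <- 0.5 * white + 0.5 * tone
  p <- eegcleanse:::welch_psd(mix, fs)
  q <- p$psd[p$freq > 0] / sum(p$psd[p$freq > 0])
  q <- q[q > 0]
  expect_equal(spectral_entropy(mix, fs), -sum(q * log2(q)),
               tolerance = 1e-12)
  expect_error(spectral_entropy(rep(0, 1000), fs), "Zero total power")
})

test_that("relative band power integrates the Welch PSD correctly", {
  fs <- fs_default
  t <- (0:9999) / fs
  expect_gte(band_power(sin(2 * pi * 10 * t), fs, c(8, 13)), 0.95)
  x20 <- sin(2 * pi * 20 * t)
  expect_lt(band_power(x20, fs, c(8, 13)), 0.02)
  expect_gte(band_power(x20, fs, c(13, 30)), 0.95)
  pair <- sin(2 * pi * 10 * t) + sin(2 * pi * 20 * t)
  expect_equal(band_power(pair, fs, c(8, 13)), 0.5, tolerance = 0.05)
  expect_equal(band_power(pair, fs, c(13, 30)), 0.5, tolerance = 0.05)
  expect_error(band_power(pair, fs, c(70, 80)), "band")
})

test_that("the SNR proxy is exactly alpha-band relative power", {
  fs <- fs_default
  t <- (0:9999) / fs
  x <- withr::with_seed(5, sin(2 * pi * 10 * t) + 0.3 * rnorm(10000))
  expect_identical(snr_proxy(x, fs), band_power(x, fs, c(8, 13)))
  expect_gte(snr_proxy(sin(2 * pi * 10 * t), fs), 0.95)
  expect_lte(snr_proxy(sin(2 * pi * 20 * t), fs), 0.05)
})

test_that("correlation to raw hits its exact and sampling limits", {
  rec <- noise_recording(k = 3, dur = 10, seed = 6)
  expect_identical(correlation_to_raw(rec, rec), 1)
  neg <- rec
  neg$data <- -neg$data
  expect_identical(correlation_to_raw(neg, rec), -1)
  a <- noise_recording(k = 1, dur = 80, seed = 7)
  b <- noise_recording(k = 1, dur = 80, seed = 8)
  expect_lt(abs(correlation_to_raw(a, b)), 0.1)
  short <- noise_recording(k = 3, dur = 5)
  expect_error(correlation_to_raw(rec, short), "Alignment")
})

test_that("effective rank counts independent directions", {
  rec <- noise_recording(k = 16, dur = 10, seed = 9)
  expect_equal(effective_rank(rec), 16)
  dup <- rec
  dup$data[2, ] <- dup$data[1, ]
  expect_equal(effective_rank(dup), 15)
  # removing channels then retaining b components bounds the rank
  proj <- withr::with_seed(2,
    matrix(rnorm(12 * 5), 12, 5) %*% matrix(rnorm(5 * 500), 5, 500))
  expect_lte(effective_rank(proj), min(12, 5))
})

test_that("IC summaries aggregate retained-component probabilities", {
  tables <- brain_prob_tables(rbind(c(1, 1, 1), c(0.8, 0.8, 0.8),
                                    c(0.2, 0.2, 0.2)))
  dec_all <- tibble::tibble(ic = 1:3, retained = c(TRUE, TRUE, FALSE))
  s <- ic_summary(tables, dec_all)
  expect_equal(s$brain_fraction, 0.9)
  expect_equal(s$artifact_fraction, 0.1)
  expect_equal(s$n_brain_ics, 2)       # both retained ICs >= 0.7
  expect_equal(s$n_artifact_ics, 0)

  one <- brain_prob_tables(rbind(0.8))
  one[[1]]$muscle <- 0.2
  one[[1]]$other <- 0
  s1 <- ic_summary(one, tibble::tibble(ic = 1, retained = TRUE))
  expect_equal(s1$brain_fraction, 0.8)

  s0 <- ic_summary(tables, tibble::tibble(ic = 1:3, retained = FALSE))
  expect_false(s0$defined)
  expect_true(is.na(s0$brain_fraction))
})

test_that("paired comparisons match the closed form and flag degeneracy", {
  a <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  same <- paired_compare(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$cohens_d, 0)
  expect_true(same$degenerate)

  b <- withr::with_seed(10, a + 0.5 + rnorm(5, sd = 0.3))
  pc <- paired_compare(b, a)
  d <- b - a
  expect_equal(pc$statistic, mean(d) * sqrt(5) / sd(d), tolerance = 1e-12)
  expect_equal(pc$cohens_d, mean(d) / sd(d), tolerance = 1e-12)
  expect_equal(pc$p_value,
               2 * pt(abs(mean(d) * sqrt(5) / sd(d)), df = 4,
                      lower.tail = FALSE), tolerance = 1e-12)
  expect_false(pc$degenerate)

  big <- withr::with_seed(11, rnorm(40))
  pc2 <- paired_compare(big + 0.8 + withr::with_seed(12, rnorm(40, sd = 0.5)),
                        big)
  expect_equal(pc2$statistic,
               with(list(d = pc2$cohens_d), d * sqrt(40)), tolerance = 1e-8)

  expect_error(paired_compare(1:4, 1:3), "equal length")
  expect_error(paired_compare(1:2, 1:2), "at least 3")
})

test_that("spectral metrics are invariant to positive channel rescaling", {
  rec <- generate_session(synth_spec(seed = 15, duration_s = 20))$recording
  scaled <- rec
  scaled$data <- rec$data * withr::with_seed(1, runif(16, 0.5, 3))
  expect_equal(spectral_entropy(scaled), spectral_entropy(rec),
               tolerance = 1e-9)
  expect_equal(band_power(scaled, band = c(8, 13)),
               band_power(rec, band = c(8, 13)), tolerance = 1e-9)
  expect_equal(snr_proxy(scaled), snr_proxy(rec), tolerance = 1e-9)
  expect_equal(correlation_to_raw(scaled, rec), 1, tolerance = 1e-9)
  expect_equal(effective_rank(scaled), effective_rank(rec))
})

test_that("band powers over a partition of the spectrum sum to one", {
  x <- generate_session(synth_spec(seed = 16, duration_s = 20))$recording
  edges <- c(0.001, 4, 8, 13, 30, fs_default / 2)
  tot <- sum(sapply(seq_len(length(edges) - 1), function(i)
    band_power(x, band = c(edges[i], edges[i + 1]))))
  expect_equal(tot, 1, tolerance = 0.01)
})

test_that("session_metrics assembles one tidy row", {
  ss <- generate_session(synth_spec(seed = 17, duration_s = 20))
  row <- session_metrics(ss$recording, ss$recording, session_id = "s1",
                         normalization = "zscore")
  expect_s3_class(row, "tbl_df")
  expect_equal(nrow(row), 1)
  expect_equal(row$corr_to_raw, 1)
  expect_true(row$snr_proxy >= 0 && row$snr_proxy <= 1)
  expect_lte(row$rank, 16)
})
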