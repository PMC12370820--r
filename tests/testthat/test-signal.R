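test_that("segment selection honours the two-hour clearance rule", {
  # seizure ending at 60 s forces the earliest window to 60 + 7200
  expect_equal(select_segment(list(c(0, 60)), 4 * 3600),
               c(start = 7260, end = 7330))
  # no clearance possible
  expect_error(select_segment(list(c(0, 600), c(8000, 8600)), 10000),
               "no interictal window")
  # random annotation sets agree with an exhaustive validity scan
  set.seed(11)
  for (rep in 1:20) {
    dur <- 6 * 3600
    k <- sample(0:3, 1)
    ann <- lapply(seq_len(k), function(i) {
      s <- runif(1, 0, dur - 120); c(s, s + runif(1, 10, 120))
    })
    brute <- NULL
    for (s in seq(0, dur - 70, by = 1)) {
      ok <- all(vapply(ann, function(iv)
        (s + 70 <= iv[1] - 7200) || (s >= iv[2] + 7200), TRUE))
      if (ok) { brute <- c(start = s, end = s + 70); break }
    }
    got <- tryCatch(select_segment(ann, dur), error = function(e) NULL)
    expect_equal(got, brute)
  }
})

test_that("channel screening flags flat, outlier and line-noise channels", {
  fs <- 256
  t <- seq(1 / fs, 12, by = 1 / fs)
  clean <- function() 10 * sin(2 * pi * 9 * t) + stats::rnorm(length(t))
  set.seed(2)
  x <- rbind(clean(), clean(), clean(), clean(), clean(), clean())
  x[2, ] <- 0.1                                   # flat
  x[4, ] <- 20 * clean()                          # amplitude outlier
  x[6, ] <- x[6, ] + 40 * sin(2 * pi * 50 * t)    # mains-dominated
  scr <- screen_channels(ts_segment(x, fs))
  expect_false(scr$keep[2]); expect_true("flat" %in% scr$reasons[[2]])
  expect_false(scr$keep[4])
  expect_true("amplitude_outlier" %in% scr$reasons[[4]])
  # verify by direct robust-z computation
  sds <- apply(x, 1, stats::sd)
  z <- abs(sds - stats::median(sds[-2])) / stats::mad(sds[-2])
  expect_gt(z[4], 5)
  expect_false(scr$keep[6])
  expect_true(any(grepl("line_noise", scr$reasons[[6]])))
  expect_true(all(scr$keep[c(1, 3, 5)]))
  # clean planted-spectrum segment passes untouched
  seg <- simulate_recording(planted_spectrum(), 8, 256, 12, seed = 3)
  expect_true(all(screen_channels(seg)$keep))
  # all-flagged input is an error
  expect_error(screen_channels(ts_segment(matrix(0, 3, fs * 4), fs)),
               "all .* flagged")
})

test_that("band-pass rejects DC, passes 10 Hz, attenuates 95 Hz", {
  fs <- 512
  t <- seq(1 / fs, 30, by = 1 / fs)
  dc <- bandpass_filter(ts_segment(matrix(5, 2, length(t)), fs))
  expect_lt(max(abs(dc$samples)), 0.05)
  s10 <- bandpass_filter(ts_segment(matrix(sin(2 * pi * 10 * t), 1), fs))
  expect_equal(proj_amp(s10$samples[1, ], 10, fs), 1, tolerance = 0.01)
  s95 <- bandpass_filter(ts_segment(matrix(sin(2 * pi * 95 * t), 1), fs))
  att_db <- -20 * log10(proj_amp(s95$samples[1, ], 95, fs))
  # 8-pole zero-phase Butterworth: ~4-pole rolloff per skirt gives ~14 dB
  # at 95 Hz analytically; assert the derived bound
  expect_gt(att_db, 12)
  expect_equal(ncol(s10$samples), length(t))
  expect_error(bandpass_filter(ts_segment(matrix(0, 2, 100), 100)),
               "too low")
})

test_that("resampling preserves sub-80 Hz content and refuses upsampling", {
  s200 <- ts_segment(matrix(stats::rnorm(400), 2), 200)
  expect_identical(downsample(s200, 200), s200)
  expect_error(downsample(s200, 500), "upsample")
  t <- seq(1 / 1000, 20, by = 1 / 1000)
  s30 <- ts_segment(matrix(sin(2 * pi * 30 * t), 1), 1000)
  y <- downsample(s30, 200)
  expect_equal(y$fs, 200)
  expect_equal(proj_amp(y$samples[1, ], 30, 200), 1, tolerance = 0.02)
  # white-noise spectral mass below 80 Hz is preserved
  set.seed(4)
  wn <- ts_segment(matrix(stats::rnorm(70 * 1000), 1), 1000)
  dn <- downsample(wn, 200)
  pi_ <- welch_psd(wn); po <- welch_psd(dn)
  mi <- sum(pi_$density[1, pi_$freq <= 80]) * 0.5
  mo <- sum(po$density[1, po$freq <= 80]) * 0.5
  expect_equal(mo, mi, tolerance = 0.05)
})

test_that("common average reference zeroes the cross-channel mean", {
  x <- matrix(stats::rnorm(5 * 100), 5)
  out <- common_average_reference(ts_segment(x, 100))
  expect_lt(max(abs(colMeans(out$samples))), 1e-12)
  # closed form for two channels
  ab <- common_average_reference(ts_segment(rbind(x[1, ], x[2, ]), 100))
  expect_equal(ab$samples[1, ], (x[1, ] - x[2, ]) / 2)
  expect_equal(ab$samples[2, ], (x[2, ] - x[1, ]) / 2)
  # identical channels cancel entirely; idempotence
  same <- common_average_reference(ts_segment(rbind(x[1, ], x[1, ]), 100))
  expect_true(all(abs(same$samples) < 1e-12))
  twice <- common_average_reference(out)
  expect_equal(twice$samples, out$samples)
  expect_error(common_average_reference(ts_segment(x[1, , drop = FALSE],
                                                   100)), "2 channels")
})

test_that("Welch PSD is density-scaled on a 0.5 Hz grid", {
  set.seed(1)
  seg <- ts_segment(matrix(stats::rnorm(2 * 70 * 200), 2), 200)
  psd <- welch_psd(seg)
  expect_equal(diff(psd$freq[1:2]), 0.5)
  # Parseval: integral of the density recovers unit variance
  expect_equal(unname(rowSums(psd$density) * 0.5), c(1, 1), tolerance = 0.05)
  # pure sinusoid concentrates its power around its frequency
  t <- seq(1 / 200, 70, by = 1 / 200)
  ps <- welch_psd(ts_segment(matrix(sin(2 * pi * 10 * t), 1), 200))
  inb <- ps$freq >= 9.5 & ps$freq <= 10.5
  expect_gt(sum(ps$density[1, inb]) / sum(ps$density[1, ]), 0.9)
  expect_error(welch_psd(ts_segment(matrix(0, 1, 100), 200)), "shorter")
})

test_that("one-window Welch equals the direct Hann periodogram", {
  set.seed(8)
  fs <- 200; nwin <- 400
  x <- stats::rnorm(nwin)
  psd <- welch_psd(ts_segment(matrix(x, 1), fs))
  # independent single-window computation
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nwin - 1) / (nwin - 1))
  xd <- (x - mean(x)) * w
  P <- Mod(stats::fft(xd))^2 / (fs * sum(w^2))
  P <- P[1:(nwin / 2 + 1)]
  P[2:(nwin / 2)] <- 2 * P[2:(nwin / 2)]
  expect_equal(psd$density[1, ], P, tolerance = 1e-12)
})

test_that("band integration follows the half-open bin rule", {
  fp <- flat_psd()
  bands <- default_bands()
  expect_equal(unname(band_power(fp, bands$delta)), 3)
  expect_equal(unname(band_power(fp, bands$theta)), 4)
  expect_equal(unname(band_power(fp, bands$alpha)), 5)
  expect_equal(unname(band_power(fp, bands$beta)), 17)
  # gamma: 47.5 Hz span minus two 5 Hz power-line exclusions
  expect_equal(unname(band_power(fp, bands$gamma)), 37.5)
  # density concentrated inside an exclusion contributes nothing
  spike <- flat_psd(0)
  spike$density[1, spike$freq == 50] <- 1000
  expect_equal(unname(band_power(spike, bands$gamma)), 0)
  expect_error(band_power(flat_psd(fmax = 40), bands$gamma), "outside")
})

test_that("relative band power is a unit-sum transform of log powers", {
  # equal band powers (10 uV^2 each): density inverse to effective width
  fp <- flat_psd(1)
  widths <- c(delta = 3, theta = 4, alpha = 5, beta = 17, gamma = 37.5)
  for (b in default_bands()) {
    sel <- fp$freq >= b$lower & fp$freq < b$upper
    fp$density[, sel] <- 10 / widths[b$name]
  }
  rbp <- relative_band_power(fp)
  expect_equal(unname(rbp[1, ]), rep(0.2, 5))
  # unit-sum contract on planted data
  seg <- simulate_recording(planted_spectrum(), 6, 512, 20, seed = 6)
  r <- extract_rbp(seg)
  expect_equal(unname(rowSums(as.matrix(r[, band_names()]))),
               rep(1, nrow(r)), tolerance = 1e-9)
  # dominant alpha planted -> alpha component largest (enough channels
  # that the common-average interference cannot cancel the oscillation)
  spa <- planted_spectrum(targets = c(delta = 1, theta = 1, alpha = 6,
                                      beta = 1, gamma = 1))
  sega <- simulate_recording(spa, 20, 512, 30, seed = 12)
  ra <- as.matrix(extract_rbp(sega)[, band_names()])
  expect_true(all(apply(ra, 1, which.max) == 3))
  # mixed-sign logs are refused: flat density 0.3 puts the delta power
  # (0.9) below 1 uV^2 and the others above it
  expect_error(relative_band_power(flat_psd(0.3)), "mixed signs")
})

test_that("the filter/resample chain is power-linear in the input", {
  seg <- simulate_recording(planted_spectrum(), 3, 512, 20, seed = 9)
  chain <- function(s) {
    s <- common_average_reference(downsample(bandpass_filter(s), 200))
    vapply(default_bands(), function(b) band_power(welch_psd(s), b)[1], 0)
  }
  b1 <- chain(seg)
  b9 <- chain(ts_segment(3 * seg$samples, 512))
  expect_equal(unname(b9 / b1), rep(9, 5), tolerance = 0.01)
})
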