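test_that("a noiseless Gaussian peak is measured essentially exactly", {
  pk <- single_gaussian_peak(rt = 10, area = 5, sigma = 0.1)
  expect_equal(pk$retention_time, 10, tolerance = 0.005 / 10)
  expect_equal(pk$area, 5, tolerance = 0.005)
  expect_equal(pk$width_at_half, 2 * sqrt(2 * log(2)) * 0.1, tolerance = 0.002)
  expect_equal(pk$height, 5 / (0.1 * sqrt(2 * pi)), tolerance = 1e-3)
})

test_that("a flat trace yields no peaks and empty chromatograms error", {
  ch <- chromatogram(seq(0, 10, 0.01), rep(0, 1001))
  out <- detect_peaks(ch, min_height = 1)
  expect_equal(nrow(out), 0L)
  expect_error(chromatogram(numeric(0), numeric(0)), "at least 2")
})

test_that("the four-analyte system elutes in the expected order", {
  ch <- generate_chromatogram()
  windows <- list(CCA = c(9.4, 9.9), ATV = c(10.7, 11.3),
                  IS = c(11.5, 12.1), CLP = c(12.4, 13.0))
  pk <- detect_peaks(ch, min_height = 1, expected = windows)
  expect_equal(pk$analyte_id, c("CCA", "ATV", "IS", "CLP"))
  expect_true(all(diff(pk$retention_time) > 0))
  expect_equal(pk$retention_time, c(9.663, 10.998, 11.802, 12.682),
               tolerance = 0.01 / 10)
  # a window with no peak is a missing-analyte error
  expect_error(detect_peaks(ch, min_height = 1, expected = list(XX = c(2, 3))),
               "missing analyte")
})

test_that("detection is invariant to a uniform signal offset", {
  ch <- gaussian_chrom(rt = 10, area = 5, sigma = 0.1)
  ch_off <- chromatogram(ch$time, ch$signal + 7.5)
  a <- detect_peaks(ch, min_height = 1)
  b <- detect_peaks(ch_off, min_height = 1)
  expect_equal(b$retention_time, a$retention_time, tolerance = 1e-10)
  expect_equal(b$height, a$height, tolerance = 1e-6)
  expect_equal(b$area, a$area, tolerance = 1e-6)
})

test_that("areas of non-overlapping peaks are additive", {
  p1 <- peak_spec("A", 8, area = 4, sigma = 0.1)
  p2 <- peak_spec("B", 14, area = 6, sigma = 0.12)
  both <- detect_peaks(generate_chromatogram(list(p1, p2)), min_height = 1)
  one <- detect_peaks(generate_chromatogram(p1), min_height = 1)
  two <- detect_peaks(generate_chromatogram(p2), min_height = 1)
  expect_equal(sum(both$area), one$area + two$area, tolerance = 0.002)
  # doubling the specified areas doubles the integrated areas
  d1 <- peak_spec("A", 8, area = 8, sigma = 0.1)
  d2 <- peak_spec("B", 14, area = 12, sigma = 0.12)
  doubled <- detect_peaks(generate_chromatogram(list(d1, d2)), min_height = 1)
  expect_equal(doubled$area, 2 * both$area, tolerance = 0.001)
})

test_that("plate count follows the half-height formula and Gaussian closed form", {
  # direct arithmetic: w0.5 = tR / sqrt(5.54) gives N = 5.54^2
  row <- synthetic_peak_row(10, width_at_half = 10 / sqrt(5.54))
  expect_equal(plate_count(row), 5.54^2)
  # Gaussian closed form: N = 5.54 (tR / (2.3548 sigma))^2
  pk <- single_gaussian_peak(rt = 10, area = 5, sigma = 0.1)
  expect_equal(plate_count(pk), 5.54 * (10 / (2 * sqrt(2 * log(2)) * 0.1))^2,
               tolerance = 0.01)
  expect_error(plate_count(synthetic_peak_row(10, width_at_half = 0)),
               "degenerate")
})

test_that("tailing factor is 1 for symmetric peaks and grows with tau", {
  pk <- single_gaussian_peak(rt = 10, area = 5, sigma = 0.1)
  expect_equal(tailing_factor(pk), 1, tolerance = 0.01)
  taus <- c(0.05, 0.1, 0.2)
  Ts <- vapply(taus, function(tau) {
    ch <- generate_chromatogram(peak_spec("E", 10, 5, 0.06, tau))
    tailing_factor(detect_peaks(ch, min_height = 1)[1, ])
  }, numeric(1))
  expect_true(all(diff(Ts) > 0))
  expect_true(all(Ts > 1))
  expect_error(tailing_factor(list(width_at_5pct = 1, front_at_5pct = 0)),
               "degenerate")
})

test_that("resolution matches the Gaussian oracle and warns on co-elution", {
  ch <- generate_chromatogram(list(peak_spec("A", 10, 5, 0.1),
                                   peak_spec("B", 11, 5, 0.1)))
  pk <- detect_peaks(ch, min_height = 1)
  # Wb = 4 sigma = 0.4 for both; Rs = 2 * 1 / 0.8 = 2.5
  expect_equal(resolution(pk[1, ], pk[2, ]), 2.5, tolerance = 0.02 * 2.5)
  expect_warning(rs0 <- resolution(pk[1, ], pk[1, ]), "co-elut")
  expect_identical(rs0, 0)
  expect_error(resolution(pk[2, ], pk[1, ]), "elute")
  # monotonicity: larger separation at fixed widths increases Rs
  shifted <- pk[2, ]; shifted$retention_time <- 12
  expect_gt(resolution(pk[1, ], shifted), resolution(pk[1, ], pk[2, ]))
})

test_that("signal-to-noise uses detrended peak-to-peak blank noise", {
  ch <- gaussian_chrom(rt = 10, area = 50, sigma = 0.1, noise = 0.05, seed = 9)
  pk <- detect_peaks(ch, min_height = 10)[1, ]
  # independent oracle for the blank excursion
  blank <- ch[ch$time >= 15 & ch$time <= 19, ]
  pp <- diff(range(resid(lm(signal ~ time, data = blank))))
  sn <- signal_to_noise(pk, ch, c(15, 19))
  expect_equal(sn, 2 * pk$height / pp, tolerance = 1e-10)
  # linear in height at fixed noise
  pk2 <- pk; pk2$height <- 2 * pk$height
  expect_equal(signal_to_noise(pk2, ch, c(15, 19)), 2 * sn, tolerance = 1e-10)
  # constructed height 1.5 x excursion gives S/N = 3
  pk3 <- pk; pk3$height <- 1.5 * pp
  expect_equal(signal_to_noise(pk3, ch, c(15, 19)), 3, tolerance = 1e-10)
})

test_that("noiseless or too-short blank regions are S/N errors", {
  ch <- gaussian_chrom(rt = 10, area = 5, sigma = 0.1)
  pk <- detect_peaks(ch, min_height = 1)[1, ]
  expect_error(signal_to_noise(pk, ch, c(15, 19)), "undefined")
  expect_error(signal_to_noise(pk, ch, c(15, 15.01)), "at least 20")
})

test_that("SST report evaluates all metrics with correct flags", {
  ch <- generate_chromatogram()
  pk <- detect_peaks(ch, min_height = 1,
                     expected = list(CCA = c(9.4, 9.9), ATV = c(10.7, 11.3),
                                     IS = c(11.5, 12.1), CLP = c(12.4, 13.0)))
  rep <- sst_evaluate(pk)
  expect_s3_class(rep, "sst_report")
  expect_true(all(rep$pass))
  expect_true(is.na(rep$resolution[1]))
  expect_true(all(rep$resolution[-1] > 2))
  expect_true(all(rep$plate_count > 2000))
  expect_true(all(rep$tailing_factor <= 2))
  # CLP's exponential tail gives a clearly asymmetric but passing peak
  expect_gt(rep$tailing_factor[rep$analyte_id == "CLP"], 1.3)
  # single peak: no resolution, with a warning
  expect_warning(one <- sst_evaluate(pk[1, ]), "one peak")
  expect_true(is.na(one$resolution))
  expect_true(one$pass)
})

test_that("a heavily tailed peak fails the tailing limit", {
  ch <- generate_chromatogram(peak_spec("E", 10, 5, 0.04, 0.4), duration = 20)
  pk <- detect_peaks(ch, min_height = 1)
  rep <- suppressWarnings(sst_evaluate(pk))
  expect_gt(rep$tailing_factor[1], 2)
  expect_false(rep$t_pass[1])
  expect_false(rep$pass[1])
})
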