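test_that("single-resonance peak and bandwidth match the closed form", {
  truth <- lorentzian_truth(500, 10)
  tf <- lorentzian_tf(500, 10, seq(100, 1500, by = 5))
  ft <- find_formants(tf)
  expect_equal(nrow(ft), 1L)
  expect_equal(ft$F_hz, truth$F, tolerance = 0.01)
  expect_equal(ft$BW_hz, truth$BW, tolerance = 0.01)
  expect_true(ft$valid)
  # the closed form itself: F = 498.75 Hz, BW ~ 50 Hz for f0=500, Q=10
  expect_equal(truth$F, 498.75, tolerance = 1e-4)
  expect_equal(truth$BW, 50, tolerance = 0.01)
})

test_that("two-resonator spectra match a continuous-crossing oracle", {
  # the exact peak and half-power crossings of the *sum* are found by
  # continuous optimization/root finding, independent of the sampled-grid
  # path under test
  mag <- function(f) lorentzian_tf(500, 10, f)$magnitude +
    lorentzian_tf(2000, 20, f)$magnitude
  oracle <- lapply(list(c(300, 700), c(1800, 2200)), function(br) {
    pk <- stats::optimize(mag, br, maximum = TRUE, tol = 1e-8)
    thr <- pk$objective / sqrt(2)
    lo <- stats::uniroot(function(f) mag(f) - thr, c(br[1] - 150,
                                                     pk$maximum),
                         tol = 1e-8)$root
    hi <- stats::uniroot(function(f) mag(f) - thr, c(pk$maximum,
                                                     br[2] + 150),
                         tol = 1e-8)$root
    c(F = pk$maximum, BW = hi - lo)
  })
  freqs <- seq(100, 3000, by = 5)
  m <- mag(freqs)
  tf <- structure(list(freqs = freqs, magnitude = m,
                       db = 20 * log10(m / max(m))),
                  class = "transfer_function")
  ft <- find_formants(tf)
  expect_equal(nrow(ft), 2L)
  expect_equal(ft$F_hz, c(oracle[[1]]["F"], oracle[[2]]["F"]),
               tolerance = 0.01, ignore_attr = TRUE)
  expect_equal(ft$BW_hz, c(oracle[[1]]["BW"], oracle[[2]]["BW"]),
               tolerance = 0.02, ignore_attr = TRUE)
  # far from each other, each peak stays within 1% of its isolated
  # resonance frequency
  t1 <- lorentzian_truth(500, 10); t2 <- lorentzian_truth(2000, 20)
  expect_equal(ft$F_hz, c(t1$F, t2$F), tolerance = 0.01)
})

test_that("flat and monotone spectra yield no formants", {
  freqs <- seq(100, 1000, by = 5)
  flat <- structure(list(freqs = freqs, magnitude = rep(1, length(freqs)),
                         db = rep(0, length(freqs))),
                    class = "transfer_function")
  expect_equal(nrow(find_formants(flat)), 0L)
  mono <- structure(list(freqs = freqs, magnitude = freqs,
                         db = 20 * log10(freqs / max(freqs))),
                    class = "transfer_function")
  expect_equal(nrow(find_formants(mono)), 0L)
})

test_that("formant extraction is invariant to magnitude scaling", {
  tf <- lorentzian_tf(500, 10, seq(100, 1500, by = 5))
  tf2 <- tf
  tf2$magnitude <- tf$magnitude * 1e3
  expect_equal(as.data.frame(find_formants(tf2)),
               as.data.frame(find_formants(tf)))
})

test_that("halving the frequency step barely moves F and BW", {
  ft5 <- find_formants(lorentzian_tf(500, 10, seq(100, 1500, by = 5)))
  ft2 <- find_formants(lorentzian_tf(500, 10, seq(100, 1500, by = 2.5)))
  expect_equal(ft2$F_hz, ft5$F_hz, tolerance = 0.002)
  expect_equal(ft2$BW_hz, ft5$BW_hz, tolerance = 0.01)
})

test_that("peaks whose half-power span leaves the sweep are invalid", {
  tf <- lorentzian_tf(500, 10, seq(480, 520, by = 5))
  ft <- find_formants(tf)
  expect_true(nrow(ft) >= 1L)
  expect_false(any(ft$valid))
})

test_that("matching identical tables is the identity", {
  ft <- formant_table(data.frame(k = 1:3, F_hz = c(500, 1500, 2500),
                                 BW_hz = c(50, 60, 70),
                                 level_db = 0, valid = TRUE))
  mt <- match_to_reference(ft, ft, window = 0.2)
  expect_equal(mt$k_found, 1:3)
  expect_true(all(mt$valid))
})

test_that("far-off candidates and short tables are flagged", {
  ref <- formant_table(data.frame(k = 1:2, F_hz = c(500, 1500),
                                  BW_hz = c(50, 60), level_db = 0,
                                  valid = TRUE))
  far <- formant_table(data.frame(k = 1, F_hz = 700, BW_hz = 50,
                                  level_db = 0, valid = TRUE))
  mt <- match_to_reference(far, ref, window = 0.2)
  expect_false(mt$valid[1])      # 40% away from 500 with a 20% window
  # 5 references, 4 candidates: exactly one invalid slot
  ref5 <- formant_table(data.frame(k = 1:5,
                                   F_hz = c(500, 1100, 1900, 2600, 3300),
                                   BW_hz = 50, level_db = 0, valid = TRUE))
  found4 <- formant_table(data.frame(k = 1:4,
                                     F_hz = c(510, 1120, 1890, 3280),
                                     BW_hz = 50, level_db = 0,
                                     valid = TRUE))
  mt <- match_to_reference(found4, ref5, window = 0.2)
  expect_equal(sum(!mt$valid), 1L)
  expect_false(mt$valid[4])
})

test_that("matching is stable under permuted candidate entry order", {
  ref <- formant_table(data.frame(k = 1:3, F_hz = c(500, 1500, 2500),
                                  BW_hz = 50, level_db = 0, valid = TRUE))
  d1 <- data.frame(k = 1:3, F_hz = c(520, 1480, 2550), BW_hz = 50,
                   level_db = 0, valid = TRUE)
  # formant_table sorts by frequency, so permuted input gives the same table
  mt1 <- match_to_reference(formant_table(d1), ref, window = 0.2)
  mt2 <- match_to_reference(formant_table(d1[c(3, 1, 2), ]), ref,
                            window = 0.2)
  expect_equal(mt1$F_found, mt2$F_found)
})

test_that("formant target tables read with kHz to Hz conversion", {
  path <- system.file("extdata", "formant_targets.csv", package = "vtfem")
  tg <- read_formant_targets(path)
  expect_equal(nrow(tg), 30L)
  a_sing <- tg[tg$vowel == "a" & tg$mode == "singing", ]
  expect_equal(a_sing$F_hz[1], 555)
  expect_equal(a_sing$BW_hz[5], 140)
  ft <- targets_as_formant_table(a_sing)
  expect_s3_class(ft, "formant_table")
  expect_equal(nrow(ft), 5L)
})
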