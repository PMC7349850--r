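test_that("band-pass keeps mid-band sinusoids and kills DC", {
  fs <- 250
  t <- seq_len(10 * fs) / fs
  data <- rbind(sin(2 * pi * 50 * t),          # mid-band
                rep(5, length(t)),             # DC
                sin(2 * pi * 10 * t))
  rownames(data) <- c("E1", "E2", "E3")
  rec <- bandpass_filter(toy_recording(data))
  mid <- seq(round(length(t) * 0.4), round(length(t) * 0.6))
  expect_lt(abs(max(abs(rec$data[1, mid])) - 1), 0.05)
  expect_lt(max(abs(rec$data[2, mid])), 1e-4)
  expect_lt(abs(max(abs(rec$data[3, mid])) - 1), 0.05)
  expect_error(bandpass_filter(toy_recording(data), high = 130),
               "Nyquist")
  expect_error(bandpass_filter(toy_recording(data), low = -1), "0 < low")
})

test_that("stop-band attenuation beats the analytic Butterworth magnitude", {
  # 5th-order high-pass at 0.3 Hz: |H(0.05)| = (f/fc)^5 / sqrt(1+(f/fc)^10)
  fs <- 250
  f <- 0.05
  t <- seq_len(100 * fs) / fs
  data <- matrix(sin(2 * pi * f * t), 1)
  rownames(data) <- "E1"
  rec <- bandpass_filter(toy_recording(data))
  h_analytic <- (f / 0.3)^5 / sqrt(1 + (f / 0.3)^10)
  mid <- seq(round(length(t) * 0.35), round(length(t) * 0.65))
  expect_lt(max(abs(rec$data[1, mid])), h_analytic)
})

test_that("designed sections are -3 dB at the band edges", {
  hp <- signal::butter(5, 0.3 / 125, type = "high")
  lp <- signal::butter(5, 75 / 125, type = "low")
  mag <- function(flt, f_hz) {
    z <- exp(-1i * 2 * pi * f_hz / 250 * (seq_along(flt$b) - 1))
    Mod(sum(flt$b * z) / sum(flt$a * z))
  }
  expect_equal(mag(hp, 0.3), 1 / sqrt(2), tolerance = 1e-4)
  expect_equal(mag(lp, 75), 1 / sqrt(2), tolerance = 1e-4)
})

test_that("segmentation cuts floor(n/500) non-overlapping windows", {
  mk <- function(n) {
    d <- matrix(seq_len(2 * n), nrow = 2, byrow = TRUE)
    rownames(d) <- c("E1", "E2")
    toy_recording(d)
  }
  expect_length(segment_recording(mk(1500))$segments, 3)
  s <- segment_recording(mk(1499))
  expect_length(s$segments, 2)
  expect_equal(unname(s$segments[[2]][1, 500]), 1000)  # contiguous windows
  expect_length(segment_recording(mk(30000))$segments, 60)
  expect_error(segment_recording(mk(499)), "fewer than one")
})

test_that("amplitude rejection drops exactly the offending windows", {
  set.seed(42)
  data <- matrix(runif(3 * 2500, -50, 50), nrow = 3)
  rownames(data) <- c("E1", "E2", "E3")
  seg_all <- reject_artifacts(segment_recording(toy_recording(data)))
  expect_length(seg_all$segments, 5)
  expect_true(all(seg_all$retained_mask))
  # one 150 uV excursion in window 3 only
  data2 <- data
  data2[2, 1250] <- 150
  seg <- reject_artifacts(segment_recording(toy_recording(data2)))
  expect_equal(seg$retained_mask, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_length(seg$segments, 4)
  # everything over threshold -> labelled error naming the subject
  data3 <- data + 200
  expect_error(reject_artifacts(segment_recording(toy_recording(data3,
                                                                id = "S9"))),
               "S9")
  # flagged bad channels do not veto windows
  seg_bad <- reject_artifacts(
    segment_recording(toy_recording(data2, bad = "E2")))
  expect_true(all(seg_bad$retained_mask))
})

test_that("bad-channel interpolation uses inverse-distance weights", {
  montage <- data.frame(
    label = c("B", "N1", "N2", "N3", "N4", "N5", "N6", "F"),
    x = c(0, 1, 2, 0, 0, 3, 0, 10),
    y = c(0, 0, 0, 2, 0, 0, 4, 0),
    z = c(0, 0, 0, 0, 3, 0, 0, 0))
  class(montage) <- c("eeg_montage", "data.frame")
  vals <- c(0, 10, 20, 30, 40, 50, 60, 70)
  data <- matrix(rep(vals, 500), nrow = 8)
  rownames(data) <- montage$label
  seg <- segment_recording(toy_recording(data, fs = 250), 500)
  out <- interpolate_bad_channels(seg, montage, bad = "B", k = 6)
  # hand-computed: the 6 nearest of B are N1..N6 at distances 1..4 (F at 10
  # is excluded); weights 1/d normalised
  d <- c(1, 2, 2, 3, 3, 4)
  w <- (1 / d) / sum(1 / d)
  expected <- sum(w * c(10, 20, 30, 40, 50, 60))
  expect_equal(unique(as.vector(out$segments[[1]]["B", ])), expected,
               tolerance = 1e-12)
  expect_identical(out$interpolated_channels, "B")
  # untouched good channels
  expect_identical(out$segments[[1]]["N3", ], seg$segments[[1]]["N3", ])
  # identity on empty bad list
  expect_identical(interpolate_bad_channels(seg, montage, bad = character()),
                   seg)
  # identical neighbours reproduce the common signal exactly (weights sum 1)
  s_t <- sin(seq_len(500) / 10)
  data_eq <- rbind(B = rep(0, 500), N1 = s_t, N2 = s_t, N3 = s_t, N4 = s_t,
                   N5 = s_t, N6 = s_t, F = rep(9, 500))
  seg_eq <- segment_recording(toy_recording(data_eq), 500)
  out_eq <- interpolate_bad_channels(seg_eq, montage, bad = "B", k = 6)
  expect_equal(as.vector(out_eq$segments[[1]]["B", ]), s_t,
               tolerance = 1e-12)
  # refuse to repair more than 20% of channels
  expect_error(interpolate_bad_channels(seg, montage, bad = c("B", "N1")),
               "20%")
  expect_error(interpolate_bad_channels(seg, montage, bad = "ZZ"),
               "not in montage")
})

test_that("average re-reference zeroes the channel mean at every sample", {
  a <- sin(seq_len(1000) / 7)
  d1 <- rbind(E1 = a, E2 = -a)
  seg1 <- rereference_average(segment_recording(toy_recording(d1)))
  expect_equal(seg1$segments[[1]], segment_recording(toy_recording(d1))$segments[[1]],
               tolerance = 1e-12)
  d2 <- rbind(E1 = a, E2 = a, E3 = a)
  seg2 <- rereference_average(segment_recording(toy_recording(d2)))
  expect_lt(max(abs(seg2$segments[[1]])), 1e-12)
  set.seed(3)
  d3 <- matrix(rnorm(4 * 500), 4, dimnames = list(paste0("E", 1:4), NULL))
  seg3 <- rereference_average(segment_recording(toy_recording(d3)))
  expect_lt(max(abs(colMeans(seg3$segments[[1]]))), 1e-10)
  # idempotent
  expect_equal(rereference_average(seg3)$segments, seg3$segments,
               tolerance = 1e-14)
})

test_that("within-segment demeaning leaves Pearson correlations unchanged", {
  set.seed(8)
  d <- matrix(rnorm(6 * 1000), 6, dimnames = list(paste0("E", 1:6), NULL))
  d <- d + c(10, -5, 3, 0, 100, -40)          # channel offsets
  seg <- segment_recording(toy_recording(d))
  w_raw <- subject_connectivity(seg)$weights
  w_dem <- subject_connectivity(demean_segments(seg))$weights
  expect_equal(w_dem, w_raw, tolerance = 1e-12)
})

test_that("the full preprocessing chain yields clean bounded segments", {
  cfg <- simulation_config(group_sizes = c(HC = 2, SCD = 2, MCI = 2, AD = 2),
                           n_channels = 32, duration_s = 10, seed = 19)
  cohort <- generate_cohort(cfg)
  montage <- attr(cohort, "montage")
  seg <- preprocess_recording(cohort[[1]], montage)
  expect_gte(length(seg$segments), 2)
  expect_lt(max(abs(colMeans(seg$segments[[1]]))), 1e-10)
  expect_true(all(cohort[[1]]$bad_channels %in% seg$interpolated_channels))
})
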