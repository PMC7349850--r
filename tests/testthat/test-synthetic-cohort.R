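small_config <- function(...) {
  args <- modifyList(list(group_sizes = c(HC = 2, SCD = 2, MCI = 2, AD = 2),
                          n_channels = 32, duration_s = 8, seed = 11),
                     list(...))
  do.call(simulation_config, args)
}

test_that("simulation config validates its invariants", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(group_sizes = c(HC = 1, SCD = 2, MCI = 2,
                                                 AD = 2)),
               "at least 2 subjects")
  expect_error(simulation_config(artifact_rate = 1.5), "artifact_rate")
  expect_error(simulation_config(duration_s = 2), "at least 2 windows")
  expect_error(simulation_config(ar_coefficient = 1), "ar_coefficient")
  expect_error(simulation_config(parietal_coupling = c(HC = -1, SCD = 1,
                                                       MCI = 1, AD = 1)),
               "non-negative")
})

test_that("generate_subject produces a well-formed recording", {
  cfg <- small_config()
  montage <- montage_subset(gsn_montage(256), cfg$n_channels)
  set.seed(1)
  rec <- generate_subject("HC", cfg, montage, "HC_01")
  expect_s3_class(rec, "eeg_recording")
  expect_equal(dim(rec$data), c(32, 8 * 250))
  expect_equal(rownames(rec$data), montage$label)
  expect_false(anyNA(rec$data))
  expect_error(generate_subject("XX", cfg, montage), "unknown group")
})

test_that("closed-form expected parietal correlation matches hand values", {
  # (alpha^2 + beta^2) / (alpha^2 + beta^2 + 1), evaluated by hand
  expect_equal(expected_parietal_pcc(1.9, 0.6), 3.97 / 4.97)
  expect_equal(expected_parietal_pcc(1.2, 0.6), 1.80 / 2.80)
  expect_equal(expected_parietal_pcc(0, 0), 0)
})

test_that("sample parietal correlations converge to the closed form", {
  # single subject, no subject-level heterogeneity, 200 windows of white
  # innovations-driven AR signal; Monte-Carlo mean of per-window |PCC|
  cfg <- simulation_config(group_sizes = c(HC = 2, SCD = 2, MCI = 2, AD = 2),
                           n_channels = 32, duration_s = 400,
                           coupling_sd = 0, global_coupling_sd = 0,
                           artifact_rate = 0, bad_channel_count = 0,
                           seed = 21)
  montage <- montage_subset(gsn_montage(256), 32)
  set.seed(21)
  for (case in list(list(g = "HC", expected = 3.97 / 4.97),
                    list(g = "AD", expected = 1.80 / 2.80))) {
    rec <- generate_subject(case$g, cfg, montage)
    seg <- segment_recording(rec)
    cm <- subject_connectivity(seg, channels = parietal_electrodes(),
                               scope = "local")
    expect_equal(cm$n_segments_used, 200)
    m <- mean(cm$weights[upper.tri(cm$weights)])
    # 0.012 = 3 Monte-Carlo SEs plus the known finite-window estimator bias
    # (-rho(1-rho^2)/(2 n_eff), about -0.006 at these autocorrelations)
    expect_lt(abs(m - case$expected), 0.012)
  }
})

test_that("uncoupled white channels decorrelate to folded-normal level", {
  cfg <- simulation_config(group_sizes = c(HC = 2, SCD = 2, MCI = 2, AD = 2),
                           n_channels = 32, duration_s = 20,
                           parietal_coupling = c(HC = 0, SCD = 0, MCI = 0,
                                                 AD = 0),
                           global_coupling = 0, ar_coefficient = 0,
                           coupling_sd = 0, global_coupling_sd = 0,
                           artifact_rate = 0, bad_channel_count = 0,
                           seed = 31)
  montage <- montage_subset(gsn_montage(256), 32)
  set.seed(31)
  rec <- generate_subject("HC", cfg, montage)
  cm <- subject_connectivity(segment_recording(rec))
  m <- mean(cm$weights[upper.tri(cm$weights)])
  expect_lt(m, 2 / sqrt(500))
})

test_that("artifact injection is rejectable by construction and seed-stable", {
  cfg <- small_config(artifact_rate = 1)
  montage <- montage_subset(gsn_montage(256), 32)
  set.seed(5)
  rec <- inject_artifacts(generate_subject("HC", cfg, montage), cfg)
  win <- cfg$window_samples
  n_win <- floor(ncol(rec$data) / win)
  for (w in seq_len(n_win)) {
    block <- rec$data[, ((w - 1) * win + 1):(w * win)]
    expect_gte(max(abs(block)), cfg$artifact_amplitude)
  }
  # rate 0 leaves the signal untouched
  cfg0 <- small_config(artifact_rate = 0, bad_channel_count = 0)
  set.seed(6); rec_a <- generate_subject("HC", cfg0, montage)
  rec_b <- inject_artifacts(rec_a, cfg0)
  expect_identical(rec_b$data, rec_a$data)
  expect_identical(rec_b$bad_channels, rec_a$bad_channels)
  # seed replay reproduces the same affected windows
  cfg2 <- small_config(artifact_rate = 0.2, duration_s = 120)
  hit <- function() {
    set.seed(77)
    rec <- inject_artifacts(generate_subject("HC", cfg2, montage), cfg2)
    attr(rec, "artifact_windows")
  }
  h1 <- hit(); h2 <- hit()
  expect_identical(h1, h2)
  expect_true(length(h1) >= 1)
  expect_error(inject_artifacts(generate_subject("HC", cfg, montage),
                                small_config(artifact_amplitude = 90)),
               "exceed the 100 uV")
})

test_that("bad channels are overwritten, listed and detectable", {
  cfg <- small_config(bad_channel_count = 2, artifact_rate = 0)
  montage <- montage_subset(gsn_montage(256), 32)
  set.seed(9)
  rec <- inject_artifacts(generate_subject("HC", cfg, montage), cfg)
  expect_length(rec$bad_channels, 2)
  expect_setequal(detect_bad_channels(rec), rec$bad_channels)
})

test_that("cohort generation is deterministic given the config seed", {
  cfg <- small_config()
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_equal(length(c1), 8)
  expect_identical(c1[["MCI_02"]]$data, c2[["MCI_02"]]$data)
  expect_identical(lapply(c1, `[[`, "bad_channels"),
                   lapply(c2, `[[`, "bad_channels"))
})

test_that("synthetic neuropsych scores carry the designed correlations", {
  # large synthetic cohort shell; only id/group are consumed
  set.seed(123)
  n <- 400
  groups <- sample(c("HC", "SCD", "MCI", "AD"), n, replace = TRUE)
  shell <- lapply(seq_len(n), function(i) {
    list(subject_id = sprintf("S%03d", i), group = groups[i])
  })
  metric <- setNames(rnorm(n), sprintf("S%03d", seq_len(n)))
  scores <- generate_neuropsych(shell, metric)
  expect_true(all(scores$MMSE >= 0 & scores$MMSE <= 30))
  expect_lt(cor(scores$MMSE, metric), 0)          # cognition down with BC
  expect_gt(cor(scores$FRSSD_sleep, metric), 0.3) # impairment up with BC
  expect_lt(cor(scores$ROCFT_copy, metric), -0.3)
  expect_error(generate_neuropsych(list(), metric), "empty cohort")
  # deterministic linear map: r = -1 and no noise recovers a perfect
  # negative correlation
  battery <- list(T1 = list(means = c(HC = 0, SCD = 0, MCI = 0, AD = 0),
                            sd = 1, r = -1))
  s2 <- generate_neuropsych(shell, metric, battery)
  expect_equal(cor(s2$T1, metric), -1, tolerance = 1e-12)
})

test_that("a cohort round-trips through the delimited on-disk format", {
  cfg <- small_config()
  cohort <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  back <- read_cohort(dir)
  expect_equal(names(back), names(cohort))
  expect_equal(back[["AD_01"]]$group, "AD")
  expect_equal(back[["AD_01"]]$data, cohort[["AD_01"]]$data,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(back[["AD_01"]]$bad_channels,
                   cohort[["AD_01"]]$bad_channels)
})
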