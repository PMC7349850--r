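#' Simulation configuration for the synthetic resting-state cohort
#'
#' Defines the study conditions the cohort generator emulates: four
#' diagnostic groups (HC, SCD, MCI, AD) whose parietal-cluster coupling
#' weakens monotonically along the disease continuum, a weaker whole-head
#' common source, autocorrelated channel noise, occasional high-amplitude
#' artifacts and a few bad channels.
#'
#' The signal model for channel \eqn{c} of subject \eqn{i} is
#' \deqn{x_c(t) = s \,[\, a_c \, s_P(t) + \beta_i h_c \, s_G(t) +
#'   \sigma \varepsilon_c(t) \,]}
#' where \eqn{s_P, s_G} are independent unit-variance AR(1) latent sources
#' with coefficient \eqn{\phi}, \eqn{a_c = \alpha_i} on parietal channels and
#' 0 elsewhere, \eqn{\varepsilon_c} is independent unit-variance AR(1) noise,
#' and \eqn{s} is the microvolt scale.  Two subject-level random effects
#' create between-subject spread (without them every subject in a group is
#' statistically identical and group discrimination degenerates):
#' \eqn{\alpha_i \sim N(\alpha_g, \code{coupling_sd})} truncated at 0, and
#' \eqn{\beta_i = \beta \exp(\tau z - \tau^2)}, \eqn{z} standard normal truncated to [-2, 2], with
#' \eqn{\tau = \code{global_coupling_sd}} (so \eqn{E\beta_i^2 = \beta^2}).
#' The whole-head source has a fixed channel topography \eqn{h_c} (1 on the
#' parietal cluster, quasi-uniform in \eqn{[0.3, 1.7]} elsewhere; see
#' [channel_topography()]), so the average reference does not cancel it
#' exactly.
#'
#' With unit noise (\code{noise_sd = 1}) the expected absolute correlation
#' between two parietal channels is \eqn{(\alpha^2+\beta^2) /
#' (\alpha^2+\beta^2+1)} and between two non-parietal channels
#' \eqn{\beta^2/(\beta^2+1)} -- the module's closed-form oracle, see
#' [expected_parietal_pcc()].
#'
#' @param group_sizes named integer vector, subjects per group.
#' @param n_channels number of electrodes (a subset of the 256-label montage
#'   that always contains the parietal set; see [montage_subset()]).
#' @param fs sampling rate in Hz.
#' @param duration_s recording length per subject in seconds.
#' @param parietal_coupling named vector \eqn{\alpha_g \ge 0} per group.
#' @param global_coupling whole-head source loading \eqn{\beta \ge 0}.
#' @param ar_coefficient AR(1) coefficient \eqn{\phi \in [0, 1)} of sources
#'   and noise.
#' @param noise_sd channel-noise scale (factor-model units).
#' @param signal_scale microvolt multiplier applied to the whole signal.
#' @param artifact_rate probability that a 500-sample window receives an
#'   injected artifact.
#' @param artifact_amplitude artifact pulse amplitude in microvolts; must
#'   exceed the 100 uV rejection threshold so injected events are rejectable
#'   by construction.
#' @param bad_channel_count number of channels overwritten with
#'   high-variance noise.
#' @param coupling_sd between-subject SD of the parietal coupling.
#' @param global_coupling_sd log-scale between-subject SD of the whole-head
#'   source loading.
#' @param window_samples segment length used to size the recording check.
#' @param seed integer seed driving all randomness of the generator.
#' @return a validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(group_sizes = c(HC = 22, SCD = 20, MCI = 30, AD = 20),
                              n_channels = 256,
                              fs = 250,
                              duration_s = 120,
                              parietal_coupling = c(HC = 1.9, SCD = 1.5,
                                                    MCI = 1.4, AD = 1.2),
                              global_coupling = 0.6,
                              ar_coefficient = 0.95,
                              noise_sd = 1,
                              signal_scale = 6,
                              artifact_rate = 0.05,
                              artifact_amplitude = 150,
                              bad_channel_count = 2,
                              coupling_sd = 0.12,
                              global_coupling_sd = 0.5,
                              window_samples = 500,
                              seed = 1L) {
  cfg <- list(group_sizes = group_sizes, n_channels = as.integer(n_channels),
              fs = fs, duration_s = duration_s,
              parietal_coupling = parietal_coupling,
              global_coupling = global_coupling,
              ar_coefficient = ar_coefficient, noise_sd = noise_sd,
              signal_scale = signal_scale, artifact_rate = artifact_rate,
              artifact_amplitude = artifact_amplitude,
              bad_channel_count = as.integer(bad_channel_count),
              coupling_sd = coupling_sd,
              global_coupling_sd = global_coupling_sd,
              window_samples = as.integer(window_samples),
              seed = as.integer(seed))
  validate_simulation_config(cfg)
}

validate_simulation_config <- function(cfg) {
  problems <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(length(cfg$group_sizes) >= 1 && !is.null(names(cfg$group_sizes)) &&
        all(nzchar(names(cfg$group_sizes))), "group_sizes must be named")
  chk(all(cfg$group_sizes >= 2), "every group needs at least 2 subjects")
  chk(all(names(cfg$group_sizes) %in% names(cfg$parietal_coupling)),
      "parietal_coupling must cover every group in group_sizes")
  chk(all(is.finite(cfg$parietal_coupling)) && all(cfg$parietal_coupling >= 0),
      "parietal couplings must be finite and non-negative")
  chk(is.finite(cfg$global_coupling) && cfg$global_coupling >= 0,
      "global_coupling must be finite and non-negative")
  chk(cfg$ar_coefficient >= 0 && cfg$ar_coefficient < 1,
      "ar_coefficient must lie in [0, 1)")
  chk(cfg$noise_sd > 0, "noise_sd must be positive")
  chk(cfg$fs > 0, "fs must be positive")
  chk(cfg$duration_s > 0, "duration must be positive")
  chk(cfg$artifact_rate >= 0 && cfg$artifact_rate <= 1,
      "artifact_rate must lie in [0, 1]")
  chk(cfg$bad_channel_count >= 0, "bad_channel_count must be non-negative")
  chk(cfg$coupling_sd >= 0 && cfg$global_coupling_sd >= 0,
      "subject-level coupling SDs must be non-negative")
  n_samples <- floor(cfg$fs * cfg$duration_s)
  chk(n_samples >= 2 * cfg$window_samples,
      sprintf("recording must hold at least 2 windows of %d samples",
              cfg$window_samples))
  if (length(problems)) {
    stop("invalid simulation config:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

#' Closed-form expected absolute correlation between two parietal channels
#'
#' Under the latent-factor signal model, two parietal channels share the
#' parietal source (loading \eqn{\alpha}) and the whole-head source
#' (loading \eqn{\beta}) on top of independent noise of standard deviation
#' \eqn{\sigma}, so their correlation is
#' \eqn{(\alpha^2 + \beta^2) / (\alpha^2 + \beta^2 + \sigma^2)}.
#' This is the generator's analytic oracle against which Monte-Carlo sample
#' correlations are checked.
#'
#' @param alpha parietal coupling.
#' @param beta whole-head coupling.
#' @param noise_sd channel-noise scale.
#' @return expected correlation in [0, 1).
#' @export
expected_parietal_pcc <- function(alpha, beta = 0.6, noise_sd = 1) {
  (alpha^2 + beta^2) / (alpha^2 + beta^2 + noise_sd^2)
}

#' Fixed whole-head source topography
#'
#' Deterministic per-channel gain of the whole-head common source.  Over
#' the parietal cluster the gain is exactly 1 (the cluster is modelled as a
#' coherent hub, and a uniform gain there keeps the parietal closed form
#' exact); elsewhere it is a low-discrepancy sequence mapped to
#' \eqn{[0.3, 1.7]} (mean approximately 1), keyed by the numeric part of
#' the electrode label so a channel keeps its gain under montage
#' subsetting.  The non-uniform scalp pattern is what survives average
#' re-referencing and gives the whole-head scope its subject-specific
#' background connectivity.
#'
#' @param labels electrode labels (`E<k>` form).
#' @return numeric vector of gains, one per label.
#' @export
channel_topography <- function(labels) {
  idx <- as.integer(sub("^E", "", labels))
  if (anyNA(idx)) stop("labels must have the form E<number>")
  golden <- (sqrt(5) - 1) / 2
  h <- 0.3 + 1.4 * ((idx * golden) %% 1)
  h[labels %in% parietal_electrodes()] <- 1
  h
}

#' Generate one synthetic resting-state recording
#'
#' Draws the subject-level couplings, simulates the latent AR(1) sources and
#' channel noise, and mixes them per the factor model described in
#' [simulation_config()].  All bulk Gaussian innovations come from a
#' compiled xoshiro256++ stream whose sub-seed is drawn from R's RNG, so the
#' whole cohort is reproducible from the single config seed.
#'
#' @param group group label; must appear in `config$group_sizes`.
#' @param config a [simulation_config()].
#' @param montage montage restricted to the channels to simulate.
#' @param subject_id identifier stored in the recording.
#' @return an `eeg_recording`: list with `subject_id`, `group`, `data`
#'   (channels x samples matrix in microvolts, rownames = labels), `fs`,
#'   `montage_ref`, `bad_channels` (empty here; filled by
#'   [inject_artifacts()]) and the drawn couplings as attributes.
#' @export
generate_subject <- function(group, config, montage, subject_id = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!group %in% names(config$group_sizes)) {
    stop("unknown group '", group, "'; configured groups: ",
         paste(names(config$group_sizes), collapse = ", "))
  }
  if (config$duration_s <= 0) stop("non-positive duration")
  labels <- setdiff(montage$label, "Cz")
  n_ch <- length(labels)
  n <- floor(config$fs * config$duration_s)
  burn <- 150L
  phi <- config$ar_coefficient

  alpha_g <- config$parietal_coupling[[group]]
  alpha_i <- max(0, rnorm(1, alpha_g, config$coupling_sd))
  tau <- config$global_coupling_sd
  # log-normal subject scale, truncated at +/- 2 SD so no subject's clean
  # signal amplitude approaches the 100 uV rejection threshold
  z <- max(-2, min(2, rnorm(1)))
  beta_i <- config$global_coupling * exp(tau * z - tau^2)

  parietal <- labels %in% parietal_electrodes()
  a <- ifelse(parietal, alpha_i, 0)
  b <- beta_i * channel_topography(labels)

  # innovations for [s_P, s_G, noise...]; AR(1) scaled to unit stationary
  # variance, 150-sample burn-in discarded; recursion and factor mixing are
  # fused in compiled code
  sub_seed <- floor(runif(1) * 2^31)
  innov <- cpp_rnorm_mat(n + burn, n_ch + 2L, sqrt(1 - phi^2), sub_seed)
  data <- cpp_simulate_channels(innov, phi, a, b, config$noise_sd,
                                config$signal_scale, burn)
  rownames(data) <- labels

  rec <- structure(
    list(subject_id = subject_id %||% paste0(group, "_x"),
         group = group, data = data, fs = config$fs,
         montage_ref = "gsn256-synthetic", bad_channels = character()),
    class = "eeg_recording")
  attr(rec, "alpha") <- alpha_i
  attr(rec, "beta") <- beta_i
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inject rejectable artifacts and bad channels into a recording
#'
#' Each 500-sample window is independently selected with probability
#' `artifact_rate`; a selected window gets a bipolar square pulse of
#' amplitude `artifact_amplitude` (above the 100 uV rejection threshold by
#' construction) added to one randomly chosen channel.  Additionally
#' `bad_channel_count` channels are overwritten with high-variance white
#' noise and listed in `bad_channels`.
#'
#' @param recording an `eeg_recording`.
#' @param config a [simulation_config()].
#' @return the modified recording.
#' @export
inject_artifacts <- function(recording, config) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (config$artifact_rate < 0 || config$artifact_rate > 1) {
    stop("artifact_rate must lie in [0, 1]")
  }
  if (config$artifact_amplitude <= 100) {
    stop("artifact_amplitude must exceed the 100 uV rejection threshold")
  }
  data <- recording$data
  n_ch <- nrow(data)
  n <- ncol(data)
  win <- config$window_samples
  n_win <- floor(n / win)

  n_bad <- min(config$bad_channel_count, n_ch)
  bad_idx <- integer()
  if (n_bad > 0) {
    bad_idx <- sample.int(n_ch, n_bad)
    # high-variance white noise; detectable by the 5x-median-variance rule
    data[bad_idx, ] <- matrix(rnorm(n_bad * n, sd = 50), n_bad, n)
    recording$bad_channels <- sort(rownames(data)[bad_idx])
  }

  if (config$artifact_rate > 0 && n_win > 0) {
    hit <- which(runif(n_win) < config$artifact_rate)
    good <- setdiff(seq_len(n_ch), bad_idx)
    # bipolar square pulse: 2 cycles of 50-sample half-periods, robust to
    # high-pass sag and to cancellation by the underlying signal
    pulse <- config$artifact_amplitude *
      rep(c(1, -1), each = 50, times = 2)
    for (w in hit) {
      ch <- good[sample.int(length(good), 1)]
      start <- (w - 1) * win + sample.int(win - length(pulse) + 1, 1)
      idx <- start:(start + length(pulse) - 1)
      data[ch, idx] <- data[ch, idx] + pulse
    }
    attr(recording, "artifact_windows") <- hit
  } else {
    attr(recording, "artifact_windows") <- integer()
  }
  recording$data <- data
  recording
}

default_montage <- function(config) {
  montage <- gsn_montage(256)
  if (config$n_channels < 256) montage <- montage_subset(montage,
                                                         config$n_channels)
  montage
}

#' Stream a synthetic cohort through a per-subject function
#'
#' Seeds R's RNG from `config$seed`, then generates and contaminates every
#' subject group by group (ids `<group>_<k>`), calling `f` on each finished
#' recording and keeping only `f`'s value.  This is the memory-frugal spine
#' of every cohort computation: a full-length 256-channel recording is tens
#' of megabytes, so whole cohorts are processed subject by subject and
#' never held in memory at once unless explicitly requested
#' ([generate_cohort()]).
#'
#' @param config a [simulation_config()].
#' @param f function of one `eeg_recording`.
#' @param montage montage to simulate on; defaults to the synthetic
#'   256-channel net subset to `config$n_channels` channels (parietal set
#'   always preserved).
#' @return named list of `f`'s return values, with the montage attached as
#'   an attribute.
#' @export
cohort_map <- function(config, f, montage = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(montage)) montage <- default_montage(config)
  set.seed(config$seed)
  out <- list()
  n_done <- 0L
  big <- config$n_channels * config$fs * config$duration_s > 5e6
  for (g in names(config$group_sizes)) {
    for (k in seq_len(config$group_sizes[[g]])) {
      id <- sprintf("%s_%02d", g, k)
      rec <- generate_subject(g, config, montage, subject_id = id)
      rec <- inject_artifacts(rec, config)
      out[[id]] <- f(rec)
      rm(rec)
      n_done <- n_done + 1L
      # keep the allocator's high-water mark down on full-length cohorts:
      # each subject churns several hundred MB of short-lived matrices
      if (big && n_done %% 4L == 0L) gc(FALSE)
    }
  }
  attr(out, "montage") <- montage
  out
}

#' Generate the full synthetic cohort
#'
#' Materialises every recording of the streamed cohort ([cohort_map()]) in
#' one list.  Intended for small study configurations; full-length default
#' cohorts are better processed subject by subject.
#'
#' @param config a [simulation_config()].
#' @param montage montage to simulate on; defaults to the full synthetic
#'   256-channel net, subset to `config$n_channels` channels while always
#'   preserving the parietal set.
#' @return list of `eeg_recording` objects with attributes `config` and
#'   `montage`, class `"eeg_cohort"`.
#' @export
generate_cohort <- function(config, montage = NULL) {
  cohort <- cohort_map(config, identity, montage)
  structure(cohort, config = config, montage = attr(cohort, "montage"),
            class = "eeg_cohort")
}

#' @export
print.eeg_cohort <- function(x, ...) {
  groups <- vapply(x, function(r) r$group, character(1))
  cat("<eeg_cohort> ", length(x), " subjects (",
      paste(sprintf("%s=%d", names(table(groups)), table(groups)),
            collapse = ", "), ")\n", sep = "")
  cfg <- attr(x, "config")
  cat("  ", nrow(x[[1]]$data), " channels x ", ncol(x[[1]]$data),
      " samples @ ", cfg$fs, " Hz\n", sep = "")
  invisible(x)
}

# anchors for the synthetic neuropsychological battery: group means and
# within-group SDs in the range reported for such cohorts, plus the target
# sign/magnitude of the correlation with local betweenness centrality
neuropsych_battery <- function() {
  list(
    MMSE        = list(means = c(HC = 29.1, SCD = 29.3, MCI = 27.1, AD = 22.3),
                       sd = 2.0, r = -0.25, lower = 0, upper = 30),
    FUCAS       = list(means = c(HC = 42.0, SCD = 42.6, MCI = 44.8, AD = 50.4),
                       sd = 4.0, r = 0.28),
    FRSSD_sleep = list(means = c(HC = 0.3, SCD = 0.5, MCI = 0.8, AD = 1.2),
                       sd = 0.8, r = 0.52, lower = 0),
    RBMT_delay  = list(means = c(HC = 15.4, SCD = 13.1, MCI = 12.0, AD = 9.5),
                       sd = 3.3, r = -0.36, lower = 0),
    ROCFT_copy  = list(means = c(HC = 33.5, SCD = 33.7, MCI = 30.2, AD = 22.8),
                       sd = 5.0, r = -0.50, lower = 0, upper = 36)
  )
}

#' Generate correlated synthetic neuropsychological scores
#'
#' Scores are anchored at group means typical for each instrument and carry
#' a component proportional to the subject's z-scored network metric
#' (by convention local betweenness centrality), with signs fixed so that
#' cognitive scores (MMSE-like, memory recall, figure copy) correlate
#' negatively and impairment scores (functional assessment, sleep problems)
#' positively with the metric, plus independent Gaussian noise.
#'
#' @param cohort an `eeg_cohort` (or any list of recordings with `group`).
#' @param metric_per_subject named numeric vector, one value per subject
#'   (names = subject ids), typically local betweenness centrality.
#' @param battery battery definition; see `eegconnectome:::neuropsych_battery`.
#' @return `data.frame` with `subject_id`, `group` and one column per test.
#' @export
generate_neuropsych <- function(cohort, metric_per_subject,
                                battery = neuropsych_battery()) {
  if (length(cohort) == 0) stop("empty cohort")
  ids <- vapply(cohort, function(r) r$subject_id, character(1))
  groups <- vapply(cohort, function(r) r$group, character(1))
  if (!all(ids %in% names(metric_per_subject))) {
    stop("metric_per_subject must provide one value per subject")
  }
  m <- metric_per_subject[ids]
  z <- as.numeric(scale(m))
  if (any(!is.finite(z))) z <- rep(0, length(m))  # degenerate: constant metric
  out <- data.frame(subject_id = ids, group = groups,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (test in names(battery)) {
    spec <- battery[[test]]
    r <- spec$r
    score <- spec$means[groups] +
      spec$sd * (r * z + sqrt(1 - r^2) * rnorm(length(z)))
    if (!is.null(spec$lower)) score <- pmax(spec$lower, score)
    if (!is.null(spec$upper)) score <- pmin(spec$upper, score)
    out[[test]] <- as.numeric(score)
  }
  out
}

#' Write / read a cohort as delimited text
#'
#' Per-subject signal matrices are written as tab-separated tables with one
#' column per electrode (header row = electrode labels) and one row per
#' sample, in microvolts; a `manifest.tsv` records subject id, group, file
#' and bad channels, and the config is stored as YAML.
#'
#' @param cohort an `eeg_cohort`.
#' @param dir output directory (created if needed).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` returns the
#'   cohort.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- attr(cohort, "config")
  montage <- attr(cohort, "montage")
  manifest <- data.frame(
    subject_id = vapply(cohort, function(r) r$subject_id, character(1)),
    group = vapply(cohort, function(r) r$group, character(1)),
    file = paste0(vapply(cohort, function(r) r$subject_id, character(1)), ".tsv"),
    bad_channels = vapply(cohort, function(r)
      paste(r$bad_channels, collapse = ";"), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  for (rec in cohort) {
    data.table::fwrite(data.table::as.data.table(t(rec$data)),
                       file.path(dir, paste0(rec$subject_id, ".tsv")),
                       sep = "\t")
  }
  data.table::fwrite(manifest, file.path(dir, "manifest.tsv"), sep = "\t")
  if (!is.null(cfg)) {
    cfg_out <- unclass(cfg)
    cfg_out$group_sizes <- as.list(cfg_out$group_sizes)
    cfg_out$parietal_coupling <- as.list(cfg_out$parietal_coupling)
    yaml::write_yaml(cfg_out, file.path(dir, "config.yaml"))
  }
  if (!is.null(montage)) write_montage(montage, file.path(dir, "montage.tsv"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- as.data.frame(data.table::fread(file.path(dir, "manifest.tsv"),
                                              sep = "\t"))
  cfg <- NULL
  cfg_path <- file.path(dir, "config.yaml")
  if (file.exists(cfg_path)) {
    raw <- yaml::read_yaml(cfg_path)
    raw$group_sizes <- unlist(raw$group_sizes)
    raw$parietal_coupling <- unlist(raw$parietal_coupling)
    cfg <- validate_simulation_config(raw)
  }
  montage <- NULL
  if (file.exists(file.path(dir, "montage.tsv"))) {
    montage <- read_montage(file.path(dir, "montage.tsv"))
  }
  fs <- if (!is.null(cfg)) cfg$fs else 250
  cohort <- list()
  for (i in seq_len(nrow(manifest))) {
    tab <- data.table::fread(file.path(dir, manifest$file[i]), sep = "\t")
    data <- t(as.matrix(tab))
    bad <- manifest$bad_channels[i]
    bad <- if (is.na(bad) || !nzchar(bad)) character() else
      strsplit(bad, ";", fixed = TRUE)[[1]]
    cohort[[manifest$subject_id[i]]] <- structure(
      list(subject_id = manifest$subject_id[i], group = manifest$group[i],
           data = data, fs = fs, montage_ref = "gsn256-synthetic",
           bad_channels = bad),
      class = "eeg_recording")
  }
  structure(cohort, config = cfg, montage = montage, class = "eeg_cohort")
}
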