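# Monte-Carlo validation studies of the whole pipeline: parameter-recovery
# of the coupling gradient, type-I calibration under equal couplings, and
# the closed-form parietal-correlation check.  These are the quantitative
# backbone of the package's self-validation; the methods vignette states
# the problem sizes used.

#' Closed-form recovery of the parietal correlation per group
#'
#' Generates a clean cohort (no injected artifacts or bad channels, so the
#' factor model's closed form applies exactly), correlates the raw parietal
#' channels per 500-sample window, and compares each group's cohort-mean
#' parietal |PCC| with the analytic expectation
#' \eqn{(\alpha_g^2+\beta^2)/(\alpha_g^2+\beta^2+\sigma^2)}.
#'
#' @param config a [simulation_config()]; defaults to the study defaults
#'   with artifacts disabled.
#' @param seed overrides the config seed when given.
#' @return data frame with one row per group: `group`, `n`, `mean_pcc`,
#'   `se` (between-subject standard error), `expected`, `z` (departure in
#'   SE units).
#' @export
parietal_pcc_recovery <- function(config = NULL, seed = NULL) {
  if (is.null(config)) {
    config <- simulation_config(artifact_rate = 0, bad_channel_count = 0)
  }
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
  }
  stopifnot(config$artifact_rate == 0, config$bad_channel_count == 0)
  parietal <- parietal_electrodes()
  per <- cohort_map(config, function(rec) {
    seg <- segment_recording(rec, config$window_samples)
    cm <- subject_connectivity(seg, channels = parietal, scope = "local")
    list(group = rec$group, m = mean(cm$weights[upper.tri(cm$weights)]))
  })
  subj_mean <- vapply(per, `[[`, numeric(1), "m")
  groups <- vapply(per, `[[`, character(1), "group")
  out <- do.call(rbind, lapply(names(config$group_sizes), function(g) {
    v <- subj_mean[groups == g]
    expected <- expected_parietal_pcc(config$parietal_coupling[[g]],
                                      config$global_coupling,
                                      config$noise_sd)
    se <- sd(v) / sqrt(length(v))
    data.frame(group = g, n = length(v), mean_pcc = mean(v), se = se,
               expected = expected, z = (mean(v) - expected) / se,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Parameter-recovery study of the coupling gradient
#'
#' Repeatedly simulates a cohort under the default coupling gradient
#' (HC > SCD > MCI > AD), runs the full pipeline (filter, segment, reject,
#' interpolate, re-reference, connectivity, clustering + strength at the
#' parietal scope), and records per run whether the cohort-mean local
#' clustering coefficient recovers the generating order, plus the local
#' ANOVA p values.  Defaults use the paper-proportioned groups at half
#' size, 30 s per subject and a 64-channel montage subset containing the
#' full parietal set.  The montage cannot be much smaller: average
#' re-referencing removes the montage-mean signal, and once the parietal
#' cluster dominates the montage the shared parietal source is largely
#' subtracted away, crushing the group gaps against the window-sampling
#' noise floor.
#'
#' @param n_runs number of independent simulated cohorts.
#' @param seed base seed; run r uses seed + r.
#' @param group_sizes,n_channels,duration_s cohort dimensions.
#' @param ... further overrides forwarded to [simulation_config()].
#' @return data frame with one row per run: `ordering_ok`, `p_local_cc`,
#'   `p_local_strength`.
#' @export
coupling_recovery_study <- function(n_runs = 100, seed = 1,
                                    group_sizes = c(HC = 11, SCD = 10,
                                                    MCI = 15, AD = 10),
                                    n_channels = 64, duration_s = 30, ...) {
  one_run <- function(r) {
    cfg <- simulation_config(group_sizes = group_sizes,
                             n_channels = n_channels,
                             duration_s = duration_s, seed = seed + r, ...)
    loc <- simulate_summaries(cfg, scopes = "local",
                              metrics = c("clustering", "strength"))
    group_order <- c("HC", "SCD", "MCI", "AD")
    gm <- tapply(loc$cc, loc$group, mean)[group_order]
    data.frame(run = r,
               ordering_ok = all(diff(gm) < 0),
               p_local_cc = one_way_anova(split(loc$cc, loc$group))$p,
               p_local_strength =
                 one_way_anova(split(loc$strength, loc$group))$p)
  }
  do.call(rbind, lapply(seq_len(n_runs), one_run))
}

#' Scope-contrast study: local versus whole-head discrimination
#'
#' Simulates small cohorts on the full 256-channel montage (keeping the
#' parietal fraction of the whole-head network at its natural 27/256, which
#' is what dilutes the group effect at the global scope), runs the full
#' pipeline at both scopes, and records the HC-vs-rest AUC (polarity
#' resolved) of clustering and strength at each scope.  The qualitative
#' expectation mirrored here is that parietal-scope discrimination beats
#' whole-head discrimination.
#'
#' @param n_runs number of independent simulated cohorts.
#' @param seed base seed; run r uses seed + 20000 + r.
#' @param group_sizes,n_channels,duration_s cohort dimensions.
#' @param ... further overrides forwarded to [simulation_config()].
#' @return data frame with per-run AUCs: `auc_local_cc`, `auc_global_cc`,
#'   `auc_local_strength`, `auc_global_strength` and the pairwise
#'   indicators `local_beats_global_cc`, `local_beats_global_strength`.
#' @export
scope_contrast_study <- function(n_runs = 100, seed = 1,
                                 group_sizes = c(HC = 5, SCD = 5,
                                                 MCI = 5, AD = 5),
                                 n_channels = 256, duration_s = 12, ...) {
  one_run <- function(r) {
    cfg <- simulation_config(group_sizes = group_sizes,
                             n_channels = n_channels,
                             duration_s = duration_s,
                             seed = seed + 20000 + r, ...)
    summaries <- simulate_summaries(cfg, scopes = c("global", "local"),
                                    metrics = c("clustering", "strength"))
    loc <- summaries[summaries$scope == "local", ]
    glo <- summaries[summaries$scope == "global", ]
    auc2 <- function(v, lab) max(roc_auc(v, lab), 1 - roc_auc(v, lab))
    lab <- loc$group == "HC"
    out <- data.frame(run = r,
                      auc_local_cc = auc2(loc$cc, lab),
                      auc_global_cc = auc2(glo$cc, glo$group == "HC"),
                      auc_local_strength = auc2(loc$strength, lab),
                      auc_global_strength = auc2(glo$strength,
                                                 glo$group == "HC"))
    out$local_beats_global_cc <- out$auc_local_cc > out$auc_global_cc
    out$local_beats_global_strength <-
      out$auc_local_strength > out$auc_global_strength
    out
  }
  do.call(rbind, lapply(seq_len(n_runs), one_run))
}

#' Type-I-error calibration under equal couplings
#'
#' Sets every group's parietal coupling to the same value (the null of no
#' group effect), runs the pipeline repeatedly, and records the local
#' clustering-coefficient ANOVA p value of each run.  The empirical
#' rejection rate at `alpha` should sit at the nominal level within
#' binomial error.
#'
#' @param n_runs number of simulated null cohorts.
#' @param seed base seed.
#' @param coupling common parietal coupling for all four groups.
#' @param alpha nominal level.
#' @param ... overrides forwarded to the reduced null config.
#' @return list with `p` (vector of per-run p values), `rejection_rate`,
#'   `alpha`, `binomial_se`.
#' @export
null_calibration_study <- function(n_runs = 200, seed = 1, coupling = 1.5,
                                   alpha = 0.05, ...) {
  p <- vapply(seq_len(n_runs), function(r) {
    cfg <- simulation_config(
      seed = seed + 10000 + r,
      group_sizes = c(HC = 8, SCD = 8, MCI = 8, AD = 8),
      n_channels = 32, duration_s = 12,
      parietal_coupling = c(HC = coupling, SCD = coupling,
                            MCI = coupling, AD = coupling), ...)
    summaries <- simulate_summaries(cfg, scopes = "local",
                                     metrics = "clustering")
    one_way_anova(split(summaries$cc, summaries$group))$p
  }, numeric(1))
  rate <- mean(p < alpha)
  list(p = p, rejection_rate = rate, alpha = alpha,
       binomial_se = sqrt(alpha * (1 - alpha) / n_runs))
}
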