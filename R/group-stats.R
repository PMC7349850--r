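# Inferential layer: one-way ANOVA across the four diagnostic groups,
# pooled-variance pairwise t tests gated on ANOVA significance, Bonferroni
# family-wise correction, and Pearson correlation tests against
# neuropsychological scores.

#' One-way ANOVA across groups
#'
#' Classical fixed-effects decomposition (equal-variance form):
#' F = MSB/MSW with k-1 and N-k degrees of freedom, p from the upper tail
#' of the F distribution.  Delegates to [stats::oneway.test()] with
#' `var.equal = TRUE`.
#'
#' @param samples named list of numeric vectors, one per group.
#' @return list with `F`, `df_between`, `df_within`, `p`.
#' @export
one_way_anova <- function(samples) {
  if (length(samples) < 2) stop("need at least 2 groups")
  n <- lengths(samples)
  if (any(n < 2)) stop("every group needs at least 2 observations")
  values <- unlist(samples, use.names = FALSE)
  if (any(!is.finite(values))) stop("non-finite values")
  group <- factor(rep(names(samples), n))
  ssw <- sum(vapply(samples, function(v) sum((v - mean(v))^2), numeric(1)))
  means <- vapply(samples, mean, numeric(1))
  if (ssw == 0) {
    if (max(means) - min(means) == 0) {
      return(list(F = 0, df_between = length(samples) - 1L,
                  df_within = sum(n) - length(samples), p = 1))
    }
    stop("degenerate variance: zero within-group variance with unequal means")
  }
  ht <- oneway.test(values ~ group, var.equal = TRUE)
  list(F = unname(ht$statistic), df_between = unname(ht$parameter[1]),
       df_within = unname(ht$parameter[2]), p = unname(ht$p.value))
}

#' Pooled-variance (Student) two-sample t test
#'
#' Independent-samples t with pooled variance, df = n_a + n_b - 2,
#' two-tailed p.  Chosen over the Welch form because the reported degrees
#' of freedom of the analysis this reproduces (40, 48, 50) equal
#' n_a + n_b - 2, which identifies the pooled convention.  Two identical
#' constant samples return t = 0 by convention; two unequal constant
#' samples are a degenerate-variance error.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @return list with `t`, `df`, `p`.
#' @export
pooled_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("non-finite values")
  df <- length(a) + length(b) - 2L
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = df, p = 1))
    stop("degenerate variance: both samples constant with unequal means")
  }
  ht <- t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = as.integer(unname(ht$parameter)),
       p = unname(ht$p.value))
}

#' Bonferroni-adjusted significance level
#'
#' alpha / m for a family of m comparisons; with the 6 pairwise contrasts
#' of four groups at alpha = 0.05 this gives the conventional 0.0083 ~ 0.008
#' level.
#'
#' @param alpha family-wise level in (0, 1).
#' @param m number of comparisons (>= 1).
#' @return the per-comparison level.
#' @export
bonferroni_level <- function(alpha = 0.05, m) {
  if (length(m) != 1 || m < 1) stop("m must be a positive count")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  alpha / m
}

#' Pearson correlation test
#'
#' r per the normalised-covariance definition; two-tailed p from
#' t = r sqrt((n-2)/(1-r^2)) against Student t with n-2 df, uncorrected
#' for multiple comparisons.  Delegates to [stats::cor.test()].
#'
#' @param x,y numeric vectors of equal length (n >= 3), non-constant.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    stop("degenerate variance: constant vector, correlation undefined")
  }
  ht <- cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = unname(ht$p.value), n = length(x))
}

#' Group comparison of network metrics
#'
#' For each metric x scope cell of a per-subject summary table: one-way
#' ANOVA across the groups; when the ANOVA is significant at `alpha`, all
#' pairwise pooled t tests, each flagged against the Bonferroni-corrected
#' level alpha / (number of pairs).
#'
#' @param summaries data frame with columns `subject_id`, `group`, `scope`
#'   and metric columns (`cc`, `strength`, `bc`), as produced by
#'   [cohort_summaries()].
#' @param metrics metric columns to analyse.
#' @param alpha family-wise significance level.
#' @return list of `group_comparison` objects (one per metric x scope),
#'   each with fields `metric`, `scope`, `F`, `df_between`, `df_within`,
#'   `p_anova`, `pairwise` (data frame or NULL), `bonferroni_level`.
#' @export
compare_network_metrics <- function(summaries,
                                    metrics = c("cc", "strength", "bc"),
                                    alpha = 0.05) {
  stopifnot(all(c("group", "scope") %in% names(summaries)))
  metrics <- intersect(metrics, names(summaries))
  groups <- unique(summaries$group)
  m_pairs <- choose(length(groups), 2)
  level <- bonferroni_level(alpha, m_pairs)
  out <- list()
  for (scope in unique(summaries$scope)) {
    sub <- summaries[summaries$scope == scope, , drop = FALSE]
    for (metric in metrics) {
      vals <- split(sub[[metric]], sub$group)[groups]
      if (any(vapply(vals, function(v) all(is.na(v)), logical(1)))) next
      an <- one_way_anova(vals)
      pairwise <- NULL
      if (an$p < alpha) {
        combs <- utils::combn(groups, 2)
        pairwise <- do.call(rbind, lapply(seq_len(ncol(combs)), function(j) {
          g1 <- combs[1, j]; g2 <- combs[2, j]
          tt <- pooled_t_test(vals[[g1]], vals[[g2]])
          data.frame(group_a = g1, group_b = g2, t = tt$t, df = tt$df,
                     p = tt$p, significant_bonferroni = tt$p < level,
                     stringsAsFactors = FALSE)
        }))
      }
      out[[paste(metric, scope, sep = ".")]] <- structure(
        list(metric = metric, scope = scope, F = an$F,
             df_between = an$df_between, df_within = an$df_within,
             p_anova = an$p, pairwise = pairwise, bonferroni_level = level),
        class = "group_comparison")
    }
  }
  out
}

#' Tabulate a list of group comparisons
#'
#' @param comparisons output of [compare_network_metrics()].
#' @return data frame with one ANOVA row per metric x scope.
#' @export
comparison_table <- function(comparisons) {
  do.call(rbind, lapply(unname(comparisons), function(cmp) {
    data.frame(metric = cmp$metric, scope = cmp$scope, F = cmp$F,
               df_between = cmp$df_between, df_within = cmp$df_within,
               p_anova = cmp$p_anova,
               n_pairwise = if (is.null(cmp$pairwise)) 0L
                            else nrow(cmp$pairwise),
               bonferroni_level = cmp$bonferroni_level,
               stringsAsFactors = FALSE)
  }))
}

#' Correlate network metrics with neuropsychological scores
#'
#' Pearson tests (uncorrected) between each score column and each metric
#' column of a per-subject table.
#'
#' @param scores data frame from [generate_neuropsych()] (or real scores):
#'   `subject_id` plus numeric test columns.
#' @param summaries per-subject summary table restricted to one scope.
#' @param metrics metric columns to correlate.
#' @return data frame with `test`, `metric`, `r`, `p`, `n`.
#' @export
metric_score_correlations <- function(scores, summaries,
                                      metrics = c("cc", "strength", "bc")) {
  merged <- merge(scores, summaries, by = "subject_id")
  tests <- setdiff(names(scores), c("subject_id", "group"))
  rows <- list()
  for (test in tests) {
    for (metric in intersect(metrics, names(summaries))) {
      pt <- pearson_test(merged[[test]], merged[[metric]])
      rows[[length(rows) + 1]] <-
        data.frame(test = test, metric = metric, r = pt$r, p = pt$p,
                   n = pt$n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
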