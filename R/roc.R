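# ROC analysis: empirical curves, Mann-Whitney AUC, Youden-optimal
# operating threshold, and the contrast battery (one-vs-rest and
# one-vs-one across the four diagnostic groups, per metric and scope).

#' Empirical ROC curve
#'
#' Steps through every distinct score as a candidate threshold (classify
#' positive when score >= threshold), with thresholds placed midway between
#' adjacent distinct scores and +/- Inf at the ends, so the curve runs from
#' (0, 0) to (1, 1).
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels logical vector (or coercible), `TRUE` = positive class.
#' @return data frame with `threshold`, `tpr`, `fpr`, ordered from (0,0)
#'   to (1,1).
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (any(!is.finite(scores))) stop("non-finite scores")
  if (!any(labels) || all(labels)) {
    stop("both classes must be present in labels")
  }
  u <- sort(unique(scores))
  mids <- if (length(u) > 1) (head(u, -1) + u[-1]) / 2 else numeric()
  thresholds <- c(Inf, rev(mids), -Inf)
  pos <- scores[labels]
  neg <- scores[!labels]
  tpr <- vapply(thresholds, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thresholds, function(t) mean(neg >= t), numeric(1))
  data.frame(threshold = thresholds, tpr = tpr, fpr = fpr)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney U probability that a random positive scores
#' above a random negative, ties counted one half -- identical to the
#' trapezoidal integral of the empirical curve.
#'
#' @inheritParams roc_curve
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) {
    stop("both classes must be present in labels")
  }
  r <- rank(scores)                      # midranks handle ties as 1/2
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Youden-optimal operating point
#'
#' Returns the threshold maximising J = sensitivity + specificity - 1;
#' ties are broken toward higher specificity (then toward the higher
#' threshold).
#'
#' @param curve a data frame from [roc_curve()].
#' @return list with `threshold`, `sensitivity`, `specificity`, `j`.
#' @export
best_threshold <- function(curve) {
  if (nrow(curve) == 0) stop("empty ROC curve")
  j <- curve$tpr - curve$fpr
  cand <- which(j >= max(j) - 1e-12)
  cand <- cand[order(curve$fpr[cand], -curve$threshold[cand])][1]
  list(threshold = curve$threshold[cand], sensitivity = curve$tpr[cand],
       specificity = 1 - curve$fpr[cand], j = j[cand])
}

roc_one <- function(scores, labels, min_rate = 0.65) {
  auc_raw <- roc_auc(scores, labels)
  polarity <- if (auc_raw >= 0.5) "higher-is-positive" else "lower-is-positive"
  s <- if (auc_raw >= 0.5) scores else -scores
  curve <- roc_curve(s, labels)
  op <- best_threshold(curve)
  thr <- if (auc_raw >= 0.5) op$threshold else -op$threshold
  list(auc = max(auc_raw, 1 - auc_raw), threshold = thr,
       sensitivity = op$sensitivity, specificity = op$specificity,
       polarity = polarity,
       acceptable = min(op$sensitivity, op$specificity) >= min_rate)
}

#' ROC contrast battery over a cohort summary table
#'
#' Runs every one-vs-rest contrast (each group against the pooled others)
#' and every one-vs-one pair, for each requested metric and scope:
#' 10 contrasts per metric-scope cell for four groups.  Score polarity is
#' resolved automatically (scores are flipped when the raw AUC is below
#' 0.5, and the flip recorded), so reported AUCs are >= 0.5.  An operating
#' point is acceptable when both sensitivity and specificity reach
#' `min_rate` (0.65 by convention).
#'
#' @param summaries per-subject table with `group`, `scope` and metric
#'   columns.
#' @param metrics metric columns to use.
#' @param min_rate acceptability floor for sensitivity and specificity.
#' @param groups the expected group set; a group absent from the data is a
#'   labelled error.
#' @return data frame with one row per contrast x scope x metric:
#'   `contrast`, `positive`, `scope`, `metric`, `auc`, `threshold`,
#'   `sensitivity`, `specificity`, `polarity`, `acceptable`.
#' @export
roc_contrasts <- function(summaries, metrics = c("cc", "strength", "bc"),
                          min_rate = 0.65,
                          groups = c("HC", "SCD", "MCI", "AD")) {
  stopifnot(all(c("group", "scope") %in% names(summaries)))
  if (length(groups) < 2) stop("need at least two groups")
  absent <- setdiff(groups, unique(summaries$group))
  if (length(absent)) {
    stop("missing group(s): ", paste(absent, collapse = ", "))
  }
  metrics <- intersect(metrics, names(summaries))
  contrasts <- c(
    lapply(groups, function(g) list(name = paste0(g, " vs rest"),
                                    pos = g, neg = setdiff(groups, g))),
    if (length(groups) >= 2) {
      combs <- utils::combn(groups, 2)
      lapply(seq_len(ncol(combs)), function(j)
        list(name = paste0(combs[1, j], " vs ", combs[2, j]),
             pos = combs[1, j], neg = combs[2, j]))
    })
  rows <- list()
  for (scope in unique(summaries$scope)) {
    sub <- summaries[summaries$scope == scope, , drop = FALSE]
    for (ct in contrasts) {
      keep <- sub$group %in% c(ct$pos, ct$neg)
      if (sum(sub$group %in% ct$pos) < 2 ||
          sum(keep & sub$group %in% ct$neg) < 2) {
        stop("contrast ", ct$name, ": missing or too-small group")
      }
      labels <- sub$group[keep] %in% ct$pos
      for (metric in metrics) {
        vals <- sub[[metric]][keep]
        if (all(is.na(vals))) next
        r <- roc_one(vals, labels, min_rate)
        rows[[length(rows) + 1]] <- data.frame(
          contrast = ct$name, positive = ct$pos, scope = scope,
          metric = metric, auc = r$auc, threshold = r$threshold,
          sensitivity = r$sensitivity, specificity = r$specificity,
          polarity = r$polarity, acceptable = r$acceptable,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
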