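#' Pearson correlation coefficient between two channels
#'
#' Normalised covariance: covariance of the two series divided by the
#' product of their standard deviations.  Degenerate (constant) input is a
#' labelled error rather than a silent `NaN`.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return correlation in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 samples")
  if (anyNA(x) || anyNA(y)) stop("missing values in input")
  if (sd(x) == 0 || sd(y) == 0) {
    stop("degenerate variance: input is constant, correlation undefined")
  }
  cor(x, y)
}

new_connectivity_matrix <- function(weights, labels, scope, n_segments_used) {
  dimnames(weights) <- list(labels, labels)
  structure(list(labels = labels, weights = weights, scope = scope,
                 n_segments_used = n_segments_used),
            class = "connectivity_matrix")
}

#' Validate a connectivity matrix's invariants
#'
#' Symmetry, exactly zero diagonal, off-diagonal weights in [0, 1] and no
#' missing values.
#'
#' @param cm a `connectivity_matrix`.
#' @param tol symmetry tolerance.
#' @return `cm`, invisibly; stops on violation.
#' @export
validate_connectivity <- function(cm, tol = 1e-12) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  w <- cm$weights
  if (anyNA(w)) stop("connectivity matrix contains NaN")
  if (max(abs(w - t(w))) > tol) stop("connectivity matrix is not symmetric")
  if (any(diag(w) != 0)) stop("diagonal must be exactly zero")
  if (min(w) < 0 || max(w) > 1) stop("weights must lie in [0, 1]")
  invisible(cm)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("<connectivity_matrix> ", length(x$labels), " nodes, scope=", x$scope,
      ", segments=", x$n_segments_used, "\n", sep = "")
  off <- x$weights[upper.tri(x$weights)]
  cat(sprintf("  |PCC| mean %.3f, range [%.3f, %.3f]\n",
              mean(off), min(off), max(off)))
  invisible(x)
}

# column-standardised crossproduct correlation; errors on constant columns.
# x: samples x channels
abs_cor_matrix <- function(x, labels) {
  xc <- x - rep(colMeans(x), each = nrow(x))
  g <- crossprod(xc)
  v <- diag(g)
  if (any(v == 0)) {
    stop("constant channel(s) within segment: ",
         paste(labels[v == 0], collapse = ", "))
  }
  w <- abs(g / tcrossprod(sqrt(v)))
  w[w > 1] <- 1          # clip float overshoot at perfectly correlated pairs
  diag(w) <- 0
  w
}

#' Connectivity matrix of a single segment
#'
#' Entry (i, j) is the absolute Pearson correlation between channels i and j
#' over the segment; the diagonal is zeroed.
#'
#' @param segment channels x samples matrix with rownames.
#' @param scope scope tag to store (`"global"` or `"local"`).
#' @return a `connectivity_matrix`.
#' @export
segment_connectivity <- function(segment, scope = "global") {
  stopifnot(is.matrix(segment), nrow(segment) >= 2)
  labels <- rownames(segment) %||% paste0("ch", seq_len(nrow(segment)))
  w <- abs_cor_matrix(t(segment), labels)
  new_connectivity_matrix(w, labels, scope, 1L)
}

#' Subject-level connectivity matrix
#'
#' Element-wise mean of the per-segment absolute-correlation matrices over
#' all retained segments (absolute value taken per segment, before
#' averaging).
#'
#' @param seg a `segmented_eeg` after preprocessing.
#' @param channels optional label subset to restrict the computation to
#'   (e.g. the parietal set); default all channels.
#' @param scope scope tag to store.
#' @return a `connectivity_matrix` with `n_segments_used` recorded.
#' @export
subject_connectivity <- function(seg, channels = NULL, scope = "global") {
  stopifnot(inherits(seg, "segmented_eeg"))
  n_seg <- length(seg$segments)
  if (n_seg < 2) {
    stop("subject ", seg$subject_id, " has ", n_seg,
         " retained segments; at least 2 required")
  }
  labels <- seg$labels
  rows <- seq_along(labels)
  if (!is.null(channels)) {
    missing <- setdiff(channels, labels)
    if (length(missing)) {
      stop("unknown channel(s): ", paste(missing, collapse = ", "))
    }
    rows <- match(channels, labels)
    labels <- channels
  }
  acc <- 0
  for (s in seg$segments) {
    acc <- acc + abs_cor_matrix(t(s[rows, , drop = FALSE]), labels)
  }
  new_connectivity_matrix(acc / n_seg, labels, scope, n_seg)
}

#' Extract the parietal (local) subnetwork
#'
#' Principal submatrix of the connectivity matrix restricted to the given
#' electrode set, in the set's order, tagged with local scope.
#'
#' @param cm a `connectivity_matrix`.
#' @param parietal_set electrode labels; defaults to the 27 unique parietal
#'   electrodes ([parietal_electrodes()]).
#' @return the local-scope `connectivity_matrix`.
#' @export
extract_local <- function(cm, parietal_set = parietal_electrodes()) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  parietal_set <- unique(parietal_set)
  missing <- setdiff(parietal_set, cm$labels)
  if (length(missing)) {
    stop("labels not in matrix: ", paste(missing, collapse = ", "))
  }
  idx <- match(parietal_set, cm$labels)
  new_connectivity_matrix(cm$weights[idx, idx, drop = FALSE], parietal_set,
                          "local", cm$n_segments_used)
}

#' Group-averaged connectivity matrix
#'
#' Element-wise mean of member matrices, used for group-level reporting.
#' Averaging and local extraction commute.
#'
#' @param matrices list of `connectivity_matrix` objects on identical label
#'   sets.
#' @return a `connectivity_matrix`.
#' @export
group_mean_connectivity <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  labels <- matrices[[1]]$labels
  scope <- matrices[[1]]$scope
  for (m in matrices) {
    if (!identical(m$labels, labels)) stop("matrices have differing labels")
  }
  w <- Reduce(`+`, lapply(matrices, `[[`, "weights")) / length(matrices)
  new_connectivity_matrix(w, labels, scope,
                          sum(vapply(matrices, `[[`, integer(1),
                                     "n_segments_used")))
}

#' Write / read a connectivity matrix as delimited text
#'
#' Tab-separated square table with a label header; a leading comment line
#' records the scope and segment count.
#'
#' @param cm a `connectivity_matrix`.
#' @param path file path.
#' @return `read_connectivity` returns the matrix; `write_connectivity` the
#'   path, invisibly.
#' @export
write_connectivity <- function(cm, path) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  con <- file(path, "w")
  writeLines(sprintf("# scope=%s n_segments_used=%d", cm$scope,
                     cm$n_segments_used), con)
  close(con)
  data.table::fwrite(data.table::as.data.table(cm$weights), path, sep = "\t",
                     append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  header <- readLines(path, n = 1)
  scope <- sub(".*scope=(\\S+).*", "\\1", header)
  n_seg <- as.integer(sub(".*n_segments_used=(\\d+).*", "\\1", header))
  w <- as.matrix(data.table::fread(path, sep = "\t", skip = 1))
  new_connectivity_matrix(w, colnames(w), scope, n_seg)
}
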