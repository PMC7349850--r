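#' Synthetic geodesic sensor-net montage
#'
#' Builds a synthetic 256-electrode montage in the style of a HydroCel
#' geodesic sensor net: electrode labels `E1`...`E256` plus the vertex
#' reference `Cz`, with 3-D positions on the upper unit hemisphere laid out
#' on a Fibonacci lattice.  The geometry is synthetic -- it reproduces the
#' labelling scheme and a plausible, evenly spaced scalp coverage, not the
#' manufacturer's digitised coordinates -- and is used only for spatial
#' operations (nearest-neighbour bad-channel interpolation).
#'
#' @param n_channels number of recording electrodes (default 256).
#' @param include_reference add the vertex reference `Cz` at the apex?  The
#'   reference is excluded from all network construction; it is carried only
#'   so montage files round-trip completely.
#' @return a `data.frame` with columns `label`, `x`, `y`, `z` (unit-sphere
#'   coordinates) and class `c("eeg_montage", "data.frame")`.
#' @export
gsn_montage <- function(n_channels = 256, include_reference = FALSE) {
  stopifnot(is.numeric(n_channels), length(n_channels) == 1, n_channels >= 1)
  n <- as.integer(n_channels)
  i <- seq_len(n)
  golden <- (1 + sqrt(5)) / 2
  # Fibonacci lattice on the upper hemisphere: z in (0, 1), azimuth by the
  # golden angle; gives near-uniform spacing for any n.
  z <- (i - 0.5) / n
  r <- sqrt(1 - z^2)
  theta <- 2 * pi * i / golden
  m <- data.frame(
    label = paste0("E", i),
    x = r * cos(theta),
    y = r * sin(theta),
    z = z,
    stringsAsFactors = FALSE
  )
  if (include_reference) {
    m <- rbind(m, data.frame(label = "Cz", x = 0, y = 0, z = 1))
  }
  class(m) <- c("eeg_montage", "data.frame")
  m
}

#' Parietal electrode set
#'
#' The parietal electrode cluster used for the local-scope network, given as
#' EGI-style channel labels.  The printed source list has 29 entries of which
#' two (`E87`, `E63`) are duplicated; by default the 27 unique labels are
#' returned, with the raw 29-entry list available for fidelity.
#'
#' @param deduplicated return the 27 unique labels (default) or the raw
#'   29-entry list with duplicates preserved.
#' @return character vector of electrode labels.
#' @export
parietal_electrodes <- function(deduplicated = TRUE) {
  raw <- c(78, 87, 100, 101, 63, 142, 154, 35, 87, 99, 110, 119, 63, 141,
           153, 163, 86, 98, 109, 118, 127, 140, 152, 162, 96, 97, 108,
           170, 161)
  labels <- paste0("E", raw)
  if (deduplicated) unique(labels) else labels
}

#' Restrict a montage to a channel subset that preserves the parietal set
#'
#' Used for reduced-size simulation studies: keeps every parietal electrode
#' and fills the remainder with evenly spaced non-parietal channels, so the
#' local scope is always fully represented while the whole-head scope can be
#' scaled down.
#'
#' @param montage a montage from [gsn_montage()].
#' @param n_channels total channels to keep (must be >= the parietal count).
#' @param parietal parietal labels to preserve.
#' @return the row-subset montage, parietal labels first in original order.
#' @export
montage_subset <- function(montage, n_channels,
                           parietal = parietal_electrodes()) {
  stopifnot(inherits(montage, "eeg_montage"))
  parietal <- intersect(montage$label, parietal)
  n_channels <- as.integer(n_channels)
  if (n_channels < length(parietal)) {
    stop("n_channels (", n_channels, ") is smaller than the parietal set (",
         length(parietal), ")")
  }
  others <- setdiff(montage$label, c(parietal, "Cz"))
  n_extra <- n_channels - length(parietal)
  if (n_extra > length(others)) {
    stop("montage has only ", length(others), " non-parietal channels")
  }
  keep_extra <- others[round(seq(1, length(others), length.out = n_extra))]
  keep <- montage$label[montage$label %in% c(parietal, keep_extra)]
  out <- montage[match(keep, montage$label), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("eeg_montage", "data.frame")
  out
}

#' Write / read a montage as delimited text
#'
#' Tab-separated table with columns `label`, `x`, `y`, `z`.
#'
#' @param montage a montage data frame.
#' @param path file path.
#' @return `read_montage` returns the montage; `write_montage` returns the
#'   path invisibly.
#' @export
write_montage <- function(montage, path) {
  stopifnot(inherits(montage, "data.frame"))
  data.table::fwrite(as.data.frame(montage), path, sep = "\t")
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  m <- as.data.frame(data.table::fread(path, sep = "\t"))
  required <- c("label", "x", "y", "z")
  if (!all(required %in% names(m))) {
    stop("montage file must have columns: ", paste(required, collapse = ", "))
  }
  if (anyDuplicated(m$label)) stop("montage labels must be unique")
  class(m) <- c("eeg_montage", "data.frame")
  m
}

# k nearest good channels (Euclidean) for one target label.
nearest_channels <- function(montage, target, candidates, k = 6) {
  pos <- as.matrix(montage[, c("x", "y", "z")])
  rownames(pos) <- montage$label
  d <- sqrt(colSums((t(pos[candidates, , drop = FALSE]) - pos[target, ])^2))
  names(sort(d))[seq_len(min(k, length(d)))]
}
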