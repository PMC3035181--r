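#' Empirical CDF of the consensus entries
#'
#' Sorts the m = n(n-1)/2 upper-triangle entries of a consensus matrix
#' (duplicates kept) and evaluates the empirical cumulative distribution at
#' each: \code{cdf[i] = #\{entries <= xs[i]\} / m}. Under perfect, stable
#' clustering the distribution is bimodal at 0 and 1. The diagonal is
#' excluded by construction.
#'
#' @param M A consensus matrix (n x n, entries in [0, 1]).
#' @return An object of class \code{"cdf_curve"}: list with \code{k} (taken
#'   from the matrix attribute, if any), sorted entries \code{xs} and
#'   matching \code{cdf} values.
#' @export
empirical_cdf <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) < 2L || nrow(M) != ncol(M)) stop("M must be square with n >= 2")
  xs <- sort(M[upper.tri(M)])
  cdf <- stats::ecdf(xs)(xs)
  structure(list(k = attr(M, "k"), xs = xs, cdf = cdf), class = "cdf_curve")
}

#' Area under a consensus CDF curve
#'
#' The discrete-sum estimate
#' \deqn{A = \sum_{i=2}^{m} (x_i - x_{i-1})\, CDF(x_i),}
#' a right Riemann sum over the sorted entries. It is 0 when all entries
#' coincide and reaches 1 for a binary matrix containing both 0 and 1.
#'
#' @param curve A \code{"cdf_curve"} from [empirical_cdf()], or a consensus
#'   matrix (converted internally).
#' @return A single numeric value in [0, 1].
#' @export
cdf_area <- function(curve) {
  if (!inherits(curve, "cdf_curve")) curve <- empirical_cdf(curve)
  xs <- curve$xs
  if (length(xs) < 2L) return(0)
  sum(diff(xs) * curve$cdf[-1L])
}

#' Proportional increase of the CDF area
#'
#' The Delta series over a contiguous area grid starting at k = 2:
#' \deqn{\Delta(2) = A(2), \qquad
#'   \Delta(k) = \frac{A(k+1) - A(k)}{A(k)} \quad (k > 2).}
#' The forward difference means the series is defined for k in
#' \code{[2, k_max - 1]}; no value exists at k_max.
#'
#' @param areas Numeric vector of areas A(k) on the contiguous grid
#'   \code{ks}.
#' @param ks Integer grid, contiguous and starting at 2.
#' @return Named numeric vector of Delta values, names \code{2:(k_max-1)}.
#' @export
delta_series <- function(areas, ks = seq(2L, length.out = length(areas))) {
  ks <- as.integer(ks)
  if (length(ks) != length(areas)) stop("areas and ks differ in length")
  if (ks[1L] != 2L || any(diff(ks) != 1L)) {
    stop("areas must be given on a contiguous k grid starting at 2")
  }
  k_max <- ks[length(ks)]
  delta <- areas[1L]
  names(delta) <- "2"
  if (k_max >= 4L) {
    denom <- areas[ks >= 3L & ks <= k_max - 1L]
    if (any(denom == 0)) {
      stop("degenerate area series: A(k) = 0 for some k used as denominator")
    }
    num <- areas[ks >= 4L] - areas[ks >= 3L & ks <= k_max - 1L]
    d <- num / denom
    names(d) <- as.character(3:(k_max - 1L))
    delta <- c(delta, d)
  }
  delta
}

#' Compute the full curve set from per-k consensus matrices
#'
#' Convenience wrapper producing, for a \code{"consensus_result"} whose k
#' grid starts at 2, the per-k CDF curves, the areas A(k), and the Delta
#' series.
#'
#' @param result A \code{"consensus_result"} from [run_consensus()] or
#'   [run_fc()].
#' @return An object of class \code{"consensus_curves"}: list with the k
#'   grid, \code{area} (named by k), \code{delta} (named by k, up to
#'   k_max - 1) and \code{cdf_curves}.
#' @export
consensus_curves <- function(result) {
  stopifnot(inherits(result, "consensus_result"))
  curves <- lapply(result$matrices, empirical_cdf)
  areas <- vapply(curves, cdf_area, numeric(1))
  names(areas) <- as.character(result$k)
  delta <- delta_series(unname(areas), result$k)
  structure(list(k = result$k, area = areas, delta = delta,
                 cdf_curves = curves),
            class = "consensus_curves")
}

#' Predict the number of clusters from the Delta curve
#'
#' Deterministic form of the plateau rule of thumb: the predicted k* is the
#' smallest k >= 3 such that \code{Delta(j) <= tau} for every j from k to
#' the end of the Delta grid — the point past which the CDF area stops
#' growing appreciably. If no such k exists the prediction falls back to
#' the last grid point with \code{stabilized = FALSE}. The rule never
#' returns k* = 2; a small Delta(2) (which lives on the absolute A-scale,
#' not the relative-increment scale) is surfaced in \code{notes} for visual
#' override, as are any negative Delta values (an empirical, not
#' guaranteed, non-negativity). The CDF curves are attached for the visual
#' disambiguation the procedure prescribes.
#'
#' @param curves A \code{"consensus_curves"} object, or a named Delta
#'   vector as from [delta_series()].
#' @param tau Plateau threshold (default 0.03).
#' @return An object of class \code{"consensus_prediction"}: list with
#'   \code{k_star}, \code{tau}, \code{stabilized}, \code{flat_range} (the
#'   maximal contiguous k-interval with Delta <= tau, or NULL), and
#'   \code{notes}.
#' @export
predict_k <- function(curves, tau = 0.03) {
  if (inherits(curves, "consensus_curves")) {
    delta <- curves$delta
    cdf_curves <- curves$cdf_curves
  } else {
    delta <- curves
    cdf_curves <- NULL
  }
  if (length(delta) == 0L) stop("empty Delta series")
  kk <- as.integer(names(delta))
  if (any(is.na(kk))) stop("Delta series must be named by k")
  notes <- character(0)
  if (any(delta < 0)) {
    notes <- c(notes, paste0("Delta negative at k = ",
                             paste(kk[delta < 0], collapse = ", "),
                             " (non-negativity is empirical only)"))
  }
  if (delta[1L] <= tau && kk[1L] == 2L) {
    notes <- c(notes,
               "Delta(2) = A(2) is itself below tau; inspect the CDF curves before accepting k* > 2")
  }
  scan <- kk >= 3L
  below <- delta <= tau
  k_star <- NA_integer_
  idx <- which(scan)
  for (i in idx) {
    if (all(below[i:length(below)])) { k_star <- kk[i]; break }
  }
  stabilized <- !is.na(k_star)
  if (!stabilized) {
    k_star <- kk[length(kk)]
    notes <- c(notes, "no plateau: Delta never stabilizes below tau; k* is the fallback upper end of the grid")
  }
  flat_range <- NULL
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  flats <- which(r$values)
  if (length(flats) > 0L) {
    best <- flats[which.max(r$lengths[flats])]
    flat_range <- c(kk[starts[best]], kk[ends[best]])
  }
  structure(list(k_star = k_star, tau = tau, stabilized = stabilized,
                 flat_range = flat_range, notes = notes,
                 delta = delta, cdf_curves = cdf_curves),
            class = "consensus_prediction")
}

#' Consensus matrix as a dissimilarity
#'
#' Entrywise \code{1 - M} with a zero diagonal: pairs that always co-cluster
#' are at distance 0, pairs that never do at distance 1. The result is a
#' valid symmetric dissimilarity matrix and can be fed to
#' [build_dendrogram()].
#'
#' @param M A consensus matrix.
#' @return Numeric matrix of the same size.
#' @export
consensus_to_dissimilarity <- function(M) {
  M <- as.matrix(M)
  D <- 1 - M
  diag(D) <- 0
  attr(D, "k") <- NULL
  D
}

#' @export
print.consensus_prediction <- function(x, ...) {
  cat("Predicted number of clusters k* =", x$k_star,
      if (x$stabilized) "(stabilized)" else "(fallback, no plateau)", "\n")
  cat("  plateau threshold tau =", x$tau, "\n")
  if (!is.null(x$flat_range)) {
    cat("  flat range: k in [", x$flat_range[1L], ", ", x$flat_range[2L],
        "]\n", sep = "")
  }
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}
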