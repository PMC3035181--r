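#' Draw one subsample of items
#'
#' The perturbation scheme behind consensus clustering: a uniform random
#' subset of \code{floor(p * n)} distinct item indices, drawn without
#' replacement from \code{1:n}. Every subset of that size is equally
#' probable. The draw consumes R's global random stream, so it is
#' deterministic after \code{set.seed()}; the integer-only sampling path
#' (\code{sample.int}) keeps it reproducible across platforms.
#'
#' @param n Number of items in the full matrix.
#' @param p Subsampling fraction in (0, 1].
#' @return A strictly increasing integer vector of \code{floor(p * n)}
#'   indices into \code{1:n}.
#' @examples
#' set.seed(1)
#' subsample(10, 0.8)   # 8 distinct indices
#' subsample(10, 1.0)   # the identity resample 1:10
#' @export
subsample <- function(n, p) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p > 1) {
    stop("p must lie in (0, 1]")
  }
  size <- floor(p * n)
  if (size < 2L) stop("sample too small: floor(p * n) = ", size, " < 2")
  sort(sample.int(n, size))
}

# Deterministic child seed for resample h. The consensus procedure draws
# fresh subsamples per k (stream indexed by (k, h)); FC shares one subsample
# across all k (stream indexed by (0, h)). Additive derivation keeps the two
# schemes alignable in tests: consensus at (k, h) equals FC at h under a
# master seed offset of 100003 * k.
child_seed <- function(master, k, h) {
  (as.double(master) + 100003 * as.double(k) + as.double(h)) %% 2147483647
}
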