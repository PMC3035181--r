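#' Estimate the number of clusters in an expression matrix
#'
#' End-to-end pipeline: run the consensus or FC procedure over the
#' configured k range, compute the CDF curves, areas and Delta series, and
#' apply the plateau rule. This is the function behind the command-line
#' driver.
#'
#' @param x Numeric item-by-condition matrix (items are rows).
#' @param cfg A [run_config()]. Arguments in \code{...} are passed to
#'   [run_config()] instead when \code{cfg} is NULL.
#' @param verbose Log progress.
#' @param ... Passed to [run_config()] when \code{cfg} is NULL.
#' @return A list of class \code{"consensus_fit"} with components
#'   \code{result} (the per-k consensus matrices), \code{curves} and
#'   \code{prediction}.
#' @examples
#' set.seed(7)
#' d <- gaussian_clusters(c(20, 20, 20), n_dims = 50, separation = 6)
#' fit <- estimate_k(d$data, method = "fc", algorithm = "hier-a",
#'                   H = 50, p = 0.8, k_max = 10, seed = 7)
#' fit$prediction$k_star   # 3
#' @export
estimate_k <- function(x, cfg = NULL, verbose = FALSE, ...) {
  if (is.null(cfg)) cfg <- run_config(...)
  stopifnot(inherits(cfg, "run_config"))
  if (cfg$k_min != 2L) {
    stop("the Delta series requires a k grid starting at 2; got k_min = ",
         cfg$k_min)
  }
  runner <- if (cfg$method == "fc") run_fc else run_consensus
  result <- runner(x, cfg, verbose = verbose)
  curves <- consensus_curves(result)
  prediction <- predict_k(curves, tau = cfg$tau)
  structure(list(config = cfg, result = result, curves = curves,
                 prediction = prediction),
            class = "consensus_fit")
}

#' @export
print.consensus_fit <- function(x, ...) {
  print(x$config)
  print(x$prediction)
  invisible(x)
}
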