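#' Read a tab-delimited expression matrix
#'
#' Expects a rectangular TSV with one header row (condition ids, optionally
#' preceded by an empty corner field) and one leading label column (item
#' ids). All cells must parse as plain decimal numbers; missing or
#' non-numeric entries are rejected, naming the offending row and column,
#' and ragged rows are rejected naming the line. With \code{transpose},
#' rows and columns are exchanged before return, so items are always rows
#' downstream (sample-clustering studies supply the flag instead of a
#' second code path).
#'
#' @param path Path to the TSV file.
#' @param transpose Exchange rows and columns after parsing.
#' @return A numeric matrix with item ids as rownames and condition ids as
#'   colnames.
#' @export
read_expression_matrix <- function(path, transpose = FALSE) {
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("empty matrix: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  # corner cell above the id column may be present or absent
  body_width <- length(fields[[2L]])
  cond_ids <- if (length(header) == body_width) header[-1L] else header
  d <- length(cond_ids)
  if (d < 1L) stop("empty matrix: no condition columns in ", path)
  n <- length(fields) - 1L
  item_ids <- character(n)
  values <- matrix(NA_real_, n, d)
  for (i in seq_len(n)) {
    row <- fields[[i + 1L]]
    if (length(row) != d + 1L) {
      stop("ragged row: line ", i + 1L, " has ", length(row),
           " fields, expected ", d + 1L)
    }
    item_ids[i] <- row[1L]
    v <- suppressWarnings(as.numeric(row[-1L]))
    bad <- which(is.na(v))
    if (length(bad) > 0L) {
      stop("non-numeric cell '", row[bad[1L] + 1L], "' at row '",
           item_ids[i], "' (line ", i + 1L, "), column '",
           cond_ids[bad[1L]], "'")
    }
    values[i, ] <- v
  }
  dimnames(values) <- list(item_ids, cond_ids)
  if (isTRUE(transpose)) values <- t(values)
  values
}

fmt_num <- function(x) sprintf("%.12g", x)

write_numeric_tsv <- function(m, path, corner = "") {
  header <- paste(c(corner, colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], fmt_num(m[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
}

#' Write consensus run outputs to a directory
#'
#' Writes, with 12-significant-digit precision so that a re-read reproduces
#' the printed values exactly: \code{consensus_k<k>.tsv} (one n x n matrix
#' per k, with item ids), \code{curves.tsv} (columns k, A, delta; delta is
#' NA at k_max where the forward difference is undefined),
#' \code{cdf_k<k>.tsv} (columns x, CDF), and \code{prediction.json}
#' (k*, tau, flags, notes and the configuration echo). Optionally renders
#' PNG plots of the CDF family and the Delta curve.
#'
#' @param out_dir Output directory; created if absent.
#' @param result A \code{"consensus_result"}.
#' @param curves A \code{"consensus_curves"} for the same k grid.
#' @param prediction A \code{"consensus_prediction"}.
#' @param config Optional [run_config()] echoed into the JSON.
#' @param plots Render \code{cdf_curves.png} and \code{delta_curve.png}.
#' @return Invisibly, the character vector of files written.
#' @export
write_outputs <- function(out_dir, result, curves, prediction,
                          config = NULL, plots = FALSE) {
  stopifnot(inherits(result, "consensus_result"),
            inherits(curves, "consensus_curves"),
            inherits(prediction, "consensus_prediction"))
  if (length(result$k) == 0L) stop("empty k range: nothing to write")
  if (!identical(as.integer(result$k), as.integer(curves$k))) {
    stop("result and curves disagree on the k grid")
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  written <- character(0)
  ids <- result$item_ids
  if (is.null(ids)) ids <- paste0("item", seq_len(result$n))
  for (kc in names(result$matrices)) {
    M <- result$matrices[[kc]]
    dimnames(M) <- list(ids, ids)
    f <- file.path(out_dir, paste0("consensus_k", kc, ".tsv"))
    write_numeric_tsv(M, f)
    written <- c(written, f)
  }
  delta_full <- rep(NA_real_, length(curves$k))
  delta_full[match(as.integer(names(curves$delta)), curves$k)] <- curves$delta
  f <- file.path(out_dir, "curves.tsv")
  writeLines(c("k\tA\tdelta",
               paste(curves$k, fmt_num(curves$area),
                     ifelse(is.na(delta_full), "NA", fmt_num(delta_full)),
                     sep = "\t")), f)
  written <- c(written, f)
  for (i in seq_along(curves$cdf_curves)) {
    cc <- curves$cdf_curves[[i]]
    f <- file.path(out_dir, paste0("cdf_k", curves$k[i], ".tsv"))
    writeLines(c("x\tCDF",
                 paste(fmt_num(cc$xs), fmt_num(cc$cdf), sep = "\t")), f)
    written <- c(written, f)
  }
  pj <- list(k_star = prediction$k_star,
             tau = prediction$tau,
             stabilized = prediction$stabilized,
             flat_range = prediction$flat_range,
             notes = prediction$notes,
             delta = as.list(prediction$delta))
  if (!is.null(config)) {
    pj$config <- list(method = config$method, algorithm = config$algorithm,
                      H = config$H, p = config$p, k_min = config$k_min,
                      k_max = config$k_max, tau = config$tau,
                      seed = config$seed, transpose = config$transpose)
  }
  f <- file.path(out_dir, "prediction.json")
  jsonlite::write_json(pj, f, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  written <- c(written, f)
  if (isTRUE(plots)) {
    written <- c(written, write_plots(out_dir, curves, prediction))
  }
  invisible(written)
}

# CDF-family and Delta-curve panels, base graphics.
write_plots <- function(out_dir, curves, prediction) {
  f1 <- file.path(out_dir, "cdf_curves.png")
  grDevices::png(f1, width = 800, height = 600)
  cols <- grDevices::hcl.colors(length(curves$k), "viridis")
  plot(NULL, xlim = c(0, 1), ylim = c(0, 1), xlab = "consensus index",
       ylab = "CDF", main = "Consensus CDF curves by k")
  for (i in seq_along(curves$cdf_curves)) {
    cc <- curves$cdf_curves[[i]]
    graphics::lines(stats::stepfun(cc$xs, c(0, cc$cdf)), col = cols[i],
                    do.points = FALSE)
  }
  graphics::legend("bottomright", legend = paste0("k=", curves$k),
                   col = cols, lty = 1, cex = 0.7, ncol = 2)
  grDevices::dev.off()
  f2 <- file.path(out_dir, "delta_curve.png")
  grDevices::png(f2, width = 800, height = 600)
  kk <- as.integer(names(curves$delta))
  plot(kk, curves$delta, type = "b", pch = 19, xlab = "k",
       ylab = expression(Delta(k)), main = "Delta curve")
  graphics::abline(h = prediction$tau, lty = 2)
  graphics::abline(v = prediction$k_star, col = "red", lty = 3)
  grDevices::dev.off()
  c(f1, f2)
}
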