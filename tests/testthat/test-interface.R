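small_fit <- function(n = 12, seed = 31, k_max = 4, H = 20) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n / 2 * 3, 0), n / 2, 3),
             matrix(rnorm(n / 2 * 3, 8), n / 2, 3))
  rownames(x) <- paste0("item", seq_len(n))
  cfg <- run_config(method = "fc", algorithm = "hier-a", H = H, p = 0.8,
                    k_max = k_max, seed = seed)
  list(x = x, cfg = cfg,
       fit = suppressWarnings(estimate_k(x, cfg = cfg)))
}

test_that("a TSV matrix round-trips through parse and transpose", {
  tsv <- write_fixture_tsv(matrix(c(1, 2, 3, 4, 5, 6), 3, 2, byrow = TRUE))
  m <- read_expression_matrix(tsv)
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(unname(m), matrix(c(1, 2, 3, 4, 5, 6), 3, 2, byrow = TRUE))
  expect_equal(rownames(m), paste0("item", 1:3))
  mt <- read_expression_matrix(tsv, transpose = TRUE)
  expect_equal(dim(mt), c(2L, 3L))
  expect_equal(unname(mt[1, ]), c(1, 3, 5))
})

test_that("malformed matrices are rejected with located errors", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.tsv")
  writeLines(c("id\tc1\tc2", "g1\t1\t2", "g2\tNA\t4"), bad)
  expect_error(read_expression_matrix(bad), "non-numeric cell 'NA'.*g2.*c1")
  writeLines(c("id\tc1\tc2", "g1\t1\t2", "g2\t3"), bad)
  expect_error(read_expression_matrix(bad), "ragged row: line 3")
  writeLines("id\tc1\tc2", bad)
  expect_error(read_expression_matrix(bad), "empty matrix")
  expect_error(read_expression_matrix(file.path(dir, "absent.tsv")),
               "not found")
})

test_that("written outputs re-parse to full printed precision", {
  s <- small_fit()
  dir <- withr::local_tempdir()
  files <- write_outputs(dir, s$fit$result, s$fit$curves, s$fit$prediction,
                         config = s$cfg)
  expect_true(all(file.exists(files)))
  for (k in 2:4) {
    M <- s$fit$result$matrices[[as.character(k)]]
    back <- read_expression_matrix(file.path(dir, paste0("consensus_k", k, ".tsv")))
    expect_equal(unname(back), unname(unclass(M)), tolerance = 1e-11,
                 ignore_attr = TRUE)
  }
  curves <- utils::read.delim(file.path(dir, "curves.tsv"))
  expect_equal(curves$k, 2:4)
  expect_equal(curves$A, unname(s$fit$curves$area), tolerance = 1e-11)
  expect_true(is.na(curves$delta[3]))  # undefined at k_max
  cdf2 <- utils::read.delim(file.path(dir, "cdf_k2.tsv"))
  expect_equal(cdf2$x, s$fit$curves$cdf_curves[[1]]$xs, tolerance = 1e-11)
  expect_equal(cdf2$CDF, s$fit$curves$cdf_curves[[1]]$cdf, tolerance = 1e-11)
})

test_that("an exact consensus matrix round-trips bit for bit", {
  res <- structure(list(
    matrices = list("2" = matrix(c(1, 0.5, 0.5, 1), 2)),
    k = 2L, method = "fc", algorithm = "hier-a", H = 1L, p = 1.0,
    seed = 1L, n = 2L, item_ids = c("a", "b")), class = "consensus_result")
  curves <- structure(list(k = 2L, area = c("2" = 0),
                           delta = c("2" = 0),
                           cdf_curves = list(empirical_cdf(res$matrices[["2"]]))),
                      class = "consensus_curves")
  pred <- predict_k(curves$delta, tau = 0.03)
  dir <- withr::local_tempdir()
  write_outputs(dir, res, curves, pred)
  back <- read_expression_matrix(file.path(dir, "consensus_k2.tsv"))
  expect_identical(unname(back), matrix(c(1, 0.5, 0.5, 1), 2))
})

test_that("prediction.json carries k*, flags and the config echo", {
  s <- small_fit()
  dir <- withr::local_tempdir()
  write_outputs(dir, s$fit$result, s$fit$curves, s$fit$prediction,
                config = s$cfg)
  pj <- jsonlite::read_json(file.path(dir, "prediction.json"),
                            simplifyVector = TRUE)
  expect_equal(pj$k_star, s$fit$prediction$k_star)
  expect_equal(pj$tau, 0.03)
  expect_equal(pj$config$H, 20)
  expect_equal(pj$config$algorithm, "hier-a")
  expect_equal(pj$config$p, 0.8)
})

test_that("degenerate or unwritable outputs fail before any file is written", {
  s <- small_fit()
  empty <- s$fit$result
  empty$matrices <- list()
  empty$k <- integer(0)
  dir <- withr::local_tempdir()
  expect_error(write_outputs(file.path(dir, "sub"), empty, s$fit$curves,
                             s$fit$prediction), "empty k range")
  expect_false(dir.exists(file.path(dir, "sub")))
  blocker <- file.path(dir, "blocker")
  writeLines("x", blocker)
  expect_error(write_outputs(file.path(blocker, "out"), s$fit$result,
                             s$fit$curves, s$fit$prediction))
})

test_that("the CLI runs end to end and writes all outputs", {
  s <- small_fit()
  dir <- withr::local_tempdir()
  tsv <- write_fixture_tsv(s$x, dir)
  out <- file.path(dir, "out")
  status <- run_cli(c("--input", tsv, "--method", "fc",
                      "--algorithm", "hier-a", "--H", "10", "--p", "0.8",
                      "--kmax", "4", "--seed", "7", "--outdir", out))
  expect_identical(status, 0L)
  expect_true(file.exists(file.path(out, "prediction.json")))
  expect_true(file.exists(file.path(out, "curves.tsv")))
  expect_true(file.exists(file.path(out, "consensus_k2.tsv")))
})

test_that("usage and constraint violations exit nonzero with the cause named", {
  dir <- withr::local_tempdir()
  tsv <- write_fixture_tsv(matrix(rnorm(38 * 3), 38, 3), dir)
  expect_message(status <- run_cli(c("--input", tsv, "--p", "1.2",
                                     "--outdir", file.path(dir, "o1"))),
                 "p must lie")
  expect_identical(status, 1L)
  expect_message(status <- run_cli(c("--input", tsv, "--p", "0.66",
                                     "--kmax", "40", "--H", "5",
                                     "--outdir", file.path(dir, "o2"))),
                 "floor\\(p \\* n\\) = 25")
  expect_identical(status, 1L)
  expect_message(status <- run_cli(c("--input", tsv, "--algorithm", "nmf",
                                     "--outdir", file.path(dir, "o3"))),
                 "unknown algorithm")
  expect_identical(status, 1L)
  expect_message(status <- run_cli(character(0)), "required")
  expect_identical(status, 1L)
})

test_that("identical arguments and seed reproduce byte-identical outputs", {
  s <- small_fit()
  dir <- withr::local_tempdir()
  tsv <- write_fixture_tsv(s$x, dir)
  args <- function(out) c("--input", tsv, "--method", "fc",
                          "--algorithm", "kmeans-r", "--H", "10",
                          "--kmax", "4", "--seed", "11", "--outdir", out)
  o1 <- file.path(dir, "r1"); o2 <- file.path(dir, "r2")
  expect_identical(run_cli(args(o1)), 0L)
  expect_identical(run_cli(args(o2)), 0L)
  f1 <- list.files(o1, full.names = TRUE)
  f2 <- file.path(o2, basename(f1))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("a YAML config file supplies defaults that CLI flags override", {
  s <- small_fit()
  dir <- withr::local_tempdir()
  tsv <- write_fixture_tsv(s$x, dir)
  cfgf <- file.path(dir, "cfg.yaml")
  writeLines(c("H: 10", "kmax: 4", "algorithm: hier-c", "seed: 5"), cfgf)
  out <- file.path(dir, "yml")
  status <- run_cli(c("--input", tsv, "--config", cfgf, "--seed", "9",
                      "--outdir", out))
  expect_identical(status, 0L)
  pj <- jsonlite::read_json(file.path(out, "prediction.json"),
                            simplifyVector = TRUE)
  expect_equal(pj$config$H, 10)              # from file
  expect_equal(pj$config$algorithm, "hier-c")
  expect_equal(pj$config$seed, 9)            # CLI wins over file
})

test_that("the CLI can simulate a benchmark dataset and label sidecar", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "sim")
  status <- suppressWarnings(  # at H = 5 a few pairs are never co-sampled
    run_cli(c("--simulate", "null", "--H", "5", "--kmax", "4",
              "--seed", "3", "--outdir", out)))
  expect_identical(status, 0L)
  expect_true(file.exists(file.path(out, "simulated_matrix.tsv")))
  labs <- utils::read.delim(file.path(out, "true_labels.tsv"))
  expect_equal(nrow(labs), 60)
  expect_true(all(labs$true_label == 1))
})
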