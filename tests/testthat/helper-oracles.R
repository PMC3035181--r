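# Brute-force agglomerative clustering from a distance matrix: recomputes
# every inter-cluster distance from the raw pairwise distances at each step
# (average = mean over cross pairs, complete = max, single = min) and merges
# the closest pair until k clusters remain. Independent of hclust/cutree.
naive_agglomerate <- function(dmat, linkage, k) {
  n <- nrow(dmat)
  clusters <- as.list(seq_len(n))
  agg <- switch(linkage, average = mean, complete = max, single = min)
  while (length(clusters) > k) {
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        d <- agg(dmat[clusters[[a]], clusters[[b]]])
        if (d < best_d) { best_d <- d; best <- c(a, b) }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labels <- integer(n)
  for (g in seq_along(clusters)) labels[clusters[[g]]] <- g
  labels
}

# Canonical partition signature: same for any relabeling of the same
# partition, different for different partitions.
partition_id <- function(labels) {
  paste(match(labels, unique(labels)), collapse = ".")
}

same_partition <- function(a, b) identical(partition_id(a), partition_id(b))

# Binary connectivity matrix of a single labeling over all n items.
connectivity_matrix <- function(labels) {
  M <- matrix(as.numeric(outer(labels, labels, "==")), length(labels))
  diag(M) <- 1
  M
}

# Tiny TSV fixture on disk; returns the path.
write_fixture_tsv <- function(values, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "matrix.tsv")
  n <- nrow(values); d <- ncol(values)
  header <- paste(c("id", paste0("cond", seq_len(d))), collapse = "\t")
  rows <- vapply(seq_len(n), function(i) {
    paste(c(paste0("item", i), format(values[i, ], trim = TRUE)), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  path
}

# Upper-triangle entries as a plain vector.
upper_entries <- function(M) M[upper.tri(M)]
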