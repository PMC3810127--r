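# Independent brute-force oracles used to validate the statistical
# primitives. These deliberately avoid the code paths they check.

# Exact two-sided Mann-Whitney p by enumerating all assignments of the
# pooled values to the two groups (no ties assumed).
oracle_mw_exact <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  u_stat <- function(xv, yv) sum(outer(xv, yv, `>`))
  u_obs <- u_stat(x, y)
  m <- nx * length(y) / 2
  combs <- utils::combn(length(pooled), nx)
  devs <- apply(combs, 2, function(idx) {
    abs(u_stat(pooled[idx], pooled[-idx]) - m)
  })
  mean(devs >= abs(u_obs - m))
}

# Friedman chi-square, tie-free hand formula:
# 12 / (n k (k+1)) * sum(Rj^2) - 3 n (k+1)
oracle_friedman_stat <- function(m) {
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1, rank))
  stopifnot(all(abs(sort(r[1, ]) - seq_len(k)) < 1e-12))  # tie-free only
  (12 / (n * k * (k + 1))) * sum(colSums(r)^2) - 3 * n * (k + 1)
}

# Spearman correlation from first principles: midranks then Pearson.
oracle_spearman <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# Naive O(n^3) UPGMA returning the cophenetic distance matrix.
oracle_upgma_cophenetic <- function(d) {
  n <- nrow(d)
  labels <- rownames(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = list(labels, labels))
  cluster_dist <- function(a, b) {
    mean(d[a, b])
  }
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in (i + 1):length(clusters)) {
        dd <- cluster_dist(clusters[[i]], clusters[[j]])
        if (dd < best[1]) best <- c(dd, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    coph[clusters[[i]], clusters[[j]]] <- best[1]
    coph[clusters[[j]], clusters[[i]]] <- best[1]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  coph
}

# Small complete study for tests: values chosen by hand, no randomness.
toy_study <- function() {
  mat <- rbind(
    A = c(1, 2, 3, 4, 5, 6, 10, 11),
    B = c(5, 5, 5, 8, 8, 8, 2, 2),
    C = c(2, 4, 8, 1, 3, 9, 7, 6)
  )
  colnames(mat) <- c("P01_S1", "P01_S2", "P01_S3",
                     "P02_S1", "P02_S2", "P02_S3", "H01", "H02")
  meta <- data.frame(
    sample_id = colnames(mat),
    patient_id = c("P01", "P01", "P01", "P02", "P02", "P02", "H01", "H02"),
    tissue_class = c(rep("tumor", 6), rep("healthy_tube", 2)),
    side = c(rep("left", 6), "na", "na"),
    stringsAsFactors = FALSE
  )
  list(matrix = mat, meta = meta)
}
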