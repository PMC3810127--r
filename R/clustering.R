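#' Log-transform and median-center an expression matrix
#'
#' Takes log2 of every value, then subtracts each protein row's median
#' (computed over non-missing entries). Missing entries stay missing. The
#' operation is deliberately not idempotent: it is applied once, before
#' clustering.
#'
#' @param mat Expression matrix with positive (or missing) values.
#' @return The transformed matrix.
#' @export
preprocess_expression <- function(mat) {
  stopifnot(is.matrix(mat))
  bad <- which(!is.na(mat) & mat <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("preprocess_expression: non-positive value at protein '",
         rownames(mat)[bad[1, 1]], "', sample '",
         colnames(mat)[bad[1, 2]], "'")
  }
  lg <- log2(mat)
  meds <- apply(lg, 1, stats::median, na.rm = TRUE)
  sweep(lg, 1, meds, `-`)
}

#' Spearman-rank correlation distance between samples
#'
#' `d(a, b) = 1 - rho_spearman(a, b)` over the proteins non-missing in both
#' samples (pairwise-complete, midrank ties). The distance is symmetric,
#' zero on the diagonal, ranges over [0, 2], and -- being rank-based -- is
#' invariant under any strictly increasing per-sample transformation of
#' the values.
#'
#' @param mat Expression matrix, proteins x samples (typically after
#'   [preprocess_expression()]).
#' @param min_shared Minimum number of proteins a pair must share.
#' @return Symmetric numeric matrix of distances with sample dimnames.
#' @export
spearman_distance <- function(mat, min_shared = 3) {
  stopifnot(is.matrix(mat))
  n <- ncol(mat)
  if (n < 2) stop("spearman_distance: need >= 2 samples")
  d <- matrix(0, n, n, dimnames = list(colnames(mat), colnames(mat)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(mat[, i]) & !is.na(mat[, j])
      if (sum(ok) < min_shared) {
        stop("spearman_distance: samples '", colnames(mat)[i], "' and '",
             colnames(mat)[j], "' share only ", sum(ok),
             " non-missing proteins (need >= ", min_shared, ")")
      }
      rho <- stats::cor(mat[ok, i], mat[ok, j], method = "spearman")
      d[i, j] <- d[j, i] <- 1 - rho
    }
  }
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerative clustering where the distance between clusters is the
#' arithmetic mean of all cross-pair distances, so merge heights are
#' monotone non-decreasing. Samples are ordered lexicographically by id
#' before agglomeration so that equal-distance merges resolve the same way
#' on every run.
#'
#' @param d Symmetric distance matrix (sample dimnames required) or a
#'   `dist` object.
#' @return An `hclust` tree over the samples.
#' @export
average_linkage <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d))
  if (is.null(rownames(d))) stop("average_linkage: distances need sample ids")
  if (!isTRUE(all.equal(d, t(d))) || any(diag(d) != 0)) {
    stop("average_linkage: distance matrix must be symmetric with a zero ",
         "diagonal")
  }
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  stats::hclust(stats::as.dist(d), method = "average")
}

#' Export a cluster tree as a Newick string
#'
#' Branch lengths are derived from the UPGMA merge heights (ultrametric
#' tree), suitable for external dendrogram viewers.
#'
#' @param tree An `hclust` tree.
#' @param path Optional file to write to.
#' @return The Newick string, invisibly when written to a file.
#' @export
tree_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "hclust"))
  phy <- ape::as.phylo(tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Do same-patient samples co-cluster?
#'
#' Cuts the tree into `k` flat clusters and scores the proportion of
#' same-patient tumor sample pairs that land in the same cluster
#' (within-patient co-membership rate). A patient whose samples spread over
#' more than one cluster is flagged as scattered.
#'
#' @param tree An `hclust` tree whose leaves are sample ids.
#' @param meta Sample metadata.
#' @param k Number of flat clusters; defaults to the number of tumor
#'   patients.
#' @return List: `score` (fraction in [0, 1]), `k`, `per_patient` data
#'   frame (`patient_id`, `n_samples`, `n_clusters`, `scattered`),
#'   `n_scattered`.
#' @export
cocluster_score <- function(tree, meta, k = NULL) {
  stopifnot(inherits(tree, "hclust"))
  tmeta <- meta[meta$tissue_class == "tumor", , drop = FALSE]
  if (is.null(k)) k <- length(unique(tmeta$patient_id))
  if (k < 1) stop("cocluster_score: k must be >= 1")
  if (k > length(tree$labels)) {
    stop("cocluster_score: k exceeds the number of samples")
  }
  cl <- stats::cutree(tree, k = k)
  tmeta <- tmeta[tmeta$sample_id %in% names(cl), , drop = FALSE]
  groups <- split(tmeta$sample_id, tmeta$patient_id)
  groups <- groups[vapply(groups, length, integer(1)) >= 2]
  if (!length(groups)) {
    stop("cocluster_score: no patient with >= 2 samples in the tree")
  }
  same <- 0; total <- 0
  per <- lapply(names(groups), function(p) {
    cls <- cl[groups[[p]]]
    pairs <- utils::combn(length(cls), 2)
    agree <- sum(cls[pairs[1, ]] == cls[pairs[2, ]])
    same <<- same + agree
    total <<- total + ncol(pairs)
    data.frame(patient_id = p, n_samples = length(cls),
               n_clusters = length(unique(cls)),
               scattered = length(unique(cls)) > 1,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  list(score = same / total, k = k, per_patient = per,
       n_scattered = sum(per$scattered))
}

#' One-call clustering of an RPPA study
#'
#' Convenience wrapper: [preprocess_expression()], [spearman_distance()],
#' [average_linkage()], and [cocluster_score()]. With
#' `per_tumor_means = TRUE` each tumor's samples are first collapsed to
#' their per-protein mean profile and clustered together with the
#' individual normal samples (tumor-vs-normal separation view).
#'
#' @param mat Expression matrix.
#' @param meta Sample metadata.
#' @param k Flat-cut size for the co-clustering score (ignored for
#'   per-tumor means).
#' @param per_tumor_means Collapse tumors to mean profiles first.
#' @return List with `tree`, `leaf_order` (sample ids in dendrogram
#'   order), `distances`, and (sample-level only) `cocluster`.
#' @export
cluster_study <- function(mat, meta, k = NULL, per_tumor_means = FALSE) {
  .check_meta_matrix(mat, meta)
  if (per_tumor_means) {
    tmeta <- meta[meta$tissue_class == "tumor", , drop = FALSE]
    groups <- split(tmeta$sample_id, tmeta$patient_id)
    means <- vapply(groups, function(cols) {
      rowMeans(mat[, cols, drop = FALSE], na.rm = TRUE)
    }, numeric(nrow(mat)))
    normals <- meta$sample_id[meta$tissue_class != "tumor"]
    mat <- cbind(means, mat[, normals, drop = FALSE])
  }
  pre <- preprocess_expression(mat)
  d <- spearman_distance(pre)
  tree <- average_linkage(d)
  out <- list(tree = tree, leaf_order = tree$labels[tree$order],
              distances = d)
  if (!per_tumor_means) out$cocluster <- cocluster_score(tree, meta, k = k)
  out
}
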