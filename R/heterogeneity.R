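#' Coefficient of variation, in percent
#'
#' The ratio of the sample standard deviation (n - 1 denominator) to the
#' mean, multiplied by 100. A scale-free dispersion measure: `cv(c * x)`
#' equals `cv(x)` for any `c > 0`.
#'
#' @param values Numeric vector of at least two finite, positive-mean
#'   values; `NA`s are rejected (drop them before calling).
#' @return CV in percent.
#' @examples
#' cv(c(1, 2, 3))  # 50
#' @export
cv <- function(values) {
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("cv: values must be finite and non-missing")
  }
  if (length(values) < 2) stop("cv: need at least 2 values")
  m <- mean(values)
  if (m <= 0) stop("cv: mean must be positive (got ", format(m), ")")
  100 * stats::sd(values) / m
}

#' Root-mean-square average of CVs
#'
#' `sqrt(mean(cvs^2))` -- the quadratic mean, used to pool per-patient CVs
#' into one intratumoral-heterogeneity summary per protein. Always at least
#' the arithmetic mean, with equality iff all inputs are equal.
#'
#' @param cvs Numeric vector of CVs (percent), length >= 1.
#' @return RMS average in percent.
#' @export
rms_average <- function(cvs) {
  cvs <- as.numeric(cvs)
  if (length(cvs) == 0) stop("rms_average: empty input")
  if (anyNA(cvs)) stop("rms_average: missing values not allowed")
  sqrt(mean(cvs^2))
}

#' Per-patient intratumoral CVs
#'
#' For every protein and every tumor patient, the CV over that patient's
#' tumor samples (non-missing values only). Patients with fewer than two
#' usable values for a protein are skipped; skipped (protein, patient)
#' cells are recorded in the `skipped` attribute with a reason code.
#'
#' @param mat Expression matrix, proteins x samples.
#' @param meta Sample metadata with `sample_id`, `patient_id`,
#'   `tissue_class`.
#' @return Data frame with `protein`, `patient_id`, `cv_percent`,
#'   `n_values`; attribute `skipped` lists omitted cells.
#' @export
intratumoral_cvs <- function(mat, meta) {
  .check_meta_matrix(mat, meta)
  tmeta <- meta[meta$tissue_class == "tumor", , drop = FALSE]
  if (nrow(tmeta) == 0) stop("intratumoral_cvs: no tumor samples")
  patients <- unique(tmeta$patient_id)
  out <- vector("list", length(patients))
  skipped <- list()
  for (pi in seq_along(patients)) {
    cols <- tmeta$sample_id[tmeta$patient_id == patients[pi]]
    sub <- mat[, cols, drop = FALSE]
    recs <- lapply(rownames(mat), function(p) {
      v <- sub[p, ]
      v <- v[!is.na(v)]
      if (length(v) < 2) {
        skipped[[length(skipped) + 1]] <<- data.frame(
          protein = p, patient_id = patients[pi],
          reason = "fewer_than_2_values", stringsAsFactors = FALSE)
        return(NULL)
      }
      data.frame(protein = p, patient_id = patients[pi],
                 cv_percent = cv(v), n_values = length(v),
                 stringsAsFactors = FALSE)
    })
    out[[pi]] <- do.call(rbind, recs)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(protein = character(0), patient_id = character(0),
               reason = character(0))
  if (nrow(skipped)) {
    message("intratumoral_cvs: skipped ", nrow(skipped),
            " (protein, patient) cells with < 2 usable values")
  }
  structure(res, skipped = skipped)
}

#' Inter-patient (or inter-individual) CV per protein
#'
#' For tumors, the CV across patients of each patient's mean expression
#' (arithmetic mean over that patient's non-missing tumor samples). For a
#' normal tissue class, each individual contributes a single sample, so
#' this is the CV across individuals' values.
#'
#' @param mat Expression matrix.
#' @param meta Sample metadata.
#' @param tissue_class One of `"tumor"`, `"healthy_tube"`,
#'   `"contralateral_tube"`.
#' @return Data frame with `protein`, `scope`, `cv_percent`, `n_values`.
#' @export
interpatient_cv <- function(mat, meta, tissue_class = "tumor") {
  .check_meta_matrix(mat, meta)
  tissue_class <- match.arg(tissue_class,
                            c("tumor", "healthy_tube", "contralateral_tube"))
  cmeta <- meta[meta$tissue_class == tissue_class, , drop = FALSE]
  groups <- split(cmeta$sample_id, cmeta$patient_id)
  if (length(groups) < 2) {
    stop("interpatient_cv: need >= 2 ", tissue_class,
         " patients/individuals, found ", length(groups))
  }
  recs <- lapply(rownames(mat), function(p) {
    summaries <- vapply(groups, function(cols) {
      v <- mat[p, cols]
      v <- v[!is.na(v)]
      if (length(v) == 0) return(NA_real_)
      mean(v)
    }, numeric(1))
    summaries <- summaries[!is.na(summaries)]
    if (length(summaries) < 2) return(NULL)
    data.frame(protein = p, scope = tissue_class,
               cv_percent = cv(summaries), n_values = length(summaries),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, recs)
  rownames(res) <- NULL
  res
}

#' Per-protein heterogeneity table
#'
#' Assembles, per protein: the RMS average of per-patient intratumoral CVs
#' and the inter-patient CV of per-patient means for tumors, plus
#' inter-individual CVs for any normal tissue classes present.
#'
#' @param mat Expression matrix.
#' @param meta Sample metadata.
#' @return List with `cv_records` (per-patient intratumoral CVs) and
#'   `per_protein` (one row per protein: `rms_cv_percent`,
#'   `interpatient_cv_percent`, and `healthy_tube_cv_percent` /
#'   `contralateral_tube_cv_percent` when those classes have >= 2
#'   individuals).
#' @export
heterogeneity_table <- function(mat, meta) {
  recs <- intratumoral_cvs(mat, meta)
  rms <- vapply(split(recs$cv_percent, factor(recs$protein, rownames(mat))),
                function(v) if (length(v)) rms_average(v) else NA_real_,
                numeric(1))
  inter <- interpatient_cv(mat, meta, "tumor")
  per <- data.frame(protein = rownames(mat),
                    rms_cv_percent = unname(rms[rownames(mat)]),
                    interpatient_cv_percent =
                      inter$cv_percent[match(rownames(mat), inter$protein)],
                    stringsAsFactors = FALSE)
  for (cls in c("healthy_tube", "contralateral_tube")) {
    ids <- unique(meta$patient_id[meta$tissue_class == cls])
    if (length(ids) >= 2) {
      icv <- interpatient_cv(mat, meta, cls)
      per[[paste0(cls, "_cv_percent")]] <-
        icv$cv_percent[match(rownames(mat), icv$protein)]
    }
  }
  list(cv_records = recs, per_protein = per)
}

#' Group summaries of heterogeneity (overall / phospho / non-phospho)
#'
#' Arithmetic mean and range of the per-protein CV summaries for all
#' proteins combined, the phosphorylated subset, and the non-phosphorylated
#' subset. Empty groups are omitted rather than reported as zero.
#'
#' @param per_protein The `per_protein` data frame from
#'   [heterogeneity_table()].
#' @param phospho_flags Named logical vector (names = protein ids) or
#'   unnamed vector in `per_protein` row order.
#' @return Data frame with one row per (group, metric): `group`, `metric`,
#'   `mean_cv`, `min_cv`, `max_cv`, `n_proteins`.
#' @export
group_summary <- function(per_protein, phospho_flags) {
  if (!is.null(names(phospho_flags))) {
    phospho_flags <- phospho_flags[per_protein$protein]
  }
  if (length(phospho_flags) != nrow(per_protein) || anyNA(phospho_flags)) {
    stop("group_summary: 'phospho_flags' must cover every protein")
  }
  metrics <- setdiff(names(per_protein), "protein")
  groups <- list(overall = rep(TRUE, nrow(per_protein)),
                 phospho = phospho_flags,
                 non_phospho = !phospho_flags)
  rows <- list()
  for (g in names(groups)) {
    sel <- groups[[g]]
    if (!any(sel)) next
    for (m in metrics) {
      v <- per_protein[[m]][sel]
      v <- v[!is.na(v)]
      if (!length(v)) next
      rows[[length(rows) + 1]] <- data.frame(
        group = g, metric = m, mean_cv = mean(v), min_cv = min(v),
        max_cv = max(v), n_proteins = length(v), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Friedman test comparing CVs across proteins
#'
#' Do proteins differ in their intratumoral heterogeneity? Blocks are
#' patients, treatments are proteins, observations are the per-(patient,
#' protein) intratumoral CVs. Blocks with any missing cell are removed
#' (listwise deletion, with the count reported), then the Friedman
#' chi-square statistic with tie correction is computed with `k - 1`
#' degrees of freedom and an upper-tail chi-square p-value.
#'
#' @param cv_records Data frame from [intratumoral_cvs()] (columns
#'   `protein`, `patient_id`, `cv_percent`).
#' @return List of class `rppa_test`: `test`, `statistic`, `df`, `p_value`,
#'   `sidedness`, `method`, `n_blocks`, `n_blocks_dropped`.
#' @export
friedman_cv_test <- function(cv_records) {
  need <- c("protein", "patient_id", "cv_percent")
  if (!all(need %in% names(cv_records))) {
    stop("friedman_cv_test: cv_records needs columns ",
         paste(need, collapse = ", "))
  }
  proteins <- unique(cv_records$protein)
  blocks <- unique(cv_records$patient_id)
  m <- matrix(NA_real_, length(blocks), length(proteins),
              dimnames = list(blocks, proteins))
  m[cbind(match(cv_records$patient_id, blocks),
          match(cv_records$protein, proteins))] <- cv_records$cv_percent
  complete <- stats::complete.cases(m)
  dropped <- sum(!complete)
  if (dropped) {
    message("friedman_cv_test: dropped ", dropped,
            " incomplete patient blocks")
  }
  m <- m[complete, , drop = FALSE]
  if (ncol(m) < 2) stop("friedman_cv_test: need >= 2 proteins")
  if (nrow(m) < 2) stop("friedman_cv_test: need >= 2 complete blocks")
  ft <- stats::friedman.test(m)
  stat <- unname(ft$statistic)
  pval <- unname(ft$p.value)
  if (is.nan(stat)) {
    # every block fully tied: no evidence of protein differences
    stat <- 0
    pval <- 1
  }
  structure(
    list(test = "Friedman",
         statistic = stat,
         df = unname(ft$parameter),
         p_value = pval,
         sidedness = "upper-tail chi-square",
         method = "chi-square approximation with tie correction",
         n_blocks = nrow(m),
         n_blocks_dropped = dropped),
    class = "rppa_test"
  )
}

#' Two-sided Mann-Whitney U test
#'
#' Compares two unrelated sample groups by ranks. The p-value is exact
#' (from the full null distribution of U) when the pooled size is at most
#' 16 and there are no ties; otherwise the normal approximation with tie
#' and continuity correction is used. The method actually applied is
#' recorded in the result.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @return List of class `rppa_test`: `test`, `statistic` (U for `x`),
#'   `p_value`, `sidedness`, `method`.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))$p_value  # 1/3
#' @export
mann_whitney <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) {
    stop("mann_whitney: both groups must be non-empty")
  }
  if (anyNA(x) || anyNA(y)) stop("mann_whitney: missing values not allowed")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 16) && !ties
  wt <- stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                           correct = TRUE)
  structure(
    list(test = "Mann-Whitney",
         statistic = unname(wt$statistic),
         p_value = unname(wt$p.value),
         sidedness = "two-sided",
         method = if (exact) "exact" else
           "normal approximation with tie and continuity correction"),
    class = "rppa_test"
  )
}

#' @export
print.rppa_test <- function(x, ...) {
  cat(x$test, "test:", "statistic =", format(x$statistic),
      if (!is.null(x$df)) paste0("df = ", x$df),
      "p =", format.pval(x$p_value), paste0("(", x$method, ")"), "\n")
  invisible(x)
}

#' Box-plot summary statistics
#'
#' Median, quartiles by linear interpolation between order statistics,
#' whiskers at the most extreme data points within 1.5 times the
#' interquartile range of the quartiles, and outliers beyond the whiskers.
#'
#' @param values Numeric vector, length >= 1.
#' @return List: `median`, `q25`, `q75`, `whisker_low`, `whisker_high`,
#'   `outliers`.
#' @examples
#' boxplot_stats(c(1, 2, 3, 4, 100))$outliers  # 100
#' @export
boxplot_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("boxplot_stats: empty input")
  if (anyNA(values)) stop("boxplot_stats: missing values not allowed")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values[values >= lo_fence & values <= hi_fence]
  list(median = q[2], q25 = q[1], q75 = q[3],
       whisker_low = min(inside), whisker_high = max(inside),
       outliers = sort(values[values < lo_fence | values > hi_fence]))
}

.check_meta_matrix <- function(mat, meta) {
  if (!is.matrix(mat) || is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("expression matrix must have protein rownames and sample colnames")
  }
  need <- c("sample_id", "patient_id", "tissue_class")
  if (!is.data.frame(meta) || !all(need %in% names(meta))) {
    stop("metadata must contain columns ", paste(need, collapse = ", "))
  }
  if (!all(colnames(mat) %in% meta$sample_id)) {
    stop("samples missing from metadata: ",
         paste(setdiff(colnames(mat), meta$sample_id), collapse = ", "))
  }
  invisible(TRUE)
}
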