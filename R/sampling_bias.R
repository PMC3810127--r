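#' Differential expression from per-tumor mean profiles
#'
#' For each protein, summarizes every tumor patient by the mean over that
#' patient's samples and compares the per-patient summaries against all
#' normal-tissue sample values with a two-sided Mann-Whitney test. The
#' summary is the geometric mean by default: expression is analyzed on the
#' log scale throughout this package, and the geometric mean is the
#' log-scale mean, which keeps the rank test calibrated under
#' multiplicative (lognormal) within-tumor noise. The arithmetic mean is
#' available as an option.
#'
#' Direction is the sign of `median(patient summaries) - median(normal
#' values)`: `"up"` means higher in tumor.
#'
#' @param mat Expression matrix.
#' @param meta Sample metadata.
#' @param alpha Two-sided significance level.
#' @param patient_summary `"geometric"` (default) or `"arithmetic"`.
#' @return Data frame with one row per protein: `protein`, `analysis`
#'   (`"mean"`), `p_value`, `direction` (`"up"`/`"down"`/`NA`),
#'   `significant`. Proteins unusable in either group are dropped, with a
#'   notice in the `skipped` attribute.
#' @export
mean_based_de <- function(mat, meta, alpha = 0.05,
                          patient_summary = c("geometric", "arithmetic")) {
  .check_meta_matrix(mat, meta)
  patient_summary <- match.arg(patient_summary)
  groups <- .tumor_groups(meta)
  normals <- .normal_samples(meta)
  if (length(groups) < 2) stop("mean_based_de: need >= 2 tumor patients")
  if (length(normals) < 2) stop("mean_based_de: need >= 2 normal samples")
  summarize <- if (patient_summary == "geometric") {
    function(v) exp(mean(log(v)))
  } else {
    mean
  }
  rows <- list(); skipped <- list()
  for (p in rownames(mat)) {
    pm <- vapply(groups, function(cols) {
      v <- mat[p, cols]; v <- v[!is.na(v)]
      if (!length(v)) return(NA_real_)
      summarize(v)
    }, numeric(1))
    pm <- pm[!is.na(pm)]
    nv <- mat[p, normals]; nv <- nv[!is.na(nv)]
    if (length(pm) < 2 || length(nv) < 2) {
      skipped[[length(skipped) + 1]] <- data.frame(
        protein = p, reason = "insufficient_group_data",
        stringsAsFactors = FALSE)
      next
    }
    rows[[length(rows) + 1]] <- .de_row(p, "mean", pm, nv, alpha)
  }
  .de_result(rows, skipped, "mean_based_de")
}

#' Differential expression from randomly selected single samples
#'
#' Repeats the tumor-vs-normal comparison using one randomly chosen sample
#' per tumor patient instead of the per-patient mean. Each repetition draws
#' a fresh selection; when every patient has at least `n_repetitions`
#' samples the draws are made without reuse across repetitions (each
#' repetition sees a sample no other repetition used), making repetitions
#' maximally independent. Set `reuse = TRUE` to allow reuse for small
#' designs. Selections are fully determined by `seed`.
#'
#' @param mat Expression matrix.
#' @param meta Sample metadata.
#' @param alpha Two-sided significance level.
#' @param n_repetitions Number of independent single-sample analyses.
#' @param seed Integer seed for the sample draws.
#' @param reuse Allow a sample to be reused across repetitions.
#' @return Data frame as in [mean_based_de()], with `analysis` labels
#'   `"single_1"`, `"single_2"`, ...; attribute `selections` records the
#'   chosen sample ids (patients x repetitions).
#' @export
single_sample_de <- function(mat, meta, alpha = 0.05, n_repetitions = 3,
                             seed = 1L, reuse = FALSE) {
  .check_meta_matrix(mat, meta)
  if (n_repetitions < 1) stop("single_sample_de: n_repetitions must be >= 1")
  groups <- .tumor_groups(meta)
  normals <- .normal_samples(meta)
  if (length(groups) < 2) stop("single_sample_de: need >= 2 tumor patients")
  if (length(normals) < 2) stop("single_sample_de: need >= 2 normal samples")
  counts <- vapply(groups, length, integer(1))
  if (!reuse && any(counts < n_repetitions)) {
    stop("single_sample_de: ", sum(counts < n_repetitions), " patient(s) ",
         "have fewer than ", n_repetitions, " samples; set reuse = TRUE ",
         "to allow repeated use of a sample")
  }
  set.seed(as.integer(seed))
  selections <- matrix(NA_character_, length(groups), n_repetitions,
                       dimnames = list(names(groups),
                                       paste0("single_",
                                              seq_len(n_repetitions))))
  for (g in seq_along(groups)) {
    ids <- groups[[g]]
    selections[g, ] <- if (length(ids) >= n_repetitions) {
      sample(ids)[seq_len(n_repetitions)]
    } else {
      sample(ids, n_repetitions, replace = TRUE)
    }
  }
  rows <- list(); skipped <- list()
  for (r in seq_len(n_repetitions)) {
    label <- paste0("single_", r)
    for (p in rownames(mat)) {
      tv <- mat[p, selections[, r]]; tv <- tv[!is.na(tv)]
      nv <- mat[p, normals]; nv <- nv[!is.na(nv)]
      if (length(tv) < 2 || length(nv) < 2) {
        skipped[[length(skipped) + 1]] <- data.frame(
          protein = p, reason = paste0("insufficient_group_data_", label),
          stringsAsFactors = FALSE)
        next
      }
      rows[[length(rows) + 1]] <- .de_row(p, label, tv, nv, alpha)
    }
  }
  res <- .de_result(rows, skipped, "single_sample_de")
  attr(res, "selections") <- selections
  res
}

#' Classify per-protein concordance between sampling strategies
#'
#' Assigns every protein to exactly one category by precedence:
#' \describe{
#'   \item{`all_four`}{significant in the mean-based analysis and in every
#'     single-sample repetition (with the default three repetitions these
#'     are the four approaches).}
#'   \item{`mean_only_strict`}{significant by mean, non-significant in
#'     every single-sample repetition -- proteins a single biopsy would
#'     miss entirely.}
#'   \item{`singles_only`}{non-significant by mean, significant in at
#'     least one repetition.}
#'   \item{`partial`}{any other protein significant somewhere.}
#'   \item{`none`}{significant nowhere.}
#' }
#' Proteins whose significant calls disagree in direction between analyses
#' are flagged (`direction_conflict`), without reinterpreting them. The
#' summary also reports, for proteins significant by mean, how many are
#' missed by *all* repetitions and by *at least one* repetition -- the two
#' readings of "not detected in single samples".
#'
#' @param mean_results Data frame from [mean_based_de()] (or the fixture
#'   converter [table2_results()]).
#' @param single_results Data frame from [single_sample_de()].
#' @param alpha Significance level used for the calls.
#' @return List of class `concordance_report`: `per_protein` (protein,
#'   category, direction_conflict), `counts` (named integer vector over
#'   categories), `n_mean_missed_by_all_singles`,
#'   `n_mean_missed_by_any_single`, `alpha`.
#' @export
classify_concordance <- function(mean_results, single_results,
                                 alpha = 0.05) {
  panel <- sort(unique(mean_results$protein))
  if (!setequal(panel, unique(single_results$protein))) {
    stop("classify_concordance: mean and single-sample analyses cover ",
         "different protein panels")
  }
  labels <- unique(single_results$analysis)
  sig_of <- function(df, p, a) {
    row <- df[df$protein == p & df$analysis == a, , drop = FALSE]
    if (nrow(row) != 1) {
      stop("classify_concordance: expected exactly one record for ",
           p, " / ", a)
    }
    list(sig = !is.na(row$p_value) && row$p_value <= alpha,
         dir = row$direction)
  }
  cats <- character(length(panel)); conflict <- logical(length(panel))
  m_sig_v <- logical(length(panel)); all_s <- logical(length(panel))
  any_s <- logical(length(panel))
  for (i in seq_along(panel)) {
    p <- panel[i]
    m <- sig_of(mean_results, p, "mean")
    s <- lapply(labels, function(a) sig_of(single_results, p, a))
    s_sig <- vapply(s, `[[`, logical(1), "sig")
    m_sig_v[i] <- m$sig; all_s[i] <- all(s_sig); any_s[i] <- any(s_sig)
    cats[i] <- if (m$sig && all(s_sig)) "all_four"
      else if (m$sig && !any(s_sig)) "mean_only_strict"
      else if (!m$sig && any(s_sig)) "singles_only"
      else if (m$sig || any(s_sig)) "partial"
      else "none"
    dirs <- c(if (m$sig) m$dir,
              unlist(lapply(s[s_sig], `[[`, "dir")))
    dirs <- dirs[!is.na(dirs)]
    conflict[i] <- length(unique(dirs)) > 1
  }
  categories <- c("all_four", "mean_only_strict", "singles_only", "partial",
                  "none")
  counts <- vapply(categories, function(cg) sum(cats == cg), integer(1))
  structure(
    list(per_protein = data.frame(protein = panel, category = cats,
                                  direction_conflict = conflict,
                                  stringsAsFactors = FALSE),
         counts = counts,
         n_mean_missed_by_all_singles = sum(m_sig_v & !any_s),
         n_mean_missed_by_any_single = sum(m_sig_v & !all_s),
         alpha = alpha),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Concordance of differential-expression calls (alpha =", x$alpha,
      ")\n")
  print(x$counts)
  cat("Significant by mean but missed by every single-sample analysis:",
      x$n_mean_missed_by_all_singles, "\n")
  cat("Significant by mean but missed by at least one:",
      x$n_mean_missed_by_any_single, "\n")
  invisible(x)
}

#' Run the full sampling-bias experiment
#'
#' Mean-based differential expression, `n_repetitions` single-sample
#' analyses, and the concordance classification, in one deterministic call.
#'
#' @inheritParams single_sample_de
#' @param patient_summary Passed to [mean_based_de()].
#' @return List: `results` (all per-protein, per-analysis rows) and
#'   `concordance` (a `concordance_report`).
#' @export
run_sampling_bias_experiment <- function(mat, meta, alpha = 0.05,
                                         n_repetitions = 3, seed = 1L,
                                         reuse = FALSE,
                                         patient_summary = "geometric") {
  mres <- mean_based_de(mat, meta, alpha, patient_summary)
  sres <- single_sample_de(mat, meta, alpha, n_repetitions, seed, reuse)
  list(results = rbind(mres, sres),
       concordance = classify_concordance(mres, sres, alpha))
}

.tumor_groups <- function(meta) {
  tmeta <- meta[meta$tissue_class == "tumor", , drop = FALSE]
  split(tmeta$sample_id, tmeta$patient_id)
}

.normal_samples <- function(meta) {
  meta$sample_id[meta$tissue_class %in%
                   c("healthy_tube", "contralateral_tube")]
}

.de_row <- function(protein, label, tumor_values, normal_values, alpha) {
  test <- mann_whitney(tumor_values, normal_values)
  diff <- stats::median(tumor_values) - stats::median(normal_values)
  direction <- if (diff > 0) "up" else if (diff < 0) "down" else
    NA_character_
  data.frame(protein = protein, analysis = label,
             p_value = test$p_value, direction = direction,
             significant = test$p_value <= alpha,
             stringsAsFactors = FALSE)
}

.de_result <- function(rows, skipped, caller) {
  if (!length(rows)) stop(caller, ": no testable proteins")
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(protein = character(0), reason = character(0))
  if (nrow(skipped)) {
    message(caller, ": skipped ", nrow(skipped),
            " protein/analysis combinations with insufficient data")
  }
  structure(res, skipped = skipped)
}
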