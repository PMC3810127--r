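#' Quantification settings for dilution-series estimation
#'
#' @param floor_threshold Signals strictly below this value (after
#'   background subtraction) are excluded as below the detection floor.
#' @param saturation_threshold Fraction of the array's maximum observed
#'   signal above which a spot is treated as saturated and excluded.
#' @param min_valid_spots Minimum number of valid spots required to report
#'   an estimate; with fewer, the cell is missing (`NA`), never zero.
#' @return An object of class `quantification_settings`.
#' @export
quantification_settings <- function(floor_threshold = 0,
                                    saturation_threshold = 0.95,
                                    min_valid_spots = 2) {
  if (floor_threshold < 0) {
    stop("quantification_settings: 'floor_threshold' must be >= 0")
  }
  if (saturation_threshold < 0 || saturation_threshold > 1) {
    stop("quantification_settings: 'saturation_threshold' must be in [0, 1]")
  }
  if (min_valid_spots < 1) {
    stop("quantification_settings: 'min_valid_spots' must be >= 1")
  }
  structure(list(floor_threshold = floor_threshold,
                 saturation_threshold = saturation_threshold,
                 min_valid_spots = as.integer(min_valid_spots)),
            class = "quantification_settings")
}

#' Subtract buffer-blank background from a dilution series
#'
#' Reduces every lysate spot signal by the mean buffer-blank signal of the
#' same series, clipping at zero, and removes the blank records. Blanks are
#' the rows with `dilution_fraction == 0`.
#'
#' @param series Data frame with columns `dilution_fraction`, `replicate`,
#'   `signal` (and optionally `protein`, `sample_id`).
#' @return The series without blank rows and with background-corrected
#'   signals.
#' @export
subtract_background <- function(series) {
  .check_series(series)
  blank <- series$dilution_fraction == 0
  if (!any(blank)) {
    stop("subtract_background: series has no buffer-blank records ",
         "(dilution_fraction == 0); run without background subtraction")
  }
  bg <- mean(series$signal[blank])
  out <- series[!blank, , drop = FALSE]
  out$signal <- pmax(out$signal - bg, 0)
  rownames(out) <- NULL
  out
}

#' Estimate one expression value from a dilution series
#'
#' Robust serial-dilution estimator: the median of `signal /
#' dilution_fraction` over valid spots. A spot is valid when its signal is
#' not below `floor_threshold` and not saturated, i.e. not above
#' `saturation_threshold * array_max`. In the noiseless, unsaturated case
#' every dilution-corrected signal equals the underlying value and the
#' estimate is exact; the estimator is linear in the input signals.
#'
#' @param series Background-subtracted series (no blank rows).
#' @param settings A [quantification_settings()].
#' @param array_max Maximum observed signal used as the saturation
#'   reference; defaults to the maximum within the series, but callers
#'   quantifying a whole study should pass the array-wide maximum.
#' @return A single non-negative estimate, or `NA` (with attribute
#'   `reason` set to `"floor"`, `"saturation"` or `"too_few"`) when fewer
#'   than `min_valid_spots` spots are valid.
#' @export
estimate_sample_value <- function(series,
                                  settings = quantification_settings(),
                                  array_max = NULL) {
  .check_series(series)
  stopifnot(inherits(settings, "quantification_settings"))
  if (nrow(series) == 0) stop("estimate_sample_value: empty series")
  if (any(series$dilution_fraction == 0)) {
    stop("estimate_sample_value: series still contains buffer blanks; ",
         "apply subtract_background() first")
  }
  if (is.null(array_max)) array_max <- max(series$signal)
  below <- series$signal < settings$floor_threshold
  sat <- series$signal > settings$saturation_threshold * array_max
  valid <- !below & !sat
  if (sum(valid) < settings$min_valid_spots) {
    reason <- if (all(below | sat)) {
      if (sum(below) >= sum(sat)) "floor" else "saturation"
    } else "too_few"
    return(structure(NA_real_, reason = reason))
  }
  stats::median(series$signal[valid] / series$dilution_fraction[valid])
}

#' Normalize an expression value to total protein
#'
#' Scales an estimate by `reference_total / total_protein_signal`, so that
#' samples with more loaded protein (stronger total-protein stain) are
#' corrected downward. With the reference set to the cohort median total,
#' the normalization is invariant to global staining intensity.
#'
#' @param value Estimate to normalize (may be `NA`).
#' @param total_protein_signal Positive total-protein signal of the sample.
#' @param reference_total Positive reference total.
#' @return The normalized value.
#' @export
normalize_total_protein <- function(value, total_protein_signal,
                                    reference_total) {
  if (any(total_protein_signal <= 0)) {
    stop("normalize_total_protein: 'total_protein_signal' must be > 0")
  }
  if (any(reference_total <= 0)) {
    stop("normalize_total_protein: 'reference_total' must be > 0")
  }
  value * (reference_total / total_protein_signal)
}

#' Quantify a whole spot table into an expression matrix
#'
#' Applies [subtract_background()] (optional), [estimate_sample_value()]
#' and [normalize_total_protein()] to every (protein, sample) series of a
#' long-format spot table. Cells whose series yields no estimate are
#' missing (`NA`), and missingness propagates rather than becoming zero.
#'
#' @param spots Data frame with columns `protein`, `sample_id`,
#'   `dilution_fraction` (0 marks buffer blanks), `replicate`, `signal`.
#' @param totals Data frame with `sample_id`, `total_signal`; required when
#'   `normalize = TRUE`.
#' @param settings A [quantification_settings()].
#' @param background Subtract buffer-blank background first.
#' @param normalize Apply total-protein normalization.
#' @param reference_total Reference for normalization; defaults to the
#'   median total-protein signal across samples.
#' @return Numeric matrix, proteins as rows and samples as columns, in
#'   order of first appearance in `spots`.
#' @export
quantify_study <- function(spots, totals = NULL,
                           settings = quantification_settings(),
                           background = TRUE, normalize = !is.null(totals),
                           reference_total = NULL) {
  need <- c("protein", "sample_id", "dilution_fraction", "replicate",
            "signal")
  missing_cols <- setdiff(need, names(spots))
  if (length(missing_cols)) {
    stop("quantify_study: spot table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  key <- paste(spots$protein, spots$sample_id, spots$dilution_fraction,
               spots$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop("quantify_study: duplicate (protein, sample, dilution, replicate) ",
         "records")
  }
  proteins <- unique(spots$protein)
  samples <- unique(spots$sample_id)
  lysate <- spots$dilution_fraction > 0
  array_max <- max(spots$signal[lysate])

  mat <- matrix(NA_real_, length(proteins), length(samples),
                dimnames = list(proteins, samples))
  idx <- split(seq_len(nrow(spots)),
               list(factor(spots$protein, proteins),
                    factor(spots$sample_id, samples)))
  for (cell in idx) {
    if (!length(cell)) next
    series <- spots[cell, , drop = FALSE]
    if (background) series <- subtract_background(series)
    est <- estimate_sample_value(series, settings, array_max = array_max)
    mat[series$protein[1], series$sample_id[1]] <- est
  }

  if (normalize) {
    if (is.null(totals)) {
      stop("quantify_study: 'totals' required when normalize = TRUE")
    }
    m <- match(samples, totals$sample_id)
    if (anyNA(m)) {
      stop("quantify_study: totals missing for samples: ",
           paste(samples[is.na(m)], collapse = ", "))
    }
    tot <- totals$total_signal[m]
    if (is.null(reference_total)) reference_total <- stats::median(tot)
    mat <- sweep(mat, 2, reference_total / tot, `*`)
  }
  mat
}

.check_series <- function(series) {
  need <- c("dilution_fraction", "signal")
  if (!is.data.frame(series) || !all(need %in% names(series))) {
    stop("series must be a data frame with columns 'dilution_fraction' ",
         "and 'signal'")
  }
  if (any(series$dilution_fraction < 0) ||
      any(series$dilution_fraction > 1)) {
    stop("series: dilution fractions must be in [0, 1] (0 = buffer blank)")
  }
  if (any(series$signal < 0)) stop("series: signals must be non-negative")
  invisible(series)
}
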