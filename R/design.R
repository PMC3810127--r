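#' Study design for a synthetic RPPA cohort
#'
#' Describes the sampling layout of a multi-region RPPA study: how many
#' tumor patients, how many spatially distinct samples per patient, how many
#' normal reference individuals (fallopian tube epithelium from healthy
#' individuals and from uninvolved contralateral tubes of cancer patients),
#' and the protein panel with its phosphoprotein flags.
#'
#' The default reproduces the cohort this package emulates: 13 high-grade
#' serous ovarian carcinomas sampled at 5--9 distinct locations each (88
#' tumor samples in total), 10 healthy-tube and 4 contralateral-tube
#' normals, and a 36-protein signaling panel of which 15 are phosphorylated.
#' The exact per-patient breakdown of the 88 samples is not published, so
#' the default uses a fixed sequence (ten patients with 7 samples, three
#' with 6) inside the stated 5--9 range.
#'
#' @param n_patients Number of tumor patients.
#' @param samples_per_patient Integer vector, one entry per patient, giving
#'   the number of spatially distinct tumor samples.
#' @param n_healthy_tubes Number of healthy-individual normal samples (one
#'   sample per individual).
#' @param n_contralateral_tubes Number of contralateral-tube normal samples
#'   from cancer patients (one per individual).
#' @param n_proteins Size of the protein panel.
#' @param phospho_flags Logical vector of length `n_proteins`; `TRUE` marks
#'   a phosphoprotein. Defaults to the first `round(15/36 * n_proteins)`
#'   proteins flagged so the default panel carries 15 phospho flags.
#' @param protein_ids Character vector of protein identifiers.
#' @return An object of class `study_design`.
#' @examples
#' d <- study_design()
#' d$n_patients            # 13
#' sum(d$samples_per_patient)  # 88
#' @export
study_design <- function(n_patients = 13,
                         samples_per_patient = c(rep(7L, 10), rep(6L, 3)),
                         n_healthy_tubes = 10,
                         n_contralateral_tubes = 4,
                         n_proteins = 36,
                         phospho_flags = NULL,
                         protein_ids = NULL) {
  if (length(n_patients) != 1 || n_patients < 1) {
    stop("study_design: 'n_patients' must be a single count >= 1")
  }
  n_patients <- as.integer(n_patients)
  samples_per_patient <- as.integer(samples_per_patient)
  if (length(samples_per_patient) != n_patients) {
    stop("study_design: length of 'samples_per_patient' (",
         length(samples_per_patient), ") must equal 'n_patients' (",
         n_patients, ")")
  }
  if (any(samples_per_patient < 1)) {
    stop("study_design: every entry of 'samples_per_patient' must be >= 1")
  }
  if (n_healthy_tubes < 0 || n_contralateral_tubes < 0) {
    stop("study_design: normal-tissue counts must be >= 0")
  }
  if (n_proteins < 1) stop("study_design: 'n_proteins' must be >= 1")
  n_proteins <- as.integer(n_proteins)
  if (is.null(phospho_flags)) {
    n_phos <- round(15 / 36 * n_proteins)
    phospho_flags <- seq_len(n_proteins) <= n_phos
  }
  if (length(phospho_flags) != n_proteins || !is.logical(phospho_flags)) {
    stop("study_design: 'phospho_flags' must be logical of length 'n_proteins'")
  }
  if (is.null(protein_ids)) {
    protein_ids <- sprintf("protein_%02d", seq_len(n_proteins))
  }
  if (length(protein_ids) != n_proteins || anyDuplicated(protein_ids)) {
    stop("study_design: 'protein_ids' must be ", n_proteins, " unique ids")
  }
  structure(
    list(n_patients = n_patients,
         samples_per_patient = samples_per_patient,
         n_healthy_tubes = as.integer(n_healthy_tubes),
         n_contralateral_tubes = as.integer(n_contralateral_tubes),
         n_proteins = n_proteins,
         phospho_flags = phospho_flags,
         protein_ids = protein_ids),
    class = "study_design"
  )
}

#' Hierarchical variance model for synthetic expression values
#'
#' Expression of protein k in sample j of patient i is modelled as
#' `mu_k * exp(b_ki) * exp(w_kij)` with independent Gaussian log-scale
#' effects: `b_ki` captures between-patient variation and `w_kij`
#' within-tumor (intratumoral) variation. Targets are stated as coefficients
#' of variation (CV, as fractions); the lognormal identity
#' `sigma = sqrt(log(1 + CV^2))` converts a CV target into the log-scale
#' standard deviation, so that the population CV of `exp(N(0, sigma^2))`
#' equals the target exactly. Normal-tissue individuals carry a single
#' between-individual component (one sample per individual, no
#' within-individual replication).
#'
#' Defaults follow the variation this package is built to study: mean
#' intratumoral CV near 25%, inter-patient CV near 21%, and normal-tissue
#' between-individual CV near 27%.
#'
#' @param baseline_mean Positive baseline expression per protein (arbitrary
#'   units); scalar or one value per protein.
#' @param between_patient_cv Between-patient CV (fraction); scalar or
#'   per protein.
#' @param within_tumor_cv Intratumoral CV (fraction); scalar or per protein.
#' @param normal_between_individual_cv Between-individual CV for normal
#'   tissue (fraction); scalar or per protein.
#' @return An object of class `variance_model`.
#' @seealso [cv_to_sigma()], [sigma_to_cv()]
#' @export
variance_model <- function(baseline_mean = 1000,
                           between_patient_cv = 0.21,
                           within_tumor_cv = 0.25,
                           normal_between_individual_cv = 0.27) {
  if (any(baseline_mean <= 0)) {
    stop("variance_model: 'baseline_mean' must be > 0")
  }
  for (nm in c("between_patient_cv", "within_tumor_cv",
               "normal_between_individual_cv")) {
    v <- get(nm)
    if (any(v < 0)) stop("variance_model: '", nm, "' must be >= 0")
  }
  structure(
    list(baseline_mean = baseline_mean,
         between_patient_cv = between_patient_cv,
         within_tumor_cv = within_tumor_cv,
         normal_between_individual_cv = normal_between_individual_cv),
    class = "variance_model"
  )
}

#' Tumor-vs-normal effect model
#'
#' Assigns a signed log fold change (natural-log scale, tumor relative to
#' normal) to a subset of the panel; all other proteins have log fold
#' change exactly 0. This is the ground truth against which differential
#' calls of the sampling-bias experiment are evaluated.
#'
#' @param differential_proteins Character vector of protein ids carrying an
#'   effect (may be empty).
#' @param log_fold_change Numeric vector of natural-log fold changes, one
#'   per differential protein (scalar recycled).
#' @return An object of class `effect_model`.
#' @export
effect_model <- function(differential_proteins = character(0),
                         log_fold_change = numeric(0)) {
  differential_proteins <- as.character(differential_proteins)
  if (anyDuplicated(differential_proteins)) {
    stop("effect_model: duplicated ids in 'differential_proteins'")
  }
  if (length(log_fold_change) == 1 && length(differential_proteins) > 1) {
    log_fold_change <- rep(log_fold_change, length(differential_proteins))
  }
  if (length(log_fold_change) != length(differential_proteins)) {
    stop("effect_model: 'log_fold_change' must have one value per ",
         "differential protein")
  }
  structure(
    list(differential_proteins = differential_proteins,
         log_fold_change = as.numeric(log_fold_change)),
    class = "effect_model"
  )
}

#' Spot-level noise model for the dilution-series layer
#'
#' Describes how a latent expression value is realized as raw spot signals:
#' a serial dilution (default 1, 1:2, 1:4, 1:8, 1:16) printed in duplicate
#' plus buffer blanks -- 12 spots per (protein, sample) under the defaults
#' -- with additive background, multiplicative lognormal spot noise, and
#' optional signal saturation. A per-sample total-protein stain signal
#' (Sypro Ruby stand-in) is emitted alongside, with its own noise CV:
#' because the stain aggregates signal over the whole dilution series its
#' noise is far smaller than single-spot noise, so `total_cv` defaults to 0.
#'
#' @param dilution_fractions Strictly decreasing positive fractions <= 1.
#' @param n_replicates Replicate spots per dilution step.
#' @param include_buffer_blank Emit buffer-blank spots (background only).
#' @param spot_cv Multiplicative noise CV per spot (fraction).
#' @param background_mean Additive background signal (>= 0).
#' @param saturation_level Signal ceiling (clip), or `NULL` for none.
#' @param total_cv Noise CV of the per-sample total-protein signal.
#' @return An object of class `spot_noise_model`.
#' @export
spot_noise_model <- function(dilution_fractions = c(1, 1/2, 1/4, 1/8, 1/16),
                             n_replicates = 2,
                             include_buffer_blank = TRUE,
                             spot_cv = 0.1,
                             background_mean = 0,
                             saturation_level = NULL,
                             total_cv = 0) {
  if (any(dilution_fractions <= 0) || any(dilution_fractions > 1)) {
    stop("spot_noise_model: 'dilution_fractions' must be in (0, 1]")
  }
  if (any(diff(dilution_fractions) >= 0)) {
    stop("spot_noise_model: 'dilution_fractions' must be strictly decreasing")
  }
  if (n_replicates < 1) stop("spot_noise_model: 'n_replicates' must be >= 1")
  if (spot_cv < 0 || total_cv < 0) {
    stop("spot_noise_model: noise CVs must be >= 0")
  }
  if (background_mean < 0) {
    stop("spot_noise_model: 'background_mean' must be >= 0")
  }
  if (!is.null(saturation_level) && saturation_level <= 0) {
    stop("spot_noise_model: 'saturation_level' must be > 0 or NULL")
  }
  structure(
    list(dilution_fractions = dilution_fractions,
         n_replicates = as.integer(n_replicates),
         include_buffer_blank = isTRUE(include_buffer_blank),
         spot_cv = spot_cv,
         background_mean = background_mean,
         saturation_level = saturation_level,
         total_cv = total_cv),
    class = "spot_noise_model"
  )
}

#' Convert a coefficient of variation to a lognormal log-scale sd
#'
#' For `X = exp(N(m, sigma^2))` the population CV is
#' `sqrt(exp(sigma^2) - 1)` regardless of `m`; inverting gives
#' `sigma = sqrt(log(1 + cv^2))`. The pair of functions is bijective on
#' `[0, Inf)`.
#'
#' @param cv Coefficient of variation as a fraction (>= 0).
#' @return Log-scale standard deviation.
#' @examples
#' sigma_to_cv(cv_to_sigma(0.25))  # 0.25
#' @export
cv_to_sigma <- function(cv) {
  if (any(cv < 0)) stop("cv_to_sigma: 'cv' must be >= 0")
  sqrt(log(1 + cv^2))
}

#' @rdname cv_to_sigma
#' @param sigma Log-scale standard deviation (>= 0).
#' @export
sigma_to_cv <- function(sigma) {
  if (any(sigma < 0)) stop("sigma_to_cv: 'sigma' must be >= 0")
  sqrt(exp(sigma^2) - 1)
}
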