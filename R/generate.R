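#' Generate a synthetic multi-region RPPA study
#'
#' Draws a proteins-by-samples expression matrix with a hierarchical
#' lognormal variance structure. The value for protein k, tumor patient i,
#' sample j is
#' \deqn{\mu_k \, e^{\delta_k} \, e^{b_{ki}} \, e^{w_{kij}},}
#' where \eqn{\delta_k} is the tumor log fold change (0 for non-differential
#' proteins), \eqn{b_{ki} \sim N(0, \sigma_{b,k}^2)} is the patient effect
#' and \eqn{w_{kij} \sim N(0, \sigma_{w,k}^2)} the within-tumor effect, with
#' each \eqn{\sigma = \sqrt{\log(1 + CV^2)}}. Normal-tissue individuals
#' (healthy and contralateral tubes) contribute one sample each:
#' \eqn{\mu_k e^{u_{ki}}} with the normal between-individual component and
#' no tumor effect.
#'
#' Randomness is drawn in a fixed, versioned order (patient effects by
#' protein within patient, then within-tumor effects by protein within
#' sample within patient, then healthy-tube and contralateral-tube
#' effects), so identical `(design, variance, effects, seed)` reproduce
#' bit-identical output.
#'
#' @param design A [study_design()].
#' @param variance A [variance_model()].
#' @param effects An [effect_model()]; defaults to no effects.
#' @param seed Integer seed.
#' @return A list with components:
#'   \describe{
#'     \item{matrix}{Numeric matrix, proteins as rows and samples as
#'       columns.}
#'     \item{meta}{Data frame with `sample_id`, `patient_id`,
#'       `tissue_class` (`tumor`, `healthy_tube`, `contralateral_tube`) and
#'       `side`, one row per matrix column in matrix order.}
#'     \item{truth}{Ground truth: per-protein `log_fold_change`, the
#'       patient-effect matrix `patient_effects`, the latent matrix, and
#'       `realized_within_cv` (per-protein, per-patient sample CVs, in
#'       percent).}
#'   }
#' @examples
#' st <- generate_study(study_design(), variance_model(), seed = 1)
#' dim(st$matrix)          # 36 x 102
#' table(st$meta$tissue_class)
#' @export
generate_study <- function(design, variance, effects = effect_model(),
                           seed = 1L) {
  stopifnot(inherits(design, "study_design"),
            inherits(variance, "variance_model"),
            inherits(effects, "effect_model"))
  np <- design$n_proteins
  mu <- .per_protein(variance$baseline_mean, np, "baseline_mean")
  sig_b <- cv_to_sigma(.per_protein(variance$between_patient_cv, np,
                                    "between_patient_cv"))
  sig_w <- cv_to_sigma(.per_protein(variance$within_tumor_cv, np,
                                    "within_tumor_cv"))
  sig_n <- cv_to_sigma(.per_protein(variance$normal_between_individual_cv,
                                    np, "normal_between_individual_cv"))

  unknown <- setdiff(effects$differential_proteins, design$protein_ids)
  if (length(unknown)) {
    stop("generate_study: differential_proteins not in panel: ",
         paste(unknown, collapse = ", "))
  }
  delta <- stats::setNames(numeric(np), design$protein_ids)
  delta[effects$differential_proteins] <- effects$log_fold_change

  set.seed(as.integer(seed))

  pat_ids <- sprintf("P%02d", seq_len(design$n_patients))
  # patient effects: one column per patient, drawn patient by patient
  b <- matrix(0, np, design$n_patients,
              dimnames = list(design$protein_ids, pat_ids))
  for (i in seq_len(design$n_patients)) b[, i] <- stats::rnorm(np) * sig_b

  n_tumor <- sum(design$samples_per_patient)
  tumor_vals <- matrix(NA_real_, np, n_tumor)
  tumor_sample_id <- character(n_tumor)
  tumor_patient <- character(n_tumor)
  col <- 0L
  for (i in seq_len(design$n_patients)) {
    for (j in seq_len(design$samples_per_patient[i])) {
      col <- col + 1L
      w <- stats::rnorm(np) * sig_w
      tumor_vals[, col] <- mu * exp(delta) * exp(b[, i]) * exp(w)
      tumor_sample_id[col] <- sprintf("%s_S%d", pat_ids[i], j)
      tumor_patient[col] <- pat_ids[i]
    }
  }

  normal_block <- function(n, prefix) {
    vals <- matrix(NA_real_, np, n)
    for (i in seq_len(n)) vals[, i] <- mu * exp(stats::rnorm(np) * sig_n)
    list(vals = vals, ids = sprintf("%s%02d", prefix, seq_len(n)))
  }
  hb <- normal_block(design$n_healthy_tubes, "H")
  cb <- normal_block(design$n_contralateral_tubes, "C")

  mat <- cbind(tumor_vals, hb$vals, cb$vals)
  rownames(mat) <- design$protein_ids
  colnames(mat) <- c(tumor_sample_id, hb$ids, cb$ids)

  # bilateral tumors: alternate sides within the first min(10, n) patients
  side <- character(n_tumor)
  col <- 0L
  for (i in seq_len(design$n_patients)) {
    for (j in seq_len(design$samples_per_patient[i])) {
      col <- col + 1L
      side[col] <- if (i <= min(10L, design$n_patients)) {
        if (j %% 2L == 1L) "left" else "right"
      } else "left"
    }
  }
  meta <- data.frame(
    sample_id = colnames(mat),
    patient_id = c(tumor_patient, hb$ids, cb$ids),
    tissue_class = c(rep("tumor", n_tumor),
                     rep("healthy_tube", design$n_healthy_tubes),
                     rep("contralateral_tube", design$n_contralateral_tubes)),
    side = c(side, rep("na", design$n_healthy_tubes),
             rep("right", design$n_contralateral_tubes)),
    stringsAsFactors = FALSE
  )

  realized <- matrix(NA_real_, np, design$n_patients,
                     dimnames = list(design$protein_ids, pat_ids))
  for (i in seq_len(design$n_patients)) {
    cols <- tumor_patient == pat_ids[i]
    if (sum(cols) >= 2) {
      sub <- tumor_vals[, cols, drop = FALSE]
      realized[, i] <- 100 * apply(sub, 1, stats::sd) / rowMeans(sub)
    }
  }

  list(matrix = mat,
       meta = meta,
       truth = list(log_fold_change = delta,
                    patient_effects = b,
                    latent = mat,
                    realized_within_cv = realized))
}

.per_protein <- function(x, n, what) {
  if (length(x) == 1) return(rep(as.numeric(x), n))
  if (length(x) != n) {
    stop("'", what, "' must be scalar or length n_proteins (", n, ")")
  }
  as.numeric(x)
}

#' Generate spot-level dilution-series data from an expression matrix
#'
#' Realizes each (protein, sample) expression value as a serial-dilution
#' spot series: for every dilution fraction d and replicate, the expected
#' signal is `background_mean + value * d`, perturbed by multiplicative
#' lognormal noise with coefficient of variation `spot_cv` (mean-one noise
#' factor), then clipped at `saturation_level` when set. Buffer blanks
#' (recorded with `dilution_fraction = 0`) have expected signal equal to
#' the background alone. Under the default noise model each (protein,
#' sample) yields 12 spot records: 5 dilution steps in duplicate plus 2
#' buffer blanks.
#'
#' A per-sample total-protein stain signal is emitted alongside. With
#' `total_reference = "sum"` it is proportional to the column sum of the
#' latent matrix (unequal protein loading across samples); with
#' `"constant"` every sample receives the same total, emulating lysates
#' adjusted to equal protein concentration before printing. Total signals
#' get multiplicative noise with CV `total_cv`.
#'
#' Noise factors are drawn column-major over the (dilution x replicate x
#' protein x sample) grid, then blanks, then totals; the order is fixed so
#' a seed pins the output exactly.
#'
#' @param mat Numeric expression matrix (proteins x samples), non-negative.
#' @param noise A [spot_noise_model()].
#' @param seed Integer seed.
#' @param total_reference `"sum"` or `"constant"` (see Details).
#' @param total_scale Proportionality constant for the total-protein signal.
#' @return A list with `spots` (data frame: `protein`, `sample_id`,
#'   `dilution_fraction`, `replicate`, `signal`) and `totals` (data frame:
#'   `sample_id`, `total_signal`).
#' @export
generate_spot_data <- function(mat, noise = spot_noise_model(), seed = 1L,
                               total_reference = c("sum", "constant"),
                               total_scale = 1) {
  stopifnot(is.matrix(mat), inherits(noise, "spot_noise_model"))
  total_reference <- match.arg(total_reference)
  if (any(mat < 0, na.rm = TRUE)) {
    stop("generate_spot_data: expression values must be non-negative")
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("generate_spot_data: matrix needs protein rownames and sample ",
         "colnames")
  }
  set.seed(as.integer(seed))

  dil <- noise$dilution_fractions
  nrep <- noise$n_replicates
  sig <- cv_to_sigma(noise$spot_cv)
  noise_factor <- function(n, s) {
    if (s == 0) rep(1, n) else exp(stats::rnorm(n) * s - s^2 / 2)
  }

  grid <- expand.grid(dilution_fraction = dil,
                      replicate = seq_len(nrep),
                      protein = rownames(mat),
                      sample_id = colnames(mat),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  value <- mat[cbind(grid$protein, grid$sample_id)]
  expected <- noise$background_mean + value * grid$dilution_fraction
  signal <- expected * noise_factor(nrow(grid), sig)

  if (noise$include_buffer_blank) {
    bgrid <- expand.grid(dilution_fraction = 0,
                         replicate = seq_len(nrep),
                         protein = rownames(mat),
                         sample_id = colnames(mat),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    bsignal <- noise$background_mean * noise_factor(nrow(bgrid), sig)
    grid <- rbind(grid, bgrid)
    signal <- c(signal, bsignal)
  }
  if (!is.null(noise$saturation_level)) {
    signal <- pmin(signal, noise$saturation_level)
  }
  spots <- data.frame(protein = grid$protein,
                      sample_id = grid$sample_id,
                      dilution_fraction = grid$dilution_fraction,
                      replicate = grid$replicate,
                      signal = signal,
                      stringsAsFactors = FALSE)
  ord <- order(match(spots$sample_id, colnames(mat)),
               match(spots$protein, rownames(mat)),
               -spots$dilution_fraction, spots$replicate)
  spots <- spots[ord, , drop = FALSE]
  rownames(spots) <- NULL

  base_total <- switch(total_reference,
                       sum = colSums(mat, na.rm = TRUE),
                       constant = rep(1, ncol(mat)))
  tsig <- cv_to_sigma(noise$total_cv)
  totals <- data.frame(
    sample_id = colnames(mat),
    total_signal = unname(total_scale * base_total *
                            noise_factor(ncol(mat), tsig)),
    stringsAsFactors = FALSE
  )
  list(spots = spots, totals = totals)
}
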