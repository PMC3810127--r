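make_de_df <- function(protein, analysis, p, dir) {
  data.frame(protein = protein, analysis = analysis, p_value = p,
             direction = dir, significant = !is.na(p) & p <= 0.05,
             stringsAsFactors = FALSE)
}

test_that("a strong effect with tiny variance is called up by the mean analysis", {
  d <- study_design(n_patients = 5, samples_per_patient = rep(4, 5),
                    n_healthy_tubes = 4, n_contralateral_tubes = 2,
                    n_proteins = 3)
  v <- variance_model(between_patient_cv = 0.02, within_tumor_cv = 0.02,
                      normal_between_individual_cv = 0.02)
  st <- generate_study(d, v, effect_model("protein_02", 1.5), seed = 12)
  res <- mean_based_de(st$matrix, st$meta)
  hit <- res[res$protein == "protein_02", ]
  expect_true(hit$significant)
  expect_equal(hit$direction, "up")
  miss <- res[res$protein != "protein_02", ]
  expect_false(any(miss$significant))
})

test_that("identical tumor and normal values give p = 1 and no direction", {
  mat <- matrix(rep(c(1, 2, 3, 4, 5, 6), each = 2), 2, 6, byrow = FALSE)
  mat <- rbind(A = c(1, 2, 3, 1, 2, 3))
  colnames(mat) <- c("P1_S1", "P2_S1", "P3_S1", "H1", "H2", "H3")
  meta <- data.frame(sample_id = colnames(mat),
                     patient_id = c("P1", "P2", "P3", "H1", "H2", "H3"),
                     tissue_class = c(rep("tumor", 3),
                                      rep("healthy_tube", 3)),
                     side = "na")
  res <- mean_based_de(mat, meta)
  expect_equal(res$p_value, 1)
  expect_true(is.na(res$direction))
})

test_that("without within-tumor heterogeneity every repetition is identical", {
  d <- study_design(n_patients = 6, samples_per_patient = rep(4, 6),
                    n_healthy_tubes = 5, n_contralateral_tubes = 0,
                    n_proteins = 4)
  v <- variance_model(between_patient_cv = 0.3, within_tumor_cv = 0)
  st <- generate_study(d, v, effect_model("protein_01", 0.8), seed = 13)
  sres <- single_sample_de(st$matrix, st$meta, n_repetitions = 3, seed = 5)
  byrep <- split(sres$p_value, sres$analysis)
  expect_equal(byrep$single_1, byrep$single_2)
  expect_equal(byrep$single_1, byrep$single_3)
  # and they match the mean-based calls (no sampling effect to exploit)
  mres <- mean_based_de(st$matrix, st$meta)
  expect_equal(mres$significant,
               sres$significant[sres$analysis == "single_1"])
})

test_that("single-sample selections are seed-reproducible and reuse-free", {
  st <- generate_study(study_design(), variance_model(), seed = 14)
  a <- single_sample_de(st$matrix, st$meta, seed = 99)
  b <- single_sample_de(st$matrix, st$meta, seed = 99)
  expect_identical(a, b)
  sel <- attr(a, "selections")
  expect_equal(dim(sel), c(13, 3))
  expect_true(all(apply(sel, 1, anyDuplicated) == 0))  # no reuse
  c2 <- single_sample_de(st$matrix, st$meta, seed = 100)
  expect_false(identical(attr(c2, "selections"), sel))
})

test_that("requesting more repetitions than samples demands reuse mode", {
  d <- study_design(n_patients = 3, samples_per_patient = c(2, 2, 2),
                    n_healthy_tubes = 3, n_contralateral_tubes = 0,
                    n_proteins = 3)
  st <- generate_study(d, variance_model(), seed = 15)
  expect_error(single_sample_de(st$matrix, st$meta, n_repetitions = 3,
                                seed = 1),
               "reuse = TRUE")
  res <- single_sample_de(st$matrix, st$meta, n_repetitions = 3, seed = 1,
                          reuse = TRUE)
  expect_equal(length(unique(res$analysis)), 3)
})

test_that("concordance categories follow the documented precedence", {
  mres <- make_de_df(letters[1:6], "mean",
                     c(0.01, 0.01, NA, 0.01, NA, 0.20),
                     c("up", "down", NA, "up", NA, "up"))
  sres <- rbind(
    make_de_df(letters[1:6], "single_1",
               c(0.02, NA, 0.01, 0.03, NA, NA),
               c("up", NA, "up", "down", NA, NA)),
    make_de_df(letters[1:6], "single_2",
               c(0.04, NA, NA, NA, NA, NA),
               c("up", NA, NA, NA, NA, NA)))
  rep <- classify_concordance(mres, sres, alpha = 0.05)
  got <- setNames(rep$per_protein$category, rep$per_protein$protein)
  expect_equal(unname(got[c("a", "b", "c", "d", "e", "f")]),
               c("all_four", "mean_only_strict", "singles_only", "partial",
                 "none", "none"))
  expect_equal(sum(rep$counts), 6)  # categories partition the panel
  # d is significant by mean (up) and single_1 (down): direction conflict
  expect_true(rep$per_protein$direction_conflict[
    rep$per_protein$protein == "d"])
  expect_false(any(rep$per_protein$direction_conflict[
    rep$per_protein$protein != "d"]))
  expect_equal(rep$n_mean_missed_by_all_singles, 1)  # b
  expect_equal(rep$n_mean_missed_by_any_single, 2)   # b and d
  expect_error(classify_concordance(mres[-1, ], sres), "different")
})

test_that("all-null inputs land every protein in 'none'", {
  mres <- make_de_df(letters[1:4], "mean", rep(1, 4), rep(NA, 4))
  sres <- make_de_df(letters[1:4], "single_1", rep(1, 4), rep(NA, 4))
  rep <- classify_concordance(mres, sres)
  expect_equal(unname(rep$counts["none"]), 4)
})

test_that("the full experiment is deterministic and finds planted effects", {
  d <- study_design()
  v <- variance_model(within_tumor_cv = 0.15)
  eff <- effect_model(sprintf("protein_%02d", 1:6), log(3))
  st <- generate_study(d, v, eff, seed = 16)
  a <- run_sampling_bias_experiment(st$matrix, st$meta, seed = 17)
  b <- run_sampling_bias_experiment(st$matrix, st$meta, seed = 17)
  expect_identical(a$results, b$results)
  got <- a$concordance$per_protein
  planted <- got$category[got$protein %in% eff$differential_proteins]
  expect_true(all(planted == "all_four"))
})

test_that("degenerate designs propagate the Mann-Whitney preconditions", {
  mat <- matrix(1:4, 1, 4,
                dimnames = list("A", c("P1_S1", "P1_S2", "H1", "H2")))
  meta <- data.frame(sample_id = colnames(mat),
                     patient_id = c("P1", "P1", "H1", "H2"),
                     tissue_class = c("tumor", "tumor", "healthy_tube",
                                      "healthy_tube"),
                     side = "na")
  expect_error(mean_based_de(mat, meta), ">= 2 tumor patients")
})
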