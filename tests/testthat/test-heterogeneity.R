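test_that("cv matches the hand-checked definition and is scale-free", {
  expect_equal(cv(c(5, 5, 5)), 0)
  expect_equal(cv(c(1, 2, 3)), 50)  # sd = 1 (n-1 denominator), mean = 2
  set.seed(1)
  x <- runif(10, 1, 5)
  for (c_scale in c(0.1, 3, 100)) expect_equal(cv(c_scale * x), cv(x))
  expect_error(cv(5), "at least 2")
  expect_error(cv(c(-3, 1)), "mean must be positive")
  expect_error(cv(c(1, NA)), "finite")
})

test_that("rms_average is the quadratic mean and dominates the mean", {
  expect_equal(rms_average(c(25, 25, 25)), 25)
  expect_equal(rms_average(c(3, 4)), sqrt(12.5))
  expect_error(rms_average(numeric(0)), "empty")
  set.seed(2)
  for (i in 1:20) {
    v <- runif(sample(2:10, 1), 0, 60)
    r <- rms_average(v)
    expect_gte(r, mean(v))
    expect_gte(r, min(v)); expect_lte(r, max(v))
  }
  expect_gt(rms_average(c(10, 30)), mean(c(10, 30)))  # strict when unequal
})

test_that("intratumoral CVs group by patient and respect tissue class", {
  ts <- toy_study()
  recs <- intratumoral_cvs(ts$matrix, ts$meta)
  expect_equal(recs$cv_percent[recs$protein == "A" &
                                 recs$patient_id == "P01"], 50)
  expect_equal(nrow(recs), 6)  # 3 proteins x 2 patients
  # normal-tissue samples never enter the intratumoral CVs
  mat2 <- cbind(ts$matrix, H99 = c(1000, 1000, 1000))
  meta2 <- rbind(ts$meta, data.frame(sample_id = "H99", patient_id = "H99",
                                     tissue_class = "healthy_tube",
                                     side = "na"))
  expect_equal(intratumoral_cvs(mat2, meta2)$cv_percent, recs$cv_percent)
})

test_that("patients with fewer than two usable values are skipped and logged", {
  ts <- toy_study()
  mat <- ts$matrix
  mat["A", c("P02_S1", "P02_S2")] <- NA  # one usable P02 value left
  expect_message(recs <- intratumoral_cvs(mat, ts$meta), "skipped 1")
  sk <- attr(recs, "skipped")
  expect_equal(sk$protein, "A")
  expect_equal(sk$patient_id, "P02")
  expect_false(any(recs$protein == "A" & recs$patient_id == "P02"))
})

test_that("inter-patient CV reduces to cv() of per-patient means", {
  ts <- toy_study()
  inter <- interpatient_cv(ts$matrix, ts$meta, "tumor")
  expect_equal(inter$cv_percent[inter$protein == "A"],
               cv(c(mean(c(1, 2, 3)), mean(c(4, 5, 6)))))
  # identical patients give zero
  mat <- rbind(A = c(2, 3, 2, 3), B = c(5, 7, 5, 7), C = 1:4)
  colnames(mat) <- c("P1_S1", "P1_S2", "P2_S1", "P2_S2")
  meta <- data.frame(sample_id = colnames(mat),
                     patient_id = c("P1", "P1", "P2", "P2"),
                     tissue_class = "tumor", side = "left")
  out <- interpatient_cv(mat, meta)
  expect_equal(out$cv_percent[out$protein == "A"], 0)
  expect_error(interpatient_cv(ts$matrix, ts$meta, "contralateral_tube"),
               ">= 2")
})

test_that("inter-patient CV recovers the between-patient component", {
  d <- study_design(n_patients = 200, samples_per_patient = rep(5, 200),
                    n_healthy_tubes = 0, n_contralateral_tubes = 0,
                    n_proteins = 4)
  v <- variance_model(between_patient_cv = 0.21, within_tumor_cv = 0)
  st <- generate_study(d, v, seed = 31)
  inter <- interpatient_cv(st$matrix, st$meta)
  expect_equal(mean(inter$cv_percent), 21, tolerance = 0.08)
})

test_that("group summaries average per-protein CVs with ranges", {
  per <- data.frame(protein = c("a", "b"),
                    rms_cv_percent = c(17, 53),
                    interpatient_cv_percent = c(12, 48))
  gs <- group_summary(per, c(a = TRUE, b = FALSE))
  ov <- gs[gs$group == "overall" & gs$metric == "rms_cv_percent", ]
  expect_equal(ov$mean_cv, 35)
  expect_equal(c(ov$min_cv, ov$max_cv), c(17, 53))
  ph <- gs[gs$group == "phospho" & gs$metric == "rms_cv_percent", ]
  expect_equal(ph$mean_cv, 17)
  # an empty group is absent, not zero
  gs2 <- group_summary(per, c(a = TRUE, b = TRUE))
  expect_false("non_phospho" %in% gs2$group)
})

test_that("Friedman test matches the hand formula on a clean design", {
  # ranks (1,2,3) in every block: statistic 6, p = exp(-3)
  recs <- data.frame(protein = rep(c("a", "b", "c"), 3),
                     patient_id = rep(c("p1", "p2", "p3"), each = 3),
                     cv_percent = c(1, 2, 3, 4, 5, 6, 7, 8, 9))
  res <- friedman_cv_test(recs)
  expect_equal(res$statistic, 6)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, exp(-3), tolerance = 1e-10)
})

test_that("Friedman statistic agrees with brute force on all 3x3 rank layouts", {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  for (i in seq_along(perms)) for (j in seq_along(perms)) {
    for (l in seq_along(perms)) {
      m <- rbind(perms[[i]], perms[[j]], perms[[l]])
      recs <- data.frame(protein = rep(c("a", "b", "c"), 3),
                         patient_id = rep(c("p1", "p2", "p3"), each = 3),
                         cv_percent = as.vector(t(m)))
      expect_equal(friedman_cv_test(recs)$statistic,
                   oracle_friedman_stat(m))
    }
  }
})

test_that("fully tied blocks give a null Friedman result; incomplete blocks drop", {
  recs <- data.frame(protein = rep(c("a", "b"), 3),
                     patient_id = rep(c("p1", "p2", "p3"), each = 2),
                     cv_percent = rep(c(4, 9, 2), each = 2))
  res <- friedman_cv_test(recs)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  recs2 <- data.frame(protein = c("a", "b", "a", "b", "a"),
                      patient_id = c("p1", "p1", "p2", "p2", "p3"),
                      cv_percent = c(1, 2, 3, 4, 5))
  expect_message(res2 <- friedman_cv_test(recs2), "dropped 1")
  expect_equal(res2$n_blocks, 2)
  expect_equal(res2$n_blocks_dropped, 1)
  expect_error(friedman_cv_test(recs2[recs2$patient_id == "p1", ]),
               ">= 2")
})

test_that("Mann-Whitney exact p equals full enumeration on small samples", {
  res <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(res$method, "exact")

  set.seed(4)
  for (i in 1:10) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    repeat {
      x <- round(runif(nx, 0, 100), 3); y <- round(runif(ny, 0, 100), 3)
      if (!anyDuplicated(c(x, y))) break
    }
    expect_equal(mann_whitney(x, y)$p_value, oracle_mw_exact(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney handles ties and identical groups sensibly", {
  res <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$p_value, 1)
  expect_match(res$method, "approximation")
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
  # large samples switch to the normal approximation
  expect_match(mann_whitney(1:10 + 0.5, 2:12)$method, "approximation")
})

test_that("boxplot_stats follows the interpolated-quartile convention", {
  bs <- boxplot_stats(c(1, 2, 3, 4, 100))
  expect_equal(bs$median, 3)
  expect_equal(bs$q25, 2)
  expect_equal(bs$q75, 4)
  expect_equal(bs$whisker_high, 4)  # fence = 4 + 1.5 * 2 = 7
  expect_equal(bs$whisker_low, 1)
  expect_equal(bs$outliers, 100)

  const <- boxplot_stats(rep(7, 4))
  expect_equal(unlist(const[1:5]), rep(7, 5), ignore_attr = TRUE)
  expect_length(const$outliers, 0)

  expect_equal(boxplot_stats(-3:3)$median, 0)
})

test_that("all CV statistics are invariant under global matrix rescaling", {
  ts <- toy_study()
  a <- heterogeneity_table(ts$matrix, ts$meta)
  b <- heterogeneity_table(ts$matrix * 37.5, ts$meta)
  expect_equal(a$per_protein, b$per_protein)
})
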