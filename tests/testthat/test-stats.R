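test_that("shapiro_wilk validates and behaves on reference samples", {
  n <- 20
  scores <- qnorm((1:n - 3 / 8) / (n + 1 / 4))  # exact normal quantiles
  r <- shapiro_wilk(scores)
  expect_gt(r$W, 0.99)
  expect_true(r$p >= 0 && r$p <= 1)

  set.seed(1)
  bimodal <- c(rnorm(25, -5, 0.5), rnorm(25, 5, 0.5))
  expect_lt(shapiro_wilk(bimodal)$p, 0.05)

  expect_error(shapiro_wilk(rep(1, 10)), "variance")
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
})

test_that("paired_t handles degenerate pairs and swaps antisymmetrically", {
  x <- c(3.2, 4.1, 5.0, 2.7, 6.1)
  same <- paired_t(x, x)
  expect_equal(same$mean_diff, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)

  shifted <- paired_t(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(shifted$mean_diff, 1)
  expect_true(shifted$degenerate)

  set.seed(7)
  y <- x + rnorm(5, 1, 0.5)
  a <- paired_t(x, y)
  b <- paired_t(y, x)
  expect_equal(a$mean_diff, -b$mean_diff)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  expect_equal(a$cohens_d, mean(y - x) / sd(y - x))
  expect_error(paired_t(x, x[1:3]), "equal length")
})

test_that("paired_t power matches the closed-form oracle at n = 18", {
  # oracle: power.t.test gives 0.893 for delta = 1, sd = 1, alpha = 0.01;
  # the observed Monte-Carlo rate must sit inside its 3-sigma binomial band
  pow <- power.t.test(n = 18, delta = 1, sd = 1, sig.level = 0.01,
                      type = "one.sample")$power
  hits <- sapply(1:200, function(s) {
    set.seed(s)
    x0 <- rnorm(18, 10, 2)
    x1 <- x0 + rnorm(18, 1, 1)
    paired_t(x0, x1)$p < 0.01
  })
  band <- 3 * sqrt(pow * (1 - pow) / 200)
  expect_lt(abs(mean(hits) - pow), band + 1e-9)
})

test_that("fit_lmm is exact on deterministic cohorts and balanced designs", {
  sp <- cohort_spec(n_patients = 6,
                    slab_means_um = c(SCP = 13, DCP = 15, CC = 19),
                    patient_sd_um = 0, residual_sd_um = 0,
                    phenotype_rates = c(rpd = 0), phenotype_effects_um = list())
  tb <- simulate_cohort(sp, seed = 1)
  r <- fit_lmm(tb)
  expect_true(r$boundary)
  expect_equal(r$emm$estimate[r$emm$slab == "SCP"], 13)
  expect_equal(r$emm$estimate[r$emm$slab == "CC"], 19)
  expect_equal(r$var_patient, 0)

  sp2 <- cohort_spec(n_patients = 18,
                     slab_means_um = c(SCP = 13, DCP = 15, CC = 19),
                     patient_sd_um = 5, residual_sd_um = 3,
                     phenotype_rates = c(rpd = 0), phenotype_effects_um = list())
  tb2 <- simulate_cohort(sp2, seed = 42)
  r2 <- fit_lmm(tb2)
  raw <- tapply(tb2$displacement_um, tb2$slab, mean)
  for (s in c("CC", "DCP", "SCP"))
    expect_equal(r2$emm$estimate[r2$emm$slab == s], unname(raw[s]),
                 tolerance = 1e-8)
  expect_true(all(r2$emm$ci_lo < r2$emm$estimate &
                  r2$emm$estimate < r2$emm$ci_hi))
  expect_gte(r2$var_patient, 0)
  expect_error(fit_lmm(tb2[tb2$patient_id == "P01", ]), "2 patients")
})

test_that("classify_max_slab uses the stated tie-break order", {
  mk <- function(eye, scp, dcp, cc) data.frame(
    patient_id = eye, eye_id = eye, slab = c("SCP", "DCP", "CC"),
    roi = "whole", displacement_um = c(scp, dcp, cc),
    rpd = FALSE, dped = FALSE, drusen = FALSE, irora = FALSE)
  tb <- rbind(mk("E1", 10, 20, 15), mk("E2", 5, 18, 18), mk("E3", 9, 8, 7))
  cl <- classify_max_slab(tb)
  expect_equal(cl$max_slab[cl$eye_id == "E1"], "DCP")
  expect_equal(cl$max_slab[cl$eye_id == "E2"], "CC")  # tie -> CC first
  expect_true(cl$tie[cl$eye_id == "E2"])
  expect_equal(cl$max_slab[cl$eye_id == "E3"], "SCP")

  expect_warning(classify_max_slab(tb[tb$slab != "CC" | tb$eye_id != "E3", ]),
                 "missing")
})

test_that("a strong DCP shift dominates the per-eye classification", {
  sp <- cohort_spec(n_patients = 40,
                    slab_means_um = c(SCP = 12, DCP = 21, CC = 12),
                    patient_sd_um = 5, residual_sd_um = 3,
                    phenotype_rates = c(rpd = 0), phenotype_effects_um = list())
  tb <- simulate_cohort(sp, seed = 3)
  cl <- classify_max_slab(tb)
  expect_gt(mean(cl$max_slab == "DCP"), 0.9)
})

test_that("phenotype_association reports exact printed-style proportions", {
  labels <- c(rep("DCP", 9), rep("CC", 3), rep("mild", 6))
  flags <- c(rep(TRUE, 6), rep(FALSE, 3),  # 6/9 DCP
             rep(FALSE, 9))                # CC and mild eyes unflagged
  a <- phenotype_association(labels, flags)
  dcp <- a$strata[a$strata$label == "DCP", ]
  expect_equal(dcp$pct, 66.7)
  expect_equal(dcp$k, 6)
  expect_true(dcp$fisher_p >= 0 && dcp$fisher_p <= 1)
  expect_equal(a$strata$pct[a$strata$label == "mild"], 0.0)

  # invariance to row order; strata counts sum to the total
  perm <- sample(length(labels))
  b <- phenotype_association(labels[perm], flags[perm])
  expect_equal(a$strata, b$strata)
  expect_equal(sum(a$strata$n), length(labels))
})

test_that("group comparison returns Welch results on simulated cohorts", {
  sp <- cohort_spec(n_patients = 24,
                    slab_means_um = c(SCP = 13, DCP = 14, CC = 19),
                    patient_sd_um = 3, residual_sd_um = 2,
                    phenotype_rates = c(rpd = 0.5),
                    phenotype_effects_um = list(rpd = c(DCP = 8)))
  tb <- simulate_cohort(sp, seed = 5)
  r <- compare_group_displacement(tb, "DCP", "rpd")
  expect_gt(r$mean_flag, r$mean_noflag)
  expect_lt(r$p, 0.05)
})
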