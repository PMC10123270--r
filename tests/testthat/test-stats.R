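# Statistical pipeline: derived variables, correlation, agreement, and the
# linear models.

test_that("derived columns follow the decomposition record by record", {
  tab <- compute_derived(toy_cohort())
  expect_equal(round(tab$al_morgan_mm[1], 2), 26.26)
  expect_equal(round(tab$al_emmetropia_mm[1], 2), 23.64)
  expect_equal(round(tab$delta_al_mm[1], 2), 2.37)
  # SER = 0 record: the Morgan estimate equals the emmetropic length.
  expect_equal(tab$al_morgan_mm[2], tab$al_emmetropia_mm[2])
  expect_equal(tab$delta_al_mm, tab$al_mm - tab$al_emmetropia_mm)
  # Idempotent recomputation.
  expect_identical(compute_derived(tab), tab)
  # Empty table stays empty with the derived schema.
  empty <- compute_derived(empty_cohort(derived = FALSE))
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("al_morgan_mm", "al_emmetropia_mm", "delta_al_mm")
                  %in% names(empty)))
})

test_that("derived-variable domain errors carry the record id", {
  tab <- toy_cohort()
  tab$ser_d[3] <- -80
  expect_error(compute_derived(tab), "A3")
})

test_that("pearson_with_t matches the brute-force definition and identity", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  ct <- pearson_with_t(x, y)
  expect_equal(ct$r, pearson_oracle(x, y), tolerance = 1e-12)
  expect_equal(ct$t, ct$r * sqrt(ct$df) / sqrt(1 - ct$r^2))
  expect_identical(ct$df, length(x) - 2L)
  # Cross-check p-value against the standard implementation.
  ref <- cor.test(x, y)
  expect_equal(ct$p, ref$p.value, tolerance = 1e-12)
  # Perfect and reversed association.
  expect_equal(pearson_with_t(x, x * 2 + 1)$r, 1)
  expect_equal(pearson_with_t(x, rev(x))$r, -1)
  expect_error(pearson_with_t(x, rep(1, 5)), "constant")
  expect_error(pearson_with_t(x, 1:4), "equal length")
})

test_that("t-r identity holds across generated correlation results", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    ct <- pearson_with_t(x, y)
    expect_equal(ct$t, ct$r * sqrt(n - 2) / sqrt(1 - ct$r^2),
                 tolerance = 1e-12)
  }
})

test_that("Bland-Altman limits follow the bias and SD exactly", {
  # From printed agreement values: bias magnitude 0.31, SD 0.61, with the
  # estimate running larger than the measurement.
  d <- c(-0.31 - 0.61, -0.31, -0.31 + 0.61)
  ba <- bland_altman(d, rep(0, 3))
  expect_equal(ba$bias, -0.31)
  expect_equal(ba$sd_diff, 0.61)
  expect_equal(round(ba$loa_low, 2), -1.51)
  expect_equal(round(ba$loa_high, 2), 0.89)

  ba2 <- bland_altman(c(1, 2, 3, 4), c(1.1, 2.1, 2.9, 4.1))
  expect_equal(ba2$bias, -0.05)
  expect_equal(ba2$sd_diff, 0.10)
  expect_equal(ba2$loa_low, -0.246)
  expect_equal(ba2$loa_high, 0.146)

  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(same$bias, same$loa_low, same$loa_high), c(0, 0, 0))
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("swapping the Bland-Altman direction negates bias and mirrors
           limits", {
  set.seed(5)
  a <- rnorm(40, 25, 1)
  b <- a + rnorm(40, 0.3, 0.5)
  fwd <- bland_altman(a, b)
  rev <- bland_altman(b, a)
  expect_equal(rev$bias, -fwd$bias)
  expect_equal(rev$loa_low, -fwd$loa_high)
  expect_equal(rev$loa_high, -fwd$loa_low)
  expect_equal(rev$sd_diff, fwd$sd_diff)
  expect_identical(fwd$direction, "measured - estimate")
})

test_that("the linear-model wrapper agrees with the normal equations", {
  tab <- compute_derived(toy_cohort())
  fit <- fit_linear_model(tab, "al_mm", c("ssi", "age", "gender", "cct_um"))
  # Gender expands to a trailing male indicator in the model frame.
  X <- cbind(1, tab$ssi, tab$age, tab$cct_um,
             as.integer(tab$gender == "male"))
  expect_equal(unname(fit$coefficients$estimate),
               unname(ols_oracle(X, tab$al_mm)), tolerance = 1e-10)
  expect_identical(fit$n, nrow(tab))
  # CI invariant: estimate +/- t_crit * SE with df = n - p.
  tcrit <- qt(0.975, fit$n - nrow(fit$coefficients))
  expect_equal(fit$coefficients$ci_low,
               fit$coefficients$estimate - tcrit * fit$coefficients$se)
  expect_equal(fit$coefficients$ci_high,
               fit$coefficients$estimate + tcrit * fit$coefficients$se)
})

test_that("an exact line is fitted with zero residuals", {
  tab <- toy_cohort()[1:3, ]
  tab$al_mm <- 2 * tab$ssi + 1
  fit <- suppressWarnings(fit_linear_model(tab, "al_mm", "ssi"))
  expect_equal(unname(fit$coefficients$estimate), c(1, 2), tolerance = 1e-12)
  expect_equal(unname(residuals(fit$fit)), rep(0, 3), tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
})

test_that("rank-deficient designs are refused with the collinear term
           named", {
  tab <- compute_derived(toy_cohort())
  tab$ssi2 <- tab$ssi
  expect_error(fit_linear_model(tab, "al_mm", c("ssi", "ssi2")), "ssi2")
})

test_that("significance stars follow the three-level legend", {
  expect_identical(axelong:::signif_stars(c(0.0005, 0.005, 0.03, 0.2)),
                   c("***", "**", "*", ""))
})

test_that("adjusted models are termwise additive across the decomposition", {
  for (tab in list(compute_derived(toy_cohort()), default_cohort(n = 800))) {
    mods <- run_adjusted_models(tab)
    expect_equal(mods$model1$coefficients$estimate,
                 mods$model2$coefficients$estimate +
                   mods$model3$coefficients$estimate,
                 tolerance = 1e-10)
    # Same additivity for the simple regressions on SSI.
    s1 <- fit_linear_model(tab, "al_mm", "ssi")
    s2 <- fit_linear_model(tab, "al_emmetropia_mm", "ssi")
    s3 <- fit_linear_model(tab, "delta_al_mm", "ssi")
    expect_equal(s1$coefficients$estimate,
                 s2$coefficients$estimate + s3$coefficients$estimate,
                 tolerance = 1e-10)
  }
})

test_that("printed adjusted coefficients exhibit the additive structure", {
  # Published three-model table: model 1 rows equal model 2 + model 3.
  expect_equal(0.48 + (-2.49), -2.01)   # SSI
  expect_equal(0.27 + 0.23, 0.50)       # male gender
  expect_equal(-0.00 + 0.07, 0.07)      # age
})

test_that("a noise-free structural cohort gives R^2 = 1 in the component
           models", {
  cfg <- calibrate_generator(generator_config(
    n = 120, seed = 8, ser_noise_sd = 0,
    slope_emm = 0.48, slope_delta = -2.49))
  cfg$emm_resid_sd <- 0
  cfg$delta_resid_sd <- 0
  tab <- generate_cohort(cfg)
  mods <- suppressWarnings(run_adjusted_models(tab))
  expect_equal(mods$model2$r_squared, 1, tolerance = 1e-9)
  expect_equal(mods$model3$r_squared, 1, tolerance = 1e-9)
})

test_that("the long-eye subgroup attenuates the stiffness effect", {
  tab <- default_cohort(n = 5000)
  full <- run_adjusted_models(tab)$model3
  sub <- subgroup_model(tab)
  ssi_full <- full$coefficients$estimate[full$coefficients$term == "ssi"]
  ssi_sub <- sub$coefficients$estimate[sub$coefficients$term == "ssi"]
  expect_true(ssi_sub < 0)
  expect_true(ssi_sub > ssi_full)  # attenuated, i.e. less negative
  expect_identical(sub$n, sum(tab$al_mm >= 26))
  # Threshold below the minimum reproduces the full-cohort model.
  all_in <- subgroup_model(tab, al_threshold = min(tab$al_mm))
  expect_equal(all_in$coefficients$estimate, full$coefficients$estimate,
               tolerance = 1e-12)
  expect_error(subgroup_model(tab, al_threshold = max(tab$al_mm) + 1),
               "0 record")
})

test_that("group summary splits at the documented boundaries", {
  tab <- compute_derived(toy_cohort())
  gs <- group_summary(tab)
  al_hi <- gs[gs$split == "AL" & grepl(">=", gs$group), ]
  expect_identical(al_hi$n, sum(tab$al_mm >= 26))
  ser_lo <- gs[gs$split == "SER" & grepl("<=", gs$group), ]
  expect_identical(ser_lo$n, sum(tab$ser_d <= -6))  # boundary is severe
  expect_equal(sum(gs$n[gs$split == "AL"]), nrow(tab))

  # All short eyes: the long-eye group is absent, not zero-filled.
  short <- tab[tab$al_mm < 26, ]
  gs2 <- group_summary(short)
  expect_false(any(grepl(">=", gs2$group[gs2$split == "AL"])))

  # Single record lands in exactly one group per split.
  one <- group_summary(tab[1, ])
  expect_identical(one$n, c(1L, 1L))
  expect_equal(one$mean_delta_al, rep(tab$delta_al_mm[1], 2))
})

test_that("longer eyes owe their length mostly to the axial increment", {
  tab <- default_cohort(n = 5000)
  gs <- group_summary(tab)
  al <- gs[gs$split == "AL", ]
  expect_true(al$mean_delta_al[grepl(">=", al$group)] >
                al$mean_delta_al[!grepl(">=", al$group)])
})

test_that("descriptive table uses clinical mean (SD) formatting", {
  tab <- compute_derived(toy_cohort())
  dt <- descriptive_table(tab)
  expect_identical(attr(dt, "n"), nrow(tab))
  age_row <- dt[dt$characteristic == "Age, years", ]
  expect_identical(age_row$formatted,
                   sprintf("%.0f (%.0f)", mean(tab$age), sd(tab$age)))
  al_row <- dt[dt$characteristic == "AL, mm", ]
  expect_identical(al_row$formatted,
                   sprintf("%.2f (%.2f)", mean(tab$al_mm), sd(tab$al_mm)))
  # Gender percentage convention: 145 of 267 formats as 54%.
  g <- rep(c("female", "male"), c(145, 122))
  tab267 <- tab[rep(1, 267), ]
  tab267$gender <- g
  dt267 <- descriptive_table(tab267)
  expect_identical(dt267$formatted[dt267$characteristic == "Gender: female"],
                   "145 (54%)")
  # Single record: SD reported as 0.
  one <- descriptive_table(tab[1, ])
  expect_identical(one$formatted[one$characteristic == "SSI"], "0.82 (0.00)")
  expect_error(descriptive_table(empty_cohort()), "empty")
})

test_that("synthetic cohorts reproduce the qualitative correlation
           structure", {
  tab <- default_cohort(n = 5000)
  expect_gte(pearson_with_t(tab$al_mm, tab$al_morgan_mm)$r, 0.85)
  expect_lte(pearson_with_t(tab$ser_d, tab$delta_al_mm)$r, -0.85)
})
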