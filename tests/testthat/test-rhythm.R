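study_zt <- rep(c(2, 6, 10, 14, 22), each = 3)

test_that("noiseless cosine recovers mesor, amplitude, acrophase exactly", {
  y <- 5 + 2 * cos(2 * pi * (study_zt - 6) / 24)
  fit <- fit_cosinor(y, study_zt)
  expect_equal(fit$mesor, 5, tolerance = 1e-10)
  expect_equal(fit$amplitude, 2, tolerance = 1e-10)
  expect_equal(fit$acrophase, 6, tolerance = 1e-10)
  expect_lt(fit$p_value, 1e-12)
  expect_true(fit$defined)
})

test_that("degenerate series follow the stated rules", {
  const <- fit_cosinor(rep(3, 15), study_zt)
  expect_equal(const$amplitude, 0)
  expect_equal(const$p_value, 1)
  expect_true(const$defined)

  few <- fit_cosinor(c(1, 2, 3), c(2, 6, 10))
  expect_false(few$defined)

  two_times <- fit_cosinor(c(1, 2, 3, 4, 2, 3), rep(c(2, 14), 3))
  expect_false(two_times$defined)  # rank-deficient: 2 distinct times
})

test_that("fit is invariant to additive shifts and equivariant in time", {
  set.seed(42)
  y <- 4 + 1.5 * cos(2 * pi * (study_zt - 9) / 24) + rnorm(15, 0, 0.3)
  f0 <- fit_cosinor(y, study_zt)
  fc <- fit_cosinor(y + 7, study_zt)
  expect_equal(fc$mesor, f0$mesor + 7)
  expect_equal(fc$amplitude, f0$amplitude)
  expect_equal(fc$acrophase, f0$acrophase)
  expect_equal(fc$p_value, f0$p_value)

  fs <- fit_cosinor(y, (study_zt + 5) %% 24)
  expect_equal(fs$acrophase, (f0$acrophase + 5) %% 24, tolerance = 1e-8)
  expect_equal(fs$amplitude, f0$amplitude)
  expect_equal(fs$p_value, f0$p_value)
})

test_that("double-plotting doubles observations but not point estimates", {
  set.seed(7)
  y <- matrix(3 + 2 * cos(2 * pi * (study_zt - 4) / 24) + rnorm(15, 0, 0.4),
              nrow = 1)
  dp <- double_plot(y, study_zt)
  expect_equal(ncol(dp$values), 30)
  expect_equal(dp$zt[16:30], study_zt + 24)

  f1 <- fit_cosinor(y[1, ], study_zt)
  f2 <- fit_cosinor(dp$values[1, ], dp$zt)
  expect_equal(f2$mesor, f1$mesor, tolerance = 1e-10)
  expect_equal(f2$amplitude, f1$amplitude, tolerance = 1e-10)
  expect_equal(f2$acrophase, f1$acrophase, tolerance = 1e-10)
  expect_lt(f2$p_value, f1$p_value)  # deflation, hence off by default
})

test_that("linear fit agrees with the phase-grid oracle on noisy genes", {
  set.seed(101)
  n_genes <- 60
  phases <- runif(n_genes, 0, 24)
  devs <- errs <- numeric(n_genes)
  for (i in seq_len(n_genes)) {
    y <- 6 + 2 * cos(2 * pi * (study_zt - phases[i]) / 24) +
      rnorm(15, 0, 2 / 3)  # amplitude/noise ratio 3
    fit <- fit_cosinor(y, study_zt)
    orc <- oracle_cosinor_grid(y, study_zt)
    devs[i] <- abs(circular_difference(fit$acrophase, orc[["phase"]]))
    errs[i] <- abs(circular_difference(fit$acrophase, phases[i]))
  }
  expect_lt(max(devs), 0.2)   # oracle equivalence per gene
  expect_lt(mean(errs), 1)    # circular MAE against planted phases
})

test_that("fit_all adjusts per family, logs exclusions, flags rhythmic", {
  d <- build_design()
  cfg <- sim_config(n_genes = 150, frac_rhythmic = 0.5, frac_responsive = 0,
                    seed = 5)
  truth <- generate_truth(cfg)
  sim <- simulate_mrna(truth, d, cfg)
  vals <- log2_transform(sim$fpkm)
  vals[3, d$condition == "ML"] <- 2  # constant within ML: A = 0, p = 1
  fits <- fit_all(vals, condition = "ML", design = d)
  expect_true(all(fits$q_value >= fits$p_value))
  expect_s3_class(fits, "data.frame")
  f3 <- fits[fits$feature_id == truth$feature_id[3], ]
  expect_equal(f3$amplitude, 0)
  expect_equal(f3$p_value, 1)
  expect_error(fit_all(vals, condition = "XX", design = d), "XX")

  # planted rhythmic genes at this SNR are overwhelmingly detected
  detected <- fits$rhythmic[match(truth$feature_id[truth$is_rhythmic],
                                  fits$feature_id)]
  expect_gt(mean(detected, na.rm = TRUE), 0.85)
})

test_that("all-constant matrix yields zero rhythmic calls", {
  d <- build_design()
  vals <- matrix(5, 10, 45, dimnames = list(paste0("g", 1:10), d$sample_id))
  fits <- fit_all(vals, condition = "HL", design = d)
  expect_equal(sum(fits$rhythmic), 0)
})

test_that("circular difference wraps with the +12 boundary convention", {
  expect_equal(circular_difference(6, 6), 0)
  expect_equal(circular_difference(23, 1), -2)
  expect_equal(circular_difference(1, 23), 2)
  expect_equal(circular_difference(2, 14), 12)
  expect_equal(circular_difference(14, 2), 12)
  expect_error(circular_difference(24, 0), "\\[0, 24\\)")
})

test_that("rhythmic fractions aggregate by compartment with intersection", {
  ann <- data.frame(feature_id = paste0("g", 1:10),
                    compartment = c(rep("nucleus", 8), "chloroplast",
                                    "chloroplast"))
  fits <- data.frame(feature_id = paste0("g", 1:10),
                     q_value = c(rep(0.01, 7), 0.5, 0.01, 0.2))
  fr <- rhythmic_fraction(list(ML = fits), ann)
  nuc <- fr[fr$compartment == "nucleus", ]
  expect_equal(nuc$fraction, 7 / 8)
  expect_equal(fr$fraction[fr$compartment == "chloroplast"], 1 / 2)

  # intersection fraction never exceeds any per-condition fraction
  set.seed(3)
  for (rep_i in 1:5) {
    fits2 <- fits
    fits2$q_value <- sample(c(0.01, 0.5), 10, replace = TRUE)
    fr2 <- rhythmic_fraction(list(a = fits, b = fits2), ann)
    for (cm in unique(fr2$compartment)) {
      sub <- fr2[fr2$compartment == cm, ]
      if ("all" %in% sub$condition)
        expect_lte(sub$fraction[sub$condition == "all"],
                   min(sub$fraction[sub$condition != "all"]))
    }
  }
})

test_that("phase concordance restricts to dual-rhythmic features", {
  fits <- data.frame(feature_id = paste0("g", 1:6),
                     acrophase = c(1, 5, 9, 13, 17, 21),
                     q_value = c(rep(0.01, 5), 0.9))
  same <- phase_concordance(fits, fits)
  expect_equal(same$summary$n, 5)
  expect_equal(same$summary$concordant_fraction, 1)
  expect_true(all(same$table$delta == 0))

  shifted <- fits
  shifted$acrophase <- (fits$acrophase + 6) %% 24
  pc <- phase_concordance(shifted, fits)
  expect_equal(median(pc$table$delta), 6)

  none <- phase_concordance(fits[fits$q_value > 0.5, ], fits)
  expect_false(none$summary$defined)
})

test_that("mRNA-protein lag uses the [0,24) convention", {
  fm <- data.frame(feature_id = c("a", "b"), acrophase = c(2, 6),
                   q_value = 0.01)
  fp <- data.frame(feature_id = c("a", "b"), acrophase = c(6, 2),
                   q_value = 0.01)
  lag <- mrna_protein_lag(fm, fp)
  expect_equal(sort(lag$table$lag_hours), c(4, 20))  # 20, not -4

  same <- mrna_protein_lag(fm, fm)
  expect_true(all(same$table$lag_hours == 0))
})
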