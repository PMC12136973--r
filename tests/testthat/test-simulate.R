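test_that("configuration validates rates and requires a seed", {
  expect_error(sim_config(seed = 1, frac_rhythmic = 1.2), "frac_rhythmic")
  expect_error(sim_config(seed = 1, protein_missing_rate = -0.1),
               "protein_missing_rate")
  expect_error(sim_config(n_genes = 10), "seed")
  cfg <- sim_config(n_genes = 10, seed = 4)
  expect_s3_class(cfg, "sim_config")
})

test_that("truth generation honors the configured fractions", {
  cfg <- sim_config(n_genes = 1000, frac_rhythmic = 0.91, seed = 3)
  truth <- generate_truth(cfg)
  expect_equal(nrow(truth), 1000)
  expect_equal(sum(truth$is_rhythmic), 910)
  expect_true(all(truth$amplitude_log2[!truth$is_rhythmic] == 0))
  expect_true(all(truth$phase_hours[truth$is_rhythmic] >= 0 &
                    truth$phase_hours[truth$is_rhythmic] < 24))
  expect_true(all(truth$protein_lag_hours >= 2 & truth$protein_lag_hours <= 8))
  expect_false(anyDuplicated(truth$feature_id) > 0)

  n_resp <- sum(truth$response_cond != "none")
  expect_equal(n_resp, round(1000 * cfg$frac_responsive))
  expect_equal(sum(truth$shared_with_LL), round(n_resp * cfg$frac_shared))
  expect_equal(sum(truth$response_mode == "constitutive"),
               round(n_resp * cfg$frac_constitutive))

  flat <- generate_truth(sim_config(n_genes = 50, frac_rhythmic = 0, seed = 8))
  expect_true(all(flat$amplitude_log2 == 0))
})

test_that("identical configurations give byte-identical outputs", {
  d <- build_design()
  cfg <- sim_config(n_genes = 60, seed = 12)
  t1 <- generate_truth(cfg); t2 <- generate_truth(cfg)
  expect_identical(t1, t2)
  expect_identical(simulate_mrna(t1, d, cfg), simulate_mrna(t2, d, cfg))
  expect_identical(simulate_protein(t1, d, cfg),
                   simulate_protein(t2, d, cfg))
  expect_identical(simulate_physio_tables(d, cfg),
                   simulate_physio_tables(d, cfg))

  cfg2 <- sim_config(n_genes = 60, seed = 13)
  expect_false(identical(generate_truth(cfg2), t1))
})

test_that("truth tables and matrices share one feature universe", {
  d <- build_design()
  cfg <- sim_config(n_genes = 40, seed = 15)
  truth <- generate_truth(cfg)
  sim <- simulate_mrna(truth, d, cfg)
  prot <- simulate_protein(truth, d, cfg)
  expect_identical(rownames(sim$counts$values), truth$feature_id)
  expect_identical(rownames(prot$values), truth$feature_id)
})

test_that("response labels expand per cellular state", {
  cfg <- sim_config(n_genes = 200, frac_responsive = 0.5, frac_shared = 0.5,
                    frac_constitutive = 0.5, seed = 19)
  truth <- generate_truth(cfg)
  const_hl <- truth$response_mode == "constitutive" &
    truth$response_cond == "HL" & truth$response_dir == "up"
  for (tp in c("-2", "+6")) {
    lab_hl <- truth_response_labels(truth, "HL", tp)
    lab_ll <- truth_response_labels(truth, "LL", tp)
    expect_true(all(lab_hl[const_hl] == "up"))
    expect_true(all(lab_ll[const_hl] == "none"))  # HL-specific
    shared <- truth$shared_with_LL & truth$response_mode == "constitutive"
    expect_identical(lab_ll[shared], lab_hl[shared])
  }
  trans <- which(truth$response_mode == "transient")[1]
  tp_t <- truth$response_tp[trans]
  other <- setdiff(c("-2", "+2", "+6", "+10", "-10"), tp_t)[1]
  expect_equal(truth_response_labels(truth, "HL", tp_t)[trans],
               truth$response_dir[trans])
  expect_equal(truth_response_labels(truth, "HL", other)[trans], "none")
})

test_that("near-noiseless rhythmic gene peaks at its planted phase", {
  d <- build_design()
  cfg <- sim_config(n_genes = 1, frac_rhythmic = 1, nb_dispersion = 1e-10,
                    frac_responsive = 0, seed = 21)
  truth <- generate_truth(cfg)
  truth$phase_hours <- 6
  sim <- simulate_mrna(truth, d, cfg)
  ml <- sim$counts$values[1, d$condition == "ML"]
  zt <- d$zt_hours[d$condition == "ML"]
  means <- tapply(ml, zt, mean)
  expect_equal(as.numeric(names(which.max(means))), 6)
})

test_that("planted condition effects shift means by 2^effect", {
  d <- build_design()
  cfg <- sim_config(n_genes = 1, frac_rhythmic = 0, frac_responsive = 1,
                    frac_shared = 0, frac_constitutive = 1,
                    effect_size_log2 = 2, nb_dispersion = 1e-10,
                    mesor_log2_mean = 12, mesor_log2_sd = 0, seed = 25)
  truth <- generate_truth(cfg)
  sim <- simulate_mrna(truth, d, cfg)
  hl <- mean(sim$counts$values[1, d$condition == "HL" &
                                 d$timepoint_label == "+2"])
  ml <- mean(sim$counts$values[1, d$condition == "ML" &
                                 d$timepoint_label == "+2"])
  expected_ratio <- if (truth$response_dir == "up") 4 else 0.25
  expect_equal(hl / ml, expected_ratio, tolerance = 0.03)
})

test_that("protein layer lags its mRNA with compressed amplitude", {
  d <- build_design(n_replicates = 3)
  cfg <- sim_config(n_genes = 1, frac_rhythmic = 1, frac_responsive = 0,
                    protein_noise_sd_log2 = 0, protein_missing_rate = 0,
                    protein_loq = 0, protein_amp_scale_range = c(0.5, 0.5),
                    protein_lag_range = c(4, 4), seed = 33)
  truth <- generate_truth(cfg)
  truth$phase_hours <- 2
  truth$amplitude_log2 <- 2
  prot <- simulate_protein(truth, d, cfg)
  ml <- log2(prot$values[1, d$condition == "ML"])
  zt <- d$zt_hours[d$condition == "ML"]
  fit <- fit_cosinor(ml, zt)
  expect_equal(fit$acrophase, 6, tolerance = 1e-6)   # 2 + 4 h lag
  expect_equal(fit$amplitude, 1, tolerance = 1e-6)   # half the mRNA range
})

test_that("protein missingness comes from censoring plus dropout", {
  d <- build_design()
  cfg <- sim_config(n_genes = 300, frac_rhythmic = 0, mesor_log2_mean = 5,
                    mesor_log2_sd = 2, protein_loq = 32,
                    protein_missing_rate = 0.1, seed = 35)
  truth <- generate_truth(cfg)
  prot <- simulate_protein(truth, d, cfg)
  expect_true(all(prot$values >= 32, na.rm = TRUE))  # left-censored at LOQ
  expect_gt(mean(is.na(prot$values)), 0.1)           # dropout + censoring
})
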