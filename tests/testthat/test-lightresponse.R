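calls_grid <- c("up", "down", "unchanged")

test_that("core classification matches the hand-enumerated truth table", {
  grid <- expand.grid(hl = calls_grid, ll = calls_grid,
                      stringsAsFactors = FALSE)
  expected <- c(
    "up.up" = "not_core", "up.down" = "core_up", "up.unchanged" = "core_up",
    "down.up" = "core_down", "down.down" = "not_core",
    "down.unchanged" = "core_down",
    "unchanged.up" = "not_core", "unchanged.down" = "not_core",
    "unchanged.unchanged" = "not_core")
  got <- classify_core(grid$hl, grid$ll)
  expect_equal(as.character(got),
               unname(expected[paste(grid$hl, grid$ll, sep = ".")]))
})

test_that("core classification is antisymmetric under direction flip", {
  flip <- function(x) c(up = "down", down = "up", unchanged = "unchanged")[x]
  grid <- expand.grid(hl = calls_grid, ll = calls_grid,
                      stringsAsFactors = FALSE)
  orig <- as.character(classify_core(grid$hl, grid$ll))
  flipped <- as.character(classify_core(flip(grid$hl), flip(grid$ll)))
  map <- c(core_up = "core_down", core_down = "core_up",
           not_core = "not_core")
  expect_equal(flipped, unname(map[orig]))
})

test_that("not_evaluable handling follows the strictness flag", {
  expect_equal(as.character(classify_core("up", "not_evaluable")), "core_up")
  expect_equal(as.character(classify_core("up", "not_evaluable",
                                          strict = TRUE)), "not_core")
  expect_equal(as.character(classify_core("not_evaluable", "down")),
               "not_core")
})

test_that("core union deduplicates genes and records provenance", {
  tab <- data.frame(
    feature_id = c("g1", "g1", "g2", "g3"), layer = "mrna",
    timepoint_label = c("+2", "+6", "+2", "+10"),
    core_call = c("core_up", "core_up", "not_core", "core_down"))
  u <- core_union(tab)
  expect_setequal(u$feature_id, c("g1", "g3"))
  expect_equal(u$n_events[u$feature_id == "g1"], 2L)
  expect_match(u$provenance[u$feature_id == "g1"], "mrna:\\+2:core_up")

  # union size is monotone as layers are added
  tab2 <- data.frame(feature_id = "g9", layer = "protein",
                     timepoint_label = "-2", core_call = "core_up")
  u2 <- core_union(list(tab, tab2))
  expect_gte(nrow(u2), nrow(u))
  expect_true("g9" %in% u2$feature_id)

  empty <- core_union(data.frame(feature_id = "x", layer = "mrna",
                                 timepoint_label = "+2",
                                 core_call = "not_core"))
  expect_equal(nrow(empty), 0)
})

test_that("constitutive fraction equals a hand count on a toy table", {
  tps <- c("-2", "+2", "+6", "+10", "-10")
  mk <- function(id, calls) data.frame(feature_id = id,
                                       timepoint_label = tps, call = calls)
  tab <- rbind(
    mk("gA", rep("up", 5)),                          # constitutive up
    mk("gB", c("up", "up", "up", "up", "unchanged")),# 4/5: responsive only
    mk("gC", rep("down", 5)),                        # constitutive down
    mk("gD", c("up", "down", "up", "up", "up")),     # mixed: responsive only
    mk("gE", rep("unchanged", 5)),                   # silent
    mk("gF", c("unchanged", "up", rep("unchanged", 3))))
  cf <- constitutive_fraction(tab)
  expect_setequal(cf$constitutive_genes, c("gA", "gC"))
  expect_setequal(cf$responsive_genes, c("gA", "gB", "gC", "gD", "gF"))
  expect_equal(cf$fraction, 2 / 5)
  expect_true(all(cf$constitutive_genes %in% cf$responsive_genes))

  cf2 <- constitutive_fraction(tab, direction_free = TRUE)
  expect_setequal(cf2$constitutive_genes, c("gA", "gC", "gD"))

  expect_error(constitutive_fraction(tab[tab$timepoint_label != "+6", ]),
               "\\+6")
})

test_that("4-h lag concordance follows the sampled ZT grid", {
  mrna <- data.frame(feature_id = c("g1", "g2", "g3", "g4"),
                     timepoint_label = c("+2", "+2", "-10", "+10"),
                     call = "up")
  prot <- data.frame(feature_id = c("g1", "g2", "g3", "g4"),
                     timepoint_label = c("+2", "+6", "-2", "-10"),
                     call = "up")
  cc <- concordance_with_lag(mrna, prot)
  m <- cc$table[cc$table$layer == "mrna", ]
  expect_equal(m$concordance[m$feature_id == "g1"], "simultaneous")
  expect_equal(m$concordance[m$feature_id == "g2"], "lagged_4h")
  # ZT14 -> ZT22 is an 8-h gap, never a 4-h lag
  expect_equal(m$concordance[m$feature_id == "g3"], "mrna_only")
  # +10 (ZT10) -> -10 (ZT14) is the 4-h step across the light-dark border
  expect_equal(m$concordance[m$feature_id == "g4"], "lagged_4h")

  p <- cc$table[cc$table$layer == "protein", ]
  expect_equal(p$concordance[p$feature_id == "g2"], "lagged_4h")
  expect_equal(p$concordance[p$feature_id == "g3"], "protein_only")

  # direction must match for a lagged pair
  prot2 <- prot
  prot2$call[2] <- "down"
  cc2 <- concordance_with_lag(mrna, prot2)
  m2 <- cc2$table[cc2$table$layer == "mrna", ]
  expect_equal(m2$concordance[m2$feature_id == "g2"], "mrna_only")

  expect_equal(cc$summary$fraction_both_levels,
               cc$summary$n_matched / cc$summary$n_events)
})

test_that("null data yields a near-empty core list", {
  d <- build_design()
  cfg <- sim_config(n_genes = 400, frac_responsive = 0, frac_rhythmic = 0,
                    seed = 77)
  sim <- simulate_mrna(generate_truth(cfg), d, cfg)
  core_tabs <- lapply(c("-2", "+2", "+6", "+10", "-10"), function(tp) {
    hl <- call_mrna_de(nb_wald_test(sim$counts, test_condition = "HL",
                                    timepoint = tp))
    ll <- call_mrna_de(nb_wald_test(sim$counts, test_condition = "LL",
                                    timepoint = tp))
    hl$timepoint_label <- tp; ll$timepoint_label <- tp
    classify_core_table(hl, ll)
  })
  u <- core_union(core_tabs)
  expect_lte(nrow(u), 0.01 * 400)
})
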