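#' Configuration for the synthetic multi-omics generator
#'
#' Bundles and validates every generator parameter. The defaults emulate
#' the statistical structure the downstream analysis assumes: a high
#' fraction of 24-h-rhythmic transcripts with arbitrary phases, protein
#' profiles lagging their cognate mRNA by 2-8 h with compressed dynamic
#' range, planted light-responsive genes (transient and constitutive,
#' condition-specific and shared with low light), tight replicate
#' correlation, and detection floors/missingness for proteins.
#'
#' @param n_genes Number of simulated genes.
#' @param frac_rhythmic Fraction of genes with a planted 24-h rhythm
#'   (default 0.91, the nucleus-encoded transcript fraction the design
#'   emulates).
#' @param amplitude_log2 Cosine amplitude (log2 units) of rhythmic genes.
#' @param mesor_log2_mean,mesor_log2_sd Across-gene distribution of the
#'   log2 mesor (count scale).
#' @param nb_dispersion Negative-binomial dispersion `alpha` shared by all
#'   genes (`var = mu + alpha * mu^2`); a stated simplification over
#'   gene-wise dispersion trends.
#' @param library_size Scale used for the FPKM-like layer: values are
#'   `counts * 1e6 / library_size`.
#' @param phase_dist `"uniform"` phases on `[0, 24)` (default, unbiased for
#'   recovery tests) or `"bimodal"` dawn/dusk phase clusters.
#' @param protein_noise_sd_log2 Gaussian log2 noise SD of protein
#'   intensities.
#' @param protein_amp_scale_range Per-gene protein amplitude compression
#'   drawn uniformly from this range (dynamic-range compression of
#'   reporter-ion data).
#' @param protein_lag_range Per-gene protein phase lag (hours) drawn
#'   uniformly from this range.
#' @param protein_loq Limit of quantitation (linear intensity scale):
#'   intensities below it are left-censored to missing.
#' @param protein_missing_rate Additional random dropout rate for protein
#'   values.
#' @param effect_size_log2 Planted condition effect (log2) for responsive
#'   genes.
#' @param frac_responsive Fraction of genes with a planted light response.
#' @param frac_shared Fraction of responsive genes whose response is shared
#'   with the LL population (same direction in HL and LL).
#' @param frac_constitutive Fraction of responsive genes responding at all
#'   five timepoints; the rest respond at a single random timepoint.
#' @param physio_noise_sd Lognormal noise SD for the physiology tables
#'   (0 gives exactly the configured means).
#' @param n_regions Thylakoid membrane regions measured per cellular state.
#' @param seed Integer seed; mandatory, all generators are deterministic
#'   under it.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, frac_rhythmic = 0.91,
                       amplitude_log2 = 2, mesor_log2_mean = 8,
                       mesor_log2_sd = 1.5, nb_dispersion = 0.05,
                       library_size = 1e6, phase_dist = c("uniform", "bimodal"),
                       protein_noise_sd_log2 = 0.4,
                       protein_amp_scale_range = c(0.3, 0.7),
                       protein_lag_range = c(2, 8), protein_loq = 16,
                       protein_missing_rate = 0.05, effect_size_log2 = 2,
                       frac_responsive = 0.1, frac_shared = 0.3,
                       frac_constitutive = 0.2, physio_noise_sd = 0.05,
                       n_regions = 40, seed) {
  if (missing(seed)) stop("seed is mandatory for reproducibility", call. = FALSE)
  phase_dist <- match.arg(phase_dist)
  stopifnot(n_genes >= 1, nb_dispersion >= 0, library_size > 0,
            protein_noise_sd_log2 >= 0, protein_loq >= 0,
            length(protein_lag_range) == 2,
            length(protein_amp_scale_range) == 2,
            physio_noise_sd >= 0, n_regions >= 1)
  rates <- c(frac_rhythmic = frac_rhythmic, frac_responsive = frac_responsive,
             frac_shared = frac_shared, frac_constitutive = frac_constitutive,
             protein_missing_rate = protein_missing_rate)
  bad <- rates < 0 | rates > 1
  if (any(bad))
    stop("rate(s) outside [0, 1]: ", paste(names(rates)[bad], collapse = ", "),
         call. = FALSE)
  if (round(n_genes * frac_responsive) > n_genes)
    stop("more responsive genes than genes", call. = FALSE)
  if (any(protein_amp_scale_range <= 0 | protein_amp_scale_range > 1))
    stop("protein_amp_scale_range must lie in (0, 1]", call. = FALSE)
  if (protein_lag_range[1] < 0 || protein_lag_range[2] < protein_lag_range[1])
    stop("invalid protein_lag_range", call. = FALSE)
  structure(list(
    n_genes = as.integer(n_genes), frac_rhythmic = frac_rhythmic,
    amplitude_log2 = amplitude_log2, mesor_log2_mean = mesor_log2_mean,
    mesor_log2_sd = mesor_log2_sd, nb_dispersion = nb_dispersion,
    library_size = library_size, phase_dist = phase_dist,
    protein_noise_sd_log2 = protein_noise_sd_log2,
    protein_amp_scale_range = protein_amp_scale_range,
    protein_lag_range = protein_lag_range, protein_loq = protein_loq,
    protein_missing_rate = protein_missing_rate,
    effect_size_log2 = effect_size_log2, frac_responsive = frac_responsive,
    frac_shared = frac_shared, frac_constitutive = frac_constitutive,
    physio_noise_sd = physio_noise_sd, n_regions = as.integer(n_regions),
    seed = as.integer(seed)), class = "sim_config")
}

#' Generate the per-gene ground-truth table
#'
#' Draws rhythm, protein-coupling, response and compartment labels for every
#' gene. `round(n_genes * frac_rhythmic)` genes are rhythmic with phases
#' from the configured distribution; non-rhythmic genes have amplitude 0.
#' `round(n_genes * frac_responsive)` genes carry a planted response:
#' `round(frac_shared * n)` of them shared with LL (same direction in both
#' test populations), the rest HL-specific; `round(frac_constitutive * n)`
#' respond at all five timepoints, the rest at one random timepoint.
#' Deterministic under `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return `data.frame` with one truth row per gene: `feature_id`,
#'   `is_rhythmic`, `phase_hours`, `amplitude_log2`, `mesor_log2`,
#'   `protein_lag_hours`, `protein_amp_scale`, `response_cond`
#'   (`none`/`HL`/`both`), `response_dir`, `response_mode`, `response_tp`
#'   (`all`, a label, or `NA`), `shared_with_LL`, `compartment`.
#' @export
generate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  ids <- sprintf("g%05d", seq_len(n))

  n_rhy <- round(n * cfg$frac_rhythmic)
  is_rhy <- c(rep(TRUE, n_rhy), rep(FALSE, n - n_rhy))
  phase <- if (cfg$phase_dist == "uniform") {
    stats::runif(n, 0, 24)
  } else {
    # dawn/dusk clusters at ZT1 and ZT13 (wrapped normal, sd 2 h)
    (stats::rnorm(n, mean = sample(c(1, 13), n, replace = TRUE), sd = 2)) %% 24
  }
  phase[!is_rhy] <- NA_real_
  amp <- ifelse(is_rhy, cfg$amplitude_log2, 0)
  mesor <- stats::rnorm(n, cfg$mesor_log2_mean, cfg$mesor_log2_sd)
  lag <- stats::runif(n, cfg$protein_lag_range[1], cfg$protein_lag_range[2])
  amp_scale <- stats::runif(n, cfg$protein_amp_scale_range[1],
                            cfg$protein_amp_scale_range[2])

  n_resp <- round(n * cfg$frac_responsive)
  resp_idx <- if (n_resp > 0) sample.int(n, n_resp) else integer(0)
  n_shared <- round(n_resp * cfg$frac_shared)
  n_const <- round(n_resp * cfg$frac_constitutive)
  response_cond <- rep("none", n)
  response_dir <- rep("none", n)
  response_mode <- rep("none", n)
  response_tp <- rep(NA_character_, n)
  if (n_resp > 0) {
    shared <- resp_idx[seq_len(n_shared)]
    response_cond[resp_idx] <- "HL"
    response_cond[shared] <- "both"
    response_dir[resp_idx] <- sample(c("up", "down"), n_resp, replace = TRUE)
    const <- sample(resp_idx, n_const)
    response_mode[resp_idx] <- "transient"
    response_mode[const] <- "constitutive"
    response_tp[resp_idx] <- sample(TIMEPOINT_LABELS, n_resp, replace = TRUE)
    response_tp[const] <- "all"
  }

  compartment <- sample(c("nucleus", "chloroplast", "mitochondrion"), n,
                        replace = TRUE, prob = c(0.90, 0.08, 0.02))
  data.frame(feature_id = ids, is_rhythmic = is_rhy, phase_hours = phase,
             amplitude_log2 = amp, mesor_log2 = mesor,
             protein_lag_hours = lag, protein_amp_scale = amp_scale,
             response_cond = response_cond, response_dir = response_dir,
             response_mode = response_mode, response_tp = response_tp,
             shared_with_LL = response_cond == "both",
             compartment = compartment, row.names = NULL)
}

#' Ground-truth response labels for one cellular state
#'
#' Expands the compact truth columns into per-gene `up`/`down`/`none`
#' labels for a (condition, timepoint) pair, mirroring the per-state call
#' contract of the differential-abundance stage.
#'
#' @param truth Output of [generate_truth()].
#' @param condition `"LL"` or `"HL"` (the ML control never responds).
#' @param timepoint Timepoint label.
#' @return Character vector aligned with `truth` rows.
#' @export
truth_response_labels <- function(truth, condition, timepoint) {
  timepoint <- normalize_label(timepoint)
  covered <- truth$response_cond == "both" |
    (truth$response_cond == "HL" & condition == "HL")
  at_tp <- !is.na(truth$response_tp) &
    (truth$response_tp == "all" | truth$response_tp == timepoint)
  ifelse(covered & at_tp, truth$response_dir, "none")
}

# log2-scale mean matrix (genes x samples): cosinor + planted effects
expected_log2_mean <- function(truth, design) {
  w <- 2 * pi / 24
  n <- nrow(truth)
  base <- matrix(truth$mesor_log2, n, nrow(design))
  rhy <- truth$is_rhythmic
  if (any(rhy)) {
    base[rhy, ] <- base[rhy, ] + truth$amplitude_log2[rhy] *
      cos(w * outer(-truth$phase_hours[rhy], design$zt_hours, `+`))
  }
  base
}

add_planted_effects <- function(log2mu, truth, design, effect) {
  states <- unique(design[, c("condition", "timepoint_label")])
  for (i in seq_len(nrow(states))) {
    cond <- states$condition[i]
    if (cond == "ML") next
    lab <- truth_response_labels(truth, cond, states$timepoint_label[i])
    if (all(lab == "none")) next
    cols <- design$condition == cond &
      design$timepoint_label == states$timepoint_label[i]
    sgn <- ifelse(lab == "up", 1, ifelse(lab == "down", -1, 0))
    log2mu[, cols] <- log2mu[, cols] + sgn * effect
  }
  log2mu
}

#' Simulate transcript counts and an FPKM-like layer
#'
#' Per-gene log2 means follow the cosinor model (mesor + amplitude at the
#' planted phase) plus additive log2 condition effects where a response is
#' planted. Counts are negative-binomial with the configured dispersion;
#' the FPKM-like layer is the counts rescaled by the configured library
#' size. Deterministic under `cfg$seed`.
#'
#' @param truth [generate_truth()] table covering all features.
#' @param design A `sample_design`.
#' @param cfg The [sim_config()] used for `truth`.
#' @return List of two `omics_matrix` objects: `counts` and `fpkm`.
#' @export
simulate_mrna <- function(truth, design, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_design(design)
  set.seed(cfg$seed + 1L)
  log2mu <- expected_log2_mean(truth, design)
  log2mu <- add_planted_effects(log2mu, truth, design, cfg$effect_size_log2)
  mu <- 2^log2mu
  size <- 1 / max(cfg$nb_dispersion, 1e-12)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = size),
                   nrow(mu), ncol(mu))
  dimnames(counts) <- list(truth$feature_id, design$sample_id)
  fpkm <- counts * (1e6 / cfg$library_size)
  list(counts = omics_matrix(counts, "mrna", design, unit = "counts"),
       fpkm = omics_matrix(fpkm, "mrna", design, unit = "FPKM-like"))
}

#' Simulate protein reporter intensities
#'
#' Log2 intensities follow the mRNA mesor plus a compressed cosine shifted
#' by the per-gene lag (`protein_amp_scale * amplitude`,
#' `phase + protein_lag_hours`), the same planted condition effects, and
#' Gaussian log2 noise. Intensities below the limit of quantitation are
#' left-censored to missing; additional values drop out at random.
#' Deterministic under `cfg$seed`.
#'
#' @inheritParams simulate_mrna
#' @return An `omics_matrix` of layer `"protein"` (missing entries `NA`).
#' @export
simulate_protein <- function(truth, design, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_design(design)
  set.seed(cfg$seed + 2L)
  w <- 2 * pi / 24
  n <- nrow(truth)
  log2mu <- matrix(truth$mesor_log2, n, nrow(design))
  rhy <- truth$is_rhythmic
  if (any(rhy)) {
    shifted_phase <- truth$phase_hours[rhy] + truth$protein_lag_hours[rhy]
    log2mu[rhy, ] <- log2mu[rhy, ] +
      (truth$protein_amp_scale * truth$amplitude_log2)[rhy] *
      cos(w * outer(-shifted_phase, design$zt_hours, `+`))
  }
  log2mu <- add_planted_effects(log2mu, truth, design, cfg$effect_size_log2)
  log2int <- log2mu + stats::rnorm(length(log2mu), 0, cfg$protein_noise_sd_log2)
  intensity <- 2^log2int
  intensity[intensity < cfg$protein_loq] <- NA_real_
  dropout <- stats::runif(length(intensity)) < cfg$protein_missing_rate
  intensity[dropout] <- NA_real_
  dimnames(intensity) <- list(truth$feature_id, design$sample_id)
  omics_matrix(intensity, "protein", design, unit = "reporter-intensity")
}

# configured physiology means; all keyed by condition then timepoint label
physio_means <- function() {
  tps <- TIMEPOINT_LABELS
  m <- function(...) {
    x <- c(...); names(x) <- tps; x  # order: -2, +2, +6, +10, -10
  }
  list(
    # pigments, pmol per 1e6 cells; cell growth over the day scales
    # per-cell contents (division at nightfall resets them)
    growth = m(0.75, 0.85, 1.0, 1.2, 0.8),
    vio = list(LL = m(35, 35, 35, 35, 35), ML = m(30, 28, 28, 30, 30),
               HL = m(25, 18, 18, 24, 25)),
    anthera = list(LL = m(0.3, 0.5, 0.5, 0.4, 0.3),
                   ML = m(0.5, 1.5, 1.5, 0.8, 0.5),
                   HL = m(1.0, 6.0, 6.0, 3.0, 1.5)),
    zea = list(LL = m(0.2, 0.5, 0.6, 0.3, 0.2),
               ML = m(0.5, 3.0, 3.5, 1.0, 0.6),
               HL = m(2.0, 20, 22, 6.0, 3.0)),
    lutein = list(LL = m(55, 55, 55, 55, 55), ML = m(60, 60, 60, 60, 60),
                  HL = m(65, 65, 65, 65, 65)),
    alpha_car = list(LL = m(9, 9, 9, 9, 9), ML = m(8, 8, 8, 8, 8),
                     HL = m(7, 7, 7, 7, 7)),
    beta_car = list(LL = m(24, 24, 24, 24, 24), ML = m(25, 25, 25, 25, 25),
                    HL = m(27, 27, 27, 27, 27)),
    chl_a = list(LL = m(250, 250, 255, 260, 250),
                 ML = m(200, 200, 205, 210, 200),
                 HL = m(140, 138, 138, 142, 140)),
    chl_ab = list(LL = m(2.3, 2.3, 2.3, 2.3, 2.3),
                  ML = m(2.6, 2.6, 2.6, 2.6, 2.6),
                  HL = m(2.8, 2.9, 2.9, 2.8, 2.8)),
    # thylakoid stacking: fewer layers and looser stacks (higher SRD) in
    # HL; daytime unstacking in all conditions
    layers = list(LL = m(6, 5, 5, 5, 6), ML = m(5, 4, 4, 4, 5),
                  HL = m(3, 2, 2, 2, 3)),
    srd = list(LL = m(16, 16.5, 16.5, 16.5, 16), ML = m(17, 18, 18, 18, 17),
               HL = m(20, 22, 22, 21, 20)),
    # PAM fluorometry: HL photoinhibition early/midday, partial recovery
    # at +10; night values high in all conditions
    fvfm = list(LL = m(0.72, 0.72, 0.71, 0.71, 0.72),
                ML = m(0.71, 0.69, 0.68, 0.69, 0.71),
                HL = m(0.68, 0.50, 0.55, 0.63, 0.66)),
    npq_max = list(LL = m(0.6, 0.6, 0.6, 0.6, 0.6),
                   ML = m(1.2, 1.2, 1.2, 1.2, 1.2),
                   HL = m(2.5, 2.4, 2.4, 2.4, 2.5)),
    # 77 K PSI(~711 nm)/PSII(~684 nm) peak ratio; state transitions in
    # ML/HL during the day, reversal at night; LL stays in State 1
    r711 = list(LL = m(0.55, 0.55, 0.56, 0.55, 0.55),
                ML = m(0.56, 0.72, 0.70, 0.73, 0.58),
                HL = m(0.60, 0.85, 0.72, 0.80, 0.62))
  )
}

#' Simulate physiology measurement tables
#'
#' Emits pigment, thylakoid-morphometry and fluorescence tables with
#' condition- and time-structured means: the HL population has the highest
#' xanthophyll de-epoxidation early/midday and low values at night, fewer
#' and more loosely stacked thylakoid layers than LL at every timepoint, a
#' midday Fv/Fm depression with late-day recovery, the highest NPQ
#' capacity, and daytime state transitions in the 77 K spectra. Values are
#' positive, lognormal noise is applied (none when
#' `cfg$physio_noise_sd = 0`), and everything is deterministic under
#' `cfg$seed`.
#'
#' @param design A `sample_design`.
#' @param cfg A [sim_config()].
#' @return List of `data.frame`s: `pigments` (per replicate), `thylakoid`
#'   (per measured membrane region: `height_nm`, `layers`), `fluorescence`
#'   (`f0`, `fm`), `npq_curve` (`actinic`, `fm_prime` per step), `spectra`
#'   (long table `wavelength_nm`, `intensity`, normalized to the PSII
#'   maximum).
#' @export
simulate_physio_tables <- function(design, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_design(design)
  set.seed(cfg$seed + 3L)
  mm <- physio_means()
  noise <- function(n) {
    if (cfg$physio_noise_sd == 0) rep(1, n)
    else exp(stats::rnorm(n, 0, cfg$physio_noise_sd))
  }
  reps <- unique(design[, c("condition", "timepoint_label", "replicate")])
  cond <- reps$condition; tp <- reps$timepoint_label
  g <- mm$growth[tp]
  pick <- function(tab) mapply(function(cd, t) tab[[cd]][[t]], cond, tp)

  chl_a <- pick(mm$chl_a) * g * noise(nrow(reps))
  pigments <- data.frame(
    condition = cond, timepoint_label = tp, replicate = reps$replicate,
    vio = pick(mm$vio) * g * noise(nrow(reps)),
    anthera = pick(mm$anthera) * g * noise(nrow(reps)),
    zea = pick(mm$zea) * g * noise(nrow(reps)),
    lutein = pick(mm$lutein) * g * noise(nrow(reps)),
    alpha_car = pick(mm$alpha_car) * g * noise(nrow(reps)),
    beta_car = pick(mm$beta_car) * g * noise(nrow(reps)),
    chl_a = chl_a,
    chl_b = chl_a / (pick(mm$chl_ab) * noise(nrow(reps))),
    row.names = NULL)

  states <- unique(design[, c("condition", "timepoint_label")])
  thylakoid <- do.call(rbind, lapply(seq_len(nrow(states)), function(i) {
    cd <- states$condition[i]; t <- states$timepoint_label[i]
    layers <- pmax(1L, round(mm$layers[[cd]][[t]] *
                               noise(cfg$n_regions)))
    data.frame(condition = cd, timepoint_label = t,
               region_id = seq_len(cfg$n_regions), layers = layers,
               height_nm = layers * mm$srd[[cd]][[t]] * noise(cfg$n_regions))
  }))
  rownames(thylakoid) <- NULL

  fm <- 1.0 * noise(nrow(reps))
  fvfm <- pmin(pick(mm$fvfm) * noise(nrow(reps)), 0.85)
  fluorescence <- data.frame(
    condition = cond, timepoint_label = tp, replicate = reps$replicate,
    fm = fm, f0 = fm * (1 - fvfm), row.names = NULL)

  actinic <- c(50, 200, 500, 1000, 1500)
  npq_curve <- do.call(rbind, lapply(seq_along(actinic), function(j) {
    level <- pick(mm$npq_max) * actinic[j] / (actinic[j] + 300) *
      noise(nrow(reps))
    data.frame(condition = cond, timepoint_label = tp,
               replicate = reps$replicate, actinic = actinic[j],
               fm = fm, fm_prime = fm / (1 + level), row.names = NULL)
  }))

  wl <- seq(650, 780, by = 2)
  spectra <- do.call(rbind, lapply(seq_len(nrow(reps)), function(i) {
    r711 <- mm$r711[[cond[i]]][[tp[i]]] * noise(1)
    intensity <- exp(-(wl - 684)^2 / (2 * 5^2)) +
      r711 * exp(-(wl - 711)^2 / (2 * 6^2)) + 0.02
    data.frame(condition = cond[i], timepoint_label = tp[i],
               replicate = reps$replicate[i], wavelength_nm = wl,
               intensity = intensity / max(intensity[wl >= 680 & wl <= 690]),
               row.names = NULL)
  }))

  list(pigments = pigments, thylakoid = thylakoid,
       fluorescence = fluorescence, npq_curve = npq_curve, spectra = spectra)
}
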