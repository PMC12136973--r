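#' Fit a fixed-period cosinor model to one abundance series
#'
#' Fits `y(t) = M + beta_c * cos(2*pi*t/period) + beta_s * sin(2*pi*t/period)`
#' by ordinary least squares. The amplitude is `A = sqrt(beta_c^2 + beta_s^2)`
#' and the acrophase is the ZT hour of the fitted maximum,
#' `atan2(beta_s, beta_c) * period / (2*pi)` wrapped to `[0, period)`.
#' Significance is the F-test of the joint null `beta_c = beta_s = 0`
#' against the intercept-only model.
#'
#' Degenerate inputs follow fixed rules: a constant series gets amplitude 0
#' and p = 1 (defined); fewer than 4 finite observations, or fewer than 3
#' distinct times (rank-deficient design), yields `defined = FALSE` and the
#' feature is excluded downstream.
#'
#' @param y Numeric abundance series (analysis scale, e.g. log2).
#' @param zt Numeric ZT hours matching `y`; replicates enter as independent
#'   observations at their ZT.
#' @param period Fixed period in hours (24 by default; no period scan).
#' @return A one-row `data.frame`: `mesor`, `amplitude`, `acrophase`,
#'   `p_value`, `n_obs`, `defined`.
#' @examples
#' zt <- rep(c(2, 6, 10, 14, 22), each = 3)
#' y <- 5 + 2 * cos(2 * pi * (zt - 6) / 24)
#' fit_cosinor(y, zt)  # mesor 5, amplitude 2, acrophase 6
#' @export
fit_cosinor <- function(y, zt, period = 24) {
  stopifnot(length(y) == length(zt))
  ok <- is.finite(y) & is.finite(zt)
  y <- y[ok]; zt <- zt[ok]
  n <- length(y)
  undefined <- data.frame(mesor = NA_real_, amplitude = NA_real_,
                          acrophase = NA_real_, p_value = NA_real_,
                          n_obs = n, defined = FALSE)
  if (n < 4 || length(unique(zt)) < 3) return(undefined)
  if (stats::sd(y) == 0) {
    return(data.frame(mesor = y[1], amplitude = 0, acrophase = NA_real_,
                      p_value = 1, n_obs = n, defined = TRUE))
  }
  w <- 2 * pi / period
  X <- cbind(1, cos(w * zt), sin(w * zt))
  fit <- stats::lm.fit(X, y)
  if (fit$rank < 3) return(undefined)
  beta <- fit$coefficients
  amp <- sqrt(beta[2]^2 + beta[3]^2)
  phi <- (atan2(beta[3], beta[2]) * period / (2 * pi)) %% period
  rss1 <- sum(fit$residuals^2)
  rss0 <- sum((y - mean(y))^2)
  f <- ((rss0 - rss1) / 2) / (rss1 / (n - 3))
  p <- if (!is.finite(f)) 0 else stats::pf(f, 2, n - 3, lower.tail = FALSE)
  data.frame(mesor = unname(beta[1]), amplitude = unname(amp),
             acrophase = unname(phi), p_value = p, n_obs = n, defined = TRUE)
}

#' Double-plot a set of diurnal observations
#'
#' Duplicates every observation at `zt + 24`, the classic double-plotting
#' convention for visualising one diurnal cycle twice. Least-squares cosinor
#' point estimates are unchanged by the duplication, but p-values deflate
#' because the observation count doubles, so double-plotting is off by
#' default in [fit_all()] and a warning is emitted when it is enabled.
#'
#' @param values Numeric matrix (features x samples) or vector.
#' @param zt ZT hours, one per column/element.
#' @return List with `values` (columns duplicated) and `zt`
#'   (original then +24 h copies).
#' @export
double_plot <- function(values, zt) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  stopifnot(ncol(values) == length(zt))
  list(values = cbind(values, values), zt = c(zt, zt + 24))
}

#' Cosinor fits for every feature of one condition
#'
#' Subsets the matrix to one light condition, fits the 24-h cosinor model
#' per feature, and applies Benjamini-Hochberg adjustment over all defined
#' p-values. The BH family is the (layer, condition) slice being fitted.
#' Features failing the fitting preconditions are reported in the
#' `"excluded"` attribute.
#'
#' @param x An `omics_matrix` (or numeric matrix with a `design`).
#' @param condition Condition to analyse (must appear in the design).
#' @param design Required when `x` is a bare matrix.
#' @param q_threshold Rhythmicity cutoff applied to the `rhythmic` column.
#' @param use_double_plot Reproduce double-plotting before fitting
#'   (point estimates unchanged; p-values deflated; a warning is issued).
#' @param average_replicates Average replicates per timepoint before fitting
#'   instead of treating them as independent observations.
#' @param period Fixed period in hours.
#' @return `data.frame` with one row per defined feature: `feature_id`,
#'   `mesor`, `amplitude`, `acrophase`, `p_value`, `q_value`, `n_obs`,
#'   `rhythmic`; excluded feature ids in `attr(, "excluded")`.
#' @export
fit_all <- function(x, condition, design = NULL, q_threshold = 0.05,
                    use_double_plot = FALSE, average_replicates = FALSE,
                    period = 24) {
  if (inherits(x, "omics_matrix")) {
    design <- x$design
    values <- x$values
  } else {
    if (is.null(design)) stop("design required for a bare matrix", call. = FALSE)
    values <- x
    design <- design[match(colnames(values), design$sample_id), , drop = FALSE]
  }
  keep <- design$condition == condition
  if (!any(keep)) stop("condition '", condition, "' not in design", call. = FALSE)
  values <- values[, keep, drop = FALSE]
  zt <- design$zt_hours[keep]

  if (average_replicates) {
    zts <- sort(unique(zt))
    values <- vapply(zts, function(t)
      rowMeans(values[, zt == t, drop = FALSE], na.rm = TRUE),
      numeric(nrow(values)))
    if (is.null(dim(values))) values <- matrix(values, nrow = 1)
    zt <- zts
  }
  if (use_double_plot) {
    warning("double-plotting duplicates observations and deflates p-values",
            call. = FALSE)
    dp <- double_plot(values, zt)
    values <- dp$values
    zt <- dp$zt
  }

  fits <- do.call(rbind, lapply(seq_len(nrow(values)), function(i)
    fit_cosinor(values[i, ], zt, period = period)))
  fits <- cbind(feature_id = rownames(values), fits)
  excluded <- fits$feature_id[!fits$defined]
  fits <- fits[fits$defined, , drop = FALSE]
  fits$q_value <- bh_adjust(fits$p_value)
  fits$rhythmic <- fits$q_value < q_threshold
  rownames(fits) <- NULL
  attr(fits, "excluded") <- as.character(excluded)
  fits
}

#' Rhythmic fractions per genome compartment
#'
#' For each condition's fit table, the fraction of detected features called
#' rhythmic (`q < q_threshold`) is computed per genome compartment, plus the
#' fraction rhythmic in *all* supplied conditions (`condition = "all"`).
#' Unannotated features are excluded and listed in the `"unannotated"`
#' attribute; compartments with no detected features are simply absent.
#'
#' @param fits_list Named list of [fit_all()] tables, one per condition.
#' @param annotation Annotation `data.frame` with `feature_id`, `compartment`.
#' @param q_threshold Rhythmicity cutoff.
#' @return `data.frame` with `condition`, `compartment`, `n_detected`,
#'   `n_rhythmic`, `fraction`.
#' @export
rhythmic_fraction <- function(fits_list, annotation, q_threshold = 0.05) {
  if (is.data.frame(fits_list)) fits_list <- list(all = fits_list)
  stopifnot(length(fits_list) >= 1)
  if (is.null(names(fits_list)))
    names(fits_list) <- paste0("cond", seq_along(fits_list))

  comp_of <- stats::setNames(annotation$compartment, annotation$feature_id)
  unannot <- unique(unlist(lapply(fits_list, function(f)
    setdiff(f$feature_id, annotation$feature_id))))

  one <- function(fits, cond) {
    fits <- fits[fits$feature_id %in% annotation$feature_id, , drop = FALSE]
    if (!nrow(fits)) return(NULL)
    comp <- comp_of[fits$feature_id]
    rhy <- fits$q_value < q_threshold
    agg <- do.call(rbind, lapply(split(seq_len(nrow(fits)), comp), function(idx)
      data.frame(condition = cond, compartment = comp[idx[1]],
                 n_detected = length(idx), n_rhythmic = sum(rhy[idx]),
                 fraction = mean(rhy[idx]))))
    agg
  }
  out <- do.call(rbind, Map(one, fits_list, names(fits_list)))

  if (length(fits_list) > 1) {
    shared <- Reduce(intersect, lapply(fits_list, `[[`, "feature_id"))
    rhy_all <- Reduce(`&`, lapply(fits_list, function(f) {
      stats::setNames(f$q_value < q_threshold, f$feature_id)[shared]
    }))
    inter <- data.frame(feature_id = shared, q_value = ifelse(rhy_all, 0, 1))
    out <- rbind(out, one(inter, "all"))
  }
  rownames(out) <- NULL
  out
}

#' Minimal signed difference between two phases on the 24-h circle
#'
#' Returns `a - b` mapped to `(-12, 12]`; the antipodal 12 h displacement
#' maps to +12 by convention.
#'
#' @param phase_a,phase_b Phases in hours, each in `[0, 24)`.
#' @param period Circle period in hours.
#' @return Signed hours in `(-period/2, period/2]`.
#' @examples
#' circular_difference(23, 1)   # -2
#' circular_difference(2, 14)   # 12
#' @export
circular_difference <- function(phase_a, phase_b, period = 24) {
  if (any(phase_a < 0 | phase_a >= period | phase_b < 0 | phase_b >= period,
          na.rm = TRUE))
    stop("phases must lie in [0, ", period, ")", call. = FALSE)
  d <- (phase_a - phase_b) %% period
  ifelse(d > period / 2, d - period, d)
}

# Fisher-Lee circular correlation between two sets of angles (radians).
circular_correlation <- function(a, b) {
  num <- 0
  n <- length(a)
  if (n < 2) return(NA_real_)
  ij <- utils::combn(n, 2)
  num <- sum(sin(a[ij[1, ]] - a[ij[2, ]]) * sin(b[ij[1, ]] - b[ij[2, ]]))
  den <- sqrt(sum(sin(a[ij[1, ]] - a[ij[2, ]])^2) *
                sum(sin(b[ij[1, ]] - b[ij[2, ]])^2))
  if (den == 0) return(NA_real_)
  num / den
}

#' Phase concordance between two conditions
#'
#' Restricts to features rhythmic (q below threshold) in both fit tables and
#' compares acrophases on the 24-h circle.
#'
#' @param fits_a,fits_b [fit_all()] tables sharing a feature universe.
#' @param q_threshold Rhythmicity cutoff applied to both tables.
#' @param concordance_window Absolute phase difference (h) counted as
#'   concordant (2 h by default).
#' @return List with `table` (`feature_id`, `phase_a`, `phase_b`, `delta`)
#'   and `summary` (`n`, `median_delta`, `median_abs_delta`,
#'   `concordant_fraction`, `circular_r`). With an empty intersection the
#'   summary values are `NA` and `defined = FALSE`.
#' @export
phase_concordance <- function(fits_a, fits_b, q_threshold = 0.05,
                              concordance_window = 2) {
  ra <- fits_a[fits_a$q_value < q_threshold, c("feature_id", "acrophase")]
  rb <- fits_b[fits_b$q_value < q_threshold, c("feature_id", "acrophase")]
  shared <- intersect(ra$feature_id, rb$feature_id)
  tab <- data.frame(feature_id = shared,
                    phase_a = ra$acrophase[match(shared, ra$feature_id)],
                    phase_b = rb$acrophase[match(shared, rb$feature_id)])
  if (!nrow(tab)) {
    return(list(table = tab,
                summary = data.frame(n = 0, median_delta = NA_real_,
                                     median_abs_delta = NA_real_,
                                     concordant_fraction = NA_real_,
                                     circular_r = NA_real_, defined = FALSE)))
  }
  tab$delta <- circular_difference(tab$phase_a, tab$phase_b)
  w <- 2 * pi / 24
  list(table = tab,
       summary = data.frame(
         n = nrow(tab),
         median_delta = stats::median(tab$delta),
         median_abs_delta = stats::median(abs(tab$delta)),
         concordant_fraction = mean(abs(tab$delta) <= concordance_window),
         circular_r = circular_correlation(w * tab$phase_a, w * tab$phase_b),
         defined = TRUE))
}

#' mRNA-to-protein acrophase lag distribution
#'
#' For genes rhythmic in both layers, the lag is the protein acrophase minus
#' the mRNA acrophase mapped to `[0, 24)` (a protein peaking 20 h "late" is
#' reported as 20, not -4). Summaries are the median lag and the fraction of
#' lags in the 2-8 h window typical of translation/turnover delays.
#'
#' @param fits_mrna,fits_protein [fit_all()] tables with shared gene ids.
#' @param q_threshold Rhythmicity cutoff for both layers.
#' @return List with `table` (`feature_id`, `phase_mrna`, `phase_protein`,
#'   `lag_hours`) and `summary` (`n`, `median_lag`, `fraction_2_8`).
#' @export
mrna_protein_lag <- function(fits_mrna, fits_protein, q_threshold = 0.05) {
  rm_ <- fits_mrna[fits_mrna$q_value < q_threshold, c("feature_id", "acrophase")]
  rp <- fits_protein[fits_protein$q_value < q_threshold,
                     c("feature_id", "acrophase")]
  shared <- intersect(rm_$feature_id, rp$feature_id)
  tab <- data.frame(feature_id = shared,
                    phase_mrna = rm_$acrophase[match(shared, rm_$feature_id)],
                    phase_protein = rp$acrophase[match(shared, rp$feature_id)])
  if (!nrow(tab)) {
    return(list(table = tab,
                summary = data.frame(n = 0, median_lag = NA_real_,
                                     fraction_2_8 = NA_real_)))
  }
  tab$lag_hours <- (tab$phase_protein - tab$phase_mrna) %% 24
  list(table = tab,
       summary = data.frame(n = nrow(tab),
                            median_lag = stats::median(tab$lag_hours),
                            fraction_2_8 = mean(tab$lag_hours >= 2 &
                                                  tab$lag_hours <= 8)))
}
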