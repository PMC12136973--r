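#' Xanthophyll de-epoxidation state
#'
#' `DES = (0.5 * antheraxanthin + zeaxanthin) / (violaxanthin +
#' antheraxanthin + zeaxanthin)`, the standard index of xanthophyll-cycle
#' activation: 0 when the pool is fully epoxidized (all Vio), 1 when fully
#' de-epoxidized (all Zea). Scale-invariant and bounded in `[0, 1]`.
#' A zero pigment pool leaves the index undefined (`NA` with a warning).
#'
#' @param vio,anthera,zea Pigment contents (same unit, e.g. pmol per 10^6
#'   cells), nonnegative; vectorized.
#' @return DES in `[0, 1]`, `NA` where the pool is zero.
#' @examples
#' de_epoxidation_state(1, 1, 1)  # 0.5
#' @export
de_epoxidation_state <- function(vio, anthera, zea) {
  if (any(c(vio, anthera, zea) < 0, na.rm = TRUE))
    stop("pigment contents must be nonnegative", call. = FALSE)
  pool <- vio + anthera + zea
  out <- ifelse(pool > 0, (0.5 * anthera + zea) / pool, NA_real_)
  if (any(pool == 0, na.rm = TRUE))
    warning("zero xanthophyll pool: DES undefined for ",
            sum(pool == 0, na.rm = TRUE), " record(s)", call. = FALSE)
  out
}

#' Stacking repeat distance of appressed thylakoid membranes
#'
#' `SRD = stack height / number of membrane layers` (nm per layer), defined
#' only for stacked membranes (2 or more layers); single membranes give
#' `NA`. Larger SRD means looser stacking.
#'
#' @param height Stack heights in nm, > 0.
#' @param layers Integer layer counts, >= 1.
#' @return SRD in nm, `NA` where `layers < 2`.
#' @examples
#' srd(800, 4)  # 200
#' @export
srd <- function(height, layers) {
  if (any(height <= 0, na.rm = TRUE))
    stop("stack height must be positive", call. = FALSE)
  if (any(layers < 1, na.rm = TRUE))
    stop("layer count must be >= 1", call. = FALSE)
  ifelse(layers >= 2, height / layers, NA_real_)
}

#' Maximum photochemical efficiency of PSII
#'
#' `Fv/Fm = (Fm - F0) / Fm` on dark-adapted cells; dimensionless and
#' invariant to fluorescence-unit rescaling.
#'
#' @param f0 Initial fluorescence of dark-adapted cells, > 0.
#' @param fm Maximum fluorescence after a saturating pulse, >= `f0`.
#' @return Value in `[0, 1)`.
#' @examples
#' fv_over_fm(0.3, 1.0)  # 0.7
#' @export
fv_over_fm <- function(f0, fm) {
  if (any(f0 <= 0 | fm <= 0, na.rm = TRUE))
    stop("fluorescence values must be positive", call. = FALSE)
  if (any(f0 > fm, na.rm = TRUE))
    stop("F0 > Fm: instrument artifact, not computable", call. = FALSE)
  (fm - f0) / fm
}

#' Non-photochemical quenching
#'
#' `NPQ = (Fm - Fm') / Fm'` where `Fm'` is the light-adapted maximum
#' fluorescence under actinic light. `Fm' > Fm` is rejected (flagged, not
#' silently clipped).
#'
#' @param fm Dark-adapted maximum fluorescence, > 0.
#' @param fm_prime Light-adapted maximum fluorescence, `0 < Fm' <= Fm`.
#' @return NPQ >= 0.
#' @examples
#' npq(1.0, 0.5)  # 1
#' @export
npq <- function(fm, fm_prime) {
  if (any(fm_prime <= 0, na.rm = TRUE))
    stop("Fm' must be positive", call. = FALSE)
  if (any(fm_prime > fm, na.rm = TRUE))
    stop("Fm' exceeds Fm: flagged as an instrument artifact", call. = FALSE)
  (fm - fm_prime) / fm_prime
}

#' PSI/PSII ratio from a 77 K fluorescence emission spectrum
#'
#' Normalizes the spectrum to the maximum in the PSII window (defaults to
#' 680-690 nm, around the ~684 nm PSII peak), then reports the ratio of the
#' peak intensity in the PSI window (705-720 nm, around ~711 nm) to the
#' PSII peak. Windowed maxima are used rather than fixed wavelengths
#' because instrument calibration shifts peak positions; a window with no
#' sampled wavelength falls back to the nearest wavelength with a warning.
#'
#' @param wavelength Wavelengths in nm covering 650-780.
#' @param intensity Matching fluorescence intensities.
#' @param psii_window,psi_window Length-2 numeric windows in nm.
#' @return Positive ratio (1 for a flat spectrum).
#' @export
psi_psii_ratio <- function(wavelength, intensity,
                           psii_window = c(680, 690),
                           psi_window = c(705, 720)) {
  stopifnot(length(wavelength) == length(intensity))
  if (min(wavelength) > 650 || max(wavelength) < 780)
    stop("spectrum must cover 650-780 nm", call. = FALSE)
  window_max <- function(win, name) {
    sel <- wavelength >= win[1] & wavelength <= win[2]
    if (!any(sel)) {
      warning("no sampled wavelength in the ", name,
              " window; using the nearest wavelength", call. = FALSE)
      sel <- which.min(pmin(abs(wavelength - win[1]), abs(wavelength - win[2])))
    }
    max(intensity[sel], na.rm = TRUE)
  }
  f_psii <- window_max(psii_window, "PSII")
  f_psi <- window_max(psi_window, "PSI")
  # normalization to the PSII maximum cancels in the ratio but is applied
  # so single-window intensities are also reported on the conventional scale
  (f_psi / f_psii)
}

#' Per-state summaries of physiology measurement tables
#'
#' Tidy descriptive summary keyed by (condition, timepoint): mean, SD and n
#' per value column, with an optional one-way ANOVA p-value across
#' conditions within each timepoint. The heavier post-hoc battery
#' (Tukey/Games-Howell/Dunn) is deliberately out of scope; qualitative
#' orderings can be asserted on the means.
#'
#' @param tab `data.frame` with `condition`, `timepoint_label` and numeric
#'   measurement columns; one row per replicate measurement.
#' @param value_cols Names of the measurement columns to summarize
#'   (default: all numeric columns other than `replicate`/`zt_hours`).
#' @param anova Also compute a one-way ANOVA p-value of condition within
#'   each timepoint for each measurement (needs >= 2 replicates per state).
#' @return `data.frame` in long form: `condition`, `timepoint_label`,
#'   `variable`, `mean`, `sd`, `n` (+ `anova_p` per timepoint when
#'   requested).
#' @export
summarize_physio <- function(tab, value_cols = NULL, anova = FALSE) {
  tab$timepoint_label <- normalize_label(tab$timepoint_label)
  if (is.null(value_cols)) {
    num <- vapply(tab, is.numeric, TRUE)
    value_cols <- setdiff(names(tab)[num], c("replicate", "zt_hours"))
  }
  out <- do.call(rbind, lapply(value_cols, function(v) {
    agg <- stats::aggregate(tab[[v]],
                            by = list(condition = tab$condition,
                                      timepoint_label = tab$timepoint_label),
                            FUN = function(x) c(mean = mean(x, na.rm = TRUE),
                                                sd = stats::sd(x),
                                                n = sum(!is.na(x))))
    data.frame(condition = agg$condition,
               timepoint_label = agg$timepoint_label, variable = v,
               mean = agg$x[, "mean"], sd = agg$x[, "sd"],
               n = as.integer(agg$x[, "n"]))
  }))
  if (anova) {
    out$anova_p <- NA_real_
    for (v in value_cols) for (tp in unique(out$timepoint_label)) {
      sub <- tab[tab$timepoint_label == tp, ]
      if (length(unique(sub$condition)) < 2) next
      p <- tryCatch(
        summary(stats::aov(sub[[v]] ~ factor(sub$condition)))[[1]][
          "factor(sub$condition)", "Pr(>F)"],
        error = function(e) NA_real_)
      out$anova_p[out$variable == v & out$timepoint_label == tp] <- p
    }
  }
  rownames(out) <- NULL
  out
}

#' Derived pigment indices for a pigment table
#'
#' Adds the xanthophyll de-epoxidation state (`des`) and the Chl a/b ratio
#' (`chl_ab`) rowwise to a pigment record table.
#'
#' @param pigments `data.frame` with columns `vio`, `anthera`, `zea`,
#'   `chl_a`, `chl_b` (plus sample keys).
#' @return The table with `des` and `chl_ab` columns appended.
#' @export
pigment_indices <- function(pigments) {
  pigments$des <- de_epoxidation_state(pigments$vio, pigments$anthera,
                                       pigments$zea)
  pigments$chl_ab <- pigments$chl_a / pigments$chl_b
  pigments
}
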