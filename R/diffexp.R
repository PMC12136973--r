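#' Benjamini-Hochberg adjustment with NA propagation
#'
#' Thin wrapper around `stats::p.adjust(method = "BH")`: `NA`/`NaN` entries
#' are propagated unchanged and excluded from the number of tests.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted p-values, clipped at 1, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Median-of-ratios size factors for a count matrix
#'
#' The classic normalization for negative-binomial count models: per sample,
#' the median ratio of its counts to the per-gene geometric mean, computed
#' over genes with nonzero counts in every sample. When no gene is nonzero
#' everywhere, falls back to library-size ratios with a warning.
#'
#' @param counts Gene x sample matrix of nonnegative counts.
#' @return Positive numeric vector of per-sample scale factors
#'   (geometric mean 1 in the fallback branch; median-ratio scale otherwise).
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    warning("no gene with nonzero counts in all samples; ",
            "using library-size ratios", call. = FALSE)
    libs <- colSums(counts)
    return(libs / exp(mean(log(libs))))
  }
  logc <- log(counts[all_pos, , drop = FALSE])
  log_geo <- rowMeans(logc)
  apply(exp(sweep(logc, 1, log_geo)), 2, stats::median)
}

#' Simplified negative-binomial Wald test for one contrast
#'
#' Tests one light condition against the control at a single timepoint.
#' Counts are normalized by median-of-ratios size factors; gene-wise
#' dispersion is estimated by method of moments from within-group variances
#' and moderated towards the across-gene median (no shrinkage towards a
#' mean-dispersion trend, no independent filtering). The Wald statistic is
#' the log2 fold change of normalized group means (with pseudocount)
#' divided by its delta-method standard error under the NB variance
#' `mu + alpha * mu^2`; p-values are two-sided normal and BH-adjusted
#' across genes within the contrast.
#'
#' @param counts Gene x sample matrix of nonnegative integer counts
#'   (an `omics_matrix` of layer `"mrna"` is also accepted).
#' @param design Sample design (taken from the `omics_matrix` if given).
#' @param test_condition Condition tested (e.g. `"HL"` or `"LL"`).
#' @param timepoint Timepoint label of the contrast.
#' @param control_condition Reference condition (default `"ML"`).
#' @param pseudocount Added to normalized means before log2 (default 0.5).
#' @return `data.frame` per gene: `feature_id`, `base_mean`, `log2fc`,
#'   `stat`, `p_value`, `p_adj`, `evaluable` (FALSE for all-zero genes,
#'   whose statistics are `NA`).
#' @export
nb_wald_test <- function(counts, design = NULL, test_condition, timepoint,
                         control_condition = "ML", pseudocount = 0.5) {
  if (inherits(counts, "omics_matrix")) {
    design <- counts$design
    counts <- counts$values
  }
  if (is.null(design)) stop("design required", call. = FALSE)
  design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  tp <- normalize_label(timepoint)
  sel_t <- design$condition == test_condition & design$timepoint_label == tp
  sel_c <- design$condition == control_condition & design$timepoint_label == tp
  if (!any(sel_t) || !any(sel_c))
    stop("no samples for contrast ", test_condition, " vs ",
         control_condition, " at ", tp, call. = FALSE)
  sub <- counts[, sel_t | sel_c, drop = FALSE]
  grp <- sel_t[sel_t | sel_c]

  sf <- size_factors(sub)
  norm <- sweep(sub, 2, sf, "/")
  nt <- sum(grp); nc <- sum(!grp)
  mt <- rowMeans(norm[, grp, drop = FALSE])
  mc <- rowMeans(norm[, !grp, drop = FALSE])
  vt <- apply(norm[, grp, drop = FALSE], 1, stats::var)
  vc <- apply(norm[, !grp, drop = FALSE], 1, stats::var)

  # method-of-moments dispersion, averaged over groups and floored;
  # moderation towards the across-gene median guards against the
  # small-sample variance collapse that makes Wald statistics explode
  amt <- ifelse(mt > 0, (vt - mt) / mt^2, NA)
  amc <- ifelse(mc > 0, (vc - mc) / mc^2, NA)
  alpha_g <- pmax(rowMeans(cbind(amt, amc), na.rm = TRUE), 0)
  alpha_g[is.nan(alpha_g)] <- 0
  alpha_med <- stats::median(alpha_g[mt + mc > 0], na.rm = TRUE)
  alpha <- pmax(alpha_g, alpha_med, 1e-8)

  lfc <- log2(mt + pseudocount) - log2(mc + pseudocount)
  se_t <- sqrt((mt + alpha * mt^2) / nt) / ((mt + pseudocount) * log(2))
  se_c <- sqrt((mc + alpha * mc^2) / nc) / ((mc + pseudocount) * log(2))
  se <- sqrt(se_t^2 + se_c^2)
  stat <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * stats::pnorm(-abs(stat))

  evaluable <- (mt + mc) > 0
  lfc[!evaluable] <- NA; stat[!evaluable] <- NA; p[!evaluable] <- NA
  out <- data.frame(feature_id = rownames(sub),
                    base_mean = (mt + mc) / 2,
                    log2fc = lfc, stat = stat, p_value = p,
                    p_adj = bh_adjust(p), evaluable = evaluable,
                    row.names = NULL)
  attr(out, "contrast") <- c(test = test_condition,
                             control = control_condition, timepoint = tp)
  out
}

#' Apply the transcript call thresholds to NB test results
#'
#' A gene is `up` when `log2fc > lfc_threshold` and `p_adj < alpha`, `down`
#' when `log2fc < -lfc_threshold` and `p_adj < alpha`, otherwise
#' `unchanged`; genes that were not evaluable stay `not_evaluable`.
#'
#' @param results Output of [nb_wald_test()].
#' @param lfc_threshold Absolute log2 fold-change gate (default 1).
#' @param alpha Adjusted p-value gate (default 0.01).
#' @return `results` with a `call` factor column added.
#' @export
call_mrna_de <- function(results, lfc_threshold = 1, alpha = 0.01) {
  call <- rep("unchanged", nrow(results))
  call[!results$evaluable] <- "not_evaluable"
  ok <- results$evaluable & !is.na(results$p_adj)
  call[ok & results$log2fc > lfc_threshold & results$p_adj < alpha] <- "up"
  call[ok & results$log2fc < -lfc_threshold & results$p_adj < alpha] <- "down"
  results$call <- factor(call, levels = c("up", "down", "unchanged",
                                          "not_evaluable"))
  results
}

#' Protein differential-abundance calls by fold-change Z-score
#'
#' Per protein, the log2 fold change of the replicate-averaged abundances
#' (test over control) is standardised against the distribution of fold
#' changes across all proteins in the contrast. Calls are `up` for `Z > 2`,
#' `down` for `Z < -2`, gated by the limit of quantitation: a protein whose
#' mean abundance in either arm is at or below `loq` is `not_evaluable`.
#' The LOQ gate vetoes the final call only; all finite fold changes stay in
#' the Z distribution (set `trim_below_loq = TRUE` to trim them instead).
#'
#' @param mean_test,mean_ctrl Named numeric vectors of per-protein mean
#'   abundances (linear scale) in the test and control populations.
#' @param loq Limit of quantitation on the abundance scale. Default `NULL`
#'   uses the 1st percentile of the finite control means.
#' @param z_threshold Z cutoff (default 2 SD).
#' @param trim_below_loq Exclude LOQ-failing proteins from the Z
#'   distribution as well as from calling (default FALSE).
#' @return `data.frame`: `feature_id`, `mean_test`, `mean_ctrl`, `log2fc`,
#'   `z`, `call`.
#' @export
protein_zscore_calls <- function(mean_test, mean_ctrl, loq = NULL,
                                 z_threshold = 2, trim_below_loq = FALSE) {
  stopifnot(length(mean_test) == length(mean_ctrl))
  ids <- names(mean_test)
  if (is.null(ids)) ids <- paste0("protein_", seq_along(mean_test))
  if (is.null(loq))
    loq <- stats::quantile(mean_ctrl[is.finite(mean_ctrl) & mean_ctrl > 0],
                           0.01, names = FALSE)

  lfc <- ifelse(is.finite(mean_test) & is.finite(mean_ctrl) &
                  mean_test > 0 & mean_ctrl > 0,
                log2(mean_test) - log2(mean_ctrl), NA_real_)
  above_loq <- is.finite(mean_test) & is.finite(mean_ctrl) &
    mean_test > loq & mean_ctrl > loq
  pool <- if (trim_below_loq) is.finite(lfc) & above_loq else is.finite(lfc)

  mu <- mean(lfc[pool])
  sdev <- stats::sd(lfc[pool])
  if (is.na(sdev) || sdev == 0) {
    warning("fold-change SD is zero; no protein can be called", call. = FALSE)
    z <- rep(NA_real_, length(lfc))
  } else {
    z <- (lfc - mu) / sdev
  }

  call <- rep("unchanged", length(lfc))
  call[!above_loq | is.na(lfc)] <- "not_evaluable"
  ok <- above_loq & !is.na(z)
  call[ok & z > z_threshold] <- "up"
  call[ok & z < -z_threshold] <- "down"
  data.frame(feature_id = ids, mean_test = unname(mean_test),
             mean_ctrl = unname(mean_ctrl), log2fc = unname(lfc),
             z = unname(z),
             call = factor(call, levels = c("up", "down", "unchanged",
                                            "not_evaluable")),
             row.names = NULL)
}

#' Replicate means of an abundance matrix per cellular state
#'
#' Convenience for the protein Z-score procedure and for clustering input:
#' averages replicates within each (condition, timepoint) state,
#' ignoring missing values.
#'
#' @param x An `omics_matrix`.
#' @param min_detected Minimum non-missing replicates for a state mean to be
#'   reported (default 1; states with fewer give `NA`).
#' @return Feature x state matrix; columns named `condition_timepoint`.
#' @export
state_means <- function(x, min_detected = 1) {
  stopifnot(inherits(x, "omics_matrix"))
  d <- x$design
  key <- paste(d$condition, d$timepoint_label, sep = "_")
  states <- unique(key)
  out <- vapply(states, function(s) {
    cols <- x$values[, key == s, drop = FALSE]
    n_ok <- rowSums(!is.na(cols))
    m <- rowMeans(cols, na.rm = TRUE)
    m[n_ok < min_detected] <- NA_real_
    m
  }, numeric(nrow(x$values)))
  colnames(out) <- states
  out
}
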