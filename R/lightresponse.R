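# Sampled diurnal grid pairs exactly 4 h apart (by ZT): 22->2, 2->6,
# 6->10, 10->14. The 14->22 night gap is 8 h and is never treated as a lag
# step. Stored as label pairs for direct lookup.
LAG4_NEXT <- c("-2" = "+2", "+2" = "+6", "+6" = "+10", "+10" = "-10")

#' Classify one gene/timepoint pair of calls as core light-specific
#'
#' A change is "core" to the high-light population when it is specific to
#' that population relative to the control: `core_up` when the HL call is
#' `up` while the LL call is `unchanged` or `down`, `core_down` when the HL
#' call is `down` while the LL call is `unchanged` or `up`. Changes shared
#' by both populations (same direction in HL and LL) are attributed to
#' productivity/synchrony differences and are `not_core`.
#'
#' `not_evaluable` inputs are treated as `unchanged` by default; with
#' `strict = TRUE` any `not_evaluable` input forces `not_core`.
#'
#' @param call_hl,call_ll Character/factor vectors of calls
#'   (`up`, `down`, `unchanged`, `not_evaluable`), aligned by gene.
#' @param strict Drop pairs with a `not_evaluable` member instead of
#'   treating them as unchanged.
#' @return Factor with levels `core_up`, `core_down`, `not_core`.
#' @export
classify_core <- function(call_hl, call_ll, strict = FALSE) {
  stopifnot(length(call_hl) == length(call_ll))
  hl <- as.character(call_hl)
  ll <- as.character(call_ll)
  ne <- hl == "not_evaluable" | ll == "not_evaluable"
  if (!strict) {
    hl[hl == "not_evaluable"] <- "unchanged"
    ll[ll == "not_evaluable"] <- "unchanged"
  }
  out <- rep("not_core", length(hl))
  out[hl == "up" & ll %in% c("unchanged", "down")] <- "core_up"
  out[hl == "down" & ll %in% c("unchanged", "up")] <- "core_down"
  if (strict) out[ne] <- "not_core"
  factor(out, levels = c("core_up", "core_down", "not_core"))
}

#' Core classification across timepoints and layers
#'
#' Joins per-timepoint HL-vs-control and LL-vs-control call tables for one
#' layer and classifies each gene at each timepoint with [classify_core()].
#'
#' @param calls_hl,calls_ll `data.frame`s with columns `feature_id`,
#'   `timepoint_label`, `call` (e.g. stacked [call_mrna_de()] outputs).
#' @param layer Layer tag recorded in the output.
#' @param strict Passed to [classify_core()].
#' @return `data.frame`: `feature_id`, `layer`, `timepoint_label`,
#'   `core_call`.
#' @export
classify_core_table <- function(calls_hl, calls_ll, layer = "mrna",
                                strict = FALSE) {
  key_hl <- paste(calls_hl$feature_id, calls_hl$timepoint_label)
  key_ll <- paste(calls_ll$feature_id, calls_ll$timepoint_label)
  shared <- intersect(key_hl, key_ll)
  if (!length(shared)) stop("no shared (gene, timepoint) keys", call. = FALSE)
  i <- match(shared, key_hl); j <- match(shared, key_ll)
  data.frame(feature_id = calls_hl$feature_id[i], layer = layer,
             timepoint_label = calls_hl$timepoint_label[i],
             core_call = classify_core(calls_hl$call[i], calls_ll$call[j],
                                       strict = strict),
             row.names = NULL)
}

#' Gene-level union of core calls over timepoints and layers
#'
#' Deduplicates by gene: a gene is in the core list if it has a core call
#' (either direction) in any layer at any timepoint. Provenance records
#' which layer/timepoint combinations contributed.
#'
#' @param core_tables A `data.frame` from [classify_core_table()] or a list
#'   of such tables (e.g. one per layer), row-bound internally.
#' @return `data.frame`: `feature_id`, `n_events`, `provenance`
#'   (semicolon-joined `layer:timepoint:direction` tokens).
#' @export
core_union <- function(core_tables) {
  if (is.data.frame(core_tables)) core_tables <- list(core_tables)
  tab <- do.call(rbind, core_tables)
  hits <- tab[tab$core_call != "not_core", , drop = FALSE]
  if (!nrow(hits)) {
    return(data.frame(feature_id = character(0), n_events = integer(0),
                      provenance = character(0)))
  }
  prov <- paste(hits$layer, hits$timepoint_label, hits$core_call, sep = ":")
  agg <- split(prov, hits$feature_id)
  data.frame(feature_id = names(agg),
             n_events = lengths(agg),
             provenance = vapply(agg, paste, "", collapse = ";"),
             row.names = NULL)
}

#' Fraction of responses that are constitutive across the diurnal cycle
#'
#' A gene's response to a light regime is *constitutive* when it is
#' significant in the same direction at all five sampled timepoints;
#' the denominator is every gene significant (either direction) at one or
#' more timepoints. With `direction_free = TRUE` the direction-consistency
#' requirement is dropped.
#'
#' @param calls `data.frame` with `feature_id`, `timepoint_label`, `call`
#'   covering every timepoint in `timepoints` for each gene.
#' @param timepoints Timepoint labels required (study default: all five).
#' @param direction_free Count a gene significant at all timepoints as
#'   constitutive regardless of direction.
#' @return List: `fraction`, `constitutive_genes`, `responsive_genes`,
#'   `n_constitutive`, `n_responsive`.
#' @export
constitutive_fraction <- function(calls, timepoints = TIMEPOINT_LABELS,
                                  direction_free = FALSE) {
  timepoints <- normalize_label(timepoints)
  present <- unique(normalize_label(calls$timepoint_label))
  miss <- setdiff(timepoints, present)
  if (length(miss))
    stop("missing timepoint(s): ", paste(miss, collapse = ", "), call. = FALSE)

  calls$timepoint_label <- normalize_label(calls$timepoint_label)
  calls <- calls[calls$timepoint_label %in% timepoints, , drop = FALSE]
  by_gene <- split(as.character(calls$call), calls$feature_id)

  sig <- function(x) x %in% c("up", "down")
  responsive <- names(by_gene)[vapply(by_gene, function(x) any(sig(x)), TRUE)]
  constitutive <- names(by_gene)[vapply(by_gene, function(x) {
    if (length(x) < length(timepoints) || !all(sig(x))) return(FALSE)
    direction_free || length(unique(x)) == 1
  }, TRUE)]

  list(fraction = if (length(responsive)) length(constitutive) /
         length(responsive) else NA_real_,
       constitutive_genes = constitutive, responsive_genes = responsive,
       n_constitutive = length(constitutive), n_responsive = length(responsive))
}

#' mRNA-protein concordance of differential calls with a 4-h lag rule
#'
#' A differential event is a significant call (`up`/`down`) for one gene at
#' one timepoint in one layer. An mRNA event is *matched* when the protein
#' layer shows a same-direction call at the same timepoint (simultaneous)
#' or at the next sampled timepoint exactly 4 h later (pairs on the ZT
#' grid: 22->2, 2->6, 6->10, 10->14; the 8-h night gap 14->22 never
#' matches). A protein event is matched by the mirror-image rules. The
#' summary fraction is matched events over all events in both layers.
#'
#' @param mrna_calls,protein_calls `data.frame`s with `feature_id`,
#'   `timepoint_label`, `call` for all five timepoints.
#' @return List: `table` (`feature_id`, `timepoint_label`, `layer`,
#'   `direction`, `concordance` in
#'   `simultaneous`/`lagged_4h`/`mrna_only`/`protein_only`) and `summary`
#'   (`n_events`, `n_matched`, `fraction_both_levels`).
#' @export
concordance_with_lag <- function(mrna_calls, protein_calls) {
  norm_tab <- function(tab) {
    tab$timepoint_label <- normalize_label(tab$timepoint_label)
    tab$call <- as.character(tab$call)
    tab[tab$call %in% c("up", "down"), c("feature_id", "timepoint_label",
                                         "call"), drop = FALSE]
  }
  m <- norm_tab(mrna_calls)
  p <- norm_tab(protein_calls)
  mk <- function(tab) paste(tab$feature_id, tab$timepoint_label, tab$call)
  m_key <- mk(m); p_key <- mk(p)

  lag_key_fwd <- paste(m$feature_id, LAG4_NEXT[m$timepoint_label], m$call)
  m_conc <- ifelse(m_key %in% p_key, "simultaneous",
                   ifelse(!is.na(LAG4_NEXT[m$timepoint_label]) &
                            lag_key_fwd %in% p_key, "lagged_4h", "mrna_only"))

  prev_of <- stats::setNames(names(LAG4_NEXT), LAG4_NEXT)
  lag_key_bwd <- paste(p$feature_id, prev_of[p$timepoint_label], p$call)
  p_conc <- ifelse(p_key %in% m_key, "simultaneous",
                   ifelse(!is.na(prev_of[p$timepoint_label]) &
                            lag_key_bwd %in% m_key, "lagged_4h",
                          "protein_only"))

  tab <- rbind(
    data.frame(feature_id = m$feature_id, timepoint_label = m$timepoint_label,
               layer = "mrna", direction = m$call, concordance = m_conc),
    data.frame(feature_id = p$feature_id, timepoint_label = p$timepoint_label,
               layer = "protein", direction = p$call, concordance = p_conc))
  rownames(tab) <- NULL
  matched <- tab$concordance %in% c("simultaneous", "lagged_4h")
  list(table = tab,
       summary = data.frame(n_events = nrow(tab), n_matched = sum(matched),
                            fraction_both_levels = if (nrow(tab))
                              mean(matched) else NA_real_))
}
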