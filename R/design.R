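#' @keywords internal
"_PACKAGE"

# Canonical study labels: hours relative to the dark-to-light transition
# under a 12 h light : 12 h dark cycle. "-10" (ZT14) precedes "-2" (ZT22)
# within one night, so chronology must use ZT, never label order.
TIMEPOINT_LABELS <- c("-2", "+2", "+6", "+10", "-10")
CONDITIONS <- c("LL", "ML", "HL")
OMICS_LAYERS <- c("mrna", "protein", "lipid", "pigment")

# Unicode minus (U+2212) appears in hand-edited sample sheets; fold it to
# the ASCII hyphen before any label arithmetic.
normalize_label <- function(label) {
  gsub("−", "-", trimws(as.character(label)))
}

#' Zeitgeber time of a diurnal timepoint label
#'
#' Timepoints are labelled relative to the dark-to-light transition (ZT0):
#' `"+k"` means k hours after lights-on, `"-k"` means k hours before the
#' *next* lights-on, i.e. ZT `24 - k`. Under the 12:12 cycle the five study
#' labels `-2, +2, +6, +10, -10` map to ZT 22, 2, 6, 10, 14, so their
#' chronological order within one cycle is `+2, +6, +10, -10, -2`.
#'
#' @param label Character vector of timepoint labels; both the ASCII hyphen
#'   and the Unicode minus sign are accepted.
#' @return Numeric vector of ZT hours in `[0, 24)`.
#' @examples
#' zt_of_label(c("+6", "-10", "-2"))  # 6 14 22
#' @export
zt_of_label <- function(label) {
  lab <- normalize_label(label)
  bad <- !(lab %in% TIMEPOINT_LABELS)
  if (any(bad)) {
    stop("unknown timepoint label(s): ",
         paste(unique(lab[bad]), collapse = ", "), call. = FALSE)
  }
  k <- as.numeric(sub("^[+-]", "", lab))
  ifelse(substr(lab, 1, 1) == "+", k, 24 - k)
}

#' Build a full-factorial diurnal sample design
#'
#' Expands conditions x timepoints x replicates into a sample sheet with one
#' row per sample, in a deterministic order (condition outermost, then
#' timepoint in the supplied order, then replicate). ZT hours are derived
#' from the timepoint labels.
#'
#' @param conditions Character vector of light regimes (default LL, ML, HL).
#' @param timepoint_labels Character vector of timepoint labels.
#' @param n_replicates Number of replicates per cellular state (>= 1).
#' @return A `data.frame` of class `sample_design` with columns `sample_id`,
#'   `condition`, `timepoint_label`, `zt_hours`, `replicate`.
#' @examples
#' d <- build_design()
#' nrow(d)                                   # 45 samples
#' nrow(unique(d[, c("condition", "timepoint_label")]))  # 15 states
#' @export
build_design <- function(conditions = CONDITIONS,
                         timepoint_labels = TIMEPOINT_LABELS,
                         n_replicates = 3) {
  if (length(conditions) == 0 || length(timepoint_labels) == 0)
    stop("conditions and timepoint_labels must be nonempty", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  if (anyDuplicated(conditions))
    stop("duplicate conditions not allowed", call. = FALSE)
  tp <- normalize_label(timepoint_labels)
  if (anyDuplicated(tp))
    stop("duplicate timepoint labels not allowed", call. = FALSE)
  zt <- zt_of_label(tp)

  d <- expand.grid(replicate = seq_len(n_replicates),
                   timepoint_label = tp,
                   condition = conditions,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d <- d[, c("condition", "timepoint_label", "replicate")]
  d$zt_hours <- zt[match(d$timepoint_label, tp)]
  d$sample_id <- paste(d$condition, d$timepoint_label, d$replicate, sep = "_")
  d <- d[, c("sample_id", "condition", "timepoint_label", "zt_hours", "replicate")]
  rownames(d) <- NULL
  class(d) <- c("sample_design", "data.frame")
  d
}

validate_design <- function(design) {
  stopifnot(is.data.frame(design))
  needed <- c("sample_id", "condition", "timepoint_label", "zt_hours", "replicate")
  missing_cols <- setdiff(needed, names(design))
  if (length(missing_cols))
    stop("design is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample ids in design", call. = FALSE)
  key <- paste(design$condition, design$timepoint_label, design$replicate)
  if (anyDuplicated(key))
    stop("duplicate (condition, timepoint, replicate) triples in design",
         call. = FALSE)
  invisible(design)
}

#' Construct a feature-by-sample abundance matrix for one molecular layer
#'
#' @param values Numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids present in `design`).
#'   Missing measurements are `NA`; raw abundances must be nonnegative.
#' @param layer One of `"mrna"`, `"protein"`, `"lipid"`, `"pigment"`.
#' @param design A `sample_design` covering every column.
#' @param unit Free-text unit label (e.g. `"FPKM"`, `"reporter-intensity"`).
#' @return An object of class `omics_matrix`: a list with elements `values`,
#'   `layer`, `unit`, `design` (design subset matching the columns, in
#'   column order).
#' @export
omics_matrix <- function(values, layer, design, unit = "") {
  layer <- match.arg(layer, OMICS_LAYERS)
  validate_design(design)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("feature ids (rownames) must be present and unique", call. = FALSE)
  if (is.null(colnames(values)))
    stop("sample ids (colnames) must be present", call. = FALSE)
  unknown <- setdiff(colnames(values), design$sample_id)
  if (length(unknown))
    stop("sample id(s) not in design: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (any(values < 0, na.rm = TRUE))
    stop("negative abundance values in raw layer '", layer, "'", call. = FALSE)
  structure(list(values = values, layer = layer, unit = unit,
                 design = design[match(colnames(values), design$sample_id), ,
                                 drop = FALSE]),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s, unit=%s]: %d features x %d samples (%d NA)\n",
              x$layer, x$unit, nrow(x$values), ncol(x$values),
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Read an abundance matrix from delimited text
#'
#' First column holds feature ids, remaining columns are samples named in
#' the header. Empty cells and `NA` tokens are preserved as missing values,
#' never coerced to zero.
#'
#' @param path File path of a TSV (default) or CSV matrix.
#' @param layer Molecular layer of the matrix.
#' @param design A `sample_design`; every sample column must map to a row.
#' @param sep Field separator, `"\t"` by default; pass `","` for CSV.
#' @param unit Unit label stored on the result.
#' @return An `omics_matrix`.
#' @export
load_matrix <- function(path, layer, design, sep = "\t", unit = "") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), quote = "")
  if (anyDuplicated(df[[1]]))
    stop("duplicated feature ids in ", path, call. = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  mode(values) <- "numeric"
  rownames(values) <- as.character(df[[1]])
  m <- omics_matrix(values, layer = layer, design = design, unit = unit)
  message(sprintf("loaded %s matrix: %d features x %d samples from %s",
                  layer, nrow(values), ncol(values), path))
  m
}

#' Write an abundance matrix as delimited text
#'
#' Inverse of [load_matrix()]: finite entries round-trip bit-exactly
#' (full-precision formatting) and missing values are written as `NA`.
#'
#' @param x An `omics_matrix` or a numeric matrix with dimnames.
#' @param path Output file path.
#' @param sep Field separator.
#' @export
write_matrix <- function(x, path, sep = "\t") {
  values <- if (inherits(x, "omics_matrix")) x$values else x
  df <- data.frame(feature_id = rownames(values),
                   format(values, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  # format() stringifies NA as "NA" which read.table maps back to NA
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature annotation table
#'
#' Expects columns `feature_id`, `compartment` (nucleus / chloroplast /
#' mitochondrion), optional `symbol`, and optional `terms` with
#' semicolon-separated term ids.
#'
#' @param path TSV file path.
#' @return A `data.frame` with a `term_list` list-column of term id vectors.
#' @export
load_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          quote = "")
  if (!all(c("feature_id", "compartment") %in% names(df)))
    stop("annotation must have feature_id and compartment columns",
         call. = FALSE)
  if (anyDuplicated(df$feature_id))
    stop("duplicated feature ids in annotation", call. = FALSE)
  df$term_list <- if ("terms" %in% names(df)) {
    lapply(strsplit(ifelse(is.na(df$terms), "", df$terms), ";", fixed = TRUE),
           function(x) x[nzchar(x)])
  } else {
    rep(list(character(0)), nrow(df))
  }
  df
}

#' Log2-transform an abundance matrix with an explicit pseudocount
#'
#' @param x An `omics_matrix` or numeric matrix.
#' @param pseudocount Added before taking log2 (default 1, suited to
#'   FPKM-like values; the offset is a user decision, not inferred).
#' @return Numeric matrix of log2 values (NA preserved).
#' @export
log2_transform <- function(x, pseudocount = 1) {
  values <- if (inherits(x, "omics_matrix")) x$values else x
  log2(values + pseudocount)
}
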