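#' Row-wise Z-score normalization of a profile matrix
#'
#' Each feature's profile (e.g. per-state means) is centred to mean 0 and
#' scaled to SD 1. Constant rows cannot be scaled and are removed; their ids
#' are returned in the `"excluded"` attribute.
#'
#' @param x Numeric matrix, features in rows.
#' @return Z-scored matrix (possibly with fewer rows).
#' @export
zscore_by_feature <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need >= 2 states per feature", call. = FALSE)
  mu <- rowMeans(x)
  sdev <- apply(x, 1, stats::sd)
  keep <- is.finite(sdev) & sdev > 0 & rowSums(!is.finite(x)) == 0
  z <- (x[keep, , drop = FALSE] - mu[keep]) / sdev[keep]
  attr(z, "excluded") <- rownames(x)[!keep]
  z
}

# k-means++ seeding: first centre uniform, then each subsequent centre
# sampled with probability proportional to squared distance to the nearest
# chosen centre. Returns the centre matrix.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[idx[1], ], n, ncol(x), byrow = TRUE))^2)
  for (i in seq_len(k - 1) + 1) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx[i] <- sample.int(n, 1, prob = prob)
    d2 <- pmin(d2, rowSums((x - matrix(x[idx[i], ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  x[idx, , drop = FALSE]
}

#' k-means clustering of merged mRNA + protein z-score profiles
#'
#' Concatenates the per-gene mRNA and protein z-score blocks (genes present
#' and complete in both layers; others are dropped and listed in the
#' `"dropped"` attribute), seeds k-means++ under the given seed, and runs
#' `stats::kmeans`. Cluster labels are canonicalized by the column position
#' at which each cluster centre peaks (ties broken by cluster size), so the
#' numbering is comparable across runs.
#'
#' @param z_mrna,z_protein Z-scored feature x state matrices sharing gene
#'   ids in their rownames.
#' @param k Number of clusters (study default 16).
#' @param max_iter Maximum iterations (study default 1000).
#' @param seed Integer seed; required, making assignments reproducible.
#' @return `data.frame` with `gene_id`, `cluster_id`; attributes `centers`,
#'   `withinss`, `tot_withinss`, `dropped`.
#' @export
kmeans_merged <- function(z_mrna, z_protein, k = 16, max_iter = 1000, seed) {
  if (missing(seed)) stop("seed is required for clustering", call. = FALSE)
  shared <- intersect(rownames(z_mrna), rownames(z_protein))
  merged <- cbind(z_mrna[shared, , drop = FALSE],
                  z_protein[shared, , drop = FALSE])
  complete <- rowSums(!is.finite(merged)) == 0
  dropped <- union(setdiff(union(rownames(z_mrna), rownames(z_protein)),
                           shared), shared[!complete])
  merged <- merged[complete, , drop = FALSE]
  if (k > nrow(merged))
    stop("k = ", k, " exceeds the ", nrow(merged), " clusterable genes",
         call. = FALSE)

  set.seed(seed)
  init <- kmeanspp_centers(merged, k)
  km <- stats::kmeans(merged, centers = init, iter.max = max_iter)

  # canonical order: by peak column of the centre, then decreasing size
  peak <- apply(km$centers, 1, which.max)
  ord <- order(peak, -km$size)
  relabel <- match(seq_len(k), ord)
  out <- data.frame(gene_id = rownames(merged),
                    cluster_id = relabel[km$cluster], row.names = NULL)
  attr(out, "centers") <- km$centers[ord, , drop = FALSE]
  attr(out, "withinss") <- km$withinss[ord]
  attr(out, "tot_withinss") <- km$tot.withinss
  attr(out, "dropped") <- dropped
  out
}

#' Hypergeometric (upper-tail) term enrichment
#'
#' For each term set, the p-value is `P(X >= overlap)` for a hypergeometric
#' draw of `list_size` genes from a universe containing `term_size`
#' successes; BH adjustment is applied across terms. Term sets are first
#' intersected with the universe, and the gene list must be a subset of it.
#'
#' @param gene_list Character vector of genes of interest.
#' @param term_sets Named list of character vectors (term id -> gene ids).
#' @param universe Character vector of all detected genes.
#' @param p_cutoff Significance threshold reported in the `significant`
#'   column (default 0.05 on `p_adj`).
#' @return `data.frame`: `term_id`, `overlap`, `list_size`, `term_size`,
#'   `universe_size`, `gene_ratio`, `p`, `p_adj`, `significant`.
#' @export
hypergeom_enrich <- function(gene_list, term_sets, universe, p_cutoff = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  gene_list <- unique(gene_list)
  if (!all(gene_list %in% universe))
    stop("gene_list must be a subset of the universe", call. = FALSE)
  n <- length(gene_list)
  N <- length(universe)
  out <- do.call(rbind, lapply(names(term_sets), function(id) {
    term <- intersect(unique(term_sets[[id]]), universe)
    K <- length(term)
    k <- length(intersect(term, gene_list))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = id, overlap = k, list_size = n, term_size = K,
               universe_size = N, gene_ratio = if (n > 0) k / n else NA_real_,
               p = p)
  }))
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p_adj < p_cutoff
  rownames(out) <- NULL
  out[order(out$p), , drop = FALSE]
}

#' PCA of samples with a bottom-variance feature filter
#'
#' Removes the `var_filter` fraction of features with the lowest variance
#' (count = `floor(var_filter * n_features)`), then decomposes the
#' transposed matrix with `stats::prcomp`. Scaling is off by default
#' because inputs are already on comparable log/z scales at point of use.
#'
#' @param x Feature x sample numeric matrix.
#' @param var_filter Fraction of lowest-variance features to drop
#'   (default 0.10).
#' @param center,scale. Passed to `stats::prcomp`.
#' @return List: `scores` (sample x PC), `explained` (variance fractions,
#'   non-increasing), `retained_features`.
#' @export
pca_scores <- function(x, var_filter = 0.10, center = TRUE, scale. = FALSE) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need >= 2 samples", call. = FALSE)
  v <- apply(x, 1, stats::var)
  n_drop <- floor(var_filter * nrow(x))
  keep <- if (n_drop > 0) {
    order(v, decreasing = TRUE)[seq_len(nrow(x) - n_drop)]
  } else {
    seq_len(nrow(x))
  }
  keep <- sort(keep)
  if (length(keep) < 2) stop("fewer than 2 features retained", call. = FALSE)
  pc <- stats::prcomp(t(x[keep, , drop = FALSE]), center = center,
                      scale. = scale.)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, explained = expl,
       retained_features = rownames(x)[keep])
}

#' Pairwise Pearson correlation between sample columns
#'
#' Wraps `stats::cor` with explicit missing-value semantics. In
#' `pairwise_complete` mode each pair uses its shared finite observations;
#' pairs with fewer than `min_obs` shared observations are set to `NA`
#' (their count is available in the `"n_shared"` attribute).
#'
#' @param x Feature x sample numeric matrix (NA allowed).
#' @param mode `"pairwise_complete"` (default) or `"complete"` (row-delete).
#' @param min_obs Minimum shared finite observations per pair (default 3).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pairwise_pearson <- function(x, mode = c("pairwise_complete", "complete"),
                             min_obs = 3) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  use <- if (mode == "complete") "complete.obs" else "pairwise.complete.obs"
  r <- suppressWarnings(stats::cor(x, use = use, method = "pearson"))
  n_shared <- crossprod(!is.na(x))
  r[n_shared < min_obs] <- NA_real_
  diag(r) <- 1
  attr(r, "n_shared") <- n_shared
  r
}

#' Median replicate correlation per cellular state
#'
#' Quality-control summary: pairwise Pearson correlation between replicate
#' samples within each (condition, timepoint) state, reported per state and
#' as a global median.
#'
#' @param x An `omics_matrix`.
#' @param log2 Log2-transform (with `pseudocount`) before correlating,
#'   appropriate for count/FPKM-like layers.
#' @param pseudocount Offset used when `log2 = TRUE`.
#' @return List: `per_state` data.frame (`condition`, `timepoint_label`,
#'   `median_r`) and `median_r` overall.
#' @export
replicate_correlation <- function(x, log2 = TRUE, pseudocount = 1) {
  stopifnot(inherits(x, "omics_matrix"))
  values <- if (log2) log2_transform(x, pseudocount) else x$values
  d <- x$design
  key <- paste(d$condition, d$timepoint_label, sep = "_")
  rows <- lapply(unique(key), function(s) {
    cols <- values[, key == s, drop = FALSE]
    if (ncol(cols) < 2) return(NULL)
    r <- pairwise_pearson(cols)
    data.frame(condition = d$condition[key == s][1],
               timepoint_label = d$timepoint_label[key == s][1],
               median_r = stats::median(r[upper.tri(r)], na.rm = TRUE))
  })
  per_state <- do.call(rbind, rows)
  list(per_state = per_state,
       median_r = stats::median(per_state$median_r, na.rm = TRUE))
}
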