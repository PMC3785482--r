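#' Per-chip quality-control summaries
#'
#' For each sample, reports the number of present calls and the 75th
#' percentile of present-call intensities. Marginal ("M") calls are treated
#' as absent. Percentiles use linear interpolation between order statistics
#' (the type-7 convention), so intensities 1..100 under all-present calls
#' give \code{p75_present = 75.25}. Samples with zero present calls are
#' flagged and carry \code{NA} for the percentile.
#'
#' @param x an [expr_matrix()].
#' @return data.frame with columns \code{sample_id}, \code{n_present_calls},
#'   \code{p75_present}, \code{flagged}.
#' @export
chip_qc_summary <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  present <- x$calls == "P"
  n_present <- colSums(present)
  p75 <- vapply(seq_len(ncol(x$intensity)), function(j) {
    v <- x$intensity[present[, j], j]
    if (length(v) == 0) NA_real_ else unname(stats::quantile(v, 0.75, type = 7))
  }, numeric(1))
  data.frame(sample_id = colnames(x$intensity),
             n_present_calls = unname(n_present),
             p75_present = p75,
             flagged = n_present == 0,
             stringsAsFactors = FALSE)
}

#' Flag outlier chips and putative tissue-label swaps
#'
#' Two screens: (a) robust z-scores (median/MAD) on the QC summary pair
#' (number of present calls, log2 of the present-call 75th percentile) flag
#' gross chip artifacts; (b) each sample's log2 profile is correlated with
#' the leave-one-out centroid of its own tissue and with the centroid of the
#' other tissue; a sample closer to the other tissue is flagged as a
#' potential tissue-assignment swap.
#'
#' @param summaries output of [chip_qc_summary()].
#' @param x the [expr_matrix()] the summaries came from.
#' @param design the matching \code{sample_design} data.frame.
#' @param z_threshold robust-z cutoff for summary-space outliers (default 6).
#' @return data.frame with columns \code{sample_id}, \code{summary_outlier},
#'   \code{tissue_swap}.
#' @export
flag_outliers <- function(summaries, x, design, z_threshold = 6) {
  stopifnot(inherits(x, "expr_matrix"))
  robust_z <- function(v) {
    s <- stats::mad(v, na.rm = TRUE)
    if (s == 0) s <- stats::sd(v, na.rm = TRUE)
    if (is.na(s) || s == 0) return(rep(0, length(v)))
    abs(v - stats::median(v, na.rm = TRUE)) / s
  }
  z1 <- robust_z(summaries$n_present_calls)
  z2 <- robust_z(log2(summaries$p75_present))
  summary_outlier <- (z1 > z_threshold) | (z2 > z_threshold)
  summary_outlier[is.na(summary_outlier)] <- TRUE

  tissues <- unique(design$tissue)
  swap <- rep(FALSE, nrow(summaries))
  if (length(tissues) < 2) {
    warning("single tissue present; tissue-swap check skipped")
  } else {
    logI <- log2(x$intensity)
    ord <- match(summaries$sample_id, design$sample_id)
    tis <- design$tissue[ord]
    for (j in seq_along(summaries$sample_id)) {
      sid <- summaries$sample_id[j]
      own <- design$sample_id[design$tissue == tis[j] &
                                design$sample_id != sid]
      oth <- design$sample_id[design$tissue != tis[j]]
      if (length(own) < 3 || length(oth) < 3) next
      prof <- logI[, sid]
      c_own <- stats::cor(prof, rowMeans(logI[, own, drop = FALSE]))
      c_oth <- stats::cor(prof, rowMeans(logI[, oth, drop = FALSE]))
      swap[j] <- c_oth > c_own
    }
  }
  data.frame(sample_id = summaries$sample_id,
             summary_outlier = summary_outlier,
             tissue_swap = swap,
             stringsAsFactors = FALSE)
}

#' Normalize chips to a common present-call 75th percentile
#'
#' Each sample is linearly rescaled so that the 75th percentile of its
#' present-call intensities equals a single common target, taken as the
#' median of the per-chip percentiles (scale-stable, and the identity for a
#' single chip). Renormalizing already-normalized data yields factors of 1.
#'
#' @param x an [expr_matrix()]; every sample must have at least one present
#'   call.
#' @param target optional explicit common value; default
#'   \code{median(p75_present)}.
#' @return list with \code{expr} (rescaled [expr_matrix()]) and
#'   \code{factors} (data.frame sample_id, p75_before, factor).
#' @export
normalize_to_common_percentile <- function(x, target = NULL) {
  qc <- chip_qc_summary(x)
  if (any(qc$n_present_calls == 0))
    stop("sample(s) with zero present calls: ",
         paste(qc$sample_id[qc$n_present_calls == 0], collapse = ", "))
  if (is.null(target)) target <- stats::median(qc$p75_present)
  factors <- target / qc$p75_present
  scaled <- sweep(x$intensity, 2, factors, `*`)
  list(expr = expr_matrix(scaled, x$calls),
       factors = data.frame(sample_id = qc$sample_id,
                            p75_before = qc$p75_present,
                            factor = factors,
                            stringsAsFactors = FALSE))
}

#' Collapse probeset intensities to gene level by maximum intensity
#'
#' For every gene and sample, the measured intensity is the maximum over the
#' gene's mapped probesets. Probesets absent from the map are dropped (count
#' reported via message); the mapping may be many-to-many.
#'
#' @param x an [expr_matrix()].
#' @param map data.frame with columns \code{probeset_id},
#'   \code{gene_symbol}.
#' @return numeric matrix, genes x samples (a gene-level intensity matrix).
#' @export
collapse_to_genes <- function(x, map) {
  stopifnot(inherits(x, "expr_matrix"))
  map <- map[map$probeset_id %in% rownames(x$intensity), , drop = FALSE]
  if (nrow(map) == 0)
    stop("no probeset in the map matches the expression matrix")
  n_unmapped <- sum(!rownames(x$intensity) %in% map$probeset_id)
  if (n_unmapped > 0)
    message(sprintf("dropped %d unmapped probeset(s) at gene collapse",
                    n_unmapped))
  genes <- sort(unique(map$gene_symbol))
  gidx <- match(map$gene_symbol, genes)
  pidx <- match(map$probeset_id, rownames(x$intensity))
  out <- matrix(-Inf, length(genes), ncol(x$intensity),
                dimnames = list(genes, colnames(x$intensity)))
  for (k in seq_len(nrow(map))) {
    g <- gidx[k]
    out[g, ] <- pmax(out[g, ], x$intensity[pidx[k], ])
  }
  out
}

#' Standardize gene profiles to z-scores on the log2 scale
#'
#' Per gene: log2-transform, subtract the mean and divide by the (n-1)
#' sample standard deviation over the selected samples. Zero-variance genes
#' standardize to all-zero rows with a warning rather than erroring.
#'
#' @param gene_matrix genes x samples positive intensity matrix.
#' @param sample_subset optional character vector of sample ids (default all).
#' @return z-score matrix over the subset.
#' @export
standardize_genes <- function(gene_matrix, sample_subset = NULL) {
  if (!is.null(sample_subset))
    gene_matrix <- gene_matrix[, sample_subset, drop = FALSE]
  if (ncol(gene_matrix) < 2) stop("need >= 2 samples to standardize")
  y <- log2(gene_matrix)
  mu <- rowMeans(y)
  sdev <- apply(y, 1, stats::sd)
  zero <- sdev == 0
  if (any(zero)) {
    warning(sprintf("%d zero-variance gene(s) standardized to zero",
                    sum(zero)))
    sdev[zero] <- 1
  }
  z <- (y - mu) / sdev
  z[zero, ] <- 0
  z
}

#' Sum-of-squares variation statistic
#'
#' \eqn{S^2 = \sum_j (y_{gj} - \bar y_g)^2} over all samples, computed on
#' log2 intensities. Large for genes with many moderate deviations or a few
#' large deviations from their mean, so it selects genes varying anywhere
#' across the breadth of samples.
#'
#' @param gene_matrix genes x samples positive intensity matrix.
#' @return named numeric vector of S-squared values.
#' @export
variation_statistic <- function(gene_matrix) {
  if (ncol(gene_matrix) < 2) stop("need >= 2 samples")
  y <- log2(gene_matrix)
  rowSums((y - rowMeans(y))^2)
}

#' Select the k most-varying genes
#'
#' @param s2 named vector from [variation_statistic()].
#' @param k number of genes to keep (default 1000); clamped with a warning
#'   when it exceeds the number of genes.
#' @return character vector of gene names, largest S-squared first (ties
#'   broken by name for determinism).
#' @export
top_variable_genes <- function(s2, k = 1000) {
  if (k > length(s2)) {
    warning("k exceeds the number of genes; clamped")
    k <- length(s2)
  }
  names(s2)[order(-s2, names(s2))][seq_len(k)]
}

#' Cluster standardized gene profiles for display
#'
#' Seeded k-means partition of the z-score profiles followed by
#' within-cluster ordering along a hierarchical-clustering (average linkage,
#' Euclidean) leaf order, giving a deterministic gene ordering suitable for
#' heat-map export. Clusters are relabelled in order of appearance in the
#' display ordering.
#'
#' @param z_matrix standardized genes x samples matrix.
#' @param n_clusters number of clusters (must not exceed the gene count).
#' @param seed RNG seed for the k-means initialization (default 1).
#' @return list with \code{cluster} (named integer vector) and \code{order}
#'   (character vector of gene names in display order).
#' @export
cluster_gene_profiles <- function(z_matrix, n_clusters, seed = 1) {
  if (n_clusters > nrow(z_matrix))
    stop("n_clusters exceeds the number of genes")
  set.seed(seed)
  if (n_clusters == 1) {
    cl <- stats::setNames(rep(1L, nrow(z_matrix)), rownames(z_matrix))
  } else {
    km <- stats::kmeans(z_matrix, centers = n_clusters, nstart = 10,
                        iter.max = 50)
    cl <- km$cluster
  }
  ord <- character(0)
  ## order clusters by their centroid's first principal direction of the
  ## display: simply iterate clusters by mean profile similarity chain
  centroids <- do.call(rbind, lapply(sort(unique(cl)), function(g)
    colMeans(z_matrix[cl == g, , drop = FALSE])))
  c_ord <- if (nrow(centroids) > 2) {
    stats::hclust(stats::dist(centroids), method = "average")$order
  } else seq_len(nrow(centroids))
  for (g in sort(unique(cl))[c_ord]) {
    members <- names(cl)[cl == g]
    if (length(members) > 2) {
      h <- stats::hclust(stats::dist(z_matrix[members, , drop = FALSE]),
                         method = "average")
      members <- members[h$order]
    }
    ord <- c(ord, members)
  }
  relabel <- stats::setNames(seq_along(unique(cl[ord])), unique(cl[ord]))
  cl <- stats::setNames(as.integer(relabel[as.character(cl)]), names(cl))
  list(cluster = cl, order = ord)
}
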