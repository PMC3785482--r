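#' Robust Bayesian expression-ratio estimate with equal-variance t-test
#'
#' Estimates the expression ratio B/A from condition means and standard
#' errors of the mean. The observed log2 ratio, with measurement standard
#' deviation obtained by the delta method, is combined with a zero-centred
#' Gaussian prior on the true log2 ratio (scale \code{prior_sd}); the
#' posterior median shrinks the estimate toward a ratio of 1 as measurement
#' noise grows, never overshooting the plain ratio of means. The P-value is
#' a two-sided equal-variance (pooled) t-test on the intensity means when
#' the per-condition sample sizes are supplied, else a z-test on the
#' standard errors.
#'
#' @param meanA,meanB positive condition means (linear intensity scale).
#' @param seA,seB standard errors of the means (>= 0).
#' @param nA,nB optional replicate counts for the pooled t-test.
#' @param prior_sd prior scale on the log2 ratio (default 1).
#' @return data.frame with columns \code{ratio_estimate},
#'   \code{log2_ratio}, \code{p_value} (vectorized over the inputs).
#' @export
estimate_ratio <- function(meanA, seA, meanB, seB, nA = NULL, nB = NULL,
                           prior_sd = 1) {
  if (any(meanA <= 0) || any(meanB <= 0)) stop("means must be positive")
  if (any(seA < 0) || any(seB < 0)) stop("standard errors must be >= 0")
  m <- log2(meanB / meanA)
  tau <- sqrt((seA / meanA)^2 + (seB / meanB)^2) / log(2)
  shrink <- prior_sd^2 / (prior_sd^2 + tau^2)
  log2_ratio <- m * shrink
  ## equal-variance t-test on the intensity scale
  if (!is.null(nA) && !is.null(nB)) {
    sdA <- seA * sqrt(nA)
    sdB <- seB * sqrt(nB)
    df <- nA + nB - 2
    sp2 <- ((nA - 1) * sdA^2 + (nB - 1) * sdB^2) / df
    se_diff <- sqrt(sp2 * (1 / nA + 1 / nB))
    tstat <- (meanB - meanA) / se_diff
    p <- 2 * stats::pt(-abs(tstat), df)
  } else {
    se_diff <- sqrt(seA^2 + seB^2)
    tstat <- (meanB - meanA) / se_diff
    p <- 2 * stats::pnorm(-abs(tstat))
  }
  ## degenerate: no noise and no difference => ratio exactly 1, P = 1
  degen <- se_diff == 0
  p[degen & meanA == meanB] <- 1
  p[degen & meanA != meanB] <- 0
  log2_ratio[degen] <- m[degen]
  data.frame(ratio_estimate = 2^log2_ratio, log2_ratio = log2_ratio,
             p_value = p)
}

#' Per-gene, per-time expression-ratio profiles between two treatments
#'
#' For every sampling time in the chosen tissue, replicate means and
#' standard errors of each probeset feed [estimate_ratio()] for the
#' contrast \code{treatmentB / treatmentA}; the P-value is the equal
#' variance (pooled) t-test computed on log2 intensities, where replicate
#' noise is close to Gaussian. Probesets are then mapped to genes and,
#' when a gene has several probesets, the (ratio, P) pair with the
#' smallest P-value is reported for that gene. Cells with fewer than two
#' replicates are flagged missing.
#'
#' @param x an [expr_matrix()] (or plain probeset intensity matrix).
#' @param map probeset-to-gene annotation data.frame; \code{NULL} keeps
#'   probeset-level results.
#' @param design \code{sample_design} data.frame.
#' @param treatmentA,treatmentB treatment labels (denominator, numerator).
#' @param tissue tissue to profile.
#' @return data.frame with columns \code{gene, time_h, ratio_estimate,
#'   log2_ratio, p_value, flagged}.
#' @export
ratio_profile <- function(x, map, design, treatmentA, treatmentB, tissue) {
  intensity <- if (inherits(x, "expr_matrix")) x$intensity else x
  out <- list()
  for (t in sort(unique(design$time_h))) {
    sel <- design$tissue == tissue & design$time_h == t
    idA <- design$sample_id[sel & design$treatment == treatmentA]
    idB <- design$sample_id[sel & design$treatment == treatmentB]
    nA <- length(idA); nB <- length(idB)
    flagged <- nA < 2 || nB < 2
    if (nA == 0 || nB == 0) next
    A <- intensity[, idA, drop = FALSE]
    B <- intensity[, idB, drop = FALSE]
    est <- estimate_ratio(
      rowMeans(A), apply(A, 1, stats::sd) / sqrt(nA),
      rowMeans(B), apply(B, 1, stats::sd) / sqrt(nB),
      nA = nA, nB = nB)
    if (nA >= 2 && nB >= 2) {
      la <- log2(A); lb <- log2(B)
      df <- nA + nB - 2
      sp2 <- ((nA - 1) * apply(la, 1, stats::var) +
                (nB - 1) * apply(lb, 1, stats::var)) / df
      tstat <- (rowMeans(lb) - rowMeans(la)) /
        sqrt(sp2 * (1 / nA + 1 / nB))
      p <- 2 * stats::pt(-abs(tstat), df)
      p[!is.finite(p)] <- 1
      est$p_value <- p
    }
    est$probeset_id <- rownames(intensity)
    est$time_h <- t
    est$flagged <- flagged
    out[[length(out) + 1]] <- est
  }
  res <- do.call(rbind, out)
  if (is.null(map)) {
    res$gene <- res$probeset_id
    return(res[, c("gene", "time_h", "ratio_estimate", "log2_ratio",
                   "p_value", "flagged")])
  }
  merged <- merge(res, map, by = "probeset_id")
  merged <- merged[order(merged$gene_symbol, merged$time_h, merged$p_value,
                         merged$probeset_id), ]
  first <- !duplicated(merged[, c("gene_symbol", "time_h")])
  best <- merged[first, ]
  data.frame(gene = best$gene_symbol, time_h = best$time_h,
             ratio_estimate = best$ratio_estimate,
             log2_ratio = best$log2_ratio, p_value = best$p_value,
             flagged = best$flagged, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Two-way ANOVA across many features at once
#'
#' Fits \code{value ~ treatment * time} for every row of a feature-by-sample
#' matrix using projection-matrix sums of squares. Unbalanced designs use
#' Type II sums of squares (each main effect adjusted for the other,
#' interaction adjusted for both), which is invariant to the cell-size
#' imbalance arising from jittered replicate counts. Rows with (numerically)
#' constant values are degenerate and get P = 1 with a flag.
#'
#' @param values numeric matrix (features x samples) or vector.
#' @param treatment_factor,time_factor factors of length \code{n_samples}
#'   with at least two levels each.
#' @return data.frame with columns \code{feature, F_treatment, p_treatment,
#'   F_time, p_time, F_interaction, p_interaction, degenerate}.
#' @export
two_way_anova <- function(values, treatment_factor, time_factor) {
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  tr <- droplevels(as.factor(treatment_factor))
  ti <- droplevels(as.factor(time_factor))
  if (nlevels(tr) < 2 || nlevels(ti) < 2)
    stop("each factor needs at least two levels")
  ns <- ncol(values)
  stopifnot(length(tr) == ns, length(ti) == ns)

  rss_of <- function(form) {
    X <- stats::model.matrix(form, data = data.frame(tr = tr, ti = ti))
    q <- qr(X)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    fitted <- (values %*% Q) %*% t(Q)
    list(rss = rowSums((values - fitted)^2), rank = q$rank)
  }
  full <- rss_of(~ tr * ti)
  add <- rss_of(~ tr + ti)
  only_ti <- rss_of(~ ti)
  only_tr <- rss_of(~ tr)

  dfe <- ns - full$rank
  if (dfe < 1) stop("no residual degrees of freedom: need replicated cells")
  mse <- full$rss / dfe
  eps <- 1e-10 * pmax(rowSums(values^2), 1)
  degenerate <- full$rss <= eps &
    pmax(only_ti$rss, only_tr$rss) - full$rss <= eps

  f_p <- function(ss, df1) {
    ss <- pmax(ss, 0)
    F <- (ss / df1) / mse
    p <- stats::pf(F, df1, dfe, lower.tail = FALSE)
    p[degenerate] <- 1
    F[degenerate] <- 0
    list(F = F, p = p)
  }
  t_eff <- f_p(only_ti$rss - add$rss, add$rank - only_ti$rank)
  h_eff <- f_p(only_tr$rss - add$rss, add$rank - only_tr$rank)
  i_eff <- f_p(add$rss - full$rss, full$rank - add$rank)

  data.frame(feature = rownames(values) %||% as.character(seq_len(nrow(values))),
             F_treatment = t_eff$F, p_treatment = t_eff$p,
             F_time = h_eff$F, p_time = h_eff$p,
             F_interaction = i_eff$F, p_interaction = i_eff$p,
             degenerate = degenerate, stringsAsFactors = FALSE,
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up adjusted P-values with selection at adjusted value <= q.
#'
#' @param p_values numeric vector in [0, 1].
#' @param q FDR level (default 0.25).
#' @return list with \code{adjusted} and integer \code{selected} indices.
#' @export
bh_fdr <- function(p_values, q = 0.25) {
  if (length(p_values) == 0)
    return(list(adjusted = numeric(0), selected = integer(0)))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("P-values must lie in [0, 1]")
  adjusted <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adjusted, selected = which(adjusted <= q))
}

#' Select a treatment-response gene set by two-way ANOVA
#'
#' Probeset-level two-way ANOVA (\code{log2 intensity ~ treatment * time})
#' within one tissue for a two-treatment contrast; probesets are selected on
#' the treatment-effect P-value, either through a false-discovery-rate
#' threshold or a raw P-value threshold, and then mapped to gene symbols and
#' deduplicated.
#'
#' @param x an [expr_matrix()] (or probeset intensity matrix).
#' @param map probeset-to-gene annotation data.frame.
#' @param design \code{sample_design} data.frame.
#' @param tissue tissue to analyse.
#' @param contrast length-2 character vector of treatment levels, e.g.
#'   \code{c("noHS", "HS")} or \code{c("HS", "HS_NBQX")}.
#' @param threshold_spec list with \code{mode} ("fdr" or "raw_p") and
#'   \code{value}; naming both modes is an error.
#' @return list with \code{genes} (sorted unique symbols),
#'   \code{probesets} (selected probeset ids) and \code{anova} (the full
#'   probeset-level table with \code{fdr_treatment}).
#' @export
select_response_set <- function(x, map, design, tissue, contrast,
                                threshold_spec = list(mode = "fdr",
                                                      value = 0.25)) {
  if (!tissue %in% design$tissue) stop("tissue not present in design")
  if (length(contrast) != 2) stop("contrast must name two treatment levels")
  if (!is.list(threshold_spec) ||
      !all(c("mode", "value") %in% names(threshold_spec)) ||
      length(threshold_spec$mode) != 1 ||
      !threshold_spec$mode %in% c("fdr", "raw_p"))
    stop("threshold_spec must be list(mode = 'fdr'|'raw_p', value = x)")
  intensity <- if (inherits(x, "expr_matrix")) x$intensity else x
  sel <- design$tissue == tissue & design$treatment %in% contrast
  d <- design[sel, ]
  y <- log2(intensity[, d$sample_id, drop = FALSE])
  an <- two_way_anova(y, d$treatment, d$time_h)
  an$fdr_treatment <- stats::p.adjust(an$p_treatment, method = "BH")
  keep <- if (threshold_spec$mode == "fdr") {
    an$fdr_treatment <= threshold_spec$value
  } else {
    an$p_treatment <= threshold_spec$value
  }
  probesets <- an$feature[keep]
  genes <- sort(unique(map$gene_symbol[map$probeset_id %in% probesets]))
  list(genes = genes, probesets = probesets, anova = an)
}

#' Expected overlap of two random gene sets and tail probability
#'
#' Under random draws of sets of sizes \code{n1} and \code{n2} from a
#' universe of \code{N} genes, the overlap is hypergeometric with mean
#' \code{n1 * n2 / N} and the standard deviation of the classical
#' hypergeometric; the upper-tail probability \code{P(X >= observed)} is
#' computed stably through \code{phyper} on the log scale.
#'
#' @param n1,n2 set sizes.
#' @param N universe size (> 0).
#' @param observed observed overlap, at most \code{min(n1, n2)}.
#' @return data.frame with \code{n1, n2, N, observed, expected_mean,
#'   expected_se, tail_p, log10_tail_p}.
#' @export
overlap_statistics <- function(n1, n2, N, observed) {
  if (N <= 0) stop("universe size must be positive")
  if (n1 > N || n2 > N) stop("set sizes cannot exceed the universe")
  if (observed > min(n1, n2) || observed < 0)
    stop("observed overlap out of range")
  n1 <- as.numeric(n1); n2 <- as.numeric(n2); N <- as.numeric(N)
  mean_ov <- n1 * n2 / N
  var_ov <- if (N > 1) {
    n1 * n2 * (N - n1) * (N - n2) / (N^2 * (N - 1))
  } else 0
  log_p <- stats::phyper(observed - 1, n1, N - n1, n2, lower.tail = FALSE,
                         log.p = TRUE)
  data.frame(n1 = n1, n2 = n2, N = N, observed = observed,
             expected_mean = mean_ov, expected_se = sqrt(var_ov),
             tail_p = exp(log_p), log10_tail_p = log_p / log(10))
}

#' Exact set algebra on gene symbol lists
#'
#' Case-sensitive exact-symbol intersection and union with sizes.
#'
#' @param listA,listB character vectors of gene symbols.
#' @return list with \code{intersection}, \code{union}, \code{n_a},
#'   \code{n_b}, \code{n_intersection}, \code{n_union}.
#' @export
set_algebra <- function(listA, listB) {
  a <- unique(listA); b <- unique(listB)
  i <- sort(intersect(a, b)); u <- sort(union(a, b))
  list(intersection = i, union = u, n_a = length(a), n_b = length(b),
       n_intersection = length(i), n_union = length(u))
}
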