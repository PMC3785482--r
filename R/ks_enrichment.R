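#' Transform an expression profile into descending ranks
#'
#' Rank 1 is assigned to the largest value and rank n to the smallest over
#' the whole gene universe. Ties are resolved deterministically by value
#' (descending) then gene name (ascending), so rank vectors are always a
#' permutation of 1..n.
#'
#' @param profile named numeric vector (e.g. log2 ratios) over the universe.
#' @return named integer vector of ranks.
#' @export
rank_transform <- function(profile) {
  if (is.null(names(profile)) || anyDuplicated(names(profile)))
    stop("profile must carry unique gene names")
  if (anyNA(profile))
    stop("missing values for gene(s): ",
         paste(utils::head(names(profile)[is.na(profile)], 5), collapse = ", "))
  ord <- order(-profile, names(profile))
  ranks <- integer(length(profile))
  ranks[ord] <- seq_along(profile)
  stats::setNames(ranks, names(profile))
}

## Max signed deviation of the empirical CDF of a group of distinct ranks
## from the discrete-uniform CDF, evaluated at every member rank and at the
## grid point just below it (both step sides). Returns the signed deviation
## at the point of maximum absolute deviation, with its grid rank.
.ks_dev <- function(group_ranks, n) {
  k <- length(group_ranks)
  if (k == 0)
    return(list(d = 0, g_star = NA_integer_, x_star = NA_real_))
  r <- sort(group_ranks)
  i <- seq_len(k)
  g <- c(r - 1L, r)                    # candidate grid ranks
  D <- c((i - 1) / k - (r - 1) / n,    # just below each member
         i / k - r / n)                # at each member
  o <- order(g)                        # leftmost maximum wins (deterministic)
  g <- g[o]; D <- D[o]
  j <- which.max(abs(D))
  list(d = D[j], g_star = g[j], x_star = g[j] / n)
}

## F_sample of a group at integer grid rank g
.ks_F <- function(group_ranks, g) {
  if (length(group_ranks) == 0) return(NA_real_)
  sum(group_ranks <= g) / length(group_ranks)
}

#' Signed KS deviations for up- and down-regulatee groups
#'
#' The empirical CDF of the ranks of each regulatee group is compared with
#' the discrete-uniform population CDF; the signed deviation at the point of
#' maximum absolute deviation is returned for each group (evaluated on both
#' sides of every step). Coherent regulation gives a positive \code{d_u}
#' (up-regulatees concentrated at top ranks) and a negative \code{d_d}.
#' An empty group has deviation 0 and an undefined argmax.
#'
#' @param ranked named integer rank vector from [rank_transform()].
#' @param up_set character vector of up-regulatee gene names (subset of the
#'   universe).
#' @param down_set character vector of down-regulatee gene names, disjoint
#'   from \code{up_set}.
#' @return list with \code{d_u}, \code{d_d}, the argmax fractional ranks
#'   \code{x_u_star}, \code{x_d_star}, the integer grid ranks
#'   \code{g_u_star}, \code{g_d_star}, and \code{k_u}, \code{k_d}.
#' @export
signed_deviations <- function(ranked, up_set, down_set = character()) {
  if (length(up_set) + length(down_set) == 0)
    stop("both regulatee groups are empty")
  if (length(intersect(up_set, down_set)) > 0)
    stop("up_set and down_set must be disjoint")
  miss <- setdiff(c(up_set, down_set), names(ranked))
  if (length(miss) > 0)
    stop("regulatee(s) not in the universe: ",
         paste(utils::head(miss, 5), collapse = ", "))
  n <- length(ranked)
  ru <- unname(ranked[up_set])
  rd <- unname(ranked[down_set])
  u <- .ks_dev(ru, n)
  d <- .ks_dev(rd, n)
  list(d_u = u$d, d_d = d$d,
       x_u_star = u$x_star, x_d_star = d$x_star,
       g_u_star = u$g_star, g_d_star = d$g_star,
       k_u = length(ru), k_d = length(rd), n = n)
}

#' Combined signed KS statistic for a regulated gene set
#'
#' \code{d_UpDown = (k_u * d_u - k_d * d_d) / (k_u + k_d)}: the
#' membership-weighted combination in which coherent regulation
#' (up-regulatees ranked high, down-regulatees ranked low) is positive.
#' It is bounded in \eqn{[-1, 1]}, reduces to \code{d_u} when
#' \code{k_d = 0} and to \code{-d_d} when \code{k_u = 0}, and weighs each
#' group in proportion to its membership so a small noisy group cannot
#' overwhelm a larger one.
#'
#' @param d_u,d_d signed deviations from [signed_deviations()].
#' @param k_u,k_d regulatee group sizes; \code{k_u + k_d >= 1}.
#' @return the combined statistic, a number in \eqn{[-1, 1]}.
#' @export
combined_statistic <- function(d_u, k_u, d_d, k_d) {
  if (k_u + k_d < 1) stop("k_u + k_d must be >= 1")
  (k_u * d_u - k_d * d_d) / (k_u + k_d)
}

#' Permutation P-value for the combined statistic
#'
#' Draws \code{n_perm} random sign-preserving memberships (\code{k_u} and
#' \code{k_d} genes sampled without replacement from the universe) and
#' reports the fraction whose combined statistic reaches the observed one
#' (one-sided toward coherent enrichment). A permutation count of zero is
#' reported as 0 with the resolution floor \code{1/n_perm} attached as the
#' attribute \code{"floor"}, so P = 0 reads as P below the floor.
#'
#' @param ranked named integer rank vector from [rank_transform()].
#' @param set a [gene_set()] (members outside the universe are dropped).
#' @param n_perm number of permutations (default 1e5).
#' @param seed optional RNG seed applied before drawing.
#' @return the permutation P-value with attributes \code{floor} and
#'   \code{observed} (the observed combined statistic).
#' @export
permutation_pvalue <- function(ranked, set, n_perm = 1e5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  up <- intersect(set$up_genes, names(ranked))
  dn <- intersect(set$down_genes, names(ranked))
  if (length(up) + length(dn) > length(ranked))
    stop("gene set larger than the universe")
  dev <- signed_deviations(ranked, up, dn)
  obs <- combined_statistic(dev$d_u, dev$k_u, dev$d_d, dev$k_d)
  null <- ks_null_dupdown(length(ranked), length(up), length(dn),
                          as.integer(n_perm))
  p <- mean(null >= obs - 1e-12)
  structure(p, floor = 1 / n_perm, observed = obs)
}

#' Left and right enrichment scores of the KS plot
#'
#' \code{c_left} is the chord slope of the up-regulatee CDF from the origin
#' to its point of maximum deviation, \code{F_up(x*) / x*}; \code{c_right}
#' is the mirrored chord slope for down-regulatees,
#' \code{(1 - F_down(x*)) / (1 - x*)}. A neutral (uniformly scattered)
#' group scores about 1; an empty group scores exactly 1. A degenerate
#' argmax at 0 or 1 falls back to the adjacent step, with a \code{flag}
#' noting it.
#'
#' @inheritParams signed_deviations
#' @return list with \code{c_left}, \code{c_right} and logical \code{flag}.
#' @export
enrichment_scores <- function(ranked, up_set, down_set = character()) {
  dev <- signed_deviations(ranked, up_set, down_set)
  n <- dev$n
  flag <- FALSE
  ru <- unname(ranked[up_set])
  rd <- unname(ranked[down_set])
  c_left <- 1
  if (dev$k_u > 0) {
    g <- dev$g_u_star
    if (g == 0) { g <- min(ru); flag <- TRUE }
    c_left <- .ks_F(ru, g) / (g / n)
  }
  c_right <- 1
  if (dev$k_d > 0) {
    g <- dev$g_d_star
    if (g == n) { g <- max(setdiff(c(rd - 1L, rd), n)); flag <- TRUE }
    c_right <- (1 - .ks_F(rd, g)) / (1 - g / n)
  }
  list(c_left = c_left, c_right = c_right, flag = flag)
}

#' Leading-edge genes of a regulated gene set
#'
#' Up-regulatees ranked at or above the point of maximum deviation of their
#' CDF, and down-regulatees ranked at or below (i.e. with larger rank than)
#' theirs: the genes that drive the enrichment.
#'
#' @inheritParams signed_deviations
#' @return list with character vectors \code{leading_edge_up} and
#'   \code{leading_edge_down}, each ordered by rank and a subset of the
#'   corresponding regulatee list.
#' @export
leading_edge <- function(ranked, up_set, down_set = character()) {
  dev <- signed_deviations(ranked, up_set, down_set)
  le_up <- character(0)
  if (dev$k_u > 0) {
    r <- ranked[up_set]
    le_up <- names(sort(r[r <= dev$g_u_star]))
  }
  le_dn <- character(0)
  if (dev$k_d > 0) {
    r <- ranked[down_set]
    le_dn <- names(sort(r[r >= dev$g_d_star]))
  }
  list(leading_edge_up = le_up, leading_edge_down = le_dn)
}

#' Screen a gene-set collection against a ranked profile
#'
#' Scores every set with the regulated KS statistic, computes permutation
#' P-values (null distributions are cached per \code{(k_u, k_d)} shape),
#' adjusts them to false-discovery rates within each source collection
#' separately, and flags the sets passing \code{fdr < fdr_max} together
#' with \code{max(c_left, c_right) >= c_min}. Sets with no member in the
#' universe are skipped with a warning.
#'
#' @param profile named numeric vector over the gene universe (e.g. log2
#'   ratios of treatment to control).
#' @param collection list of [gene_set()] objects.
#' @param fdr_max FDR selection threshold (default 0.25).
#' @param c_min minimum enrichment score (default 2).
#' @param n_perm permutations per null shape (default 1e4).
#' @param seed RNG seed for the permutation draws (default 1).
#' @return data.frame with columns \code{name, source, ku, kd, d_updown,
#'   p_value, fdr, c_left, c_right, selected} and list-columns
#'   \code{leading_edge_up}, \code{leading_edge_down}.
#' @export
screen_collection <- function(profile, collection, fdr_max = 0.25, c_min = 2,
                              n_perm = 1e4, seed = 1) {
  if (length(collection) == 0) stop("empty gene-set collection")
  set.seed(seed)
  ranked <- rank_transform(profile)
  n <- length(ranked)
  null_cache <- new.env(parent = emptyenv())
  rows <- vector("list", length(collection))
  for (i in seq_along(collection)) {
    s <- collection[[i]]
    up <- intersect(s$up_genes, names(ranked))
    dn <- intersect(s$down_genes, names(ranked))
    if (length(up) + length(dn) == 0) {
      warning(sprintf("gene set '%s' has no member in the universe; skipped",
                      s$name))
      next
    }
    dev <- signed_deviations(ranked, up, dn)
    obs <- combined_statistic(dev$d_u, dev$k_u, dev$d_d, dev$k_d)
    key <- paste(length(up), length(dn), sep = "_")
    if (is.null(null_cache[[key]]))
      null_cache[[key]] <- ks_null_dupdown(n, length(up), length(dn),
                                           as.integer(n_perm))
    p <- mean(null_cache[[key]] >= obs - 1e-12)
    sc <- enrichment_scores(ranked, up, dn)
    le <- leading_edge(ranked, up, dn)
    rows[[i]] <- data.frame(
      name = s$name, source = s$source,
      ku = length(up), kd = length(dn),
      d_updown = obs, p_value = p,
      c_left = sc$c_left, c_right = sc$c_right,
      stringsAsFactors = FALSE)
    rows[[i]]$leading_edge_up <- I(list(le$leading_edge_up))
    rows[[i]]$leading_edge_down <- I(list(le$leading_edge_down))
  }
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  res$fdr <- NA_real_
  for (src in unique(res$source)) {
    j <- res$source == src
    res$fdr[j] <- stats::p.adjust(res$p_value[j], method = "BH")
  }
  res$selected <- res$fdr < fdr_max & pmax(res$c_left, res$c_right) >= c_min
  res[, c("name", "source", "ku", "kd", "d_updown", "p_value", "fdr",
          "c_left", "c_right", "selected", "leading_edge_up",
          "leading_edge_down")]
}

#' Step-function coordinates and null band for a KS plot
#'
#' Returns, for each regulatee group, the cumulative fraction of the group
#' (fractional rank in the sample) against the fractional rank in the
#' population, plus the two-sided null confidence band for the combined
#' group size \code{k = k_u + k_d} (half-width = the asymptotic KS critical
#' value at the stated confidence).
#'
#' @inheritParams signed_deviations
#' @param confidence band confidence level in (0, 1), default 0.95.
#' @return list with \code{steps} (data.frame \code{group, x, y}),
#'   \code{band_halfwidth} and \code{confidence}.
#' @export
ks_plot_data <- function(ranked, up_set, down_set = character(),
                         confidence = 0.95) {
  if (confidence <= 0 || confidence >= 1)
    stop("confidence must be in (0, 1)")
  dev <- signed_deviations(ranked, up_set, down_set)
  n <- dev$n
  step_df <- function(group, label) {
    k <- length(group)
    if (k == 0) return(NULL)
    r <- sort(unname(ranked[group]))
    data.frame(group = label, x = c(0, r / n, 1),
               y = c(0, seq_len(k) / k, 1), stringsAsFactors = FALSE)
  }
  steps <- rbind(step_df(up_set, "up"), step_df(down_set, "down"))
  k_tot <- dev$k_u + dev$k_d
  alpha <- 1 - confidence
  band <- sqrt(log(2 / alpha) / (2 * k_tot))
  list(steps = steps, band_halfwidth = band, confidence = confidence)
}
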