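# Independent brute-force oracles used across the suite. These re-derive
# each quantity from its definition, never through the package's own
# shortcut formulas.

# Max signed deviation of the group-rank empirical CDF from the discrete
# uniform CDF, evaluated at every grid rank 0..n (exhaustive step-point
# enumeration; leftmost maximum on ties).
oracle_signed_dev <- function(group_ranks, n) {
  if (length(group_ranks) == 0) return(list(d = 0, g = NA_integer_))
  g <- 0:n
  Fs <- vapply(g, function(x) mean(group_ranks <= x), numeric(1))
  D <- Fs - g / n
  j <- which.max(abs(D))
  list(d = D[j], g = g[j])
}

oracle_leading_edge_up <- function(group_ranks, n) {
  g <- oracle_signed_dev(group_ranks, n)$g
  sort(group_ranks[group_ranks <= g])
}

oracle_leading_edge_down <- function(group_ranks, n) {
  g <- oracle_signed_dev(group_ranks, n)$g
  sort(group_ranks[group_ranks >= g])
}

# Exhaustive null distribution of d_UpDown for small universes: every
# placement of ku up and kd down regulatees on ranks 1..n.
oracle_combn_sets <- function(x, m) {
  # combn() interprets a length-1 x as seq_len(x); always index positions
  if (m == 0) return(list(integer(0)))
  lapply(utils::combn(seq_along(x), m, simplify = FALSE), function(i) x[i])
}

oracle_dupdown_all <- function(n, ku, kd) {
  stopifnot(ku + kd >= 1, ku + kd <= n)
  out <- numeric(0)
  up_sets <- oracle_combn_sets(seq_len(n), ku)
  for (up in up_sets) {
    rest <- setdiff(seq_len(n), up)
    dn_sets <- oracle_combn_sets(rest, kd)
    for (dn in dn_sets) {
      du <- oracle_signed_dev(up, n)$d
      dd <- oracle_signed_dev(dn, n)$d
      out <- c(out, (ku * du - kd * dd) / (ku + kd))
    }
  }
  out
}

# Step-up BH adjustment from the brute-force min-over-tail definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    j <- which(o == i)  # position of p[i] in the sorted order
    tail_vals <- n * p[o][j:n] / (j:n)
    adj[i] <- min(1, min(tail_vals))
  }
  adj
}

# Posterior median of the log2 ratio under the shrinkage model, by numeric
# integration of the posterior density on a grid.
oracle_posterior_median <- function(m, tau, prior_sd = 1) {
  if (tau == 0) return(m)
  rho <- seq(-12, 12, by = 1e-3)
  dens <- stats::dnorm(rho, 0, prior_sd) * stats::dnorm(m, rho, tau)
  cdf <- cumsum(dens) / sum(dens)
  stats::approx(cdf, rho, xout = 0.5, ties = "ordered")$y
}

# Small fully-specified expression fixture: nps probesets, ns samples.
tiny_expr <- function(nps = 6, ns = 4, seed = 42) {
  set.seed(seed)
  m <- matrix(2^rnorm(nps * ns, 7, 1), nps, ns,
              dimnames = list(sprintf("ps%02d", seq_len(nps)),
                              sprintf("s%02d", seq_len(ns))))
  calls <- matrix(sample(c("P", "A"), nps * ns, TRUE, prob = c(0.8, 0.2)),
                  nps, ns, dimnames = dimnames(m))
  expr_matrix(m, calls)
}

# Quiet config for fast tests.
fast_config <- function(...) {
  sim_config(n_genes = 300L, n_gene_sets = 30L, ...)
}

# A null configuration: no planted effects of any kind.
null_config <- function(...) {
  sim_config(dev_frac_up = 0, dev_frac_down = 0, tissue_frac = 0,
             hs_frac = 0, nbqx_frac = 0, frac_enriched = 0, ...)
}
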