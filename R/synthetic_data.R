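#' Simulation configuration for a synthetic hypoxic-seizure study
#'
#' Returns the full configuration that [generate_study()] and its companions
#' consume, with defaults describing the documented strong-signal study: a
#' 2,000-gene universe measured by 1-3 probesets each, a full factorial
#' design (2 tissues x 3 treatments x 5 sampling times, 4-6 replicates per
#' cell), developmental trends, hypoxic-seizure (HS) responsive genes with a
#' temporal profile peaking at 12 h and a roughly 2:1 up:down direction mix,
#' an NBQX-responsive subset of the HS genes, log2-additive Gaussian noise,
#' intensity-dependent absent calls, and 100 signed gene sets of which 20
#' are truly enriched at regulatee purity 0.9.
#'
#' @param ... named overrides of any default listed below.
#' @return A validated list of class \code{sim_config}.
#' @details Defaults: \code{n_genes = 2000}; \code{probesets_per_gene =
#'   c(1, 3)} (uniform); \code{n_replicates = c(4, 6)} (uniform per design
#'   cell); baseline log2 intensity \code{baseline_mean = 7},
#'   \code{baseline_sd = 1.5}; developmental fractions
#'   \code{dev_frac_up = 0.15}, \code{dev_frac_down = 0.15} with
#'   \code{dev_effect = 2} log2 units across the time course; tissue-specific
#'   fraction \code{tissue_frac = 0.1} with \code{tissue_effect = 2};
#'   \code{hs_frac = 0.1} of genes HS-responsive with \code{hs_up_prop = 2/3}
#'   induced, \code{hs_effect = 1.5} log2 units scaled by
#'   \code{hs_time_weights = c(0.6, 0.8, 1, 0.5, 0.3)} over
#'   \code{c(1, 6, 12, 48, 168)} h (maximal at 12 h); \code{nbqx_frac = 0.3}
#'   of HS genes NBQX-responsive with \code{nbqx_effect = 1} and
#'   \code{nbqx_up_prop = 0.7} shifted further up; residual
#'   \code{noise_sd = 0.5} shared by a gene's probesets plus independent
#'   \code{probe_noise_sd = 0.25} and fixed probe offsets
#'   \code{probe_offset_sd = 0.5}; absent-call logistic midpoint
#'   \code{call_midpoint = 5} on the log2 scale with slope
#'   \code{call_slope = 1} and \code{marginal_rate = 0.01};
#'   \code{cross_map_frac = 0.01} of probesets annotated to a second gene;
#'   gene sets: \code{n_gene_sets = 100}, \code{set_size_range = c(10, 40)},
#'   \code{frac_enriched = 0.2}, \code{purity = 0.9}; seizure phenotypes:
#'   \code{latency_mean_s = 114}, \code{seizure_count_mean = 10.6},
#'   \code{seizure_count_sd = 2.9}; \code{seed = 1}.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_genes = 2000L,
    probesets_per_gene = c(1L, 3L),
    n_replicates = c(4L, 6L),
    baseline_mean = 7,
    baseline_sd = 1.5,
    dev_frac_up = 0.15,
    dev_frac_down = 0.15,
    dev_effect = 2,
    tissue_frac = 0.1,
    tissue_effect = 2,
    hs_frac = 0.1,
    hs_up_prop = 2 / 3,
    hs_effect = 1.5,
    hs_time_weights = c(0.6, 0.8, 1.0, 0.5, 0.3),
    nbqx_frac = 0.3,
    nbqx_effect = 1,
    nbqx_up_prop = 0.7,
    noise_sd = 0.5,
    probe_noise_sd = 0.25,
    probe_offset_sd = 0.5,
    call_midpoint = 5,
    call_slope = 1,
    marginal_rate = 0.01,
    cross_map_frac = 0.01,
    n_gene_sets = 100L,
    set_size_range = c(10L, 40L),
    frac_enriched = 0.2,
    purity = 0.9,
    latency_mean_s = 114,
    seizure_count_mean = 10.6,
    seizure_count_sd = 2.9,
    seed = 1L
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown) > 0)
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  fracs <- c("dev_frac_up", "dev_frac_down", "tissue_frac", "hs_frac",
             "hs_up_prop", "nbqx_frac", "nbqx_up_prop", "frac_enriched",
             "purity", "marginal_rate", "cross_map_frac")
  for (f in fracs) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(sprintf("%s must be in [0, 1]", f))
  }
  for (f in c("dev_effect", "tissue_effect", "hs_effect", "nbqx_effect",
              "noise_sd", "probe_noise_sd", "probe_offset_sd")) {
    if (cfg[[f]] < 0) stop(sprintf("%s must be >= 0", f))
  }
  if (any(cfg$n_replicates < 1))
    stop("replicate counts must be >= 1")
  if (length(cfg$hs_time_weights) != length(.TIMES_H))
    stop("hs_time_weights must have one weight per sampling time")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a complete synthetic study with ground truth
#'
#' Draws a full factorial study (tissue x treatment x time with jittered
#' replicate counts), probeset-level intensities on the linear scale as
#' \code{2^(baseline + tissue + developmental trend + HS effect + NBQX effect
#' + noise)}, intensity-dependent detection calls, a many-to-many
#' probeset-to-gene map, seizure phenotypes for the hypoxia-treated samples,
#' and the planted-truth labels needed to score downstream recovery.
#'
#' @param config a [sim_config()].
#' @return A list with elements \code{expr} ([expr_matrix()]), \code{design}
#'   (\code{sample_design} data.frame), \code{map} (probeset/gene pairs) and
#'   \code{truth} (list with per-gene data.frame \code{genes}).
#' @export
generate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  genes <- sprintf("g%05d", seq_len(ng))

  ## per-gene truth labels
  dev <- rep("flat", ng)
  n_up <- round(config$dev_frac_up * ng)
  n_dn <- round(config$dev_frac_down * ng)
  idx <- sample.int(ng, n_up + n_dn)
  dev[idx[seq_len(n_up)]] <- "up"
  if (n_dn > 0) dev[idx[n_up + seq_len(n_dn)]] <- "down"

  tissue_pref <- rep("none", ng)
  n_ts <- round(config$tissue_frac * ng)
  if (n_ts > 0) {
    idx <- sample(which(dev == "flat"), min(n_ts, sum(dev == "flat")))
    half <- length(idx) %/% 2
    tissue_pref[idx[seq_len(half)]] <- "hippocampus"
    tissue_pref[idx[-seq_len(half)]] <- "cortex"
  }

  hs <- rep("null", ng)
  n_hs <- round(config$hs_frac * ng)
  if (n_hs > 0) {
    idx <- sample.int(ng, n_hs)
    up <- stats::rbinom(n_hs, 1, config$hs_up_prop) == 1
    hs[idx[up]] <- "up"
    hs[idx[!up]] <- "down"
  }

  nbqx <- rep("null", ng)
  nbqx_dir <- rep(0, ng)
  hs_idx <- which(hs != "null")
  n_nb <- round(config$nbqx_frac * length(hs_idx))
  if (n_nb > 0) {
    idx <- sample(hs_idx, n_nb)
    nbqx[idx] <- "responsive"
    nbqx_dir[idx] <- ifelse(
      stats::rbinom(n_nb, 1, config$nbqx_up_prop) == 1, 1, -1)
  }

  ## probesets and annotation
  pr <- config$probesets_per_gene
  nps <- sample(seq(pr[1], pr[2]), ng, replace = TRUE)
  probe_gene <- rep(seq_len(ng), nps)
  np <- length(probe_gene)
  probesets <- sprintf("ps%05d_at", seq_len(np))
  map <- data.frame(probeset_id = probesets,
                    gene_symbol = genes[probe_gene],
                    stringsAsFactors = FALSE)
  n_cross <- round(config$cross_map_frac * np)
  if (n_cross > 0) {
    cp <- sample.int(np, n_cross)
    second <- sample.int(ng, n_cross, replace = TRUE)
    extra <- data.frame(probeset_id = probesets[cp],
                        gene_symbol = genes[second],
                        stringsAsFactors = FALSE)
    map <- unique(rbind(map, extra))
    map <- map[order(map$probeset_id, map$gene_symbol), ]
    rownames(map) <- NULL
  }

  ## design: full factorial with jittered replicate counts
  cells <- expand.grid(tissue = .TISSUES, treatment = .TREATMENTS,
                       time_h = .TIMES_H, stringsAsFactors = FALSE)
  reps <- sample(seq(config$n_replicates[1], config$n_replicates[2]),
                 nrow(cells), replace = TRUE)
  design <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(cells[i, , drop = FALSE], replicate = seq_len(reps[i]),
               row.names = NULL)
  }))
  design$sample_id <- sprintf("%s_%s_%03dh_r%d",
                              substr(design$tissue, 1, 4), design$treatment,
                              design$time_h, design$replicate)
  design <- design[, c("sample_id", "tissue", "treatment", "time_h",
                       "replicate")]
  ns <- nrow(design)

  ## seizure phenotypes for hypoxia-treated animals
  design$latency_s <- NA_real_
  design$seizure_count <- NA_integer_
  hyp <- design$treatment != "noHS"
  ph <- generate_phenotypes(sum(hyp), config, .reset_seed = FALSE)
  design$latency_s[hyp] <- ph$latency_s
  design$seizure_count[hyp] <- ph$seizure_count

  ## gene-level log2 signal
  baseline <- stats::rnorm(ng, config$baseline_mean, config$baseline_sd)
  t_idx <- match(design$time_h, .TIMES_H)
  trend <- (t_idx - 1) / (length(.TIMES_H) - 1)       # 0 at 1 h, 1 at 168 h
  dev_sign <- (dev == "up") - (dev == "down")
  hs_sign <- (hs == "up") - (hs == "down")
  hs_on <- as.numeric(design$treatment %in% c("HS", "HS_NBQX"))
  nb_on <- as.numeric(design$treatment == "HS_NBQX")
  w <- config$hs_time_weights[t_idx]

  logI_gene <- matrix(baseline, ng, ns)
  logI_gene <- logI_gene +
    outer(dev_sign * config$dev_effect, trend) +
    outer(hs_sign * config$hs_effect, hs_on * w) +
    outer(nbqx_dir * config$nbqx_effect, nb_on) +
    matrix(stats::rnorm(ng * ns, 0, config$noise_sd), ng, ns)
  ts_eff <- config$tissue_effect *
    ((tissue_pref == "hippocampus") %o% (design$tissue == "hippocampus") +
     (tissue_pref == "cortex") %o% (design$tissue == "cortex"))
  logI_gene <- logI_gene + ts_eff

  ## probeset-level measurements: shared gene signal + probe noise
  probe_offset <- stats::rnorm(np, 0, config$probe_offset_sd)
  logI <- logI_gene[probe_gene, , drop = FALSE] + probe_offset +
    matrix(stats::rnorm(np * ns, 0, config$probe_noise_sd), np, ns)
  intensity <- 2^logI
  dimnames(intensity) <- list(probesets, design$sample_id)

  ## detection calls thin with decreasing intensity
  p_absent <- stats::plogis(config$call_slope * (config$call_midpoint - logI))
  calls <- ifelse(matrix(stats::runif(np * ns), np, ns) < p_absent, "A", "P")
  m_flip <- calls == "P" &
    matrix(stats::runif(np * ns), np, ns) < config$marginal_rate
  calls[m_flip] <- "M"
  dimnames(calls) <- dimnames(intensity)

  truth <- list(
    genes = data.frame(
      gene = genes, dev = dev, tissue_pref = tissue_pref, hs = hs,
      hs_peak_h = ifelse(hs == "null", NA_real_,
                         .TIMES_H[which.max(config$hs_time_weights)]),
      nbqx = nbqx, nbqx_direction = nbqx_dir, stringsAsFactors = FALSE),
    config = config
  )

  list(expr = expr_matrix(intensity, calls),
       design = validate_design(design),
       map = map,
       truth = truth)
}

#' Draw seizure phenotypes for hypoxia-treated animals
#'
#' Latency to first seizure is exponential with the configured mean (default
#' 114 s); the seizure count over the hypoxic interval is Gaussian (default
#' mean 10.6, sd 2.9), truncated at zero and rounded to an integer.
#'
#' @param n number of hypoxia-treated animals (>= 1).
#' @param config a [sim_config()].
#' @param .reset_seed internal; set the module seed before drawing (default
#'   \code{TRUE}; [generate_study()] passes \code{FALSE} to keep a single
#'   reproducible stream).
#' @return data.frame with columns \code{latency_s} and \code{seizure_count}.
#' @export
generate_phenotypes <- function(n, config = sim_config(), .reset_seed = TRUE) {
  if (n < 1) stop("need at least one hypoxia-treated animal")
  if (config$latency_mean_s <= 0 || config$seizure_count_mean <= 0)
    stop("phenotype means must be positive")
  if (.reset_seed) set.seed(config$seed + 1L)
  latency <- stats::rexp(n, rate = 1 / config$latency_mean_s)
  count <- round(pmax(0, stats::rnorm(n, config$seizure_count_mean,
                                      config$seizure_count_sd)))
  data.frame(latency_s = latency, seizure_count = as.integer(count))
}

#' Generate signed gene sets with planted enrichment
#'
#' Truly enriched sets draw their positive regulatees preferentially (with
#' probability \code{purity}) from genes planted as HS-induced and their
#' negative regulatees from HS-repressed genes; null sets draw uniformly
#' from the gene universe. About two thirds of the members of an enriched
#' set are positive regulatees; most null sets are up-only, mirroring
#' typical curated collections.
#'
#' @param truth the \code{truth} element returned by [generate_study()].
#' @param config a [sim_config()].
#' @return A list with \code{sets} (list of [gene_set()]) and
#'   \code{enriched} (logical vector, the planted labels).
#' @export
generate_signed_gene_sets <- function(truth, config = sim_config()) {
  set.seed(config$seed + 2L)
  genes <- truth$genes$gene
  ng <- length(genes)
  up_pool <- genes[truth$genes$hs == "up"]
  dn_pool <- genes[truth$genes$hs == "down"]
  n_sets <- config$n_gene_sets
  n_enr <- round(config$frac_enriched * n_sets)
  sizes <- sample(seq(config$set_size_range[1], config$set_size_range[2]),
                  n_sets, replace = TRUE)
  if (any(sizes > ng)) stop("gene set size exceeds gene universe")
  enriched <- c(rep(TRUE, n_enr), rep(FALSE, n_sets - n_enr))
  sets <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    size <- sizes[i]
    if (enriched[i]) {
      ku <- max(1L, round(2 * size / 3))
      kd <- size - ku
      pick_signal <- function(k, pool) {
        take <- stats::rbinom(1, k, config$purity)
        take <- min(take, length(pool))
        sig <- if (take > 0) sample(pool, take) else character(0)
        bg <- sample(setdiff(genes, c(pool, sig)), k - take)
        c(sig, bg)
      }
      up <- pick_signal(ku, up_pool)
      dn <- if (kd > 0) pick_signal(kd, setdiff(dn_pool, up)) else character(0)
      dn <- setdiff(dn, up)
    } else {
      memb <- sample(genes, size)
      kd <- if (stats::runif(1) < 0.3) round(size / 3) else 0L
      up <- memb[seq_len(size - kd)]
      dn <- if (kd > 0) memb[(size - kd + 1):size] else character(0)
    }
    sets[[i]] <- gene_set(sprintf("set%03d", i), up, dn, source = "synthetic")
  }
  list(sets = sets, enriched = enriched)
}
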