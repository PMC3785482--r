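test_that("ratio estimation shrinks toward 1 and matches numeric integration", {
  # symmetry: equal means give ratio 1 at any noise level
  for (se in c(0, 0.5, 5)) {
    est <- estimate_ratio(10, se, 10, se, nA = 4, nB = 4)
    expect_equal(est$ratio_estimate, 1)
  }
  # noiseless limit recovers the plain ratio of means
  est0 <- estimate_ratio(10, 0, 20, 0, nA = 4, nB = 4)
  expect_equal(est0$ratio_estimate, 2)
  expect_equal(est0$p_value, 0)
  est_eq <- estimate_ratio(10, 0, 10, 0, nA = 4, nB = 4)
  expect_equal(est_eq$ratio_estimate, 1)
  expect_equal(est_eq$p_value, 1)

  # grid: |log2 estimate| <= |log2 ratio of means|, nonincreasing in se,
  # and equal to the numeric posterior-integration oracle
  for (ratio in c(1.5, 3)) {
    prev <- Inf
    for (se in c(0.1, 0.5, 1, 2, 5)) {
      est <- estimate_ratio(10, se, 10 * ratio, se * ratio, nA = 5, nB = 5)
      expect_lte(abs(est$log2_ratio), abs(log2(ratio)) + 1e-12)
      expect_lte(abs(est$log2_ratio), prev + 1e-12)
      prev <- abs(est$log2_ratio)
      tau <- sqrt((se / 10)^2 + ((se * ratio) / (10 * ratio))^2) / log(2)
      expect_equal(est$log2_ratio,
                   oracle_posterior_median(log2(ratio), tau),
                   tolerance = 2e-3)
    }
  }
  # antisymmetry: ratio(A,B) = 1 / ratio(B,A)
  a <- estimate_ratio(8, 1, 20, 2, nA = 4, nB = 6)
  b <- estimate_ratio(20, 2, 8, 1, nA = 6, nB = 4)
  expect_equal(a$ratio_estimate, 1 / b$ratio_estimate)
  expect_equal(a$p_value, b$p_value)
})

test_that("the ratio P-value is the classical equal-variance t-test", {
  set.seed(2)
  for (i in 1:5) {
    va <- rnorm(5, 100, 10); vb <- rnorm(7, 115, 10)
    est <- estimate_ratio(mean(va), sd(va) / sqrt(5),
                          mean(vb), sd(vb) / sqrt(7), nA = 5, nB = 7)
    expect_equal(est$p_value,
                 stats::t.test(vb, va, var.equal = TRUE)$p.value)
  }
})

test_that("ratio profiles use the min-P rule across a gene's probesets", {
  cfg <- fast_config(seed = 41)
  study <- generate_study(cfg)
  res <- ratio_profile(study$expr, study$map, study$design,
                       "noHS", "HS", "hippocampus")
  # recompute one gene by hand: the probeset with smallest P wins
  ps_res <- ratio_profile(study$expr, NULL, study$design,
                          "noHS", "HS", "hippocampus")
  multi <- names(which(table(study$map$gene_symbol) > 1))[1]
  ps <- study$map$probeset_id[study$map$gene_symbol == multi]
  for (t in unique(res$time_h)) {
    sub <- ps_res[ps_res$gene %in% ps & ps_res$time_h == t, ]
    best <- sub[order(sub$p_value, sub$gene), ][1, ]
    got <- res[res$gene == multi & res$time_h == t, ]
    expect_equal(got$p_value, best$p_value)
    expect_equal(got$ratio_estimate, best$ratio_estimate)
  }
})

test_that("null contrasts give unit ratios and uniform P-values", {
  cfg <- null_config(seed = 43)
  study <- generate_study(cfg)
  # probeset-level: the min-P gene rule deliberately skews gene-level P
  res <- ratio_profile(study$expr, NULL, study$design,
                       "noHS", "HS", "cortex")
  expect_lt(abs(median(res$log2_ratio)), 0.1)
  one_t <- res[res$time_h == 12, ]
  expect_gt(stats::ks.test(one_t$p_value, "punif")$p.value, 0.01)
})

test_that("planted fold change at the peak time is recovered", {
  cfg <- sim_config(n_genes = 500L, seed = 47)
  study <- generate_study(cfg)
  res <- ratio_profile(study$expr, study$map, study$design,
                       "noHS", "HS", "hippocampus")
  up <- study$truth$genes$gene[study$truth$genes$hs == "up"]
  got <- res$log2_ratio[res$gene %in% up & res$time_h == 12]
  # planted effect is hs_effect * weight(12 h) = 1.5 log2 units
  expect_lt(abs(mean(got) - 1.5), 0.25)
})

test_that("two-way ANOVA matches the balanced textbook decomposition", {
  # balanced 2x2 with 2 replicates, hand-computable sums of squares
  y <- c(10, 12, 20, 22, 14, 16, 30, 32)
  tr <- factor(rep(c("a", "a", "b", "b"), 2))
  ti <- factor(rep(c("t1", "t2"), each = 4))
  res <- two_way_anova(y, tr, ti)
  # textbook oracle: balanced data, sequential = partial sums of squares
  tab <- stats::anova(stats::lm(y ~ tr * ti))
  expect_equal(res$F_treatment, tab["tr", "F value"], tolerance = 1e-10)
  expect_equal(res$p_treatment, tab["tr", "Pr(>F)"], tolerance = 1e-10)
  expect_equal(res$F_time, tab["ti", "F value"], tolerance = 1e-10)
  expect_equal(res$F_interaction, tab["tr:ti", "F value"], tolerance = 1e-10)
})

test_that("unbalanced ANOVA agrees with the Type II reference", {
  skip_if_not_installed("car")
  set.seed(8)
  tr <- factor(sample(c("a", "b"), 26, TRUE))
  ti <- factor(sample(paste0("t", 1:5), 26, TRUE))
  while (any(table(tr, ti) == 0) || max(table(tr, ti)) < 2) {
    tr <- factor(sample(c("a", "b"), 26, TRUE))
    ti <- factor(sample(paste0("t", 1:5), 26, TRUE))
  }
  Y <- matrix(rnorm(3 * 26), 3, dimnames = list(paste0("f", 1:3), NULL))
  res <- two_way_anova(Y, tr, ti)
  for (i in 1:3) {
    ref <- car::Anova(stats::lm(Y[i, ] ~ tr * ti), type = 2)
    expect_equal(res$p_treatment[i], ref["tr", "Pr(>F)"], tolerance = 1e-8)
    expect_equal(res$p_time[i], ref["ti", "Pr(>F)"], tolerance = 1e-8)
    expect_equal(res$p_interaction[i], ref["tr:ti", "Pr(>F)"],
                 tolerance = 1e-8)
  }
})

test_that("constant responses are degenerate with P = 1", {
  tr <- factor(rep(c("a", "b"), each = 4))
  ti <- factor(rep(c("t1", "t2"), 4))
  res <- two_way_anova(rep(5, 8), tr, ti)
  expect_true(res$degenerate)
  expect_equal(res$p_treatment, 1)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  got <- bh_fdr(c(0.01, 0.02, 0.5), q = 0.25)
  expect_equal(got$adjusted, c(0.03, 0.03, 0.5))
  expect_equal(got$selected, c(1L, 2L))
  expect_equal(bh_fdr(numeric(0))$selected, integer(0))
  expect_length(bh_fdr(rep(1, 5), 0.25)$selected, 0)
  set.seed(12)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_fdr(p)$adjusted, oracle_bh(p))
  }
})

test_that("response-set selection is calibrated and recovers planted genes", {
  cfg <- null_config(seed = 51)
  study <- generate_study(cfg)
  # raw-P mode on a null study selects about the nominal fraction
  sel_raw <- select_response_set(study$expr, study$map, study$design,
                                 "hippocampus", c("noHS", "HS"),
                                 list(mode = "raw_p", value = 0.01))
  n_ps <- nrow(study$expr$intensity)
  expect_lt(length(sel_raw$probesets) / n_ps, 0.03)
  # FDR mode on a null study selects essentially nothing
  sel_fdr <- select_response_set(study$expr, study$map, study$design,
                                 "hippocampus", c("noHS", "HS"),
                                 list(mode = "fdr", value = 0.25))
  expect_lt(length(sel_fdr$genes), 10)

  strong <- generate_study(sim_config(seed = 52))
  truth <- strong$truth$genes
  hs_true <- truth$gene[truth$hs != "null"]
  hits <- unique(unlist(lapply(c("hippocampus", "cortex"), function(t)
    select_response_set(strong$expr, strong$map, strong$design, t,
                        c("noHS", "HS"),
                        list(mode = "fdr", value = 0.25))$genes)))
  expect_gte(mean(hs_true %in% hits), 0.9)

  expect_error(select_response_set(study$expr, study$map, study$design,
                                   "hippocampus", c("noHS", "HS"),
                                   list(mode = "both", value = 0.1)),
               "threshold_spec")
})

test_that("overlap statistics match exhaustive enumeration on small universes", {
  # fixed small case: all overlaps of a 4-set with random 5-sets from 10
  subsets <- utils::combn(10, 5, simplify = FALSE)
  fixed <- 1:4
  ov <- vapply(subsets, function(s) length(intersect(fixed, s)), numeric(1))
  for (k in 0:4) {
    got <- overlap_statistics(4, 5, 10, k)
    expect_equal(got$expected_mean, 2)
    expect_equal(got$tail_p, mean(ov >= k))
  }
  expect_equal(got$expected_se, sd(ov) * sqrt((length(ov) - 1) / length(ov)),
               tolerance = 1e-12)
  z <- overlap_statistics(0, 5, 10, 0)
  expect_equal(z$expected_mean, 0)
  expect_equal(z$tail_p, 1)
})

test_that("set algebra obeys inclusion-exclusion", {
  s <- set_algebra(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(s$intersection, c("b", "c"))
  expect_equal(s$union, c("a", "b", "c", "d"))
  ident <- set_algebra(c("x", "y"), c("x", "y"))
  expect_equal(ident$intersection, ident$union)
  set.seed(3)
  for (i in 1:20) {
    a <- sample(letters, sample(5:20, 1))
    b <- sample(letters, sample(5:20, 1))
    s <- set_algebra(a, b)
    expect_equal(s$n_union, s$n_a + s$n_b - s$n_intersection)
  }
})
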