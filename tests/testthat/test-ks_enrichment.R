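test_that("rank transform is a deterministic descending permutation", {
  expect_equal(unname(rank_transform(setNames(c(5, 3, 9), c("a", "b", "c")))),
               c(2, 3, 1))
  # ties resolved by gene name, reproducibly
  tied <- setNames(c(1, 1, 2), c("b", "a", "c"))
  r1 <- rank_transform(tied)
  expect_equal(r1[["a"]], 2)
  expect_equal(r1[["b"]], 3)
  expect_identical(r1, rank_transform(tied))
  set.seed(6)
  v <- setNames(rnorm(100), paste0("g", 1:100))
  expect_setequal(rank_transform(v), 1:100)
  expect_error(rank_transform(setNames(c(1, NA), c("a", "b"))), "missing")
})

test_that("signed deviations reproduce the worked step-point cases", {
  rk <- rank_transform(setNames(seq(10, 1), paste0("g", 1:10)))
  d <- signed_deviations(rk, c("g1", "g2"))
  expect_equal(d$d_u, 0.8)
  expect_equal(d$x_u_star, 0.2)
  # mirror symmetry for a bottom-ranked down group
  d2 <- signed_deviations(rk, character(0), c("g9", "g10"))
  expect_equal(d2$d_d, -0.8)
  # saturation: the whole universe deviates by at most 1/n
  full <- signed_deviations(rk, paste0("g", 1:10))
  expect_lte(abs(full$d_u), 1 / 10)
  expect_error(signed_deviations(rk, character(0), character(0)), "empty")
  expect_error(signed_deviations(rk, c("g1"), c("g1")), "disjoint")
})

test_that("deviations and leading edges equal exhaustive enumeration", {
  set.seed(17)
  for (rep in 1:500) {
    n <- sample(3:12, 1)
    rk <- rank_transform(setNames(rnorm(n), sprintf("x%02d", 1:n)))
    k_u <- sample(0:min(3, n - 1), 1)
    k_d <- sample(0:min(3, n - k_u), 1)
    if (k_u + k_d == 0) k_u <- 1
    picks <- sample(names(rk), k_u + k_d)
    up <- picks[seq_len(k_u)]
    dn <- picks[k_u + seq_len(k_d)]
    dev <- signed_deviations(rk, up, dn)
    ou <- oracle_signed_dev(unname(rk[up]), n)
    od <- oracle_signed_dev(unname(rk[dn]), n)
    expect_equal(dev$d_u, ou$d)
    expect_equal(dev$d_d, od$d)
    le <- leading_edge(rk, up, dn)
    expect_equal(sort(unname(rk[le$leading_edge_up])),
                 oracle_leading_edge_up(unname(rk[up]), n))
    expect_equal(sort(unname(rk[le$leading_edge_down])),
                 oracle_leading_edge_down(unname(rk[dn]), n))
    expect_true(all(le$leading_edge_up %in% up))
    expect_true(all(le$leading_edge_down %in% dn))
  }
})

test_that("the combined statistic satisfies its stated limits and bounds", {
  expect_equal(combined_statistic(0.43, 7, 0, 0), 0.43)     # k_d = 0 limit
  expect_equal(combined_statistic(0, 0, -0.6, 4), 0.6)      # k_u = 0 limit
  expect_equal(combined_statistic(0.8, 2, -0.8, 2), 0.8)    # coherent case
  expect_error(combined_statistic(0, 0, 0, 0), ">= 1")
  # continuity: dropping the last down-regulatee moves d_UpDown to d_u
  d_full <- combined_statistic(0.5, 9, -0.3, 1)
  expect_lt(abs(d_full - 0.5), 0.1)
  expect_equal(combined_statistic(0.5, 9, 0, 0), 0.5)
})

test_that("the statistic is bounded by 1 over exhaustive placements", {
  worst <- 0
  for (n in 2:8) {
    for (ku in 0:min(3, n)) {
      for (kd in 0:min(3, n - ku)) {
        if (ku + kd == 0) next
        vals <- oracle_dupdown_all(n, ku, kd)
        worst <- max(worst, max(abs(vals)))
      }
    }
  }
  expect_lte(worst, 1)
  expect_gt(worst, 0.5)  # the bound is approached, not vacuous
})

test_that("mirror antisymmetry: negated profile with swapped groups preserves d_UpDown", {
  # D'(n - g) = -D(g) exactly under the mirror map, so the statistic is
  # invariant whenever the maximum absolute deviation of each group is
  # attained at a unique grid point (ties may legitimately resolve to the
  # opposite-signed achiever under the deterministic leftmost rule).
  has_tie <- function(r, n) {
    g <- 0:n
    D <- vapply(g, function(x) mean(r <= x), numeric(1)) - g / n
    sum(abs(abs(D) - max(abs(D))) < 1e-12) > 1
  }
  set.seed(19)
  checked <- 0
  for (rep in 1:80) {
    n <- 30
    v <- setNames(rnorm(n), sprintf("g%02d", 1:n))
    rk <- rank_transform(v)
    up <- sample(names(v), 4); dn <- sample(setdiff(names(v), up), 3)
    if (has_tie(unname(rk[up]), n) || has_tie(unname(rk[dn]), n)) next
    d1 <- signed_deviations(rk, up, dn)
    s1 <- combined_statistic(d1$d_u, d1$k_u, d1$d_d, d1$k_d)
    rk2 <- rank_transform(-v)
    d2 <- signed_deviations(rk2, dn, up)
    s2 <- combined_statistic(d2$d_u, d2$k_u, d2$d_d, d2$k_d)
    expect_equal(s1, s2, tolerance = 1e-12)
    checked <- checked + 1
  }
  expect_gte(checked, 30)
})

test_that("permutation P matches exhaustive enumeration on a 4-gene universe", {
  rk <- rank_transform(setNames(c(4, 3, 2, 1), c("a", "b", "c", "d")))
  exhaustive <- oracle_dupdown_all(4, 1, 0)  # 4 placements
  for (gene in c("a", "c")) {
    obs <- signed_deviations(rk, gene)$d_u
    p_true <- mean(exhaustive >= obs - 1e-12)
    nper <- 4000
    p_mc <- as.numeric(permutation_pvalue(rk, gene_set("s", gene),
                                          n_perm = nper, seed = 3))
    mc_se <- sqrt(p_true * (1 - p_true) / nper)
    expect_lt(abs(p_mc - p_true), 3 * mc_se + 1e-9)
  }
})

test_that("permutation P is calibrated and ordered under the null", {
  set.seed(23)
  n <- 200
  rk <- rank_transform(setNames(rnorm(n), sprintf("g%03d", 1:n)))
  null <- ks_null_dupdown(n, 5, 3, 20000)
  # observed statistic below the null median must give P > 0.5
  low_obs <- quantile(null, 0.2)
  expect_gt(mean(null >= low_obs), 0.5)
  # type-I: random sets rejected at about the nominal rate
  ps <- replicate(400, {
    picks <- sample(names(rk), 8)
    as.numeric(permutation_pvalue(rk, gene_set("s", picks[1:5], picks[6:8]),
                                  n_perm = 400))
  })
  expect_gt(mean(ps <= 0.05), 0.02)
  expect_lt(mean(ps <= 0.05), 0.09)
})

test_that("enrichment scores are chord slopes with neutral value 1", {
  # all 5 up-regulatees at the top of 100 ranks: c_left = 20
  rk <- rank_transform(setNames(seq(100, 1), sprintf("g%03d", 1:100)))
  es <- enrichment_scores(rk, sprintf("g%03d", 1:5))
  expect_equal(es$c_left, 20)
  expect_equal(es$c_right, 1)  # no down group -> neutral
  es2 <- enrichment_scores(rk, character(0), sprintf("g%03d", 96:100))
  expect_equal(es2$c_right, 20)
  expect_equal(es2$c_left, 1)
  # uniformly scattered regulatees score about 1
  set.seed(29)
  cl <- replicate(300, {
    enrichment_scores(rk, sample(names(rk), 10))$c_left
  })
  expect_gt(mean(cl), 0.8)
  expect_lt(mean(cl), 1.3)
})

test_that("collection screening recovers planted sets within FDR control", {
  cfg <- sim_config(seed = 61)
  study <- generate_study(cfg)
  gs <- generate_signed_gene_sets(study$truth, cfg)
  res <- ratio_profile(study$expr, study$map, study$design,
                       "noHS", "HS", "hippocampus")
  r12 <- res[res$time_h == 12, ]
  profile <- setNames(r12$log2_ratio, r12$gene)
  tab <- screen_collection(profile, gs$sets, n_perm = 2000, seed = 2)
  expect_named(tab, c("name", "source", "ku", "kd", "d_updown", "p_value",
                      "fdr", "c_left", "c_right", "selected",
                      "leading_edge_up", "leading_edge_down"))
  hit <- tab$selected[match(sprintf("set%03d", 1:cfg$n_gene_sets), tab$name)]
  tp <- sum(hit & gs$enriched); fp <- sum(hit & !gs$enriched)
  expect_gte(tp, 18)
  expect_lte(fp / max(1, tp + fp), 0.25)
  expect_true(all(abs(tab$d_updown) <= 1))
  expect_true(all(tab$fdr >= tab$p_value - 1e-12))
})

test_that("screening an all-null collection selects essentially nothing", {
  cfg <- sim_config(seed = 67, frac_enriched = 0)
  study <- generate_study(cfg)
  gs <- generate_signed_gene_sets(study$truth, cfg)
  res <- ratio_profile(study$expr, study$map, study$design,
                       "noHS", "HS", "hippocampus")
  r12 <- res[res$time_h == 12, ]
  profile <- setNames(r12$log2_ratio, r12$gene)
  # null sets on a signal-bearing profile: none should pass FDR + C
  tab <- screen_collection(profile, gs$sets, n_perm = 2000, seed = 2)
  expect_lte(sum(tab$selected), 0.05 * nrow(tab))
})

test_that("KS plot data yields monotone steps and a calibrated null band", {
  set.seed(31)
  n <- 400
  rk <- rank_transform(setNames(rnorm(n), sprintf("g%03d", 1:n)))
  pd <- ks_plot_data(rk, sprintf("g%03d", 1:10), sprintf("g%03d", 390:400 - 1))
  for (gr in unique(pd$steps$group)) {
    s <- pd$steps[pd$steps$group == gr, ]
    expect_true(all(diff(s$x) >= 0))
    expect_true(all(diff(s$y) >= 0))
  }
  expect_error(ks_plot_data(rk, "g001", confidence = 1.2), "confidence")
  # coverage: sup deviation of a random group stays inside the 95% band
  # about 95% of the time
  k <- 30
  band <- ks_plot_data(rk, sample(names(rk), k))$band_halfwidth
  inside <- replicate(600, {
    g <- sort(sample(n, k))
    abs(oracle_signed_dev(g, n)$d) <= band
  })
  expect_gt(mean(inside), 0.90)
  expect_lt(mean(inside), 0.995)
  # a top-ranked up-set exits the band upward
  top <- signed_deviations(rk, names(sort(rk))[1:k])
  expect_gt(top$d_u, band)
})
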