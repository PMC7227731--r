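test_that("geometry generation is deterministic and geometrically bounded", {
  cfg <- synthetic_config(n_samples = 300, n_tissues = 20, n_genes = 10,
                          length_scales = list(c(10, 0)),
                          network_spec = list(n_clusters = 8,
                                              composition = c(3, 2, 2, 1),
                                              cluster_radius_mm = 10),
                          seed = 1)
  tab1 <- generate_cortex_geometry(cfg)
  tab2 <- generate_cortex_geometry(cfg)
  expect_equal(as.data.frame(tab1), as.data.frame(tab2))
  expect_equal(nrow(tab1), 300)
  expect_equal(length(unique(tab1$tissue_label)), 20)
  # max pairwise distance bounded by the shell diameter (+ jitter tail)
  d <- dist(as.matrix(as.data.frame(tab1)[, c("x", "y", "z")]))
  expect_lte(max(d), 2 * (cfg$shell_radius_mm + 5 * cfg$shell_jitter_mm))
})

test_that("network labels are disjoint contiguous cluster groups inside their spheres", {
  cfg <- synthetic_config(n_samples = 400, n_tissues = 30, n_genes = 10,
                          length_scales = list(c(10, 0)), seed = 4)
  tab <- generate_cortex_geometry(cfg)
  labs <- setdiff(unique(tab$network_label), 0L)
  expect_setequal(labs, 1:13)  # 13 non-empty networks
  clusters <- attr(tab, "network_clusters")
  coords <- as.matrix(as.data.frame(tab)[, c("x", "y", "z")])
  rownames(coords) <- tab$sample_id
  # every network sample lies within one of the generating spheres
  centers <- coords[clusters$centers, , drop = FALSE]
  net_ids <- tab$sample_id[tab$network_label > 0]
  for (id in net_ids) {
    d2 <- colSums((t(centers) - coords[id, ])^2)
    expect_lte(min(d2), clusters$radius_mm^2 + 1e-9)
  }
  # network sample fraction tracks the calibrated ~28% design target
  expect_gt(mean(tab$network_label > 0), 0.18)
  expect_lt(mean(tab$network_label > 0), 0.40)
  # infeasible request: more network samples than samples
  expect_error(
    synthetic_config(n_samples = 50, n_genes = 10,
                     length_scales = list(c(10, 0)),
                     network_spec = list(n_clusters = 2, composition = c(1, 1),
                                         cluster_radius_mm = 5,
                                         target_samples = 100)),
    class = "ssf_config_error")
})

test_that("expression blocks have the requested spatial autocorrelation structure", {
  n <- 300
  cfg <- synthetic_config(n_samples = n, n_tissues = 40, n_genes = 400,
                          length_scales = list(c(200, 30), c(200, 0)),
                          noise_sd = 0.3,
                          network_spec = list(n_clusters = 8,
                                              composition = c(3, 2, 2, 1),
                                              cluster_radius_mm = 10),
                          seed = 6)
  tab <- generate_cortex_geometry(cfg)
  expr <- generate_expression(tab, cfg)
  expect_equal(dim(expr), c(400, n))
  expect_identical(expr, generate_expression(tab, cfg))  # seed determinism
  ls <- attr(expr, "length_scale")
  w <- suppressMessages(build_weights(tab))
  pg <- suppressMessages(moran_per_gene(expr, w))
  i0 <- pg$I[ls == 0]
  i30 <- pg$I[ls == 30]
  # lambda = 0 block: mean Moran's I at the permutation-null expectation
  n_eff <- n - length(w$islands)
  expect_lt(abs(mean(i0) - (-1 / (n_eff - 1))), 4 * sd(i0) / sqrt(length(i0)))
  # lambda = 30 block: strong positive autocorrelation, above the null block
  expect_gt(mean(i30), 0.2)
  expect_gt(mean(i30), mean(i0))
  # the same ordering holds across independent seeds
  for (s in c(7, 8)) {
    cfg_s <- synthetic_config(n_samples = 200, n_tissues = 30, n_genes = 120,
                              length_scales = list(c(60, 30), c(60, 0)),
                              noise_sd = 0.3,
                              network_spec = list(n_clusters = 6,
                                                  composition = c(3, 2, 1),
                                                  cluster_radius_mm = 10),
                              seed = s)
    tab_s <- generate_cortex_geometry(cfg_s)
    expr_s <- generate_expression(tab_s, cfg_s)
    w_s <- suppressMessages(build_weights(tab_s))
    pg_s <- suppressMessages(moran_per_gene(expr_s, w_s))
    ls_s <- attr(expr_s, "length_scale")
    expect_gt(mean(pg_s$I[ls_s == 30]), mean(pg_s$I[ls_s == 0]))
  }
})

test_that("coincident samples share latent expression (kernel at d = 0 is 1)", {
  coords <- rbind(c(10, 0, 0), c(10, 0, 0), matrix(runif(54, -30, 30), 18, 3))
  tab <- toy_table(coords)
  cfg <- synthetic_config(n_samples = 20, n_tissues = 5, n_genes = 300,
                          length_scales = list(c(300, 15)), noise_sd = 0,
                          network_spec = list(n_clusters = 1, composition = 1,
                                              cluster_radius_mm = 2),
                          seed = 9)
  expr <- generate_expression(tab, cfg)
  expect_gt(cor(expr[, 1], expr[, 2]), 0.999)
})

test_that("distance-correlation profile bins half-open and decays for GP data", {
  # binning arithmetic: mutual distances 5, 9, 13 -> bins [0,8) and [8,16)
  p3 <- c((81 - 169 + 25) / 10, sqrt(81 - ((81 - 169 + 25) / 10)^2), 0)
  tab <- toy_table(rbind(c(0, 0, 0), c(5, 0, 0), p3), tissue = letters[1:3])
  d <- dist(rbind(c(0, 0, 0), c(5, 0, 0), p3))
  expect_equal(sort(round(as.numeric(d))), c(5, 9, 13))
  expr <- random_expr(10, tab, seed = 5)
  prof <- distance_correlation_profile(expr, tab)
  expect_equal(prof$bin_lo, c(0, 8))
  expect_equal(prof$n_pairs, c(1L, 2L))
  # identical profiles across samples -> every bin median is exactly 1
  same <- matrix(rep(rnorm(10), 3), 10, 3)
  dimnames(same) <- dimnames(expr)
  prof1 <- distance_correlation_profile(same, tab)
  expect_true(all(prof1$median_correlation == 1))
  # GP data: per-bin medians match brute-force pairwise correlations and the
  # curve is non-increasing over the first bins (one inversion allowed)
  cortex <- structured_cortex()
  sub <- cortex$table[1:120, ]
  class(sub) <- c("sample_table", "data.frame")
  expr_s <- cortex$expr[, sub$sample_id]
  prof2 <- distance_correlation_profile(expr_s, sub, within_tissue_corrected = FALSE)
  coords <- as.matrix(as.data.frame(sub)[, c("x", "y", "z")])
  D <- as.matrix(dist(coords))
  cors <- dists <- c()
  for (i in 1:119) {
    for (j in (i + 1):120) {
      cors <- c(cors, pearson_oracle(expr_s[, i], expr_s[, j]))
      dists <- c(dists, D[i, j])
    }
  }
  for (b in seq_len(nrow(prof2))) {
    in_bin <- dists >= prof2$bin_lo[b] & dists < prof2$bin_lo[b] + 8
    expect_equal(prof2$median_correlation[b], median(cors[in_bin]),
                 tolerance = 1e-12)
  }
  first5 <- prof2$median_correlation[1:5]
  expect_lte(sum(diff(first5) > 0), 1)
  expect_gt(first5[1], first5[5])
})
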