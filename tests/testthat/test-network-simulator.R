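test_that("34 centers at radius 0 give 561 center pairs", {
  cortex <- structured_cortex()
  centers <- sample_cluster_centers(cortex$table, 0, 34, "All", seed = 1)
  expect_length(centers, 34)
  expect_length(unique(centers), 34)
  expect_equal(ncol(combn(length(centers), 2)), 561)
})

test_that("center placement enforces the non-overlap constraint and covers all valid sets", {
  toy <- line_table(seq(0, 90, by = 10), tissue = letters[1:10])
  xs <- seq(0, 90, by = 10)
  valid <- combn(10, 3)
  valid <- valid[, apply(valid, 2, function(ix) min(diff(xs[ix])) > 12), drop = FALSE]
  expect_equal(ncol(valid), 56)  # enumeration oracle
  keys <- apply(valid, 2, paste, collapse = "-")
  set.seed(123)
  n_draws <- 20000
  drawn <- vapply(seq_len(n_draws), function(i) {
    cen <- sample_cluster_centers(toy, 6, 3, "All")
    paste(sort(match(cen, toy$sample_id)), collapse = "-")
  }, "")
  # every draw satisfies the pairwise gap > 12 mm constraint
  expect_true(all(drawn %in% keys))
  counts <- table(factor(drawn, levels = keys))
  expect_true(all(counts > 0))  # full support coverage
  # frequencies close to the uniform enumeration (sequential placement is
  # approximately uniform here; exact sequential-vs-uniform TV is 0.043)
  expect_lt(0.5 * sum(abs(counts / n_draws - 1 / 56)), 0.07)
})

test_that("variant constraints restrict centers and member pools", {
  tab <- line_table(seq(0, 150, by = 10),
                    tissue = letters[1:16],
                    network = c(rep(0L, 7), 4L, rep(0L, 6), 2L, 0L))
  # Z-cn: sample 8 (network 4) never a center
  for (s in 1:200) {
    cen <- sample_cluster_centers(tab, 4, 3, "Z-cn", seed = s)
    expect_false("s08" %in% cen)
  }
  # but Z-cn clusters may still contain rsfMRI members
  cl <- build_clusters("s07", 11, tab, "Z-cn")
  expect_true("s08" %in% cl$members[[1]])
  # omit-RS: an rsfMRI sample 3 mm from a center is excluded from the cluster
  tab2 <- line_table(c(0, 3, 6), network = c(0L, 2L, 0L))
  cl2 <- build_clusters("s01", 4, tab2, "omit-RS")
  expect_setequal(cl2$members[[1]], c("s01"))
  cl2b <- build_clusters("s01", 8, tab2, "omit-RS")
  expect_setequal(cl2b$members[[1]], c("s01", "s03"))
})

test_that("cluster membership equals a brute-force distance filter", {
  set.seed(21)
  tab <- toy_table(matrix(runif(90, 0, 60), 30, 3))
  coords <- as.matrix(as.data.frame(tab)[, c("x", "y", "z")])
  centers <- sample_cluster_centers(tab, 9, 3, "All", seed = 2)
  cl <- build_clusters(centers, 9, tab)
  for (k in seq_along(centers)) {
    ci <- coords[match(centers[k], tab$sample_id), ]
    d <- sqrt(colSums((t(coords) - ci)^2))
    expect_setequal(cl$members[[k]], tab$sample_id[d <= 9])  # closed ball
  }
  # isolation: radius below nearest-neighbor distance -> singleton cluster
  iso <- line_table(c(0, 7, 50))
  cli <- build_clusters("s01", 6, iso, "All")
  expect_equal(cli$members[[1]], "s01")
  # packing failure reports how many clusters were placed
  err <- tryCatch(sample_cluster_centers(line_table(c(0, 5, 10)), 20, 3, "All",
                                         seed = 1, max_proposals = 50),
                  ssf_packing_error = function(e) e)
  expect_s3_class(err, "ssf_packing_error")
  expect_match(conditionMessage(err), "placed 1 of 3")
})

test_that("cluster grouping is uniform over partitions and deterministic by seed", {
  tab <- line_table(c(0, 30, 60), tissue = letters[1:3])
  cl <- build_clusters(c("s01", "s02", "s03"), 5, tab)
  # composition (2,1) on 3 singleton clusters: exactly 3 possible partitions
  seen <- integer(3)
  set.seed(77)
  n_draws <- 3000
  for (i in seq_len(n_draws)) {
    nets <- group_into_networks(cl, composition = c(2, 1))
    lone <- nets$networks[[2]]
    seen[match(lone, tab$sample_id)] <- seen[match(lone, tab$sample_id)] + 1
  }
  expect_true(all(seen > 0))
  expect_lt(max(abs(seen / n_draws - 1 / 3)), 0.035)
  # determinism and each-cluster-used-once
  a <- group_into_networks(cl, composition = c(2, 1), seed = 5)
  b <- group_into_networks(cl, composition = c(2, 1), seed = 5)
  expect_identical(a$networks, b$networks)
  expect_setequal(unlist(a$cluster_assignment), 1:3)
  expect_error(group_into_networks(cl, composition = c(2, 2)),
               class = "ssf_config_error")
})

test_that("network metrics match exhaustive pair enumeration", {
  # one network of two samples 3 mm apart
  tab <- line_table(c(0, 3, 50), tissue = letters[1:3])
  cl <- build_clusters("s01", 3, tab)
  nets <- group_into_networks(cl, composition = 1, seed = 1)
  m <- network_metrics(nets, cl, tab)
  expect_equal(m$W, 2)
  expect_equal(m$median_within_edge_mm, 3.0)
  # hand-placed toy: all three metrics against brute force
  set.seed(13)
  tab2 <- toy_table(matrix(runif(60, 0, 80), 20, 3))
  coords <- as.matrix(as.data.frame(tab2)[, c("x", "y", "z")])
  centers <- sample_cluster_centers(tab2, 10, 3, "All", seed = 4)
  cl2 <- build_clusters(centers, 10, tab2)
  nets2 <- group_into_networks(cl2, composition = c(2, 1), seed = 9)
  m2 <- network_metrics(nets2, cl2, tab2)
  expect_equal(m2$W, length(unlist(nets2$networks)))
  within <- c()
  for (net in nets2$networks) {
    ix <- match(net, tab2$sample_id)
    if (length(ix) < 2) next
    for (a in seq_len(length(ix) - 1)) {
      for (b in (a + 1):length(ix)) {
        within <- c(within, sqrt(sum((coords[ix[a], ] - coords[ix[b], ])^2)))
      }
    }
  }
  expect_equal(m2$median_within_edge_mm, median(within), tolerance = 1e-12)
  cix <- match(centers, tab2$sample_id)
  cent_d <- c()
  for (a in 1:2) for (b in (a + 1):3) {
    cent_d <- c(cent_d, sqrt(sum((coords[cix[a], ] - coords[cix[b], ])^2)))
  }
  expect_equal(m2$median_center_edge_mm, median(cent_d), tolerance = 1e-12)
  # center-pair distances do not depend on the cluster radius
  cl3 <- build_clusters(centers, 2, tab2)
  nets3 <- group_into_networks(cl3, composition = c(2, 1), seed = 9)
  m3 <- network_metrics(nets3, cl3, tab2)
  expect_equal(m3$median_center_edge_mm, m2$median_center_edge_mm)
})

test_that("W grows with cluster radius in expectation", {
  cortex <- structured_cortex()
  w_by_radius <- sapply(c(6, 14), function(r) {
    mean(sapply(1:10, function(s) {
      cen <- sample_cluster_centers(cortex$table, r, 20, "All",
                                    seed = derive_seed(400, r, s))
      cl <- build_clusters(cen, r, cortex$table)
      nets <- group_into_networks(cl, composition = c(rep(3, 5), rep(2, 2), 1))
      sum(lengths(nets$networks))
    }))
  })
  expect_gt(w_by_radius[2], w_by_radius[1])
})

test_that("real-network centroids use size-ranked cluster counts and hit blob means", {
  # two well-separated blobs, k = 2 -> centroids within 1 mm of blob means
  set.seed(31)
  blob1 <- matrix(rnorm(30, sd = 2), 10, 3)
  blob2 <- sweep(matrix(rnorm(30, sd = 2), 10, 3), 2, c(20, 0, 0), "+")
  tab <- toy_table(rbind(blob1, blob2), network = rep(1L, 20))
  res <- real_network_centroids(tab, k_per_network = c("1" = 2L))
  ord <- order(res$centroids[, 1])
  expect_lt(sqrt(sum((res$centroids[ord[1], ] - colMeans(blob1))^2)), 1)
  expect_lt(sqrt(sum((res$centroids[ord[2], ] - colMeans(blob2))^2)), 1)
  # k = 1 is the coordinate mean
  one <- toy_table(blob1, network = rep(2L, 10))
  r1 <- real_network_centroids(one, k_per_network = c("2" = 1L))
  expect_equal(unname(drop(r1$centroids)), unname(colMeans(blob1)),
               tolerance = 1e-12)
  # size ranking: nine largest -> 3, next three -> 2, smallest -> 1
  sizes <- c(40, 38, 36, 34, 32, 30, 28, 26, 24, 20, 18, 16, 4)
  labs <- rep(1:13, times = sizes)
  tab13 <- toy_table(matrix(rnorm(3 * length(labs), sd = 30), ncol = 3),
                     network = labs)
  k <- default_k_per_network(tab13)
  expect_equal(unname(k[as.character(1:9)]), rep(3L, 9))
  expect_equal(unname(k[as.character(10:12)]), rep(2L, 3))
  expect_equal(unname(k["13"]), 1L)
  full <- real_network_centroids(tab13)
  expect_equal(nrow(full$centroids), 34)
  expect_error(real_network_centroids(one, k_per_network = c("2" = 20L)),
               class = "ssf_validation_error")
})
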