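# Random spatially contiguous "noise" networks.
#
# A simulated network set is built from non-overlapping spherical clusters:
# cluster centers are cortical samples drawn at random under the constraint
# that spheres of the chosen radius do not overlap (center spacing strictly
# greater than 2r); each cluster collects every pool sample within the radius
# (closed ball); clusters are then grouped at random into 13 networks with
# the composition nine networks of three clusters, three of two and one of a
# single cluster. Three pool variants mirror the experiment arms: "All"
# (no restriction), "Z-cn" (centers must be non-network samples, members
# unrestricted) and "omit-RS" (centers and members both drawn only from
# non-network samples).

variant_pools <- function(table, variant) {
  non_rs <- table$network_label == 0L
  switch(variant,
    "All"     = list(member = rep(TRUE, nrow(table)), center = rep(TRUE, nrow(table))),
    "Z-cn"    = list(member = rep(TRUE, nrow(table)), center = non_rs),
    "omit-RS" = list(member = non_rs, center = non_rs),
    ssf_stop("ssf_config_error", "unknown variant: %s", variant)
  )
}

#' Draw non-overlapping spherical cluster centers
#'
#' Sequential rejection sampling: candidate centers are proposed uniformly at
#' random from the variant's center pool and accepted when they lie strictly
#' more than `2 * radius_mm` from every previously accepted center, so the
#' spheres never overlap. An exhausted proposal budget raises a packing
#' error stating how many centers were placed.
#'
#' @param table a [sample_table()].
#' @param radius_mm sphere radius in mm.
#' @param n_clusters number of centers to place.
#' @param variant `"All"`, `"Z-cn"` or `"omit-RS"`.
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @param max_proposals rejection-sampling budget (default 10000).
#' @return Character vector of `n_clusters` center sample ids.
#' @export
sample_cluster_centers <- function(table, radius_mm, n_clusters,
                                   variant = c("All", "Z-cn", "omit-RS"),
                                   seed = NULL, max_proposals = 10000) {
  variant <- match.arg(variant)
  if (!is.null(seed)) set.seed(seed)
  pools <- variant_pools(table, variant)
  cand <- which(pools$center)
  if (length(cand) < n_clusters) {
    ssf_stop("ssf_config_error",
             "center pool has %d samples but %d clusters requested",
             length(cand), n_clusters)
  }
  coords <- coord_matrix(table)
  min_sq <- (2 * radius_mm)^2
  # greedy dart throwing with restart: a stalled partial packing (too many
  # consecutive rejections) is abandoned and rebuilt from scratch, all within
  # the same overall proposal budget
  stall_limit <- max(200, 10 * n_clusters)
  accepted <- integer(0)
  best_placed <- 0
  proposals <- 0
  since_accept <- 0
  while (length(accepted) < n_clusters) {
    if (proposals >= max_proposals) {
      ssf_stop("ssf_packing_error",
               "placed %d of %d non-overlapping clusters (radius %g mm) within %d proposals",
               max(best_placed, length(accepted)), n_clusters, radius_mm, max_proposals)
    }
    if (since_accept >= stall_limit) {
      best_placed <- max(best_placed, length(accepted))
      accepted <- integer(0)
      since_accept <- 0
    }
    proposals <- proposals + 1
    since_accept <- since_accept + 1
    p <- cand[sample.int(length(cand), 1)]
    if (p %in% accepted) next
    if (length(accepted) > 0) {
      d2 <- colSums((t(coords[accepted, , drop = FALSE]) - coords[p, ])^2)
      if (any(d2 <= min_sq)) next
    }
    accepted <- c(accepted, p)
    since_accept <- 0
  }
  table$sample_id[accepted]
}

#' Build clusters around centers
#'
#' Each cluster's members are every sample of the variant's member pool
#' within `radius_mm` (inclusive) of its center. Disjointness follows from
#' the > 2r center spacing.
#'
#' @param centers character vector of center sample ids.
#' @param radius_mm sphere radius in mm.
#' @param table a [sample_table()].
#' @param variant pool variant (members restricted only for `"omit-RS"`).
#' @return Object of class `cluster_set`: `centers`, `radius_mm`, `members`
#'   (list of sample-id vectors, one per center).
#' @export
build_clusters <- function(centers, radius_mm, table,
                           variant = c("All", "Z-cn", "omit-RS")) {
  variant <- match.arg(variant)
  pools <- variant_pools(table, variant)
  pool_idx <- which(pools$member)
  coords <- coord_matrix(table)
  cidx <- match(centers, table$sample_id)
  if (anyNA(cidx)) {
    ssf_stop("ssf_validation_error", "center id(s) not in table: %s",
             paste(centers[is.na(cidx)], collapse = ", "))
  }
  pc <- coords[pool_idx, , drop = FALSE]
  r2 <- radius_mm^2
  members <- lapply(cidx, function(ci) {
    d2 <- colSums((t(pc) - coords[ci, ])^2)
    table$sample_id[pool_idx[d2 <= r2]]
  })
  flat <- unlist(members)
  if (anyDuplicated(flat)) {
    ssf_stop("ssf_validation_error",
             "cluster members overlap; center spacing must exceed 2 * radius")
  }
  structure(list(centers = centers, radius_mm = radius_mm, members = members),
            class = "cluster_set")
}

#' Group clusters into networks at random
#'
#' Clusters are partitioned uniformly at random into groups whose sizes are
#' given by `composition`; each network is the union of its clusters'
#' members.
#'
#' @param clusters a [build_clusters()] result.
#' @param composition integer vector of clusters per network (sums to the
#'   number of clusters); default nine 3s, three 2s, one 1.
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return Object of class `simulated_network_set`: `networks` (list of
#'   sample-id vectors), `composition`, `cluster_assignment`.
#' @export
group_into_networks <- function(clusters,
                                composition = c(rep(3, 9), rep(2, 3), 1),
                                seed = NULL) {
  n_cl <- length(clusters$members)
  if (sum(composition) != n_cl) {
    ssf_stop("ssf_config_error",
             "composition sums to %d but there are %d clusters",
             sum(composition), n_cl)
  }
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(n_cl)
  ends <- cumsum(composition)
  starts <- ends - composition + 1
  assignment <- lapply(seq_along(composition), function(j) perm[starts[j]:ends[j]])
  networks <- lapply(assignment, function(ix) {
    unlist(clusters$members[ix], use.names = FALSE)
  })
  structure(list(
    networks = networks, composition = composition,
    cluster_assignment = assignment,
    radius_mm = clusters$radius_mm
  ), class = "simulated_network_set")
}

#' Geometric summaries of a simulated network set
#'
#' @param nets a [group_into_networks()] result.
#' @param clusters the generating [build_clusters()] result.
#' @param table a [sample_table()].
#' @return List: `W` (total samples across networks),
#'   `median_within_edge_mm` (median Euclidean distance over all
#'   within-network sample pairs, pooled across networks; `NA` if no network
#'   has two samples) and `median_center_edge_mm` (median over all center
#'   pairs).
#' @export
network_metrics <- function(nets, clusters, table) {
  coords <- coord_matrix(table)
  rownames(coords) <- table$sample_id
  within <- unlist(lapply(nets$networks, function(ids) {
    if (length(ids) < 2) return(numeric(0))
    as.numeric(stats::dist(coords[ids, , drop = FALSE]))
  }))
  centers <- coords[clusters$centers, , drop = FALSE]
  list(
    W = sum(lengths(nets$networks)),
    median_within_edge_mm = if (length(within)) stats::median(within) else NA_real_,
    median_center_edge_mm = stats::median(as.numeric(stats::dist(centers)))
  )
}

#' Default clusters-per-network map for the real networks
#'
#' Ranks the 13 networks by sample count (descending, ties broken by label
#' order): the nine largest get 3 clusters, the next three get 2, the
#' smallest gets 1.
#'
#' @param table a [sample_table()] with non-zero network labels.
#' @return Named integer vector (names = network labels).
#' @export
default_k_per_network <- function(table) {
  sizes <- base::table(factor(table$network_label[table$network_label > 0]))
  labels <- names(sizes)[order(-as.integer(sizes), as.integer(names(sizes)))]
  k <- c(rep(3L, 9), rep(2L, 3), 1L)[seq_along(labels)]
  stats::setNames(k, labels)
}

#' Cluster the real networks and summarize their centroid geometry
#'
#' Each network's sample coordinates are hierarchically clustered (Euclidean
#' distance) into its assigned number of groups; each group's centroid is the
#' coordinate mean. Returns all centroids and the median over all centroid
#' pairs.
#'
#' @param table a [sample_table()] with network labels.
#' @param k_per_network named integer vector mapping network label to number
#'   of clusters; default [default_k_per_network()].
#' @param linkage hierarchical-clustering linkage (default `"single"`).
#' @return List: `centroids` (matrix, one row per centroid, with a
#'   `network` column attribute), `median_centroid_edge_mm`, `k_per_network`.
#' @export
real_network_centroids <- function(table, k_per_network = NULL,
                                   linkage = c("single", "complete", "ward.D2", "average")) {
  linkage <- match.arg(linkage)
  if (is.null(k_per_network)) k_per_network <- default_k_per_network(table)
  coords <- coord_matrix(table)
  cents <- list()
  nets <- integer(0)
  for (lab in names(k_per_network)) {
    k <- k_per_network[[lab]]
    rows <- which(table$network_label == as.integer(lab))
    if (length(rows) < k) {
      ssf_stop("ssf_validation_error",
               "network %s has %d samples, fewer than k = %d", lab, length(rows), k)
    }
    xy <- coords[rows, , drop = FALSE]
    groups <- if (k == 1) rep(1L, nrow(xy)) else {
      stats::cutree(stats::hclust(stats::dist(xy), method = linkage), k = k)
    }
    for (g in seq_len(k)) {
      cents[[length(cents) + 1]] <- colMeans(xy[groups == g, , drop = FALSE])
      nets <- c(nets, as.integer(lab))
    }
  }
  centroids <- do.call(rbind, cents)
  list(
    centroids = centroids,
    network = nets,
    median_centroid_edge_mm = stats::median(as.numeric(stats::dist(centroids))),
    k_per_network = k_per_network
  )
}
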