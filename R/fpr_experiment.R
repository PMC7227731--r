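# Orchestration of the false-positive-rate experiment: sweep cluster radii
# and pool variants, run the strength-fraction permutation test on every
# simulated noise network set, and estimate the SSF false-positive rate
# (fraction of network sets whose SF exceeds every null SF). Every
# (radius, simulation) task derives its own RNG stream from the master seed,
# so results are bit-for-bit reproducible and order-independent.

# Restrict table and expression to the variant's analysis pool (omit-RS
# removes the rsfMRI samples from the whole analysis, not just the centers).
analysis_pool <- function(table, expr, variant) {
  if (variant == "omit-RS") {
    keep <- table$network_label == 0L
    tab <- table[keep, , drop = FALSE]
    class(tab) <- class(table)
    list(table = tab, expr = expr[, tab$sample_id, drop = FALSE])
  } else {
    list(table = table, expr = expr[, table$sample_id, drop = FALSE])
  }
}

simulate_one <- function(table, graph, radius_mm, cfg, sim_seed) {
  set.seed(sim_seed)
  centers <- sample_cluster_centers(table, radius_mm, cfg$n_clusters,
                                    variant = cfg$variant, seed = NULL,
                                    max_proposals = cfg$max_proposals)
  clusters <- build_clusters(centers, radius_mm, table, variant = cfg$variant)
  nets <- group_into_networks(clusters, cfg$network_composition, seed = NULL)
  metrics <- network_metrics(nets, clusters, table)
  res <- sf_permutation_test(graph, nets$networks, cfg$n_shuffles, seed = NULL,
                             denominator = cfg$denominator)
  list(sf = res$sf, p_value = res$p_value, significant = res$significant,
       W = metrics$W,
       median_within_edge_mm = metrics$median_within_edge_mm,
       median_center_edge_mm = metrics$median_center_edge_mm)
}

#' Sweep cluster radii and estimate the SSF false-positive rate
#'
#' For each radius, draws `cfg$n_networks` simulated contiguous noise
#' network sets, runs the SF label-shuffle permutation test on each, and
#' reports the fraction found significant (the SSF-FPR) with a Wilson 95%
#' interval and the sets' geometric summaries. A radius where sphere packing
#' fails is marked infeasible (`fpr = NA`) rather than silently computed
#' from the draws that happened to pack, which would bias the estimate.
#'
#' @param table a [sample_table()].
#' @param expr genes x samples matrix aligned to `table`.
#' @param cfg a [run_config()].
#' @param per_sim_file optional path; per-simulation rows are streamed there
#'   as CSV while the sweep runs.
#' @return data.frame of class `fpr_curve`, one row per radius:
#'   `radius_mm`, `variant`, `n_networks`, `n_shuffles`, `n_significant`,
#'   `fpr`, `ci_lower`, `ci_upper`, `median_W`, `median_within_edge_mm`,
#'   `n_packing_failures`, `feasible`. Per-simulation rows in the
#'   `"simulations"` attribute.
#' @export
run_fpr <- function(table, expr, cfg, per_sim_file = NULL) {
  pool <- analysis_pool(table, expr, cfg$variant)
  graph <- correlation_graph(pool$expr, pool$table,
                             within_tissue = cfg$within_tissue,
                             edge_weights = cfg$edge_weights)
  rows <- list()
  sims <- list()
  for (ri in seq_along(cfg$radii_mm)) {
    radius <- cfg$radii_mm[ri]
    n_fail <- 0
    sim_rows <- vector("list", cfg$n_networks)
    for (sim in seq_len(cfg$n_networks)) {
      sim_seed <- derive_seed(cfg$seed, ri, sim)
      one <- tryCatch(
        simulate_one(pool$table, graph, radius, cfg, sim_seed),
        ssf_packing_error = function(e) e
      )
      if (inherits(one, "ssf_packing_error")) {
        n_fail <- n_fail + 1
        next
      }
      sim_rows[[sim]] <- data.frame(
        radius_mm = radius, variant = cfg$variant, sim = sim, seed = sim_seed,
        sf = one$sf, p_value = one$p_value, significant = one$significant,
        W = one$W, median_within_edge_mm = one$median_within_edge_mm,
        stringsAsFactors = FALSE
      )
    }
    sim_df <- do.call(rbind, sim_rows)
    if (!is.null(per_sim_file) && !is.null(sim_df)) {
      utils::write.table(sim_df, per_sim_file, sep = ",", append = file.exists(per_sim_file),
                         col.names = !file.exists(per_sim_file), row.names = FALSE, quote = FALSE)
    }
    feasible <- n_fail == 0
    n_sig <- if (feasible) sum(sim_df$significant) else NA_integer_
    ci <- if (feasible) wilson_ci(n_sig, cfg$n_networks) else c(NA_real_, NA_real_)
    rows[[ri]] <- data.frame(
      radius_mm = radius, variant = cfg$variant,
      n_networks = cfg$n_networks, n_shuffles = cfg$n_shuffles,
      n_significant = n_sig,
      fpr = if (feasible) n_sig / cfg$n_networks else NA_real_,
      ci_lower = unname(ci[1]), ci_upper = unname(ci[2]),
      median_W = if (is.null(sim_df)) NA_real_ else stats::median(sim_df$W),
      median_within_edge_mm = if (is.null(sim_df)) NA_real_ else
        stats::median(sim_df$median_within_edge_mm, na.rm = TRUE),
      n_packing_failures = n_fail, feasible = feasible,
      stringsAsFactors = FALSE
    )
    if (!feasible) {
      warning(sprintf("radius %g mm: %d of %d draws failed sphere packing; row marked infeasible",
                      radius, n_fail, cfg$n_networks))
    }
    sims[[ri]] <- sim_df
  }
  curve <- do.call(rbind, rows)
  rownames(curve) <- NULL
  class(curve) <- c("fpr_curve", "data.frame")
  attr(curve, "simulations") <- do.call(rbind, sims)
  attr(curve, "config") <- cfg
  curve
}

#' Pearson correlation of cluster radius with SSF-FPR
#'
#' @param curve an `fpr_curve` (rows of one variant; >= 3 feasible rows).
#' @return List with `r` (Pearson correlation of radius vs FPR) and `p`
#'   (two-sided).
#' @export
radius_fpr_correlation <- function(curve) {
  rows <- curve[!is.na(curve$fpr), , drop = FALSE]
  if (length(unique(rows$variant)) > 1) {
    ssf_stop("ssf_config_error", "curve mixes variants; filter to one variant first")
  }
  if (nrow(rows) < 3) ssf_stop("ssf_config_error", "need >= 3 feasible rows")
  if (stats::sd(rows$fpr) == 0) {
    ssf_stop("ssf_degenerate_error", "FPR has zero variance; correlation undefined")
  }
  ct <- stats::cor.test(rows$radius_mm, rows$fpr, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Scale the 13-network cluster composition to a new total cluster count
#'
#' The default (3x9, 2x3, 1) template is scaled proportionally; remainders
#' are distributed one at a time round-robin starting from the largest
#' network (ties broken by position).
#'
#' @param template integer vector of clusters per network.
#' @param n_target total cluster count to reach.
#' @return Integer vector summing to `n_target`, same length as `template`.
#' @export
scale_composition <- function(template, n_target) {
  raw <- template * n_target / sum(template)
  base <- floor(raw)
  rem <- n_target - sum(base)
  ord <- order(-template, seq_along(template))
  i <- 1
  while (rem > 0) {
    base[ord[i]] <- base[ord[i]] + 1
    i <- if (i == length(ord)) 1 else i + 1
    rem <- rem - 1
  }
  as.integer(base)
}

#' Control experiment: vary cluster count at fixed cluster size
#'
#' Holds the contiguous cluster radius fixed (6 mm by default) while scaling
#' factors modulate the number of clusters (`round(34 * factor)`), so the
#' total within-network sample count W varies without changing cluster size.
#' If cluster size rather than W drives the SSF false-positive rate, the FPR
#' should stay flat (or fall) as W grows.
#'
#' @param table a [sample_table()].
#' @param expr genes x samples matrix aligned to `table`.
#' @param scaling_factors multipliers of the base 34-cluster count
#'   (default `seq(1, 5, by = 0.5)`).
#' @param base_radius_mm fixed cluster radius (default 6 mm).
#' @param n_networks simulated network sets per factor (default 200).
#' @param n_shuffles shuffles per permutation test (default 200).
#' @param seed master seed.
#' @param base_n_clusters cluster count at factor 1 (default 34).
#' @param template composition template scaled by [scale_composition()].
#' @param ... further [run_config()] arguments (variant, edge weights, ...).
#' @return data.frame of class `control_curve`: one row per factor with
#'   `scaling`, `n_clusters`, `median_W`, `fpr`, Wilson CI; Pearson
#'   correlation of `median_W` with `fpr` in the `"w_fpr_correlation"`
#'   attribute.
#' @export
control_experiment <- function(table, expr,
                               scaling_factors = seq(1, 5, by = 0.5),
                               base_radius_mm = 6,
                               n_networks = 200, n_shuffles = 200,
                               seed = 1, base_n_clusters = 34,
                               template = c(rep(3, 9), rep(2, 3), 1), ...) {
  if (any(scaling_factors < 1)) {
    ssf_stop("ssf_config_error", "scaling factors must be >= 1")
  }
  rows <- list()
  for (fi in seq_along(scaling_factors)) {
    f <- scaling_factors[fi]
    n_cl <- round(base_n_clusters * f)
    comp <- scale_composition(template, n_cl)
    cfg <- run_config(radii_mm = base_radius_mm, n_clusters = n_cl,
                      network_composition = comp,
                      n_networks = n_networks, n_shuffles = n_shuffles,
                      seed = derive_seed(seed, 7, fi), ...)
    curve <- run_fpr(table, expr, cfg)
    rows[[fi]] <- data.frame(
      scaling = f, n_clusters = n_cl,
      median_W = curve$median_W, fpr = curve$fpr,
      ci_lower = curve$ci_lower, ci_upper = curve$ci_upper,
      n_significant = curve$n_significant,
      feasible = curve$feasible,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  class(out) <- c("control_curve", "data.frame")
  ok <- out$feasible & !is.na(out$fpr)
  if (sum(ok) >= 3 && stats::sd(out$fpr[ok]) > 0) {
    ct <- stats::cor.test(out$median_W[ok], out$fpr[ok])
    attr(out, "w_fpr_correlation") <- list(r = unname(ct$estimate), p = ct$p.value)
  }
  out
}
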