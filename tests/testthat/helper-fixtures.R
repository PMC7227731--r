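# Shared in-code fixtures: tiny hand-sized tables and matrices, plus a
# cached mid-size synthetic cortex so expensive generation runs once per
# test session.

toy_table <- function(coords, tissue = NULL, network = NULL) {
  n <- nrow(coords)
  sample_table(data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    tissue_label = if (is.null(tissue)) rep("t1", n) else tissue,
    network_label = if (is.null(network)) rep(0L, n) else network,
    stringsAsFactors = FALSE
  ))
}

# 1-D line of points along x, one per mm position given.
line_table <- function(xs, ...) {
  toy_table(cbind(xs, 0, 0), ...)
}

random_expr <- function(n_genes, table, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * nrow(table)), n_genes, nrow(table))
  rownames(m) <- sprintf("G%04d", seq_len(n_genes))
  colnames(m) <- table$sample_id
  m
}

# Pearson correlation from the textbook formula, element by element.
pearson_oracle <- function(a, b) {
  za <- a - mean(a); zb <- b - mean(b)
  sum(za * zb) / sqrt(sum(za^2) * sum(zb^2))
}

# Strength fraction by exhaustive enumeration of all unordered sample pairs.
sf_oracle <- function(weights, eligible, membership) {
  n <- nrow(weights)
  num <- 0; den <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (!eligible[i, j]) next
      w <- max(weights[i, j], 0)
      den <- den + w
      if (membership[i] != 0 && membership[i] == membership[j]) num <- num + w
    }
  }
  num / den
}

# Moran's I by a direct double loop over all ordered pairs.
moran_oracle <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + W[i, j] * z[i] * z[j]
  (n / sum(W)) * s / sum(z^2)
}

# Expression whose sample profiles all correlate positively: independent
# noise plus a strong gene-wise component shared by every sample.
positive_expr <- function(n_genes, table, seed = 1, shared_sd = 3) {
  set.seed(seed)
  base <- random_expr(n_genes, table, seed = seed)
  common <- rnorm(n_genes, sd = shared_sd)
  base + matrix(common, n_genes, nrow(table))
}

# Total variation between an empirical null-SF sample and the exhaustive
# enumeration of labelings (uniform over labelings; SF values may repeat,
# so compare distributions over unique values).
sf_null_tv <- function(null_sfs, sf_all) {
  key <- function(v) sprintf("%.12f", v)
  theo <- table(key(sf_all)) / length(sf_all)
  emp <- table(factor(key(null_sfs), levels = names(theo))) / length(null_sfs)
  if (any(!key(null_sfs) %in% names(theo))) return(Inf)
  0.5 * sum(abs(as.numeric(emp) - as.numeric(theo)))
}

# Mid-size spatially structured cortex shared across tests (generated once).
structured_cortex <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(n_samples = 500, n_tissues = 120, n_genes = 400,
                              length_scales = list(c(200, 30), c(200, 0)),
                              noise_sd = 0.3, seed = 3)
      tab <- generate_cortex_geometry(cfg)
      expr <- generate_expression(tab, cfg)
      cache <<- list(cfg = cfg, table = tab, expr = expr)
    }
    cache
  }
})
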