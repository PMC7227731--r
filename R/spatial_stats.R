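# Distance-banded spatial weights and Moran's I spatial autocorrelation.
#
# Moran's I for per-sample values x with weights w_ij:
#   I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2
# with S0 = sum_ij w_ij. I approaches +1 when values cluster in space,
# has expectation -1/(n-1) under random arrangement, and approaches -1 for
# perfect dispersion. Weights follow the distance-band convention:
# continuously diminishing 1/d^alpha up to a threshold (16 mm default) beyond
# which all weights are zero, or binary within the band; rows are
# row-standardized by default for inference.

#' Build distance-band spatial weights
#'
#' @param table a [sample_table()].
#' @param threshold_mm band limit in mm (default 16); pairs farther apart get
#'   weight zero.
#' @param scheme `"inverse_distance"` (w = 1/d^alpha within the band,
#'   default) or `"binary"`.
#' @param transformation `"row_standardized"` (default) divides each row by
#'   its sum; `"raw"` leaves weights untouched.
#' @param alpha exponent of the inverse-distance decay (default 1).
#' @return Object of class `spatial_weights`: sparse matrix `w`, the band
#'   and scheme, and `islands` (ids of samples with no neighbor in the band;
#'   they are dropped from Moran statistics with a logged count).
#' @export
build_weights <- function(table, threshold_mm = 16,
                          scheme = c("inverse_distance", "binary"),
                          transformation = c("row_standardized", "raw"),
                          alpha = 1) {
  scheme <- match.arg(scheme)
  transformation <- match.arg(transformation)
  n <- nrow(table)
  if (n < 2) ssf_stop("ssf_config_error", "need >= 2 samples for spatial weights")
  d <- as.matrix(stats::dist(coord_matrix(table)))
  band <- d <= threshold_mm
  diag(band) <- FALSE
  if (scheme == "inverse_distance") {
    dup <- which(band & d == 0, arr.ind = TRUE)
    if (nrow(dup) > 0) {
      i <- dup[1, 1]; j <- dup[1, 2]
      ssf_stop("ssf_validation_error",
               "duplicate coordinates (d = 0) between samples %s and %s under inverse-distance weights",
               table$sample_id[i], table$sample_id[j])
    }
    w <- ifelse(band, 1 / d^alpha, 0)
  } else {
    w <- band * 1
  }
  rs <- rowSums(w)
  islands <- table$sample_id[rs == 0]
  if (length(islands) == n) {
    ssf_stop("ssf_degenerate_error", "no sample pair within %g mm", threshold_mm)
  }
  if (length(islands) > 0) {
    message(sprintf("%d island sample(s) with no neighbor within %g mm dropped from Moran statistics",
                    length(islands), threshold_mm))
  }
  if (transformation == "row_standardized") {
    nz <- rs > 0
    w[nz, ] <- w[nz, , drop = FALSE] / rs[nz]
  }
  dimnames(w) <- list(table$sample_id, table$sample_id)
  structure(list(
    w = Matrix::Matrix(w, sparse = TRUE),
    threshold_mm = threshold_mm, scheme = scheme,
    transformation = transformation, alpha = alpha,
    sample_id = table$sample_id, islands = islands
  ), class = "spatial_weights")
}

# Non-island weight submatrix and the sample ids it keeps.
active_weights <- function(weights) {
  keep <- setdiff(weights$sample_id, weights$islands)
  list(w = weights$w[keep, keep, drop = FALSE], keep = keep)
}

#' Moran's I for one variable
#'
#' @param x numeric vector, one value per sample of the weights object
#'   (named or in table order).
#' @param weights a [build_weights()] result. Island samples are dropped.
#' @return Moran's I (scalar).
#' @export
morans_i <- function(x, weights) {
  aw <- active_weights(weights)
  x <- align_values(x, weights, aw$keep)
  z <- x - mean(x)
  denom <- sum(z^2)
  if (denom == 0) ssf_stop("ssf_degenerate_error", "constant variable: Moran's I undefined")
  W <- aw$w
  s0 <- sum(W)
  n <- length(z)
  (n / s0) * as.numeric(t(z) %*% (W %*% z)) / denom
}

align_values <- function(x, weights, keep) {
  if (!is.null(names(x))) {
    x <- x[keep]
  } else {
    if (length(x) != length(weights$sample_id)) {
      ssf_stop("ssf_validation_error", "value vector length %d != %d samples",
               length(x), length(weights$sample_id))
    }
    x <- x[match(keep, weights$sample_id)]
  }
  if (anyNA(x)) ssf_stop("ssf_validation_error", "missing values in variable")
  x
}

# Moments of Moran's I under the randomization (permutation) null.
moran_null_moments <- function(W, z) {
  n <- length(z)
  s0 <- sum(W)
  Ws <- W + Matrix::t(W)
  s1 <- sum(Ws^2) / 2
  rc <- Matrix::rowSums(W) + Matrix::colSums(W)
  s2 <- sum(rc^2)
  ei <- -1 / (n - 1)
  b2 <- n * sum(z^4) / sum(z^2)^2
  num <- n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * s0^2) -
    b2 * ((n^2 - n) * s1 - 2 * n * s2 + 6 * s0^2)
  vi <- num / ((n - 1) * (n - 2) * (n - 3) * s0^2) - ei^2
  list(ei = ei, vi = vi)
}

#' Significance of Moran's I
#'
#' `"normal_approx"` standardizes I by its randomization-null mean
#' E(I) = -1/(n-1) and variance; `"permutation"` shuffles the values and uses
#' the add-one p-value convention. Both test the alternative of positive
#' spatial autocorrelation by default.
#'
#' @param x numeric per-sample vector.
#' @param weights a [build_weights()] result.
#' @param method `"normal_approx"` (default) or `"permutation"`.
#' @param n_perm permutations when `method = "permutation"`.
#' @param seed optional seed for the permutation method.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return List with `I`, `z` (NA for permutation) and `p`.
#' @export
morans_i_significance <- function(x, weights,
                                  method = c("normal_approx", "permutation"),
                                  n_perm = 999, seed = NULL,
                                  alternative = c("greater", "two.sided")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  aw <- active_weights(weights)
  xv <- align_values(x, weights, aw$keep)
  z <- xv - mean(xv)
  if (sum(z^2) == 0) ssf_stop("ssf_degenerate_error", "constant variable: Moran's I undefined")
  W <- aw$w
  s0 <- sum(W)
  n <- length(z)
  i_obs <- (n / s0) * as.numeric(t(z) %*% (W %*% z)) / sum(z^2)
  if (method == "normal_approx") {
    mom <- moran_null_moments(W, z)
    zscore <- (i_obs - mom$ei) / sqrt(mom$vi)
    p <- switch(alternative,
      greater = stats::pnorm(zscore, lower.tail = FALSE),
      two.sided = 2 * stats::pnorm(abs(zscore), lower.tail = FALSE)
    )
    list(I = i_obs, z = zscore, p = p)
  } else {
    if (!is.null(seed)) set.seed(seed)
    null_i <- numeric(n_perm)
    denom <- sum(z^2)
    for (s in seq_len(n_perm)) {
      zp <- z[sample.int(n)]
      null_i[s] <- (n / s0) * as.numeric(t(zp) %*% (W %*% zp)) / denom
    }
    p <- switch(alternative,
      greater = (1 + sum(null_i >= i_obs)) / (1 + n_perm),
      two.sided = (1 + sum(abs(null_i) >= abs(i_obs))) / (1 + n_perm)
    )
    list(I = i_obs, z = NA_real_, p = p, null_i = null_i)
  }
}

#' Moran's I for every gene of an expression matrix
#'
#' Vectorized over genes; constant genes get `NA` and are reported in a
#' message rather than silently dropped. Inference uses the normal
#' approximation (one-sided, clustering alternative).
#'
#' @param expr genes x samples numeric matrix.
#' @param weights a [build_weights()] result built on the same samples.
#' @return data.frame with `gene_id`, `I`, `z`, `p`.
#' @export
moran_per_gene <- function(expr, weights) {
  aw <- active_weights(weights)
  V <- expr[, aw$keep, drop = FALSE]
  n <- ncol(V)
  W <- aw$w
  s0 <- sum(W)
  Z <- V - rowMeans(V)
  m2 <- rowSums(Z^2)
  constant <- m2 == 0
  if (any(constant)) {
    message(sprintf("%d constant gene(s) have undefined Moran's I (set to NA)",
                    sum(constant)))
  }
  num <- rowSums(as.matrix(Z %*% W) * Z)
  I <- (n / s0) * num / m2
  I[constant] <- NA_real_
  # randomization-null moments, vectorized over genes (kurtosis varies per gene)
  Ws <- W + Matrix::t(W)
  s1 <- sum(Ws^2) / 2
  rc <- Matrix::rowSums(W) + Matrix::colSums(W)
  s2 <- sum(rc^2)
  ei <- -1 / (n - 1)
  b2 <- n * rowSums(Z^4) / m2^2
  numv <- n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * s0^2) -
    b2 * ((n^2 - n) * s1 - 2 * n * s2 + 6 * s0^2)
  vi <- numv / ((n - 1) * (n - 2) * (n - 3) * s0^2) - ei^2
  zscore <- (I - ei) / sqrt(vi)
  data.frame(
    gene_id = rownames(expr),
    I = I, z = zscore,
    p = stats::pnorm(zscore, lower.tail = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Compare Moran's I between a gene set and all remaining genes
#'
#' Reports the two groups' means and standard deviations and a two-sample
#' Wilcoxon rank-sum test, plus the raw per-group I values for plotting
#' (histogram / boxplot data).
#'
#' @param results data.frame from [moran_per_gene()].
#' @param in_set character vector of gene ids defining the set.
#' @return List: `mean_in`, `sd_in`, `mean_out`, `sd_out`, `n_in`, `n_out`,
#'   `test` (htest), `I_in`, `I_out`, `unresolved`.
#' @export
compare_gene_sets <- function(results, in_set) {
  in_set <- unique(as.character(in_set))
  if (length(in_set) == 0) ssf_stop("ssf_config_error", "gene set is empty")
  is_in <- results$gene_id %in% in_set
  if (!any(is_in)) ssf_stop("ssf_config_error", "no gene-set id resolves against the results")
  if (all(is_in)) ssf_stop("ssf_config_error", "gene set covers all genes; complement is empty")
  I_in <- results$I[is_in & !is.na(results$I)]
  I_out <- results$I[!is_in & !is.na(results$I)]
  list(
    mean_in = mean(I_in), sd_in = stats::sd(I_in),
    mean_out = mean(I_out), sd_out = stats::sd(I_out),
    n_in = length(I_in), n_out = length(I_out),
    test = stats::wilcox.test(I_in, I_out, exact = FALSE),
    I_in = I_in, I_out = I_out,
    unresolved = setdiff(in_set, results$gene_id)
  )
}
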