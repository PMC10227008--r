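#' Choose the TMM reference sample
#'
#' The reference is the sample whose 75th percentile of counts-per-million is
#' closest to the mean 75th percentile across samples; ties break by column
#' order.
#'
#' @param x A [count_matrix()] or plain counts matrix.
#' @return A sample id (character scalar).
#' @export
select_reference <- function(x) {
  cts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  if (ncol(cts) < 2) stop("reference selection needs at least 2 samples")
  lib <- colSums(cts)
  if (any(lib == 0)) stop("all-zero sample: ", colnames(cts)[which(lib == 0)[1]])
  uq <- apply(cts, 2, function(col) quantile(col, 0.75, names = FALSE)) / lib
  colnames(cts)[which.min(abs(uq - mean(uq)))]
}

#' Pairwise TMM scaling factor
#'
#' Trimmed mean of M-values of `obs` against `ref`. Genes with a zero count
#' in either sample are excluded. With relative abundances `p = count/libsize`,
#' `M = log2(p_obs/p_ref)` and `A = (log2(p_obs) + log2(p_ref))/2`; genes in
#' the upper/lower `trim_m` tails of M and `trim_a` tails of A (by rank) are
#' removed, and the factor is `2^` of the weighted mean of the surviving M,
#' weighted by inverse delta-method variances
#' `1/((N_obs-y_obs)/(N_obs y_obs) + (N_ref-y_ref)/(N_ref y_ref))`.
#'
#' @param obs,ref Count vectors over the same genes.
#' @param trim_m Two-sided trim fraction on M (default 0.30).
#' @param trim_a Two-sided trim fraction on A (default 0.05).
#' @return Scaling factor (numeric scalar). If fewer than 10 genes survive
#'   trimming the factor is 1, with a warning.
#' @export
tmm_pair_factor <- function(obs, ref, trim_m = 0.30, trim_a = 0.05) {
  stopifnot(length(obs) == length(ref))
  n_obs <- sum(obs)
  n_ref <- sum(ref)
  keep <- obs > 0 & ref > 0
  o <- obs[keep]; r <- ref[keep]
  m <- log2((o / n_obs) / (r / n_ref))
  a <- 0.5 * log2((o / n_obs) * (r / n_ref))
  w <- 1 / ((n_obs - o) / (n_obs * o) + (n_ref - r) / (n_ref * r))

  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m, ties.method = "first")
  ra_ <- rank(a, ties.method = "first")
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
  if (sum(keep2) < 10) {
    warning("fewer than 10 genes survived TMM trimming; factor set to 1")
    return(1)
  }
  2^(sum(w[keep2] * m[keep2]) / sum(w[keep2]))
}

#' TMM normalization factors for a count matrix
#'
#' Computes the pairwise TMM factor of every sample against the
#' [select_reference()] sample, then rescales so the factors have geometric
#' mean 1. Effective library size = raw library size x factor.
#'
#' @param x A [count_matrix()] or counts matrix.
#' @param trim_m,trim_a Trim fractions passed to [tmm_pair_factor()].
#' @return `data.frame` of class `norm_factors` with columns `sample_id`,
#'   `lib_size`, `factor`, `eff_lib_size`, plus attribute `reference`.
#' @export
tmm_factors <- function(x, trim_m = 0.30, trim_a = 0.05) {
  cts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  ref_id <- select_reference(cts)
  ref <- cts[, ref_id]
  f <- vapply(seq_len(ncol(cts)),
              function(j) tmm_pair_factor(cts[, j], ref, trim_m, trim_a),
              numeric(1))
  f <- f / exp(mean(log(f)))
  lib <- colSums(cts)
  out <- data.frame(sample_id = colnames(cts), lib_size = unname(lib),
                    factor = f, eff_lib_size = unname(lib) * f,
                    stringsAsFactors = FALSE)
  attr(out, "reference") <- ref_id
  class(out) <- c("norm_factors", "data.frame")
  out
}

#' Normalized counts per million with a pseudo-count
#'
#' `cpm = 1e6 * (count + prior_j) / eff_lib_j` with the pseudo-count defined
#' on the per-million scale, `prior_j = prior * eff_lib_j / 1e6` (i.e. the
#' value is `1e6 * count / eff_lib_j + prior`). Zero counts map to `prior`
#' rather than zero, and rescaling all counts and library sizes by a common
#' factor leaves the result unchanged.
#'
#' @param x A [count_matrix()] or counts matrix.
#' @param factors Output of [tmm_factors()]; computed if `NULL`.
#' @param prior Pseudo-count on the CPM scale (default 0.5).
#' @return Numeric matrix of normalized CPM values (strictly positive).
#' @export
cpm <- function(x, factors = NULL, prior = 0.5) {
  cts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  if (is.null(factors)) factors <- tmm_factors(cts)
  stopifnot(identical(factors$sample_id, colnames(cts)))
  sweep(cts, 2, factors$eff_lib_size / 1e6, "/") + prior
}

#' Write TMM factors as TSV
#' @param factors A `norm_factors` table.
#' @param path Output path.
#' @param seed Optional seed recorded in the header.
#' @return Invisibly, the path.
#' @export
write_norm_factors <- function(factors, path, seed = NULL) {
  write_tsv(as.data.frame(factors), path, seed = seed)
  invisible(path)
}
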