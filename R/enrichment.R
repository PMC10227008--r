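#' Expressed-gene universe
#'
#' Genes whose maximum raw count across the in-scope samples strictly exceeds
#' the threshold. This universe defines the gene space shared by the observed
#' enrichment curves and the permutation null.
#'
#' @param x A [count_matrix()] or counts matrix.
#' @param threshold Raw-count threshold (default 100; strict inequality).
#' @return Character vector of gene ids, with attributes `threshold` and
#'   `max_count` (named numeric).
#' @export
expressed_universe <- function(x, threshold = 100) {
  cts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  stopifnot(nrow(cts) > 0, ncol(cts) > 0)
  mx <- apply(cts, 1, max)
  out <- rownames(cts)[mx > threshold]
  attr(out, "threshold") <- threshold
  attr(out, "max_count") <- mx
  out
}

#' Cumulative enrichment curve of sex-specific genes in a ranked list
#'
#' For each k up to `k_max`, the fraction of the top-k genes of the ranked
#' exposure list that belong to the male- and female-specific sets. Both the
#' ranked list and the sets are first intersected with the expressed-gene
#' universe, so the curve and its permutation null share one gene space.
#'
#' @param ranked A [rank_exposure_degs()] result (or a character vector of
#'   ordered gene ids).
#' @param sets A [call_sex_specific()] result (or a list with
#'   `male_specific` / `female_specific`).
#' @param universe Character vector from [expressed_universe()].
#' @param k_max Largest list size (default 200). If fewer ranked genes remain
#'   after the universe restriction, the curve is truncated with a warning.
#' @return `data.frame` of class `enrichment_curve`: `k`, `n_male`,
#'   `n_female`, `frac_male`, `frac_female`; attributes `contrast`,
#'   `universe_size`, `set_sizes`.
#' @export
enrichment_curve <- function(ranked, sets, universe, k_max = 200) {
  ids <- if (is.data.frame(ranked)) ranked$gene else as.character(ranked)
  contrast <- attr(ranked, "contrast") %||% "unlabelled contrast"
  ids <- ids[ids %in% universe]
  male <- intersect(sets$male_specific, universe)
  female <- intersect(sets$female_specific, universe)
  if (length(ids) < k_max) {
    warning(sprintf("ranked list has only %d in-universe genes; curve truncated from k_max = %d",
                    length(ids), k_max))
    k_max <- length(ids)
  }
  top <- ids[seq_len(k_max)]
  n_male <- cumsum(top %in% male)
  n_female <- cumsum(top %in% female)
  k <- seq_len(k_max)
  out <- data.frame(k = k, n_male = n_male, n_female = n_female,
                    frac_male = n_male / k, frac_female = n_female / k)
  class(out) <- c("enrichment_curve", "data.frame")
  attr(out, "contrast") <- contrast
  attr(out, "universe_size") <- length(universe)
  attr(out, "set_sizes") <- c(male = length(male), female = length(female))
  out
}

#' Permutation null for top-k sex-specific fractions
#'
#' Draws `n_iter` random gene sets of size `s` from the expressed universe
#' without replacement and records the fraction belonging to the sex-specific
#' set. The draws are summarized by a gamma distribution fitted by moment
#' matching ([gamma_fit_mme()]) and by empirical tail probabilities and
#' quantiles. With zero variance across draws (empty set, or set equal to
#' the universe) the gamma fit is refused and the result flagged degenerate;
#' empirical summaries are still returned.
#'
#' @param universe Character vector of expressed gene ids.
#' @param sex_set Character vector of sex-specific gene ids (intersected with
#'   the universe).
#' @param s Sample size (e.g. 50, 100 or 200); must not exceed the universe.
#' @param n_iter Number of permutation iterations (default 5000).
#' @param seed RNG seed.
#' @param q Fraction threshold(s) for tail probabilities (default 0.10).
#' @return List of class `enrichment_null`: `s`, `n_iter`, `fractions`,
#'   `shape`, `rate` (NA when degenerate), `degenerate`, `tail` (data.frame
#'   of empirical and gamma `P(frac > q)` per threshold), `q95_empirical`,
#'   `q95_gamma`, `K`, `N`, `seed`.
#' @export
permutation_null <- function(universe, sex_set, s, n_iter = 5000, seed = 1L, q = 0.10) {
  N <- length(universe)
  K <- length(intersect(sex_set, universe))
  stopifnot(s >= 1, s <= N, n_iter >= 2)
  fractions <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) sum(sample.int(N, s) <= K) / s, numeric(1))
  })
  v <- var(fractions)
  degenerate <- !is.finite(v) || v == 0
  if (degenerate) {
    shape <- rate <- NA_real_
  } else {
    fit <- gamma_fit_mme(fractions)
    shape <- fit$shape; rate <- fit$rate
  }
  tail <- data.frame(
    q = q,
    p_empirical = vapply(q, function(qi) mean(fractions > qi), numeric(1)),
    p_gamma = if (degenerate) NA_real_ else
      vapply(q, function(qi) pgamma(qi, shape = shape, rate = rate, lower.tail = FALSE),
             numeric(1)))
  structure(list(
    s = s, n_iter = n_iter, fractions = fractions,
    shape = shape, rate = rate, degenerate = degenerate,
    tail = tail,
    q95_empirical = quantile(fractions, 0.95, names = FALSE),
    q95_gamma = if (degenerate) NA_real_ else qgamma(0.95, shape = shape, rate = rate),
    K = K, N = N, seed = seed), class = "enrichment_null")
}

#' @export
print.enrichment_null <- function(x, ...) {
  cat(sprintf("enrichment_null: s = %d, %d draws from universe N = %d (set K = %d)\n",
              x$s, x$n_iter, x$N, x$K))
  if (x$degenerate) {
    cat("  degenerate (zero variance); gamma fit refused\n")
  } else {
    cat(sprintf("  gamma MME: shape = %.4g, rate = %.4g; q95 = %.4g (empirical %.4g)\n",
                x$shape, x$rate, x$q95_gamma, x$q95_empirical))
  }
  for (i in seq_len(nrow(x$tail)))
    cat(sprintf("  P(frac > %g): empirical %.4g, gamma %.4g\n",
                x$tail$q[i], x$tail$p_empirical[i], x$tail$p_gamma[i]))
  invisible(x)
}

#' Gamma fit by moment matching
#'
#' `shape = m^2 / v`, `rate = m / v` from the sample mean `m` and unbiased
#' sample variance `v` of the draws.
#'
#' @param draws Numeric vector (at least 2 values, positive variance).
#' @return List with `shape` and `rate`.
#' @export
gamma_fit_mme <- function(draws) {
  stopifnot(length(draws) >= 2)
  m <- mean(draws)
  v <- var(draws)
  if (!is.finite(v) || v == 0) stop("zero variance: gamma moment matching undefined")
  list(shape = m^2 / v, rate = m / v)
}

#' Exact hypergeometric tail for a sampled fraction
#'
#' `P(X/s > q)` for `X ~ Hypergeometric(N, K, s)` (number of set members in
#' a size-`s` draw without replacement from a universe of `N` containing `K`
#' set members), computed by exact summation of the probability mass.
#'
#' @param N Universe size.
#' @param K Set size (`0 <= K <= N`).
#' @param s Sample size (`1 <= s <= N`).
#' @param q Fraction threshold in `[0, 1)` (strict inequality).
#' @return Probability (numeric scalar).
#' @export
hypergeom_tail <- function(N, K, s, q) {
  stopifnot(K >= 0, K <= N, s >= 1, s <= N, q >= 0, q < 1)
  x0 <- floor(q * s) + 1        # smallest integer count with x/s > q
  x_hi <- min(K, s)
  if (x0 > x_hi) return(0)
  sum(dhyper(x0:x_hi, K, N - K, s))
}

#' Per-k significance calls for an enrichment curve
#'
#' Compares each observed fraction to the upper `1 - alpha` quantile of the
#' null calibrated at the nearest sample size (k below the smallest s uses
#' the smallest s). The gamma-fit quantile is used; for degenerate nulls the
#' empirical quantile is used instead. The summary reports whether enrichment
#' is sustained (flagged at every k) over `sustained_range`; the lower end of
#' that default range excludes k < 5, where the observed fraction is
#' integer-quantized too coarsely to carry a per-k signal.
#'
#' @param curve An [enrichment_curve()].
#' @param nulls_male,nulls_female Lists of [permutation_null()] objects (one
#'   per sample size) for the male- and female-specific sets.
#' @param alpha Significance level (default 0.05).
#' @param sustained_range Length-2 k-range for the summary (default `c(5, 50)`).
#' @return `data.frame` of class `enrichment_calls` with per-k thresholds and
#'   flags; attribute `summary` (list with sustained flags and flag rates).
#' @export
call_enrichment <- function(curve, nulls_male, nulls_female, alpha = 0.05,
                            sustained_range = c(5, 50)) {
  stopifnot(inherits(curve, "enrichment_curve"))
  thr <- function(nulls, k) {
    ss <- vapply(nulls, `[[`, numeric(1), "s")
    nl <- nulls[[which.min(abs(ss - k))]]
    if (nl$degenerate) quantile(nl$fractions, 1 - alpha, names = FALSE)
    else qgamma(1 - alpha, shape = nl$shape, rate = nl$rate)
  }
  thr_m <- vapply(curve$k, function(k) thr(nulls_male, k), numeric(1))
  thr_f <- vapply(curve$k, function(k) thr(nulls_female, k), numeric(1))
  out <- data.frame(k = curve$k,
                    frac_male = curve$frac_male, thr_male = thr_m,
                    flag_male = curve$frac_male > thr_m,
                    frac_female = curve$frac_female, thr_female = thr_f,
                    flag_female = curve$frac_female > thr_f)
  in_range <- out$k >= sustained_range[1] & out$k <= sustained_range[2]
  summary <- list(
    contrast = attr(curve, "contrast"),
    alpha = alpha,
    sustained_range = sustained_range,
    sustained_male = all(out$flag_male[in_range]),
    sustained_female = all(out$flag_female[in_range]),
    flag_rate_male = mean(out$flag_male),
    flag_rate_female = mean(out$flag_female))
  class(out) <- c("enrichment_calls", "data.frame")
  attr(out, "summary") <- summary
  out
}

#' Top-k sex-specific enrichment analysis with permutation/gamma null
#'
#' The package's central statistic in one call: computes the cumulative
#' enrichment curve of male- and female-specific genes along a
#' p-value-ranked exposure list, builds seeded permutation nulls at the
#' requested sample sizes for each set, fits gamma distributions by moment
#' matching, and flags each k whose observed fraction exceeds the null
#' `1 - alpha` quantile.
#'
#' @param ranked A [rank_exposure_degs()] result.
#' @param sets A [call_sex_specific()] result.
#' @param universe Character vector from [expressed_universe()].
#' @param k_max Largest list size (default 200).
#' @param sizes Null calibration sample sizes (default `c(50, 100, 200)`).
#' @param n_iter Permutation iterations per null (default 5000).
#' @param alpha Significance level (default 0.05).
#' @param seed RNG seed (per-size child seeds are derived deterministically).
#' @param sustained_range Summary k-range, see [call_enrichment()].
#' @return Object of class `masc_enrichment`: list with `curve`, `calls`,
#'   `nulls_male`, `nulls_female`, `summary`, and the parameters used.
#' @export
masc_enrichment <- function(ranked, sets, universe, k_max = 200,
                            sizes = c(50, 100, 200), n_iter = 5000,
                            alpha = 0.05, seed = 1L,
                            sustained_range = c(5, 50)) {
  curve <- enrichment_curve(ranked, sets, universe, k_max = k_max)
  nulls_male <- lapply(seq_along(sizes), function(i)
    permutation_null(universe, sets$male_specific, sizes[i],
                     n_iter = n_iter, seed = seed + 1000L * i))
  nulls_female <- lapply(seq_along(sizes), function(i)
    permutation_null(universe, sets$female_specific, sizes[i],
                     n_iter = n_iter, seed = seed + 1000L * i + 500L))
  calls <- call_enrichment(curve, nulls_male, nulls_female,
                           alpha = alpha, sustained_range = sustained_range)
  structure(list(curve = curve, calls = calls,
                 nulls_male = nulls_male, nulls_female = nulls_female,
                 summary = attr(calls, "summary"),
                 k_max = k_max, sizes = sizes, n_iter = n_iter,
                 alpha = alpha, seed = seed),
            class = "masc_enrichment")
}

#' @export
print.masc_enrichment <- function(x, ...) {
  s <- x$summary
  cat("masc_enrichment:", s$contrast, "\n")
  cat(sprintf("  universe %d genes; sets: male %d, female %d (in universe)\n",
              attr(x$curve, "universe_size"),
              attr(x$curve, "set_sizes")["male"], attr(x$curve, "set_sizes")["female"]))
  cat(sprintf("  nulls: %d draws at s = {%s}, alpha = %g\n",
              x$n_iter, paste(x$sizes, collapse = ", "), x$alpha))
  cat(sprintf("  male-specific:   flagged at %.0f%% of k (sustained over k %d-%d: %s)\n",
              100 * s$flag_rate_male, s$sustained_range[1], s$sustained_range[2],
              ifelse(s$sustained_male, "yes", "no")))
  cat(sprintf("  female-specific: flagged at %.0f%% of k (sustained over k %d-%d: %s)\n",
              100 * s$flag_rate_female, s$sustained_range[1], s$sustained_range[2],
              ifelse(s$sustained_female, "yes", "no")))
  invisible(x)
}

#' Summarize an enrichment analysis by null sample size
#' @param object A `masc_enrichment` object.
#' @param ... Unused.
#' @return `data.frame` with one row per null sample size.
#' @method summary masc_enrichment
#' @export
summary.masc_enrichment <- function(object, ...) {
  s <- object$summary
  gm <- vapply(object$nulls_male, function(n)
    if (n$degenerate) NA_real_ else n$q95_gamma, numeric(1))
  data.frame(contrast = s$contrast,
             s = object$sizes,
             null_q95_male = gm,
             null_q95_female = vapply(object$nulls_female, function(n)
               if (n$degenerate) NA_real_ else n$q95_gamma, numeric(1)),
             sustained_male = s$sustained_male,
             sustained_female = s$sustained_female)
}

#' Plot an enrichment analysis (observed curves versus null quantiles)
#'
#' Two lines per panel — the male- (blue) and female-specific (red) observed
#' fractions by k — with the male-set null `1 - alpha` threshold as a dashed
#' step line.
#'
#' @param x A `masc_enrichment` object.
#' @param ... Passed to `plot`.
#' @return Invisibly, `x`.
#' @method plot masc_enrichment
#' @export
plot.masc_enrichment <- function(x, ...) {
  cv <- x$curve
  plot(cv$k, cv$frac_male, type = "l", col = "blue", lwd = 2,
       ylim = c(0, max(cv$frac_male, cv$frac_female, 0.2)),
       xlab = "top-k exposure-ranked genes",
       ylab = "fraction sex-specific",
       main = attr(cv, "contrast"), ...)
  lines(cv$k, cv$frac_female, col = "red", lwd = 2)
  lines(x$calls$k, x$calls$thr_male, lty = 2, col = "grey40")
  legend("topright", legend = c("male-specific", "female-specific",
                                sprintf("null q%d (male set)", round(100 * (1 - x$alpha)))),
         col = c("blue", "red", "grey40"), lty = c(1, 1, 2), lwd = c(2, 2, 1), bty = "n")
  invisible(x)
}

#' Write an enrichment analysis as TSV + JSON summary
#' @param x A `masc_enrichment` object.
#' @param tsv_path,json_path Output paths.
#' @param seed Seed recorded in the TSV header.
#' @return Invisibly, the paths.
#' @export
write_enrichment <- function(x, tsv_path, json_path, seed = NULL) {
  write_tsv(as.data.frame(x$calls), tsv_path, seed = seed)
  jsonlite::write_json(x$summary, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv_path, json_path))
}
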