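#' Moment-based NB dispersion estimates with empirical-Bayes shrinkage
#'
#' Raw gene-wise dispersions come from the method of moments on
#' library-size-normalized counts. For a gene with within-group means `m_i`,
#' variances `v_i` and group sizes `n_i`, the moment equation
#' `E(v_i) = h_i m_i + phi m_i^2` (where `h_i` is the group mean of the
#' reciprocal relative library size, the exact Poisson-part coefficient after
#' normalization) is solved pooled across groups,
#' `phi_raw = sum_i (n_i-1)(v_i - h_i m_i) / sum_i (n_i-1)(m_i^2 - v_i/n_i)`,
#' with the denominator the unbiased estimate of `m_i^2`, and floored at
#' zero. The common dispersion `phi0` is the same moment ratio pooled over
#' all genes (read-weighted, hence nearly unbiased; the median of floored
#' per-gene estimates systematically underestimates the center of their
#' right-skewed distribution). Each raw estimate is shrunk toward `phi0`
#' with weight `w = n0 / (n0 + df_resid)`:
#' `phi = w * phi0 + (1 - w) * phi_raw`.
#'
#' @param x A [count_matrix()] or counts matrix.
#' @param factors [tmm_factors()] output; computed if `NULL`.
#' @param group Factor over samples defining the design cells.
#' @param n0 Prior sample size of the shrinkage (default 10).
#' @return List of class `dispersion_estimates`: `phi` (named, shrunk),
#'   `phi_raw`, `phi_common`, `weight`.
#' @export
estimate_dispersions <- function(x, factors = NULL, group, n0 = 10) {
  cts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  group <- droplevels(as.factor(group))
  stopifnot(length(group) == ncol(cts))
  sizes <- table(group)
  if (all(sizes < 2)) stop("dispersion estimation needs at least one group with >= 2 samples")
  if (is.null(factors)) factors <- tmm_factors(cts)
  s <- factors$eff_lib_size / mean(factors$eff_lib_size)
  z <- sweep(cts, 2, s, "/")

  num <- 0; den <- 0
  for (lvl in levels(group)) {
    j <- which(group == lvl)
    if (length(j) < 2) next
    nj <- length(j)
    m <- rowMeans(z[, j, drop = FALSE])
    v <- apply(z[, j, drop = FALSE], 1, var)
    h <- mean(1 / s[j])
    num <- num + (nj - 1) * (v - h * m)
    den <- den + (nj - 1) * pmax(m^2 - v / nj, 0)
  }
  phi_raw <- ifelse(den > 0, pmax(0, num / den), 0)
  phi0 <- max(0, sum(num) / sum(den))
  df_resid <- length(group) - nlevels(group)
  w <- n0 / (n0 + df_resid)
  phi <- w * phi0 + (1 - w) * phi_raw
  structure(list(phi = setNames(phi, rownames(cts)),
                 phi_raw = setNames(phi_raw, rownames(cts)),
                 phi_common = phi0, weight = w),
            class = "dispersion_estimates")
}

# Vectorized Fisher scoring for the one-way NB GLM with log link and offsets:
# one mean parameter per group level, mu = exp(beta_level + offset).
# Returns per-gene coefficients (log scale), log-likelihood and convergence.
fit_nb_oneway <- function(y, offset, group, phi, max_iter = 100, tol = 1e-10) {
  group <- droplevels(as.factor(group))
  G <- nrow(y)
  beta <- matrix(NA_real_, G, nlevels(group),
                 dimnames = list(rownames(y), levels(group)))
  ll <- numeric(G)
  converged <- rep(TRUE, G)
  size <- ifelse(phi > 1e-12, 1 / phi, Inf)

  for (lvl in levels(group)) {
    j <- which(group == lvl)
    yj <- y[, j, drop = FALSE]
    oj <- offset[j]
    eo <- exp(oj)
    rs <- rowSums(yj)
    b <- log((rs + 0.5) / sum(eo))
    zero <- rs == 0
    b[zero] <- log(1e-10 / sum(eo))
    active <- !zero
    iter <- 0
    while (any(active) && iter < max_iter) {
      iter <- iter + 1
      mu <- exp(outer(b[active], oj, "+"))
      denom <- 1 + phi[active] * mu
      score <- rowSums((yj[active, , drop = FALSE] - mu) / denom)
      info <- rowSums(mu / denom)
      step <- score / info
      step <- pmin(pmax(step, -5), 5)  # damp early overshoot
      b[active] <- b[active] + step
      done <- abs(step) < tol
      idx <- which(active)
      active[idx[done]] <- FALSE
    }
    converged <- converged & !active
    mu <- exp(outer(b, oj, "+"))
    mu <- pmax(mu, 1e-12)
    nb <- phi > 1e-12
    if (any(nb))
      ll[nb] <- ll[nb] + rowSums(dnbinom(yj[nb, , drop = FALSE],
                                         size = 1 / phi[nb],
                                         mu = mu[nb, , drop = FALSE], log = TRUE))
    if (any(!nb))
      ll[!nb] <- ll[!nb] + rowSums(dpois(yj[!nb, , drop = FALSE],
                                         mu[!nb, , drop = FALSE], log = TRUE))
    beta[, lvl] <- b
  }
  list(beta = beta, ll = ll, converged = converged)
}

#' Negative-binomial GLM likelihood-ratio test per gene
#'
#' Fits a log-link NB GLM per gene with fixed gene-wise dispersion and
#' log-effective-library-size offsets, under a full one-way design (`group`)
#' and a nested reduced design (`reduced`, default: a single pooled mean).
#' The statistic is `LRT = 2 (ll_full - ll_reduced)` with a chi-square
#' reference whose degrees of freedom equal the difference in the number of
#' group levels. Genes with all-zero counts across the tested samples are
#' excluded from testing (and from the multiple-testing denominator).
#'
#' @param x A [count_matrix()] or counts matrix (samples of the contrast).
#' @param factors [tmm_factors()] output for those samples; computed if `NULL`.
#' @param group Factor over samples (full design). For a two-level factor,
#'   `log2FC` is the second level versus the first.
#' @param phi Per-gene dispersions (a `dispersion_estimates` object or a
#'   named/plain numeric vector); estimated from `group` if `NULL`.
#' @param reduced Factor over samples for the reduced design; `NULL` means
#'   the intercept-only model. Must be nested in `group`.
#' @return `data.frame` of class `deg_result`: `gene`, `log2FC`, `LRT`, `p`,
#'   `fdr` (Benjamini-Hochberg across the tested genes), `converged`.
#' @export
nb_glm_lrt <- function(x, factors = NULL, group, phi = NULL, reduced = NULL) {
  cts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  group <- droplevels(as.factor(group))
  stopifnot(length(group) == ncol(cts), nlevels(group) >= 2)
  if (is.null(reduced)) reduced <- factor(rep("all", ncol(cts)))
  reduced <- droplevels(as.factor(reduced))
  if (nlevels(reduced) >= nlevels(group))
    stop("reduced design must have fewer levels than the full design")
  # nesting check: each full level maps into exactly one reduced level
  if (any(rowSums(table(group, reduced) > 0) != 1))
    stop("reduced design is not nested in the full design")
  if (is.null(factors)) factors <- tmm_factors(cts)
  if (is.null(phi)) phi <- estimate_dispersions(cts, factors, group)
  if (inherits(phi, "dispersion_estimates")) phi <- phi$phi
  if (!is.null(names(phi))) phi <- phi[rownames(cts)]
  phi <- unname(phi)
  stopifnot(length(phi) == nrow(cts), all(is.finite(phi)), all(phi >= 0))

  keep <- rowSums(cts) > 0
  y <- cts[keep, , drop = FALSE]
  phik <- phi[keep]
  offset <- log(factors$eff_lib_size)

  full <- fit_nb_oneway(y, offset, group, phik)
  red <- fit_nb_oneway(y, offset, reduced, phik)

  lrt <- pmax(0, 2 * (full$ll - red$ll))
  df <- nlevels(group) - nlevels(reduced)
  p <- pchisq(lrt, df = df, lower.tail = FALSE)
  conv <- full$converged & red$converged
  if (!all(conv)) {
    warning(sprintf("%d gene(s) did not converge; their p-values are set to 1", sum(!conv)))
    p[!conv] <- 1
  }
  log2fc <- if (nlevels(group) == 2) {
    (full$beta[, 2] - full$beta[, 1]) / log(2)
  } else rep(NA_real_, nrow(y))

  out <- data.frame(gene = rownames(y), log2FC = unname(log2fc),
                    LRT = unname(lrt), p = unname(p),
                    fdr = bh_fdr(unname(p)), converged = unname(conv),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("deg_result", "data.frame")
  attr(out, "df") <- df
  attr(out, "contrast") <- if (nlevels(group) == 2)
    paste(levels(group)[2], "vs", levels(group)[1]) else paste(levels(group), collapse = "/")
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement (wraps the standard
#' `p.adjust` implementation).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1))
  p.adjust(p, method = "BH")
}

#' Call sex-specific genes from vehicle samples
#'
#' Tests male versus female among dose-0 (vehicle) samples with the NB GLM
#' LRT and classifies genes by the study criteria: FDR < `fdr_threshold` and
#' more than a two-fold change (`|log2FC| > lfc_threshold`). Positive
#' `log2FC` means higher in males.
#'
#' @param x A [count_matrix()] containing (at least) vehicle samples of both
#'   sexes.
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @param lfc_threshold log2 fold-change cutoff (default 1, i.e. two-fold).
#' @param n0 Shrinkage prior sample size for [estimate_dispersions()].
#' @return List of class `sex_deg_sets`: `male_specific`, `female_specific`
#'   (disjoint character vectors), `table` (the full `deg_result`), and the
#'   thresholds used.
#' @export
call_sex_specific <- function(x, fdr_threshold = 0.05, lfc_threshold = 1, n0 = 10) {
  stopifnot(inherits(x, "count_matrix"))
  veh <- x$metadata$dose == "0"
  if (!any(veh)) stop("no vehicle (dose 0) samples")
  sub <- subset_counts(x, samples = which(veh))
  sexes <- unique(sub$metadata$sex)
  if (!all(c("M", "F") %in% sexes))
    stop("both sexes must be present among vehicle samples; found: ",
         paste(sexes, collapse = ", "))
  group <- factor(sub$metadata$sex, levels = c("F", "M"))
  factors <- tmm_factors(sub)
  phi <- estimate_dispersions(sub, factors, group, n0 = n0)
  tab <- nb_glm_lrt(sub, factors, group, phi)
  male <- tab$gene[tab$fdr < fdr_threshold & tab$log2FC > lfc_threshold]
  female <- tab$gene[tab$fdr < fdr_threshold & tab$log2FC < -lfc_threshold]
  structure(list(male_specific = sort(male), female_specific = sort(female),
                 table = tab, fdr_threshold = fdr_threshold,
                 lfc_threshold = lfc_threshold),
            class = "sex_deg_sets")
}

#' @export
print.sex_deg_sets <- function(x, ...) {
  cat(sprintf("sex_deg_sets: %d male-specific, %d female-specific (FDR < %g, |log2FC| > %g) of %d tested genes\n",
              length(x$male_specific), length(x$female_specific),
              x$fdr_threshold, x$lfc_threshold, nrow(x$table)))
  invisible(x)
}

#' P-value-ranked exposure differential-expression list
#'
#' Tests exposed versus vehicle samples of one sex (optionally restricted to
#' given generations; several doses may be pooled as "exposed") and returns
#' every tested gene ordered by ascending p-value, with deterministic
#' tie-breaking by descending `|log2FC|` then lexicographic gene id.
#' Positive `log2FC` means higher in exposed samples.
#'
#' @param x A [count_matrix()].
#' @param sex `"M"` or `"F"`.
#' @param doses Exposure dose level(s) to include (pooled against vehicle).
#' @param generations Generations to include; `NULL` means all.
#' @param n0 Shrinkage prior sample size for [estimate_dispersions()].
#' @return `data.frame` of class `ranked_deg_list` with columns `rank`,
#'   `gene`, `log2FC`, `LRT`, `p`, `fdr`; attribute `contrast` labels the
#'   comparison.
#' @export
rank_exposure_degs <- function(x, sex, doses, generations = NULL, n0 = 10) {
  stopifnot(inherits(x, "count_matrix"), sex %in% c("M", "F"))
  doses <- canonical_dose(doses)
  if ("0" %in% doses) stop("doses must not include the vehicle '0'")
  md <- x$metadata
  pick <- md$sex == sex & md$dose %in% c("0", doses)
  if (!is.null(generations)) pick <- pick & md$generation %in% generations
  if (!any(pick)) stop("contrast selects no samples")
  sub <- subset_counts(x, samples = which(pick))
  exposed <- sub$metadata$dose != "0"
  if (sum(!exposed) < 2 || sum(exposed) < 2)
    stop("contrast needs at least 2 samples per group (vehicle/exposed)")
  group <- factor(ifelse(exposed, "exposed", "vehicle"),
                  levels = c("vehicle", "exposed"))
  factors <- tmm_factors(sub)
  phi <- estimate_dispersions(sub, factors, group, n0 = n0)
  tab <- nb_glm_lrt(sub, factors, group, phi)
  ord <- order(tab$p, -abs(tab$log2FC), tab$gene, method = "radix")
  tab <- tab[ord, c("gene", "log2FC", "LRT", "p", "fdr")]
  tab <- data.frame(rank = seq_len(nrow(tab)), tab, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  class(tab) <- c("ranked_deg_list", "data.frame")
  attr(tab, "contrast") <- sprintf(
    "%s: dose {%s} vs vehicle%s", sex, paste(doses, collapse = ","),
    if (is.null(generations)) "" else paste0(" (", paste(generations, collapse = ","), ")"))
  tab
}
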