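#' Configuration for the synthetic germ-cell count simulator
#'
#' Defaults mirror the study conditions at the gene level (15,423 genes of
#' which about 3100 exceed raw count 100; 1862 male-specific and 1669
#' female-specific genes) combined with a desk-scale sample profile (one
#' generation, five samples per sex-by-dose cell). The full three-generation
#' profile is obtained with `generations = c("F1","F2","F3")`.
#'
#' @param n_genes Number of genes.
#' @param generations Character subset of `c("F1","F2","F3")`.
#' @param doses Character subset of `c("0","0.033","0.2","2")` (mg/kg-day);
#'   must include the vehicle `"0"`.
#' @param n_per_cell Samples per (generation, sex, dose) cell.
#' @param n_male_specific,n_female_specific Numbers of sex-dimorphic genes.
#' @param sex_log2fc True male-vs-female log2 fold change of sex-dimorphic
#'   genes (applied symmetrically: half up in the favoured sex, half down in
#'   the other). `0` gives a null configuration.
#' @param masc_effect Log2 up-shift applied to a subset of male-specific genes
#'   in exposed (dose > 0) female samples — the masculinization signal.
#' @param masc_fraction Fraction of male-specific genes carrying that shift.
#' @param libsize_mu,libsize_sigma Log-normal parameters of the per-sample
#'   library-size factor (mean-log and sd-log; factor multiplies every gene
#'   mean in a sample).
#' @param dispersion_shape,dispersion_rate Gamma prior for gene-wise NB
#'   dispersions (defaults give mean 0.1).
#' @param universe_target Intended number of genes whose expression exceeds
#'   `universe_threshold`; baseline means are calibrated to this by
#'   closed-form log-normal quantile matching.
#' @param universe_threshold Raw-count expression threshold (default 100).
#' @param baseline_sdlog Spread (sd of log) of baseline gene means.
#' @param seed RNG seed; identical configurations and seeds give identical
#'   output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 15423,
                       generations = "F1",
                       doses = c("0", "0.033", "0.2", "2"),
                       n_per_cell = 5,
                       n_male_specific = 1862,
                       n_female_specific = 1669,
                       sex_log2fc = 2,
                       masc_effect = 1.5,
                       masc_fraction = 0.5,
                       libsize_mu = 0,
                       libsize_sigma = 0.25,
                       dispersion_shape = 2,
                       dispersion_rate = 20,
                       universe_target = 3100,
                       universe_threshold = 100,
                       baseline_sdlog = 2,
                       seed = 1L) {
  doses <- canonical_dose(doses)
  stopifnot(
    n_genes >= 1, n_per_cell >= 1,
    all(generations %in% c("F1", "F2", "F3")),
    "0" %in% doses,
    n_male_specific >= 0, n_female_specific >= 0,
    sex_log2fc >= 0, masc_effect >= 0,
    masc_fraction >= 0, masc_fraction <= 1,
    libsize_sigma >= 0, dispersion_shape > 0, dispersion_rate > 0,
    universe_target >= 1, universe_target <= n_genes,
    universe_threshold >= 0, baseline_sdlog > 0
  )
  if (n_male_specific + n_female_specific > n_genes)
    stop("n_male_specific + n_female_specific exceeds n_genes")
  structure(list(
    n_genes = as.integer(n_genes), generations = generations, doses = doses,
    n_per_cell = as.integer(n_per_cell),
    n_male_specific = as.integer(n_male_specific),
    n_female_specific = as.integer(n_female_specific),
    sex_log2fc = sex_log2fc, masc_effect = masc_effect,
    masc_fraction = masc_fraction,
    libsize_mu = libsize_mu, libsize_sigma = libsize_sigma,
    dispersion_shape = dispersion_shape, dispersion_rate = dispersion_rate,
    universe_target = as.integer(universe_target),
    universe_threshold = universe_threshold,
    baseline_sdlog = baseline_sdlog, seed = as.integer(seed)
  ), class = "sim_config")
}

# Closed-form calibration: choose meanlog so that a fraction
# universe_target/n_genes of log-normal baseline means exceeds the expression
# threshold (quantile matching, no rejection sampling).
baseline_meanlog <- function(config) {
  p <- config$universe_target / config$n_genes
  log(config$universe_threshold) - config$baseline_sdlog * qnorm(1 - p)
}

#' Simulate a germ-cell count matrix with known sex-dimorphic structure
#'
#' Draws gene-wise negative-binomial counts with mean
#' `baseline * library_factor * 2^(effects)` where the effects encode (i) a
#' symmetric sex-dimorphism of `sex_log2fc` log2 units on the configured
#' male- and female-specific gene sets and (ii) a `masc_effect` log2 up-shift
#' of a random `masc_fraction` of male-specific genes in exposed (dose > 0)
#' female samples. Gene-wise dispersions come from the configured gamma prior;
#' a dispersion of zero yields Poisson counts.
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{counts}{a [count_matrix()]}
#'     \item{truth}{ground-truth labels: `male_specific_genes`,
#'       `female_specific_genes`, `masc_affected_genes`, per-gene
#'       `true_sex_lfc` (male vs female) and `true_masc_lfc` (exposed female
#'       vs vehicle female), `dispersions`, `baseline_means`,
#'       `library_factors`}
#'   }
#' @export
simulate_pgc_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    G <- config$n_genes
    genes <- sprintf("g%05d", seq_len(G))

    cells <- expand.grid(generation = config$generations, sex = c("M", "F"),
                         dose = config$doses, rep = seq_len(config$n_per_cell),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    metadata <- data.frame(
      sample_id = sprintf("s%03d_%s_%s_d%s", seq_len(nrow(cells)),
                          cells$generation, cells$sex, gsub("\\.", "p", cells$dose)),
      generation = cells$generation, sex = cells$sex, dose = cells$dose,
      stringsAsFactors = FALSE)
    n <- nrow(metadata)

    base_mu <- rlnorm(G, meanlog = baseline_meanlog(config), sdlog = config$baseline_sdlog)
    phi <- rgamma(G, shape = config$dispersion_shape, rate = config$dispersion_rate)
    libfac <- rlnorm(n, meanlog = config$libsize_mu, sdlog = config$libsize_sigma)

    idx <- sample.int(G, config$n_male_specific + config$n_female_specific)
    male_idx <- idx[seq_len(config$n_male_specific)]
    female_idx <- idx[seq_len(config$n_female_specific) + config$n_male_specific]
    n_aff <- round(config$masc_fraction * config$n_male_specific)
    masc_idx <- if (n_aff > 0) sort(sample(male_idx, n_aff)) else integer(0)

    # per-gene log2 effect by sample: symmetric sex split, plus masculinization
    # shift in exposed females
    half <- config$sex_log2fc / 2
    eff_male_sample <- numeric(G)   # effect when sample is male
    eff_female_sample <- numeric(G) # effect when sample is female (vehicle)
    eff_male_sample[male_idx] <- half
    eff_female_sample[male_idx] <- -half
    eff_male_sample[female_idx] <- -half
    eff_female_sample[female_idx] <- half

    masc_vec <- numeric(G)
    masc_vec[masc_idx] <- config$masc_effect

    mu <- matrix(0, G, n, dimnames = list(genes, metadata$sample_id))
    for (j in seq_len(n)) {
      eff <- if (metadata$sex[j] == "M") eff_male_sample else eff_female_sample
      if (metadata$sex[j] == "F" && metadata$dose[j] != "0")
        eff <- eff + masc_vec
      mu[, j] <- base_mu * libfac[j] * 2^eff
    }

    counts <- matrix(0, G, n, dimnames = dimnames(mu))
    pois <- phi < 1e-12
    for (j in seq_len(n)) {
      counts[!pois, j] <- rnbinom(sum(!pois), mu = mu[!pois, j], size = 1 / phi[!pois])
      if (any(pois)) counts[pois, j] <- rpois(sum(pois), mu[pois, j])
    }

    true_sex_lfc <- eff_male_sample - eff_female_sample
    true_masc_lfc <- numeric(G)
    true_masc_lfc[masc_idx] <- config$masc_effect

    truth <- list(
      male_specific_genes = genes[sort(male_idx)],
      female_specific_genes = genes[sort(female_idx)],
      masc_affected_genes = genes[masc_idx],
      true_sex_lfc = setNames(true_sex_lfc, genes),
      true_masc_lfc = setNames(true_masc_lfc, genes),
      dispersions = setNames(phi, genes),
      baseline_means = setNames(base_mu, genes),
      library_factors = setNames(libfac, metadata$sample_id)
    )
    list(counts = count_matrix(counts, metadata), truth = truth)
  })
}

#' Write simulation ground truth as TSV + JSON
#' @param truth Truth component of [simulate_pgc_counts()] output.
#' @param dir Output directory.
#' @param seed Seed recorded in headers.
#' @return Invisibly, the directory.
#' @export
write_sim_truth <- function(truth, dir, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes <- names(truth$true_sex_lfc)
  df <- data.frame(
    gene_id = genes,
    male_specific = genes %in% truth$male_specific_genes,
    female_specific = genes %in% truth$female_specific_genes,
    masc_affected = genes %in% truth$masc_affected_genes,
    true_sex_lfc = unname(truth$true_sex_lfc),
    true_masc_lfc = unname(truth$true_masc_lfc),
    dispersion = unname(truth$dispersions),
    baseline_mean = unname(truth$baseline_means))
  write_tsv(df, file.path(dir, "truth_genes.tsv"), seed = seed)
  jsonlite::write_json(
    list(male_specific_genes = truth$male_specific_genes,
         female_specific_genes = truth$female_specific_genes,
         masc_affected_genes = truth$masc_affected_genes,
         library_factors = as.list(truth$library_factors)),
    file.path(dir, "truth_sets.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
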