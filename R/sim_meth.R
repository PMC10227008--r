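#' Default repeat-family specifications for the methylation simulator
#'
#' Emulates the qualitative methylome of fetal germ cells: genome-wide
#' demethylation with the IAP endogenous-retrovirus family retaining high
#' methylation, LINE-1 at a low-intermediate level, and the B1-B4 SINE
#' families nearly unmethylated; an exposure shifts a fraction of B3-like
#' loci upward (hypermethylation).
#'
#' @return `data.frame` with one row per family: `name`, `class`, `n_loci`,
#'   `locus_len`, `baseline_meth`, `exposure_shift`, `shift_fraction`.
#' @export
default_meth_families <- function() {
  data.frame(
    name = c("IAPEz_like", "L1Md_like", "B1_like", "B2_like", "B3_like", "B4_like"),
    class = c("IAP", "LINE-1", "B1-B4", "B1-B4", "B1-B4", "B1-B4"),
    n_loci = c(200L, 250L, 200L, 200L, 200L, 200L),
    locus_len = c(500L, 1000L, 150L, 180L, 150L, 150L),
    baseline_meth = c(0.80, 0.15, 0.05, 0.05, 0.05, 0.05),
    exposure_shift = c(0, 0, 0, 0, 0.30, 0),
    shift_fraction = c(0, 0, 0, 0, 0.5, 0),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic repeat-methylome simulator
#'
#' @param families `data.frame` of family specifications, as in
#'   [default_meth_families()].
#' @param depth_mean Mean sequencing depth per CpG (Poisson; zero-depth CpGs
#'   are dropped, as a coverage file only reports covered positions).
#' @param cpg_spacing Distance in bp between consecutive CpGs within a locus.
#' @param gap Gap in bp between consecutive loci (guarantees non-overlap).
#' @param genome_length Length of the single synthetic chromosome; must
#'   accommodate all loci plus gaps.
#' @param chrom Chromosome name used in output records.
#' @param seed RNG seed.
#' @return A validated list of class `meth_sim_config`.
#' @export
meth_sim_config <- function(families = default_meth_families(),
                            depth_mean = 20,
                            cpg_spacing = 20L,
                            gap = 200L,
                            genome_length = NULL,
                            chrom = "chrS1",
                            seed = 1L) {
  req <- c("name", "class", "n_loci", "locus_len", "baseline_meth",
           "exposure_shift", "shift_fraction")
  stopifnot(is.data.frame(families), all(req %in% names(families)))
  if (anyDuplicated(families$name)) stop("duplicated family names")
  if (any(families$baseline_meth < 0 | families$baseline_meth > 1))
    stop("baseline_meth must lie in [0, 1]")
  if (any(families$shift_fraction < 0 | families$shift_fraction > 1))
    stop("shift_fraction must lie in [0, 1]")
  stopifnot(depth_mean > 0, cpg_spacing >= 1, gap >= 0)
  needed <- sum(families$n_loci * (families$locus_len + gap))
  if (is.null(genome_length)) genome_length <- needed
  if (needed > genome_length)
    stop(sprintf("family loci require %d bp but genome_length is %d", needed, genome_length))
  structure(list(families = families, depth_mean = depth_mean,
                 cpg_spacing = as.integer(cpg_spacing), gap = as.integer(gap),
                 genome_length = as.integer(genome_length), chrom = chrom,
                 seed = as.integer(seed)),
            class = "meth_sim_config")
}

#' Simulate per-CpG repeat methylation calls with ground truth
#'
#' Loci are laid end-to-end (family blocks interleaved gene-by-gap, so
#' non-overlap holds by construction) along one synthetic chromosome, with
#' CpGs at a fixed spacing inside each locus. Each CpG receives
#' `Binomial(depth, locus methylation)` methylated reads, where depth is
#' Poisson and the locus methylation is the family baseline plus, when
#' `exposed = TRUE`, the configured hypermethylation shift on a random
#' `shift_fraction` of that family's loci (clipped to `[0, 1]`).
#'
#' The set of shifted loci depends only on the configuration seed, so exposed
#' and unexposed runs of the same configuration shift the same loci.
#'
#' @param config A [meth_sim_config()].
#' @param exposed Logical: apply the exposure hypermethylation shifts?
#' @return List with `calls` (chrom, pos, meth, unmeth; 0-based positions),
#'   `annotation` (BED-like, 0-based half-open), and `truth`
#'   (`families`: per-family true mean methylation under this condition;
#'   `loci`: per-locus true methylation and shift flag).
#' @export
simulate_repeat_meth <- function(config, exposed = FALSE) {
  stopifnot(inherits(config, "meth_sim_config"))
  fams <- config$families
  fams <- fams[fams$n_loci > 0, , drop = FALSE]

  # locus layout and shift assignment are seed-determined, independent of
  # the exposure flag
  with_seed(config$seed, {
    loci <- do.call(rbind, lapply(seq_len(nrow(fams)), function(i) {
      data.frame(family = fams$name[i], class = fams$class[i],
                 locus = seq_len(fams$n_loci[i]),
                 len = fams$locus_len[i],
                 base = fams$baseline_meth[i],
                 shift = fams$exposure_shift[i],
                 stringsAsFactors = FALSE)
    }))
    ord <- sample.int(nrow(loci))          # interleave families along the chromosome
    loci <- loci[ord, , drop = FALSE]
    loci$start <- cumsum(c(0L, utils::head(loci$len + config$gap, -1)))
    loci$end <- loci$start + loci$len
    shifted <- logical(nrow(loci))
    for (i in seq_len(nrow(fams))) {
      rows <- which(loci$family == fams$name[i])
      k <- round(fams$shift_fraction[i] * length(rows))
      if (k > 0) shifted[sample(rows, k)] <- TRUE
    }
    loci$shifted <- shifted
    loci$locus_id <- sprintf("%s_%04d", loci$family, loci$locus)

    loci$true_meth <- pmin(1, pmax(0, loci$base + ifelse(exposed, 1, 0) * ifelse(loci$shifted, loci$shift, 0)))

    # draw reads; exposed and unexposed runs consume the same RNG stream
    # positions so layout stays identical
    calls <- do.call(rbind, lapply(seq_len(nrow(loci)), function(i) {
      pos <- seq(loci$start[i], loci$end[i] - 1L, by = config$cpg_spacing)
      depth <- rpois(length(pos), config$depth_mean)
      meth <- rbinom(length(pos), depth, loci$true_meth[i])
      keep <- depth >= 1
      data.frame(chrom = config$chrom, pos = as.integer(pos[keep]),
                 meth = as.integer(meth[keep]),
                 unmeth = as.integer(depth[keep] - meth[keep]),
                 stringsAsFactors = FALSE)
    }))
    calls <- calls[order(calls$pos), , drop = FALSE]
    rownames(calls) <- NULL

    annotation <- data.frame(chrom = config$chrom, start = loci$start,
                             end = loci$end, family = loci$family,
                             class = loci$class, strand = "+",
                             stringsAsFactors = FALSE)
    fam_truth <- aggregate(true_meth ~ family, data = loci, FUN = mean)
    names(fam_truth)[2] <- "true_mean_meth"
    fam_truth <- merge(fam_truth,
                       unique(data.frame(family = fams$name, class = fams$class)),
                       by = "family", sort = TRUE)
    truth <- list(families = fam_truth,
                  loci = loci[, c("locus_id", "family", "class", "start", "end",
                                  "true_meth", "shifted")])
    list(calls = calls, annotation = annotation, truth = truth)
  })
}
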