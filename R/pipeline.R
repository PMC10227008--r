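#' Assemble and validate an end-to-end pipeline configuration
#'
#' Holds the stage inputs (a simulation configuration or paths to count and
#' metadata TSVs), the contrast definitions, and every analysis threshold.
#' Validation happens here, before any compute.
#'
#' @param sim A [sim_config()] for synthetic input, or `NULL` when reading
#'   counts from disk.
#' @param counts_path,metadata_path TSV paths used when `sim` is `NULL`.
#' @param meth_sim A [meth_sim_config()] to run the repeat-methylome stage on
#'   synthetic data, or `NULL` to skip the stage.
#' @param contrasts Non-empty list of exposure contrasts; each element is a
#'   list with `label`, `sex` (`"M"`/`"F"`), `doses` (non-vehicle dose
#'   strings, pooled), and optional `generations`.
#' @param fdr_threshold,lfc_threshold Sex-specific DEG criteria (defaults
#'   0.05 and 1, i.e. FDR < 0.05 and more than two-fold).
#' @param universe_threshold Expressed-universe raw-count threshold (100).
#' @param k_max Enrichment curve length (200).
#' @param n_iter Permutation iterations per null (5000).
#' @param sizes Null calibration sample sizes (50, 100, 200).
#' @param alpha Enrichment significance level (0.05).
#' @param top_n Repeat ranking table length (35).
#' @param min_cpg Coverage floor for methylation rankings (50).
#' @param seed Global seed; per-stage child seeds are derived from it.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            counts_path = NULL, metadata_path = NULL,
                            meth_sim = NULL,
                            contrasts,
                            fdr_threshold = 0.05, lfc_threshold = 1,
                            universe_threshold = 100,
                            k_max = 200, n_iter = 5000,
                            sizes = c(50, 100, 200), alpha = 0.05,
                            top_n = 35, min_cpg = 50,
                            seed = 1L) {
  if (missing(contrasts) || is.null(contrasts) || length(contrasts) == 0)
    stop("pipeline_config requires at least one contrast")
  if (is.null(sim) && (is.null(counts_path) || is.null(metadata_path)))
    stop("either a sim_config or counts_path + metadata_path must be given")
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  if (!is.null(meth_sim)) stopifnot(inherits(meth_sim, "meth_sim_config"))
  stopifnot(fdr_threshold > 0, lfc_threshold > 0, universe_threshold >= 0,
            k_max > 0, n_iter > 1, all(sizes > 0), alpha > 0, alpha < 1,
            top_n > 0, min_cpg > 0)
  for (ct in contrasts) {
    if (is.null(ct$label) || is.null(ct$sex) || is.null(ct$doses))
      stop("each contrast needs label, sex and doses")
    if (!ct$sex %in% c("M", "F")) stop("contrast sex must be 'M' or 'F'")
    d <- canonical_dose(ct$doses)
    if ("0" %in% d) stop("contrast doses must not include the vehicle '0'")
    if (!is.null(sim)) {
      if (!all(d %in% sim$doses))
        stop(sprintf("contrast '%s' references dose(s) absent from the simulation: %s",
                     ct$label, paste(setdiff(d, sim$doses), collapse = ", ")))
      if (!is.null(ct$generations) && !all(ct$generations %in% sim$generations))
        stop(sprintf("contrast '%s' references generation(s) absent from the simulation",
                     ct$label))
    }
  }
  structure(list(sim = sim, counts_path = counts_path,
                 metadata_path = metadata_path, meth_sim = meth_sim,
                 contrasts = contrasts,
                 fdr_threshold = fdr_threshold, lfc_threshold = lfc_threshold,
                 universe_threshold = universe_threshold, k_max = k_max,
                 n_iter = n_iter, sizes = sizes, alpha = alpha,
                 top_n = top_n, min_cpg = min_cpg, seed = as.integer(seed)),
            class = "pipeline_config")
}

# deterministic per-stage child seeds (all well below 2^31)
stage_seeds <- function(seed) {
  list(sim = seed + 11L, meth = seed + 23L, enrich = seed + 37L)
}

#' Run the full analysis pipeline and write all artifacts
#'
#' Stages: simulate (or load) counts -> TMM normalization -> sex-specific DEG
#' calling on vehicle samples -> expressed universe -> per-contrast p-value
#' ranked exposure lists and top-k enrichment against permutation/gamma
#' nulls -> optional repeat-methylome rankings. Writes versioned TSV/JSON
#' outputs, a JSON run manifest recording every threshold and seed, and a
#' plain-text + JSON report. A failing stage aborts with a stage-named error;
#' outputs written so far are retained alongside a `FAILED_<stage>` marker.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`counts`, `truth`,
#'   `factors`, `sex_sets`, `universe`, `enrichments`, `repeats`, `report`).
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seeds <- stage_seeds(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(conditionMessage(e), file.path(outdir, paste0("FAILED_", name)))
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  input <- stage("input", {
    if (!is.null(config$sim)) {
      sim_cfg <- config$sim
      sim_cfg$seed <- seeds$sim
      sim <- simulate_pgc_counts(sim_cfg)
      write_counts(sim$counts, file.path(outdir, "counts.tsv"),
                   file.path(outdir, "metadata.tsv"), seed = seeds$sim)
      write_sim_truth(sim$truth, file.path(outdir, "truth"), seed = seeds$sim)
      sim
    } else {
      list(counts = read_counts(config$counts_path, config$metadata_path),
           truth = NULL)
    }
  })
  counts <- input$counts
  truth <- input$truth

  factors <- stage("normalize", {
    f <- tmm_factors(counts)
    write_norm_factors(f, file.path(outdir, "tmm_factors.tsv"), seed = config$seed)
    f
  })

  sex_sets <- stage("sex_degs", {
    ss <- call_sex_specific(counts, fdr_threshold = config$fdr_threshold,
                            lfc_threshold = config$lfc_threshold)
    write_tsv(as.data.frame(ss$table), file.path(outdir, "sex_deg_table.tsv"),
              seed = config$seed)
    writeLines(ss$male_specific, file.path(outdir, "male_specific_genes.txt"))
    writeLines(ss$female_specific, file.path(outdir, "female_specific_genes.txt"))
    ss
  })

  universe <- stage("universe", {
    u <- expressed_universe(counts, threshold = config$universe_threshold)
    writeLines(u, file.path(outdir, "expressed_universe.txt"))
    u
  })

  enrichments <- stage("enrichment", {
    res <- list()
    for (i in seq_along(config$contrasts)) {
      ct <- config$contrasts[[i]]
      ranked <- rank_exposure_degs(counts, sex = ct$sex, doses = ct$doses,
                                   generations = ct$generations)
      write_tsv(as.data.frame(ranked),
                file.path(outdir, sprintf("ranked_degs_%s.tsv", ct$label)),
                seed = config$seed)
      enr <- masc_enrichment(ranked, sex_sets, universe,
                             k_max = config$k_max, sizes = config$sizes,
                             n_iter = config$n_iter, alpha = config$alpha,
                             seed = seeds$enrich + i)
      write_enrichment(enr,
                       file.path(outdir, sprintf("enrichment_%s.tsv", ct$label)),
                       file.path(outdir, sprintf("enrichment_%s.json", ct$label)),
                       seed = seeds$enrich + i)
      res[[ct$label]] <- enr
    }
    res
  })

  repeats <- if (!is.null(config$meth_sim)) stage("repeats", {
    meth_cfg <- config$meth_sim
    meth_cfg$seed <- seeds$meth
    out <- list()
    for (cond in c("vehicle", "exposed")) {
      sim <- simulate_repeat_meth(meth_cfg, exposed = cond == "exposed")
      write_meth_coverage(sim$calls, file.path(outdir, sprintf("meth_%s.cov", cond)))
      asg <- assign_cpgs(sim$calls, sim$annotation)
      cov_rank <- coverage_ranking(asg, N = config$top_n)
      most <- methylation_ranking(asg, N = config$top_n, min_cpg = config$min_cpg,
                                  direction = "most")
      least <- methylation_ranking(asg, N = config$top_n, min_cpg = config$min_cpg,
                                   direction = "least")
      write_ranking(cov_rank, file.path(outdir, sprintf("repeat_coverage_%s.tsv", cond)),
                    seed = seeds$meth)
      write_ranking(most, file.path(outdir, sprintf("repeat_most_meth_%s.tsv", cond)),
                    seed = seeds$meth)
      write_ranking(least, file.path(outdir, sprintf("repeat_least_meth_%s.tsv", cond)),
                    seed = seeds$meth)
      out[[cond]] <- list(assignment = asg, coverage = cov_rank,
                          most = most, least = least, truth = sim$truth)
    }
    write_repeat_annotation(out$vehicle$assignment$annotation,
                            file.path(outdir, "repeat_annotation.bed"))
    out
  }) else NULL

  report <- stage("report", {
    per_contrast <- lapply(enrichments, function(e) e$summary)
    rep_json <- list(contrasts = per_contrast,
                     n_male_specific = length(sex_sets$male_specific),
                     n_female_specific = length(sex_sets$female_specific),
                     universe_size = length(universe))
    jsonlite::write_json(rep_json, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    txt <- c(sprintf("pgcmasc pipeline report (package %s)",
                     as.character(packageVersion("pgcmasc"))),
             sprintf("genes: %d, samples: %d", nrow(counts$counts), ncol(counts$counts)),
             sprintf("sex-specific genes: %d male, %d female (FDR < %g, |log2FC| > %g)",
                     length(sex_sets$male_specific), length(sex_sets$female_specific),
                     config$fdr_threshold, config$lfc_threshold),
             sprintf("expressed universe (> %g): %d genes",
                     config$universe_threshold, length(universe)),
             "",
             "per-contrast enrichment (sustained over summary k-range):")
    for (lab in names(per_contrast)) {
      s <- per_contrast[[lab]]
      txt <- c(txt, sprintf("  %-24s male-specific: %-3s  female-specific: %s",
                            lab, ifelse(s$sustained_male, "YES", "no"),
                            ifelse(s$sustained_female, "YES", "no")))
    }
    writeLines(txt, file.path(outdir, "report.txt"))
    rep_json
  })

  manifest <- list(
    package_version = as.character(packageVersion("pgcmasc")),
    global_seed = config$seed,
    stage_seeds = seeds,
    thresholds = list(fdr = config$fdr_threshold, lfc = config$lfc_threshold,
                      universe = config$universe_threshold, k_max = config$k_max,
                      n_iter = config$n_iter, sizes = config$sizes,
                      alpha = config$alpha, top_n = config$top_n,
                      min_cpg = config$min_cpg),
    input = if (is.null(config$sim)) list(counts_path = config$counts_path,
                                          metadata_path = config$metadata_path)
            else unclass(config$sim)[setdiff(names(unclass(config$sim)), "seed")],
    contrasts = config$contrasts,
    meth_stage = !is.null(config$meth_sim))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(counts = counts, truth = truth, factors = factors,
                 sex_sets = sex_sets, universe = universe,
                 enrichments = enrichments, repeats = repeats, report = report))
}
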