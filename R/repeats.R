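#' Assign CpG methylation calls to repeat annotations
#'
#' A call at 0-based position `p` joins every annotation interval with
#' `start <= p < end` (half-open convention); lookups use an interval index.
#' Nested or overlapping annotations each receive the call. Calls overlapping
#' no repeat are grouped as `"non-repeat"` (including calls on chromosomes
#' absent from the annotation).
#'
#' @param calls `data.frame` with `chrom`, `pos` (0-based), `meth`, `unmeth`
#'   (as from [read_meth_coverage()] or [simulate_repeat_meth()]).
#' @param annotation `data.frame` with `chrom`, `start`, `end` (0-based
#'   half-open), `family`, `class` (as from [read_repeat_annotation()]).
#' @return Object of class `repeat_assignment`: list with `hits` (one row per
#'   call-by-locus overlap: `call_idx`, `locus_idx`, `family`, `class`),
#'   `calls`, `annotation`, `non_repeat_idx` (call rows hitting no repeat).
#' @export
assign_cpgs <- function(calls, annotation) {
  stopifnot(all(c("chrom", "pos", "meth", "unmeth") %in% names(calls)),
            all(c("chrom", "start", "end", "family", "class") %in% names(annotation)))
  if (nrow(annotation) && any(annotation$start >= annotation$end))
    stop("annotation has start >= end")
  hits_list <- list()
  for (chr in unique(calls$chrom)) {
    ci <- which(calls$chrom == chr)
    ai <- which(annotation$chrom == chr)
    if (!length(ai)) next
    q <- IRanges::IRanges(start = calls$pos[ci] + 1L, width = 1L)
    s <- IRanges::IRanges(start = annotation$start[ai] + 1L, end = annotation$end[ai])
    ov <- IRanges::findOverlaps(q, s)
    if (length(ov))
      hits_list[[chr]] <- data.frame(
        call_idx = ci[S4Vectors::queryHits(ov)],
        locus_idx = ai[S4Vectors::subjectHits(ov)])
  }
  hits <- if (length(hits_list)) do.call(rbind, hits_list) else
    data.frame(call_idx = integer(), locus_idx = integer())
  rownames(hits) <- NULL
  hits$family <- annotation$family[hits$locus_idx]
  hits$class <- annotation$class[hits$locus_idx]
  structure(list(hits = hits, calls = calls, annotation = annotation,
                 non_repeat_idx = setdiff(seq_len(nrow(calls)), unique(hits$call_idx))),
            class = "repeat_assignment")
}

# Per-family summary: covered CpGs, pooled read counts, weighted methylation.
# Within a family a call is counted once even if it overlaps several of the
# family's loci; across families multi-overlap calls count once per family.
family_stats <- function(asg) {
  stopifnot(inherits(asg, "repeat_assignment"))
  h <- unique(asg$hits[, c("call_idx", "family", "class")])
  if (!nrow(h))
    return(data.frame(family = character(), class = character(),
                      n_cpg = integer(), total_meth = numeric(),
                      total_reads = numeric(), weighted_meth = numeric()))
  meth <- asg$calls$meth[h$call_idx]
  tot <- meth + asg$calls$unmeth[h$call_idx]
  out <- do.call(rbind, lapply(split(seq_len(nrow(h)), h$family), function(i) {
    data.frame(family = h$family[i[1]], class = h$class[i[1]],
               n_cpg = length(i), total_meth = sum(meth[i]),
               total_reads = sum(tot[i]),
               weighted_meth = sum(meth[i]) / sum(tot[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$family, method = "radix"), , drop = FALSE]
}

#' Rank repeat families by WGBS coverage
#'
#' Families ordered by the number of interrogated (covered) CpGs, descending;
#' ties break lexicographically by family name.
#'
#' @param asg A [assign_cpgs()] result.
#' @param N Table length (default 35).
#' @return `data.frame` of class `ranking_table`: `rank`, `family`, `class`,
#'   `metric` (covered CpG count); attribute `metric_name`.
#' @export
coverage_ranking <- function(asg, N = 35) {
  fs <- family_stats(asg)
  ord <- order(-fs$n_cpg, fs$family, method = "radix")
  fs <- fs[ord, , drop = FALSE][seq_len(min(N, nrow(fs))), , drop = FALSE]
  out <- data.frame(rank = seq_len(nrow(fs)), family = fs$family,
                    class = fs$class, metric = fs$n_cpg,
                    stringsAsFactors = FALSE)
  class(out) <- c("ranking_table", "data.frame")
  attr(out, "metric_name") <- "n_cpg_interrogated"
  out
}

#' Rank repeat families by read-weighted methylation
#'
#' Family-level methylation is pooled-read weighted
#' (`sum(meth) / sum(meth + unmeth)` over all covered CpGs in the family).
#' Families with fewer than `min_cpg` covered CpGs are excluded so that
#' sparsely covered families cannot top the table.
#'
#' @param asg A [assign_cpgs()] result.
#' @param N Table length (default 35).
#' @param min_cpg Minimum covered CpGs for eligibility (default 50).
#' @param direction `"most"` (descending) or `"least"` (ascending).
#' @return A `ranking_table` (`rank`, `family`, `class`, `metric` =
#'   weighted methylation, `n_cpg`); empty with a warning when no family is
#'   eligible.
#' @export
methylation_ranking <- function(asg, N = 35, min_cpg = 50,
                                direction = c("most", "least")) {
  direction <- match.arg(direction)
  fs <- family_stats(asg)
  fs <- fs[fs$n_cpg >= min_cpg, , drop = FALSE]
  if (!nrow(fs)) {
    warning("no family passes the min_cpg coverage floor")
    out <- data.frame(rank = integer(), family = character(),
                      class = character(), metric = numeric(), n_cpg = integer())
    class(out) <- c("ranking_table", "data.frame")
    attr(out, "metric_name") <- paste0("weighted_meth_", direction)
    return(out)
  }
  key <- if (direction == "most") -fs$weighted_meth else fs$weighted_meth
  ord <- order(key, fs$family, method = "radix")
  fs <- fs[ord, , drop = FALSE][seq_len(min(N, nrow(fs))), , drop = FALSE]
  out <- data.frame(rank = seq_len(nrow(fs)), family = fs$family,
                    class = fs$class, metric = fs$weighted_meth,
                    n_cpg = fs$n_cpg, stringsAsFactors = FALSE)
  class(out) <- c("ranking_table", "data.frame")
  attr(out, "metric_name") <- paste0("weighted_meth_", direction)
  out
}

#' Count ranking-table members per repeat class
#' @param ranking A `ranking_table`.
#' @return Named integer vector over `LINE-1`, `IAP`, `B1-B4`, `other`.
#' @export
ranking_class_counts <- function(ranking) {
  classes <- c("LINE-1", "IAP", "B1-B4", "other")
  vapply(classes, function(cl) sum(ranking$class == cl), integer(1))
}

#' Per-locus methylation distribution of one repeat family
#'
#' One read-weighted methylation fraction per annotated locus of the family
#' (not per CpG). Loci with no covered CpG are excluded and counted.
#'
#' @param asg A [assign_cpgs()] result.
#' @param family Family name (must be present in the annotation).
#' @return List of class `locus_distribution`: `family`, `fractions` (named
#'   by `chrom:start-end`), `quartiles` (0/25/50/75/100%), `n_loci_covered`,
#'   `n_loci_uncovered`.
#' @export
locus_distributions <- function(asg, family) {
  ann <- asg$annotation
  loci <- which(ann$family == family)
  if (!length(loci)) stop("family not present in annotation: ", family)
  h <- asg$hits[asg$hits$locus_idx %in% loci, , drop = FALSE]
  meth <- asg$calls$meth[h$call_idx]
  tot <- meth + asg$calls$unmeth[h$call_idx]
  by_locus <- split(seq_len(nrow(h)), h$locus_idx)
  fr <- vapply(by_locus, function(i) sum(meth[i]) / sum(tot[i]), numeric(1))
  covered <- as.integer(names(by_locus))
  names(fr) <- sprintf("%s:%d-%d", ann$chrom[covered], ann$start[covered], ann$end[covered])
  structure(list(family = family, fractions = fr,
                 quartiles = quantile(fr, c(0, 0.25, 0.5, 0.75, 1)),
                 n_loci_covered = length(fr),
                 n_loci_uncovered = length(loci) - length(fr)),
            class = "locus_distribution")
}

#' @export
print.locus_distribution <- function(x, ...) {
  cat(sprintf("locus_distribution: %s, %d covered loci (%d uncovered)\n",
              x$family, x$n_loci_covered, x$n_loci_uncovered))
  print(round(x$quartiles, 4))
  invisible(x)
}

#' Read-weighted methylation in tiling genomic windows
#'
#' Tiles each chromosome in fixed windows from position 0 to the last covered
#' CpG and reports pooled-read methylation per window; windows with fewer
#' than `min_calls` covered CpGs are reported as `NA`.
#'
#' @param calls Methylation calls (`chrom`, `pos`, `meth`, `unmeth`).
#' @param window Window size in bp (> 0).
#' @param min_calls Minimum covered CpGs per window (default 1).
#' @return `data.frame`: `chrom`, `start`, `end`, `n_calls`, `weighted_meth`.
#' @export
windowed_methylation <- function(calls, window, min_calls = 1) {
  stopifnot(window > 0)
  out <- do.call(rbind, lapply(split(calls, calls$chrom), function(cc) {
    win <- cc$pos %/% window
    n_win <- max(win) + 1
    n_calls <- tabulate(win + 1, n_win)
    meth <- unmeth <- numeric(n_win)
    agg_m <- tapply(cc$meth, win, sum)
    agg_u <- tapply(cc$unmeth, win, sum)
    meth[as.integer(names(agg_m)) + 1] <- agg_m
    unmeth[as.integer(names(agg_u)) + 1] <- agg_u
    wm <- ifelse(n_calls >= min_calls & (meth + unmeth) > 0,
                 meth / (meth + unmeth), NA_real_)
    data.frame(chrom = cc$chrom[1], start = (seq_len(n_win) - 1) * window,
               end = seq_len(n_win) * window, n_calls = n_calls,
               weighted_meth = wm, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write a ranking table as TSV
#' @param ranking A `ranking_table`.
#' @param path Output path.
#' @param seed Optional seed recorded in the header.
#' @return Invisibly, the path.
#' @export
write_ranking <- function(ranking, path, seed = NULL) {
  write_tsv(as.data.frame(ranking), path, seed = seed)
  invisible(path)
}
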