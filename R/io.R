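#' Construct a validated gene-by-sample count container
#'
#' The central expression container: an integer gene-by-sample matrix plus
#' per-sample metadata (generation, sex, dose). All downstream stages
#' (normalization, differential expression, enrichment) consume this class.
#'
#' @param counts Integer matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames). Entries must be finite, non-negative whole
#'   numbers.
#' @param metadata `data.frame` with columns `sample_id`, `generation`
#'   (one of `"F1"`, `"F2"`, `"F3"`), `sex` (`"M"` or `"F"`) and `dose`
#'   (one of `"0"`, `"0.033"`, `"0.2"`, `"2"`, mg/kg-day; stored as exact
#'   decimal strings to avoid floating-point key mismatches). Must cover
#'   every sample id exactly once.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `metadata` (metadata reordered to match the column order).
#' @export
count_matrix <- function(counts, metadata) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicated gene ids: ", paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicated sample ids: ", paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts) || any(!is.finite(counts)))
    stop("counts must be finite numbers")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at gene '%s', sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at gene '%s', sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  storage.mode(counts) <- "double"  # integer overflow safety for large libraries

  req <- c("sample_id", "generation", "sex", "dose")
  if (!is.data.frame(metadata) || !all(req %in% names(metadata)))
    stop("metadata must be a data.frame with columns: ", paste(req, collapse = ", "))
  metadata$sample_id <- as.character(metadata$sample_id)
  metadata$generation <- as.character(metadata$generation)
  metadata$sex <- as.character(metadata$sex)
  metadata$dose <- canonical_dose(metadata$dose)
  if (anyDuplicated(metadata$sample_id))
    stop("duplicated sample ids in metadata")
  if (!setequal(metadata$sample_id, colnames(counts)))
    stop("metadata sample ids do not match count matrix columns; missing: ",
         paste(setdiff(colnames(counts), metadata$sample_id), collapse = ", "),
         "; extra: ", paste(setdiff(metadata$sample_id, colnames(counts)), collapse = ", "))
  if (!all(metadata$generation %in% c("F1", "F2", "F3")))
    stop("generation must be one of F1, F2, F3")
  if (!all(metadata$sex %in% c("M", "F")))
    stop("sex must be 'M' or 'F'")
  metadata <- metadata[match(colnames(counts), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(counts = counts, metadata = metadata), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n", nrow(x$counts), ncol(x$counts)))
  tab <- table(sex = x$metadata$sex, dose = x$metadata$dose)
  print(tab)
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by gene and/or sample
#' @param x A `count_matrix`.
#' @param genes,samples Character vectors (or logical/integer indices) of
#'   genes / samples to keep; `NULL` keeps all.
#' @return A `count_matrix` restricted to the selection.
#' @export
subset_counts <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  cts <- x$counts
  if (!is.null(genes)) cts <- cts[genes, , drop = FALSE]
  if (!is.null(samples)) cts <- cts[, samples, drop = FALSE]
  md <- x$metadata[match(colnames(cts), x$metadata$sample_id), , drop = FALSE]
  count_matrix(cts, md)
}

# Canonical dose coding: exact decimal strings, validated against the study's
# dose groups. Numeric input is matched by value.
canonical_dose <- function(dose) {
  levels <- c("0", "0.033", "0.2", "2")
  d <- as.character(dose)
  d[d %in% c("0.0", "0.00")] <- "0"
  d[d %in% c("2.0", "2.00")] <- "2"
  if (!all(d %in% levels))
    stop("dose must be one of ", paste(levels, collapse = ", "), " (mg/kg-day); got: ",
         paste(unique(d[!d %in% levels]), collapse = ", "))
  d
}

#' Numeric value of a canonical dose string
#' @param dose Character vector of canonical dose strings.
#' @return Numeric vector in mg/kg-day.
#' @export
dose_value <- function(dose) as.numeric(canonical_dose(dose))

# ---- TSV plumbing -----------------------------------------------------------

# All writers emit one comment header line recording the package version and,
# when supplied, the seed that produced the data; readers skip '#' comments.
write_tsv <- function(df, path, seed = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  seed_str <- if (is.null(seed)) "NA" else format(seed)
  writeLines(sprintf("# pgcmasc %s seed=%s", as.character(packageVersion("pgcmasc")), seed_str), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE,
             colClasses = NA, ...)
}

#' Write a count matrix and its metadata as TSV
#'
#' @param x A `count_matrix`.
#' @param counts_path,metadata_path Output file paths.
#' @param seed Optional seed recorded in the header comment.
#' @return Invisibly, the two paths.
#' @export
write_counts <- function(x, counts_path, metadata_path, seed = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, counts_path, seed = seed)
  write_tsv(x$metadata, metadata_path, seed = seed)
  invisible(c(counts_path, metadata_path))
}

#' Read a count matrix (genes x samples TSV) with sample metadata
#'
#' Strictly validated: entries must be non-negative integers, gene and sample
#' ids unique, and the metadata must cover every sample exactly once.
#'
#' @param counts_path TSV with a `gene_id` column then one column per sample.
#' @param metadata_path TSV with columns `sample_id`, `generation`, `sex`, `dose`.
#' @return A validated `count_matrix`.
#' @export
read_counts <- function(counts_path, metadata_path) {
  df <- read_tsv(counts_path)
  if (names(df)[1] != "gene_id") stop("first column of counts TSV must be 'gene_id'")
  genes <- as.character(df$gene_id)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2, as.numeric))), arr.ind = TRUE)
    stop(sprintf("non-numeric count near row %s", paste(utils::head(bad, 3), collapse = ",")))
  }
  rownames(m) <- genes
  md <- read_tsv(metadata_path)
  md$dose <- as.character(md$dose)
  count_matrix(m, md)
}

# ---- Bismark coverage -------------------------------------------------------

#' Read CpG methylation calls from a Bismark coverage file
#'
#' Bismark coverage format is 1-based inclusive:
#' `chrom  start  end  methylation_percent  count_methylated  count_unmethylated`.
#' Positions are converted to the package-internal 0-based convention. The
#' percentage column is recomputed from the counts and must agree within 0.5
#' percentage points; records with zero total reads are dropped with a warning.
#'
#' @param path Path to a (plain-text) Bismark coverage file.
#' @return `data.frame` with columns `chrom`, `pos` (0-based), `meth`, `unmeth`.
#' @export
read_meth_coverage <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      meth = integer(), unmeth = integer()))
  parts <- strsplit(lines, "[ \t]+")
  nf <- lengths(parts)
  if (any(nf != 6))
    stop(sprintf("malformed Bismark coverage line %d: expected 6 fields, got %d",
                 which(nf != 6)[1], nf[which(nf != 6)[1]]))
  m <- do.call(rbind, parts)
  start1 <- suppressWarnings(as.numeric(m[, 2]))
  pct <- suppressWarnings(as.numeric(m[, 4]))
  meth <- suppressWarnings(as.numeric(m[, 5]))
  unmeth <- suppressWarnings(as.numeric(m[, 6]))
  bad <- which(is.na(start1) | is.na(pct) | is.na(meth) | is.na(unmeth))
  if (length(bad))
    stop(sprintf("malformed Bismark coverage line %d: non-numeric field", bad[1]))
  if (any(start1 < 1))
    stop(sprintf("malformed Bismark coverage line %d: position < 1", which(start1 < 1)[1]))
  total <- meth + unmeth
  zero <- total == 0
  if (any(zero)) {
    warning(sprintf("dropped %d coverage record(s) with zero reads", sum(zero)))
  }
  recomputed <- ifelse(total > 0, 100 * meth / total, NA_real_)
  off <- which(!zero & abs(recomputed - pct) > 0.5)
  if (length(off))
    stop(sprintf(
      "inconsistent methylation percentage at line %d: stated %.3f, counts give %.3f",
      off[1], pct[off[1]], recomputed[off[1]]))
  out <- data.frame(chrom = m[!zero, 1], pos = as.integer(start1[!zero] - 1L),
                    meth = as.integer(meth[!zero]), unmeth = as.integer(unmeth[!zero]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write CpG methylation calls in Bismark coverage format
#' @param calls `data.frame` with `chrom`, `pos` (0-based), `meth`, `unmeth`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_meth_coverage <- function(calls, path) {
  total <- calls$meth + calls$unmeth
  stopifnot(all(total >= 1))
  pct <- 100 * calls$meth / total
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d",
                   calls$chrom, calls$pos + 1L, calls$pos + 1L,
                   format(pct, trim = TRUE, digits = 15),
                   calls$meth, calls$unmeth)
  writeLines(lines, path)
  invisible(path)
}

# ---- Repeat annotation ------------------------------------------------------

# Default grouping of RepeatMasker repeat names into the classes used by the
# ranking figures. Anything unmatched maps to "other".
default_class_map <- function() {
  c("IAP" = "IAP", "L1" = "LINE-1", "Lx" = "LINE-1",
    "B1" = "B1-B4", "B2" = "B1-B4", "B3" = "B1-B4", "B4" = "B1-B4")
}

classify_repeat_family <- function(family, class_map = default_class_map()) {
  cls <- rep("other", length(family))
  for (prefix in names(class_map)) {
    hit <- startsWith(family, prefix)
    cls[hit] <- class_map[[prefix]]
  }
  cls
}

#' Read a BED6-like repeat annotation
#'
#' Columns: chrom, start, end (0-based half-open), family name, class, strand.
#' When the class column is missing or empty, class is derived from the family
#' name via a configurable prefix map (IAP / LINE-1 / B1-B4 groups; anything
#' unmatched becomes "other"). Strand is retained but ignored downstream
#' (methylation calls are destranded).
#'
#' @param path Path to the TSV/BED file.
#' @param class_map Named character vector mapping family-name prefixes to
#'   classes.
#' @return `data.frame` with `chrom`, `start`, `end`, `family`, `class`,
#'   `strand`.
#' @export
read_repeat_annotation <- function(path, class_map = default_class_map()) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "[ \t]+")
  nf <- lengths(parts)
  if (any(nf < 4))
    stop(sprintf("malformed repeat annotation line %d: fewer than 4 fields", which(nf < 4)[1]))
  get_col <- function(i) vapply(parts, function(p) if (length(p) >= i) p[i] else NA_character_, "")
  start <- suppressWarnings(as.numeric(get_col(2)))
  end <- suppressWarnings(as.numeric(get_col(3)))
  if (any(is.na(start) | is.na(end)))
    stop("non-numeric start/end in repeat annotation")
  if (any(start < 0))
    stop(sprintf("negative start at annotation line %d", which(start < 0)[1]))
  if (any(start >= end))
    stop(sprintf("start >= end at annotation line %d", which(start >= end)[1]))
  family <- get_col(4)
  cls <- get_col(5)
  missing_cls <- is.na(cls) | cls == "" | cls == "."
  cls[missing_cls] <- classify_repeat_family(family[missing_cls], class_map)
  known <- c("LINE-1", "IAP", "B1-B4", "other")
  cls[!cls %in% known] <- "other"
  strand <- get_col(6)
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "*"
  data.frame(chrom = get_col(1), start = as.integer(start), end = as.integer(end),
             family = family, class = cls, strand = strand, stringsAsFactors = FALSE)
}

#' Write a repeat annotation as BED6-like TSV
#' @param annot `data.frame` as returned by [read_repeat_annotation()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_repeat_annotation <- function(annot, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   annot$chrom, annot$start, annot$end,
                   annot$family, annot$class, annot$strand)
  writeLines(lines, path)
  invisible(path)
}
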