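# Shared fixtures: everything is generated in code at test time.

# A small, fast simulation profile used across tests.
small_sim_config <- function(seed = 1, ...) {
  args <- list(n_genes = 2000, n_male_specific = 100, n_female_specific = 100,
               universe_target = 1200, n_per_cell = 5, seed = seed)
  args[names(list(...))] <- list(...)
  args$universe_target <- min(args$universe_target, round(0.6 * args$n_genes))
  sets <- args$n_male_specific + args$n_female_specific
  if (sets > args$n_genes) {
    args$n_male_specific <- round(args$n_genes * args$n_male_specific / sets / 2)
    args$n_female_specific <- round(args$n_genes * args$n_female_specific / sets / 2)
  }
  do.call(sim_config, args)
}

# A null profile: no sex dimorphism, no exposure effect, vehicle only.
null_sim_config <- function(seed = 1, ...) {
  small_sim_config(seed = seed, n_male_specific = 0, n_female_specific = 0,
                   sex_log2fc = 0, masc_effect = 0, doses = "0", ...)
}

# Deterministic toy count_matrix with hand-set metadata.
toy_count_matrix <- function(counts, sex = NULL, dose = NULL, generation = NULL) {
  n <- ncol(counts)
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("s%02d", seq_len(n))
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  md <- data.frame(sample_id = colnames(counts),
                   generation = generation %||% rep("F1", n),
                   sex = sex %||% rep(c("M", "F"), length.out = n),
                   dose = dose %||% rep("0", n))
  count_matrix(counts, md)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force TMM oracle: recomputed from the definitions with
# order()-based index selection (a different code path from the implementation).
brute_tmm <- function(obs, ref, trim_m = 0.30, trim_a = 0.05) {
  No <- sum(obs); Nr <- sum(ref)
  keep <- obs > 0 & ref > 0
  o <- obs[keep]; r <- ref[keep]
  M <- log2((o / No) / (r / Nr))
  A <- 0.5 * log2((o / No) * (r / Nr))
  w <- 1 / ((No - o) / (No * o) + (Nr - r) / (Nr * r))
  n <- length(M)
  sel <- function(x, trim) {
    lo <- floor(n * trim) + 1; hi <- n - floor(n * trim)
    keep <- logical(n)
    keep[order(x)[lo:hi]] <- TRUE
    keep
  }
  k <- sel(M, trim_m) & sel(A, trim_a)
  2^(sum(w[k] * M[k]) / sum(w[k]))
}

# Quadratic all-pairs overlap oracle for CpG -> repeat assignment.
brute_overlaps <- function(calls, annotation) {
  hits <- list()
  for (i in seq_len(nrow(calls))) {
    for (j in seq_len(nrow(annotation))) {
      if (calls$chrom[i] == annotation$chrom[j] &&
          calls$pos[i] >= annotation$start[j] &&
          calls$pos[i] < annotation$end[j]) {
        hits[[length(hits) + 1]] <- c(i, j)
      }
    }
  }
  if (!length(hits)) return(data.frame(call_idx = integer(), locus_idx = integer()))
  m <- do.call(rbind, hits)
  data.frame(call_idx = m[, 1], locus_idx = m[, 2])
}
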