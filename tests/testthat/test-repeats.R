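toy_assignment <- function() {
  ann <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                    start = c(0L, 100L, 120L, 0L), end = c(100L, 200L, 140L, 80L),
                    family = c("IAPEz", "B3", "B3", "L1Md"),
                    class = c("IAP", "B1-B4", "B1-B4", "LINE-1"),
                    strand = "+")
  calls <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2", "chr3"),
                      pos = c(0L, 100L, 125L, 10L, 5L),
                      meth = c(8L, 5L, 2L, 10L, 1L),
                      unmeth = c(2L, 5L, 8L, 0L, 9L))
  list(calls = calls, ann = ann)
}

test_that("CpG assignment respects the half-open convention and multi-overlap", {
  tc <- toy_assignment()
  asg <- assign_cpgs(tc$calls, tc$ann)
  h <- asg$hits
  # pos 0 == start -> assigned; pos 100 == end of [0,100) -> not assigned there
  expect_true(any(h$call_idx == 1 & h$locus_idx == 1))
  expect_false(any(h$call_idx == 2 & h$locus_idx == 1))
  expect_true(any(h$call_idx == 2 & h$locus_idx == 2))  # but == start of [100,200)
  # pos 125 is inside both nested B3 loci -> assigned to both
  expect_equal(sort(h$locus_idx[h$call_idx == 3]), c(2, 3))
  # chromosome missing from the annotation -> non-repeat, no error
  expect_true(5 %in% asg$non_repeat_idx)
  expect_error(assign_cpgs(tc$calls, transform(tc$ann, end = start)), "start >= end")
})

test_that("interval-index assignment equals the quadratic all-pairs scan", {
  set.seed(131)
  n_ann <- 100
  ann <- data.frame(chrom = sample(c("chr1", "chr2"), n_ann, TRUE),
                    start = sample.int(20000, n_ann) - 1L)
  ann$end <- ann$start + sample.int(500, n_ann)
  ann$family <- sample(c("IAPEz", "B3", "L1Md", "MTA"), n_ann, TRUE)
  ann$class <- "other"; ann$strand <- "+"
  calls <- data.frame(chrom = sample(c("chr1", "chr2", "chr3"), 1000, TRUE),
                      pos = sample.int(21000, 1000) - 1L,
                      meth = rpois(1000, 5), unmeth = rpois(1000, 5))
  calls <- calls[calls$meth + calls$unmeth > 0, ]
  asg <- assign_cpgs(calls, ann)
  brute <- brute_overlaps(calls, ann)
  key <- function(d) sort(paste(d$call_idx, d$locus_idx))
  expect_identical(key(asg$hits), key(brute))
})

test_that("coverage ranking counts covered CpGs with deterministic ties", {
  tc <- toy_assignment()
  asg <- assign_cpgs(tc$calls, tc$ann)
  rk <- coverage_ranking(asg, N = 35)
  # recount oracle: per family, distinct covered calls (a call inside two B3
  # loci counts once for B3)
  expect_equal(rk$metric[rk$family == "IAPEz"], 1L)
  expect_equal(rk$metric[rk$family == "B3"], 2L)
  expect_equal(rk$metric[rk$family == "L1Md"], 1L)
  # equal counts -> lexicographic family order among the tied pair
  expect_equal(rk$family, c("B3", "IAPEz", "L1Md"))
  expect_equal(rk$rank, 1:3)
})

test_that("methylation ranking pools reads, filters by coverage and orders correctly", {
  tc <- toy_assignment()
  asg <- assign_cpgs(tc$calls, tc$ann)
  rk <- methylation_ranking(asg, N = 35, min_cpg = 1)
  expect_equal(rk$metric[rk$family == "IAPEz"], 0.8)  # one CpG, 8/10 reads
  expect_equal(rk$metric[rk$family == "L1Md"], 1.0)
  expect_equal(rk$metric[rk$family == "B3"], 7 / 20)  # pooled over two calls
  expect_equal(rk$family[1], "L1Md")
  rk_least <- methylation_ranking(asg, N = 35, min_cpg = 1, direction = "least")
  expect_equal(rk_least$family[1], "B3")
  expect_warning(empty <- methylation_ranking(asg, min_cpg = 50), "coverage floor")
  expect_equal(nrow(empty), 0)
})

test_that("synthetic families rank as constructed and class counts match a recount", {
  sim <- simulate_repeat_meth(meth_sim_config(seed = 17))
  asg <- assign_cpgs(sim$calls, sim$annotation)
  rk <- methylation_ranking(asg, N = 35, min_cpg = 50)
  expect_equal(rk$family[1], "IAPEz_like")
  pos <- match(c("IAPEz_like", "L1Md_like", "B1_like"), rk$family)
  expect_true(!is.unsorted(pos))
  counts <- ranking_class_counts(rk)
  expect_equal(unname(counts), c(sum(rk$class == "LINE-1"), sum(rk$class == "IAP"),
                                 sum(rk$class == "B1-B4"), sum(rk$class == "other")))
  expect_equal(sum(counts), nrow(rk))

  # coverage ranking equals an independent per-family recount
  cov <- coverage_ranking(asg, N = 35)
  recount <- vapply(cov$family, function(fam) {
    loci <- which(sim$annotation$family == fam)
    length(unique(asg$hits$call_idx[asg$hits$locus_idx %in% loci]))
  }, integer(1))
  expect_equal(cov$metric, unname(recount))
})

test_that("per-locus distributions aggregate reads per locus", {
  ann <- data.frame(chrom = "chr1", start = c(0L, 100L), end = c(50L, 150L),
                    family = "B3", class = "B1-B4", strand = "+")
  calls <- data.frame(chrom = "chr1", pos = c(10L, 20L, 110L),
                      meth = c(10L, 2L, 0L), unmeth = c(0L, 2L, 6L))
  asg <- assign_cpgs(calls, ann)
  ld <- locus_distributions(asg, "B3")
  expect_equal(unname(ld$fractions), c(12 / 14, 0))
  expect_equal(ld$n_loci_covered, 2)

  # single-locus family, one fully methylated CpG -> fraction 1.0
  ann1 <- ann[1, ]; calls1 <- data.frame(chrom = "chr1", pos = 5L, meth = 10L, unmeth = 0L)
  ld1 <- locus_distributions(assign_cpgs(calls1, ann1), "B3")
  expect_equal(unname(ld1$fractions), 1.0)
  expect_error(locus_distributions(asg, "nope"), "not present")

  # uncovered loci are excluded but counted
  ann2 <- rbind(ann, data.frame(chrom = "chr1", start = 500L, end = 600L,
                                family = "B3", class = "B1-B4", strand = "+"))
  ld2 <- locus_distributions(assign_cpgs(calls, ann2), "B3")
  expect_equal(ld2$n_loci_uncovered, 1)
})

test_that("locus fractions match brute-force per-locus aggregation on synthetic data", {
  sim <- simulate_repeat_meth(meth_sim_config(seed = 19))
  asg <- assign_cpgs(sim$calls, sim$annotation)
  ld <- locus_distributions(asg, "B2_like")
  loci <- which(sim$annotation$family == "B2_like")
  brute <- vapply(loci, function(i) {
    inside <- sim$calls$pos >= sim$annotation$start[i] & sim$calls$pos < sim$annotation$end[i]
    if (!any(inside)) return(NA_real_)
    sum(sim$calls$meth[inside]) / sum(sim$calls$meth[inside] + sim$calls$unmeth[inside])
  }, numeric(1))
  expect_equal(sort(unname(ld$fractions)), sort(brute[!is.na(brute)]))
})

test_that("read totals are conserved across family groups", {
  sim <- simulate_repeat_meth(meth_sim_config(seed = 23))
  asg <- assign_cpgs(sim$calls, sim$annotation)
  h <- unique(asg$hits[, c("call_idx", "family")])
  fam_reads <- sum(sim$calls$meth[h$call_idx] + sim$calls$unmeth[h$call_idx])
  nr <- asg$non_repeat_idx
  nr_reads <- sum(sim$calls$meth[nr] + sim$calls$unmeth[nr])
  total <- sum(sim$calls$meth + sim$calls$unmeth)
  expect_gte(fam_reads + nr_reads, total)
  # loci are disjoint within and across families by construction -> equality
  expect_equal(fam_reads + nr_reads, total)
})

test_that("pooled family methylation is the read-weighted mean of locus values", {
  sim <- simulate_repeat_meth(meth_sim_config(seed = 29))
  asg <- assign_cpgs(sim$calls, sim$annotation)
  rk <- methylation_ranking(asg, N = 35, min_cpg = 1)
  fam <- "L1Md_like"
  loci <- which(sim$annotation$family == fam)
  h <- asg$hits[asg$hits$locus_idx %in% loci, ]
  reads <- sim$calls$meth[h$call_idx] + sim$calls$unmeth[h$call_idx]
  meth <- sim$calls$meth[h$call_idx]
  by_locus <- split(seq_len(nrow(h)), h$locus_idx)
  locus_fr <- vapply(by_locus, function(i) sum(meth[i]) / sum(reads[i]), numeric(1))
  locus_rd <- vapply(by_locus, function(i) sum(reads[i]), numeric(1))
  expect_equal(rk$metric[rk$family == fam],
               sum(locus_fr * locus_rd) / sum(locus_rd), tolerance = 1e-12)
})

test_that("windowed methylation tiles correctly and matches a recomputation", {
  calls <- data.frame(chrom = "chr1", pos = c(5L, 8L, 25L, 250L),
                      meth = c(5L, 0L, 3L, 4L), unmeth = c(0L, 5L, 1L, 0L))
  w <- windowed_methylation(calls, window = 10)
  expect_equal(w$weighted_meth[1], 5 / 10)      # window [0,10): 5/10 reads
  expect_equal(w$weighted_meth[3], 3 / 4)       # window [20,30)
  expect_true(is.na(w$weighted_meth[2]))        # empty window [10,20)
  expect_equal(w$weighted_meth[nrow(w)], 1.0)   # single fully methylated CpG

  sim <- simulate_repeat_meth(meth_sim_config(seed = 37))
  wv <- windowed_methylation(sim$calls, window = 1000)
  i <- which(wv$n_calls > 0)[10]
  inside <- sim$calls$pos >= wv$start[i] & sim$calls$pos < wv$end[i]
  expect_equal(wv$weighted_meth[i],
               sum(sim$calls$meth[inside]) /
                 sum(sim$calls$meth[inside] + sim$calls$unmeth[inside]))
})
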