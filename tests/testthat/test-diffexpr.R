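unit_factors <- function(m) {
  data.frame(sample_id = colnames(m), lib_size = colSums(m),
             factor = 1, eff_lib_size = colSums(m))
}

test_that("dispersion estimation: floor, Poisson limit and recovery", {
  # Poisson data (variance = mean), 20 samples: common dispersion near zero
  set.seed(31)
  y <- matrix(rpois(500 * 20, lambda = rlnorm(500, 4, 1)), 500, 20,
              dimnames = list(sprintf("g%03d", 1:500), sprintf("s%02d", 1:20)))
  grp <- factor(rep(c("a", "b"), each = 10))
  d <- estimate_dispersions(y, unit_factors(y), grp)
  expect_lt(d$phi_common, 0.05)

  # a gene whose sample variance is below its mean gets raw dispersion 0
  ylow <- rbind(y, low = rep(c(10L, 11L), 10))
  dl <- estimate_dispersions(ylow, unit_factors(ylow), grp)
  expect_equal(unname(dl$phi_raw["low"]), 0)

  # NB with phi = 0.4, 50 samples per gene: median recovered in [0.3, 0.5]
  set.seed(32)
  y2 <- matrix(rnbinom(400 * 50, mu = 200, size = 1 / 0.4), 400, 50,
               dimnames = list(sprintf("g%03d", 1:400), sprintf("s%02d", 1:50)))
  grp2 <- factor(rep(c("a", "b"), each = 25))
  d2 <- estimate_dispersions(y2, unit_factors(y2), grp2)
  expect_gt(median(d2$phi), 0.3)
  expect_lt(median(d2$phi), 0.5)

  expect_error(estimate_dispersions(y[, 1:2], unit_factors(y[, 1:2]),
                                    factor(c("a", "b"))),
               ">= 2 samples")
})

test_that("NB GLM LRT is null on identical groups and matches the Poisson limit", {
  set.seed(41)
  y <- matrix(rpois(50 * 5, 30), 50, 5)
  y <- cbind(y, y)  # two groups with identical counts -> identical fitted means
  dimnames(y) <- list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:10))
  grp <- factor(rep(c("a", "b"), each = 5))
  tab <- nb_glm_lrt(y, unit_factors(y), grp, phi = rep(0.1, 50))
  expect_lt(max(tab$LRT), 1e-6)
  expect_gt(min(tab$p), 1 - 1e-6)
  expect_equal(tab$log2FC, rep(0, 50), tolerance = 1e-8)

  # phi -> 0 limit equals the Poisson GLM likelihood-ratio statistic
  set.seed(42)
  y2 <- matrix(rpois(40 * 10, lambda = rep(c(20, 35), each = 5 * 40)), 40, 10,
               dimnames = list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:10)))
  fac <- unit_factors(y2)
  tab2 <- nb_glm_lrt(y2, fac, grp, phi = rep(1e-8, 40))
  lrt_pois <- vapply(seq_len(nrow(y2)), function(i) {
    d <- data.frame(y = y2[i, ], g = grp, o = log(fac$eff_lib_size))
    m1 <- stats::glm(y ~ g + offset(o), family = stats::poisson, data = d)
    m0 <- stats::glm(y ~ 1 + offset(o), family = stats::poisson, data = d)
    m0$deviance - m1$deviance
  }, numeric(1))
  expect_equal(tab2$LRT, lrt_pois, tolerance = 1e-4)
})

test_that("NB GLM LRT matches an independent fixed-dispersion GLM fit", {
  skip_if_not_installed("MASS")
  phi0 <- 0.25
  set.seed(43)
  y <- matrix(rnbinom(30 * 12, mu = rep(c(50, 80), each = 6 * 30), size = 1 / phi0),
              30, 12, dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:12)))
  grp <- factor(rep(c("a", "b"), each = 6))
  fac <- unit_factors(y)
  tab <- nb_glm_lrt(y, fac, grp, phi = rep(phi0, 30))
  lrt_ref <- vapply(seq_len(nrow(y)), function(i) {
    d <- data.frame(y = y[i, ], g = grp, o = log(fac$eff_lib_size))
    fam <- MASS::negative.binomial(theta = 1 / phi0)
    m1 <- stats::glm(y ~ g + offset(o), family = fam, data = d)
    m0 <- stats::glm(y ~ 1 + offset(o), family = fam, data = d)
    as.numeric(2 * (stats::logLik(m1) - stats::logLik(m0)))
  }, numeric(1))
  expect_equal(tab$LRT, lrt_ref, tolerance = 1e-6)

  # log2FC from the coefficients matches the independent fit too
  lfc_ref <- vapply(seq_len(nrow(y)), function(i) {
    d <- data.frame(y = y[i, ], g = grp, o = log(fac$eff_lib_size))
    stats::coef(stats::glm(y ~ g + offset(o),
                           family = MASS::negative.binomial(theta = 1 / phi0),
                           data = d))[["gb"]] / log(2)
  }, numeric(1))
  expect_equal(tab$log2FC, lfc_ref, tolerance = 1e-6)

  expect_error(nb_glm_lrt(y, fac, grp, phi = rep(phi0, 30),
                          reduced = factor(rep(c("x", "y"), 6))),
               "fewer levels")
})

test_that("Benjamini-Hochberg adjustment matches the direct step-up formula", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_identical(bh_fdr(numeric(0)), numeric(0))

  set.seed(51)
  p <- runif(200)^2
  direct <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- rev(cummin(rev(p[o] * m / seq_len(m))))
    out <- numeric(m); out[o] <- pmin(adj, 1); out
  }
  expect_equal(bh_fdr(p), direct(p))
  expect_true(all(bh_fdr(p) >= p))
  perm <- sample.int(200)
  expect_equal(bh_fdr(p[perm]), bh_fdr(p)[perm])
})

test_that("sex-specific calling applies both criteria and is label-symmetric", {
  sim <- simulate_pgc_counts(small_sim_config(seed = 61, doses = "0"))
  sets <- call_sex_specific(sim$counts)
  tab <- sets$table
  expect_setequal(sets$male_specific, tab$gene[tab$fdr < 0.05 & tab$log2FC > 1])
  expect_setequal(sets$female_specific, tab$gene[tab$fdr < 0.05 & tab$log2FC < -1])
  expect_length(intersect(sets$male_specific, sets$female_specific), 0)
  # a significant gene below two-fold is in neither set
  near <- tab$gene[tab$fdr < 0.05 & abs(tab$log2FC) <= 1]
  expect_false(any(near %in% c(sets$male_specific, sets$female_specific)))

  # swapping sex labels exchanges the sets exactly
  swapped <- sim$counts
  swapped$metadata$sex <- ifelse(swapped$metadata$sex == "M", "F", "M")
  sets2 <- call_sex_specific(swapped)
  expect_identical(sets2$male_specific, sets$female_specific)
  expect_identical(sets2$female_specific, sets$male_specific)

  only_m <- subset_counts(sim$counts, samples = sim$counts$metadata$sex == "M")
  expect_error(call_sex_specific(only_m), "both sexes")
})

test_that("sex-specific calling recovers truth at moderate effect size", {
  # 20-replicate average: sensitivity >= 0.8, false-discovery proportion <= 0.1
  res <- vapply(1:20, function(r) {
    sim <- simulate_pgc_counts(small_sim_config(
      seed = 700 + r, n_genes = 1200, n_male_specific = 60, n_female_specific = 60,
      sex_log2fc = 1.5, doses = "0", universe_target = 800))
    sets <- call_sex_specific(sim$counts)
    called <- c(sets$male_specific, sets$female_specific)
    truth <- c(sim$truth$male_specific_genes, sim$truth$female_specific_genes)
    c(sens = mean(truth %in% called),
      fdp = if (length(called)) mean(!called %in% truth) else 0)
  }, numeric(2))
  expect_gte(mean(res["sens", ]), 0.8)
  expect_lte(mean(res["fdp", ]), 0.1)
})

test_that("exposure ranking is ordered, deterministic and tie-broken lexicographically", {
  sim <- simulate_pgc_counts(small_sim_config(seed = 71, n_genes = 600))
  rk <- rank_exposure_degs(sim$counts, sex = "F", doses = "2")
  expect_equal(rk$rank, seq_len(nrow(rk)))
  expect_true(!is.unsorted(rk$p))
  expect_equal(rk$gene[1], rk$gene[which.min(rk$p)][1])

  # permuting input gene order leaves the ranking unchanged
  perm <- sample(nrow(sim$counts$counts))
  shuffled <- count_matrix(sim$counts$counts[perm, ], sim$counts$metadata)
  rk2 <- rank_exposure_degs(shuffled, sex = "F", doses = "2")
  expect_identical(rk2$gene, rk$gene)

  # duplicated gene rows force exact ties -> lexicographic order
  cts <- sim$counts$counts[1:50, ]
  dup <- rbind(cts, cts)
  rownames(dup) <- c(sprintf("zz%03d", 1:50), sprintf("aa%03d", 1:50))
  md <- sim$counts$metadata
  rk3 <- rank_exposure_degs(count_matrix(dup, md), sex = "F", doses = "2")
  pairs <- split(rk3$rank, rep(1:50, 2)[match(rk3$gene, rownames(dup))])
  for (pr in pairs) expect_equal(diff(sort(pr)), 1)  # twins adjacent
  twins <- rk3$gene[order(rk3$rank)]
  first_of_pair <- twins[seq(1, 99, by = 2)]
  expect_true(all(startsWith(first_of_pair, "aa")))

  expect_error(rank_exposure_degs(sim$counts, sex = "F", doses = "0"), "must not include")
  one <- subset_counts(sim$counts,
                       samples = which(sim$counts$metadata$sex == "F")[1:3])
  expect_error(rank_exposure_degs(one, sex = "F", doses = "2"), "at least 2")
})
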