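ideal_xy <- function(n_m = 10, n_f = 10, n_auto = 0, seed = 1) {
  simulate_sexlinked(n_m, n_f, n_autosomal = n_auto, n_sexlinked_snps = 3,
                     system = "XY", seed = seed)
}

test_that("method I flags the ideal fixed-XY pattern and not its ZW reading", {
  sim <- ideal_xy()
  p <- scan_params(het_freq_tol = 0.05, hom_freq_max = 0.05)
  xy <- scan_method_I(sim$genotypes, sim$meta, "XY", p)
  expect_setequal(xy$locus_id, sim$truth$loci$locus_id)
  expect_equal(unique(xy$alt_freq_het_sex), 0.5)
  expect_equal(unique(xy$alt_freq_hom_sex), 0)
  expect_equal(nrow(scan_method_I(sim$genotypes, sim$meta, "ZW", p)), 0L)
})

test_that("method I respects the frequency tolerance boundary", {
  # 9/10 males dosage 1, 1 male dosage 0, females all 0: male freq 0.45
  d <- matrix(0L, nrow = 1, ncol = 20)
  d[1, 1:9] <- 1L
  g <- geno_matrix(d)
  meta <- tibble::tibble(
    sample_id = g$samples,
    sex = c(rep("M", 10), rep("F", 10))
  )
  hit <- function(tol) nrow(scan_method_I(g, meta, "XY",
                                          scan_params(het_freq_tol = tol)))
  expect_equal(hit(0.05), 1L)
  expect_equal(hit(0.04), 0L)
})

test_that("method II thresholds heterozygote fractions on both sides", {
  sim <- ideal_xy()
  g <- sim$genotypes
  # degrade locus 1: 8/10 males heterozygous
  g$dosage[1, which(sim$meta$sex == "M")[1:2]] <- 0L
  strict <- scan_method_II(g, sim$meta, "XY", scan_params(het_het_min = 0.9))
  loose <- scan_method_II(g, sim$meta, "XY", scan_params(het_het_min = 0.75))
  expect_false(g$loci$locus_id[1] %in% strict$locus_id)
  expect_true(g$loci$locus_id[1] %in% loose$locus_id)
})

test_that("Z-polymorphism mimics XY segregation only at relaxed thresholds", {
  # full-sib ZW family, father's two Z alleles differ (Z1 != Z2), mother Z3/W.
  # Sons are Z1/Z3 or Z2/Z3, daughters Z3-hemizygous read as homozygous;
  # if Z1 carries the alternate allele half the sons are heterozygous.
  n_sons <- 12; n_daughters <- 12
  sons <- rep(c(1L, 0L), 6)   # half Z1Z3 heterozygous, half Z2Z3 homozygous
  d <- matrix(c(sons, rep(0L, n_daughters)), nrow = 1)
  g <- geno_matrix(d)
  meta <- tibble::tibble(
    sample_id = g$samples,
    sex = c(rep("M", n_sons), rep("F", n_daughters))
  )
  strict <- scan_method_II(g, meta, "XY", scan_params(het_het_min = 0.9))
  relaxed <- scan_method_II(g, meta, "XY",
                            scan_params(het_het_min = 0.4, hom_het_max = 0.1))
  expect_equal(nrow(strict), 0L)
  expect_equal(nrow(relaxed), 1L)
})

test_that("method III requires strict absence in the homogametic sex", {
  pres <- matrix(FALSE, nrow = 3, ncol = 41,
                 dimnames = list(paste0("t", 1:3), sprintf("s%02d", 1:41)))
  meta <- tibble::tibble(sample_id = colnames(pres),
                         sex = c(rep("F", 20), rep("M", 21)))
  pres[1, 1:20] <- TRUE            # 20/20 females
  pres[2, 1:19] <- TRUE            # 19/20 females
  pres[3, c(1:19, 21)] <- TRUE     # 19/20 females + 1 male
  res90 <- scan_method_III(pres, meta, "ZW", scan_params(specificity_min = 0.9))
  expect_setequal(res90$tag_id, c("t1", "t2"))
  res95 <- scan_method_III(pres, meta, "ZW", scan_params(specificity_min = 0.95))
  expect_true("t2" %in% res95$tag_id) # 19/20 = 0.95 >= 0.95
  expect_false("t3" %in% res95$tag_id)
  res50 <- scan_method_III(pres, meta, "ZW", scan_params(specificity_min = 0.5))
  expect_false("t3" %in% res50$tag_id) # one male presence disqualifies
})

test_that("scans agree with brute-force oracles on random instances", {
  n_cases <- 0
  for (rep in 1:25) {
    g <- random_geno(40, 16, miss = 0.15, seed = rep)
    meta <- random_meta(g$samples, seed = rep + 100)
    if (min(table(factor(meta$sex, c("M", "F")))) < 2) next
    for (sys in c("XY", "ZW")) {
      p <- scan_params(het_freq_tol = runif(1, 0.02, 0.3),
                       hom_freq_max = runif(1, 0, 0.3),
                       het_het_min = runif(1, 0.5, 1),
                       hom_het_max = runif(1, 0, 0.4),
                       min_informative_per_sex = 2)
      got_I <- scan_method_I(g, meta, sys, p)$locus_id
      want_I <- g$loci$locus_id[oracle_scan_I(g$dosage, meta$sex, sys,
                                              p$het_freq_tol, p$hom_freq_max, 2)]
      expect_setequal(got_I, want_I)
      got_II <- scan_method_II(g, meta, sys, p)$locus_id
      want_II <- g$loci$locus_id[oracle_scan_II(g$dosage, meta$sex, sys,
                                                p$het_het_min, p$hom_het_max, 2)]
      expect_setequal(got_II, want_II)
      pres <- g$dosage
      pres[is.na(pres)] <- 0L
      pres <- pres > 0
      got_III <- scan_method_III(pres, meta, sys, p)$tag_id
      want_III <- rownames(pres)[oracle_scan_III(pres, meta$sex, sys,
                                                 p$specificity_min)]
      expect_setequal(got_III, want_III)
      n_cases <- n_cases + 3 * nrow(g$dosage)
    }
  }
  expect_gt(n_cases, 1000)
})

test_that("relabelling the sexes swaps XY and ZW candidate sets", {
  for (rep in 1:5) {
    sim <- simulate_sexlinked(9, 11, n_autosomal = 80, n_sexlinked_snps = 4,
                              genotyping_error_rate = 0.05, seed = rep)
    swapped <- sim$meta
    swapped$sex <- c(M = "F", F = "M")[swapped$sex]
    p <- scan_params(het_freq_tol = 0.15, hom_freq_max = 0.1,
                     het_het_min = 0.75, hom_het_max = 0.1)
    expect_setequal(
      scan_method_I(sim$genotypes, sim$meta, "XY", p)$locus_id,
      scan_method_I(sim$genotypes, swapped, "ZW", p)$locus_id
    )
    expect_setequal(
      scan_method_II(sim$genotypes, sim$meta, "ZW", p)$locus_id,
      scan_method_II(sim$genotypes, swapped, "XY", p)$locus_id
    )
  }
})

test_that("candidate sets shrink as thresholds tighten", {
  sim <- simulate_sexlinked(15, 15, n_autosomal = 300, n_sexlinked_snps = 10,
                            genotyping_error_rate = 0.05, missing_rate = 0.05,
                            seed = 13)
  g <- sim$genotypes
  meta <- sim$meta
  base <- scan_params(het_freq_tol = 0.2, hom_freq_max = 0.1,
                      het_het_min = 0.7, hom_het_max = 0.2)
  ids_I <- scan_method_I(g, meta, "XY", base)$locus_id
  for (tol in c(0.1, 0.05)) {
    tighter <- scan_method_I(g, meta, "XY",
                             scan_params(het_freq_tol = tol, hom_freq_max = 0.1))$locus_id
    expect_true(all(tighter %in% ids_I))
    ids_I <- tighter
  }
  ids_II <- scan_method_II(g, meta, "XY", base)$locus_id
  for (hmin in c(0.85, 1.0)) {
    tighter <- scan_method_II(g, meta, "XY",
                              scan_params(het_het_min = hmin, hom_het_max = 0.2))$locus_id
    expect_true(all(tighter %in% ids_II))
    ids_II <- tighter
  }
})

test_that("permutation p-value follows the add-one formula and flags planted signal", {
  sim <- simulate_sexlinked(12, 12, n_autosomal = 300, n_sexlinked_snps = 10,
                            genotyping_error_rate = 0.01, seed = 6)
  pt <- permutation_test(sim$genotypes, sim$meta, "XY", "I",
                         n_permutations = 100, seed = 3)
  expect_true(pt$significant)
  expect_equal(pt$p_value,
               (1 + sum(pt$null_counts >= pt$observed_count)) / 101)
  if (all(pt$null_counts < pt$observed_count)) {
    expect_equal(pt$p_value, 1 / 101)
  }
  expect_equal(pt$optimality_score,
               mean(pt$null_counts) / max(pt$observed_count, 1))

  # pre-shuffling the labels destroys the signal
  shuffled <- sim$meta
  set.seed(99)
  shuffled$sex <- sample(shuffled$sex)
  pt0 <- permutation_test(sim$genotypes, shuffled, "XY", "I",
                          n_permutations = 100, seed = 3)
  expect_false(pt0$significant)
})

test_that("grid optimisation picks the lowest false-positive setting with documented ties", {
  sim <- simulate_sexlinked(15, 15, n_autosomal = 500, n_sexlinked_snps = 10,
                            genotyping_error_rate = 0.05, missing_rate = 0.05,
                            seed = 10)
  grid <- tibble::tibble(het_freq_tol = c(0.02, 0.2), hom_freq_max = c(0.02, 0.1))
  opt <- optimize_params(sim$genotypes, sim$meta, "XY", "I", grid = grid,
                         n_permutations = 30, seed = 1)
  expect_false(opt$none_found)
  expect_equal(opt$best_index, which.min(opt$table$optimality_score))
  # a grid point that flags nothing can never win
  grid0 <- tibble::tibble(het_freq_tol = c(0.0, 0.1), hom_freq_max = c(0.0, 0.05))
  sim0 <- simulate_sexlinked(8, 8, n_autosomal = 0, n_sexlinked_snps = 2,
                             genotyping_error_rate = 0.3, seed = 2)
  opt0 <- optimize_params(sim0$genotypes, sim0$meta, "XY", "I", grid = grid0,
                          n_permutations = 20, seed = 1)
  if (!opt0$none_found) {
    expect_gt(opt0$table$observed_count[opt0$best_index], 0)
  }
  # all-zero case returns the none-found status rather than an error
  auto <- simulate_sexlinked(6, 6, n_autosomal = 20, seed = 7)
  optA <- optimize_params(auto$genotypes, auto$meta, "XY", "I",
                          grid = tibble::tibble(het_freq_tol = 0.0,
                                                hom_freq_max = 0.0),
                          n_permutations = 10, seed = 1)
  expect_true(optA$none_found)
  expect_null(optA$best)
})
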