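#' Simulate a sex-linkage discovery dataset
#'
#' Generates the three classes of marker the sex scans are designed to
#' separate: fully sex-linked SNPs (the heterogametic sex heterozygous, the
#' homogametic sex homozygous reference, before noise), autosomal SNPs drawn
#' in Hardy-Weinberg proportions at a minor-allele frequency sampled
#' uniformly from `autosomal_maf_range` identically in both sexes, and
#' sex-specific RAD tags whose read depth is Poisson in the heterogametic
#' sex (with per-sample dropout) and zero in the homogametic sex. Optional
#' background tags are present in both sexes under the same depth/dropout
#' model. Genotyping errors are symmetric dosage flips (`0 -> 1`, `2 -> 1`,
#' `1 -> 0` or `2` with equal odds); missingness is applied per cell.
#'
#' @param n_males,n_females Sample sizes.
#' @param n_autosomal Number of autosomal SNPs.
#' @param n_sexlinked_snps Number of fully sex-linked SNPs.
#' @param n_sex_specific_tags Number of Y- (XY) or W- (ZW) specific tags.
#' @param n_background_tags Tags present in both sexes (default 0).
#' @param system `"XY"` (males heterogametic) or `"ZW"` (females).
#' @param autosomal_maf_range Length-2 numeric in `[0, 0.5]`.
#' @param genotyping_error_rate Per-genotype dosage-flip probability.
#' @param missing_rate Per-genotype missingness probability.
#' @param tag_dropout_rate Per-sample probability that a carried tag yields
#'   no reads.
#' @param mean_depth Mean of the Poisson read-depth model for tags.
#' @param seed Integer seed; the simulation is fully reproducible.
#' @return A list of class `sexlink_sim` with elements `genotypes`
#'   ([geno_matrix()]), `tags` ([tag_matrix()]), `meta` (tibble) and `truth`
#'   (list of tibbles labelling every locus and tag).
#' @export
simulate_sexlinked <- function(n_males, n_females,
                               n_autosomal = 0L, n_sexlinked_snps = 0L,
                               n_sex_specific_tags = 0L, n_background_tags = 0L,
                               system = c("XY", "ZW"),
                               autosomal_maf_range = c(0.05, 0.5),
                               genotyping_error_rate = 0,
                               missing_rate = 0,
                               tag_dropout_rate = 0,
                               mean_depth = 20,
                               seed = 1L) {
  system <- match.arg(system)
  stopifnot(
    n_males >= 1, n_females >= 1, n_autosomal >= 0, n_sexlinked_snps >= 0,
    n_sex_specific_tags >= 0, n_background_tags >= 0,
    length(autosomal_maf_range) == 2,
    all(autosomal_maf_range >= 0), all(autosomal_maf_range <= 0.5),
    genotyping_error_rate >= 0, genotyping_error_rate < 1,
    missing_rate >= 0, missing_rate < 1,
    tag_dropout_rate >= 0, tag_dropout_rate < 1,
    mean_depth > 0
  )
  set.seed(seed)
  n <- n_males + n_females
  sex <- c(rep("M", n_males), rep("F", n_females))
  het_sex <- if (system == "XY") "M" else "F"
  is_het <- sex == het_sex
  meta <- tibble(
    sample_id = sprintf("ind_%03d", seq_len(n)),
    sex = sex, population_id = "ref", distance_km = 0,
    mitotype = "unknown"
  )

  n_loci <- n_sexlinked_snps + n_autosomal
  dosage <- matrix(0L, nrow = n_loci, ncol = n)
  type <- character(n_loci)
  if (n_sexlinked_snps > 0) {
    dosage[seq_len(n_sexlinked_snps), is_het] <- 1L
    type[seq_len(n_sexlinked_snps)] <- "sex_linked"
  }
  if (n_autosomal > 0) {
    rows <- n_sexlinked_snps + seq_len(n_autosomal)
    maf <- runif(n_autosomal, autosomal_maf_range[1], autosomal_maf_range[2])
    dosage[rows, ] <- matrix(
      rbinom(n_autosomal * n, 2L, rep(maf, n)), nrow = n_autosomal
    )
    type[rows] <- "autosomal"
  }
  if (genotyping_error_rate > 0 && n_loci > 0) {
    flip <- which(runif(length(dosage)) < genotyping_error_rate)
    cur <- dosage[flip]
    new <- integer(length(flip))
    new[cur == 0L] <- 1L
    new[cur == 2L] <- 1L
    hets <- cur == 1L
    new[hets] <- sample(c(0L, 2L), sum(hets), replace = TRUE)
    dosage[flip] <- new
  }
  if (missing_rate > 0 && n_loci > 0) {
    dosage[runif(length(dosage)) < missing_rate] <- NA
  }
  locus_id <- c(
    if (n_sexlinked_snps > 0) sprintf("sl_%04d", seq_len(n_sexlinked_snps)),
    if (n_autosomal > 0) sprintf("auto_%05d", seq_len(n_autosomal))
  )
  loci <- tibble(
    locus_id = locus_id %||% character(),
    tag_id = paste0("tag_", locus_id %||% character()),
    snp_index = 0L, ref = "A", alt = "T"
  )
  genotypes <- geno_matrix(dosage, loci = loci, samples = meta$sample_id)

  n_tags <- n_sex_specific_tags + n_background_tags
  depth <- matrix(0L, nrow = n_tags, ncol = n)
  tag_type <- character(n_tags)
  draw_depth <- function(nt, cols) {
    d <- matrix(rpois(nt * length(cols), mean_depth), nrow = nt)
    if (tag_dropout_rate > 0) {
      d[matrix(runif(length(d)) < tag_dropout_rate, nrow = nt)] <- 0L
    }
    d
  }
  if (n_sex_specific_tags > 0) {
    depth[seq_len(n_sex_specific_tags), is_het] <-
      draw_depth(n_sex_specific_tags, which(is_het))
    tag_type[seq_len(n_sex_specific_tags)] <- "sex_specific"
  }
  if (n_background_tags > 0) {
    rows <- n_sex_specific_tags + seq_len(n_background_tags)
    depth[rows, ] <- draw_depth(n_background_tags, seq_len(n))
    tag_type[rows] <- "background"
  }
  tag_id <- c(
    if (n_sex_specific_tags > 0) sprintf("sextag_%04d", seq_len(n_sex_specific_tags)),
    if (n_background_tags > 0) sprintf("bgtag_%05d", seq_len(n_background_tags))
  )
  sequences <- .random_tag_sequences(n_tags)
  tags <- tag_matrix(
    depth,
    tags = tibble(tag_id = tag_id %||% character(), sequence = sequences),
    samples = meta$sample_id
  )

  structure(
    list(
      genotypes = genotypes, tags = tags, meta = meta,
      truth = list(
        loci = tibble(locus_id = loci$locus_id, type = type),
        tags = tibble(tag_id = tags$tags$tag_id, type = tag_type)
      ),
      system = system, seed = seed
    ),
    class = "sexlink_sim"
  )
}

# unique random 24-mers; length chosen so collisions are vanishingly rare
.random_tag_sequences <- function(n, len = 24L) {
  if (n == 0) return(character())
  repeat {
    seqs <- vapply(
      seq_len(n),
      function(i) paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
      character(1)
    )
    if (!anyDuplicated(seqs)) return(seqs)
  }
}

#' Simulate a hybrid-zone transect
#'
#' Populations sit at fixed transect positions; the mean ancestry at position
#' `x` follows `true_cline`. Each individual draws a hybrid index `h` from a
#' Beta distribution with that mean and concentration
#' `hybrid_index_concentration` (shape parameters `m * conc` and
#' `(1 - m) * conc`), which generates admixture linkage disequilibrium: the
#' within-population variance of `h` equals the Beta variance
#' `m (1 - m) / (conc + 1)`. Genotypes at each diagnostic locus are
#' `Binomial(2, h)` draws of the southern-species (focal) allele; per-locus
#' cline jitter (`per_locus_center_sd_km`, `per_locus_width_logsd`) shifts
#' the per-locus success probability by the offset between the locus cline
#' and the shared cline. Mitotypes are Bernoulli draws from `mtdna_cline`.
#'
#' @param pop_positions_km Strictly increasing population positions (km).
#' @param n_ind_per_pop Diploid individuals per population.
#' @param n_diagnostic_loci Number of species-diagnostic loci.
#' @param true_cline A [cline_model()] for the shared ancestry cline.
#' @param per_locus_center_sd_km SD of per-locus center jitter (km).
#' @param per_locus_width_logsd SD of per-locus log-width jitter.
#' @param hybrid_index_concentration Beta concentration of individual
#'   ancestry around the population mean (larger = tighter).
#' @param mtdna_cline Optional [cline_model()] for the mitochondrial cline;
#'   if `NULL`, mitotypes are `"unknown"`.
#' @param missing_rate Per-genotype missingness probability.
#' @param seed Integer seed.
#' @return A list of class `zone_sim` with `genotypes`, `meta`, `freqs`
#'   (per-locus population frequency table, one stack of rows per locus) and
#'   `truth` (shared and per-locus [cline_model()]s plus individual hybrid
#'   indices).
#' @export
simulate_zone <- function(pop_positions_km, n_ind_per_pop,
                          n_diagnostic_loci,
                          true_cline,
                          per_locus_center_sd_km = 0,
                          per_locus_width_logsd = 0,
                          hybrid_index_concentration = 50,
                          mtdna_cline = NULL,
                          missing_rate = 0,
                          seed = 1L) {
  stopifnot(
    length(pop_positions_km) >= 1,
    !is.unsorted(pop_positions_km, strictly = TRUE),
    n_ind_per_pop >= 1, n_diagnostic_loci >= 1,
    inherits(true_cline, "cline_model"),
    per_locus_center_sd_km >= 0, per_locus_width_logsd >= 0,
    hybrid_index_concentration > 0,
    missing_rate >= 0, missing_rate < 1
  )
  set.seed(seed)
  n_pop <- length(pop_positions_km)
  n <- n_pop * n_ind_per_pop
  pop_id <- sprintf("pop_%02d", seq_len(n_pop))
  meta <- tibble(
    sample_id = sprintf("ind_%04d", seq_len(n)),
    sex = sample(c("M", "F"), n, replace = TRUE),
    population_id = rep(pop_id, each = n_ind_per_pop),
    distance_km = rep(pop_positions_km, each = n_ind_per_pop)
  )
  m_pop <- cline_value(pop_positions_km, true_cline)
  m_ind <- rep(m_pop, each = n_ind_per_pop)
  conc <- hybrid_index_concentration
  eps <- 1e-9
  m_clamped <- pmin(pmax(m_ind, eps), 1 - eps)
  h <- rbeta(n, m_clamped * conc, (1 - m_clamped) * conc)
  # guard against numeric NaN at extreme shapes
  h[!is.finite(h)] <- m_clamped[!is.finite(h)]

  per_locus <- purrr::map(seq_len(n_diagnostic_loci), function(l) {
    cline_model(
      center = true_cline$center + rnorm(1, 0, per_locus_center_sd_km),
      width = true_cline$width * exp(rnorm(1, 0, per_locus_width_logsd)),
      tails = true_cline$tails,
      delta_l = true_cline$delta_l, tau_l = true_cline$tau_l,
      delta_r = true_cline$delta_r, tau_r = true_cline$tau_r
    )
  })
  locus_id <- sprintf("diag_%04d", seq_len(n_diagnostic_loci))
  names(per_locus) <- locus_id

  x_ind <- meta$distance_km
  dosage <- matrix(0L, nrow = n_diagnostic_loci, ncol = n)
  for (l in seq_len(n_diagnostic_loci)) {
    p <- h + cline_value(x_ind, per_locus[[l]]) - m_ind
    p <- pmin(pmax(p, 0), 1)
    dosage[l, ] <- rbinom(n, 2L, p)
  }
  if (missing_rate > 0) {
    dosage[runif(length(dosage)) < missing_rate] <- NA
  }
  loci <- tibble(
    locus_id = locus_id, tag_id = paste0("tag_", locus_id),
    snp_index = 0L, ref = "A", alt = "T"
  )
  genotypes <- geno_matrix(dosage, loci = loci, samples = meta$sample_id)

  meta$mitotype <- if (is.null(mtdna_cline)) {
    "unknown"
  } else {
    ifelse(runif(n) < cline_value(x_ind, mtdna_cline), "B", "A")
  }

  pop_index <- rep(seq_len(n_pop), each = n_ind_per_pop)
  freqs <- purrr::map_dfr(seq_len(n_diagnostic_loci), function(l) {
    called <- !is.na(dosage[l, ])
    tibble(
      locus_id = locus_id[l],
      population_id = pop_id,
      distance_km = pop_positions_km,
      n_alleles = as.integer(2 * tapply(called, pop_index, sum)),
      focal_allele_count = as.integer(tapply(dosage[l, ], pop_index,
                                             sum, na.rm = TRUE))
    )
  })
  freqs <- freqs %>% mutate(frequency = ifelse(.data$n_alleles > 0,
                                               .data$focal_allele_count / .data$n_alleles,
                                               NA_real_))

  structure(
    list(
      genotypes = genotypes, meta = meta, freqs = freqs,
      truth = list(
        shared_cline = true_cline,
        per_locus_clines = per_locus,
        hybrid_index = tibble(sample_id = meta$sample_id, h = h),
        mtdna_cline = mtdna_cline
      ),
      seed = seed
    ),
    class = "zone_sim"
  )
}

#' Simulate binomial allele counts along a cline
#'
#' Draws `focal_allele_count ~ Binomial(n_alleles, y(x))` at each position —
#' the sampling model the cline likelihood assumes. Used for parameter
#' recovery experiments.
#'
#' @param model A [cline_model()].
#' @param positions_km Population positions.
#' @param n_alleles Alleles sampled per population (scalar or vector).
#' @param seed Integer seed.
#' @return A population frequency table (tibble).
#' @export
sim_cline_counts <- function(model, positions_km, n_alleles, seed = 1L) {
  set.seed(seed)
  n_alleles <- rep_len(n_alleles, length(positions_km))
  y <- cline_value(positions_km, model)
  tibble(
    population_id = sprintf("pop_%02d", seq_along(positions_km)),
    distance_km = positions_km,
    n_alleles = as.integer(n_alleles),
    focal_allele_count = rbinom(length(positions_km), n_alleles, y)
  ) %>%
    mutate(frequency = .data$focal_allele_count / .data$n_alleles)
}
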