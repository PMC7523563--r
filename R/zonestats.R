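#' Call species-diagnostic SNPs from transect-edge populations
#'
#' A locus is diagnostic when every non-missing genotype in the edge-A
#' populations is homozygous for one allele and every non-missing genotype
#' in the edge-B populations is homozygous for the other, with the missing
#' fraction within each edge group at most `max_missing_in_edges`. Only one
#' SNP per RAD tag is retained (the lowest `snp_index`), and the polarity —
#' which allele is the species-B allele — is recorded per locus.
#'
#' The result is invariant to the order of samples and loci in the input.
#'
#' @param g A [geno_matrix()].
#' @param meta Sample metadata with `population_id`.
#' @param edge_pops_A,edge_pops_B Population ids of the two edge groups
#'   (species A, e.g. the northern taxon, and species B).
#' @param max_missing_in_edges Maximum missing fraction tolerated within
#'   each edge group at a diagnostic locus (default 0.1).
#' @return A tibble of class `diagnostic_panel`: `locus_id`, `tag_id`,
#'   `snp_index`, `b_allele` (`"ref"` or `"alt"`). Empty (with a warning)
#'   when no locus qualifies.
#' @export
call_diagnostic_snps <- function(g, meta, edge_pops_A, edge_pops_B,
                                 max_missing_in_edges = 0.1) {
  meta <- validate_meta(meta)
  pop <- meta$population_id[match(g$samples, meta$sample_id)]
  ia <- which(pop %in% edge_pops_A)
  ib <- which(pop %in% edge_pops_B)
  if (length(ia) == 0 || length(ib) == 0) abort("both edge groups must be non-empty")
  da <- g$dosage[, ia, drop = FALSE]
  db <- g$dosage[, ib, drop = FALSE]
  miss_a <- rowMeans(is.na(da))
  miss_b <- rowMeans(is.na(db))
  n_a <- rowSums(!is.na(da))
  n_b <- rowSums(!is.na(db))
  # fixed homozygous: all non-missing calls equal and in {0, 2}
  all_zero_a <- rowSums(da != 0L, na.rm = TRUE) == 0
  all_two_a <- rowSums(da != 2L, na.rm = TRUE) == 0
  all_zero_b <- rowSums(db != 0L, na.rm = TRUE) == 0
  all_two_b <- rowSums(db != 2L, na.rm = TRUE) == 0
  ok <- n_a > 0 & n_b > 0 &
    miss_a <= max_missing_in_edges & miss_b <= max_missing_in_edges &
    ((all_zero_a & all_two_b) | (all_two_a & all_zero_b))
  panel <- g$loci %>%
    mutate(
      .row = row_number(),
      b_allele = dplyr::case_when(all_two_b ~ "alt", all_two_a ~ "ref",
                                  TRUE ~ NA_character_)
    ) %>%
    filter(ok) %>%
    arrange(.data$tag_id, .data$snp_index) %>%
    group_by(.data$tag_id) %>%
    slice(1) %>%
    ungroup() %>%
    arrange(.data$locus_id) %>%
    select("locus_id", "tag_id", "snp_index", "b_allele")
  if (nrow(panel) == 0) warn("no diagnostic locus found; returning an empty panel")
  structure(panel,
            class = c("diagnostic_panel", class(panel)),
            edge_pops_A = edge_pops_A, edge_pops_B = edge_pops_B)
}

# dosage of the species-B allele for panel loci, loci x samples
.panel_b_dosage <- function(g, panel) {
  idx <- match(panel$locus_id, g$loci$locus_id)
  if (anyNA(idx)) abort("panel contains loci absent from the genotype matrix")
  d <- g$dosage[idx, , drop = FALSE]
  flip <- panel$b_allele == "ref"
  d[flip, ] <- 2L - d[flip, , drop = FALSE]
  d
}

#' Per-individual hybrid index and interspecific heterozygosity
#'
#' The hybrid index `q` is the fraction of species-B alleles among an
#' individual's genotyped panel loci — the maximum-likelihood ancestry
#' estimate under binomial sampling of diagnostic alleles. Interspecific
#' heterozygosity is the fraction of genotyped panel loci that are
#' heterozygous (1 for an F1, at most `2 min(q, 1 - q)` plus discreteness
#' slack otherwise).
#'
#' @param g A [geno_matrix()].
#' @param panel A [call_diagnostic_snps()] panel.
#' @return A tibble with one row per sample: `sample_id`, `hybrid_index_q`,
#'   `interspecific_het`, `n_loci_used`. Individuals with zero genotyped
#'   panel loci get `NA` statistics.
#' @export
hybrid_index <- function(g, panel) {
  if (nrow(panel) == 0) abort("empty diagnostic panel")
  d <- .panel_b_dosage(g, panel)
  n_used <- colSums(!is.na(d))
  q <- colSums(d, na.rm = TRUE) / (2 * pmax(n_used, 1L))
  het <- colSums(d == 1L, na.rm = TRUE) / pmax(n_used, 1L)
  q[n_used == 0] <- NA_real_
  het[n_used == 0] <- NA_real_
  tibble(
    sample_id = g$samples,
    hybrid_index_q = unname(q),
    interspecific_het = unname(het),
    n_loci_used = unname(as.integer(n_used))
  )
}

#' Per-population admixture statistics
#'
#' For every population: the mean hybrid index; observed heterozygosity
#' `Ho` (heterozygote fraction averaged over panel loci); mean pairwise
#' linkage disequilibrium `ld_r2` (squared Pearson correlation between
#' dosage vectors, averaged over all locus pairs with non-zero variance);
#' and admixture linkage disequilibrium `admix_ld_Dprime`, the variance of
#' the individual hybrid index within the population (denominator `n`, so
#' the maximum is 0.25). Both `Ho` and `D'` peak where parental genomes mix,
#' i.e. at the cline center.
#'
#' @param g A [geno_matrix()].
#' @param panel A [call_diagnostic_snps()] panel.
#' @param meta Sample metadata with `population_id` and `distance_km`.
#' @return A tibble with one row per population: `population_id`,
#'   `distance_km`, `n`, `mean_q`, `Ho`, `ld_r2`, `admix_ld_Dprime`.
#'   Variance-based statistics are `NA` for single-individual populations.
#' @export
population_summaries <- function(g, panel, meta) {
  meta <- validate_meta(meta)
  hi <- hybrid_index(g, panel) %>%
    left_join(meta %>% select("sample_id", "population_id", "distance_km"),
              by = "sample_id")
  d <- .panel_b_dosage(g, panel)
  pops <- hi %>% distinct(.data$population_id, .data$distance_km) %>%
    arrange(.data$distance_km)
  purrr::map_dfr(seq_len(nrow(pops)), function(i) {
    pid <- pops$population_id[i]
    cols <- which(hi$population_id == pid)
    sub <- d[, cols, drop = FALSE]
    q <- hi$hybrid_index_q[cols]
    n <- length(cols)
    ho_loci <- rowSums(sub == 1L, na.rm = TRUE) / pmax(rowSums(!is.na(sub)), 1L)
    ho_loci[rowSums(!is.na(sub)) == 0] <- NA_real_
    ld <- NA_real_
    if (n >= 2 && nrow(sub) >= 2) {
      suppressWarnings(
        cc <- cor(t(sub), use = "pairwise.complete.obs")
      )
      r2 <- cc[upper.tri(cc)]^2
      ld <- if (all(is.na(r2))) NA_real_ else mean(r2, na.rm = TRUE)
    }
    dprime <- if (n >= 2) {
      qq <- q[!is.na(q)]
      mean((qq - mean(qq))^2) # population (n-denominator) variance
    } else {
      NA_real_
    }
    tibble(
      population_id = pid, distance_km = pops$distance_km[i], n = n,
      mean_q = mean(q, na.rm = TRUE),
      Ho = mean(ho_loci, na.rm = TRUE),
      ld_r2 = ld,
      admix_ld_Dprime = dprime
    )
  })
}
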