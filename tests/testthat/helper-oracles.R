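# Independent brute-force oracles. These deliberately share no code with the
# package internals: per-locus loops, explicit allele counting, and a separate
# algebraic arrangement of the cline formulas.

# sex vector ("M"/"F") aligned to columns of `dosage`
oracle_scan_I <- function(dosage, sex, system, het_freq_tol, hom_freq_max,
                          min_informative = 1) {
  het_sex <- if (system == "XY") "M" else "F"
  hits <- logical(nrow(dosage))
  for (l in seq_len(nrow(dosage))) {
    flag <- FALSE
    for (allele in c("alt", "ref")) {
      cnt <- c(0, 0); tot <- c(0, 0) # [1] het sex, [2] hom sex
      for (s in seq_along(sex)) {
        d <- dosage[l, s]
        if (is.na(d) || !(sex[s] %in% c("M", "F"))) next
        grp <- if (sex[s] == het_sex) 1 else 2
        tot[grp] <- tot[grp] + 2
        cnt[grp] <- cnt[grp] + (if (allele == "alt") d else 2 - d)
      }
      if (tot[1] < 2 * min_informative || tot[2] < 2 * min_informative) next
      f_het <- cnt[1] / tot[1]
      f_hom <- cnt[2] / tot[2]
      if (f_het >= 0.5 - het_freq_tol && f_het <= 0.5 && f_hom <= hom_freq_max) {
        flag <- TRUE
      }
    }
    hits[l] <- flag
  }
  hits
}

oracle_scan_II <- function(dosage, sex, system, het_het_min, hom_het_max,
                           min_informative = 1) {
  het_sex <- if (system == "XY") "M" else "F"
  hits <- logical(nrow(dosage))
  for (l in seq_len(nrow(dosage))) {
    n_het <- c(0, 0); tot <- c(0, 0)
    for (s in seq_along(sex)) {
      d <- dosage[l, s]
      if (is.na(d) || !(sex[s] %in% c("M", "F"))) next
      grp <- if (sex[s] == het_sex) 1 else 2
      tot[grp] <- tot[grp] + 1
      if (d == 1) n_het[grp] <- n_het[grp] + 1
    }
    hits[l] <- tot[1] >= min_informative && tot[2] >= min_informative &&
      n_het[1] / tot[1] >= het_het_min &&
      n_het[2] / tot[2] <= hom_het_max
  }
  hits
}

oracle_scan_III <- function(presence, sex, system, specificity_min) {
  het_sex <- if (system == "XY") "M" else "F"
  hits <- logical(nrow(presence))
  for (l in seq_len(nrow(presence))) {
    n_het <- 0; tot_het <- 0; n_hom <- 0
    for (s in seq_along(sex)) {
      if (sex[s] == het_sex) {
        tot_het <- tot_het + 1
        if (presence[l, s]) n_het <- n_het + 1
      } else if (sex[s] %in% c("M", "F")) {
        if (presence[l, s]) n_hom <- n_hom + 1
      }
    }
    hits[l] <- n_hom == 0 && n_het / tot_het >= specificity_min
  }
  hits
}

# direct cline evaluation with plogis and explicit tail pieces
oracle_cline_value <- function(x, center, width, delta_l = 0, tau_l = 0,
                               delta_r = 0, tau_r = 0,
                               left = FALSE, right = FALSE,
                               p_min = 0, p_max = 1) {
  vapply(x, function(xi) {
    if (left && xi < center - delta_l) {
      y_join <- stats::plogis(-4 * delta_l / width)
      slope_scale <- 4 * tau_l / (width * (1 + exp(-4 * delta_l / width)))
      y <- y_join * exp(slope_scale * (xi - (center - delta_l)))
    } else if (right && xi > center + delta_r) {
      y_join <- stats::plogis(4 * delta_r / width)
      slope_scale <- 4 * tau_r / (width * (1 + exp(-4 * delta_r / width)))
      y <- 1 - (1 - y_join) * exp(-slope_scale * (xi - (center + delta_r)))
    } else {
      y <- stats::plogis(4 * (xi - center) / width)
    }
    p_min + (p_max - p_min) * y
  }, numeric(1))
}

# independent binomial log-likelihood (dbinom-based, per-row loop)
oracle_cline_loglik <- function(freqs, center, width, ...) {
  sum(vapply(seq_len(nrow(freqs)), function(i) {
    y <- oracle_cline_value(freqs$distance_km[i], center, width, ...)
    y <- min(max(y, 1e-9), 1 - 1e-9)
    stats::dbinom(freqs$focal_allele_count[i], freqs$n_alleles[i], y, log = TRUE) -
      lchoose(freqs$n_alleles[i], freqs$focal_allele_count[i])
  }, numeric(1)))
}

# grid-search ML hybrid index under binomial sampling of diagnostic alleles
oracle_hybrid_index_ml <- function(n_b_alleles, n_loci_used, grid_n = 20001) {
  qs <- seq(0, 1, length.out = grid_n)
  ll <- n_b_alleles * log(pmax(qs, 1e-12)) +
    (2 * n_loci_used - n_b_alleles) * log(pmax(1 - qs, 1e-12))
  qs[which.max(ll)]
}

# small random genotype fixture
random_geno <- function(n_loci, n_samples, miss = 0.1, seed = 1) {
  set.seed(seed)
  d <- matrix(sample(0:2, n_loci * n_samples, replace = TRUE), nrow = n_loci)
  d[matrix(runif(length(d)) < miss, nrow = n_loci)] <- NA
  geno_matrix(d)
}

random_meta <- function(samples, seed = 1, pops = 1) {
  set.seed(seed)
  tibble::tibble(
    sample_id = samples,
    sex = sample(c("M", "F"), length(samples), replace = TRUE),
    population_id = sample(sprintf("pop_%02d", seq_len(pops)),
                           length(samples), replace = TRUE),
    distance_km = NA_real_
  ) |>
    dplyr::group_by(population_id) |>
    dplyr::mutate(distance_km = as.numeric(sub("pop_", "", population_id[1])) * 10) |>
    dplyr::ungroup()
}
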