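#' Thresholds for the three sex-linkage scans
#'
#' Method I flags loci whose allele frequencies match the expectation for a
#' fixed X/Y (Z/W) difference: one allele at frequency ~0.5 in the
#' heterogametic sex and near 0 in the homogametic sex. Method II flags loci
#' by heterozygote excess in the heterogametic sex and deficit in the other.
#' Method III flags RAD tags present in most of one sex and absent from the
#' other (strict zero).
#'
#' @param het_freq_tol Method I: tolerance below 0.5 for the sex-limited
#'   allele's frequency in the heterogametic sex.
#' @param hom_freq_max Method I: ceiling on that allele's frequency in the
#'   homogametic sex.
#' @param het_het_min Method II: minimum heterozygote fraction in the
#'   heterogametic sex.
#' @param hom_het_max Method II: maximum heterozygote fraction in the
#'   homogametic sex (must be below `het_het_min`).
#' @param specificity_min Method III: minimum presence fraction in the
#'   heterogametic sex, given zero presence in the other.
#' @param min_informative_per_sex Minimum genotyped individuals per sex for a
#'   locus to be scanned.
#' @return A list of class `scan_params`.
#' @export
scan_params <- function(het_freq_tol = 0.1, hom_freq_max = 0.05,
                        het_het_min = 0.9, hom_het_max = 0.05,
                        specificity_min = 0.9,
                        min_informative_per_sex = 5L) {
  stopifnot(
    het_freq_tol >= 0, het_freq_tol <= 0.5,
    hom_freq_max >= 0, hom_freq_max <= 0.5,
    het_het_min > 0, het_het_min <= 1,
    hom_het_max >= 0, hom_het_max < 1,
    het_het_min > hom_het_max,
    specificity_min > 0, specificity_min <= 1,
    min_informative_per_sex >= 1
  )
  structure(
    list(het_freq_tol = het_freq_tol, hom_freq_max = hom_freq_max,
         het_het_min = het_het_min, hom_het_max = hom_het_max,
         specificity_min = specificity_min,
         min_informative_per_sex = as.integer(min_informative_per_sex)),
    class = "scan_params"
  )
}

# per-locus per-sex counts shared by methods I and II
.sex_counts <- function(dosage, idx) {
  sub <- dosage[, idx, drop = FALSE]
  n_called <- rowSums(!is.na(sub))
  list(
    n_called = n_called,
    alt_freq = rowSums(sub, na.rm = TRUE) / pmax(2 * n_called, 1L),
    het_frac = rowSums(sub == 1L, na.rm = TRUE) / pmax(n_called, 1L)
  )
}

.het_hom_idx <- function(samples, meta, system) {
  sx <- .sex_index(samples, meta)
  if (system == "XY") list(het = sx$M, hom = sx$F) else list(het = sx$F, hom = sx$M)
}

#' Scan for sex-linked SNPs by allele frequency (method I)
#'
#' Flags loci where either allele sits in `[0.5 - het_freq_tol, 0.5]` in the
#' heterogametic sex (males for XY, females for ZW) while that same allele is
#' at frequency `<= hom_freq_max` in the homogametic sex. Loci with fewer
#' than `min_informative_per_sex` genotyped individuals in either sex are
#' skipped; samples of unknown sex are excluded.
#'
#' @param g A [geno_matrix()].
#' @param meta Sample metadata.
#' @param system `"XY"` or `"ZW"`.
#' @param params A [scan_params()].
#' @return A tibble of candidates with per-locus diagnostics (`system`,
#'   `method`, alternate-allele frequencies and sample counts per sex).
#' @export
scan_method_I <- function(g, meta, system = c("XY", "ZW"), params = scan_params()) {
  system <- match.arg(system)
  meta <- validate_meta(meta)
  idx <- .het_hom_idx(g$samples, meta, system)
  het <- .sex_counts(g$dosage, idx$het)
  hom <- .sex_counts(g$dosage, idx$hom)
  informative <- het$n_called >= params$min_informative_per_sex &
    hom$n_called >= params$min_informative_per_sex
  lo <- 0.5 - params$het_freq_tol
  alt_ok <- het$alt_freq >= lo & het$alt_freq <= 0.5 &
    hom$alt_freq <= params$hom_freq_max
  ref_ok <- (1 - het$alt_freq) >= lo & (1 - het$alt_freq) <= 0.5 &
    (1 - hom$alt_freq) <= params$hom_freq_max
  hit <- informative & (alt_ok | ref_ok)
  tibble(
    locus_id = g$loci$locus_id[hit],
    system = system, method = "I",
    allele = ifelse(alt_ok[hit], "alt", "ref"),
    alt_freq_het_sex = het$alt_freq[hit],
    alt_freq_hom_sex = hom$alt_freq[hit],
    n_het_sex = het$n_called[hit],
    n_hom_sex = hom$n_called[hit]
  )
}

#' Scan for sex-linked SNPs by heterozygosity (method II)
#'
#' Flags loci whose heterozygote fraction is `>= het_het_min` in the
#' heterogametic sex and `<= hom_het_max` in the homogametic sex.
#'
#' @inheritParams scan_method_I
#' @return A tibble of candidates with per-sex heterozygote fractions.
#' @export
scan_method_II <- function(g, meta, system = c("XY", "ZW"), params = scan_params()) {
  system <- match.arg(system)
  meta <- validate_meta(meta)
  idx <- .het_hom_idx(g$samples, meta, system)
  het <- .sex_counts(g$dosage, idx$het)
  hom <- .sex_counts(g$dosage, idx$hom)
  hit <- het$n_called >= params$min_informative_per_sex &
    hom$n_called >= params$min_informative_per_sex &
    het$het_frac >= params$het_het_min &
    hom$het_frac <= params$hom_het_max
  tibble(
    locus_id = g$loci$locus_id[hit],
    system = system, method = "II",
    het_frac_het_sex = het$het_frac[hit],
    het_frac_hom_sex = hom$het_frac[hit],
    n_het_sex = het$n_called[hit],
    n_hom_sex = hom$n_called[hit]
  )
}

#' Scan for sex-specific RAD tags (method III)
#'
#' Flags tags present in at least `specificity_min` of the heterogametic sex
#' and in zero individuals of the homogametic sex (a strict zero: a single
#' presence in the wrong sex disqualifies the tag).
#'
#' @param presence Logical tags-by-samples matrix from [tag_presence()].
#' @inheritParams scan_method_I
#' @return A tibble of candidate tags with presence counts per sex.
#' @export
scan_method_III <- function(presence, meta, system = c("XY", "ZW"),
                            params = scan_params()) {
  system <- match.arg(system)
  meta <- validate_meta(meta)
  idx <- .het_hom_idx(colnames(presence), meta, system)
  if (length(idx$het) < params$min_informative_per_sex ||
      length(idx$hom) < params$min_informative_per_sex) {
    abort("too few sexed samples for the tag scan")
  }
  n_het <- rowSums(presence[, idx$het, drop = FALSE])
  n_hom <- rowSums(presence[, idx$hom, drop = FALSE])
  hit <- n_hom == 0 & n_het / length(idx$het) >= params$specificity_min
  ids <- rownames(presence) %||% as.character(seq_len(nrow(presence)))
  tibble(
    tag_id = ids[hit],
    system = system, method = "III",
    n_present_het_sex = n_het[hit], n_het_sex = length(idx$het),
    n_present_hom_sex = n_hom[hit], n_hom_sex = length(idx$hom)
  )
}

#' Run one or all sex-linkage scans
#'
#' Convenience wrapper combining methods I-III over one or both systems into
#' a single candidate tibble.
#'
#' @param g A [geno_matrix()] (methods I and II); may be `NULL`.
#' @param presence Tag presence matrix (method III); may be `NULL`.
#' @param meta Sample metadata.
#' @param system `"XY"`, `"ZW"` or `"both"`.
#' @param methods Subset of `c("I", "II", "III")`.
#' @param params A [scan_params()].
#' @return A tibble with one row per (marker, system, method) candidate.
#' @export
scan_sex_markers <- function(g = NULL, presence = NULL, meta,
                             system = c("both", "XY", "ZW"),
                             methods = c("I", "II", "III"),
                             params = scan_params()) {
  system <- match.arg(system)
  systems <- if (system == "both") c("XY", "ZW") else system
  out <- purrr::map_dfr(systems, function(sys) {
    res <- list()
    if ("I" %in% methods && !is.null(g)) {
      res <- c(res, list(scan_method_I(g, meta, sys, params)))
    }
    if ("II" %in% methods && !is.null(g)) {
      res <- c(res, list(scan_method_II(g, meta, sys, params)))
    }
    if ("III" %in% methods && !is.null(presence)) {
      res <- c(res, list(scan_method_III(presence, meta, sys, params)))
    }
    dplyr::bind_rows(res)
  })
  out
}

#' Permutation test for the number of sex-linked candidates
#'
#' Shuffles the male/female labels across the whole sample set (preserving
#' the observed totals), re-runs the scan, and compares the observed
#' candidate count with the null distribution of shuffled counts. Sex
#' linkage is significant when the observed count exceeds the null's 95th
#' percentile. The reported p-value uses the add-one permutation estimator
#' `(1 + #{null >= observed}) / (1 + n_permutations)`; the optimality score
#' (smaller is better) is the mean null count over `max(observed, 1)`.
#'
#' @param x A [geno_matrix()] (methods I/II) or a presence matrix (III).
#' @param meta Sample metadata.
#' @param system `"XY"` or `"ZW"`.
#' @param method `"I"`, `"II"` or `"III"`.
#' @param params A [scan_params()].
#' @param n_permutations Number of label shuffles (default 100).
#' @param seed Integer seed for the shuffles.
#' @return A list of class `sex_perm_test` with `observed_count`,
#'   `null_counts`, `p_value`, `percentile95`, `optimality_score`,
#'   `significant`.
#' @export
permutation_test <- function(x, meta, system = c("XY", "ZW"),
                             method = c("I", "II", "III"),
                             params = scan_params(),
                             n_permutations = 100L, seed = 1L) {
  system <- match.arg(system)
  method <- match.arg(method)
  stopifnot(n_permutations >= 1)
  meta <- validate_meta(meta)
  count_fun <- switch(
    method,
    I = function(m) nrow(scan_method_I(x, m, system, params)),
    II = function(m) nrow(scan_method_II(x, m, system, params)),
    III = function(m) nrow(scan_method_III(x, m, system, params))
  )
  observed <- count_fun(meta)
  sexed <- which(meta$sex %in% c("M", "F"))
  set.seed(seed)
  null_counts <- vapply(seq_len(n_permutations), function(b) {
    m <- meta
    m$sex[sexed] <- sample(m$sex[sexed])
    count_fun(m)
  }, integer(1))
  p95 <- unname(quantile(null_counts, 0.95))
  structure(
    list(
      observed_count = observed,
      null_counts = null_counts,
      p_value = (1 + sum(null_counts >= observed)) / (1 + n_permutations),
      percentile95 = p95,
      optimality_score = mean(null_counts) / max(observed, 1),
      significant = observed > p95,
      system = system, method = method, params = params,
      n_permutations = as.integer(n_permutations), seed = seed
    ),
    class = "sex_perm_test"
  )
}

#' @export
print.sex_perm_test <- function(x, ...) {
  cat(sprintf(
    "<sex_perm_test> method %s, %s: observed %d, null mean %.2f, 95th pct %.1f, p = %.4g%s\n",
    x$method, x$system, x$observed_count, mean(x$null_counts),
    x$percentile95, x$p_value, if (x$significant) " *" else ""
  ))
  invisible(x)
}

#' @method glance sex_perm_test
#' @export
glance.sex_perm_test <- function(x, ...) {
  tibble(
    system = x$system, method = x$method,
    observed_count = x$observed_count,
    mean_null = mean(x$null_counts),
    percentile95 = x$percentile95,
    p_value = x$p_value,
    optimality_score = x$optimality_score,
    significant = x$significant
  )
}

#' Default scan parameter grids
#'
#' The search grids over the heterogametic/homogametic thresholds of methods
#' I and II and the six specificity values of method III.
#'
#' @param method `"I"`, `"II"` or `"III"`.
#' @return A tibble, one row per grid point, with `scan_params` arguments.
#' @export
default_scan_grid <- function(method = c("I", "II", "III")) {
  method <- match.arg(method)
  switch(
    method,
    I = tidyr::expand_grid(het_freq_tol = c(0.05, 0.1, 0.2),
                           hom_freq_max = c(0.01, 0.05)),
    II = tidyr::expand_grid(het_het_min = c(0.75, 0.9, 1.0),
                            hom_het_max = c(0.05, 0.1)),
    III = tibble(specificity_min = c(0.5, 0.6, 0.7, 0.8, 0.9, 1.0))
  )
}

#' Select scan thresholds by minimising permutation false positives
#'
#' Runs [permutation_test()] at every grid point and returns the point with
#' the smallest optimality score (mean null count relative to the observed
#' count), i.e. the setting with the fewest expected false positives per
#' observed candidate. Ties are broken by larger observed count, then by
#' grid order. If no grid point flags any candidate, `none_found` is set and
#' `best` is `NULL`.
#'
#' @param x Data for the scan ([geno_matrix()] or presence matrix).
#' @param meta Sample metadata.
#' @param system `"XY"` or `"ZW"`.
#' @param method `"I"`, `"II"` or `"III"`.
#' @param grid Tibble of `scan_params` arguments, one row per candidate
#'   setting (defaults to [default_scan_grid()]).
#' @param base_params Settings for parameters not varied by the grid.
#' @param n_permutations,seed Passed to [permutation_test()]; each grid row
#'   uses an independently derived seed.
#' @return A list of class `scan_optimization`: `best` (a `scan_params` or
#'   `NULL`), `best_index`, `table` (grid plus permutation summaries),
#'   `none_found`.
#' @export
optimize_params <- function(x, meta, system = c("XY", "ZW"),
                            method = c("I", "II", "III"),
                            grid = NULL, base_params = scan_params(),
                            n_permutations = 100L, seed = 1L) {
  system <- match.arg(system)
  method <- match.arg(method)
  if (is.null(grid)) grid <- default_scan_grid(method)
  if (nrow(grid) == 0) abort("empty parameter grid")
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    args <- modifyList(unclass(base_params), as.list(grid[i, ]))
    p <- do.call(scan_params, args)
    pt <- permutation_test(x, meta, system, method, p,
                           n_permutations = n_permutations,
                           seed = seed + i - 1L)
    list(params = p, test = pt)
  })
  table <- dplyr::bind_cols(
    grid,
    purrr::map_dfr(rows, ~ glance(.x$test) %>%
                     select(-"system", -"method"))
  )
  none_found <- all(table$observed_count == 0)
  best_index <- NA_integer_
  if (!none_found) {
    ord <- order(table$optimality_score, -table$observed_count,
                 seq_len(nrow(table)))
    best_index <- ord[1]
  }
  structure(
    list(
      best = if (none_found) NULL else rows[[best_index]]$params,
      best_index = best_index,
      best_test = if (none_found) NULL else rows[[best_index]]$test,
      table = table, none_found = none_found,
      system = system, method = method
    ),
    class = "scan_optimization"
  )
}

#' @export
print.scan_optimization <- function(x, ...) {
  if (x$none_found) {
    cat(sprintf("<scan_optimization> method %s, %s: no candidates at any grid point\n",
                x$method, x$system))
  } else {
    cat(sprintf("<scan_optimization> method %s, %s: best grid row %d (score %.3g, observed %d)\n",
                x$method, x$system, x$best_index,
                x$table$optimality_score[x$best_index],
                x$table$observed_count[x$best_index]))
  }
  invisible(x)
}

#' @method tidy scan_optimization
#' @export
tidy.scan_optimization <- function(x, ...) x$table
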