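#' Tag presence distribution across the sexes
#'
#' Summarises, for every (number of males, number of females) combination,
#' how many tags are present in exactly that many individuals of each sex —
#' the full `(M+1) x (F+1)` contingency surface. Sex-specific tags
#' concentrate on the edges (high in one sex, zero in the other).
#'
#' @param presence Logical tags-by-samples matrix from [tag_presence()].
#' @param meta Sample metadata; only samples sexed `M`/`F` are counted.
#' @return A tibble with columns `n_males`, `n_females`, `n_tags`, covering
#'   the complete grid (zero cells included).
#' @export
radsex_distribution <- function(presence, meta) {
  meta <- validate_meta(meta)
  sx <- .sex_index(colnames(presence), meta)
  n_m <- rowSums(presence[, sx$M, drop = FALSE])
  n_f <- rowSums(presence[, sx$F, drop = FALSE])
  tibble(n_males = n_m, n_females = n_f) %>%
    dplyr::count(.data$n_males, .data$n_females, name = "n_tags") %>%
    tidyr::complete(
      n_males = 0:length(sx$M), n_females = 0:length(sx$F),
      fill = list(n_tags = 0L)
    ) %>%
    arrange(.data$n_males, .data$n_females)
}

#' Chi-squared test of sex association for each tag
#'
#' For every tag, builds the 2x2 presence/absence-by-sex table and applies
#' the Yates continuity-corrected chi-squared test (1 df), with Bonferroni
#' correction across all testable tags. A tag is testable when it is present
#' in at least one and at most all-but-one of the sexed samples; degenerate
#' tags get `chi2 = 0`, `p = 1` and do not enter the Bonferroni denominator.
#'
#' @param presence Logical tags-by-samples matrix.
#' @param meta Sample metadata.
#' @param alpha Family-wise significance level (default 0.05).
#' @return A tibble with one row per tag: presence counts per sex,
#'   `chi2_yates`, `p_raw`, `p_bonferroni`, `significant`. The Bonferroni
#'   denominator is recorded in the `n_tests` attribute and column.
#' @export
radsex_test <- function(presence, meta, alpha = 0.05) {
  meta <- validate_meta(meta)
  sx <- .sex_index(colnames(presence), meta)
  if (length(sx$M) < 1 || length(sx$F) < 1) {
    abort("need at least one sample of each sex")
  }
  n_m <- length(sx$M)
  n_f <- length(sx$F)
  n <- n_m + n_f
  a <- unname(rowSums(presence[, sx$M, drop = FALSE])) # present, male
  b <- unname(rowSums(presence[, sx$F, drop = FALSE])) # present, female
  c_ <- n_m - a                                # absent, male
  d <- n_f - b                                 # absent, female
  present <- a + b
  testable <- present >= 1 & present <= n - 1
  # Yates: chi2 = N (|ad - bc| - N/2)^2 / (R1 R2 C1 C2), truncated at 0
  num <- pmax(abs(a * d - b * c_) - n / 2, 0)
  denom <- as.numeric(present) * (n - present) * n_m * n_f
  chi2 <- ifelse(testable, n * num^2 / denom, 0)
  p_raw <- ifelse(testable, pchisq(chi2, df = 1, lower.tail = FALSE), 1)
  m_tests <- sum(testable)
  p_bonf <- ifelse(testable, pmin(1, p_raw * m_tests), 1)
  ids <- rownames(presence) %||% as.character(seq_len(nrow(presence)))
  out <- tibble(
    tag_id = ids,
    n_present_m = as.integer(a), n_males = n_m,
    n_present_f = as.integer(b), n_females = n_f,
    chi2_yates = chi2, p_raw = p_raw, p_bonferroni = p_bonf,
    n_tests = m_tests,
    significant = p_bonf < alpha
  )
  attr(out, "n_tests") <- m_tests
  out
}
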