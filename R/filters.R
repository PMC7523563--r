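#' Genotype-quality filter settings
#'
#' The post-assembly filters applied before any scan: a per-genotype read
#' depth floor, a per-group call-rate floor applied to every group (both
#' sexes, or every population), and a whole-dataset heterozygosity ceiling
#' that removes over-merged paralogous loci.
#'
#' @param min_locus_coverage Minimum reads backing a genotype call (default 8).
#'   Only enforced when the genotype matrix carries per-genotype depth.
#' @param min_call_rate_per_group Minimum fraction of genotyped individuals
#'   required in every group (default 0.8).
#' @param n_groups_required Number of groups the call-rate must hold in
#'   (default 2, i.e. both sexes).
#' @param max_locus_heterozygosity Maximum heterozygote fraction across the
#'   whole dataset (default 0.75).
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(min_locus_coverage = 8L,
                          min_call_rate_per_group = 0.8,
                          n_groups_required = 2L,
                          max_locus_heterozygosity = 0.75) {
  stopifnot(
    min_locus_coverage >= 1,
    min_call_rate_per_group > 0, min_call_rate_per_group <= 1,
    n_groups_required >= 1,
    max_locus_heterozygosity > 0, max_locus_heterozygosity <= 1
  )
  structure(
    list(
      min_locus_coverage = as.integer(min_locus_coverage),
      min_call_rate_per_group = min_call_rate_per_group,
      n_groups_required = as.integer(n_groups_required),
      max_locus_heterozygosity = max_locus_heterozygosity
    ),
    class = "filter_params"
  )
}

#' Apply per-locus genotype filters
#'
#' Masks genotype calls below the depth floor (when depth is available;
#' otherwise the depth filter is skipped with a notice), then keeps loci that
#' are called in at least `min_call_rate_per_group` of the individuals of
#' every group and whose heterozygote fraction across all non-missing calls
#' does not exceed `max_locus_heterozygosity`.
#'
#' @param g A [geno_matrix()].
#' @param meta Sample metadata (see [validate_meta()]).
#' @param params A [filter_params()].
#' @param group_by `"sex"` (default) or `"population"`. Samples with unknown
#'   sex are excluded from sex groups.
#' @return A filtered `geno_matrix`. If no locus survives, an empty matrix is
#'   returned with a warning.
#' @export
apply_locus_filters <- function(g, meta, params = filter_params(),
                                group_by = c("sex", "population")) {
  group_by <- match.arg(group_by)
  meta <- validate_meta(meta)
  dosage <- g$dosage
  if (!is.null(g$depth)) {
    dosage[!is.na(g$depth) & g$depth < params$min_locus_coverage] <- NA
  } else {
    inform("no per-genotype depth available; coverage filter skipped")
  }
  key <- meta[[if (group_by == "sex") "sex" else "population_id"]]
  key <- key[match(g$samples, meta$sample_id)]
  if (anyNA(key)) abort("every sample needs a metadata row")
  if (group_by == "sex") key[key == "unknown"] <- NA
  groups <- split(seq_along(g$samples), key)
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < params$n_groups_required) {
    abort(sprintf("need %d non-empty groups, found %d",
                  params$n_groups_required, length(groups)))
  }
  call_ok <- rep(TRUE, nrow(dosage))
  for (idx in groups) {
    rate <- rowMeans(!is.na(dosage[, idx, drop = FALSE]))
    call_ok <- call_ok & rate >= params$min_call_rate_per_group
  }
  n_called <- rowSums(!is.na(dosage))
  het <- rowSums(dosage == 1L, na.rm = TRUE) / pmax(n_called, 1L)
  keep <- call_ok & n_called > 0 & het <= params$max_locus_heterozygosity
  if (!any(keep)) warn("no locus passed the filters; returning an empty matrix")
  out <- subset_geno(g, loci = which(keep))
  out$dosage[] <- dosage[keep, , drop = FALSE]
  out
}

#' Tag presence at a coverage threshold
#'
#' @param t A [tag_matrix()].
#' @param min_cov Minimum read depth for a tag to count as present
#'   (default 5).
#' @return A tags-by-samples logical matrix.
#' @export
tag_presence <- function(t, min_cov = 5L) {
  stopifnot(min_cov >= 1)
  t$depth >= min_cov
}
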