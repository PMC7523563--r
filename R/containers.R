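#' Genotype matrix container
#'
#' Bundles a loci-by-samples diploid dosage matrix (count of the designated
#' alternate allele, in `{0, 1, 2, NA}`) with a per-locus annotation table and
#' optionally a matching per-genotype read-depth matrix. This is the object
#' every scan and hybrid-zone function consumes; derived results come back as
#' tibbles.
#'
#' @param dosage Integer matrix, loci in rows, samples in columns. Entries
#'   must be 0, 1, 2 or `NA`. Row names are taken as locus ids when `loci` is
#'   missing; column names as sample ids.
#' @param loci Tibble with one row per locus: `locus_id`, `tag_id` (RAD tag of
#'   origin), `snp_index` (0-based position of the SNP within its tag),
#'   `ref`, `alt` (single characters). Generated if omitted.
#' @param samples Character vector of sample ids (defaults to column names).
#' @param depth Optional matrix of per-genotype read depths, same shape as
#'   `dosage`.
#'
#' @return An object of class `geno_matrix`: a list with elements `dosage`,
#'   `loci`, `samples` and (optionally) `depth`.
#' @export
geno_matrix <- function(dosage, loci = NULL, samples = NULL, depth = NULL) {
  dosage <- as.matrix(dosage)
  if (!all(dosage[!is.na(dosage)] %in% 0:2)) {
    abort("dosage entries must be 0, 1, 2 or NA")
  }
  storage.mode(dosage) <- "integer"
  if (is.null(samples)) samples <- colnames(dosage)
  if (is.null(samples)) samples <- sprintf("sample_%03d", seq_len(ncol(dosage)))
  if (anyDuplicated(samples)) abort("sample ids must be unique")
  if (is.null(loci)) {
    ids <- rownames(dosage)
    if (is.null(ids)) ids <- sprintf("locus_%05d", seq_len(nrow(dosage)))
    loci <- tibble(
      locus_id = ids, tag_id = ids, snp_index = 0L,
      ref = "A", alt = "T"
    )
  }
  loci <- as_tibble(loci)
  stopifnot(all(c("locus_id", "tag_id", "snp_index", "ref", "alt") %in% names(loci)))
  if (nrow(loci) != nrow(dosage)) abort("loci table and dosage rows disagree")
  if (length(samples) != ncol(dosage)) abort("samples and dosage columns disagree")
  if (anyDuplicated(loci$locus_id)) abort("locus ids must be unique")
  if (anyDuplicated(loci[, c("tag_id", "snp_index")])) {
    abort("(tag_id, snp_index) pairs must be unique")
  }
  dimnames(dosage) <- list(loci$locus_id, samples)
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    if (!identical(dim(depth), dim(dosage))) abort("depth must match dosage shape")
    dimnames(depth) <- dimnames(dosage)
  }
  structure(
    list(dosage = dosage, loci = loci, samples = samples, depth = depth),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d loci x %d samples (%.1f%% missing%s)\n",
    nrow(x$dosage), ncol(x$dosage),
    100 * mean(is.na(x$dosage)),
    if (is.null(x$depth)) "" else ", with depth"
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by loci and/or samples
#'
#' @param x A [geno_matrix()].
#' @param loci,samples Indices, logical masks or ids.
#' @return A `geno_matrix` restricted to the selection.
#' @export
subset_geno <- function(x, loci = NULL, samples = NULL) {
  li <- if (is.null(loci)) seq_len(nrow(x$dosage)) else loci
  if (is.character(li)) li <- match(li, x$loci$locus_id)
  si <- if (is.null(samples)) seq_len(ncol(x$dosage)) else samples
  if (is.character(si)) si <- match(si, x$samples)
  geno_matrix(
    x$dosage[li, si, drop = FALSE],
    loci = x$loci[li, , drop = FALSE],
    samples = x$samples[si],
    depth = if (is.null(x$depth)) NULL else x$depth[li, si, drop = FALSE]
  )
}

#' RAD-tag depth matrix container
#'
#' Unique RAD tags by samples, with non-negative integer read depths.
#' Presence/absence at a coverage threshold is derived with [tag_presence()].
#'
#' @param depth Integer matrix of read depths, tags in rows.
#' @param tags Tibble with `tag_id` and `sequence` (ACGT string), or a
#'   character vector of sequences. Generated ids if omitted.
#' @param samples Character vector of sample ids.
#' @return An object of class `tag_matrix`.
#' @export
tag_matrix <- function(depth, tags = NULL, samples = NULL) {
  depth <- as.matrix(depth)
  if (any(depth < 0, na.rm = TRUE)) abort("tag depths must be non-negative")
  storage.mode(depth) <- "integer"
  if (is.null(samples)) samples <- colnames(depth)
  if (is.null(samples)) samples <- sprintf("sample_%03d", seq_len(ncol(depth)))
  if (is.null(tags)) {
    ids <- rownames(depth)
    if (is.null(ids)) ids <- sprintf("tag_%06d", seq_len(nrow(depth)))
    tags <- tibble(tag_id = ids, sequence = NA_character_)
  } else if (is.character(tags)) {
    tags <- tibble(tag_id = sprintf("tag_%06d", seq_along(tags)), sequence = tags)
  }
  tags <- as_tibble(tags)
  stopifnot(all(c("tag_id", "sequence") %in% names(tags)))
  if (nrow(tags) != nrow(depth)) abort("tags table and depth rows disagree")
  if (anyDuplicated(tags$tag_id)) abort("tag ids must be unique")
  if (!all(is.na(tags$sequence)) && anyDuplicated(stats::na.omit(tags$sequence))) {
    abort("tag sequences must be unique")
  }
  dimnames(depth) <- list(tags$tag_id, samples)
  structure(
    list(depth = depth, tags = tags, samples = samples),
    class = "tag_matrix"
  )
}

#' @export
print.tag_matrix <- function(x, ...) {
  cat(sprintf("<tag_matrix> %d tags x %d samples\n", nrow(x$depth), ncol(x$depth)))
  invisible(x)
}

#' @export
dim.tag_matrix <- function(x) dim(x$depth)

#' Validate a sample metadata table
#'
#' Checks the per-sample metadata contract used throughout the package:
#' unique `sample_id`; `sex` in `{M, F, unknown}`; a single `distance_km`
#' (position along the transect, km from the northeastern end, increasing
#' southwestward) per `population_id`; `mitotype` in `{A, B, unknown}`
#' (A = northern taxon, B = southern taxon).
#'
#' @param meta A data frame with at least `sample_id` and `sex`; optional
#'   `population_id`, `distance_km`, `mitotype`, `species_label`.
#' @return The metadata as a tibble with missing optional columns filled.
#' @export
validate_meta <- function(meta) {
  meta <- as_tibble(meta)
  if (!all(c("sample_id", "sex") %in% names(meta))) {
    abort("metadata needs sample_id and sex columns")
  }
  if (anyDuplicated(meta$sample_id)) abort("sample_id must be unique")
  if (!all(meta$sex %in% c("M", "F", "unknown"))) {
    abort("sex must be one of 'M', 'F', 'unknown'")
  }
  if (!"population_id" %in% names(meta)) meta$population_id <- NA_character_
  if (!"distance_km" %in% names(meta)) meta$distance_km <- NA_real_
  if (!"mitotype" %in% names(meta)) meta$mitotype <- "unknown"
  if (!all(meta$mitotype %in% c("A", "B", "unknown"))) {
    abort("mitotype must be one of 'A', 'B', 'unknown'")
  }
  if (any(meta$distance_km < 0, na.rm = TRUE)) abort("distance_km must be >= 0")
  chk <- meta %>%
    filter(!is.na(.data$population_id)) %>%
    distinct(.data$population_id, .data$distance_km)
  if (anyDuplicated(chk$population_id)) {
    abort("each population must have a single distance_km")
  }
  meta
}

# sample indices per sex, in matrix column order; unknowns dropped
.sex_index <- function(samples, meta) {
  sex <- meta$sex[match(samples, meta$sample_id)]
  if (anyNA(sex)) abort("every sample needs a metadata row")
  list(M = which(sex == "M"), F = which(sex == "F"))
}
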