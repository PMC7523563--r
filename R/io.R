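#' Read a genotype matrix from TSV or VCF
#'
#' The TSV dialect is the package's canonical interchange format: a header
#' row, five annotation columns (`locus_id`, `tag_id`, `snp_index`, `ref`,
#' `alt`) followed by one column per sample, one locus per row, entries in
#' `{0, 1, 2}` with `NA` or `.` for missing. VCF support is read-only:
#' genotypes are converted to alternate-allele dosage, `./.` to missing, and
#' per-genotype depth is taken from the `DP` FORMAT field when present.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"vcf"`.
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  switch(format, tsv = .read_genotypes_tsv(path), vcf = .read_genotypes_vcf(path))
}

.read_genotypes_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        na = c("NA", "."), progress = FALSE)
  ann <- c("locus_id", "tag_id", "snp_index", "ref", "alt")
  if (!all(ann %in% names(df))) {
    abort(paste0("genotype TSV must start with columns: ", paste(ann, collapse = ", ")))
  }
  sample_cols <- setdiff(names(df), ann)
  if (length(sample_cols) == 0) abort("genotype TSV has no sample columns")
  gcols <- as.matrix(df[, sample_cols])
  bad <- !is.na(gcols) & !(gcols %in% c("0", "1", "2"))
  if (any(bad)) {
    row <- which(rowSums(bad) > 0)[1]
    abort(sprintf("malformed genotype entry at data line %d of %s", row, basename(path)))
  }
  dosage <- matrix(suppressWarnings(as.integer(gcols)), nrow = nrow(df))
  loci <- tibble(
    locus_id = df$locus_id, tag_id = df$tag_id,
    snp_index = as.integer(df$snp_index), ref = df$ref, alt = df$alt
  )
  geno_matrix(dosage, loci = loci, samples = sample_cols)
}

.read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  # tolerate phased separators; reject anything not diploid
  alleles <- gsub("\\|", "/", gt)
  parts <- strsplit(ifelse(is.na(alleles), "./.", alleles), "/", fixed = TRUE)
  n_alleles <- lengths(parts)
  if (any(n_alleles != 2)) {
    abort(sprintf("non-diploid genotype at VCF record %d",
                  which(rowSums(matrix(n_alleles != 2, nrow = nrow(gt))) > 0)[1]))
  }
  flat <- unlist(parts)
  if (!all(flat %in% c("0", "1", "."))) {
    abort("only biallelic records (alleles 0/1) are supported")
  }
  a <- matrix(flat[c(TRUE, FALSE)], nrow = nrow(gt))
  b <- matrix(flat[c(FALSE, TRUE)], nrow = nrow(gt))
  dosage <- (a == "1") + (b == "1")
  dosage[a == "." | b == "."] <- NA
  fix <- vcfR::getFIX(vcf)
  fix <- if (is.matrix(fix)) fix else matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], "_", fix[no_id, "POS"])
  loci <- tibble(
    locus_id = ids, tag_id = fix[, "CHROM"],
    snp_index = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"]
  )
  depth <- NULL
  if ("DP" %in% vcfR::vcf_field_names(vcf, tag = "FORMAT")$ID) {
    depth <- suppressWarnings(
      vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
    )
  }
  geno_matrix(dosage, loci = loci, samples = colnames(gt), depth = depth)
}

#' Write a genotype matrix to the canonical TSV dialect
#'
#' @param g A [geno_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  gm <- g$dosage
  df <- dplyr::bind_cols(
    g$loci[, c("locus_id", "tag_id", "snp_index", "ref", "alt")],
    as_tibble(as.data.frame(gm))
  )
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read/write sample metadata
#'
#' Tab-separated with columns `sample_id`, `sex`, `population_id`,
#' `distance_km`, `mitotype` (and optionally `species_label`).
#'
#' @param path Path to the TSV file.
#' @return A validated metadata tibble.
#' @export
read_meta <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_meta(df)
}

#' @rdname read_meta
#' @param meta Metadata tibble.
#' @export
write_meta <- function(meta, path) {
  readr::write_tsv(validate_meta(meta), path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a RAD-tag depth matrix
#'
#' Expects the layout produced by RadSex-style processing: columns `id` and
#' `sequence` followed by one depth column per sample.
#'
#' @param path Path to the TSV file.
#' @return A [tag_matrix()].
#' @export
read_tags <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("id", "sequence") %in% names(df))) {
    abort("tag depth TSV must have 'id' and 'sequence' columns")
  }
  sample_cols <- setdiff(names(df), c("id", "sequence"))
  depth <- as.matrix(df[, sample_cols])
  tag_matrix(depth, tags = tibble(tag_id = as.character(df$id), sequence = df$sequence),
             samples = sample_cols)
}

#' @rdname read_tags
#' @param t A [tag_matrix()].
#' @export
write_tags <- function(t, path) {
  df <- dplyr::bind_cols(
    tibble(id = t$tags$tag_id, sequence = t$tags$sequence),
    as_tibble(as.data.frame(t$depth))
  )
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a population allele-frequency table
#'
#' Tab-separated with columns `population_id`, `distance_km`, `n_alleles`,
#' `focal_allele_count` (optionally `locus_id` for per-locus stacks). Rows
#' are validated and returned sorted by transect distance.
#'
#' @param path Path to the TSV file.
#' @return A tibble sorted by `distance_km`, with a `frequency` column added.
#' @export
read_frequency_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_frequency_table(df)
}

#' @rdname read_frequency_table
#' @param freqs A frequency table.
#' @export
write_frequency_table <- function(freqs, path) {
  readr::write_tsv(freqs, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' @rdname read_frequency_table
#' @export
validate_frequency_table <- function(freqs) {
  freqs <- as_tibble(freqs)
  need <- c("population_id", "distance_km", "n_alleles", "focal_allele_count")
  if (!all(need %in% names(freqs))) {
    abort(paste0("frequency table needs columns: ", paste(need, collapse = ", ")))
  }
  if (any(freqs$n_alleles <= 0)) abort("n_alleles must be positive")
  bad <- freqs$focal_allele_count < 0 | freqs$focal_allele_count > freqs$n_alleles
  if (any(bad)) {
    abort(sprintf("focal_allele_count out of [0, n_alleles] for population '%s'",
                  freqs$population_id[which(bad)[1]]))
  }
  key <- if ("locus_id" %in% names(freqs)) c("locus_id", "population_id") else "population_id"
  if (anyDuplicated(freqs[, key, drop = FALSE])) {
    abort("one row per population (per marker) required")
  }
  freqs %>%
    mutate(frequency = .data$focal_allele_count / .data$n_alleles) %>%
    arrange(.data$distance_km)
}
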