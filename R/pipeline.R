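#' Read a pipeline configuration file
#'
#' A flat sectioned key-value format: `[section]` headers followed by
#' `key = value` lines. Values are coerced to numeric or logical where
#' possible; comma-separated values become vectors; dotted keys
#' (`true_cline.center = 184`) nest. Blank lines and `#` comments are
#' ignored.
#'
#' @param path Path to the config file.
#' @return A nested named list of sections.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[lines != ""]
  config <- list()
  section <- NULL
  coerce <- function(v) {
    v <- trimws(strsplit(v, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) return(num)
    if (all(v %in% c("TRUE", "FALSE"))) return(as.logical(v))
    v
  }
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(config[[section]])) config[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(section)) abort("key before any [section] header")
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- coerce(trimws(paste(kv[-1], collapse = "=")))
      keys <- c(section, strsplit(key, ".", fixed = TRUE)[[1]])
      config <- .assign_nested(config, keys, val)
    } else {
      abort(paste0("cannot parse config line: ", ln))
    }
  }
  config
}

.assign_nested <- function(lst, keys, val) {
  if (length(keys) == 1) {
    lst[[keys]] <- val
    return(lst)
  }
  if (is.null(lst[[keys[1]]])) lst[[keys[1]]] <- list()
  lst[[keys[1]]] <- .assign_nested(lst[[keys[1]]], keys[-1], val)
  lst
}

.cline_from_config <- function(cfg) {
  do.call(cline_model, cfg)
}

.manifest_file <- function(dir, file) {
  tibble(file = file, md5 = unname(tools::md5sum(file.path(dir, file))))
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the requested stages in a fixed order — `simulate_sexlink`,
#' `simulate_zone`, `scan`, `radsex`, `diagnostics`, `zone_stats`,
#' `clines` — writing each stage's outputs as TSV/JSON under the output
#' directory and a closing `manifest.json` listing every file with its MD5
#' hash, the seed, the package version and the full configuration, so a run
#' is self-describing and reproducible. Rerunning with an identical
#' configuration and seed reproduces identical outputs.
#'
#' @param config A nested list (or path to a [read_run_config()] file) with
#'   a `run` section (`seed`, `out_dir`, `stages`) and one section per
#'   requested stage holding its arguments.
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  run <- config$run %||% list()
  seed <- as.integer(run$seed %||% 1L)
  out_dir <- run$out_dir %||% abort("config needs run.out_dir")
  stages <- run$stages %||% character()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  order_all <- c("simulate_sexlink", "simulate_zone", "scan", "radsex",
                 "diagnostics", "zone_stats", "clines")
  unknown <- setdiff(stages, order_all)
  if (length(unknown) > 0) abort(paste0("unknown stage: ", unknown[1]))
  stages <- order_all[order_all %in% stages]

  state <- list()
  manifest_stages <- list()
  status <- "complete"
  failed_stage <- NULL

  for (stage in stages) {
    res <- tryCatch(
      .run_stage(stage, config[[stage]] %||% list(), state, seed, out_dir),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      status <- "partial"
      failed_stage <- list(stage = stage, error = conditionMessage(res))
      break
    }
    state <- res$state
    manifest_stages[[stage]] <- .manifest_file(out_dir, res$files)
  }

  manifest <- list(
    package = "radzone",
    version = as.character(utils::packageVersion("radzone")),
    seed = seed,
    status = status,
    failed_stage = failed_stage,
    stages = manifest_stages,
    config = config
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE, null = "null")
  invisible(manifest)
}

.run_stage <- function(stage, cfg, state, seed, out_dir) {
  files <- character()
  w <- function(fun, obj, file) {
    fun(obj, file.path(out_dir, file))
    files <<- c(files, file)
  }
  wjson <- function(obj, file) {
    jsonlite::write_json(obj, file.path(out_dir, file),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE, null = "null")
    files <<- c(files, file)
  }
  wtsv <- function(df, file) {
    readr::write_tsv(df, file.path(out_dir, file), na = "NA", progress = FALSE)
    files <<- c(files, file)
  }

  if (stage == "simulate_sexlink") {
    cfg$seed <- as.integer(cfg$seed %||% seed)
    sim <- do.call(simulate_sexlinked, cfg)
    state$sexlink <- sim
    w(write_genotypes, sim$genotypes, "sexlink_genotypes.tsv")
    w(write_tags, sim$tags, "sexlink_tags.tsv")
    w(write_meta, sim$meta, "sexlink_meta.tsv")
    wjson(sim$truth, "sexlink_truth.json")
  } else if (stage == "simulate_zone") {
    cfg$seed <- as.integer(cfg$seed %||% seed)
    cfg$true_cline <- .cline_from_config(cfg$true_cline)
    if (!is.null(cfg$mtdna_cline)) cfg$mtdna_cline <- .cline_from_config(cfg$mtdna_cline)
    sim <- do.call(simulate_zone, cfg)
    state$zone <- sim
    w(write_genotypes, sim$genotypes, "zone_genotypes.tsv")
    w(write_meta, sim$meta, "zone_meta.tsv")
    wtsv(sim$freqs, "zone_frequencies.tsv")
    wjson(
      list(
        shared_cline = unclass(sim$truth$shared_cline),
        per_locus = purrr::map(sim$truth$per_locus_clines, unclass)
      ),
      "zone_truth.json"
    )
  } else if (stage == "scan") {
    g <- state$sexlink$genotypes %||%
      (if (!is.null(cfg$genotypes_path)) read_genotypes(cfg$genotypes_path) else
        abort("scan stage needs simulate_sexlink or genotypes_path"))
    meta <- state$sexlink$meta %||% read_meta(cfg$meta_path)
    systems <- cfg$system %||% c("XY", "ZW")
    n_perm <- as.integer(cfg$n_permutations %||% 100L)
    report <- list()
    cands <- list()
    for (sys in systems) {
      for (method in intersect(cfg$methods %||% c("I", "II"), c("I", "II"))) {
        opt <- optimize_params(g, meta, sys, method,
                               n_permutations = n_perm, seed = seed)
        report[[paste0(sys, "_", method)]] <- list(
          none_found = opt$none_found,
          best = if (opt$none_found) NULL else unclass(opt$best),
          table = opt$table
        )
        if (!opt$none_found) {
          scan_fun <- if (method == "I") scan_method_I else scan_method_II
          cands[[paste0(sys, "_", method)]] <- scan_fun(g, meta, sys, opt$best)
        }
      }
    }
    state$scan_candidates <- dplyr::bind_rows(cands)
    wjson(report, "scan_report.json")
    wtsv(state$scan_candidates %||% tibble(), "scan_candidates.tsv")
  } else if (stage == "radsex") {
    tg <- state$sexlink$tags %||%
      (if (!is.null(cfg$tags_path)) read_tags(cfg$tags_path) else
        abort("radsex stage needs simulate_sexlink or tags_path"))
    meta <- state$sexlink$meta %||% read_meta(cfg$meta_path)
    pres <- tag_presence(tg, min_cov = as.integer(cfg$min_cov %||% 5L))
    wtsv(radsex_distribution(pres, meta), "radsex_distribution.tsv")
    wtsv(radsex_test(pres, meta, alpha = cfg$alpha %||% 0.05), "radsex_test.tsv")
  } else if (stage == "diagnostics") {
    g <- state$zone$genotypes %||% read_genotypes(cfg$genotypes_path)
    meta <- state$zone$meta %||% read_meta(cfg$meta_path)
    panel <- call_diagnostic_snps(
      g, meta,
      edge_pops_A = cfg$edge_pops_A %||% head(unique(meta$population_id), 1),
      edge_pops_B = cfg$edge_pops_B %||% utils::tail(unique(meta$population_id), 1),
      max_missing_in_edges = cfg$max_missing_in_edges %||% 0.1
    )
    state$panel <- panel
    wtsv(as_tibble(panel), "diagnostic_panel.tsv")
  } else if (stage == "zone_stats") {
    g <- state$zone$genotypes %||% abort("zone_stats needs a diagnostics/zone stage")
    meta <- state$zone$meta
    panel <- state$panel %||% abort("zone_stats needs the diagnostics stage")
    wtsv(hybrid_index(g, panel), "hybrid_indices.tsv")
    state$pop_summaries <- population_summaries(g, panel, meta)
    wtsv(state$pop_summaries, "population_summaries.tsv")
  } else if (stage == "clines") {
    freqs <- if (!is.null(state$zone)) state$zone$freqs else
      read_frequency_table(cfg$freqs_path)
    n_starts <- as.integer(cfg$n_starts %||% 20L)
    if (!is.null(state$pop_summaries)) {
      # mean-ancestry cline: effective alleles = 2 x individuals
      qf <- state$pop_summaries %>%
        mutate(
          n_alleles = 2L * .data$n,
          focal_allele_count = as.integer(round(.data$n_alleles * .data$mean_q))
        ) %>%
        select("population_id", "distance_km", "n_alleles", "focal_allele_count")
      sel <- model_select(qf, n_starts = n_starts, seed = seed, ci = FALSE)
      wjson(
        list(best_tails = sel$best_tails,
             best = as.list(tidy(sel$best) %>% select("term", "estimate")) ,
             table = sel$table),
        "ancestry_cline.json"
      )
    }
    if (isTRUE(cfg$per_locus %||% FALSE)) {
      fl <- fit_all_loci(freqs, tails = cfg$per_locus_tails %||% "both",
                         n_starts = as.integer(cfg$per_locus_starts %||% 10L),
                         seed = seed)
      wtsv(fl$table, "per_locus_clines.tsv")
      wtsv(fl$summary, "per_locus_summary.tsv")
    }
  }
  list(state = state, files = files)
}
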