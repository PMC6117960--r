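#' Run the differential-methylation pipeline end to end
#'
#' Orchestrates genome construction, intensity quantification, CpG-site
#' segmentation into methylation units, unit scoring, and iterative
#' events-exclusive permutation testing, writing all outputs plus a
#' provenance sidecar under `out_dir`.
#'
#' The input source is exactly one of:
#' \itemize{
#'   \item `config$generate`: arguments for [simulate_genome()] and
#'     [simulate_intensities()] (e.g. `n_promoters`, `depth`,
#'     `frac_planted`, `effect`); the planted truth is written alongside
#'     the calls.
#'   \item `config$files`: paths `sites_bed` (CpG sites), `profiles_tsv`
#'     (site-by-sample intensity matrix) and `samples_tsv` (sample sheet).
#' }
#' Analysis parameters live in `config$params` (any of `beta`, `L`,
#' `gap_threshold`, `corr_threshold`, `min_samples`, `n_perm`, `n_strata`,
#' `alpha0`, `max_iter`, `correction`, `null_mode`); unset entries take the
#' package defaults. `config$seed` drives every random draw.
#'
#' @param config A named list as described above (or a path to a YAML file
#'   holding one).
#' @param out_dir Output directory, created if needed. Files written:
#'   `units.bed`, `calls.tsv`, `iterations.tsv`, `config.yaml`, and
#'   `truth.tsv` for generated inputs. On error a `FAILED` marker file is
#'   left next to any partial outputs.
#' @return The [iterative_detect()] result, invisibly, with the unit table
#'   attached as attribute `"units"`.
#' @export
run_diffmeth <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!xor(is.null(config$generate), is.null(config$files))) {
    rlang::abort("config must have exactly one of 'generate' or 'files'")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  failed_marker <- file.path(out_dir, "FAILED")
  if (file.exists(failed_marker)) file.remove(failed_marker)

  p <- config$params %||% list()
  seed <- config$seed %||% 1

  tryCatch({
    truth <- NULL
    if (!is.null(config$generate)) {
      g <- config$generate
      genome <- simulate_genome(
        n_promoters = g$n_promoters %||% 100,
        mean_cpg = g$mean_cpg %||% 8,
        seed = seed)
      sim <- simulate_intensities(
        genome,
        samples_per_group = g$samples_per_group %||% 3,
        depth = g$depth %||% 50,
        dispersion = g$dispersion %||% 0.1,
        rho = g$rho %||% 0.8,
        frac_planted = g$frac_planted %||% 0,
        effect = g$effect %||% 4,
        noise = g$noise %||% "nb",
        seed = seed + 1)
      sites <- genome$sites
      profiles <- sim$profiles
      samples <- sim$samples
      truth <- sim$truth
    } else {
      f <- config$files
      sites <- read_bed(f$sites_bed, role = "cpg_site")
      profiles <- read_intensity_tsv(f$profiles_tsv)
      samples <- read_sample_sheet(f$samples_tsv)
    }
    assert_valid_regions(sites)

    units <- segment_methylation_units(
      sites, profiles,
      gap_threshold = p$gap_threshold %||% 300,
      corr_threshold = p$corr_threshold %||% 0.3,
      min_samples = p$min_samples %||% 4)
    umat <- unit_profiles(units, profiles)
    uregions <- dplyr::select(units, region_id = "unit_id", "role", "chrom",
                              "start", "end", "n_sites")

    fit <- iterative_detect(
      umat, samples, uregions,
      beta = p$beta %||% 10, L = p$L %||% 36,
      n_perm = p$n_perm %||% 1000, n_strata = p$n_strata %||% 5,
      alpha0 = p$alpha0 %||% 0.05, max_iter = p$max_iter %||% 10,
      seed = seed, correction = p$correction %||% "BH",
      null_mode = p$null_mode %||% "label_permutation")

    write_bed(dplyr::mutate(units, region_id = .data$unit_id, strand = "."),
              file.path(out_dir, "units.bed"))
    readr::write_tsv(fit$calls, file.path(out_dir, "calls.tsv"))
    readr::write_tsv(fit$iterations, file.path(out_dir, "iterations.tsv"))
    if (!is.null(truth)) {
      readr::write_tsv(
        dplyr::select(tidyr::unnest(truth, "site_ids"),
                      "block_id", site_id = "site_ids", "direction", "effect"),
        file.path(out_dir, "truth.tsv"))
    }
    yaml::write_yaml(
      list(pipeline = "diffmeth",
           package_version = as.character(utils::packageVersion("permeth")),
           seed = seed, config = config),
      file.path(out_dir, "config.yaml"))
    attr(fit, "units") <- units
    invisible(fit)
  }, error = function(e) {
    writeLines(conditionMessage(e), failed_marker)
    rlang::abort(paste0("diffmeth pipeline failed: ", conditionMessage(e)),
                 parent = e)
  })
}

#' Run the small-RNA differential-expression pipeline
#'
#' TPM normalization followed by the permutation significance test, with
#' outputs and a provenance sidecar written under `out_dir`. Input is
#' either `config$generate` (arguments for [simulate_smallrna()]) or
#' `config$files` with `counts_tsv` and `samples_tsv` (and optionally
#' `subtypes_tsv` with columns `feature_id`, `subtype`).
#'
#' @param config Named list (or YAML path): `generate` XOR `files`,
#'   optional `params` (`n_perm`, `alpha`), `seed`.
#' @param out_dir Output directory. Files written: `tpm.tsv`,
#'   `de_results.tsv`, `composition.tsv` (when subtypes are known),
#'   `config.yaml`, `truth.tsv` for generated input.
#' @return The differential-expression tibble, invisibly.
#' @export
run_smallrna <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!xor(is.null(config$generate), is.null(config$files))) {
    rlang::abort("config must have exactly one of 'generate' or 'files'")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  failed_marker <- file.path(out_dir, "FAILED")
  if (file.exists(failed_marker)) file.remove(failed_marker)

  p <- config$params %||% list()
  seed <- config$seed %||% 1

  tryCatch({
    truth <- NULL
    subtypes <- NULL
    if (!is.null(config$generate)) {
      g <- config$generate
      sim <- rlang::exec(simulate_smallrna,
                         !!!g[intersect(names(g),
                                        names(formals(simulate_smallrna)))],
                         seed = seed)
      counts <- sim$counts
      samples <- sim$samples
      subtypes <- sim$subtypes
      truth <- sim$truth
    } else {
      f <- config$files
      counts <- read_intensity_tsv(f$counts_tsv)
      names(counts)[1] <- "feature_id"
      samples <- read_sample_sheet(f$samples_tsv)
      if (!is.null(f$subtypes_tsv)) {
        subtypes <- readr::read_tsv(f$subtypes_tsv, col_types = "cc",
                                    show_col_types = FALSE)
      }
    }

    tpm <- tpm_normalize(counts)
    de <- permutation_de(tpm, samples,
                         n_perm = p$n_perm %||% 1000, seed = seed,
                         alpha = p$alpha %||% 0.05, subtypes = subtypes)

    readr::write_tsv(tpm, file.path(out_dir, "tpm.tsv"))
    readr::write_tsv(de, file.path(out_dir, "de_results.tsv"))
    if (!is.null(subtypes)) {
      readr::write_tsv(subtype_composition(counts, subtypes),
                       file.path(out_dir, "composition.tsv"))
    }
    if (!is.null(truth)) {
      readr::write_tsv(truth, file.path(out_dir, "truth.tsv"))
    }
    yaml::write_yaml(
      list(pipeline = "smallrna",
           package_version = as.character(utils::packageVersion("permeth")),
           seed = seed, config = config),
      file.path(out_dir, "config.yaml"))
    invisible(de)
  }, error = function(e) {
    writeLines(conditionMessage(e), failed_marker)
    rlang::abort(paste0("smallrna pipeline failed: ", conditionMessage(e)),
                 parent = e)
  })
}

#' Overlap between differential-methylation calls and a gene list
#'
#' Reports which genes appear both among significant promoter-level
#' methylation calls and in an external gene list (e.g. differentially
#' expressed small RNAs), with the methylation direction — the integration
#' check between methylation and expression results.
#'
#' @param calls A call tibble carrying `gene_id`, `direction`,
#'   `significant` (e.g. promoter calls joined with their gene ids).
#' @param gene_list Character vector of gene ids.
#' @return A list with `overlap` (tibble `gene_id`, `direction`) and
#'   `summary` (tibble with `n_calls`, `n_list`, `n_overlap`).
#' @export
overlap_report <- function(calls, gene_list) {
  calls <- tibble::as_tibble(calls)
  sig <- calls[calls$significant, , drop = FALSE]
  overlap <- sig[sig$gene_id %in% gene_list, c("gene_id", "direction")]
  list(
    overlap = tibble::as_tibble(overlap),
    summary = tibble::tibble(
      n_calls = nrow(sig),
      n_list = length(unique(gene_list)),
      n_overlap = nrow(overlap)
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
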