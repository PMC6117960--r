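#' Read a BED (3- or 6-column) file as a region tibble
#'
#' BED coordinates are 0-based half-open and kept that way internally.
#'
#' @param path Path to a tab-separated BED file without header.
#' @param role Role tag to assign to the regions (default `"interval"`).
#' @return A tibble with columns `chrom`, `start`, `end` and, when present,
#'   `region_id` (BED name), `score`, `strand`, plus `role`.
#' @export
read_bed <- function(path, role = "interval") {
  first <- readr::read_tsv(path, col_names = FALSE, n_max = 1,
                           show_col_types = FALSE)
  ncol_bed <- ncol(first)
  nm <- c("chrom", "start", "end", "region_id", "score", "strand")[seq_len(ncol_bed)]
  bed <- readr::read_tsv(path, col_names = nm, show_col_types = FALSE,
                         col_types = readr::cols(
                           chrom = readr::col_character(),
                           start = readr::col_double(),
                           end = readr::col_double(),
                           .default = readr::col_guess()
                         ))
  bed$role <- role
  tibble::as_tibble(bed)
}

#' Write regions as BED
#'
#' Writes 6 columns when `region_id` and `strand` are available, otherwise 3.
#'
#' @param regions Region tibble with `chrom`, `start`, `end` and optionally
#'   `region_id`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  regions <- tibble::as_tibble(regions)
  if (all(c("region_id", "strand") %in% names(regions))) {
    out <- tibble::tibble(
      chrom = regions$chrom,
      start = format(regions$start, scientific = FALSE, trim = TRUE),
      end = format(regions$end, scientific = FALSE, trim = TRUE),
      name = regions$region_id,
      score = if ("score" %in% names(regions)) regions$score else 0,
      strand = regions$strand
    )
  } else {
    out <- tibble::tibble(
      chrom = regions$chrom,
      start = format(regions$start, scientific = FALSE, trim = TRUE),
      end = format(regions$end, scientific = FALSE, trim = TRUE)
    )
  }
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a TSS table
#'
#' Expects a header row and columns `gene_id`, `chrom`, `strand`, `tss`,
#' `exon1_start`, `exon1_end`; coordinates 0-based half-open.
#'
#' @param path Path to a TSV file.
#' @return A tibble, one row per gene.
#' @export
read_tss_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    gene_id = readr::col_character(),
                    chrom = readr::col_character(),
                    strand = readr::col_character(),
                    .default = readr::col_double()
                  ))
}

#' Read chromosome sizes (two-column TSV: chrom, size)
#' @param path Path to a headerless two-column TSV.
#' @return A tibble with columns `chrom`, `size`.
#' @export
read_chrom_sizes <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "size"),
                  col_types = "cd", show_col_types = FALSE)
}

#' Read an intensity (or count) matrix TSV
#'
#' First column is the feature/region id, remaining columns one per sample,
#' with a header row of sample ids.
#'
#' @param path Path to a TSV file.
#' @return A wide tibble; first column renamed `region_id`.
#' @export
read_intensity_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  names(x)[1] <- "region_id"
  tibble::as_tibble(x)
}

#' Write a wide intensity/count tibble as TSV
#' @param x Wide tibble whose first column is the feature/region id.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intensity_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read a sample sheet (sample_id, group)
#' @param path Path to a TSV with header columns `sample_id` and `group`.
#' @return A tibble with columns `sample_id`, `group`.
#' @export
read_sample_sheet <- function(path) {
  readr::read_tsv(path, col_types = "cc", show_col_types = FALSE)
}
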