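#' Regional methylation intensity from aligned reads
#'
#' The methylation intensity of a region is the total number of read bases
#' falling inside it: each read contributes the length of its intersection
#' with the region, clipped at the region boundary. A region with no
#' overlapping reads has intensity 0.
#'
#' @param reads Read intervals: a data frame with columns `chrom`, `start`,
#'   `end` (0-based half-open) for one sample.
#' @param regions Region tibble with `region_id`, `chrom`, `start`, `end`.
#' @return A tibble with columns `region_id`, `intensity` (bases), in the
#'   region input order.
#' @examples
#' reads <- tibble::tibble(chrom = "chr1", start = 100, end = 136)
#' regions <- tibble::tibble(region_id = "r1", chrom = "chr1",
#'                           start = 0, end = 1000)
#' region_intensity(reads, regions) # 36 bases
#' @export
region_intensity <- function(reads, regions) {
  reads <- tibble::as_tibble(reads)
  regions <- tibble::as_tibble(regions)
  if (nrow(reads) > 0 && any(reads$end <= reads$start)) {
    rlang::abort("reads with non-positive length are not allowed")
  }
  intensity <- rep(0, nrow(regions))
  if (nrow(reads) > 0 && nrow(regions) > 0) {
    # GRanges are 1-based closed; shift starts by +1 going in
    gr_reads <- GenomicRanges::GRanges(
      reads$chrom, IRanges::IRanges(reads$start + 1, reads$end))
    gr_regions <- GenomicRanges::GRanges(
      regions$chrom, IRanges::IRanges(regions$start + 1, regions$end))
    hits <- GenomicRanges::findOverlaps(gr_reads, gr_regions)
    if (length(hits) > 0) {
      ov <- GenomicRanges::pintersect(
        gr_reads[S4Vectors::queryHits(hits)],
        gr_regions[S4Vectors::subjectHits(hits)])
      per_hit <- GenomicRanges::width(ov)
      sums <- tapply(per_hit, S4Vectors::subjectHits(hits), sum)
      intensity[as.integer(names(sums))] <- as.numeric(sums)
    }
  }
  tibble::tibble(region_id = regions$region_id, intensity = intensity)
}

#' Assemble a region-by-sample intensity matrix
#'
#' @param reads Read intervals for all samples: a data frame with columns
#'   `chrom`, `start`, `end`, `sample_id`.
#' @param regions Region tibble with `region_id`, `chrom`, `start`, `end`.
#' @param samples Sample sheet: data frame with `sample_id` and `group`
#'   (`"case"` / `"control"`); fixes the column order of the result.
#' @return A wide tibble: `region_id` plus one intensity column per sample,
#'   rows in region input order, columns in sample-sheet order. Samples with
#'   zero reads yield an all-zero column with a warning.
#' @export
build_intensity_matrix <- function(reads, regions, samples) {
  reads <- tibble::as_tibble(reads)
  samples <- tibble::as_tibble(samples)
  stopifnot(all(c("sample_id", "group") %in% names(samples)))
  if (length(unique(samples$group)) < 2) {
    rlang::abort("need at least one sample in each of two groups")
  }
  empty <- setdiff(samples$sample_id, unique(reads$sample_id))
  if (length(empty) > 0) {
    rlang::warn(paste0("sample(s) with zero reads: ",
                       paste(empty, collapse = ", ")))
  }
  cols <- purrr::map(samples$sample_id, function(s) {
    region_intensity(reads[reads$sample_id == s, , drop = FALSE],
                     regions)$intensity
  })
  names(cols) <- samples$sample_id
  dplyr::bind_cols(
    tibble::tibble(region_id = tibble::as_tibble(regions)$region_id),
    tibble::as_tibble(cols)
  )
}

#' Group-mean intensities per region
#'
#' Averages intensities across replicates within each group, yielding the
#' per-region case and control intensities the fold-change is computed from.
#' The mean (rather than the sum) keeps fold-changes comparable across
#' unequal replicate counts.
#'
#' @param mat Wide intensity tibble (`region_id` + sample columns), as from
#'   [build_intensity_matrix()].
#' @param samples Sample sheet with `sample_id`, `group`.
#' @return A tibble with columns `region_id`, `I_case`, `I_control`.
#' @export
aggregate_groups <- function(mat, samples) {
  samples <- tibble::as_tibble(samples)
  case_ids <- samples$sample_id[samples$group == "case"]
  ctrl_ids <- samples$sample_id[samples$group == "control"]
  if (length(case_ids) == 0 || length(ctrl_ids) == 0) {
    rlang::abort("both groups must be non-empty")
  }
  m <- as.matrix(mat[, samples$sample_id, drop = FALSE])
  tibble::tibble(
    region_id = mat$region_id,
    I_case = rowMeans(m[, case_ids, drop = FALSE]),
    I_control = rowMeans(m[, ctrl_ids, drop = FALSE])
  )
}
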