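#' Construct promoter regions from a TSS table
#'
#' A promoter is the window extending `upstream_bp` bases upstream of the
#' transcription start site (TSS), optionally extended through the first
#' exon — methylation in these two regions correlates most strongly with
#' reduced expression, which is why capture-based methylation studies score
#' them as a unit. On the plus strand the promoter is
#' `[TSS - upstream_bp, exon1_end)`; on the minus strand it is the mirror
#' image `[exon1_start, TSS + upstream_bp)`. Windows are clipped to
#' chromosome bounds.
#'
#' All coordinates are 0-based half-open (BED convention). On the plus
#' strand `tss` is the first transcribed base (equal to `exon1_start`); on
#' the minus strand it is the half-open boundary one past the 5'-most base
#' (equal to `exon1_end`), so mirroring a gene mirrors its promoter exactly.
#'
#' @param tss A data frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"` or `"-"`), `tss`, `exon1_start`, `exon1_end`, one row per gene.
#' @param chrom_sizes A data frame with columns `chrom`, `size`.
#' @param upstream_bp Bases upstream of the TSS to include (default 5000).
#' @param include_first_exon Extend the window through the first exon
#'   (default `TRUE`).
#' @return A tibble of promoter regions with columns `region_id`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `role` (`"promoter"`). Records on
#'   unknown chromosomes or whose first exon lies on the wrong side of the
#'   TSS are dropped with a warning.
#' @examples
#' tss <- tibble::tibble(
#'   gene_id = "g1", chrom = "chr1", strand = "+",
#'   tss = 10000, exon1_start = 10000, exon1_end = 10200
#' )
#' sizes <- tibble::tibble(chrom = "chr1", size = 1e6)
#' define_promoters(tss, sizes)
#' @export
define_promoters <- function(tss, chrom_sizes, upstream_bp = 5000,
                             include_first_exon = TRUE) {
  stopifnot(upstream_bp > 0)
  req <- c("gene_id", "chrom", "strand", "tss", "exon1_start", "exon1_end")
  missing_cols <- setdiff(req, names(tss))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("tss table lacks columns: ",
                        paste(missing_cols, collapse = ", ")))
  }

  tss <- dplyr::left_join(tibble::as_tibble(tss),
                          dplyr::select(tibble::as_tibble(chrom_sizes),
                                        "chrom", "size"),
                          by = "chrom")

  bad_chrom <- is.na(tss$size)
  if (any(bad_chrom)) {
    rlang::warn(paste0(sum(bad_chrom), " gene(s) on unknown chromosomes dropped: ",
                       paste(utils::head(tss$gene_id[bad_chrom], 5), collapse = ", ")))
    tss <- tss[!bad_chrom, ]
  }

  # exon1 must sit downstream of (or abut) the TSS on the transcribed strand;
  # on the minus strand the TSS is the half-open boundary, so exon1_end <= tss
  wrong_side <- ifelse(tss$strand == "+",
                       tss$exon1_start < tss$tss,
                       tss$exon1_end > tss$tss)
  wrong_side <- wrong_side | tss$exon1_start >= tss$exon1_end
  if (any(wrong_side)) {
    rlang::warn(paste0(sum(wrong_side),
                       " gene(s) with first exon on the wrong side of the TSS dropped"))
    tss <- tss[!wrong_side, ]
  }

  # On the plus strand the TSS is the first transcribed base; on the minus
  # strand it is the half-open boundary one past the 5'-most base, so the
  # upstream window is [tss - upstream, tss) on + and [tss, tss + upstream)
  # on -.
  plus <- tss$strand == "+"
  if (include_first_exon) {
    start <- ifelse(plus, pmax(0, tss$tss - upstream_bp), tss$exon1_start)
    end <- ifelse(plus, tss$exon1_end, pmin(tss$size, tss$tss + upstream_bp))
  } else {
    start <- ifelse(plus, pmax(0, tss$tss - upstream_bp), tss$tss)
    end <- ifelse(plus, tss$tss, pmin(tss$size, tss$tss + upstream_bp))
  }

  tibble::tibble(
    region_id = paste0("prom_", tss$gene_id),
    gene_id = tss$gene_id,
    chrom = tss$chrom,
    start = as.numeric(start),
    end = as.numeric(end),
    strand = tss$strand,
    role = "promoter"
  )
}

#' Validate a set of genomic regions
#'
#' Report-only structural checks run before any scoring: duplicate region
#' ids, zero- or negative-length regions, negative coordinates, and (when
#' `chrom_sizes` is given) regions overrunning chromosome ends. Pipelines
#' refuse to proceed when the report is non-empty.
#'
#' @param regions A data frame with columns `region_id`, `chrom`, `start`,
#'   `end`.
#' @param chrom_sizes Optional data frame with columns `chrom`, `size`.
#' @return A tibble with columns `region_id`, `problem`; zero rows when the
#'   set is well formed.
#' @export
validate_regions <- function(regions, chrom_sizes = NULL) {
  regions <- tibble::as_tibble(regions)
  findings <- list()

  dup <- regions$region_id[duplicated(regions$region_id)]
  if (length(dup) > 0) {
    findings <- c(findings, list(tibble::tibble(
      region_id = unique(dup), problem = "duplicate_id"
    )))
  }
  zl <- regions$start >= regions$end
  if (any(zl)) {
    findings <- c(findings, list(tibble::tibble(
      region_id = regions$region_id[zl], problem = "zero_or_negative_length"
    )))
  }
  neg <- regions$start < 0
  if (any(neg)) {
    findings <- c(findings, list(tibble::tibble(
      region_id = regions$region_id[neg], problem = "negative_coordinate"
    )))
  }
  if (!is.null(chrom_sizes)) {
    joined <- dplyr::left_join(regions, tibble::as_tibble(chrom_sizes),
                               by = "chrom")
    oob <- !is.na(joined$size) & joined$end > joined$size
    unk <- is.na(joined$size)
    if (any(oob)) {
      findings <- c(findings, list(tibble::tibble(
        region_id = regions$region_id[oob], problem = "beyond_chromosome_end"
      )))
    }
    if (any(unk)) {
      findings <- c(findings, list(tibble::tibble(
        region_id = regions$region_id[unk], problem = "unknown_chromosome"
      )))
    }
  }
  if (length(findings) == 0) {
    return(tibble::tibble(region_id = character(), problem = character()))
  }
  dplyr::bind_rows(findings)
}

#' Stop unless a region set validates cleanly
#' @noRd
assert_valid_regions <- function(regions, chrom_sizes = NULL) {
  report <- validate_regions(regions, chrom_sizes)
  if (nrow(report) > 0) {
    rlang::abort(paste0(
      "invalid region set: ", nrow(report), " finding(s), e.g. ",
      report$region_id[1], " [", report$problem[1], "]"
    ))
  }
  invisible(regions)
}
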