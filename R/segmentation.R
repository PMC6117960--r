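#' Merge nearby CpG sites into methylation intervals
#'
#' Single greedy pass along each chromosome: a new interval starts whenever
#' the gap from the previous CpG site exceeds `gap_threshold`, leaving the
#' stretches of no or minimal CpG density as separators. The interval span
#' runs from the first member site's start to the last member site's end.
#'
#' @param sites CpG-site tibble with `region_id`, `chrom`, `start`, `end`
#'   (each site 1 bp wide), sorted by (`chrom`, `start`) and unique; unsorted
#'   input is rejected.
#' @param gap_threshold Maximum gap in bp between consecutive member sites
#'   (default 300).
#' @return An interval tibble: `interval_id`, `chrom`, `start`, `end`,
#'   `role` (`"interval"`), `n_sites`, and a list-column `site_ids` of the
#'   member site ids in coordinate order.
#' @export
merge_cpg_sites <- function(sites, gap_threshold = 300) {
  stopifnot(gap_threshold > 0)
  sites <- tibble::as_tibble(sites)
  if (nrow(sites) == 0) {
    return(tibble::tibble(interval_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          role = character(), n_sites = integer(),
                          site_ids = list()))
  }
  ord <- order(sites$chrom, sites$start)
  if (!identical(ord, seq_len(nrow(sites)))) {
    rlang::abort("sites must be sorted by (chrom, start); sort before calling")
  }
  if (anyDuplicated(sites[, c("chrom", "start")]) > 0) {
    rlang::abort("duplicate site coordinates")
  }
  new_chrom <- c(TRUE, sites$chrom[-1] != sites$chrom[-nrow(sites)])
  gap <- c(Inf, sites$start[-1] - sites$end[-nrow(sites)])
  interval_index <- cumsum(new_chrom | gap > gap_threshold)

  sites |>
    dplyr::mutate(.iv = interval_index) |>
    dplyr::group_by(.data$.iv) |>
    dplyr::summarise(
      chrom = dplyr::first(.data$chrom),
      start = min(.data$start),
      end = max(.data$end),
      n_sites = dplyr::n(),
      site_ids = list(.data$region_id),
      .groups = "drop"
    ) |>
    dplyr::mutate(interval_id = sprintf("iv_%05d", .data$.iv),
                  role = "interval") |>
    dplyr::select("interval_id", "chrom", "start", "end", "role",
                  "n_sites", "site_ids")
}

#' Pearson correlations between adjacent CpG sites of an interval
#'
#' For each consecutive pair of member sites, the Pearson correlation of
#' their intensity profiles across all samples (both groups pooled, so the
#' segmentation is blind to group labels). A pair in which either profile
#' has zero variance is assigned correlation 0 — treated as uncorrelated
#' rather than propagating an undefined value.
#'
#' @param site_ids Character vector of member site ids in coordinate order.
#' @param profiles Wide intensity tibble (`region_id` + sample columns)
#'   covering at least the member sites.
#' @param min_samples Minimum number of samples required (default 4).
#' @return A tibble with columns `site_a`, `site_b`, `r`, one row per
#'   adjacent pair (zero rows for a single-site interval).
#' @export
adjacent_correlations <- function(site_ids, profiles, min_samples = 4) {
  profiles <- tibble::as_tibble(profiles)
  sample_cols <- setdiff(names(profiles), "region_id")
  if (length(sample_cols) < min_samples) {
    rlang::abort(paste0("need at least ", min_samples,
                        " samples to estimate site correlations"))
  }
  m <- as.matrix(profiles[match(site_ids, profiles$region_id), sample_cols,
                          drop = FALSE])
  if (anyNA(m)) rlang::abort("missing profiles for some member sites")
  if (length(site_ids) < 2) {
    return(tibble::tibble(site_a = character(), site_b = character(),
                          r = numeric()))
  }
  a <- m[-nrow(m), , drop = FALSE]
  b <- m[-1, , drop = FALSE]
  sd_a <- apply(a, 1, stats::sd)
  sd_b <- apply(b, 1, stats::sd)
  r <- rep(0, nrow(a))
  ok <- sd_a > 0 & sd_b > 0
  if (any(ok)) {
    r[ok] <- purrr::map_dbl(which(ok), function(i) stats::cor(a[i, ], b[i, ]))
  }
  tibble::tibble(site_a = site_ids[-length(site_ids)],
                 site_b = site_ids[-1],
                 r = r)
}

#' Split a methylation interval into methylation units
#'
#' Breaks the interval at every adjacent-site pair whose correlation falls
#' below `corr_threshold`; the resulting units are the maximal runs of
#' member sites joined by correlations at or above the threshold, so each
#' unit contains a subset of highly correlated nearby CpG sites. A
#' single-site interval yields one single-site unit. With
#' `mode = "local_minima"` cuts are instead placed only at strict local
#' minima of the correlation sequence that also fall below the threshold
#' (sensitivity-analysis variant).
#'
#' @param interval One row of the tibble from [merge_cpg_sites()] (or any
#'   list with `interval_id`, `chrom`, `site_ids`).
#' @param correlations Tibble from [adjacent_correlations()] for the same
#'   member sites.
#' @param sites CpG-site tibble giving `region_id`, `start`, `end` for the
#'   member sites (used for unit spans).
#' @param corr_threshold Minimum adjacent correlation to remain joined
#'   (default 0.3).
#' @param mode `"threshold"` (default) or `"local_minima"`.
#' @return A unit tibble: `unit_id`, `interval_id`, `chrom`, `start`, `end`,
#'   `role` (`"unit"`), `n_sites`, `site_ids` (list-column). The units
#'   partition the interval's member sites in order.
#' @export
split_units <- function(interval, correlations, sites, corr_threshold = 0.3,
                        mode = c("threshold", "local_minima")) {
  mode <- match.arg(mode)
  stopifnot(corr_threshold >= -1, corr_threshold <= 1)
  site_ids <- interval$site_ids
  if (is.list(site_ids) && !is.character(site_ids)) site_ids <- site_ids[[1]]
  n <- length(site_ids)
  sites <- tibble::as_tibble(sites)

  if (n == 1) {
    cut_after <- logical(0)
  } else {
    stopifnot(nrow(correlations) == n - 1)
    r <- correlations$r
    if (mode == "threshold") {
      cut_after <- r < corr_threshold
    } else {
      is_min <- purrr::map_lgl(seq_along(r), function(i) {
        left_ok <- i == 1 || r[i] < r[i - 1]
        right_ok <- i == length(r) || r[i] < r[i + 1]
        left_ok && right_ok
      })
      cut_after <- is_min & r < corr_threshold
    }
  }
  unit_index <- cumsum(c(TRUE, cut_after))

  pos <- sites[match(site_ids, sites$region_id), ]
  tibble::tibble(site_id = site_ids, .u = unit_index,
                 start = pos$start, end = pos$end) |>
    dplyr::group_by(.data$.u) |>
    dplyr::summarise(
      start = min(.data$start),
      end = max(.data$end),
      n_sites = dplyr::n(),
      site_ids = list(.data$site_id),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      unit_id = paste0(interval$interval_id, "_u", .data$.u),
      interval_id = interval$interval_id,
      chrom = interval$chrom,
      role = "unit"
    ) |>
    dplyr::select("unit_id", "interval_id", "chrom", "start", "end", "role",
                  "n_sites", "site_ids")
}

#' Segment CpG sites into methylation units
#'
#' End-to-end segmentation: merge sites into intervals by gap, estimate
#' adjacent-site correlations across all samples, and split each interval
#' at break points of sub-threshold correlation.
#'
#' @param sites CpG-site tibble (`region_id`, `chrom`, `start`, `end`),
#'   sorted and unique.
#' @param profiles Wide per-site intensity tibble (`region_id` + sample
#'   columns).
#' @param gap_threshold Merge gap in bp (default 300).
#' @param corr_threshold Break threshold on adjacent correlation
#'   (default 0.3).
#' @param min_samples Minimum samples for correlation (default 4).
#' @param mode Break rule passed to [split_units()].
#' @return A unit tibble as from [split_units()], over all intervals, with
#'   the interval table attached as attribute `"intervals"`.
#' @export
segment_methylation_units <- function(sites, profiles, gap_threshold = 300,
                                      corr_threshold = 0.3, min_samples = 4,
                                      mode = "threshold") {
  intervals <- merge_cpg_sites(sites, gap_threshold = gap_threshold)
  units <- purrr::map(seq_len(nrow(intervals)), function(i) {
    iv <- intervals[i, ]
    ids <- iv$site_ids[[1]]
    corr <- adjacent_correlations(ids, profiles, min_samples = min_samples)
    split_units(iv, corr, sites, corr_threshold = corr_threshold, mode = mode)
  })
  out <- dplyr::bind_rows(units)
  attr(out, "intervals") <- intervals
  out
}

#' Sum per-site intensity profiles into unit-level profiles
#'
#' A unit's intensity in a sample is the summed intensity of its member CpG
#' sites, so units inherit the base-count scale of the sites.
#'
#' @param units Unit tibble with `unit_id` and `site_ids` list-column.
#' @param profiles Wide per-site intensity tibble.
#' @return Wide tibble: `region_id` (= unit id) + sample columns.
#' @export
unit_profiles <- function(units, profiles) {
  profiles <- tibble::as_tibble(profiles)
  sample_cols <- setdiff(names(profiles), "region_id")
  m <- as.matrix(profiles[, sample_cols, drop = FALSE])
  rownames(m) <- profiles$region_id
  rows <- purrr::map(units$site_ids, function(ids) {
    colSums(m[ids, , drop = FALSE])
  })
  out <- tibble::as_tibble(do.call(rbind, rows))
  dplyr::bind_cols(tibble::tibble(region_id = units$unit_id), out)
}
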