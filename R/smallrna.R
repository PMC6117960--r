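#' TPM-normalize a small-RNA count table
#'
#' Transcripts per kilobase million: each feature's count is divided by its
#' length in kilobases, and the per-sample rates are rescaled to sum to one
#' million. When no lengths are supplied every feature is treated as 1 kb,
#' which reduces TPM to counts per million — appropriate for small-RNA
#' subtypes (miRNA, tRF) whose lengths are near-constant.
#'
#' @param counts Wide count tibble: `feature_id` plus one integer column per
#'   sample.
#' @param lengths Optional tibble with `feature_id`, `length_nt`.
#' @return A tibble of the same shape with TPM values; samples with zero
#'   total count are dropped with a warning. Each retained column sums to
#'   1e6.
#' @examples
#' counts <- tibble::tibble(feature_id = c("a", "b"), s1 = c(5L, 15L))
#' tpm_normalize(counts) # 250000, 750000
#' @export
tpm_normalize <- function(counts, lengths = NULL) {
  counts <- tibble::as_tibble(counts)
  sample_cols <- setdiff(names(counts), "feature_id")
  m <- as.matrix(counts[, sample_cols, drop = FALSE])
  if (any(m < 0) || any(m != round(m))) {
    rlang::abort("counts must be nonnegative integers")
  }
  kb <- if (is.null(lengths)) {
    rep(1, nrow(counts))
  } else {
    lengths <- tibble::as_tibble(lengths)
    l <- lengths$length_nt[match(counts$feature_id, lengths$feature_id)]
    if (anyNA(l)) rlang::abort("missing lengths for some features")
    l / 1000
  }
  rate <- m / kb
  totals <- colSums(rate)
  zero <- totals == 0
  if (any(zero)) {
    rlang::warn(paste0("dropping zero-total sample(s): ",
                       paste(sample_cols[zero], collapse = ", ")))
    rate <- rate[, !zero, drop = FALSE]
    totals <- totals[!zero]
    sample_cols <- sample_cols[!zero]
  }
  tpm <- sweep(rate, 2, totals, "/") * 1e6
  dplyr::bind_cols(tibble::tibble(feature_id = counts$feature_id),
                   tibble::as_tibble(tpm))
}

#' Permutation test for differential small-RNA expression
#'
#' Per feature, the statistic is the difference of group means of
#' `log2(TPM + 1)`. Two-sided significance comes from permuting group
#' labels: exact enumeration of all distinct assignments whenever their
#' number does not exceed `n_perm` (p is then the exact tail fraction, with
#' a 3v3 design bottoming out at 2/20), otherwise `n_perm` sampled
#' assignments with the add-one estimator. Benjamini–Hochberg q-values
#' follow; features with `q < 0.05` are flagged significant. A feature
#' constant across all samples gets `p = 1`.
#'
#' @param tpm Wide TPM tibble (`feature_id` + sample columns), as from
#'   [tpm_normalize()].
#' @param samples Sample sheet with `sample_id`, `group`
#'   (`"case"`/`"control"`); at least 2 samples per group.
#' @param n_perm Permutations (default 1000).
#' @param seed RNG seed (default 1).
#' @param alpha Significance threshold on q (default 0.05).
#' @param subtypes Optional tibble with `feature_id`, `subtype`, carried
#'   through to the result.
#' @return A tibble: `feature_id`, (`subtype`), `log2FC`, `p`, `q`,
#'   `significant`.
#' @export
permutation_de <- function(tpm, samples, n_perm = 1000, seed = 1,
                           alpha = 0.05, subtypes = NULL) {
  samples <- tibble::as_tibble(samples)
  n_case <- sum(samples$group == "case")
  n_ctrl <- sum(samples$group == "control")
  if (n_case < 2 || n_ctrl < 2) {
    rlang::abort("need at least 2 samples per group")
  }
  m <- log2(as.matrix(tpm[, samples$sample_id, drop = FALSE]) + 1)

  assignments <- label_assignments(nrow(samples), n_case,
                                   n_perm = n_perm, seed = seed)
  w_case <- sweep(assignments, 2, colSums(assignments), "/")
  ctrl <- !assignments
  w_ctrl <- sweep(ctrl, 2, colSums(ctrl), "/")
  perm_stat <- m %*% w_case - m %*% w_ctrl

  obs_case <- samples$group == "case"
  obs <- rowMeans(m[, obs_case, drop = FALSE]) -
    rowMeans(m[, !obs_case, drop = FALSE])

  n_assign <- ncol(assignments)
  exceed <- rowSums(abs(perm_stat) >= abs(obs) - 1e-12)
  # exact p under full enumeration (the observed labeling is in the set, so
  # exceed >= 1); add-one correction when assignments are sampled
  p <- if (isTRUE(attr(assignments, "enumerated"))) {
    pmin(1, exceed / n_assign)
  } else {
    pmin(1, (1 + exceed) / (1 + n_assign))
  }
  constant <- apply(m, 1, function(x) max(x) - min(x) == 0)
  p[constant] <- 1

  out <- tibble::tibble(
    feature_id = tpm$feature_id,
    log2FC = obs,
    p = p,
    q = correct_multiple(p)
  )
  out$significant <- out$q < alpha
  if (!is.null(subtypes)) {
    out <- dplyr::left_join(out, tibble::as_tibble(subtypes), by = "feature_id")
    out <- dplyr::relocate(out, "feature_id", "subtype")
  }
  out
}

#' Per-sample subtype composition of a small-RNA library
#'
#' The fraction of total counts assigned to each small-RNA subtype (miRNA,
#' tRF, piRNA, rRNA, other) per sample; fractions sum to 1. Sperm libraries
#' are typically tRF-dominant, somatic tissue miRNA-dominant.
#'
#' @param counts Wide count tibble (`feature_id` + sample columns).
#' @param subtypes Tibble with `feature_id`, `subtype`.
#' @return A long tibble: `sample_id`, `subtype`, `fraction`.
#' @export
subtype_composition <- function(counts, subtypes) {
  counts <- tibble::as_tibble(counts)
  long <- tidyr::pivot_longer(counts, -"feature_id",
                              names_to = "sample_id", values_to = "count")
  long <- dplyr::left_join(long, tibble::as_tibble(subtypes), by = "feature_id")
  totals <- dplyr::summarise(dplyr::group_by(long, .data$sample_id),
                             total = sum(.data$count), .groups = "drop")
  if (any(totals$total == 0)) rlang::abort("sample with zero total count")
  long |>
    dplyr::group_by(.data$sample_id, .data$subtype) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::left_join(totals, by = "sample_id") |>
    dplyr::mutate(fraction = .data$count / .data$total) |>
    dplyr::select("sample_id", "subtype", "fraction")
}
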