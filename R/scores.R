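#' Offset fold-change of methylation intensity
#'
#' The differential-methylation measure for capture-based methylation data:
#' \deqn{f = (I_{case} + \beta L) / (I_{control} + \beta L)}
#' where the intensities are total read bases in the region, `L` is the
#' short-read length and `beta` an offset multiplier. The additive offset
#' `beta * L` (360 bases at the defaults) suppresses the effect of weak
#' methylation signals in the denominator: for weakly covered regions the
#' ratio shrinks toward 1, while for strongly covered regions f approaches
#' the raw intensity ratio.
#'
#' @param I_case,I_control Nonnegative group-mean intensities, in bases.
#'   Vectorized.
#' @param beta Offset multiplier (default 10).
#' @param L Short-read length in bases (default 36).
#' @return The fold-change `f > 0`, same length as the inputs.
#' @examples
#' fold_change(720, 360) # (720+360)/(360+360) = 1.5
#' fold_change(0, 0)     # 1: both sides equal the offset
#' @export
fold_change <- function(I_case, I_control, beta = 10, L = 36) {
  stopifnot(L > 0, beta >= 0)
  if (any(I_case < 0) || any(I_control < 0)) {
    rlang::abort("intensities must be nonnegative")
  }
  if (beta * L == 0 && any(I_case == 0 & I_control == 0)) {
    rlang::abort("fold-change undefined: zero intensities with zero offset")
  }
  (I_case + beta * L) / (I_control + beta * L)
}

#' Signed M-score from a fold-change
#'
#' `M = log2(f)`: positive for hypermethylation in the case group, negative
#' for hypomethylation, zero when case and control intensities agree. The
#' log makes hyper- and hypomethylation symmetric around 0, so one-sided
#' tests on either tail of the (possibly asymmetric) null are direct.
#'
#' @param f Fold-change(s), strictly positive.
#' @return The M-score(s).
#' @export
m_score <- function(f) {
  if (any(f <= 0)) rlang::abort("fold-change must be strictly positive")
  log2(f)
}

#' Score regions for differential methylation
#'
#' Computes the offset fold-change and M-score for every region of an
#' intensity matrix, one case-vs-control comparison. Scores for different
#' region roles (promoters, CpG islands, CpG sites, methylation units) are
#' computed the same way but must be tested against separate nulls; keep
#' roles in separate tables or filter downstream.
#'
#' @param mat Wide intensity tibble (`region_id` + one column per sample).
#' @param samples Sample sheet with `sample_id`, `group`.
#' @param regions Optional region tibble supplying `role`, `chrom`, `start`,
#'   `end` per `region_id`; carried through when given.
#' @param beta,L Fold-change offset parameters (defaults 10 and 36).
#' @return A score table: `region_id`, (region columns if supplied),
#'   `I_case`, `I_control`, `f`, `M`.
#' @export
score_regions <- function(mat, samples, regions = NULL, beta = 10, L = 36) {
  agg <- aggregate_groups(mat, samples)
  agg$f <- fold_change(agg$I_case, agg$I_control, beta = beta, L = L)
  agg$M <- m_score(agg$f)
  if (!is.null(regions)) {
    keep <- intersect(c("region_id", "role", "chrom", "start", "end", "n_sites"),
                      names(regions))
    agg <- dplyr::left_join(agg, tibble::as_tibble(regions)[, keep],
                            by = "region_id")
    agg <- dplyr::relocate(agg, dplyr::any_of(c("region_id", "role", "chrom",
                                                "start", "end", "n_sites")))
  }
  agg
}
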