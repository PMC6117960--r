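#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a permutation differential-methylation result
#'
#' One row per tested region with its scores and calls.
#'
#' @param x A `perm_diffmeth` object from [iterative_detect()].
#' @param ... Unused.
#' @return The call tibble: `region_id`, `I_case`, `I_control`, `f`, `M`,
#'   `direction`, `p`, `q`, `significant`, `iteration_called`.
#' @method tidy perm_diffmeth
#' @export
tidy.perm_diffmeth <- function(x, ...) {
  x$calls
}

#' One-row summary of a permutation differential-methylation result
#'
#' @param x A `perm_diffmeth` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_regions`, `n_significant`, `n_hyper`,
#'   `n_hypo`, `n_iterations`, `converged`, `alpha0`, `n_perm`.
#' @method glance perm_diffmeth
#' @export
glance.perm_diffmeth <- function(x, ...) {
  sig <- x$calls[x$calls$significant, , drop = FALSE]
  tibble::tibble(
    n_regions = nrow(x$calls),
    n_significant = nrow(sig),
    n_hyper = sum(sig$direction == "hyper"),
    n_hypo = sum(sig$direction == "hypo"),
    n_iterations = nrow(x$iterations),
    converged = x$converged,
    alpha0 = x$config$alpha0,
    n_perm = x$config$n_perm
  )
}

#' Volcano-style plot of differential-methylation calls
#'
#' M-score against -log10(q), significant calls highlighted by direction.
#'
#' @param object A `perm_diffmeth` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot perm_diffmeth
#' @export
autoplot.perm_diffmeth <- function(object, ...) {
  d <- object$calls
  d$status <- ifelse(!d$significant, "not significant", d$direction)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$M, y = -log10(.data$q),
                                  colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(object$config$alpha0),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(
      hyper = "#c0392b", hypo = "#2471a3", `not significant` = "grey60")) +
    ggplot2::labs(x = "M-score (log2 offset fold-change)",
                  y = expression(-log[10](q)), colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the stratified permutation null against observed M-scores
#'
#' Density of the pooled null M-scores per length stratum, with the
#' observed scores overlaid as a rug — a visual check of null calibration
#' and of how far called regions sit in the tails.
#'
#' @param x A `perm_diffmeth` object.
#' @return A ggplot object.
#' @export
plot_null_distribution <- function(x) {
  null_long <- purrr::imap(x$null$null, function(v, s) {
    tibble::tibble(stratum = paste0("stratum ", s), M = v)
  }) |> dplyr::bind_rows()
  obs <- tibble::tibble(
    stratum = paste0("stratum ", x$null$strata),
    M = x$calls$M)
  ggplot2::ggplot(null_long, ggplot2::aes(x = .data$M)) +
    ggplot2::geom_density(fill = "grey80", colour = "grey40") +
    ggplot2::geom_rug(data = obs, colour = "#c0392b", alpha = 0.5,
                      length = ggplot2::unit(0.06, "npc")) +
    ggplot2::facet_wrap(~stratum, scales = "free_y") +
    ggplot2::labs(x = "M-score", y = "null density") +
    ggplot2::theme_minimal()
}

#' Plot per-sample small-RNA subtype composition
#'
#' Stacked bar chart of the count fraction per subtype, as produced by
#' [subtype_composition()].
#'
#' @param composition Long tibble `sample_id`, `subtype`, `fraction`.
#' @return A ggplot object.
#' @export
plot_subtype_composition <- function(composition) {
  ggplot2::ggplot(composition,
                  ggplot2::aes(x = .data$sample_id, y = .data$fraction,
                               fill = .data$subtype)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of counts", fill = "subtype") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
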