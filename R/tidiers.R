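#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a functional network into its edge list
#'
#' @param x A [build_network()] result.
#' @param ... Unused.
#' @return A tibble with one row per edge (`cell_i`, `cell_j`, `r`, `p_raw`,
#'   `p_adjusted`).
#' @export
tidy.functional_network <- function(x, ...) x$edges

#' One-row summary of a functional network
#'
#' @inheritParams tidy.functional_network
#' @return The [network_summary()] tibble.
#' @export
glance.functional_network <- function(x, ...) network_summary(x)

#' Tidy a statistical report into its pairwise comparisons
#'
#' @param x A `stat_report` from [compare_sessions_within()] or
#'   [compare_groups_between()].
#' @param ... Unused.
#' @return The pairwise tibble (raw and Holm-adjusted p-values).
#' @export
tidy.stat_report <- function(x, ...) x$pairwise

#' One-row omnibus summary of a statistical report
#'
#' @inheritParams tidy.stat_report
#' @return The omnibus tibble plus the design label.
#' @export
glance.stat_report <- function(x, ...) {
  dplyr::mutate(x$omnibus, design = x$design)
}

#' Tidy a simulated study's ground truth
#'
#' @param x A [simulate_study()] result.
#' @param ... Unused.
#' @return The per-cell ground-truth tibble.
#' @export
tidy.sim_study <- function(x, ...) x$truth$cells
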