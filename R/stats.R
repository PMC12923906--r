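#' Nonparametric within-group comparison across sessions
#'
#' Runs the omnibus test across sessions — a Friedman rank-sum test when the
#' design is paired (every subject observed in every session exactly once),
#' a Kruskal-Wallis test otherwise — followed by the matching pairwise
#' Wilcoxon tests (signed-rank when paired, rank-sum otherwise) with Holm
#' adjustment for multiple comparisons.
#'
#' @param data A tidy data frame with one value per subject x session.
#' @param value_col,session_col,subject_col Column names (defaults `value`,
#'   `session`, `animal_id`).
#' @param paired Force the paired/unpaired design; `NULL` (default) detects
#'   it from the data.
#' @return An object of class `stat_report`: `omnibus` (one-row tibble with
#'   `method`, `statistic`, `df`, `p_value`), `pairwise` (tibble with
#'   `group_a`, `group_b`, `statistic`, `p_value`, `p_holm`) and `design`.
#' @export
compare_sessions_within <- function(data, value_col = "value",
                                    session_col = "session",
                                    subject_col = "animal_id",
                                    paired = NULL) {
  data <- tibble::as_tibble(data)
  v <- data[[value_col]]
  s <- factor(data[[session_col]], levels = intersect(session_labels(),
                                                      unique(data[[session_col]])))
  if (anyNA(s)) s <- factor(data[[session_col]])
  if (nlevels(s) < 2) stop("need data from at least 2 sessions", call. = FALSE)
  subj <- data[[subject_col]]
  if (is.null(paired)) {
    tab <- table(subj, s)
    paired <- !is.null(subj) && all(tab == 1)
  }
  if (paired) {
    ord <- order(s, subj)
    om <- stats::friedman.test(v[ord], s[ord], factor(subj)[ord])
    omnibus <- tibble::tibble(method = "Friedman rank sum test",
                              statistic = unname(om$statistic),
                              df = unname(om$parameter),
                              p_value = om$p.value)
  } else {
    om <- stats::kruskal.test(v, s)
    omnibus <- tibble::tibble(method = "Kruskal-Wallis rank sum test",
                              statistic = unname(om$statistic),
                              df = unname(om$parameter),
                              p_value = om$p.value)
  }
  # fully tied data make the rank statistics 0/0; report the degenerate
  # "no difference" outcome explicitly
  if (!is.finite(omnibus$statistic)) {
    omnibus$statistic <- 0
    omnibus$p_value <- 1
  }
  combos <- utils::combn(levels(s), 2, simplify = FALSE)
  pw <- purrr::map_dfr(combos, function(pr) {
    if (paired) {
      ia <- s == pr[1]; ib <- s == pr[2]
      a <- v[ia][order(subj[ia])]
      b <- v[ib][order(subj[ib])]
      wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
    } else {
      wt <- suppressWarnings(stats::wilcox.test(v[s == pr[1]], v[s == pr[2]]))
    }
    tibble::tibble(group_a = pr[1], group_b = pr[2],
                   statistic = unname(wt$statistic), p_value = wt$p.value)
  })
  pw$p_holm <- stats::p.adjust(pw$p_value, method = "holm")
  structure(list(omnibus = omnibus, pairwise = pw,
                 design = if (paired) "paired" else "unpaired"),
            class = "stat_report")
}

#' Nonparametric between-group comparison
#'
#' Two-sided Mann-Whitney U test between two groups at one session/metric
#' (exact p-value for small tie-free samples, normal approximation with tie
#' correction otherwise, following `stats::wilcox.test`).
#'
#' @param data Tidy data frame.
#' @param value_col,group_col Column names (defaults `value`, `group`).
#' @return A `stat_report` whose `omnibus` row carries the U statistic and
#'   p-value; `pairwise` holds the same single comparison.
#' @export
compare_groups_between <- function(data, value_col = "value",
                                   group_col = "group") {
  data <- tibble::as_tibble(data)
  g <- factor(data[[group_col]])
  if (nlevels(g) != 2) stop("need exactly 2 groups", call. = FALSE)
  a <- data[[value_col]][g == levels(g)[1]]
  b <- data[[value_col]][g == levels(g)[2]]
  if (length(a) == 0 || length(b) == 0) stop("empty group", call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(a, b))
  row <- tibble::tibble(group_a = levels(g)[1], group_b = levels(g)[2],
                        statistic = unname(wt$statistic), p_value = wt$p.value)
  structure(list(
    omnibus = tibble::tibble(method = "Mann-Whitney U test",
                             statistic = row$statistic, df = NA_real_,
                             p_value = row$p_value),
    pairwise = dplyr::mutate(row, p_holm = .data$p_value),
    design = "between"), class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat(sprintf("<stat_report> %s (%s design): statistic %.3g, p = %.4g\n",
              x$omnibus$method, x$design, x$omnibus$statistic,
              x$omnibus$p_value))
  if (nrow(x$pairwise)) {
    cat("pairwise (Holm-adjusted):\n")
    print(as.data.frame(x$pairwise), row.names = FALSE)
  }
  invisible(x)
}
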