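#' Build a functional connectivity network from ΔF/F traces
#'
#' Pairwise Spearman correlations are computed between all cells' full-rate
#' ΔF/F traces; two-sided p-values (large-sample t approximation on the
#' rank-transformed traces) are Bonferroni-adjusted by the number of tested
#' pairs, and pairs with adjusted `p < edge_alpha` and positive correlation
#' become edges weighted by the correlation coefficient. Constant traces stay
#' in the network as nodes but can form no edges (warned).
#'
#' @param traces Numeric matrix, cells x frames, rownames = cell ids.
#' @param edge_alpha Significance threshold on the (adjusted) p (default
#'   0.001).
#' @param correction `"bonferroni"` (default) or `"none"` (threshold applied
#'   to raw p-values).
#' @param positive_only Keep only positive correlations (default TRUE).
#' @param distance Edge length used for closeness: `"inverse"` (1/r, default)
#'   or `"one_minus"` (1 - r).
#' @return An object of class `functional_network`: the igraph `graph`, a
#'   `nodes` tibble (`cell_id`, `degree`, `clustering`, `closeness`), an
#'   `edges` tibble (`cell_i`, `cell_j`, `r`, `p_raw`, `p_adjusted`) and the
#'   parameters used.
#' @export
build_network <- function(traces, edge_alpha = 0.001,
                          correction = c("bonferroni", "none"),
                          positive_only = TRUE,
                          distance = c("inverse", "one_minus")) {
  correction <- match.arg(correction)
  distance <- match.arg(distance)
  stopifnot(is.matrix(traces), nrow(traces) >= 2)
  ids <- rownames(traces)
  if (is.null(ids)) ids <- paste0("cell", seq_len(nrow(traces)))
  nf <- ncol(traces)
  sds <- apply(traces, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0),
            " constant trace(s): nodes retained without edges", call. = FALSE)
  }
  ok <- which(sds > 0)
  edges <- empty_edges()
  if (length(ok) >= 2) {
    ranks <- t(apply(traces[ok, , drop = FALSE], 1, rank))
    r_mat <- stats::cor(t(ranks))
    ut <- which(upper.tri(r_mat), arr.ind = TRUE)
    r <- r_mat[ut]
    p <- spearman_p(r, nf)
    m <- length(r)
    p_adj <- if (correction == "bonferroni") pmin(1, p * m) else p
    keep <- p_adj < edge_alpha & (!positive_only | r > 0)
    edges <- tibble::tibble(cell_i = ids[ok[ut[keep, 1]]],
                            cell_j = ids[ok[ut[keep, 2]]],
                            r = r[keep], p_raw = p[keep],
                            p_adjusted = p_adj[keep])
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("cell_i", "cell_j")], directed = FALSE,
    vertices = data.frame(name = ids))
  igraph::E(g)$weight <- edges$r
  net <- structure(list(graph = g, edges = edges, n_cells = length(ids),
                        n_frames = nf,
                        params = list(edge_alpha = edge_alpha,
                                      correction = correction,
                                      positive_only = positive_only,
                                      distance = distance)),
                   class = "functional_network")
  net$nodes <- tibble::tibble(cell_id = ids,
                              degree = degree_centrality(net),
                              clustering = clustering_coefficient(net),
                              closeness = closeness_centrality(net))
  net
}

empty_edges <- function() {
  tibble::tibble(cell_i = character(), cell_j = character(), r = numeric(),
                 p_raw = numeric(), p_adjusted = numeric())
}

# two-sided p for a Spearman coefficient via the t approximation
spearman_p <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  p
}

#' @export
print.functional_network <- function(x, ...) {
  cat(sprintf("<functional_network> %d cells, %d edges (%s p < %g%s)\n",
              x$n_cells, nrow(x$edges), x$params$correction,
              x$params$edge_alpha,
              if (x$params$positive_only) ", positive only" else ""))
  invisible(x)
}

#' Weighted node centralities
#'
#' `degree_centrality()` is the edge count per node normalised by the network
#' size (`n - 1`). `clustering_coefficient()` is the Barrat weighted local
#' clustering coefficient (nodes with fewer than 2 neighbours score 0).
#' `closeness_centrality()` is the inverse of a node's mean shortest-path
#' distance to the other nodes of its connected component, with edge lengths
#' `1/r` by default (stronger correlation = closer); isolated nodes score 0.
#'
#' @param net A [build_network()] result (or an igraph graph with a `weight`
#'   edge attribute).
#' @param distance Edge-length convention for closeness (defaults to the one
#'   stored in the network).
#' @return Numeric vector, one value per node in node order.
#' @export
degree_centrality <- function(net) {
  g <- as_graph(net)
  n <- igraph::vcount(g)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  as.numeric(igraph::degree(g)) / (n - 1)
}

#' @rdname degree_centrality
#' @export
clustering_coefficient <- function(net) {
  g <- as_graph(net)
  cc <- igraph::transitivity(g, type = "barrat", isolates = "zero")
  cc[!is.finite(cc)] <- 0
  as.numeric(cc)
}

#' @rdname degree_centrality
#' @export
closeness_centrality <- function(net, distance = NULL) {
  g <- as_graph(net)
  if (is.null(distance)) {
    distance <- if (inherits(net, "functional_network"))
      net$params$distance else "inverse"
  }
  w <- igraph::E(g)$weight
  len <- if (identical(distance, "one_minus")) 1 - w else 1 / w
  if (igraph::ecount(g) == 0) return(rep(0, igraph::vcount(g)))
  d <- igraph::distances(g, weights = len)
  vapply(seq_len(nrow(d)), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (length(di) == 0 || mean(di) == 0) 0 else 1 / mean(di)
  }, 0)
}

as_graph <- function(net) {
  if (inherits(net, "functional_network")) net$graph else net
}

#' Session-level network summary
#'
#' @param net A [build_network()] result.
#' @return One-row tibble: `n_cells`, `n_edges`, `mean_degree`,
#'   `mean_clustering`, `mean_closeness`, `mean_edge_weight`.
#' @export
network_summary <- function(net) {
  tibble::tibble(n_cells = net$n_cells, n_edges = nrow(net$edges),
                 mean_degree = mean(net$nodes$degree),
                 mean_clustering = mean(net$nodes$clustering),
                 mean_closeness = mean(net$nodes$closeness),
                 mean_edge_weight = if (nrow(net$edges)) mean(net$edges$r)
                 else NA_real_)
}

#' Express per-session means as a percentage of habituation
#'
#' @param summaries A tidy tibble with columns `session`, `metric`, `value`
#'   containing an `HA` row for every metric.
#' @param strict Error on a missing/zero habituation baseline (default); with
#'   `strict = FALSE` the affected metric gets `NA` percentages instead.
#' @return The input with a `percent_of_HA` column added.
#' @export
normalize_to_habituation <- function(summaries, strict = TRUE) {
  stopifnot(all(c("session", "metric", "value") %in% names(summaries)))
  summaries |>
    dplyr::group_by(.data$metric) |>
    dplyr::group_modify(function(df, key) {
      ha <- df$value[df$session == "HA"]
      if (length(ha) != 1 || is.na(ha) || ha == 0) {
        if (strict) {
          stop("metric ", key$metric,
               ": habituation baseline missing or zero", call. = FALSE)
        }
        df$percent_of_HA <- NA_real_
        return(df)
      }
      df$percent_of_HA <- 100 * df$value / ha
      df
    }) |>
    dplyr::ungroup()
}
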