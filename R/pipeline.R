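#' Run the full analysis pipeline on a study directory
#'
#' Executes every stage in order — behaviour, ensembles, bursts, spatial,
#' network, statistics — on a study tree (real or written by
#' [write_study()]), writes one tidy CSV per stage into `out_dir`, and
#' returns the results. The run is deterministic given `config$seed`; every
#' parameter used is taken from `config` and a stage failure aborts with a
#' stage-tagged error.
#'
#' @param study_dir Directory containing `sessions/<label>/` and
#'   `registration.csv`.
#' @param config An [analysis_config()].
#' @param out_dir Output directory for the stage CSVs (created; `NULL` skips
#'   writing).
#' @param quiet Suppress per-stage progress messages.
#' @return (Invisibly) a list with `behavior`, `ensembles`, `bursts`,
#'   `burst_summary`, `spatial_cells`, `network_nodes`, `network_summary`,
#'   `stats`, `metrics` (the combined tidy metric table).
#' @export
run_pipeline <- function(study_dir, config = analysis_config(),
                         out_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  study <- stage("input", {
    missing <- session_labels()[!dir.exists(file.path(study_dir, "sessions",
                                                      session_labels()))]
    if (length(missing)) {
      stop("missing session directory: ", paste(missing, collapse = ", "))
    }
    read_study(study_dir)
  })
  sessions <- study$sessions
  meta1 <- sessions[[1]]$meta
  say("pipeline: ", meta1$animal_id, " [", meta1$group_label, "], seed ",
      config$seed)

  # --- behaviour ----------------------------------------------------------
  behavior <- stage("behavior", {
    rows <- purrr::map_dfr(sessions, function(ss) {
      if (nrow(ss$arena$objects) == 0) return(NULL)
      dplyr::mutate(score_object_exploration(ss$trajectory, ss$arena),
                    session = ss$meta$session_label, .before = 1)
    })
    # discrimination index in the recall session: the displaced object is the
    # one whose position changed relative to the previous session
    if (all(c("S2", "S3") %in% names(sessions)) && nrow(rows)) {
      o2 <- sessions$S2$arena$objects
      o3 <- sessions$S3$arena$objects
      moved <- dplyr::anti_join(o3, o2, by = c("object_id", "x", "y"))$object_id
      s3 <- rows[rows$session == "S3", ]
      if (length(moved) == 1 && nrow(s3) == 2) {
        td <- s3$exploration_time_s[s3$object_id == moved]
        ts <- s3$exploration_time_s[s3$object_id != moved]
        rows$discrimination_index <- NA_real_
        rows$discrimination_index[rows$session == "S3"] <-
          discrimination_index(td, ts)
      }
    }
    rows
  })
  say("behavior: ", nrow(behavior), " object-session rows")

  # --- ensembles ----------------------------------------------------------
  ensembles <- stage("ensembles", {
    counts <- lapply(sessions, function(ss)
      table(factor(ss$events$cell_id, levels = rownames(ss$traces))))
    counts <- lapply(counts, function(x) stats::setNames(as.integer(x), names(x)))
    ensemble_summary(study$regmap, event_counts = counts)
  })
  say("ensembles: ", nrow(ensembles), " metric rows")

  # --- bursts -------------------------------------------------------------
  burst_out <- stage("bursts", {
    per_session <- purrr::imap(sessions, function(ss, lab) {
      popz <- population_zscore(ss$traces)
      b <- detect_bursts(popz, ss$meta$fps, config$burst$z_threshold,
                         config$burst$min_duration_s)
      b <- burst_participation(event_trains(ss), b)
      speed_cor <- tryCatch(
        activity_speed_correlation(popz, ss$trajectory, ss$meta$fps, b),
        error = function(e) tibble::tibble(scope = "session", rho = NA_real_,
                                           n_frames = length(popz)))
      summ <- dplyr::mutate(
        burst_session_metrics(b), session = lab,
        mean_participation = if (nrow(b)) mean(b$participation_frac) else NA_real_,
        speed_rho = speed_cor$rho[speed_cor$scope == "session"])
      list(events = dplyr::mutate(b, session = lab, .before = 1), summary = summ)
    })
    list(events = purrr::map_dfr(per_session, "events"),
         summary = purrr::map_dfr(per_session, "summary"))
  })
  say("bursts: ", nrow(burst_out$events), " bursts across sessions")

  # --- spatial ------------------------------------------------------------
  spatial_cells <- stage("spatial", {
    purrr::imap_dfr(sessions, function(ss, lab)
      dplyr::mutate(analyze_spatial_cells(ss, config), session = lab,
                    .before = 1))
  })
  say("spatial: ", sum(spatial_cells$is_place_cell_like),
      " place-cell-like of ", nrow(spatial_cells), " cell-sessions")

  # --- network ------------------------------------------------------------
  network_out <- stage("network", {
    nets <- purrr::imap(sessions, function(ss, lab)
      build_network(ss$traces, edge_alpha = config$network$edge_alpha,
                    correction = config$network$correction,
                    positive_only = config$network$positive_only,
                    distance = config$network$distance))
    nodes <- purrr::imap_dfr(nets, function(nn, lab)
      dplyr::mutate(nn$nodes, session = lab, .before = 1))
    summ <- purrr::imap_dfr(nets, function(nn, lab)
      dplyr::mutate(network_summary(nn), session = lab, .before = 1))
    tidy_summ <- tidyr::pivot_longer(
      summ[, c("session", "mean_degree", "mean_clustering", "mean_closeness")],
      -"session", names_to = "metric", values_to = "value")
    norm <- normalize_to_habituation(tidy_summ, strict = FALSE)
    list(nodes = nodes, summary = summ, normalized = norm)
  })
  say("network: ", paste(network_out$summary$n_edges, collapse = "/"),
      " edges per session")

  # --- statistics ---------------------------------------------------------
  stats_out <- stage("stats", {
    out <- list()
    pc <- spatial_cells[!is.na(spatial_cells$info_bits_per_event), ]
    if (length(unique(pc$session)) >= 2 && nrow(pc) >= 8) {
      out$spatial_info <- compare_sessions_within(
        pc, value_col = "info_bits_per_event", subject_col = "cell_id",
        paired = FALSE)
    }
    nd <- network_out$nodes
    if (length(unique(nd$session)) >= 2 && nrow(nd) >= 8) {
      out$network_degree <- compare_sessions_within(
        nd, value_col = "degree", subject_col = "cell_id", paired = FALSE)
    }
    out
  })

  metrics <- dplyr::bind_rows(
    dplyr::transmute(ensembles, scope, label, metric, value),
    dplyr::transmute(burst_out$summary, scope = "session", label = session,
                     metric = "n_bursts", value = as.numeric(n_bursts)),
    dplyr::transmute(network_out$normalized, scope = "session",
                     label = session, metric = paste0(metric, "_pct_HA"),
                     value = percent_of_HA))
  metrics <- dplyr::mutate(metrics, animal_id = meta1$animal_id,
                           group = meta1$group_label, .before = 1)

  result <- list(behavior = behavior, ensembles = ensembles,
                 bursts = burst_out$events, burst_summary = burst_out$summary,
                 spatial_cells = spatial_cells,
                 network_nodes = network_out$nodes,
                 network_summary = network_out$summary,
                 network_normalized = network_out$normalized,
                 stats = stats_out, metrics = metrics)

  if (!is.null(out_dir)) {
    stage("report", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      wr <- function(df, name) {
        if (!is.null(df) && nrow(df)) {
          readr::write_csv(df, file.path(out_dir, name), na = "NA",
                           progress = FALSE)
        }
      }
      wr(behavior, "behavior.csv")
      wr(ensembles, "ensembles.csv")
      wr(burst_out$events, "burst_events.csv")
      wr(burst_out$summary, "burst_summary.csv")
      wr(spatial_cells, "spatial_cells.csv")
      wr(network_out$nodes, "network_nodes.csv")
      wr(network_out$summary, "network_summary.csv")
      wr(network_out$normalized, "network_normalized.csv")
      wr(metrics, "metrics.csv")
      for (nm in names(stats_out)) {
        wr(dplyr::mutate(stats_out[[nm]]$pairwise,
                         omnibus_method = stats_out[[nm]]$omnibus$method,
                         omnibus_p = stats_out[[nm]]$omnibus$p_value),
           paste0("stats_", nm, ".csv"))
      }
    })
    say("report written to ", out_dir)
  }
  invisible(result)
}
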