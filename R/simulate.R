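#' Simulation parameter presets
#'
#' Named parameter bundles for the synthetic study generator. Two presets are
#' provided: `"vehicle_like"`, mirroring an intact-consolidation group
#' (sustained cross-session reactivation, frequent strong population bursts,
#' growing object tuning by the recall session), and `"antagonist_like"`,
#' mirroring a beta-adrenergic-blockade group (reduced reactivation, fewer and
#' weaker bursts, flat object tuning). A preset plus a seed fully determines
#' the planted ground truth.
#'
#' @param name Preset name.
#' @param ... Named overrides of individual preset fields.
#' @return A list of class `sim_preset`.
#' @export
sim_preset <- function(name = c("vehicle_like", "antagonist_like"), ...) {
  name <- match.arg(name)
  base <- list(
    name = name,
    # ensemble dynamics: directional overlap (fraction of the earlier
    # session's active set re-active in the later one) and recruitment of
    # previously inactive cells
    overlap = c("HA->S1" = 0.75, "S1->S2" = 0.80, "S2->S3" = 0.40),
    recruit_p = 0.10,
    # cell tuning
    frac_place = 0.30, place_peak_gain = 6, place_width_cm = 5,
    frac_object_tuned = 0.10, object_gain_by_session = c(S1 = 1, S2 = 1.2, S3 = 1.5),
    base_rate_meanlog = log(0.10), base_rate_sdlog = 0.30,
    # population bursts
    n_bursts_per_session = 12, burst_gain = 8, burst_duration_s = 0.3,
    burst_participation = 0.7, burst_min_separation_s = 10,
    # correlated blocks
    n_blocks = 3, block_size = 10, block_sigma = 0.8, block_tau_s = 2,
    # calcium trace model
    kernel_rise_s = 0.05, kernel_decay_s = 0.6, noise_sd = 0.15
  )
  if (name == "antagonist_like") {
    base <- utils::modifyList(base, list(
      overlap = c("HA->S1" = 0.60, "S1->S2" = 0.50, "S2->S3" = 0.35),
      n_bursts_per_session = 5, burst_gain = 4,
      frac_object_tuned = 0.05,
      object_gain_by_session = c(S1 = 1, S2 = 1, S3 = 1)))
  }
  out <- utils::modifyList(base, list(...))
  if (any(out$overlap < 0 | out$overlap > 1)) {
    stop("overlap fractions must lie in [0, 1]", call. = FALSE)
  }
  structure(out, class = "sim_preset")
}

#' Simulate one session of calcium events and traces
#'
#' Each cell emits events from an inhomogeneous Poisson process whose rate is
#' `base_rate_hz` multiplied by a Gaussian spatial gain (for place-tuned
#' cells: `peak_gain * exp(-d^2 / (2 * width_cm^2))` with `d` the distance to
#' the tuning centre, so firing concentrates in the field and decays to near
#' zero away from it), a
#' shared slow latent modulation within correlated blocks, and a burst gain
#' during planted population bursts. ΔF/F traces are the per-frame event
#' counts convolved with a difference-of-exponentials calcium kernel plus
#' white Gaussian noise.
#'
#' @param cells Tibble of per-cell ground truth: `global_id`, `base_rate_hz`,
#'   `place_cell` (logical), `center_x`, `center_y`, `width_cm`, `peak_gain`,
#'   optionally `block_id` and `session_gain` (extra rate multiplier,
#'   default 1).
#' @param trajectory Trajectory tibble sampled at the imaging frame rate.
#' @param meta A [recording_meta()].
#' @param arena An [arena_config()].
#' @param bursts Tibble of planted bursts (`time_s`, `duration_s`,
#'   `participation_frac`, `gain`) or `NULL`.
#' @param params Trace-model parameters; see [sim_preset()] fields
#'   `kernel_rise_s`, `kernel_decay_s`, `noise_sd`, `block_sigma`,
#'   `block_tau_s`.
#' @param seed Integer seed.
#' @return A [session_dataset()] whose trace rownames are the `global_id`s.
#' @export
simulate_session <- function(cells, trajectory, meta, arena, bursts = NULL,
                             params = sim_preset(), seed = 1L) {
  cells <- tibble::as_tibble(cells)
  if (is.null(cells[["block_id"]])) cells$block_id <- NA_integer_
  if (is.null(cells[["session_gain"]])) cells$session_gain <- 1
  pc <- cells$place_cell
  if (any(pc & (cells$center_x < 0 | cells$center_x > arena$width_cm |
                cells$center_y < 0 | cells$center_y > arena$height_cm),
          na.rm = TRUE)) {
    stop("tuning centres must lie inside the arena", call. = FALSE)
  }
  set.seed(as.integer(seed))
  n_cells <- nrow(cells)
  fps <- meta$fps
  dt <- 1 / fps
  nf <- round(meta$duration_s * fps)
  if (nrow(trajectory) != nf) {
    stop("trajectory must be sampled at the imaging frame rate", call. = FALSE)
  }

  # cells x frames rate matrix
  rate <- matrix(cells$base_rate_hz * cells$session_gain, n_cells, nf)
  if (any(pc)) {
    d2 <- outer(cells$center_x[pc], trajectory$x, `-`)^2 +
      outer(cells$center_y[pc], trajectory$y, `-`)^2
    gain <- cells$peak_gain[pc] * exp(-d2 / (2 * cells$width_cm[pc]^2))
    rate[pc, ] <- rate[pc, , drop = FALSE] * gain
  }

  # shared slow modulation within correlated blocks (log-normal, mean 1)
  blocks <- unique(cells$block_id[!is.na(cells$block_id)])
  if (length(blocks) && params$block_sigma > 0) {
    a <- exp(-dt / params$block_tau_s)
    for (b in blocks) {
      u <- stats::filter(stats::rnorm(nf, 0, sqrt(1 - a^2)), a,
                         method = "recursive",
                         init = stats::rnorm(1))
      g <- exp(params$block_sigma * as.numeric(u) - params$block_sigma^2 / 2)
      idx <- which(!is.na(cells$block_id) & cells$block_id == b)
      rate[idx, ] <- rate[idx, , drop = FALSE] *
        matrix(g, length(idx), nf, byrow = TRUE)
    }
  }

  # planted synchronous bursts: gain applied to a sampled participant subset
  if (!is.null(bursts) && nrow(bursts) > 0) {
    for (i in seq_len(nrow(bursts))) {
      frames <- which(trajectory$t >= bursts$time_s[i] &
                        trajectory$t < bursts$time_s[i] + bursts$duration_s[i])
      k <- max(1L, round(bursts$participation_frac[i] * n_cells))
      members <- sample.int(n_cells, k)
      rate[members, frames] <- rate[members, frames, drop = FALSE] * bursts$gain[i]
    }
  }

  counts <- matrix(stats::rpois(n_cells * nf, rate * dt), n_cells, nf)

  # event times: frame start + uniform jitter within the frame
  ids <- as.character(cells$global_id)
  ev_list <- lapply(seq_len(n_cells), function(i) {
    ci <- counts[i, ]
    tot <- sum(ci)
    if (tot == 0) return(numeric(0))
    sort(rep(trajectory$t[ci > 0], ci[ci > 0]) + stats::runif(tot, 0, dt))
  })
  events <- tibble::tibble(
    cell_id = rep(ids, lengths(ev_list)),
    time_s = unlist(ev_list, use.names = FALSE),
    amplitude = 1)
  if (nrow(events) == 0) {
    events <- tibble::tibble(cell_id = character(), time_s = numeric(),
                             amplitude = numeric())
  }

  traces <- calcium_traces(counts, fps, params$kernel_rise_s,
                           params$kernel_decay_s, params$noise_sd)
  rownames(traces) <- ids
  session_dataset(meta, trajectory, traces, events, arena)
}

# convolve per-frame event counts with a difference-of-exponentials kernel
# (unit peak) and add white noise
calcium_traces <- function(counts, fps, rise_s, decay_s, noise_sd) {
  dt <- 1 / fps
  tk <- seq(0, 5 * decay_s, by = dt)
  k <- exp(-tk / decay_s) - exp(-tk / rise_s)
  if (max(k) > 0) k <- k / max(k)
  n_cells <- nrow(counts)
  nf <- ncol(counts)
  out <- t(apply(counts, 1, function(ci)
    as.numeric(stats::filter(ci, k, method = "convolution", sides = 1))))
  # stats::filter(sides = 1) leaves the first length(k)-1 samples NA for the
  # incomplete window; fill them by direct partial convolution
  nlead <- min(length(k) - 1, nf)
  if (nlead > 0) {
    for (j in seq_len(nlead)) {
      out[, j] <- counts[, seq_len(j), drop = FALSE] %*% rev(k[seq_len(j)])
    }
  }
  out + matrix(stats::rnorm(n_cells * nf, 0, noise_sd), n_cells, nf)
}

#' Simulate a full item-place study
#'
#' Generates the four-session design — a habituation session (`HA`, no
#' objects) followed by three object sessions (`S1`, `S2` same object
#' configuration, `S3` with one object displaced) — for one animal, together
#' with the longitudinal registration map and the planted ground truth.
#' Cross-session ensemble membership follows the preset's directional overlap
#' fractions via independent Bernoulli draws; object-tuned cells are
#' place-tuned on an object location with a session-dependent gain.
#'
#' @param preset A [sim_preset()] or preset name.
#' @param n_cells Number of globally registered cells (>= 20; default 400).
#' @param seed Integer seed; the full study is reproducible from it.
#' @param fps,duration_s Recording parameters (defaults 20 fps, 600 s).
#' @param animal_id,group_label Identifiers; `group_label` defaults to the
#'   preset name.
#' @return A list of class `sim_study` with elements `sessions` (named list
#'   of four [session_dataset()]s), `regmap` ([registration_map()]), `truth`
#'   (list: `cells`, `bursts`, `overlap` tibbles) and `preset`.
#' @export
simulate_study <- function(preset = "vehicle_like", n_cells = 400, seed = 1L,
                           fps = 20, duration_s = 600,
                           animal_id = "sim1", group_label = NULL) {
  if (is.character(preset)) preset <- sim_preset(preset)
  if (n_cells < 20) stop("n_cells must be >= 20", call. = FALSE)
  if (is.null(group_label)) group_label <- preset$name
  seed <- as.integer(seed)
  set.seed(seed)

  arena_ha <- arena_config()
  obj_s12 <- data.frame(object_id = c("stationary", "displaced"),
                        x = c(12, 28), y = c(20, 20))
  obj_s3 <- data.frame(object_id = c("stationary", "displaced"),
                       x = c(12, 28), y = c(20, 8))
  arenas <- list(HA = arena_ha,
                 S1 = arena_config(objects = obj_s12),
                 S2 = arena_config(objects = obj_s12),
                 S3 = arena_config(objects = obj_s3))

  # per-cell ground truth
  ids <- sprintf("g%04d", seq_len(n_cells))
  place <- stats::runif(n_cells) < preset$frac_place
  obj_tuned <- place & (stats::runif(n_cells) < preset$frac_object_tuned /
                          max(preset$frac_place, 1e-9))
  cx <- stats::runif(n_cells, 2, arena_ha$width_cm - 2)
  cy <- stats::runif(n_cells, 2, arena_ha$height_cm - 2)
  which_obj <- sample(1:2, n_cells, replace = TRUE)
  cx[obj_tuned] <- obj_s12$x[which_obj[obj_tuned]]
  cy[obj_tuned] <- obj_s12$y[which_obj[obj_tuned]]
  block_id <- rep(NA_integer_, n_cells)
  if (preset$n_blocks > 0) {
    pool <- sample.int(n_cells, min(n_cells, preset$n_blocks * preset$block_size))
    block_id[pool] <- rep(seq_len(preset$n_blocks), length.out = length(pool))
  }
  cells <- tibble::tibble(
    global_id = ids,
    base_rate_hz = stats::rlnorm(n_cells, preset$base_rate_meanlog,
                                 preset$base_rate_sdlog),
    place_cell = place, center_x = cx, center_y = cy,
    width_cm = preset$place_width_cm,
    peak_gain = ifelse(place, preset$place_peak_gain, 1),
    object_tuned = obj_tuned, block_id = block_id)

  # cross-session active sets: every registered cell is active in the
  # reference (HA) session; later membership follows the directional overlap
  active <- list(HA = rep(TRUE, n_cells))
  pairs <- list(c("HA", "S1"), c("S1", "S2"), c("S2", "S3"))
  for (p in pairs) {
    frac <- preset$overlap[[paste0(p[1], "->", p[2])]]
    prev <- active[[p[1]]]
    nxt <- logical(n_cells)
    nxt[prev] <- stats::runif(sum(prev)) < frac
    nxt[!prev] <- stats::runif(sum(!prev)) < preset$recruit_p
    if (!any(nxt)) nxt[sample.int(n_cells, 1)] <- TRUE
    active[[p[2]]] <- nxt
  }

  regtab <- tibble::tibble(global_id = ids)
  for (s in session_labels()) {
    idx <- rep(NA_integer_, n_cells)
    idx[active[[s]]] <- seq_len(sum(active[[s]]))
    regtab[[s]] <- idx
  }
  regmap <- registration_map(regtab)

  # planted bursts: jittered grid guaranteeing the minimum separation
  make_bursts <- function(n, dur_total, sseed) {
    set.seed(sseed)
    if (n == 0) return(tibble::tibble(time_s = numeric(), duration_s = numeric(),
                                      participation_frac = numeric(),
                                      gain = numeric()))
    lo <- 20; hi <- dur_total - 20
    slots <- seq(lo, hi, length.out = n)
    jit <- (min(diff(c(lo, slots, hi))) - preset$burst_min_separation_s) / 2
    jit <- max(0, min(jit, 4))
    tibble::tibble(
      time_s = slots + stats::runif(n, -jit, jit),
      duration_s = preset$burst_duration_s,
      participation_frac = preset$burst_participation,
      gain = preset$burst_gain)
  }

  sessions <- list()
  truth_bursts <- list()
  for (k in seq_along(session_labels())) {
    s <- session_labels()[k]
    meta <- recording_meta(s, fps = fps, duration_s = duration_s,
                           animal_id = animal_id, group_label = group_label)
    traj <- simulate_trajectory(arenas[[s]], meta, seed = seed + 100L + k)
    bursts <- make_bursts(preset$n_bursts_per_session, duration_s,
                          seed + 200L + k)
    sc <- cells[active[[s]], , drop = FALSE]
    sc$session_gain <- 1
    if (s != "HA") {
      og <- preset$object_gain_by_session[[s]]
      sc$session_gain[sc$object_tuned] <- og
    } else {
      # no objects during habituation: object-tuned cells are untuned
      sc$place_cell[sc$object_tuned] <- FALSE
    }
    sessions[[s]] <- simulate_session(sc, traj, meta, arenas[[s]],
                                      bursts = bursts, params = preset,
                                      seed = seed + 300L + k)
    bursts$session_label <- s
    truth_bursts[[s]] <- bursts
  }

  overlap <- tibble::tibble(
    earlier = vapply(pairs, `[`, "", 1), later = vapply(pairs, `[`, "", 2),
    fraction = vapply(pairs, function(p)
      preset$overlap[[paste0(p[1], "->", p[2])]], 0))

  structure(list(sessions = sessions, regmap = regmap,
                 truth = list(cells = cells,
                              bursts = dplyr::bind_rows(truth_bursts),
                              overlap = overlap),
                 preset = preset),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("<sim_study> preset %s: %d cells, sessions %s\n",
              x$preset$name, nrow(x$truth$cells),
              paste(names(x$sessions), collapse = ", ")))
  invisible(x)
}

#' Write / read a simulated study directory tree
#'
#' [write_study()] lays out `sessions/<label>/` (each readable by
#' [read_session()]), `registration.csv`, and plain-CSV ground-truth sidecars
#' (`ground_truth_cells.csv`, `ground_truth_bursts.csv`,
#' `ground_truth_overlap.csv`). [read_study()] reads the tree back;
#' ground-truth sidecars are optional on read.
#'
#' @param study A `sim_study` (or a list with `sessions` and `regmap`).
#' @param dir Study directory.
#' @return [write_study()] returns `dir` invisibly; [read_study()] returns a
#'   list with `sessions`, `regmap` and (if present) `truth`.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(study$sessions)) {
    write_session(study$sessions[[s]], file.path(dir, "sessions", s))
  }
  write_registration(study$regmap, file.path(dir, "registration.csv"))
  if (!is.null(study$truth)) {
    readr::write_csv(study$truth$cells,
                     file.path(dir, "ground_truth_cells.csv"), na = "NA",
                     progress = FALSE)
    readr::write_csv(study$truth$bursts,
                     file.path(dir, "ground_truth_bursts.csv"), progress = FALSE)
    readr::write_csv(study$truth$overlap,
                     file.path(dir, "ground_truth_overlap.csv"), progress = FALSE)
  }
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  sdirs <- file.path(dir, "sessions", session_labels())
  present <- dir.exists(sdirs)
  if (!any(present)) stop("no session directories under ", dir, call. = FALSE)
  sessions <- lapply(sdirs[present], read_session)
  names(sessions) <- session_labels()[present]
  regmap <- read_registration(file.path(dir, "registration.csv"))
  out <- list(sessions = sessions, regmap = regmap)
  gt <- file.path(dir, "ground_truth_cells.csv")
  if (file.exists(gt)) {
    out$truth <- list(
      cells = readr::read_csv(gt, show_col_types = FALSE, progress = FALSE),
      bursts = readr::read_csv(file.path(dir, "ground_truth_bursts.csv"),
                               show_col_types = FALSE, progress = FALSE),
      overlap = readr::read_csv(file.path(dir, "ground_truth_overlap.csv"),
                                show_col_types = FALSE, progress = FALSE))
  }
  out
}
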