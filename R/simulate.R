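# Agent-based cage simulator: 4 group-housed mice on a correlated random
# walk with reflective walls, soft mutual avoidance, and scheduled social
# episodes during which an initiator seeks and holds body contact with a
# partner. Contact-seeking rates are genotype-specific and can be modulated
# transiently after a simulated injection (the "cno" epoch).

#' Build a cage identity table
#'
#' Default cage composition is two control and two experimental mice, the
#' mixed-genotype housing used for within-cage normalized behavior indexes.
#'
#' @param cage_id Cage label.
#' @param n_control,n_experimental Number of mice per genotype.
#' @return A tibble with columns `mouse_id`, `genotype`, `cage_id`, `rfid`.
#' @export
make_identities <- function(cage_id = "cage1", n_control = 2L,
                            n_experimental = 2L) {
  if (n_control + n_experimental < 1L)
    stop("cage must contain at least one mouse")
  ids <- c(
    if (n_control > 0) paste0(cage_id, "_c", seq_len(n_control)),
    if (n_experimental > 0) paste0(cage_id, "_e", seq_len(n_experimental))
  )
  tibble(
    mouse_id = ids,
    genotype = c(rep("control", n_control),
                 rep("experimental", n_experimental)),
    cage_id = cage_id,
    rfid = sprintf("RF%09d", vapply(ids, substream_seed, 0, seed = 7L) %% 1e9)
  )
}

#' Simulation configuration
#'
#' Assembles and validates the parameter set of the cage simulator. Defaults
#' describe an LMT-like recording: a 50 x 50 cm arena sampled at 30 frames/s
#' during the dark (active) phase.
#'
#' @param arena_size Side length of the square arena (cm).
#' @param frame_rate Sampling rate (frames/s).
#' @param duration Session length (s).
#' @param seed Root integer seed; per-mouse substreams are derived from it by
#'   stable hashing of the mouse id, so adding a mouse does not reshuffle the
#'   trajectories of the others.
#' @param motion List: `speed_scale` (cm/s), `persistence` (0-1 heading
#'   correlation), `wall_margin` (cm kept between the body centre and the
#'   wall so that nose and tail base stay inside the arena), and
#'   `avoid_radius` (cm below which free mice steer away from the nearest
#'   cage-mate; 0 disables mutual avoidance).
#' @param sociability Per-genotype list; each entry has `contact_seek_rate`
#'   (episodes/min), `mean_contact_duration` (s) and optional
#'   `partner_weights` (named, defaults to uniform over cage-mates).
#' @param epochs List of `list(label, start, end)` with labels among
#'   `baseline`, `saline`, `cno`; non-overlapping and ordered. The effect
#'   modulation is anchored at the start of the `cno` epoch.
#' @param effect List: `amplitude` (> -1, multiplier delta on the
#'   experimental genotype's contact-seeking rate), `onset`, `peak_window`
#'   and `return_to_baseline` (s after injection). The multiplier is exactly
#'   1 from `return_to_baseline` onward.
#' @return A validated list of class `etho_config`.
#' @export
simulation_config <- function(arena_size = 50, frame_rate = 30,
                              duration = 3600, seed = 1L,
                              motion = list(), sociability = list(),
                              epochs = NULL, effect = list()) {
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be positive")
  if (!is.numeric(frame_rate) || frame_rate <= 0)
    stop("frame_rate must be positive")
  if (!is.numeric(arena_size) || arena_size <= 15)
    stop("arena_size must exceed 15 cm (body length)")

  motion <- utils::modifyList(
    list(speed_scale = 8, persistence = 0.85, wall_margin = 3.8,
         avoid_radius = 9), motion)
  stopifnot(motion$persistence >= 0, motion$persistence <= 1)

  soc_default <- list(contact_seek_rate = 2.5, mean_contact_duration = 2.5,
                      partner_weights = NULL)
  sociability <- list(
    control = utils::modifyList(soc_default, sociability$control %||% list()),
    experimental = utils::modifyList(soc_default,
                                     sociability$experimental %||% list())
  )

  effect <- utils::modifyList(
    list(amplitude = 0, onset = 0, peak_window = 5400,
         return_to_baseline = 9000, genotype = "experimental"), effect)
  if (effect$amplitude <= -1) stop("effect amplitude must exceed -1")
  if (effect$return_to_baseline < effect$peak_window)
    stop("return_to_baseline must be >= peak_window")

  if (is.null(epochs))
    epochs <- list(list(label = "baseline", start = 0, end = duration))
  starts <- vapply(epochs, function(e) e$start, 0)
  ends <- vapply(epochs, function(e) e$end, 0)
  labels <- vapply(epochs, function(e) e$label, "")
  if (any(!labels %in% c("baseline", "saline", "cno")))
    stop("epoch labels must be baseline, saline or cno")
  if (any(ends <= starts)) stop("epochs must have positive length")
  if (is.unsorted(starts, strictly = TRUE) ||
      any(utils::head(ends, -1) > starts[-1] + 1e-9))
    stop("epochs must be ordered and non-overlapping")

  structure(list(arena_size = arena_size, frame_rate = frame_rate,
                 duration = duration, seed = as.integer(seed),
                 motion = motion, sociability = sociability,
                 epochs = epochs, effect = effect,
                 body = list(nose_off = 3.0, tail_off = 3.0,
                             contact_dist = 2.0)),
            class = "etho_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Transient effect multiplier
#'
#' Time course of the injection effect on the contact-seeking rate:
#' `1 + amplitude * w(t)` where `w` plateaus at 1 from `onset` through
#' `peak_window` and decays linearly to 0 at `return_to_baseline`. The
#' multiplier equals 1 exactly for any time at or beyond
#' `return_to_baseline`, i.e. the behavior is back to baseline 2.5 h after
#' injection under the default time constants.
#'
#' @param t_since_injection Seconds since injection (vectorized, `>= 0`).
#' @param effect Effect parameter list (see [simulation_config()]).
#' @return Non-negative multiplier(s).
#' @export
effect_multiplier <- function(t_since_injection, effect) {
  if (any(t_since_injection < 0)) stop("t_since_injection must be >= 0")
  on <- effect$onset
  pk <- effect$peak_window
  rt <- effect$return_to_baseline
  t <- t_since_injection
  w <- ifelse(t < on, 0,
       ifelse(t <= pk, 1,
       ifelse(t >= rt, 0,
              if (rt > pk) (rt - t) / (rt - pk) else 0)))
  1 + effect$amplitude * w
}

# stable 31-bit hash of a string combined with the root seed; the basis of
# per-mouse random substreams
substream_seed <- function(key, seed) {
  codes <- utf8ToInt(as.character(key))
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 2147483647
  as.integer((h + as.numeric(seed) * 48271) %% 2147483647)
}

# evaluate code under a temporary RNG state
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# alternating move/stop bouts expanded to a per-frame logical vector
moving_bouts <- function(n_frames, frame_rate, mean_move = 8, mean_stop = 4) {
  total <- n_frames / frame_rate
  durs <- numeric(0)
  while (sum(durs) < total) {
    durs <- c(durs, rexp(16, 1 / mean_move), rexp(16, 1 / mean_stop))
  }
  k <- 2L * ceiling(length(durs) / 2L)
  move_first <- runif(1) < mean_move / (mean_move + mean_stop)
  states <- rep(c(move_first, !move_first), k / 2L)[seq_along(durs)]
  rep(states, times = pmax(1L, round(durs * frame_rate)))[seq_len(n_frames)]
}

# per-mouse contact-seeking rate (episodes/s) on the frame grid
episode_rate <- function(t, genotype, config) {
  soc <- config$sociability[[genotype]]
  base <- soc$contact_seek_rate / 60
  mult <- rep(1, length(t))
  if (genotype == config$effect$genotype && config$effect$amplitude != 0) {
    for (ep in config$epochs) {
      if (ep$label == "cno") {
        after <- t >= ep$start
        mult[after] <- effect_multiplier(t[after] - ep$start, config$effect)
      }
    }
  }
  base * mult
}

# schedule social episodes for one mouse by thinning a homogeneous Poisson
# stream at the peak rate; partner, contact type and intended duration are
# drawn from the same substream
schedule_episodes <- function(mouse, others, genotype, config) {
  soc <- config$sociability[[genotype]]
  if (soc$contact_seek_rate <= 0) {
    return(tibble(initiator = character(0), target = character(0),
                  type = character(0), start_s = numeric(0),
                  dur_s = numeric(0)))
  }
  lam_max <- soc$contact_seek_rate / 60 *
    (1 + max(config$effect$amplitude, 0))
  times <- numeric(0)
  t_cur <- 0
  while (t_cur < config$duration) {
    gaps <- rexp(64, lam_max)
    times <- c(times, t_cur + cumsum(gaps))
    t_cur <- times[length(times)]
  }
  times <- times[times < config$duration]
  keep <- runif(length(times)) <
    episode_rate(times, genotype, config) / lam_max
  times <- times[keep]
  n <- length(times)
  if (n == 0) {
    return(tibble(initiator = character(0), target = character(0),
                  type = character(0), start_s = numeric(0),
                  dur_s = numeric(0)))
  }
  w <- soc$partner_weights
  prob <- if (is.null(w)) rep(1, length(others)) else unname(w[others])
  tibble(
    initiator = mouse,
    target = others[sample.int(length(others), n, replace = TRUE,
                               prob = prob)],
    type = c("nose_nose", "nose_anogenital", "side_side")[
      sample.int(3L, n, replace = TRUE, prob = c(0.25, 0.35, 0.40))],
    start_s = times,
    dur_s = pmax(1.5, rexp(n, 1 / soc$mean_contact_duration))
  )
}

#' Simulate one cage session
#'
#' Runs the agent-based simulator for the mice in `identities` under
#' `config`, returning the pose stream (long format, one row per frame and
#' mouse) together with the ground-truth log of realized contact episodes.
#' Deterministic for a fixed seed.
#'
#' @param config An `etho_config` from [simulation_config()].
#' @param identities Identity table from [make_identities()].
#' @return A list of class `etho_session` with elements `frames`,
#'   `identities`, `ground_truth` and `config`.
#' @export
simulate_session <- function(config, identities = make_identities()) {
  stopifnot(inherits(config, "etho_config"))
  if (nrow(identities) < 1) stop("identities must contain at least one mouse")
  if (anyDuplicated(identities$mouse_id))
    stop("mouse_id must be unique within a cage")

  n_mice <- nrow(identities)
  n_frames <- as.integer(round(config$duration * config$frame_rate))
  dt <- 1 / config$frame_rate
  margin <- config$motion$wall_margin
  lo <- margin
  hi <- config$arena_size - margin

  x0 <- matrix(0, n_mice, 2)
  heading0 <- numeric(n_mice)
  dheading <- matrix(0, n_frames, n_mice)
  speed <- matrix(0, n_frames, n_mice)
  elong <- matrix(1, n_frames, n_mice)
  turn_sd <- (1 - config$motion$persistence) * 3 * sqrt(dt)

  for (i in seq_len(n_mice)) {
    id <- identities$mouse_id[i]
    with_local_seed(substream_seed(paste0(id, "/move"), config$seed), {
      x0[i, ] <- runif(2, lo, hi)
      heading0[i] <- runif(1, -pi, pi)
      dheading[, i] <- rnorm(n_frames, 0, turn_sd)
      mv <- moving_bouts(n_frames, config$frame_rate)
      speed[, i] <- ifelse(mv, config$motion$speed_scale *
                             rgamma(n_frames, shape = 4, rate = 4), 0)
      elong[, i] <- pmin(1.15, pmax(0.8, 1 + 0.05 * rnorm(n_frames)))
    })
  }

  episodes <- vector("list", n_mice)
  for (i in seq_len(n_mice)) {
    id <- identities$mouse_id[i]
    episodes[[i]] <- with_local_seed(
      substream_seed(paste0(id, "/social"), config$seed),
      schedule_episodes(id, sort(setdiff(identities$mouse_id, id)),
                        identities$genotype[i], config))
  }
  episodes <- dplyr::bind_rows(episodes) %>% arrange(start_s, initiator)

  idx <- setNames(seq_len(n_mice) - 1L, identities$mouse_id)
  type_code <- c(nose_nose = 0L, nose_anogenital = 1L, side_side = 2L)
  res <- sim_core_cpp(
    n_frames, n_mice, dt, lo, hi, x0, heading0, dheading, speed, elong,
    config$body$nose_off, config$body$tail_off,
    avoid_radius = config$motion$avoid_radius, avoid_gain = 0.5,
    ep_initiator = unname(idx[episodes$initiator]),
    ep_target = unname(idx[episodes$target]),
    ep_type = unname(type_code[episodes$type]),
    ep_start_frame = as.integer(floor(episodes$start_s * config$frame_rate)),
    ep_dur_frames = episodes$dur_s * config$frame_rate,
    contact_reach = 1.2,
    approach_speed = 2 * config$motion$speed_scale,
    max_step = config$motion$speed_scale * 4.9 * dt,
    timeout_frames = as.integer(15 * config$frame_rate),
    gt_dist = config$body$contact_dist,
    depart_frames = as.integer(round(config$frame_rate)),
    queue_wait_frames = as.integer(120 * config$frame_rate))

  frames <- tibble(
    frame = rep(seq_len(n_frames) - 1L, each = n_mice),
    t = rep((seq_len(n_frames) - 1L) / config$frame_rate, each = n_mice),
    mouse_id = rep(identities$mouse_id, n_frames),
    nose_x = as.vector(t(res$nx)), nose_y = as.vector(t(res$ny)),
    center_x = as.vector(t(res$cx)), center_y = as.vector(t(res$cy)),
    tail_x = as.vector(t(res$tx)), tail_y = as.vector(t(res$ty)),
    detected = TRUE
  )

  # ground-truth bounds are the first/last frames at which the two bodies
  # were within the contact threshold, i.e. what a geometric annotator can
  # in principle recover
  realized <- res$ep_state == 2L & res$ep_first_le >= 0L &
    res$ep_last_le >= res$ep_first_le
  ground_truth <- episodes[realized, c("initiator", "target", "type")]
  ground_truth$start_s <- res$ep_first_le[realized] / config$frame_rate
  ground_truth$end_s <- (res$ep_last_le[realized] + 1L) / config$frame_rate

  structure(list(frames = frames, identities = identities,
                 ground_truth = as_tibble(ground_truth), config = config),
            class = "etho_session")
}

#' @export
print.etho_session <- function(x, ...) {
  cat(sprintf(
    "<etho_session> %d mice, %d frames @ %g fps (%.1f min), %d ground-truth episodes\n",
    nrow(x$identities), max(x$frames$frame) + 1L, x$config$frame_rate,
    x$config$duration / 60, nrow(x$ground_truth)))
  invisible(x)
}
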