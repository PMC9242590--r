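# Event annotation: converts a pose stream into ethogram event intervals.
# All intervals are half-open [start_frame, end_frame); durations are
# (end - start) / frame_rate.

#' Geometry parameters for event annotation
#'
#' Thresholds are LMT-plausible defaults, configurable and echoed into the
#' pipeline manifest: a contact is a pair of body polylines within
#' `contact_dist`; nose-mediated contact types use `nose_dist`; side-by-side
#' requires body axes within `parallel_angle` degrees; events shorter than
#' `min_event_frames` are discarded and interruptions up to
#' `merge_gap_frames` are bridged.
#'
#' @param contact_dist Body polyline distance threshold (cm).
#' @param nose_dist Nose-to-point distance threshold (cm).
#' @param parallel_angle Side-by-side axis angle threshold (degrees, in
#'   (0, 90)).
#' @param min_event_frames Minimum event length (frames).
#' @param merge_gap_frames Maximum bridged interruption (frames).
#' @param speed_threshold Moving/stopped cut-off on smoothed centre speed
#'   (cm/s).
#' @param smoothing_window Frames in the centred moving-average speed filter.
#' @param approach_cone Half-width of the frontal cone for social approach
#'   (degrees).
#' @param sap_quantile Session elongation quantile above which a slow mouse
#'   is in stretch-attend posture.
#' @return A list of class `etho_geometry`.
#' @export
geometry_params <- function(contact_dist = 2.0, nose_dist = 1.5,
                            parallel_angle = 45, min_event_frames = 3L,
                            merge_gap_frames = 2L, speed_threshold = 1.75,
                            smoothing_window = 5L, approach_cone = 60,
                            sap_quantile = 0.9) {
  vals <- c(contact_dist, nose_dist, parallel_angle, min_event_frames,
            merge_gap_frames, speed_threshold, smoothing_window)
  if (any(vals <= 0)) stop("geometry parameters must be strictly positive")
  if (parallel_angle <= 0 || parallel_angle >= 90)
    stop("parallel_angle must lie in (0, 90) degrees")
  structure(list(contact_dist = contact_dist, nose_dist = nose_dist,
                 parallel_angle = parallel_angle,
                 min_event_frames = as.integer(min_event_frames),
                 merge_gap_frames = as.integer(merge_gap_frames),
                 speed_threshold = speed_threshold,
                 smoothing_window = as.integer(smoothing_window),
                 approach_cone = approach_cone,
                 sap_quantile = sap_quantile),
            class = "etho_geometry")
}

# ---------------------------------------------------------------------------
# internal helpers
# ---------------------------------------------------------------------------

# infer the sampling rate from the frame/time grid
frame_rate_of <- function(frames) {
  ft <- unique(frames[c("frame", "t")])
  ft <- ft[order(ft$frame), ]
  if (nrow(ft) < 2) return(1)
  1 / stats::median(diff(ft$t) / diff(ft$frame))
}

# split a long pose stream into per-mouse coordinate matrices aligned on the
# common frame grid; undetected or absent rows become NA
pose_split <- function(frames) {
  f_all <- sort(unique(frames$frame))
  ft <- unique(frames[c("frame", "t")])
  t_all <- ft$t[match(f_all, ft$frame)]
  mice <- sort(unique(frames$mouse_id))
  cols <- c("nose_x", "nose_y", "center_x", "center_y", "tail_x", "tail_y")
  per <- lapply(mice, function(m) {
    sub <- frames[frames$mouse_id == m, , drop = FALSE]
    idx <- match(f_all, sub$frame)
    mat <- as.matrix(sub[cols])[idx, , drop = FALSE]
    det <- !is.na(idx) & sub$detected[pmax(idx, 1L)] %in% TRUE
    mat[!det, ] <- NA_real_
    list(mat = mat, detected = det)
  })
  names(per) <- mice
  list(frames = f_all, t = t_all, mice = mice, per = per,
       frame_rate = frame_rate_of(frames))
}

# run-length interval assembly with gap bridging and minimum length;
# returns 1-based start positions and exclusive end positions
assemble_intervals <- function(active, merge_gap = 0L, min_len = 1L) {
  active[is.na(active)] <- FALSE
  if (!any(active)) return(data.frame(start = integer(0), end = integer(0)))
  if (merge_gap > 0) {
    r <- rle(active)
    inner <- seq_along(r$values)
    bridge <- !r$values & r$lengths <= merge_gap &
      inner > 1L & inner < length(r$values)
    r$values[bridge] <- TRUE
    active <- inverse.rle(r)
  }
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep] + 1L)
}

# positions -> event tibble on the original frame grid
intervals_to_events <- function(iv, ps, trait, subject,
                                partner = NA_character_,
                                members = NA_character_) {
  n <- length(ps$frames)
  if (nrow(iv) == 0) return(empty_events())
  start_f <- ps$frames[iv$start]
  end_f <- ifelse(iv$end > n, ps$frames[n] + 1L, ps$frames[pmin(iv$end, n)])
  fr <- ps$frame_rate
  t0 <- ps$t[1] - ps$frames[1] / fr
  tibble(trait = trait, subject = subject, partner = partner,
         members = members,
         start_frame = as.integer(start_f), end_frame = as.integer(end_f),
         start_s = t0 + start_f / fr, end_s = t0 + end_f / fr,
         duration_s = (end_f - start_f) / fr)
}

empty_events <- function() {
  tibble(trait = character(0), subject = character(0), partner = character(0),
         members = character(0), start_frame = integer(0),
         end_frame = integer(0), start_s = numeric(0), end_s = numeric(0),
         duration_s = numeric(0))
}

# centred moving average with shrinking window at the edges
roll_mean <- function(x, w) {
  if (w <= 1L || length(x) < 2) return(x)
  half <- (w - 1L) %/% 2L
  n <- length(x)
  xx <- ifelse(is.na(x), 0, x)
  ok <- as.numeric(!is.na(x))
  cs <- c(0, cumsum(xx))
  co <- c(0, cumsum(ok))
  i1 <- pmax(seq_len(n) - half, 1L)
  i2 <- pmin(seq_len(n) + half, n)
  denom <- co[i2 + 1L] - co[i1]
  out <- (cs[i2 + 1L] - cs[i1]) / ifelse(denom == 0, NA_real_, denom)
  out
}

# per-frame centre speed (cm/s), smoothed
mouse_speed <- function(mat, ps, params) {
  n <- nrow(mat)
  dx <- diff(mat[, "center_x"])
  dy <- diff(mat[, "center_y"])
  v <- sqrt(dx^2 + dy^2) * ps$frame_rate
  v <- c(v[1], v)  # speed at the first frame copies the first step
  roll_mean(v, params$smoothing_window)
}

# boolean per-frame coverage of intervals involving a mouse
events_to_mask <- function(events, ps, mouse = NULL, pair = NULL) {
  n <- length(ps$frames)
  mask <- rep(FALSE, n)
  if (nrow(events) == 0) return(mask)
  sel <- rep(TRUE, nrow(events))
  if (!is.null(mouse))
    sel <- events$subject == mouse | (!is.na(events$partner) &
                                        events$partner == mouse)
  if (!is.null(pair)) {
    p <- sort(pair)
    sel <- sel & pmin(events$subject, events$partner, na.rm = TRUE) == p[1] &
      pmax(events$subject, events$partner, na.rm = TRUE) == p[2]
  }
  for (k in which(sel)) {
    i1 <- match(events$start_frame[k], ps$frames)
    i2 <- events$end_frame[k] - events$start_frame[k] + i1 - 1L
    mask[i1:min(i2, n)] <- TRUE
  }
  mask
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

# ---------------------------------------------------------------------------
# contact detection
# ---------------------------------------------------------------------------

#' Detect pairwise body contacts
#'
#' An (undirected) contact interval is a maximal run of frames during which
#' the minimum distance between the two mice's body polylines
#' (nose - centre - tail base) is at most `contact_dist`, after bridging
#' interruptions up to `merge_gap_frames` and discarding events shorter than
#' `min_event_frames`. Frames where either mouse is undetected count as
#' interruptions.
#'
#' @param frames Pose stream (long format).
#' @param params [geometry_params()].
#' @return Event tibble with `trait = "contact"`, `subject` < `partner`
#'   lexicographically, half-open `[start_frame, end_frame)`.
#' @export
detect_contacts <- function(frames, params = geometry_params()) {
  ps <- pose_split(frames)
  if (length(ps$mice) < 2) return(empty_events())
  out <- list()
  for (i in seq_along(ps$mice)) {
    for (j in seq_along(ps$mice)) {
      if (j <= i) next
      a <- ps$per[[i]]
      b <- ps$per[[j]]
      d <- polyline_pair_dist_cpp(a$mat, b$mat)
      active <- a$detected & b$detected & !is.na(d) & d <= params$contact_dist
      iv <- assemble_intervals(active, params$merge_gap_frames,
                               params$min_event_frames)
      out[[pair_key(ps$mice[i], ps$mice[j])]] <-
        intervals_to_events(iv, ps, "contact", ps$mice[i], ps$mice[j])
    }
  }
  bind_rows(out)
}

# ---------------------------------------------------------------------------
# contact typing
# ---------------------------------------------------------------------------

# angle (degrees, 0..180) between two body axes
axis_angle <- function(ax, ay, bx, by) {
  na <- sqrt(ax^2 + ay^2)
  nb <- sqrt(bx^2 + by^2)
  cosv <- (ax * bx + ay * by) / (na * nb)
  cosv[na == 0 | nb == 0] <- NA_real_
  acos(pmin(1, pmax(-1, cosv))) * 180 / pi
}

#' Classify the contact type of a single pose pair
#'
#' Evaluates, for one frame, which contact classes fire between mouse `a`
#' and mouse `b`. Classes are non-exclusive: every class whose geometric
#' predicate holds is returned. Directional ano-genital contacts are tagged
#' `nose_anogenital_ab` (a's nose at b's tail base) and `nose_anogenital_ba`.
#' With a degenerate body (nose equal to tail base) the orientation is
#' undefined and the side classes are suppressed; nose classes are still
#' evaluated.
#'
#' @param pose_a,pose_b Named numeric vectors (or one-row data frames) with
#'   `nose_x`, `nose_y`, `center_x`, `center_y`, `tail_x`, `tail_y`.
#' @param params [geometry_params()].
#' @return Character vector of firing class labels (possibly empty).
#' @export
classify_contact_type <- function(pose_a, pose_b,
                                  params = geometry_params()) {
  g <- function(p, f) as.numeric(p[[f]])
  out <- character(0)
  dn <- sqrt((g(pose_a, "nose_x") - g(pose_b, "nose_x"))^2 +
               (g(pose_a, "nose_y") - g(pose_b, "nose_y"))^2)
  if (dn <= params$nose_dist) out <- c(out, "nose_nose")
  dab <- sqrt((g(pose_a, "nose_x") - g(pose_b, "tail_x"))^2 +
                (g(pose_a, "nose_y") - g(pose_b, "tail_y"))^2)
  if (dab <= params$nose_dist) out <- c(out, "nose_anogenital_ab")
  dba <- sqrt((g(pose_b, "nose_x") - g(pose_a, "tail_x"))^2 +
                (g(pose_b, "nose_y") - g(pose_a, "tail_y"))^2)
  if (dba <= params$nose_dist) out <- c(out, "nose_anogenital_ba")
  dc <- sqrt((g(pose_a, "center_x") - g(pose_b, "center_x"))^2 +
               (g(pose_a, "center_y") - g(pose_b, "center_y"))^2)
  ang <- axis_angle(g(pose_a, "nose_x") - g(pose_a, "tail_x"),
                    g(pose_a, "nose_y") - g(pose_a, "tail_y"),
                    g(pose_b, "nose_x") - g(pose_b, "tail_x"),
                    g(pose_b, "nose_y") - g(pose_b, "tail_y"))
  if (!is.na(ang) && dc <= params$contact_dist) {
    if (ang <= params$parallel_angle) out <- c(out, "side_side")
    if (ang >= 180 - params$parallel_angle)
      out <- c(out, "side_side_opposite")
  }
  out
}

#' Classify contact intervals by type
#'
#' Within frames covered by a pairwise contact, evaluates the type
#' predicates of [classify_contact_type()] per frame and assembles typed
#' event intervals with the same bridging and minimum-length rules as
#' contact detection. Types are non-exclusive; `nose_anogenital` events are
#' directional with `subject` the giver (its nose at the partner's tail
#' base) and `partner` the receiver.
#'
#' @param frames Pose stream.
#' @param contacts Output of [detect_contacts()].
#' @param params [geometry_params()].
#' @return Event tibble with traits `nose_nose`, `nose_anogenital`,
#'   `side_side`, `side_side_opposite`.
#' @export
classify_contacts <- function(frames, contacts,
                              params = geometry_params()) {
  ps <- pose_split(frames)
  if (nrow(contacts) == 0) return(empty_events())
  out <- list()
  pairs <- unique(contacts[c("subject", "partner")])
  for (k in seq_len(nrow(pairs))) {
    a_id <- pairs$subject[k]
    b_id <- pairs$partner[k]
    a <- ps$per[[a_id]]$mat
    b <- ps$per[[b_id]]$mat
    in_ct <- events_to_mask(contacts, ps, pair = c(a_id, b_id))
    dn <- sqrt((a[, "nose_x"] - b[, "nose_x"])^2 +
                 (a[, "nose_y"] - b[, "nose_y"])^2)
    dab <- sqrt((a[, "nose_x"] - b[, "tail_x"])^2 +
                  (a[, "nose_y"] - b[, "tail_y"])^2)
    dba <- sqrt((b[, "nose_x"] - a[, "tail_x"])^2 +
                  (b[, "nose_y"] - a[, "tail_y"])^2)
    dc <- sqrt((a[, "center_x"] - b[, "center_x"])^2 +
                 (a[, "center_y"] - b[, "center_y"])^2)
    ang <- axis_angle(a[, "nose_x"] - a[, "tail_x"],
                      a[, "nose_y"] - a[, "tail_y"],
                      b[, "nose_x"] - b[, "tail_x"],
                      b[, "nose_y"] - b[, "tail_y"])
    asm <- function(active, trait, subject, partner) {
      iv <- assemble_intervals(in_ct & active %in% TRUE,
                               params$merge_gap_frames,
                               params$min_event_frames)
      intervals_to_events(iv, ps, trait, subject, partner)
    }
    out[[length(out) + 1L]] <- asm(dn <= params$nose_dist, "nose_nose",
                                   a_id, b_id)
    out[[length(out) + 1L]] <- asm(dab <= params$nose_dist,
                                   "nose_anogenital", a_id, b_id)
    out[[length(out) + 1L]] <- asm(dba <= params$nose_dist,
                                   "nose_anogenital", b_id, a_id)
    side_ok <- !is.na(ang) & dc <= params$contact_dist
    out[[length(out) + 1L]] <- asm(side_ok & ang <= params$parallel_angle,
                                   "side_side", a_id, b_id)
    out[[length(out) + 1L]] <- asm(
      side_ok & ang >= 180 - params$parallel_angle,
      "side_side_opposite", a_id, b_id)
  }
  bind_rows(out)
}

# ---------------------------------------------------------------------------
# locomotion states
# ---------------------------------------------------------------------------

#' Annotate locomotion-by-contact states
#'
#' Per frame each mouse is moving (smoothed centre speed above
#' `speed_threshold`) or stopped, and in contact (covered by any contact
#' interval) or alone; the four combinations `move_alone`, `stop_alone`,
#' `move_in_contact`, `stop_in_contact` partition each mouse's detected
#' frames exactly, so state intervals are assembled as raw runs without gap
#' bridging or minimum-length filtering.
#'
#' @param frames Pose stream.
#' @param contacts Output of [detect_contacts()].
#' @param params [geometry_params()].
#' @return Event tibble with the four state traits per mouse.
#' @export
annotate_states <- function(frames, contacts, params = geometry_params()) {
  ps <- pose_split(frames)
  out <- list()
  for (m in ps$mice) {
    p <- ps$per[[m]]
    v <- mouse_speed(p$mat, ps, params)
    moving <- v > params$speed_threshold
    in_ct <- events_to_mask(contacts, ps, mouse = m)
    state <- ifelse(moving, ifelse(in_ct, "move_in_contact", "move_alone"),
                    ifelse(in_ct, "stop_in_contact", "stop_alone"))
    state[!p$detected | is.na(v)] <- NA_character_
    for (s in c("move_alone", "stop_alone", "move_in_contact",
                "stop_in_contact")) {
      iv <- assemble_intervals(state %in% s, merge_gap = 0L, min_len = 1L)
      out[[length(out) + 1L]] <- intervals_to_events(iv, ps, s, m)
    }
  }
  bind_rows(out)
}

# ---------------------------------------------------------------------------
# social approach / escape
# ---------------------------------------------------------------------------

#' Detect social approach and escape events
#'
#' Approach: the focal mouse is moving, its distance to a specific partner
#' is decreasing, and the partner lies within the frontal cone
#' (`approach_cone` degrees around the nose-centre axis); the run ends at
#' contact onset or when the geometry breaks. Escape: within 1 s after a
#' contact between the pair ends, the focal mouse is moving with increasing
#' distance to that partner. Both are directional (subject = focal).
#'
#' @param frames Pose stream.
#' @param contacts Output of [detect_contacts()].
#' @param params [geometry_params()].
#' @return Event tibble with traits `social_approach` and `social_escape`.
#' @export
detect_approach_escape <- function(frames, contacts,
                                   params = geometry_params()) {
  ps <- pose_split(frames)
  if (length(ps$mice) < 2) return(empty_events())
  fr <- ps$frame_rate
  n <- length(ps$frames)
  out <- list()
  for (i_id in ps$mice) {
    p <- ps$per[[i_id]]
    v <- mouse_speed(p$mat, ps, params)
    moving <- v > params$speed_threshold
    for (j_id in setdiff(ps$mice, i_id)) {
      q <- ps$per[[j_id]]
      d <- roll_mean(sqrt((p$mat[, "center_x"] - q$mat[, "center_x"])^2 +
                            (p$mat[, "center_y"] - q$mat[, "center_y"])^2),
                     params$smoothing_window)
      dd <- c(diff(d), 0)
      closing <- dd < -1e-9
      departing <- dd > 1e-9
      hx <- p$mat[, "nose_x"] - p$mat[, "center_x"]
      hy <- p$mat[, "nose_y"] - p$mat[, "center_y"]
      tx <- q$mat[, "center_x"] - p$mat[, "center_x"]
      ty <- q$mat[, "center_y"] - p$mat[, "center_y"]
      ang <- axis_angle(hx, hy, tx, ty)
      cone <- !is.na(ang) & ang <= params$approach_cone
      in_ct <- events_to_mask(contacts, ps, pair = c(i_id, j_id))
      appr <- moving %in% TRUE & closing & cone & !in_ct &
        p$detected & q$detected
      iv <- assemble_intervals(appr, params$merge_gap_frames,
                               params$min_event_frames)
      out[[length(out) + 1L]] <-
        intervals_to_events(iv, ps, "social_approach", i_id, j_id)
      # escapes seeded at each contact end of this pair
      pair_ct <- contacts[pair_key(contacts$subject, contacts$partner) ==
                            pair_key(i_id, j_id), , drop = FALSE]
      esc <- moving %in% TRUE & departing & !in_ct & p$detected & q$detected
      if (nrow(pair_ct) > 0 && any(esc)) {
        r <- rle(esc)
        run_end <- cumsum(r$lengths)
        run_start <- run_end - r$lengths + 1L
        run_start <- run_start[r$values]
        run_end <- run_end[r$values]
        run_len <- run_end - run_start + 1L
        for (e_f in pair_ct$end_frame) {
          e_pos <- match(e_f, ps$frames)
          if (is.na(e_pos)) e_pos <- n + 1L
          w_hi <- e_pos + as.integer(round(fr)) - 1L
          hit <- which(run_start >= e_pos & run_start <= w_hi &
                         run_len >= params$min_event_frames)
          if (length(hit)) {
            k <- hit[1]
            iv <- data.frame(start = run_start[k], end = run_end[k] + 1L)
            out[[length(out) + 1L]] <-
              intervals_to_events(iv, ps, "social_escape", i_id, j_id)
          }
        }
      }
    }
  }
  res <- bind_rows(out)
  if (nrow(res) > 0) res <- distinct(res)
  res
}

# ---------------------------------------------------------------------------
# stretch-attend posture
# ---------------------------------------------------------------------------

#' Detect stretch-attend posture (SAP)
#'
#' SAP frames combine body elongation (nose-to-tail-base distance above the
#' mouse's own session `sap_quantile`) with near-immobility (smoothed speed
#' below half of `speed_threshold`); runs are assembled with the usual
#' bridging and minimum-length rules. Sessions shorter than 1000 detected
#' frames cannot support the quantile estimate and yield an empty set with
#' a warning.
#'
#' @param frames Pose stream.
#' @param params [geometry_params()].
#' @return Event tibble with `trait = "SAP"`.
#' @export
detect_sap <- function(frames, params = geometry_params()) {
  ps <- pose_split(frames)
  out <- list()
  for (m in ps$mice) {
    p <- ps$per[[m]]
    if (sum(p$detected) < 1000) {
      warning("session too short to estimate the elongation quantile for ",
              m, "; no SAP events emitted")
      next
    }
    elong <- sqrt((p$mat[, "nose_x"] - p$mat[, "tail_x"])^2 +
                    (p$mat[, "nose_y"] - p$mat[, "tail_y"])^2)
    thr <- quantile(elong, params$sap_quantile, na.rm = TRUE, names = FALSE)
    v <- mouse_speed(p$mat, ps, params)
    active <- elong > thr & v < params$speed_threshold / 2
    iv <- assemble_intervals(active %in% TRUE, params$merge_gap_frames,
                             params$min_event_frames)
    out[[length(out) + 1L]] <- intervals_to_events(iv, ps, "SAP", m)
  }
  bind_rows(out)
}

#' Run the full annotation stage
#'
#' Convenience wrapper producing the complete event set: contacts, typed
#' contacts, locomotion states, approach/escape and SAP.
#'
#' @param frames Pose stream.
#' @param params [geometry_params()].
#' @return Combined event tibble.
#' @export
annotate_events <- function(frames, params = geometry_params()) {
  contacts <- detect_contacts(frames, params)
  bind_rows(
    contacts,
    classify_contacts(frames, contacts, params),
    annotate_states(frames, contacts, params),
    detect_approach_escape(frames, contacts, params),
    detect_sap(frames, params)
  )
}
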