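# Fixture builders and independent brute-force oracles. Oracles are written
# from first principles (per-frame loops, endpoint-based segment distances,
# naive run assembly) so they share no code with the package internals.

# build a long-format pose stream from per-mouse data frames with columns
# frame, nose_x .. tail_y (detected defaults to TRUE)
build_frames <- function(per_mouse, frame_rate = 10) {
  rows <- lapply(names(per_mouse), function(id) {
    df <- as.data.frame(per_mouse[[id]])
    df$mouse_id <- id
    if (is.null(df$detected)) df$detected <- TRUE
    df$t <- df$frame / frame_rate
    df
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$frame, out$mouse_id), ]
  tibble::as_tibble(out[c("frame", "t", "mouse_id", "nose_x", "nose_y",
                          "center_x", "center_y", "tail_x", "tail_y",
                          "detected")])
}

# a mouse whose centre follows `centers` (n x 2) with heading along the path
# (or fixed), body length 2 * half
path_mouse <- function(centers, heading = NULL, half = 0.3) {
  n <- nrow(centers)
  if (is.null(heading)) {
    dx <- c(diff(centers[, 1]), 0)
    dy <- c(diff(centers[, 2]), 0)
    heading <- atan2(dy, dx)
    heading[dx == 0 & dy == 0] <- NA
    # carry last defined heading forward
    for (i in seq_len(n)) {
      if (is.na(heading[i])) heading[i] <- if (i > 1) heading[i - 1] else 0
    }
  } else if (length(heading) == 1) {
    heading <- rep(heading, n)
  }
  data.frame(frame = seq_len(n) - 1L,
             nose_x = centers[, 1] + half * cos(heading),
             nose_y = centers[, 2] + half * sin(heading),
             center_x = centers[, 1], center_y = centers[, 2],
             tail_x = centers[, 1] - half * cos(heading),
             tail_y = centers[, 2] - half * sin(heading))
}

static_mouse <- function(x, y, heading = 0, n = 100, half = 0.3) {
  path_mouse(cbind(rep(x, n), rep(y, n)), heading = heading, half = half)
}

# random poses on a small arena: dense enough for frequent contacts
random_scene <- function(n_frames, mice = c("a", "b", "c"), seed = 1,
                         span = 8, half = 1.5, frame_rate = 10) {
  set.seed(seed)
  per <- lapply(mice, function(m) {
    cx <- cumsum(rnorm(n_frames, 0, 0.6))
    cy <- cumsum(rnorm(n_frames, 0, 0.6))
    cx <- span / 2 + (cx %% span) - span / 2
    cy <- span / 2 + (cy %% span) - span / 2
    h <- runif(n_frames, -pi, pi)
    data.frame(frame = seq_len(n_frames) - 1L,
               nose_x = cx + half * cos(h), nose_y = cy + half * sin(h),
               center_x = cx, center_y = cy,
               tail_x = cx - half * cos(h), tail_y = cy - half * sin(h))
  })
  names(per) <- mice
  build_frames(per, frame_rate = frame_rate)
}

# static frames for a set of mice (positions only matter for tie-breaking)
flat_frames_acc <- function(mice, n) {
  per <- lapply(seq_along(mice), function(i) static_mouse(10 * i, 10, n = n))
  names(per) <- mice
  build_frames(per)
}

# --- independent geometry oracle ------------------------------------------

# distance from point p to segment ab, by projection
.pt_seg <- function(px, py, ax, ay, bx, by) {
  ux <- bx - ax
  uy <- by - ay
  L2 <- ux^2 + uy^2
  if (L2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  tt <- max(0, min(1, ((px - ax) * ux + (py - ay) * uy) / L2))
  sqrt((px - ax - tt * ux)^2 + (py - ay - tt * uy)^2)
}

# do segments p1p2 and q1q2 properly intersect (or touch)?
.seg_intersect <- function(p1, p2, q1, q2) {
  o <- function(a, b, c) {
    v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    sign(v)
  }
  o1 <- o(p1, p2, q1); o2 <- o(p1, p2, q2)
  o3 <- o(q1, q2, p1); o4 <- o(q1, q2, p2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  on_seg <- function(a, b, c) {
    o(a, b, c) == 0 &&
      min(a[1], b[1]) - 1e-12 <= c[1] && c[1] <= max(a[1], b[1]) + 1e-12 &&
      min(a[2], b[2]) - 1e-12 <= c[2] && c[2] <= max(a[2], b[2]) + 1e-12
  }
  on_seg(p1, p2, q1) || on_seg(p1, p2, q2) ||
    on_seg(q1, q2, p1) || on_seg(q1, q2, p2)
}

# min distance between two segments: zero if they intersect, else the
# smallest endpoint-to-segment distance (exact for non-intersecting
# segments)
.seg_seg <- function(p1, p2, q1, q2) {
  if (.seg_intersect(p1, p2, q1, q2)) return(0)
  min(.pt_seg(q1[1], q1[2], p1[1], p1[2], p2[1], p2[2]),
      .pt_seg(q2[1], q2[2], p1[1], p1[2], p2[1], p2[2]),
      .pt_seg(p1[1], p1[2], q1[1], q1[2], q2[1], q2[2]),
      .pt_seg(p2[1], p2[2], q1[1], q1[2], q2[1], q2[2]))
}

# per-frame polyline distance between two mice, plain loop
oracle_pair_dist <- function(frames, id_a, id_b) {
  fa <- as.data.frame(frames[frames$mouse_id == id_a, ])
  fb <- as.data.frame(frames[frames$mouse_id == id_b, ])
  fa <- fa[order(fa$frame), ]
  fb <- fb[order(fb$frame), ]
  n <- nrow(fa)
  d <- numeric(n)
  for (i in seq_len(n)) {
    segs_a <- list(
      list(c(fa$nose_x[i], fa$nose_y[i]), c(fa$center_x[i], fa$center_y[i])),
      list(c(fa$center_x[i], fa$center_y[i]), c(fa$tail_x[i], fa$tail_y[i])))
    segs_b <- list(
      list(c(fb$nose_x[i], fb$nose_y[i]), c(fb$center_x[i], fb$center_y[i])),
      list(c(fb$center_x[i], fb$center_y[i]), c(fb$tail_x[i], fb$tail_y[i])))
    best <- Inf
    for (sa in segs_a) for (sb in segs_b) {
      best <- min(best, .seg_seg(sa[[1]], sa[[2]], sb[[1]], sb[[2]]))
    }
    d[i] <- best
  }
  d
}

# naive interval assembly: walk the boolean vector, bridge short gaps,
# drop short runs
oracle_assemble <- function(active, merge_gap, min_len) {
  active[is.na(active)] <- FALSE
  n <- length(active)
  # bridge gaps
  if (merge_gap > 0) {
    i <- 1
    while (i <= n) {
      if (!active[i]) {
        j <- i
        while (j <= n && !active[j]) j <- j + 1
        gap <- j - i
        if (i > 1 && j <= n && gap <= merge_gap) active[i:(j - 1)] <- TRUE
        i <- j
      } else i <- i + 1
    }
  }
  res <- NULL
  i <- 1
  while (i <= n) {
    if (active[i]) {
      j <- i
      while (j <= n && active[j]) j <- j + 1
      if (j - i >= min_len)
        res <- rbind(res, data.frame(start = i, end = j))
      i <- j
    } else i <- i + 1
  }
  if (is.null(res)) data.frame(start = integer(0), end = integer(0)) else res
}

# brute-force contact events for a scene (frames must start at frame 0 and
# be contiguous)
oracle_contacts <- function(frames, params) {
  mice <- sort(unique(frames$mouse_id))
  out <- NULL
  for (i in seq_along(mice)) for (j in seq_along(mice)) {
    if (j <= i) next
    d <- oracle_pair_dist(frames, mice[i], mice[j])
    iv <- oracle_assemble(d <= params$contact_dist,
                          params$merge_gap_frames, params$min_event_frames)
    if (nrow(iv) > 0)
      out <- rbind(out, data.frame(subject = mice[i], partner = mice[j],
                                   start_frame = iv$start - 1L,
                                   end_frame = iv$end - 1L))
  }
  out
}
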