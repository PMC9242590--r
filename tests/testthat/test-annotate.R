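# Event annotation: thresholds, scripted fixtures with known switch points,
# and exact agreement with brute-force oracles.

test_that("distant static mice produce no contact events", {
  fr <- build_frames(list(a = static_mouse(5, 5, n = 200),
                          b = static_mouse(45, 45, n = 200)))
  expect_equal(nrow(detect_contacts(fr)), 0)
})

test_that("contact length threshold is exact at the boundary", {
  p <- geometry_params(min_event_frames = 4, merge_gap_frames = 1)
  make_scene <- function(k) {
    n <- 60
    ax <- rep(40, n)
    ax[30:(30 + k - 1)] <- 5.5  # within contact_dist of b for k frames
    build_frames(list(
      a = path_mouse(cbind(ax, rep(5, n)), heading = 0),
      b = static_mouse(5, 5, heading = 0, n = n)))
  }
  ev <- detect_contacts(make_scene(4), p)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$end_frame - ev$start_frame, 4)
  expect_equal(nrow(detect_contacts(make_scene(3), p)), 0)
})

test_that("contact assembly equals the brute-force oracle on random scenes", {
  p <- geometry_params()
  for (sd in c(2, 11)) {
    fr <- random_scene(500, mice = c("a", "b", "c"), seed = sd)
    got <- detect_contacts(fr, p)
    want <- oracle_contacts(fr, p)
    expect_gt(nrow(got), 0)
    got <- got[order(got$subject, got$partner, got$start_frame), ]
    want <- want[order(want$subject, want$partner, want$start_frame), ]
    expect_equal(got$subject, want$subject)
    expect_equal(got$partner, want$partner)
    expect_equal(got$start_frame, want$start_frame)
    expect_equal(got$end_frame, want$end_frame)
  }
})

test_that("enlarging contact_dist never removes a contact frame", {
  fr <- random_scene(400, seed = 3)
  mask_of <- function(dist) {
    ev <- detect_contacts(fr, geometry_params(contact_dist = dist))
    m <- rep(FALSE, 400)
    for (i in seq_len(nrow(ev)))
      m[(ev$start_frame[i] + 1):ev$end_frame[i]] <- TRUE
    m
  }
  m1 <- mask_of(1.5)
  m2 <- mask_of(2.5)
  expect_true(all(m2[m1]))
})

test_that("relabeling mouse ids permutes contact events correspondingly", {
  fr <- random_scene(300, mice = c("a", "b", "c"), seed = 8)
  relab <- c(a = "zeta", b = "alpha", c = "mu")
  fr2 <- fr
  fr2$mouse_id <- unname(relab[fr$mouse_id])
  ev1 <- detect_contacts(fr)
  ev2 <- detect_contacts(fr2)
  key1 <- sort(paste(pmin(relab[ev1$subject], relab[ev1$partner]),
                     pmax(relab[ev1$subject], relab[ev1$partner]),
                     ev1$start_frame, ev1$end_frame))
  key2 <- sort(paste(pmin(ev2$subject, ev2$partner),
                     pmax(ev2$subject, ev2$partner),
                     ev2$start_frame, ev2$end_frame))
  expect_equal(key2, key1)
})

test_that("contact type predicates fire with correct directionality", {
  p <- geometry_params()
  # facing mice, noses 0.75 cm apart
  a <- c(nose_x = 0, nose_y = 0, center_x = -3, center_y = 0,
         tail_x = -6, tail_y = 0)
  b <- c(nose_x = 0.75, nose_y = 0, center_x = 3.75, center_y = 0,
         tail_x = 6.75, tail_y = 0)
  expect_equal(classify_contact_type(a, b, p), "nose_nose")

  # parallel side-by-side 1 cm apart, then one reversed
  a2 <- c(nose_x = 3, nose_y = 0, center_x = 0, center_y = 0,
          tail_x = -3, tail_y = 0)
  b2 <- c(nose_x = 3, nose_y = 1, center_x = 0, center_y = 1,
          tail_x = -3, tail_y = 1)
  cls <- classify_contact_type(a2, b2, p)
  expect_true("side_side" %in% cls)
  expect_false("side_side_opposite" %in% cls)
  b2r <- c(nose_x = -3, nose_y = 1, center_x = 0, center_y = 1,
           tail_x = 3, tail_y = 1)
  cls <- classify_contact_type(a2, b2r, p)
  expect_true("side_side_opposite" %in% cls)
  expect_false("side_side" %in% cls)

  # a's nose at b's tail base, b's nose far: strictly a -> b
  bT <- c(nose_x = 6, nose_y = 0, center_x = 3, center_y = 0,
          tail_x = 0, tail_y = 0)
  aT <- c(nose_x = 0, nose_y = 1, center_x = 0, center_y = 4,
          tail_x = 0, tail_y = 7)
  expect_equal(classify_contact_type(aT, bT, p), "nose_anogenital_ab")

  # degenerate body: side classes suppressed, nose classes still evaluated
  bd <- c(nose_x = 0.5, nose_y = 0, center_x = 0.5, center_y = 0,
          tail_x = 0.5, tail_y = 0)
  cls <- classify_contact_type(a, bd, p)
  expect_true("nose_nose" %in% cls)
  expect_false(any(grepl("side", cls)))
})

# scripted scene: A approaches B, circles it in contact, freezes, B leaves.
# Contact spans frames [100, 200); A stops moving during [150, 250).
state_fixture <- function() {
  bx <- c(rep(25, 200), 25 + 3 * (1:100))
  b <- path_mouse(cbind(bx, rep(25, 300)), heading = 0)
  th <- pi + 0.5 * (0:49)
  ax <- c(21 - 3 * (99:0),                      # approach from the left
          25 + cos(th), rep(25 + cos(th[50]), 100),
          25 + cos(th[50]) - 3 * (1:50))
  ay <- c(rep(25, 100), 25 + sin(th), rep(25 + sin(th[50]), 100),
          rep(25 + sin(th[50]), 50))
  a <- path_mouse(cbind(ax, ay))
  build_frames(list(a = a, b = b))
}

test_that("state switches occur at the scripted frames and partition time", {
  p <- geometry_params(smoothing_window = 1)
  fr <- state_fixture()
  ct <- detect_contacts(fr, p)
  expect_equal(nrow(ct), 1)
  expect_equal(c(ct$start_frame, ct$end_frame), c(100, 200))
  st <- annotate_states(fr, ct, p)
  a_st <- st[st$subject == "a", ]
  a_st <- a_st[order(a_st$start_frame), ]
  expect_equal(a_st$trait, c("move_alone", "move_in_contact",
                             "stop_in_contact", "stop_alone", "move_alone"))
  expect_equal(a_st$start_frame, c(0, 100, 150, 200, 250))
  expect_equal(a_st$end_frame, c(100, 150, 200, 250, 300))
  # the four states partition each mouse's frames exactly
  for (m in c("a", "b")) {
    tot <- sum(st$end_frame[st$subject == m] -
                 st$start_frame[st$subject == m])
    expect_equal(tot, 300)
  }
})

test_that("single always-moving mouse is move_alone throughout", {
  fr <- build_frames(list(solo = path_mouse(
    cbind(5 + 0.4 * (0:199), rep(10, 200)), heading = 0)))
  st <- annotate_states(fr, detect_contacts(fr), geometry_params())
  expect_equal(unique(st$trait), "move_alone")
  expect_equal(sum(st$end_frame - st$start_frame), 200)
})

test_that("approach ends at contact onset; the fleeing mouse escapes", {
  p <- geometry_params(smoothing_window = 1)
  fr <- state_fixture()
  ct <- detect_contacts(fr, p)
  ae <- detect_approach_escape(fr, ct, p)
  appr <- ae[ae$trait == "social_approach" & ae$subject == "a", ]
  expect_equal(nrow(appr), 1)
  expect_equal(appr$end_frame, 100)  # ends exactly at contact onset
  expect_equal(appr$partner, "b")
  esc <- ae[ae$trait == "social_escape", ]
  expect_equal(esc$subject, "b")    # only the fleeing mouse escapes
  expect_equal(esc$start_frame, 200)
})

test_that("static pairs yield neither approach nor escape", {
  fr <- build_frames(list(a = static_mouse(10, 10, n = 150),
                          b = static_mouse(12, 10, n = 150)))
  ae <- detect_approach_escape(fr, detect_contacts(fr), geometry_params())
  expect_equal(nrow(ae), 0)
})

test_that("SAP requires the elongation-immobility conjunction", {
  n <- 1500
  speed_path <- function(stops) {
    x <- numeric(n)
    for (f in 2:n) x[f] <- x[f - 1] + (if ((f - 1) %in% stops) 0 else 0.5)
    x
  }
  stops <- 1000:1099
  cx <- speed_path(stops)
  half <- rep(2.5, n) + 0.05 * sin(1:n)
  half[stops + 1] <- 3.5                 # elongated while frozen
  half[501:540] <- 3.5                   # elongated but moving fast
  m <- data.frame(frame = 0:(n - 1),
                  nose_x = cx + half, nose_y = 0,
                  center_x = cx, center_y = 0,
                  tail_x = cx - half, tail_y = 0)
  fr <- build_frames(list(s = m))
  sap <- detect_sap(fr, geometry_params(smoothing_window = 1))
  expect_equal(nrow(sap), 1)
  expect_equal(c(sap$start_frame, sap$end_frame), c(1000, 1100))

  # constant body length, always fast: nothing fires
  m2 <- path_mouse(cbind(0.5 * (0:(n - 1)), rep(0, n)), heading = 0,
                   half = 2.5)
  expect_equal(nrow(detect_sap(build_frames(list(s = m2)),
                               geometry_params())), 0)
  # session too short for the quantile
  expect_warning(
    short <- detect_sap(build_frames(list(s = m[1:500, ])),
                        geometry_params()),
    "too short")
  expect_equal(nrow(short), 0)
})
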