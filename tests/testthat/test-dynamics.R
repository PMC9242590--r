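# Group dynamics: chance baselines, observed dyad probabilities, triad
# detection against a graph-library oracle, and triad summaries.

test_that("chance dyad probability matches combinatorics and enumeration", {
  ch <- chance_dyad_probability(c(control = 2, experimental = 2), "control")
  expect_equal(ch$p_same, 1 / 3)
  expect_equal(ch$p_different, 2 / 3)
  expect_equal(chance_dyad_probability(c(control = 4), "control"),
               list(p_same = 1, p_different = 0))
  ch <- chance_dyad_probability(c(control = 2, experimental = 3), "control")
  expect_equal(ch$p_same, 0.25)
  expect_equal(ch$p_different, 0.75)

  # exhaustive enumeration over partners for every composition with N <= 6
  for (n1 in 1:5) for (n2 in 0:(6 - n1)) {
    if (n1 + n2 < 2) next
    comp <- c(g1 = n1, g2 = n2)
    partners <- rep(names(comp), comp)
    partners <- partners[-match("g1", partners)]  # remove the focal mouse
    expect_equal(chance_dyad_probability(comp, "g1")$p_same,
                 mean(partners == "g1"))
  }
  expect_error(chance_dyad_probability(c(g = 1), "g"), "at least 2")
  expect_error(chance_dyad_probability(c(g = 3), "absent"), "absent")
})

dyad_event <- function(subject, partner, start_s, dur = 2) {
  tibble::tibble(trait = "contact", subject = subject, partner = partner,
                 members = NA_character_,
                 start_frame = as.integer(start_s * 10),
                 end_frame = as.integer((start_s + dur) * 10),
                 start_s = start_s, end_s = start_s + dur, duration_s = dur)
}

test_that("observed dyad probabilities reproduce hand-computed ratios", {
  ids <- make_identities("cg")
  # c1: 2 events with e1, 1 with c2; c2: 1 with c1, 1 with e2
  ev <- rbind(dyad_event("cg_c1", "cg_e1", 10),
              dyad_event("cg_c1", "cg_e1", 20),
              dyad_event("cg_c1", "cg_c2", 30),
              dyad_event("cg_c2", "cg_e2", 40))
  sch <- bin_scheme("checkpoint_cumulative", checkpoints = 1, anchor_s = 0)
  tab <- observed_dyad_probabilities(ev, ids, sch)
  # per-mouse shares: c1 -> same 1/3; c2 -> same 1/2 (1 of 2 events)
  p_cc <- tab$p_observed[tab$focal_genotype == "control" &
                           tab$partner_genotype == "control"]
  expect_equal(p_cc, mean(c(1 / 3, 1 / 2)))
  # rows sum to one over partner genotype per focal genotype
  sums <- tapply(tab$p_observed, tab$focal_genotype, sum)
  expect_equal(as.vector(sums), c(1, 1))
  expect_equal(unique(tab$p_chance[tab$focal_genotype ==
                                     tab$partner_genotype]), 1 / 3)
})

test_that("all-different partners give probability one on that row", {
  ids <- make_identities("cg")
  ev <- rbind(dyad_event("cg_c1", "cg_e1", 10),
              dyad_event("cg_c2", "cg_e2", 12))
  sch <- bin_scheme("checkpoint_cumulative", checkpoints = 1, anchor_s = 0)
  tab <- observed_dyad_probabilities(ev, ids, sch)
  expect_equal(tab$p_observed[tab$focal_genotype == "control" &
                                tab$partner_genotype == "experimental"], 1)
  expect_equal(tab$p_observed[tab$focal_genotype == "control" &
                                tab$partner_genotype == "control"], 0)
})

test_that("condition differences are zero on identical tables, antisymmetric", {
  ids <- make_identities("cg")
  ev <- rbind(dyad_event("cg_c1", "cg_e1", 10),
              dyad_event("cg_c2", "cg_c1", 40),
              dyad_event("cg_e1", "cg_e2", 100))
  sch <- bin_scheme("checkpoint_cumulative", checkpoints = c(-1, 1, 3),
                    anchor_s = 120)
  t1 <- observed_dyad_probabilities(ev, ids, sch)
  d0 <- condition_difference(t1, t1, baseline_label = "T-1")
  expect_true(all(d0$delta == 0 | is.na(d0$delta)))

  ev2 <- rbind(dyad_event("cg_c1", "cg_c2", 10),
               dyad_event("cg_e1", "cg_c1", 50),
               dyad_event("cg_e2", "cg_e1", 130))
  t2 <- observed_dyad_probabilities(ev2, ids, sch)
  d12 <- condition_difference(t1, t2, baseline_label = "T-1")
  d21 <- condition_difference(t2, t1, baseline_label = "T-1")
  expect_equal(d12$delta, -d21$delta)

  t3 <- t2[t2$bin_label != "T3", ]
  expect_error(condition_difference(t1, t3), "share")
})

# static frames for n mice: positions only matter for tie-breaking
flat_frames <- function(mice, n) {
  per <- lapply(seq_along(mice), function(i)
    static_mouse(10 * i, 10, n = n))
  names(per) <- mice
  build_frames(per)
}

iv_contact <- function(a, b, s, e) {
  tibble::tibble(trait = "contact", subject = a, partner = b,
                 members = NA_character_, start_frame = as.integer(s),
                 end_frame = as.integer(e), start_s = s / 10, end_s = e / 10,
                 duration_s = (e - s) / 10)
}

test_that("a joining third mouse creates and breaks the triad", {
  fr <- flat_frames(c("a", "b", "c"), 300)
  ct <- rbind(iv_contact("a", "b", 0, 300), iv_contact("b", "c", 100, 200))
  tri <- detect_triads(ct, fr)
  expect_equal(nrow(tri), 1)
  expect_equal(tri$members, "a+b+c")
  expect_equal(tri$creator, "c")
  expect_equal(tri$breaker, "c")
  expect_equal(tri$end_frame - tri$start_frame, 100L)
})

test_that("no triad without three connected mice", {
  fr <- flat_frames(c("a", "b", "c", "d"), 100)
  ct <- rbind(iv_contact("a", "b", 0, 50), iv_contact("c", "d", 20, 80))
  expect_equal(nrow(detect_triads(ct, fr)), 0)
})

test_that("a fully connected fourth mouse suspends the triad", {
  fr <- flat_frames(c("a", "b", "c", "d"), 100)
  ct <- rbind(iv_contact("a", "b", 0, 100), iv_contact("b", "c", 0, 100),
              iv_contact("c", "d", 50, 60))
  tri <- detect_triads(ct, fr)
  abc <- tri[tri$members == "a+b+c", ]
  expect_equal(nrow(abc), 2)
  expect_equal(abc$start_frame, c(0L, 60L))
  expect_equal(abc$end_frame, c(50L, 100L))
})

test_that("triad frames match an igraph connected-component oracle", {
  skip_if_not_installed("igraph")
  mice <- c("a", "b", "c", "d")
  fr <- flat_frames(mice, 400)
  set.seed(33)
  pairs <- combn(mice, 2, simplify = FALSE)
  ct <- dplyr::bind_rows(lapply(pairs, function(p) {
    k <- sample(2:5, 1)
    ss <- sort(sample(0:380, k))
    dplyr::bind_rows(lapply(ss, function(s)
      iv_contact(p[1], p[2], s, min(400, s + sample(10:80, 1)))))
  }))
  tri <- detect_triads(ct, fr)

  # oracle: per frame, a triple is a triad iff it is exactly a component
  triples <- combn(mice, 3, simplify = FALSE)
  oracle_mask <- matrix(FALSE, 400, length(triples))
  for (f in 0:399) {
    act <- ct[ct$start_frame <= f & ct$end_frame > f, ]
    g <- igraph::graph_from_data_frame(
      act[c("subject", "partner")], directed = FALSE,
      vertices = data.frame(name = mice))
    comp <- igraph::components(g)
    for (k in seq_along(triples)) {
      tt <- triples[[k]]
      cid <- comp$membership[tt]
      is_comp <- length(unique(cid)) == 1 &&
        sum(comp$membership == cid[1]) == 3
      oracle_mask[f + 1, k] <- is_comp
    }
  }
  got_mask <- matrix(FALSE, 400, length(triples))
  key <- vapply(triples, function(tt) paste(sort(tt), collapse = "+"), "")
  for (i in seq_len(nrow(tri))) {
    k <- match(tri$members[i], key)
    got_mask[(tri$start_frame[i] + 1):tri$end_frame[i], k] <- TRUE
  }
  expect_equal(got_mask, oracle_mask)
})

test_that("triad summaries reproduce scripted creation and durations", {
  ids <- make_identities("cg")
  fr <- flat_frames(ids$mouse_id, 1000)
  # e1 creates two triads of 100 frames; c1 creates one of 50 frames
  ct <- rbind(
    iv_contact("cg_c1", "cg_c2", 0, 120), iv_contact("cg_c2", "cg_e1", 20, 120),
    iv_contact("cg_c1", "cg_c2", 300, 420), iv_contact("cg_c2", "cg_e1", 320, 420),
    iv_contact("cg_e1", "cg_e2", 600, 700), iv_contact("cg_e2", "cg_c1", 650, 700)
  )
  tri <- detect_triads(ct, fr, ids)
  expect_equal(nrow(tri), 3)
  st <- triad_statistics(tri, ids)
  cr <- st$creation
  expect_equal(sum(cr$probability), 1)
  expect_equal(cr$probability[cr$genotype == "experimental"], 2 / 3)
  expect_equal(cr$composition[cr$genotype == "experimental"],
               "control+control")
  du <- st$duration
  expect_equal(du$mean_s[du$genotype == "experimental"], 10)  # 100 frames
  expect_equal(du$mean_s[du$genotype == "control"], 5)
  # single-creator case: probability one
  st1 <- triad_statistics(tri[1:2, ], ids)
  expect_equal(st1$creation$probability, 1)
})

test_that("neutral simulated dyads converge to the chance baseline", {
  ok <- 0
  for (sd in 1:20) {
    cfg <- simulation_config(duration = 9600, frame_rate = 10,
                             seed = 9000 + sd)
    s <- simulate_session(cfg)
    gt <- s$ground_truth
    ev <- tibble::tibble(
      trait = "contact", subject = gt$initiator, partner = gt$target,
      members = NA_character_,
      start_frame = as.integer(gt$start_s * 10),
      end_frame = as.integer(gt$end_s * 10),
      start_s = gt$start_s, end_s = gt$end_s,
      duration_s = gt$end_s - gt$start_s)
    expect_gt(2 * nrow(ev), 2000)  # each event credits both members
    sch <- bin_scheme("checkpoint_cumulative", checkpoints = 160,
                      anchor_s = 0)
    tab <- observed_dyad_probabilities(ev, s$identities, sch)
    dev <- max(abs(tab$p_observed - tab$p_chance), na.rm = TRUE)
    if (dev < 0.05) ok <- ok + 1
  }
  expect_gte(ok, 19)
})
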