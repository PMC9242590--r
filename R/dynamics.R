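# Group dynamics: dyadic interaction probabilities against combinatorial
# chance baselines, condition-difference time courses, and group-of-three
# (triad) creation/breaking/persistence statistics.

#' Chance dyad probability from cage composition
#'
#' Under uniform partner choice, a focal mouse has probability
#' `(n_same - 1) / (N - 1)` of interacting with a same-genotype partner.
#' In the default mixed cage of two controls and two experimental mice this
#' is 1/3 same-genotype and 2/3 different-genotype.
#'
#' @param composition Named integer vector of genotype counts, e.g.
#'   `c(control = 2, experimental = 2)`.
#' @param focal_genotype Genotype of the focal mouse.
#' @return List with `p_same` and `p_different`.
#' @export
chance_dyad_probability <- function(composition, focal_genotype) {
  n_total <- sum(composition)
  if (n_total < 2) stop("cage must contain at least 2 mice")
  if (!focal_genotype %in% names(composition) ||
      composition[[focal_genotype]] < 1)
    stop("focal genotype absent from the cage")
  p_same <- (composition[[focal_genotype]] - 1) / (n_total - 1)
  list(p_same = p_same, p_different = 1 - p_same)
}

#' Observed dyadic interaction probabilities
#'
#' For each focal mouse and checkpoint window, the probability that a
#' dyadic contact event involves a partner of a given genotype:
#' events with that partner genotype divided by all dyadic events of the
#' focal mouse in the window (or total contact duration when
#' `weight = "duration"`), averaged over the mice of each focal genotype.
#'
#' @param events Event tibble; only undirected `contact` events are used.
#' @param identities Identity table.
#' @param scheme [bin_scheme()] (checkpoint modes).
#' @param weight `"count"` (default) or `"duration"`.
#' @return Tibble `focal_genotype`, `partner_genotype`, `bin_label`,
#'   `p_observed`, `n_events`, `p_chance`. `p_observed` is `NA` when a
#'   focal genotype has no events in a window.
#' @export
observed_dyad_probabilities <- function(events, identities, scheme,
                                        weight = c("count", "duration")) {
  weight <- match.arg(weight)
  ev <- events[events$trait == "contact" & !is.na(events$partner), ]
  ev <- events_per_mouse(ev)
  ev <- ev[ev$trait == "contact", ]
  geno <- setNames(identities$genotype, identities$mouse_id)
  ev$focal_genotype <- unname(geno[ev$subject])
  ev$partner_genotype <- unname(geno[ev$partner])
  wins <- scheme_windows(scheme)
  comp <- table(identities$genotype)
  genotypes <- sort(unique(identities$genotype))
  out <- list()
  for (k in seq_len(nrow(wins))) {
    sel <- ev$start_s >= wins$lo[k] & ev$start_s < wins$hi[k]
    sub <- ev[sel, ]
    sub$w <- if (weight == "count") 1 else sub$duration_s
    for (fg in genotypes) {
      mice_fg <- identities$mouse_id[identities$genotype == fg]
      # per-mouse partner-genotype shares, then averaged within genotype
      per_mouse <- lapply(mice_fg, function(m) {
        mm <- sub[sub$subject == m, ]
        tot <- sum(mm$w)
        if (tot == 0) return(NULL)
        vapply(genotypes,
               function(pg) sum(mm$w[mm$partner_genotype == pg]) / tot, 0)
      })
      per_mouse <- per_mouse[!vapply(per_mouse, is.null, TRUE)]
      for (pg in genotypes) {
        p_obs <- if (length(per_mouse) == 0) NA_real_ else
          mean(vapply(per_mouse, function(v) v[[pg]], 0))
        ch <- chance_dyad_probability(comp, fg)
        out[[length(out) + 1L]] <- tibble(
          focal_genotype = fg, partner_genotype = pg,
          bin_label = wins$bin_label[k],
          p_observed = p_obs,
          n_events = sum(sub$focal_genotype == fg),
          p_chance = if (pg == fg) ch$p_same else
            ch$p_different * comp[[pg]] / sum(comp[names(comp) != fg]))
      }
    }
  }
  bind_rows(out)
}

#' Condition difference of dyad probabilities
#'
#' Per row, `delta = p_cno - p_saline`; each checkpoint's delta is also
#' contrasted against the delta at the baseline checkpoint (by default the
#' pre-injection window labelled `T-60`, i.e. one hour before injection).
#'
#' @param table_cno,table_saline Outputs of
#'   [observed_dyad_probabilities()] sharing rows and checkpoints.
#' @param baseline_label Bin label of the baseline checkpoint.
#' @return Tibble with `delta` and `delta_vs_baseline`.
#' @export
condition_difference <- function(table_cno, table_saline,
                                 baseline_label = "T-60") {
  key <- c("focal_genotype", "partner_genotype", "bin_label")
  if (!identical(table_cno[key], table_saline[key]))
    stop("tables must share rows and checkpoints")
  res <- table_cno[key]
  res$delta <- table_cno$p_observed - table_saline$p_observed
  base <- res[res$bin_label == baseline_label, ]
  if (nrow(base) == 0) {
    res$delta_vs_baseline <- NA_real_
  } else {
    bmap <- setNames(base$delta,
                     paste(base$focal_genotype, base$partner_genotype))
    res$delta_vs_baseline <- res$delta -
      unname(bmap[paste(res$focal_genotype, res$partner_genotype)])
  }
  res
}

# ---------------------------------------------------------------------------
# triads
# ---------------------------------------------------------------------------

# per-frame displacement of each mouse summed over the second preceding a
# frame position; used for creator/breaker tie-breaking
displacement_before <- function(ps, pos, mouse) {
  fr <- ps$frame_rate
  mat <- ps$per[[mouse]]$mat
  i1 <- max(2L, pos - as.integer(round(fr)))
  i2 <- max(i1, min(pos, nrow(mat)))
  if (i2 <= i1) return(0)
  sum(sqrt(diff(mat[i1:i2, "center_x"])^2 +
             diff(mat[i1:i2, "center_y"])^2), na.rm = TRUE)
}

triple_connected <- function(e12, e13, e23) {
  (e12 + e13 + e23) >= 2
}

#' Detect groups of three (triads)
#'
#' Builds the per-frame contact graph from pairwise contact intervals. A
#' triad event is a maximal run of frames during which a fixed set of three
#' mice forms a connected subgraph (a chain suffices). Frames where all
#' four mice form one connected component suspend triad events rather than
#' counting ambiguous sub-triads. The creator is the member whose joining
#' completed connectivity at the start (when the other two were already a
#' connected pair); the breaker is the member whose departure first
#' disconnects the set. Ambiguous cases (simultaneous edge changes,
#' suspension boundaries, session edges) are resolved by the member that
#' moved most in the preceding second, then by lexicographic id.
#'
#' @param contacts Contact events from [detect_contacts()].
#' @param frames Pose stream (used for the frame grid and tie-breaking).
#' @param identities Optional identity table; adds genotype compositions.
#' @return Tibble of triad events: `members`, `creator`, `breaker`,
#'   `base_composition`, `composition`, `start_frame`, `end_frame`,
#'   `duration_s`.
#' @export
detect_triads <- function(contacts, frames, identities = NULL) {
  ps <- pose_split(frames)
  mice <- ps$mice
  if (length(mice) < 3) return(triad_empty())
  n <- length(ps$frames)
  # pairwise adjacency masks
  adj <- list()
  for (i in seq_along(mice)) for (j in seq_along(mice)) {
    if (j <= i) next
    adj[[pair_key(mice[i], mice[j])]] <-
      events_to_mask(contacts, ps, pair = c(mice[i], mice[j]))
  }
  edge <- function(a, b) adj[[pair_key(a, b)]]
  triples <- utils::combn(mice, 3, simplify = FALSE)
  out <- list()
  for (tri in triples) {
    e12 <- edge(tri[1], tri[2])
    e13 <- edge(tri[1], tri[3])
    e23 <- edge(tri[2], tri[3])
    conn <- triple_connected(e12, e13, e23)
    # suspended if any outside mouse is attached to the triple
    outside <- setdiff(mice, tri)
    attached <- rep(FALSE, n)
    for (o in outside) {
      attached <- attached | edge(tri[1], o) | edge(tri[2], o) |
        edge(tri[3], o)
    }
    active <- conn & !attached
    iv <- assemble_intervals(active, merge_gap = 0L, min_len = 1L)
    if (nrow(iv) == 0) next
    for (k in seq_len(nrow(iv))) {
      s <- iv$start[k]
      e <- iv$end[k]
      pair_at <- function(pos) {
        if (pos < 1 || pos > n) return(NULL)
        con <- c(e12[pos], e13[pos], e23[pos])
        pairs <- list(tri[c(1, 2)], tri[c(1, 3)], tri[c(2, 3)])
        if (sum(con) == 1) pairs[[which(con)]] else NULL
      }
      tie_break <- function(pos) {
        disp <- vapply(tri, function(m) displacement_before(ps, pos, m), 0)
        cand <- tri[disp == max(disp)]
        sort(cand)[1]
      }
      prev_pair <- pair_at(s - 1L)
      creator <- if (!is.null(prev_pair) && !conn[max(s - 1L, 1L)] &&
                     s > 1L) {
        setdiff(tri, prev_pair)
      } else {
        tie_break(s)
      }
      next_pair <- if (e <= n && !conn[e]) pair_at(e) else NULL
      breaker <- if (!is.null(next_pair)) setdiff(tri, next_pair)
                 else tie_break(min(e, n))
      base_comp <- if (is.null(identities)) NA_character_ else
        genotype_multiset(setdiff(tri, creator), identities)
      comp <- if (is.null(identities)) NA_character_ else
        genotype_multiset(tri, identities)
      start_f <- ps$frames[s]
      end_f <- if (e > n) ps$frames[n] + 1L else ps$frames[e]
      out[[length(out) + 1L]] <- tibble(
        members = paste(sort(tri), collapse = "+"),
        creator = creator, breaker = breaker,
        base_composition = base_comp, composition = comp,
        start_frame = as.integer(start_f), end_frame = as.integer(end_f),
        duration_s = (end_f - start_f) / ps$frame_rate,
        start_s = ps$t[1] - ps$frames[1] / ps$frame_rate +
          start_f / ps$frame_rate)
    }
  }
  if (length(out) == 0) return(triad_empty())
  bind_rows(out) %>% arrange(start_frame, members)
}

triad_empty <- function() {
  tibble(members = character(0), creator = character(0),
         breaker = character(0), base_composition = character(0),
         composition = character(0), start_frame = integer(0),
         end_frame = integer(0), duration_s = numeric(0),
         start_s = numeric(0))
}

genotype_multiset <- function(ids, identities) {
  g <- sort(identities$genotype[match(ids, identities$mouse_id)])
  paste(g, collapse = "+")
}

#' Summarise triad creation, breaking and persistence
#'
#' Creation probability: the fraction of triad events falling in each
#' creator-genotype x base-composition cell (cells sum to 1); breaking
#' probability is analogous over breaker genotype. Durations are
#' summarised as mean and standard error per creator genotype and total
#' group composition.
#'
#' @param triads Output of [detect_triads()].
#' @param identities Identity table.
#' @param scheme Optional [bin_scheme()]; when given, summaries are
#'   computed per checkpoint window on event start times.
#' @return List with tibbles `creation`, `breaking` and `duration`.
#' @export
triad_statistics <- function(triads, identities, scheme = NULL) {
  if (nrow(triads) == 0) {
    empty <- tibble(bin_label = character(0), genotype = character(0),
                    composition = character(0), n = integer(0),
                    probability = numeric(0))
    return(list(creation = empty, breaking = empty,
                duration = tibble(bin_label = character(0),
                                  genotype = character(0),
                                  composition = character(0), n = integer(0),
                                  mean_s = numeric(0), sem_s = numeric(0))))
  }
  geno <- setNames(identities$genotype, identities$mouse_id)
  tr <- triads
  tr$creator_genotype <- unname(geno[tr$creator])
  tr$breaker_genotype <- unname(geno[tr$breaker])
  wins <- if (is.null(scheme)) {
    data.frame(bin_label = "all", lo = -Inf, hi = Inf)
  } else {
    scheme_windows(scheme)
  }
  creation <- list()
  breaking <- list()
  duration <- list()
  for (k in seq_len(nrow(wins))) {
    sub <- tr[tr$start_s >= wins$lo[k] & tr$start_s < wins$hi[k], ]
    if (nrow(sub) == 0) next
    cr <- sub %>%
      group_by(genotype = creator_genotype,
               composition = base_composition) %>%
      summarise(n = dplyr::n(), .groups = "drop") %>%
      mutate(probability = n / sum(n), bin_label = wins$bin_label[k])
    br <- sub %>%
      group_by(genotype = breaker_genotype,
               composition = base_composition) %>%
      summarise(n = dplyr::n(), .groups = "drop") %>%
      mutate(probability = n / sum(n), bin_label = wins$bin_label[k])
    du <- sub %>%
      group_by(genotype = creator_genotype, composition) %>%
      summarise(n = dplyr::n(), mean_s = mean(duration_s),
                sem_s = sd(duration_s) / sqrt(dplyr::n()),
                .groups = "drop") %>%
      mutate(bin_label = wins$bin_label[k])
    creation[[k]] <- cr
    breaking[[k]] <- br
    duration[[k]] <- du
  }
  list(creation = bind_rows(creation), breaking = bind_rows(breaking),
       duration = bind_rows(duration))
}
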