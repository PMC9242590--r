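# Trait aggregation and cage-normalized indexes.
#
# A trait table holds, per mouse x trait x time bin, the number of events
# and their total duration. The LMT index divides each value by the mean of
# the cage's two control mice for the same trait/bin, a within-cage
# normalization that controls for cage effects.

UNDIRECTED_TRAITS <- c("contact", "nose_nose", "side_side",
                       "side_side_opposite")

# the full internal checkpoint grid (minutes after injection) and the
# displayed subset used in reports
CHECKPOINTS_FULL <- c(30, 60, 90, 120, 150, 210, 270, 330, 390)
CHECKPOINTS_DISPLAY <- c(30, 60, 90, 150, 210, 270, 330, 390)

#' Time-binning scheme for trait aggregation
#'
#' Three modes: `dark_phase_sum` sums events per dark phase (plus a total
#' across phases); `checkpoint_cumulative` accumulates from the anchor
#' (injection time) to each checkpoint; `checkpoint_interval` uses the
#' increments between consecutive checkpoints, which is the right currency
#' for asking whether behavior at a late checkpoint has returned to
#' baseline (cumulative sums retain any early excess by construction).
#' Negative checkpoints denote pre-injection windows `[c, 0)`.
#'
#' @param mode One of `dark_phase_sum`, `checkpoint_cumulative`,
#'   `checkpoint_interval`.
#' @param checkpoints Strictly increasing checkpoint minutes.
#' @param anchor_s Anchor clock time in session seconds (injection time, or
#'   phase start for `dark_phase_sum`).
#' @param phases For `dark_phase_sum`: data frame with `label`, `start_s`,
#'   `end_s` describing the dark phases.
#' @return A list of class `etho_bins`.
#' @export
bin_scheme <- function(mode = c("checkpoint_cumulative",
                                "checkpoint_interval", "dark_phase_sum"),
                       checkpoints = CHECKPOINTS_FULL, anchor_s = 0,
                       phases = NULL) {
  mode <- match.arg(mode)
  if (mode != "dark_phase_sum") {
    if (is.unsorted(checkpoints, strictly = TRUE))
      stop("checkpoints must be strictly increasing")
  } else {
    if (is.null(phases)) stop("dark_phase_sum requires a phase table")
    stopifnot(all(c("label", "start_s", "end_s") %in% names(phases)))
  }
  structure(list(mode = mode, checkpoints = checkpoints,
                 anchor_s = anchor_s, phases = phases),
            class = "etho_bins")
}

# windows (label, lo, hi in session seconds) implied by a scheme
scheme_windows <- function(scheme) {
  if (scheme$mode == "dark_phase_sum") {
    ph <- scheme$phases
    w <- data.frame(bin_label = as.character(ph$label),
                    lo = ph$start_s, hi = ph$end_s,
                    stringsAsFactors = FALSE)
    rbind(w, data.frame(bin_label = "total", lo = min(ph$start_s),
                        hi = max(ph$end_s)))
  } else if (scheme$mode == "checkpoint_cumulative") {
    cp <- scheme$checkpoints
    data.frame(bin_label = paste0("T", cp),
               lo = ifelse(cp < 0, scheme$anchor_s + cp * 60,
                           scheme$anchor_s),
               hi = ifelse(cp < 0, scheme$anchor_s,
                           scheme$anchor_s + cp * 60),
               stringsAsFactors = FALSE)
  } else {
    # interval mode: negative checkpoints are baseline windows [c, 0);
    # positive checkpoints span from the previous positive one (or 0)
    cp <- scheme$checkpoints
    lo <- numeric(length(cp))
    hi <- numeric(length(cp))
    prev <- 0
    for (k in seq_along(cp)) {
      if (cp[k] <= 0) {
        lo[k] <- cp[k]
        hi[k] <- 0
      } else {
        lo[k] <- prev
        hi[k] <- cp[k]
        prev <- cp[k]
      }
    }
    data.frame(bin_label = paste0("T", cp),
               lo = scheme$anchor_s + lo * 60,
               hi = scheme$anchor_s + hi * 60,
               stringsAsFactors = FALSE)
  }
}

# expand events so that undirected pairwise traits are credited to both
# members, and derive total_contact_received for the receiving mouse of
# directional ano-genital contacts
events_per_mouse <- function(events) {
  und <- events[events$trait %in% UNDIRECTED_TRAITS & !is.na(events$partner), ]
  flipped <- und
  flipped$subject <- und$partner
  flipped$partner <- und$subject
  received <- events[events$trait == "nose_anogenital" &
                       !is.na(events$partner), ]
  if (nrow(received)) {
    tmp <- received$subject
    received$subject <- received$partner
    received$partner <- tmp
    received$trait <- "total_contact_received"
  }
  bind_rows(events, flipped, received)
}

#' Aggregate events into a trait table
#'
#' Counts and total durations per mouse, trait and time bin. An event is
#' counted in the bin containing its start time; durations contribute the
#' fraction of the event contained in each bin, so cumulative checkpoint
#' durations are monotone and straddling events are handled consistently.
#' Undirected pairwise traits are credited to both members.
#'
#' @param events Event tibble (must carry `start_s`/`end_s`).
#' @param scheme [bin_scheme()].
#' @param expand Credit undirected events to both mice (default TRUE).
#' @return Tibble `mouse_id`, `trait`, `bin_label`, `n_events`,
#'   `total_duration`.
#' @export
aggregate_traits <- function(events, scheme, expand = TRUE) {
  wins <- scheme_windows(scheme)
  if (nrow(events) > 0 && any(events$end_s < events$start_s))
    stop("malformed events: end before start")
  ev <- if (expand) events_per_mouse(events) else events
  out <- vector("list", nrow(wins))
  for (k in seq_len(nrow(wins))) {
    lo <- wins$lo[k]
    hi <- wins$hi[k]
    contained <- pmax(0, pmin(ev$end_s, hi) - pmax(ev$start_s, lo))
    counted <- ev$start_s >= lo & ev$start_s < hi
    sub <- tibble(mouse_id = ev$subject, trait = ev$trait,
                  n = as.integer(counted), d = contained)
    agg <- sub %>%
      group_by(mouse_id, trait) %>%
      summarise(n_events = sum(n), total_duration = sum(d),
                .groups = "drop")
    agg$bin_label <- wins$bin_label[k]
    out[[k]] <- agg
  }
  res <- bind_rows(out)
  res[c("mouse_id", "trait", "bin_label", "n_events", "total_duration")]
}

#' Cage-normalized LMT index
#'
#' For every cage, trait, bin and measure (event count and duration), each
#' mouse's value is divided by the mean value of the two control mice of
#' the same cage. By construction the mean of the two control indexes is 1;
#' experimental indexes are unconstrained. A zero control mean leaves the
#' index undefined (`NA`, with a warning), not 0 or infinite.
#'
#' @param traits Trait table from [aggregate_traits()].
#' @param identities Identity table with `mouse_id`, `genotype`, `cage_id`.
#' @return Tibble `mouse_id`, `trait`, `bin_label`, `measure`, `value`,
#'   `index`.
#' @export
lmt_index <- function(traits, identities) {
  nctrl <- table(identities$cage_id[identities$genotype == "control"])
  if (length(nctrl) == 0 || any(nctrl != 2) ||
      !all(unique(identities$cage_id) %in% names(nctrl)))
    stop("each cage must contain exactly 2 control mice")
  if (any(!traits$mouse_id %in% identities$mouse_id))
    stop("identities missing for: ",
         paste(setdiff(traits$mouse_id, identities$mouse_id), collapse = ", "))
  long <- bind_rows(
    traits %>% mutate(measure = "n_events", value = as.numeric(n_events)),
    traits %>% mutate(measure = "total_duration", value = total_duration)
  ) %>% select(mouse_id, trait, bin_label, measure, value)
  # complete the grid: a mouse without events has value 0, so control means
  # are always taken over both control mice
  grid <- merge(identities["mouse_id"],
                unique(long[c("trait", "bin_label", "measure")]))
  long <- left_join(as_tibble(grid), long,
                    by = c("mouse_id", "trait", "bin_label", "measure"))
  long$value[is.na(long$value)] <- 0
  long <- left_join(long, identities[c("mouse_id", "genotype", "cage_id")],
                    by = "mouse_id")
  ctrl <- long %>%
    filter(genotype == "control") %>%
    group_by(cage_id, trait, bin_label, measure) %>%
    summarise(ctrl_mean = mean(value), .groups = "drop")
  res <- left_join(long, ctrl,
                   by = c("cage_id", "trait", "bin_label", "measure"))
  zero <- !is.na(res$ctrl_mean) & res$ctrl_mean == 0
  if (any(zero))
    warning(sum(zero), " trait/bin cell(s) have a zero control mean; ",
            "index undefined (NA)")
  res$index <- ifelse(zero, NA_real_, res$value / res$ctrl_mean)
  res[c("mouse_id", "genotype", "cage_id", "trait", "bin_label", "measure",
        "value", "index")]
}

#' Classify reciprocal, unilateral and passive interactions
#'
#' Contact events that overlap a nose-nose or side-by-side episode of the
#' same pair are reciprocal interactions, credited to both mice. Giving an
#' ano-genital contact (subject's nose at the partner's tail base) is a
#' unilateral interaction of the giver; the same episode is a passive
#' interaction of the receiver, so unilateral and passive rows pair up
#' one-to-one.
#'
#' @param events Combined event tibble containing `contact`, `nose_nose`,
#'   `side_side`, `side_side_opposite` and `nose_anogenital` traits.
#' @return Event-level tibble with `trait` in
#'   `reciprocal`/`unilateral`/`passive` (suitable for
#'   [aggregate_traits()] with `expand = FALSE`).
#' @export
classify_interactions <- function(events) {
  contacts <- events[events$trait == "contact", ]
  mutual <- events[events$trait %in% c("nose_nose", "side_side",
                                       "side_side_opposite"), ]
  ag <- events[events$trait == "nose_anogenital", ]
  out <- list()
  if (nrow(contacts) > 0 && nrow(mutual) > 0) {
    ck <- pair_key(contacts$subject, contacts$partner)
    mk <- pair_key(mutual$subject, mutual$partner)
    for (i in seq_len(nrow(contacts))) {
      m <- mutual[mk == ck[i] &
                    mutual$start_frame < contacts$end_frame[i] &
                    mutual$end_frame > contacts$start_frame[i], ]
      if (nrow(m) > 0) {
        both <- contacts[c(i, i), ]
        both$subject <- c(contacts$subject[i], contacts$partner[i])
        both$partner <- c(contacts$partner[i], contacts$subject[i])
        both$trait <- "reciprocal"
        out[[length(out) + 1L]] <- both
      }
    }
  }
  if (nrow(ag) > 0) {
    uni <- ag
    uni$trait <- "unilateral"
    pas <- ag
    pas$trait <- "passive"
    pas$subject <- ag$partner
    pas$partner <- ag$subject
    out[[length(out) + 1L]] <- bind_rows(uni, pas)
  }
  if (length(out) == 0) return(empty_events())
  bind_rows(out)
}

#' Three-chamber social preference index
#'
#' `(time in stranger side - time in object side) / exploration time`,
#' dimensionless in `[-1, 1]`.
#'
#' @param t_stranger,t_object,t_exploration Times in seconds;
#'   `t_exploration > 0` and `t_stranger + t_object <= t_exploration`.
#' @return The preference index.
#' @export
preference_index <- function(t_stranger, t_object, t_exploration) {
  if (any(t_exploration <= 0)) stop("exploration time must be positive")
  if (any(t_stranger < 0) || any(t_object < 0))
    stop("side times must be non-negative")
  if (any(t_stranger + t_object > t_exploration + 1e-9))
    stop("side times cannot exceed exploration time")
  (t_stranger - t_object) / t_exploration
}
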