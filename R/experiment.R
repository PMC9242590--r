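# Orchestration of a chemogenetic-style checkpoint experiment: several
# mixed cages, each recorded once after a saline and once after a cno
# injection, with the experimental genotype's contact seeking transiently
# boosted after cno. This is the in-silico analogue of the crossover design
# used for checkpoint time-course analyses.

#' Simulate a checkpoint-index experiment over several cages
#'
#' For each cage, simulates a saline and a cno session (shared per-cage
#' substreams derived from `seed`), detects contact events, aggregates them
#' at the given checkpoints both cumulatively and per interval, and returns
#' the cage-normalized contact index per mouse, condition and checkpoint.
#' The effect (amplitude on the experimental genotype's contact-seeking
#' rate) is active only in the cno session, from injection onward.
#'
#' @param seed Root seed; each cage/condition session derives its own
#'   substream.
#' @param n_cages Number of independent cages (2 control + 2 experimental
#'   mice each).
#' @param frame_rate Frames/s of the simulated recordings.
#' @param duration_min Session length (min); must cover the last
#'   checkpoint plus the pre-injection baseline.
#' @param injection_min Injection time within the session (min).
#' @param amplitude Effect amplitude (multiplier delta) after cno.
#' @param peak_min,return_min Effect plateau end and return-to-baseline
#'   (min after injection).
#' @param checkpoints Checkpoint minutes relative to injection.
#' @param params [geometry_params()] used for contact detection.
#' @return Tibble with `cage_id`, `condition`, `mouse_id`, `genotype`,
#'   `bin_label`, `mode` (`cumulative`/`interval`), `measure`, `value`,
#'   `index` for the `contact` trait.
#' @export
checkpoint_index_experiment <- function(seed, n_cages = 5L,
                                        frame_rate = 10,
                                        duration_min = 450,
                                        injection_min = 60,
                                        amplitude = 0.5,
                                        peak_min = 90, return_min = 150,
                                        checkpoints = c(-60, CHECKPOINTS_DISPLAY),
                                        params = geometry_params()) {
  anchor <- injection_min * 60
  schemes <- list(
    cumulative = bin_scheme("checkpoint_cumulative",
                            checkpoints = checkpoints, anchor_s = anchor),
    interval = bin_scheme("checkpoint_interval",
                          checkpoints = checkpoints, anchor_s = anchor)
  )
  out <- list()
  for (cg in seq_len(n_cages)) {
    cage_id <- paste0("cage", cg)
    identities <- make_identities(cage_id)
    for (cond in c("saline", "cno")) {
      cfg <- simulation_config(
        frame_rate = frame_rate, duration = duration_min * 60,
        seed = substream_seed(paste0(cage_id, "/", cond), seed),
        epochs = list(
          list(label = "baseline", start = 0, end = anchor),
          list(label = cond, start = anchor, end = duration_min * 60)),
        effect = list(amplitude = if (cond == "cno") amplitude else 0,
                      onset = 0, peak_window = peak_min * 60,
                      return_to_baseline = return_min * 60))
      sess <- simulate_session(cfg, identities)
      contacts <- detect_contacts(sess$frames, params)
      for (md in names(schemes)) {
        traits <- aggregate_traits(contacts, schemes[[md]])
        idx <- lmt_index(traits, identities)
        idx$condition <- cond
        idx$mode <- md
        out[[length(out) + 1L]] <- idx
      }
    }
  }
  res <- bind_rows(out)
  res[c("cage_id", "condition", "mouse_id", "genotype", "trait",
        "bin_label", "mode", "measure", "value", "index")]
}

#' Test the per-checkpoint condition contrast of experimental-mouse indexes
#'
#' Permutation test (cno vs saline) on the contact index of the
#' experimental mice at each requested checkpoint, with Holm-Sidak
#' adjustment across checkpoints.
#'
#' @param experiment Output of [checkpoint_index_experiment()].
#' @param bins Bin labels to test.
#' @param mode `cumulative` or `interval` values.
#' @param measure `n_events` (default) or `total_duration`.
#' @param n_perm,seed Passed to [permutation_test()].
#' @return Tibble with per-checkpoint `delta`, `p` and `p_adjusted`.
#' @export
contrast_checkpoints <- function(experiment, bins,
                                 mode = c("cumulative", "interval"),
                                 measure = "n_events", n_perm = 1999L,
                                 seed = 1L) {
  mode <- match.arg(mode)
  rows <- list()
  for (bl in bins) {
    sub <- experiment[experiment$genotype == "experimental" &
                        experiment$trait == "contact" &
                        experiment$measure == measure &
                        experiment$mode == mode &
                        experiment$bin_label == bl, ]
    x <- sub$index[sub$condition == "cno"]
    y <- sub$index[sub$condition == "saline"]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    pt <- permutation_test(x, y, n_perm = n_perm,
                           seed = substream_seed(paste0("ck/", bl), seed))
    rows[[bl]] <- tibble(bin_label = bl, n_cno = length(x),
                         n_saline = length(y),
                         delta = mean(x) - mean(y), p = pt$p)
  }
  out <- bind_rows(rows)
  out$p_adjusted <- holm_sidak(out$p)
  out
}
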