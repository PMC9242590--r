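# End-to-end pipeline: simulate (or read) poses -> annotate events ->
# aggregate traits and LMT indexes -> group dynamics -> condition
# contrasts, with a machine-readable run manifest. Each stage failure is
# reported with the stage name.

#' Default pipeline configuration
#'
#' A compact demonstration setup: one mixed cage (2 control +
#' 2 experimental mice), a saline and a cno session of 80 min sampled at
#' 10 frames/s with injection at 20 min, an experimental-genotype effect of
#' amplitude +0.5 lasting 30 min, and checkpoint analysis at
#' -15, 15, 30, 45 and 60 min around injection. All values can be
#' overridden via [load_config()] or by editing the returned list.
#'
#' @param seed Root seed.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    cage_id = "cage1",
    conditions = c("saline", "cno"),
    arena_size = 50,
    frame_rate = 10,
    duration_min = 80,
    injection_min = 20,
    sociability = list(
      control = list(contact_seek_rate = 3, mean_contact_duration = 3),
      experimental = list(contact_seek_rate = 3, mean_contact_duration = 3)
    ),
    effect = list(amplitude = 0.5, onset = 0, peak_window = 1800,
                  return_to_baseline = 2700),
    geometry = list(),
    checkpoints = c(-15, 15, 30, 45, 60),
    baseline_checkpoint = -15,
    bin_mode = "checkpoint_cumulative",
    weight = "count",
    write_poses = FALSE
  )
}

#' Load a pipeline configuration from YAML
#'
#' Values in the file override the defaults of [default_config()]; unknown
#' keys are kept (and recorded in the manifest).
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  utils::modifyList(default_config(), yaml::read_yaml(path))
}

# build the simulator config of one condition session
session_config <- function(config, condition) {
  inj <- config$injection_min * 60
  dur <- config$duration_min * 60
  epochs <- list(
    list(label = "baseline", start = 0, end = inj),
    list(label = condition, start = inj, end = dur)
  )
  amp <- if (condition == "cno") config$effect$amplitude else 0
  simulation_config(
    arena_size = config$arena_size, frame_rate = config$frame_rate,
    duration = dur,
    seed = substream_seed(paste0(config$cage_id, "/", condition),
                          config$seed),
    sociability = config$sociability,
    epochs = epochs,
    effect = utils::modifyList(config$effect, list(amplitude = amp))
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) one cage under each condition, annotates the
#' ethogram, aggregates traits and LMT indexes at the configured
#' checkpoints, computes dyad probabilities, their condition difference and
#' triad statistics, and tests the per-checkpoint index contrast of the
#' experimental mice between conditions (permutation test with Holm-Sidak
#' adjustment across checkpoints). All tables are written as CSV plus a
#' JSON manifest; reruns with the same configuration are byte-identical.
#'
#' @param config Configuration list ([default_config()], possibly edited,
#'   or [load_config()]).
#' @param out_dir Output directory (created if missing).
#' @param poses Optional named list of pre-loaded pose streams per
#'   condition (bypasses simulation, e.g. from [read_pose_csv()]).
#' @return Invisibly, a list with all in-memory results.
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         poses = NULL) {
  if (missing(out_dir)) stop("out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- do.call(geometry_params, config$geometry)
  identities <- make_identities(config$cage_id)
  anchor <- config$injection_min * 60
  scheme <- bin_scheme(config$bin_mode, checkpoints = config$checkpoints,
                       anchor_s = anchor)

  res <- list(config = config, identities = identities)
  files <- character(0)
  wcsv <- function(df, name) {
    p <- file.path(out_dir, name)
    write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
    p
  }

  for (cond in config$conditions) {
    frames <- stage(paste0("poses/", cond), {
      if (!is.null(poses)) {
        poses[[cond]]
      } else {
        sess <- simulate_session(session_config(config, cond), identities)
        res[[paste0("session_", cond)]] <- sess
        sess$frames
      }
    })
    if (isTRUE(config$write_poses))
      wcsv(frames, paste0("poses_", cond, ".csv"))
    events <- stage(paste0("annotate/", cond),
                    annotate_events(frames, params))
    wcsv(events, paste0("events_", cond, ".csv"))
    traits <- stage(paste0("aggregate/", cond),
                    aggregate_traits(events, scheme))
    wcsv(traits, paste0("traits_", cond, ".csv"))
    index <- stage(paste0("index/", cond), lmt_index(traits, identities))
    wcsv(index, paste0("index_", cond, ".csv"))
    dyads <- stage(paste0("dyads/", cond),
                   observed_dyad_probabilities(events, identities, scheme,
                                               weight = config$weight))
    wcsv(dyads, paste0("dyads_", cond, ".csv"))
    triads <- stage(paste0("triads/", cond),
                    detect_triads(events[events$trait == "contact", ],
                                  frames, identities))
    wcsv(triads, paste0("triads_", cond, ".csv"))
    tstats <- triad_statistics(triads, identities, scheme)
    wcsv(bind_rows(creation = tstats$creation, breaking = tstats$breaking,
                   .id = "which"), paste0("triad_summary_", cond, ".csv"))
    wcsv(tstats$duration, paste0("triad_duration_", cond, ".csv"))
    res[[paste0("events_", cond)]] <- events
    res[[paste0("traits_", cond)]] <- traits
    res[[paste0("index_", cond)]] <- index
    res[[paste0("dyads_", cond)]] <- dyads
    res[[paste0("triads_", cond)]] <- triads
  }

  if (all(c("saline", "cno") %in% config$conditions)) {
    dd <- stage("dyad_difference", condition_difference(
      res$dyads_cno, res$dyads_saline,
      baseline_label = paste0("T", config$baseline_checkpoint)))
    wcsv(dd, "dyad_difference.csv")
    res$dyad_difference <- dd

    res$index_contrast <- stage("index_contrast", index_contrast(
      res$index_cno, res$index_saline, identities, config))
    jsonlite::write_json(res$index_contrast,
                         file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, file.path(out_dir, "stats.json"))
  }

  manifest <- list(
    package = "ethotouch",
    version = as.character(utils::packageVersion("ethotouch")),
    seed = config$seed,
    config = config,
    geometry = unclass(params),
    outputs = lapply(
      setNames(files, basename(files)),
      function(p) unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

# per-checkpoint permutation contrast of experimental-mouse contact indexes
# between conditions, Holm-Sidak adjusted across checkpoints
index_contrast <- function(index_cno, index_saline, identities, config,
                           trait_name = "contact", measure_name = "n_events",
                           n_perm = 999L) {
  exp_ids <- identities$mouse_id[identities$genotype == "experimental"]
  pick <- function(tab, bl) {
    v <- tab$index[tab$mouse_id %in% exp_ids & tab$trait == trait_name &
                     tab$measure == measure_name & tab$bin_label == bl]
    v[!is.na(v)]
  }
  labels <- paste0("T", config$checkpoints[config$checkpoints > 0])
  rows <- list()
  for (bl in labels) {
    x <- pick(index_cno, bl)
    y <- pick(index_saline, bl)
    if (length(x) < 2 || length(y) < 2) next
    pt <- permutation_test(x, y, n_perm = n_perm,
                           seed = substream_seed(paste0("contrast/", bl),
                                                 config$seed))
    rows[[bl]] <- tibble(bin_label = bl, mean_cno = mean(x),
                         mean_saline = mean(y),
                         delta = mean(x) - mean(y),
                         ratio_pct = 100 * (mean(x) - mean(y)) /
                           ifelse(mean(y) == 0, NA, mean(y)),
                         p = pt$p)
  }
  out <- bind_rows(rows)
  if (nrow(out) > 0) out$p_adjusted <- holm_sidak(out$p)
  out
}
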