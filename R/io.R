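#' Write a raw intensity recording to TSV + JSON sidecar
#'
#' Serializes a raw recording set as one long-format TSV
#' (`session, block, time_s, channel, wavelength_nm, intensity`) plus a JSON
#' sidecar carrying the sampling rate, wavelengths and channel count, and the
#' events as a second TSV (`session, block, onset_s, duration_s, task`).
#' Plain-text formats are used throughout so recordings diff cleanly.
#'
#' @param raw a `nirs_raw_set`.
#' @param prefix path prefix; writes `<prefix>.tsv`, `<prefix>.json`,
#'   `<prefix>_events.tsv`.
#' @return `prefix`, invisibly.
#' @export
write_recording <- function(raw, prefix) {
  rows <- do.call(rbind, lapply(raw, function(bl) {
    n <- dim(bl$intensity)[1]; n_ch <- dim(bl$intensity)[2]
    data.frame(
      session = bl$session, block = bl$block,
      time_s = rep((seq_len(n) - 1) / bl$fs, times = n_ch * 2),
      channel = rep(rep(seq_len(n_ch), each = n), 2),
      wavelength_nm = rep(bl$wavelengths, each = n * n_ch),
      intensity = as.numeric(bl$intensity)
    )
  }))
  utils::write.table(rows, paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  ev <- do.call(rbind, lapply(raw, function(bl)
    cbind(session = bl$session, block = bl$block, bl$events)))
  utils::write.table(ev, paste0(prefix, "_events.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  sidecar <- list(fs_hz = attr(raw, "fs"),
                  wavelengths_nm = raw[[1]]$wavelengths,
                  n_channels = dim(raw[[1]]$intensity)[2],
                  format = "nirsbci-raw-v1")
  jsonlite::write_json(sidecar, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read a raw intensity recording written by [write_recording()]
#'
#' Validates the sidecar (sampling rate, wavelengths, channel completeness)
#' and the intensities (strictly positive). A sidecar whose wavelengths are
#' not the conventional 690/830 nm pair produces a warning and proceeds with
#' the declared values.
#'
#' @param prefix path prefix used at write time.
#' @return a `nirs_raw_set`.
#' @export
read_recording <- function(prefix) {
  sidecar_path <- paste0(prefix, ".json")
  if (!file.exists(sidecar_path)) stop2("missing sidecar ", sidecar_path)
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (f in c("fs_hz", "wavelengths_nm", "n_channels"))
    if (is.null(side[[f]])) stop2("sidecar missing field '", f, "'")
  if (!isTRUE(all.equal(sort(side$wavelengths_nm), c(690, 830))))
    warning("sidecar wavelengths are ",
            paste(side$wavelengths_nm, collapse = "/"),
            " nm, not the conventional 690/830 pair; proceeding as declared")
  rows <- utils::read.table(paste0(prefix, ".tsv"), header = TRUE, sep = "\t")
  need <- c("session", "block", "time_s", "channel", "wavelength_nm",
            "intensity")
  if (!all(need %in% names(rows)))
    stop2("recording TSV missing column(s): ",
          paste(setdiff(need, names(rows)), collapse = ", "))
  if (any(!(rows$intensity > 0))) {
    bad <- which(!(rows$intensity > 0))[1]
    stop2("non-positive intensity at TSV line ", bad + 1)
  }
  ev <- utils::read.table(paste0(prefix, "_events.tsv"), header = TRUE,
                          sep = "\t")
  fs <- side$fs_hz
  keys <- unique(rows[, c("session", "block")])
  blocks <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- rows[rows$session == keys$session[i] & rows$block == keys$block[i], ]
    n <- length(unique(sub$time_s))
    n_ch <- side$n_channels
    if (nrow(sub) != n * n_ch * 2)
      stop2("incomplete channel/wavelength grid in session ",
            keys$session[i], " block ", keys$block[i])
    sub <- sub[order(sub$wavelength_nm, sub$channel, sub$time_s), ]
    inten <- array(sub$intensity, dim = c(n, n_ch, 2),
                   dimnames = list(NULL, paste0("ch", seq_len(n_ch)),
                                   paste0("wl", sort(side$wavelengths_nm))))
    evb <- ev[ev$session == keys$session[i] & ev$block == keys$block[i],
              c("onset_s", "duration_s", "task")]
    list(session = keys$session[i], block = keys$block[i], fs = fs,
         wavelengths = sort(side$wavelengths_nm), intensity = inten,
         events = evb)
  })
  structure(blocks, class = "nirs_raw_set", fs = fs)
}

#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end pipeline in one serializable
#' object: the random seed, protocol layout, effect/noise/participant
#' specifications, optics, filter, cross-validation layout, the class counts
#' to personalize over, and the alpha levels for chance limits and
#' correlations.
#'
#' @param seed integer master seed.
#' @param n_sessions,n_blocks protocol dimensions.
#' @param tasks task labels.
#' @param n_classes class counts to personalize (subset of 2:5).
#' @param n_folds,n_iterations cross-validation layout.
#' @param chance_alpha,corr_alpha significance levels.
#' @param effects,noise,optics,participants,filter component specifications.
#' @param out_dir optional output directory for CSV/JSON exports.
#' @return object of class `nirs_config`.
#' @export
run_config <- function(seed = 1, n_sessions = 5, n_blocks = 3,
                       tasks = c("MM", "WG", "HT", "RF", "RS", "RR"),
                       n_classes = 2:5, n_folds = 10, n_iterations = 10,
                       chance_alpha = 0.05, corr_alpha = 0.1,
                       effects = effect_spec(), noise = noise_spec(),
                       optics = optics_parameters(),
                       participants = participant_spec(),
                       filter = filter_spec(), out_dir = NULL) {
  if (chance_alpha <= 0 || chance_alpha >= 1 || corr_alpha <= 0 ||
      corr_alpha >= 1) stop2("alpha levels must lie in (0, 1)")
  if (n_folds < 2) stop2("n_folds must be at least 2")
  structure(list(seed = seed, n_sessions = n_sessions, n_blocks = n_blocks,
                 tasks = tasks, n_classes = n_classes, n_folds = n_folds,
                 n_iterations = n_iterations, chance_alpha = chance_alpha,
                 corr_alpha = corr_alpha, effects = effects, noise = noise,
                 optics = optics, participants = participants,
                 filter = filter, out_dir = out_dir),
            class = "nirs_config")
}

#' Save / load a pipeline configuration as JSON
#'
#' Serializes a [run_config()] to JSON and reconstructs it losslessly
#' (matrices keep their dimnames; component specs regain their classes).
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return `load_config` returns the reconstructed `nirs_config`.
#' @export
save_config <- function(config, path) {
  enc <- unclass(config)
  enc$effects <- unclass(config$effects)
  enc$effects$amplitudes <- mat_to_json(config$effects$amplitudes)
  enc$noise <- unclass(config$noise)
  enc$optics <- unclass(config$optics)
  enc$optics$extinction <- mat_to_json(config$optics$extinction)
  enc$participants <- unclass(config$participants)
  enc$participants$likert_mean <- as.list(config$participants$likert_mean)
  enc$participants$likert_sd <- as.list(config$participants$likert_sd)
  enc$filter <- unclass(config$filter)
  enc <- enc[!vapply(enc, is.null, TRUE)]
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  enc <- jsonlite::read_json(path, simplifyVector = TRUE)
  enc$participants$likert_mean <- unlist(enc$participants$likert_mean)
  enc$participants$likert_sd <- unlist(enc$participants$likert_sd)
  enc$effects$amplitudes <- mat_from_json(enc$effects$amplitudes)
  effects <- do.call(effect_spec, c(enc$effects, amplitude_scale = 1))
  noise <- do.call(noise_spec, c(enc$noise, list(scale = 1)))
  enc$optics$extinction <- mat_from_json(enc$optics$extinction)
  optics <- do.call(optics_parameters, enc$optics)
  participants <- do.call(participant_spec, enc$participants)
  filter <- do.call(filter_spec, enc$filter)
  run_config(seed = enc$seed, n_sessions = enc$n_sessions,
             n_blocks = enc$n_blocks, tasks = enc$tasks,
             n_classes = enc$n_classes, n_folds = enc$n_folds,
             n_iterations = enc$n_iterations,
             chance_alpha = enc$chance_alpha, corr_alpha = enc$corr_alpha,
             effects = effects, noise = noise, optics = optics,
             participants = participants, filter = filter,
             out_dir = enc$out_dir)
}

mat_to_json <- function(m) {
  list(rows = rownames(m), cols = colnames(m), data = as.numeric(m),
       nrow = nrow(m))
}

mat_from_json <- function(x) {
  m <- matrix(x$data, nrow = x$nrow)
  rownames(m) <- x$rows; colnames(m) <- x$cols
  m
}

#' Simulate and analyse one participant end to end
#'
#' The per-participant pipeline: generate the protocol schedule, simulate
#' hemodynamics, forward-model to raw intensities, invert via the modified
#' Beer-Lambert law with per-block baseline referencing, low-pass filter,
#' segment trials, and extract the three feature sets.
#'
#' @param config a [run_config()].
#' @param participant participant id (seeds its own streams).
#' @param effect_scale amplitude multiplier for this participant.
#' @return a [epoch_features()] object.
#' @export
simulate_participant_features <- function(config, participant = 1,
                                          effect_scale = 1) {
  pseed <- sub_seed(config$seed, paste0("participant", participant))
  schedule <- generate_protocol(config$n_sessions, config$n_blocks,
                                config$tasks, seed = pseed)
  eff <- config$effects
  eff$amplitudes <- eff$amplitudes * effect_scale
  montage <- nirs_montage()
  hemo <- simulate_hemodynamics(schedule, eff, config$noise, montage,
                                fs = config$filter$fs, seed = pseed)
  raw <- hemodynamics_to_intensity(hemo, config$optics, config$noise,
                                   seed = pseed)
  hemo2 <- raw_to_hemo(raw, config$optics)
  filt <- design_lowpass(config$filter)
  epochs <- segment_trials(filter_recording(hemo2, filt))
  epoch_features(epochs, montage)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Simulates a cohort of participants (with per-participant effect scales
#' tied to their characteristics), runs the per-participant pipeline and
#' personalization for every requested class count, computes chance
#' intervals, and correlates the best two-class accuracies with the
#' simulated characteristics. With a fixed seed the whole bundle is
#' bit-identical across runs. If the config names an `out_dir`, the
#' best-subset table (one row per participant, one column per class count),
#' the correlation table and a provenance log (seed, config hash, package
#' version) are written there.
#'
#' @param config a [run_config()].
#' @return object of class `nirs_pipeline_result`: `personalization`
#'   (participant x class-count list), `best_table`, `chance`,
#'   `correlations`, `profiles`, `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  cohort <- simulate_participants(config$participants, config$seed)
  n_part <- nrow(cohort$profiles)
  trials_per_class <- 4 * config$n_blocks * config$n_sessions
  pers <- vector("list", n_part)
  for (p in seq_len(n_part)) {
    feats <- simulate_participant_features(config, p, cohort$effect_scale[p])
    pseed <- sub_seed(config$seed, paste0("cv.participant", p))
    pers[[p]] <- lapply(config$n_classes, function(n)
      personalize(feats, n, seed = pseed, n_folds = config$n_folds,
                  n_iterations = config$n_iterations))
    names(pers[[p]]) <- paste0("n", config$n_classes)
  }
  best_table <- data.frame(participant = seq_len(n_part))
  for (j in seq_along(config$n_classes)) {
    nm <- paste0("n", config$n_classes[j])
    best_table[[paste0(nm, "_subset")]] <-
      vapply(pers, function(pp) paste(pp[[nm]]$best_subset, collapse = " "), "")
    best_table[[paste0(nm, "_accuracy")]] <-
      vapply(pers, function(pp) pp[[nm]]$best_accuracy, 0)
  }
  chance <- lapply(config$n_classes, chance_interval,
                   n_trials = trials_per_class, alpha = config$chance_alpha)
  names(chance) <- paste0("n", config$n_classes)
  correlations <- NULL
  if (2 %in% config$n_classes && n_part >= 4) {
    acc2 <- data.frame(participant = seq_len(n_part),
                       accuracy = best_table$n2_accuracy)
    correlations <- correlate_report(acc2, cohort$profiles,
                                     alpha = config$corr_alpha)
  }
  out <- structure(list(personalization = pers, best_table = best_table,
                        chance = chance, correlations = correlations,
                        profiles = cohort$profiles, config = config),
                   class = "nirs_pipeline_result")
  if (!is.null(config$out_dir)) export_results(out, config$out_dir)
  out
}

export_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$best_table,
                   file.path(dir, "best_task_subsets.csv"), row.names = FALSE)
  if (!is.null(result$correlations))
    utils::write.csv(as.data.frame(result$correlations),
                     file.path(dir, "accuracy_correlations.csv"),
                     row.names = FALSE)
  utils::write.csv(result$profiles, file.path(dir, "participant_profiles.csv"),
                   row.names = FALSE)
  cfg <- result$config
  prov <- list(seed = cfg$seed,
               package_version = as.character(utils::packageVersion("nirsbci")),
               n_sessions = cfg$n_sessions, n_blocks = cfg$n_blocks,
               n_classes = cfg$n_classes, n_folds = cfg$n_folds,
               n_iterations = cfg$n_iterations)
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.nirs_pipeline_result <- function(x, ...) {
  cat("Personalized multi-class pipeline result:",
      nrow(x$best_table), "participants\n")
  print(x$best_table)
  invisible(x)
}
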