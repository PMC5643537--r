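#' Read a recording from disk
#'
#' @param path file path.
#' @param format `"edf"`, `"bdf"`, or `"delim"` (tab-delimited numeric
#'   matrix, samples in rows, with a channel-label header line);
#'   `"auto"` guesses from the extension.
#' @param rate sampling rate in Hz — required for delimited input, ignored
#'   for EDF/BDF (embedded in the header).
#' @param modality `"EEG"` or `"EMG"`.
#' @return a [recording].
#' @export
read_recording <- function(path, format = c("auto", "edf", "bdf", "delim"),
                           rate = NULL, modality = "EEG") {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", bdf = "bdf",
                     tsv = "delim", txt = "delim", csv = "delim",
                     stop(sprintf("cannot infer format from extension '%s'", ext)))
  }
  if (format %in% c("edf", "bdf")) return(read_edf(path, modality = modality))
  if (is.null(rate)) stop("delimited input requires an explicit rate")
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  if (!any(is.na(suppressWarnings(as.numeric(header)))))
    stop("delimited matrix must have a channel-label header")
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  recording(t(m), rate, labels = colnames(m), modality = modality)
}

#' Write a recording as a delimited matrix
#'
#' Tab-delimited, samples in rows, channel labels as the header line.
#' @param rec a [recording].
#' @param path output path.
#' @export
write_recording_delim <- function(rec, path) {
  m <- t(rec$data)
  colnames(m) <- rec$labels
  utils::write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated dataset to disk
#'
#' EEG trials as EDF, EMG trials as delimited matrices, per-trial events
#' tables as delimited text, and a JSON manifest listing every path plus
#' the seed and configuration.
#'
#' @param subject one subject entry from [simulate_experiment()].
#' @param dir output directory (created if needed).
#' @param seed the seed that generated the dataset (recorded in the
#'   manifest).
#' @param config the generating configuration (recorded in the manifest).
#' @return the manifest, invisibly.
#' @export
write_dataset <- function(subject, dir, seed = NA_integer_, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  rest_path <- file.path(dir, "rest.edf")
  write_edf(subject$rest, rest_path)
  paths$rest <- rest_path
  paths$trials <- lapply(seq_along(subject$trials), function(i) {
    tr <- subject$trials[[i]]
    base <- sprintf("trial%03d_%s", i, tr$task)
    eeg_p <- file.path(dir, paste0(base, "_eeg.edf"))
    emg_p <- file.path(dir, paste0(base, "_emg.tsv"))
    ev_p <- file.path(dir, paste0(base, "_events.tsv"))
    write_edf(tr$eeg, eeg_p)
    write_recording_delim(tr$emg, emg_p)
    utils::write.table(tr$eeg$events, ev_p, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    list(task = tr$task, eeg = eeg_p, emg = emg_p, events = ev_p)
  })
  manifest <- list(seed = seed, config = config, paths = paths)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# hash of a configuration, via its canonical JSON serialization
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the end-to-end per-subject analysis
#'
#' Orchestrates the full pipeline on a synthetic experiment: simulate,
#' re-reference, extract subject-specific microstates (resting and
#' movement-phase task data, CV model order), back-fit and smooth single
#' trials, extract muscle synergies per task (VAF model order), compute
#' microstate and synergy occurrence histograms, run the per-subject
#' canonical correlation between the two occurrence sets, and decode
#' grasp type from preparation-window microstate occupancy with a
#' permutation-calibrated LDA.
#'
#' @param config generator configuration from [default_config()].
#' @param seed integer master seed for every stochastic stage.
#' @param out_dir optional directory; when given, occurrence tables,
#'   templates, decoding summaries and a manifest (with config hash and
#'   seed) are written under `out_dir/subject<NN>/`.
#' @param k_range candidate microstate model orders.
#' @param n_init k-means restarts.
#' @param nnmf_restarts NNMF restarts per model order.
#' @param k_max_syn largest synergy model order tried.
#' @param lda_reps decoder cross-validation repetitions.
#' @param lda_null_reps label-shuffled null repetitions.
#' @return list of per-subject result lists (`microstates_rest`,
#'   `microstates_task`, `synergies`, `ms_occurrence`, `syn_occurrence`,
#'   `cca`, `decoding`, `null`, `manifest`).
#' @export
run_pipeline <- function(config = default_config(), seed = 1L,
                         out_dir = NULL, k_range = 2:8, n_init = 5L,
                         nnmf_restarts = 10L, k_max_syn = 8L,
                         lda_reps = 100L, lda_null_reps = 200L) {
  experiment <- simulate_experiment(config, seed)
  grasps <- setdiff(config$tasks, "reach")
  lapply(seq_along(experiment), function(si) {
    subj <- experiment[[si]]
    # --- microstates: resting ---
    rest <- rereference_average(subj$rest)
    pk <- find_gfp_peaks(gfp(rest$data))
    ms_rest <- select_k(t(rest$data[, pk]), k_range, n_init = n_init,
                        seed = seed + 11L)
    # --- microstates: movement phase, all tasks pooled peaks ---
    task_peak_maps <- do.call(rbind, lapply(subj$trials, function(tr) {
      eeg <- rereference_average(tr$eeg)
      on <- tr$eeg$events$sample[tr$eeg$events$label == "movement_onset"]
      hd <- tr$eeg$events$sample[tr$eeg$events$label == "holding_onset"]
      seg <- eeg$data[, max(1L, on - 2L * round(eeg$rate)):(hd - 1L)]
      p <- find_gfp_peaks(gfp(seg))
      t(seg[, p, drop = FALSE])
    }))
    ms_task <- select_k(task_peak_maps, k_range, n_init = n_init,
                        seed = seed + 12L)
    n_states <- nrow(ms_task$maps)
    matched <- match_sets(ms_task, ms_rest)

    # --- per-trial segmentation + occupancy ---
    grid <- window_grid(prep_s = 2, move_s = config$move_s, hold_s = 2)
    prep_grid <- grid[grid$phase == "preparation", ]
    occup <- list(); occ_task <- character(0)
    feat_occ <- list()
    for (tr in subj$trials) {
      eeg <- rereference_average(tr$eeg)
      seg <- smooth_segmentation(backfit(eeg, ms_task))
      on <- tr$eeg$events$sample[tr$eeg$events$label == "movement_onset"]
      # rescale trial timeline onto the grid's nominal movement duration
      t0 <- -(on - 1L) / eeg$rate
      occup[[length(occup) + 1L]] <-
        epoch_occupancy(seg, grid, n_states, t0 = t0)
      feat_occ[[length(feat_occ) + 1L]] <-
        epoch_occupancy(seg, prep_grid, n_states, t0 = t0)
      occ_task <- c(occ_task, tr$task)
    }
    ms_occ <- lapply(config$tasks, function(task)
      occurrence_histogram(occup[occ_task == task], grid))
    names(ms_occ) <- config$tasks

    # --- synergies per task (movement-phase epochs pooled) ---
    syn <- list(); syn_occ <- list()
    move_grid <- grid[grid$phase != "preparation", ]
    move_grid_rel <- move_grid
    for (task in config$tasks) {
      idx <- which(occ_task == task)
      epochs <- lapply(subj$trials[idx], function(tr) {
        on <- tr$emg$events$sample[tr$emg$events$label == "movement_onset"]
        n_move <- round((config$move_s + 2) * tr$emg$rate)
        tr$emg$data[, on:min(on + n_move - 1L, ncol(tr$emg$data)),
                    drop = FALSE]
      })
      len <- min(vapply(epochs, ncol, 1L))
      epochs <- lapply(epochs, function(e) e[, seq_len(len), drop = FALSE])
      V <- do.call(cbind, epochs)
      model <- select_n_synergies(V, k_max = k_max_syn,
                                  n_restarts = nnmf_restarts,
                                  seed = seed + 20L)
      syn[[task]] <- model
      # epochs start at movement onset: shift the grid to epoch-relative
      # time for the correlation windows, then restore the onset-relative
      # grid so the windows align with the microstate occurrence grid
      off <- min(move_grid_rel$start)
      g <- move_grid_rel
      g$start <- g$start - off; g$end <- g$end - off
      syn_occ[[task]] <- synergy_occurrence(model, epochs, g,
                                            rate = config$emg_rate)
      syn_occ[[task]]$grid <- move_grid_rel
    }

    # --- canonical correlation per subject ---
    n_syn <- min(vapply(syn, function(m) ncol(m$W), 1L))
    stacked <- stack_occurrences(
      lapply(config$tasks, function(t) ms_occ[[t]]),
      lapply(config$tasks, function(t) {
        o <- syn_occ[[t]]
        occurrence_matrix(o$values[seq_len(n_syn), , drop = FALSE], o$grid,
                          o$n_epochs, kind = "synergy")
      }))
    cca_res <- tryCatch(cca(stacked$X, stacked$Y, subject = si),
                        error = function(e) e)

    # --- LDA decoding on preparation occupancy (grasp tasks only) ---
    gi <- occ_task %in% grasps
    features <- build_feature_vectors(feat_occ[gi])
    decoding <- lda_decode(features, occ_task[gi], n_reps = lda_reps,
                           seed = seed + 30L)
    null <- lda_null(features, occ_task[gi], n_null = lda_null_reps,
                     seed = seed + 31L)

    manifest <- list(subject = si, seed = seed,
                     config_hash = config_hash(config),
                     k_rest = nrow(ms_rest$maps), k_task = n_states,
                     n_synergies = vapply(syn, function(m) ncol(m$W), 1L),
                     decoding_accuracy = mean(decoding$accuracy),
                     significance_level = null$significance_level)
    if (!is.null(out_dir)) {
      sd_dir <- file.path(out_dir, sprintf("subject%02d", si))
      dir.create(sd_dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.table(ms_rest$maps, file.path(sd_dir, "templates_rest.tsv"),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
      utils::write.table(ms_task$maps, file.path(sd_dir, "templates_task.tsv"),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
      for (task in config$tasks)
        utils::write.table(ms_occ[[task]]$values,
                           file.path(sd_dir, sprintf("occurrence_%s.tsv", task)),
                           sep = "\t", row.names = FALSE, col.names = FALSE)
      utils::write.table(decoding$confusion, file.path(sd_dir, "confusion.tsv"),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
      jsonlite::write_json(manifest, file.path(sd_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    list(microstates_rest = ms_rest, microstates_task = ms_task,
         match_to_rest = matched, synergies = syn, ms_occurrence = ms_occ,
         syn_occurrence = syn_occ, cca = cca_res, decoding = decoding,
         null = null, manifest = manifest)
  })
}
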