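#' Generate well-separated scalp topographies
#'
#' Draws random average-referenced, unit-norm channel vectors and redraws
#' until every pair has absolute spatial correlation at or below
#' `min_separation`.  Because the maps are zero-mean and unit-norm, the
#' Pearson correlation between two maps equals their inner product.
#'
#' @param n_states number of maps (1 <= n_states < n_channels).
#' @param n_channels number of channels (>= 2).
#' @param min_separation bound on pairwise absolute correlation, in [0, 1).
#' @param seed integer seed.
#' @param max_redraws redraw budget per map before giving up.
#' @return list of numeric channel vectors, each zero-mean with unit norm.
#' @export
make_topographies <- function(n_states, n_channels, min_separation = 0.5,
                              seed = 1L, max_redraws = 500L) {
  if (n_states < 1L || n_states >= n_channels)
    stop("need 1 <= n_states < n_channels")
  if (min_separation < 0 || min_separation >= 1)
    stop("min_separation must be in [0, 1)")
  set.seed(seed)
  maps <- list()
  for (k in seq_len(n_states)) {
    ok <- FALSE
    for (try in seq_len(max_redraws)) {
      v <- stats::rnorm(n_channels)
      v <- v - mean(v)
      nv <- sqrt(sum(v^2))
      if (nv == 0) next
      v <- v / nv
      if (all(vapply(maps, function(m) abs(sum(m * v)), 0) <= min_separation)) {
        ok <- TRUE; break
      }
    }
    if (!ok)
      stop(sprintf(
        "could not place map %d with |corr| <= %.2f after %d redraws; request over-constrained",
        k, min_separation, max_redraws))
    maps[[k]] <- v
  }
  maps
}

#' Ground-truth model for the synthetic generator
#'
#' Bundles everything the generator needs to emit EEG/EMG with a known
#' answer key: the scalp topographies and their Markov switching model, the
#' nonnegative synergy weights and per-task activation templates, the
#' state-to-synergy coupling matrix, and per-task state-preference profiles
#' over the movement-preparation windows.
#'
#' @param n_states number of microstate topographies (tasks use all of
#'   them; resting uses the first `n_rest_states`).
#' @param n_rest_states number of states active at rest.
#' @param n_channels EEG channel count.
#' @param n_muscles EMG channel count.
#' @param n_synergies number of muscle synergies.
#' @param tasks character vector of task labels; the first is treated as
#'   pure reaching, the rest as grasp types.
#' @param dwell_ms mean microstate dwell time in ms.
#' @param min_separation topography separation bound (see
#'   [make_topographies()]).
#' @param coupling_strength scales the state-to-synergy coupling matrix
#'   (0 = no coupling: EMG independent of the microstate sequence).
#' @param occupancy_separation strength of the per-task state preference
#'   during movement preparation (0 = identical occupancy across tasks).
#' @param seed integer seed.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(n_states = 5L, n_rest_states = 4L, n_channels = 64L,
                         n_muscles = 15L, n_synergies = 5L,
                         tasks = c("reach", "ulnar", "pulp", "five_finger",
                                   "cylindrical"),
                         dwell_ms = 100, min_separation = 0.5,
                         coupling_strength = 0, occupancy_separation = 3,
                         seed = 1L) {
  stopifnot(n_rest_states <= n_states, dwell_ms > 0)
  topographies <- make_topographies(n_states, n_channels, min_separation,
                                    seed = seed)
  set.seed(seed + 1L)
  trans <- matrix(1 / (n_states - 1), n_states, n_states)
  diag(trans) <- 0

  # sparse-ish synergy weights: each synergy dominated by a few muscles,
  # with a moderate co-activation floor on the rest (real envelopes are
  # never silent; the floor also keeps the EMG RMS realistic relative to
  # its peak)
  W <- matrix(stats::runif(n_muscles * n_synergies, 0.03, 0.12),
              n_muscles, n_synergies)
  for (k in seq_len(n_synergies)) {
    dom <- ((k - 1L) * 3L) %% n_muscles + seq_len(3L)
    dom <- ((dom - 1L) %% n_muscles) + 1L
    W[dom, k] <- stats::runif(3L, 0.9, 1.2)
  }

  # per task, per synergy: sequential recruitment — a wide Gaussian burst
  # centered at a synergy-specific point of the trial (early-preparation
  # postural synergies through movement-phase and holding bursts) over a
  # small tonic background.  Distinct centers keep the activation profiles
  # linearly independent so the factorization rank equals n_synergies.
  templates <- lapply(seq_along(tasks), function(ti) {
    lapply(seq_len(n_synergies), function(k) {
      amp <- 0.75 + 0.25 * ((k + ti) %% 3) / 2
      list(center_frac = (k - 0.5) / n_synergies,  # fraction of the trial
           width = 0.30 + 0.04 * k,                # s
           amplitude = amp, baseline = 0.22)
    })
  })
  names(templates) <- tasks

  coupling <- coupling_strength *
    matrix(stats::runif(n_states * n_synergies, 0.5, 1.5) *
             sample(c(0, 1), n_states * n_synergies, TRUE, c(0.5, 0.5)),
           n_states, n_synergies)

  # state-preference multipliers over 20 preparation windows, per task
  n_win <- 20L
  occ <- array(1, dim = c(length(tasks), n_states, n_win))
  for (ti in seq_along(tasks)) {
    pref <- (ti - 1L) %% n_states + 1L
    ramp <- seq(0.3, 1, length.out = n_win)
    occ[ti, pref, ] <- 1 + occupancy_separation * ramp
  }
  dimnames(occ) <- list(tasks, NULL, NULL)

  structure(list(topographies = topographies,
                 transition = trans, dwell_ms = dwell_ms,
                 n_rest_states = n_rest_states,
                 synergy_weights = W, activation_templates = templates,
                 coupling = coupling, class_occupancy = occ,
                 tasks = tasks, seed = seed),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d states (%d at rest) x %d channels; %d synergies x %d muscles; tasks: %s\n",
    length(x$topographies), x$n_rest_states, length(x$topographies[[1]]),
    ncol(x$synergy_weights), nrow(x$synergy_weights),
    paste(x$tasks, collapse = ", ")))
  invisible(x)
}

# Markov state sequence with geometric dwell truncated below 2 samples.
# window_probs: optional states x windows multiplier matrix with a parallel
# window index per sample (win_of); biases the state drawn at each switch.
simulate_state_sequence <- function(n_samples, n_states, dwell_samples,
                                    transition, window_probs = NULL,
                                    win_of = NULL) {
  if (n_states == 1L) return(rep(1L, n_samples))
  p <- 1 / max(dwell_samples - 1, 1.0001)
  draw_state <- function(prev, at) {
    w <- if (is.null(prev)) rep(1, n_states) else transition[prev, ]
    if (!is.null(window_probs)) {
      wi <- win_of[at]
      if (!is.na(wi)) w <- w * window_probs[, wi]
    }
    sample.int(n_states, 1L, prob = w)
  }
  labels <- integer(n_samples)
  t <- 1L
  prev <- NULL
  while (t <= n_samples) {
    s <- draw_state(prev, t)
    d <- 2L + stats::rgeom(1L, p)
    idx <- t:min(t + d - 1L, n_samples)
    labels[idx] <- s
    prev <- s
    t <- t + d
  }
  labels
}

#' Simulate continuous microstate EEG
#'
#' Emits `signal(t) = topography[state(t)] * envelope(t) + noise`, where
#' the state sequence follows a first-order Markov chain with the
#' configured mean dwell time, the envelope is a positive GFP-like
#' fluctuation (`0.5 + |sin|` at ~10 Hz), and white sensor noise is scaled
#' so that `sd(signal)/sd(noise) = snr`.
#'
#' @param truth a [ground_truth()].
#' @param duration length in seconds.
#' @param rate sampling rate in Hz.
#' @param snr amplitude signal-to-noise ratio (> 0, finite).
#' @param seed integer seed.
#' @param states which topographies to use (default: all); e.g.
#'   `seq_len(truth$n_rest_states)` for a resting segment.
#' @param window_probs,win_of optional state-preference bias (see
#'   [simulate_experiment()]); internal use.
#' @return list with elements `rec` (a [recording]) and `labels`
#'   (per-sample true state indices into `states`).
#' @export
simulate_eeg <- function(truth, duration, rate, snr = 5, seed = 1L,
                         states = seq_along(truth$topographies),
                         window_probs = NULL, win_of = NULL) {
  if (!is.finite(snr) || snr <= 0) stop("snr must be positive and finite")
  if (length(states) == 0L) stop("empty topography list")
  n <- round(duration * rate)
  if (n < 1L) stop("duration * rate must be >= 1")
  set.seed(seed)
  n_states <- length(states)
  trans <- truth$transition[states, states, drop = FALSE]
  trans <- sweep(trans, 1L, pmax(rowSums(trans), 1e-12), "/")
  dwell_samples <- truth$dwell_ms * rate / 1000
  labels <- simulate_state_sequence(n, n_states, dwell_samples, trans,
                                    window_probs, win_of)
  tt <- (seq_len(n) - 1L) / rate
  env <- 20 * (0.5 + abs(sin(2 * pi * 10 * tt)))
  topo <- do.call(cbind, truth$topographies[states])  # channels x states
  X <- topo[, labels, drop = FALSE] * rep(env, each = nrow(topo))
  noise_sd <- stats::sd(X) / snr
  X <- X + matrix(stats::rnorm(length(X), 0, noise_sd), nrow(X))
  list(rec = recording(X, rate, modality = "EEG"), labels = labels)
}

# activation profile of one synergy over the trial timeline (seconds
# relative to trial start); onset = movement-onset time, move_s = movement
# duration, both in seconds.
activation_profile <- function(tmpl, tt, onset, move_s) {
  total <- max(tt)
  center <- tmpl$center_frac * total
  bump <- exp(-((tt - center)^2) / (2 * tmpl$width^2))
  tmpl$amplitude * (bump + tmpl$baseline)
}

#' Simulate one trial of multichannel EMG
#'
#' Builds nonnegative EMG as `W %*% H` plus clipped Gaussian noise, where
#' `W` holds the ground-truth synergy weights and `H` stacks per-synergy
#' activation profiles: tonic synergies stay on through preparation and
#' movement, phasic synergies follow Gaussian bumps timed within the
#' movement phase.
#'
#' @param truth a [ground_truth()].
#' @param task task label (must be in `truth$tasks`).
#' @param timing numeric `c(prep, move, hold)` durations in seconds (> 0).
#' @param noise_sd noise standard deviation as a fraction of the peak
#'   noiseless EMG value (>= 0).
#' @param seed integer seed.
#' @param rate EMG sampling rate in Hz.
#' @param state_labels optional per-sample microstate labels (at
#'   `state_rate`); combined with `truth$coupling` they scale each
#'   synergy's activation per 100-ms window.
#' @param state_rate sampling rate of `state_labels`.
#' @return list with `rec` (a [recording], modality EMG), `H` (true
#'   activations) and `W` (true weights).
#' @export
simulate_trial_emg <- function(truth, task, timing = c(2, 1, 2),
                               noise_sd = 0.05, seed = 1L, rate = 500,
                               state_labels = NULL, state_rate = NULL) {
  if (!task %in% truth$tasks) stop(sprintf("unknown task '%s'", task))
  if (any(timing <= 0)) stop("all trial phase durations must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  W <- truth$synergy_weights
  K <- ncol(W)
  total <- sum(timing)
  n <- round(total * rate)
  tt <- (seq_len(n) - 1L) / rate
  onset <- timing[1]
  tmpl <- truth$activation_templates[[task]]
  H <- do.call(rbind, lapply(seq_len(K), function(k)
    activation_profile(tmpl[[k]], tt, onset, timing[2])))

  if (!is.null(state_labels) && any(truth$coupling != 0)) {
    win_len <- 0.1  # 100-ms coupling windows over the whole trial
    win_idx_emg <- pmin(floor(tt / win_len) + 1L, ceiling(total / win_len))
    ts <- (seq_along(state_labels) - 1L) / state_rate
    win_idx_st <- pmin(floor(ts / win_len) + 1L, ceiling(total / win_len))
    n_win <- max(win_idx_emg)
    frac <- matrix(0, nrow(truth$coupling), n_win)
    for (w in seq_len(n_win)) {
      lab <- state_labels[win_idx_st == w]
      if (length(lab))
        frac[, w] <- tabulate(lab, nbins = nrow(frac)) / length(lab)
    }
    mult <- 1 + t(truth$coupling) %*% frac        # K x n_win
    H <- H * mult[, win_idx_emg, drop = FALSE]
  }

  V <- W %*% H
  if (noise_sd > 0) {
    V <- V + matrix(stats::rnorm(length(V), 0, noise_sd * max(V)), nrow(V))
    V[V < 0] <- 0
  }
  muscles <- paste0("m", seq_len(nrow(W)))
  list(rec = recording(V, rate, labels = muscles, modality = "EMG"),
       H = H, W = W)
}

#' Default configuration for the synthetic experiment
#'
#' Mirrors the study conditions: 5 motor tasks (pure reaching + 4 grasp
#' types) x 15 trials per subject, 64 EEG channels, 15 muscles, ~2 s
#' movement preparation, ~1 s movement, 2 s holding, plus a resting
#' segment.  Signals are generated directly at analysis rates (EEG 128 Hz,
#' EMG 500 Hz).
#'
#' @param ... overrides for any field.
#' @export
default_config <- function(...) {
  cfg <- list(n_subjects = 1L,
              tasks = c("reach", "ulnar", "pulp", "five_finger", "cylindrical"),
              n_trials = 15L, n_channels = 64L, n_muscles = 15L,
              n_states = 5L, n_rest_states = 4L, n_synergies = 5L,
              eeg_rate = 128, emg_rate = 500, snr = 5, noise_sd = 0.05,
              dwell_ms = 100, coupling_strength = 0, occupancy_separation = 3,
              rest_duration = 60, prep_s = 2.5, move_s = 1.1, hold_s = 2,
              move_jitter = 0.1, min_separation = 0.5)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Simulate a full per-subject experiment
#'
#' For each subject: a resting EEG segment (restricted to the resting
#' subset of states), and `n_trials` paired EEG/EMG trials per task with a
#' `task_cue` / `movement_onset` / `holding_onset` / `release` events
#' table.  Task-specific state preferences during the 2 s before movement
#' onset and the state-to-synergy coupling are embedded exactly as
#' configured; with `coupling_strength = 0` and `occupancy_separation = 0`
#' the dataset is null for the downstream canonical-correlation and
#' decoding analyses.
#'
#' @param config a list from [default_config()].
#' @param seed integer seed.
#' @return list of subjects; each subject is a list with `truth`, `rest`
#'   (a [recording]), `rest_labels`, and `trials` (list of lists with
#'   `task`, `eeg`, `emg`, `eeg_labels`, `timing`).
#' @export
simulate_experiment <- function(config = default_config(), seed = 1L) {
  cfg <- config
  lapply(seq_len(cfg$n_subjects), function(s) {
    truth <- ground_truth(n_states = cfg$n_states,
                          n_rest_states = cfg$n_rest_states,
                          n_channels = cfg$n_channels,
                          n_muscles = cfg$n_muscles,
                          n_synergies = cfg$n_synergies,
                          tasks = cfg$tasks, dwell_ms = cfg$dwell_ms,
                          min_separation = cfg$min_separation,
                          coupling_strength = cfg$coupling_strength,
                          occupancy_separation = cfg$occupancy_separation,
                          seed = seed + 1000L * s)
    rest <- simulate_eeg(truth, cfg$rest_duration, cfg$eeg_rate, cfg$snr,
                         seed = seed + 1000L * s + 1L,
                         states = seq_len(cfg$n_rest_states))
    trials <- list()
    ti <- 0L
    for (task_i in seq_along(cfg$tasks)) {
      task <- cfg$tasks[task_i]
      for (tr in seq_len(cfg$n_trials)) {
        ti <- ti + 1L
        tseed <- seed + 1000L * s + 10L * ti
        set.seed(tseed)
        move_s <- max(0.6, stats::rnorm(1L, cfg$move_s, cfg$move_jitter))
        prep_s <- cfg$prep_s; hold_s <- cfg$hold_s
        total <- prep_s + move_s + hold_s + 0.5
        n <- round(total * cfg$eeg_rate)
        # task-specific state preference over the 20 windows spanning the
        # 2 s before movement onset
        tt <- (seq_len(n) - 1L) / cfg$eeg_rate
        win_of <- rep(NA_integer_, n)
        in_prep <- tt >= prep_s - 2 & tt < prep_s
        win_of[in_prep] <- pmin(floor((tt[in_prep] - (prep_s - 2)) / 0.1) + 1L, 20L)
        eeg <- simulate_eeg(truth, total, cfg$eeg_rate, cfg$snr,
                            seed = tseed + 1L,
                            window_probs = truth$class_occupancy[task, , ],
                            win_of = win_of)
        onset_smp <- round(prep_s * cfg$eeg_rate) + 1L
        hold_smp <- round((prep_s + move_s) * cfg$eeg_rate) + 1L
        rel_smp <- min(round((prep_s + move_s + hold_s) * cfg$eeg_rate) + 1L, n)
        eeg$rec$events <- data.frame(
          sample = c(1L, onset_smp, hold_smp, rel_smp),
          label = c("task_cue", "movement_onset", "holding_onset", "release"))
        emg <- simulate_trial_emg(truth, task,
                                  timing = c(prep_s, move_s, hold_s + 0.5),
                                  noise_sd = cfg$noise_sd, seed = tseed + 2L,
                                  rate = cfg$emg_rate,
                                  state_labels = eeg$labels,
                                  state_rate = cfg$eeg_rate)
        r <- cfg$emg_rate / cfg$eeg_rate
        emg$rec$events <- data.frame(
          sample = pmin(round((eeg$rec$events$sample - 1L) * r) + 1L,
                        ncol(emg$rec$data)),
          label = eeg$rec$events$label)
        trials[[ti]] <- list(task = task, eeg = eeg$rec, emg = emg$rec,
                             eeg_labels = eeg$labels,
                             timing = c(prep = prep_s, move = move_s,
                                        hold = hold_s))
      }
    }
    list(truth = truth, rest = rest$rec, rest_labels = rest$labels,
         trials = trials)
  })
}
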