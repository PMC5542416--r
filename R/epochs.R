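#' Epoched sensor data container
#'
#' An `epoch_set` holds peri-stimulus sensor epochs as a 3D numeric array
#' (trials x channels x time, femtotesla) together with the time axis in ms
#' relative to stimulus onset and per-trial metadata.
#'
#' @param data Numeric array, trials x channels x time.
#' @param times Strictly increasing regular numeric time axis (ms).
#' @param info Tibble with one row per trial; must contain `condition_id` and
#'   `subject_id` (and typically `run_id`).
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, times, info) {
  stopifnot(length(dim(data)) == 3)
  if (length(times) != dim(data)[3]) {
    rlang::abort("`times` length must match the third dimension of `data`")
  }
  dt <- diff(times)
  if (any(dt <= 0) || (length(dt) > 1 && max(abs(dt - dt[1])) > 1e-9)) {
    rlang::abort("`times` must be strictly increasing and regular")
  }
  info <- tibble::as_tibble(info)
  if (nrow(info) != dim(data)[1]) {
    rlang::abort("`info` must have one row per trial")
  }
  if (!all(c("condition_id", "subject_id") %in% names(info))) {
    rlang::abort("`info` must contain `condition_id` and `subject_id`")
  }
  structure(list(data = data, times = as.numeric(times), info = info),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d trials x %d channels x %d time points [%g..%g ms, step %g ms]\n",
    d[1], d[2], d[3], min(x$times), max(x$times), diff(x$times)[1]))
  cat(sprintf("  %d subject(s), %d condition(s)\n",
              dplyr::n_distinct(x$info$subject_id),
              dplyr::n_distinct(x$info$condition_id)))
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

n_subjects <- function(epochs) dplyr::n_distinct(epochs$info$subject_id)

subset_trials <- function(epochs, idx) {
  epoch_set(epochs$data[idx, , , drop = FALSE], epochs$times, epochs$info[idx, ])
}

split_subjects <- function(epochs) {
  ids <- sort(unique(epochs$info$subject_id))
  stats::setNames(lapply(ids, function(s) {
    subset_trials(epochs, which(epochs$info$subject_id == s))
  }), ids)
}

#' Specify injected multivariate effects
#'
#' A signal specification lists the ground-truth effects the generator injects
#' on top of noise. Each effect targets one design factor (or `"identity"` for
#' condition-unique image effects) and has a half-cosine temporal envelope
#' rising from `onset_ms` to `peak_ms` and falling back to zero at
#' `offset_ms`, scaled by `amplitude` (fT). Effects appear as level-specific
#' (or condition-specific) spatial patterns across channels; per-subject
#' pattern jitter makes subjects heterogeneous.
#'
#' @param effects Tibble/data frame with columns `factor`, `onset_ms`,
#'   `peak_ms`, `offset_ms`, `amplitude`. Use [signal_effect()] rows; an empty
#'   default gives a pure-noise (null) generator.
#' @param pattern_seed Integer seed for the group-level spatial patterns.
#' @param subject_jitter_sd Per-subject pattern jitter, as a fraction of the
#'   pattern norm.
#' @return A `signal_spec` list.
#' @export
signal_spec <- function(effects = NULL, pattern_seed = 42, subject_jitter_sd = 0.2) {
  if (is.null(effects)) {
    effects <- tibble::tibble(factor = character(), onset_ms = numeric(),
                              peak_ms = numeric(), offset_ms = numeric(),
                              amplitude = numeric())
  }
  effects <- tibble::as_tibble(effects)
  req <- c("factor", "onset_ms", "peak_ms", "offset_ms", "amplitude")
  if (!all(req %in% names(effects))) {
    rlang::abort(paste("signal effects need columns:", paste(req, collapse = ", ")))
  }
  bad <- with(effects, onset_ms >= peak_ms | peak_ms > offset_ms | amplitude < 0)
  if (any(bad)) {
    rlang::abort("each effect needs onset_ms < peak_ms <= offset_ms and amplitude >= 0")
  }
  ok <- c(design_factors(), "identity")
  if (!all(effects$factor %in% ok)) {
    rlang::abort(paste("effect factors must be one of:", paste(ok, collapse = ", ")))
  }
  structure(list(effects = effects, pattern_seed = as.integer(pattern_seed),
                 subject_jitter_sd = subject_jitter_sd),
            class = "signal_spec")
}

#' @rdname signal_spec
#' @param factor Design factor name or `"identity"`.
#' @param onset_ms,peak_ms,offset_ms Envelope latencies in ms.
#' @param amplitude Peak amplitude in fT.
#' @export
signal_effect <- function(factor, onset_ms, peak_ms, offset_ms, amplitude) {
  tibble::tibble(factor = factor, onset_ms = onset_ms, peak_ms = peak_ms,
                 offset_ms = offset_ms, amplitude = amplitude)
}

#' Specify the additive sensor noise
#'
#' Noise is zero-mean Gaussian with a random low-rank-plus-diagonal channel
#' covariance (correlated sensors) filtered over time by an AR(1) process.
#'
#' @param n_channels Number of sensors (306 for a full Neuromag-style array).
#' @param sd Marginal channel noise SD in fT.
#' @param cov_rank Rank of the shared (correlated) noise component.
#' @param shared_frac Fraction of variance carried by the shared component.
#' @param ar_coef AR(1) coefficient of the temporal autocorrelation.
#' @param spike_rate,spike_amplitude Fraction of trials receiving a
#'   single-channel artifact spike of the given amplitude (fT); defaults off.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(n_channels = 306, sd = 100, cov_rank = 5,
                       shared_frac = 0.3, ar_coef = 0.8,
                       spike_rate = 0, spike_amplitude = 10000) {
  stopifnot(n_channels >= 1, sd > 0, cov_rank >= 0, ar_coef >= 0, ar_coef < 1,
            spike_rate >= 0, spike_rate <= 1, spike_amplitude >= 0)
  structure(list(n_channels = as.integer(n_channels), sd = sd,
                 cov_rank = as.integer(cov_rank), shared_frac = shared_frac,
                 ar_coef = ar_coef, spike_rate = spike_rate,
                 spike_amplitude = spike_amplitude),
            class = "noise_spec")
}

# half-cosine ramp up (onset -> peak) and down (peak -> offset)
envelope_halfcos <- function(times, onset, peak, offset) {
  env <- numeric(length(times))
  up <- times >= onset & times <= peak
  env[up] <- 0.5 * (1 - cos(pi * (times[up] - onset) / (peak - onset)))
  dn <- times > peak & times <= offset
  if (offset > peak) {
    env[dn] <- 0.5 * (1 + cos(pi * (times[dn] - peak) / (offset - peak)))
  }
  env
}

unit_pattern <- function(n) {
  w <- stats::rnorm(n)
  w / sqrt(sum(w^2))
}

# AR(1) + correlated channel noise for one subject, trials x channels x time
gen_noise <- function(n_trials, noise, n_time) {
  nc <- noise$n_channels
  lowrank <- matrix(stats::rnorm(nc * max(noise$cov_rank, 1)), nc)
  if (noise$cov_rank == 0) lowrank[] <- 0
  sigma <- (1 - noise$shared_frac) * diag(nc) +
    noise$shared_frac * tcrossprod(lowrank) / max(noise$cov_rank, 1)
  # normalize to unit marginal variances, then scale to the requested sd
  dscale <- 1 / sqrt(diag(sigma))
  sigma <- sigma * tcrossprod(dscale)
  L <- chol(sigma)
  phi <- noise$ar_coef
  x <- array(0, c(n_trials, nc, n_time))
  innov_sd <- sqrt(1 - phi^2)
  prev <- matrix(stats::rnorm(n_trials * nc), n_trials) %*% L
  x[, , 1] <- prev
  for (t in seq_len(n_time)[-1]) {
    prev <- phi * prev + innov_sd * (matrix(stats::rnorm(n_trials * nc), n_trials) %*% L)
    x[, , t] <- prev
  }
  x * noise$sd
}

#' Generate multi-subject synthetic MEG epochs with known injected effects
#'
#' Emulates a factorial scene experiment: for every subject, every condition
#' receives `n_trials_per_condition` epochs of correlated sensor noise, and
#' each effect in `signal` adds its level-specific (or condition-unique, for
#' `"identity"`) spatial pattern scaled by a half-cosine temporal envelope.
#' The pre-stimulus window contains noise only. Trials are labeled with run
#' ids cycling through `n_runs` presentations blocks.
#'
#' @param design Design tibble from [generate_design()].
#' @param signal A [signal_spec()]; the empty default injects nothing (null data).
#' @param noise A [noise_spec()].
#' @param n_trials_per_condition Trials per condition per subject (60 in a
#'   15-run session with 4 presentations per image per run).
#' @param n_subjects Number of subjects.
#' @param times Time axis in ms (default -100..900 ms at 1 ms).
#' @param master_seed Integer master seed; per-subject seeds derive from it by
#'   a fixed offset so subjects are independent but reproducible.
#' @param n_runs Number of runs the trials are attributed to.
#' @return An `epoch_set` containing all subjects.
#' @export
generate_epochs <- function(design, signal = signal_spec(), noise = noise_spec(),
                            n_trials_per_condition = 60, n_subjects = 15,
                            times = seq(-100, 900, by = 1), master_seed = 1,
                            n_runs = 15) {
  if (n_trials_per_condition < 2) {
    rlang::abort("`n_trials_per_condition` must be at least 2")
  }
  n_cond <- nrow(design)
  n_time <- length(times)
  nc <- noise$n_channels
  n_tr <- n_cond * n_trials_per_condition

  # group-level spatial patterns, shared across subjects
  set.seed(signal$pattern_seed)
  eff <- signal$effects
  patterns <- vector("list", nrow(eff))
  for (e in seq_len(nrow(eff))) {
    if (eff$factor[e] == "identity") {
      patterns[[e]] <- lapply(seq_len(n_cond), function(i) unit_pattern(nc))
    } else {
      patterns[[e]] <- list(unit_pattern(nc), unit_pattern(nc))
    }
  }

  all_data <- vector("list", n_subjects)
  all_info <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    set.seed(master_seed + 1009L * s)
    x <- gen_noise(n_tr, noise, n_time)
    cond <- rep(design$condition_id, each = n_trials_per_condition)
    for (e in seq_len(nrow(eff))) {
      env <- eff$amplitude[e] *
        envelope_halfcos(times, eff$onset_ms[e], eff$peak_ms[e], eff$offset_ms[e])
      if (all(env == 0)) next
      for (i in seq_len(n_cond)) {
        w <- if (eff$factor[e] == "identity") {
          patterns[[e]][[i]]
        } else {
          lev <- design[[eff$factor[e]]][i]
          patterns[[e]][[match(lev, sort(unique(design[[eff$factor[e]]])))]]
        }
        if (signal$subject_jitter_sd > 0) {
          w <- w + signal$subject_jitter_sd * stats::rnorm(nc) / sqrt(nc)
        }
        add <- outer(w, env) # channels x time
        rows <- which(cond == design$condition_id[i])
        for (r in rows) x[r, , ] <- x[r, , ] + add
      }
    }
    run <- rep(rep(seq_len(n_runs), length.out = n_trials_per_condition), n_cond)
    all_data[[s]] <- x
    all_info[[s]] <- tibble::tibble(condition_id = cond, subject_id = s, run_id = run)
  }

  data <- array(0, c(n_tr * n_subjects, nc, n_time))
  for (s in seq_len(n_subjects)) {
    data[(s - 1) * n_tr + seq_len(n_tr), , ] <- all_data[[s]]
  }
  info <- dplyr::bind_rows(all_info)
  info$trial <- seq_len(nrow(info))
  epoch_set(data, times, info)
}

#' Inject single-channel artifact spikes into a fraction of trials
#'
#' Marks a random fraction of trials and adds a brief single-channel spike of
#' the given amplitude, to exercise peak-to-peak trial rejection. The selection
#' is recorded in the metadata column `spiked`.
#'
#' @param epochs An `epoch_set`.
#' @param rate Fraction of trials to spike, in \[0, 1\].
#' @param amplitude Spike amplitude in fT.
#' @param seed Integer seed for the trial/channel/time selection.
#' @return The modified `epoch_set` with `info$spiked` set.
#' @export
inject_artifacts <- function(epochs, rate, amplitude = 10000, seed = 1) {
  stopifnot(rate >= 0, rate <= 1)
  n <- dim(epochs$data)[1]
  set.seed(seed)
  n_spike <- round(rate * n)
  hit <- sort(sample.int(n, n_spike))
  epochs$info$spiked <- seq_len(n) %in% hit
  if (amplitude > 0 && n_spike > 0) {
    ch <- sample.int(dim(epochs$data)[2], n_spike, replace = TRUE)
    tp <- sample.int(dim(epochs$data)[3], n_spike, replace = TRUE)
    for (i in seq_along(hit)) {
      epochs$data[hit[i], ch[i], tp[i]] <-
        epochs$data[hit[i], ch[i], tp[i]] + amplitude
    }
  }
  epochs
}

#' Serialize an epoch set
#'
#' Writes the epoch array, time axis and trial metadata to a directory
#' (`data.rds`, `times.csv`, `info.csv`).
#'
#' @param epochs An `epoch_set`.
#' @param dir Target directory (created if needed).
#' @return `write_epochs()` returns `dir` invisibly; `read_epochs()` the set.
#' @export
write_epochs <- function(epochs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(epochs$data, file.path(dir, "data.rds"))
  readr::write_csv(tibble::tibble(time_ms = epochs$times), file.path(dir, "times.csv"))
  readr::write_csv(epochs$info, file.path(dir, "info.csv"))
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  epoch_set(readRDS(file.path(dir, "data.rds")),
            readr::read_csv(file.path(dir, "times.csv"), show_col_types = FALSE)$time_ms,
            readr::read_csv(file.path(dir, "info.csv"), show_col_types = FALSE))
}

#' Analysis scale profiles
#'
#' Bundled parameter sets: `full_profile()` mirrors a full experiment
#' (306 channels, 1 ms sampling, 60 trials/condition, 15 subjects, 100
#' sub-averaging repetitions, 1000 permutations/bootstraps); `desk_profile()`
#' is a reduced configuration (30 channels, 5 ms sampling, 20
#' trials/condition, 8 subjects, 5 repetitions with 20 ms decoding decimation,
#' 200 permutations/bootstraps) sized so that an end-to-end run completes in
#' minutes on one core.
#'
#' @return A named list of generator/analysis parameters.
#' @export
desk_profile <- function() {
  list(n_channels = 30, step_ms = 5, n_trials_per_condition = 20, n_subjects = 8,
       times = seq(-100, 900, by = 5),
       decoding = list(k = 5, n_repetitions = 5, time_step = 4),
       cross_k = 60, n_perm = 200, n_boot = 200)
}

#' @rdname desk_profile
#' @export
full_profile <- function() {
  list(n_channels = 306, step_ms = 1, n_trials_per_condition = 60, n_subjects = 15,
       times = seq(-100, 900, by = 1),
       decoding = list(k = 5, n_repetitions = 100, time_step = 1),
       cross_k = 60, n_perm = 1000, n_boot = 1000)
}
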