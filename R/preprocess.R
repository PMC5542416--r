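#' Reject trials by peak-to-peak amplitude
#'
#' A trial is kept iff the maximum over channels of its peak-to-peak amplitude
#' (max minus min over time, per channel) is below `p2p_threshold` — a single
#' bad channel rejects the whole trial. The default 8000 fT targets spike-like
#' signal deviations.
#'
#' @param epochs An `epoch_set`.
#' @param p2p_threshold Peak-to-peak rejection threshold in fT.
#' @return A list with `epochs` (kept trials only) and `report`, a
#'   `rejection_report` tibble with one row per input trial: its metadata,
#'   `p2p` and `kept`.
#' @export
reject_trials <- function(epochs, p2p_threshold = 8000) {
  stopifnot(p2p_threshold > 0)
  d <- dim(epochs$data)
  n <- d[1]
  # running per-trial/channel extrema over time (vectorized across trials)
  hi <- lo <- epochs$data[, , 1]
  for (t in seq_len(d[3])[-1]) {
    hi <- pmax(hi, epochs$data[, , t])
    lo <- pmin(lo, epochs$data[, , t])
  }
  rng <- matrix(hi - lo, nrow = n)
  p2p <- do.call(pmax, lapply(seq_len(d[2]), function(ch) rng[, ch]))
  kept <- p2p < p2p_threshold
  report <- dplyr::mutate(epochs$info, p2p = p2p, kept = kept)
  class(report) <- c("rejection_report", class(report))

  lost <- dplyr::summarise(
    dplyr::group_by(report, .data$subject_id, .data$condition_id),
    all_gone = !any(.data$kept), .groups = "drop")
  if (any(lost$all_gone)) {
    bad <- lost[lost$all_gone, ]
    rlang::abort(sprintf(
      "all trials rejected for condition(s) %s (subject %s)",
      paste(bad$condition_id, collapse = ", "),
      paste(unique(bad$subject_id), collapse = ", ")))
  }
  list(epochs = subset_trials(epochs, which(kept)), report = report)
}

#' Per-subject rejected-trial counts by factor level
#'
#' @param report A `rejection_report` from [reject_trials()].
#' @param design The design tibble.
#' @return Tibble: `subject_id`, `factor`, `level`, `n_rejected`.
#' @export
rejection_counts <- function(report, design) {
  joined <- dplyr::left_join(report, design, by = "condition_id")
  purrr::map_dfr(design_factors(), function(f) {
    dplyr::summarise(
      dplyr::group_by(joined, .data$subject_id, level = .data[[f]]),
      n_rejected = sum(!.data$kept), .groups = "drop") |>
      dplyr::mutate(factor = f, .before = 1)
  })
}

#' Test whether trial rejection is imbalanced across factor levels
#'
#' For each experimental factor, computes the per-subject difference in
#' rejected-trial counts between the two levels and tests its mean against
#' zero with a two-sided sign-permutation test (exhaustive when the number of
#' subjects permits, random sign flips otherwise).
#'
#' @param report A `rejection_report`.
#' @param design The design tibble.
#' @param n_perm Number of sign permutations.
#' @param seed Integer seed for random sign flips.
#' @return Tibble: `factor`, `mean_diff` (level 1 minus level 2, levels in
#'   sorted order), `p_value`.
#' @export
rejection_imbalance_test <- function(report, design, n_perm = 1000, seed = 1) {
  counts <- rejection_counts(report, design)
  if (dplyr::n_distinct(counts$subject_id) < 2) {
    rlang::abort("imbalance test needs at least 2 subjects")
  }
  purrr::map_dfr(design_factors(), function(f) {
    cf <- counts[counts$factor == f, ]
    wide <- tidyr::pivot_wider(cf, id_cols = "subject_id",
                               names_from = "level", values_from = "n_rejected")
    levs <- sort(setdiff(names(wide), "subject_id"))
    d <- wide[[levs[1]]] - wide[[levs[2]]]
    tibble::tibble(factor = f, mean_diff = mean(d),
                   p_value = sign_flip_pvalue(d, n_perm = n_perm, seed = seed))
  })
}

# two-sided sign-permutation p for the mean of a vector against 0;
# exhaustive over all 2^n flips when feasible, else n_perm random flips
sign_flip_pvalue <- function(d, n_perm = 1000, seed = 1) {
  n <- length(d)
  obs <- abs(mean(d))
  if (2^n <= n_perm) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    null <- abs(signs %*% d) / n
    mean(null >= obs - 1e-12)
  } else {
    set.seed(seed)
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    null <- abs(signs %*% d) / n
    (1 + sum(null >= obs - 1e-12)) / (1 + n_perm)
  }
}

#' Baseline-normalize each trial and channel
#'
#' Subtracts the baseline mean and divides by the baseline standard deviation,
#' per trial and channel. The baseline window is closed on the left and open
#' on the right (default \[-100, 0) ms).
#'
#' @param epochs An `epoch_set`.
#' @param window Length-2 numeric, baseline window in ms.
#' @return The normalized `epoch_set`.
#' @export
baseline_normalize <- function(epochs, window = c(-100, 0)) {
  idx <- which(epochs$times >= window[1] & epochs$times < window[2])
  if (length(idx) < 2) {
    rlang::abort("baseline window must contain at least 2 samples within the epoch")
  }
  base <- epochs$data[, , idx, drop = FALSE]
  d <- dim(base)
  bm <- matrix(base, d[1] * d[2], d[3]) # (trial, channel) rows x baseline samples
  mu0 <- rowMeans(bm)
  sd0 <- sqrt(rowSums((bm - mu0)^2) / (d[3] - 1))
  mu <- matrix(mu0, d[1], d[2])
  sdv <- matrix(sd0, d[1], d[2])
  if (any(sdv == 0)) {
    bad <- which(sdv == 0, arr.ind = TRUE)[1, ]
    rlang::abort(sprintf("zero baseline SD in trial %d, channel %d",
                         bad[1], bad[2]))
  }
  nt <- length(epochs$times)
  epochs$data <- (epochs$data - array(mu, c(dim(mu), nt))) /
    array(sdv, c(dim(sdv), nt))
  epochs
}

#' Smooth epoch time courses with a centered sliding window
#'
#' Boxcar moving average over time, per trial and channel, with truncated
#' windows at the epoch edges (no padding); the time grid is unchanged.
#'
#' @param epochs An `epoch_set`.
#' @param window_ms Window length in ms (20 ms by default); must cover at
#'   least one sampling step.
#' @return The smoothed `epoch_set`.
#' @export
smooth_timecourse <- function(epochs, window_ms = 20) {
  step <- diff(epochs$times)[1]
  if (window_ms < step) {
    rlang::abort("smoothing window is shorter than one sampling step")
  }
  half <- floor((window_ms / step) / 2)
  if (half == 0) return(epochs)
  nt <- length(epochs$times)
  # cumulative sums over time give every truncated-window mean in O(nt)
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = nt)
  cs <- rbind(0, apply(flat, 2, cumsum))
  lo <- pmax(seq_len(nt) - half, 1)
  hi <- pmin(seq_len(nt) + half, nt)
  sm <- (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
  epochs$data <- aperm(array(sm, c(nt, d[1], d[2])), c(2, 3, 1))
  epochs
}
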