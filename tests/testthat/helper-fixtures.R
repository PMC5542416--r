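# Small fixtures shared across tests. Everything is generated in code with
# fixed seeds; no data files.

# quick epoch set: `conds` conditions x `n_trials` trials of iid noise per
# subject, optional per-level "size" signal added over [onset, offset]
tiny_epochs <- function(design, n_subjects = 2, n_trials = 12, n_channels = 10,
                        times = seq(-100, 300, by = 20), seed = 1,
                        signal = signal_spec(), noise_sd = 100) {
  generate_epochs(design, signal,
                  noise_spec(n_channels = n_channels, sd = noise_sd),
                  n_trials_per_condition = n_trials, n_subjects = n_subjects,
                  times = times, master_seed = seed)
}

preprocess <- function(epochs, smoothing = 20) {
  smooth_timecourse(baseline_normalize(reject_trials(epochs)$epochs), smoothing)
}

# rdm_series built directly from an accuracy array
manual_rdms <- function(acc, times = seq_len(dim(acc)[2]),
                        conditions = seq_len(dim(acc)[3]),
                        subjects = seq_len(dim(acc)[1])) {
  megrsa:::new_rdm_series(acc, times, conditions, subjects)
}

# group_timecourse from a subjects x time matrix
manual_tc <- function(m, times = seq(0, by = 10, length.out = ncol(m)),
                      statistic = "test statistic", chance = 0) {
  megrsa:::matrix_to_tc(`rownames<-`(m, seq_len(nrow(m))), times, statistic,
                        chance)
}

# independent rank-then-Pearson Spearman (test oracle)
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# direct circular 2D convolution (test oracle for the FFT path)
conv2_direct <- function(img, kernel) {
  n <- nrow(img); m <- ncol(img)
  h1 <- (nrow(kernel) - 1) / 2; h2 <- (ncol(kernel) - 1) / 2
  out <- matrix(0 + 0i, n, m)
  for (u in seq_len(n)) {
    for (v in seq_len(m)) {
      s <- 0 + 0i
      for (a in -h1:h1) {
        for (b in -h2:h2) {
          s <- s + kernel[a + h1 + 1, b + h2 + 1] *
            img[((u - 1 - a) %% n) + 1, ((v - 1 - b) %% m) + 1]
        }
      }
      out[u, v] <- s
    }
  }
  out
}
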