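#' Decoding configuration
#'
#' @param k Sub-averaging group size (raw trials per pseudo-trial); 5 for
#'   single-image decoding, 60 for pooled cross-classification.
#' @param n_repetitions Number of random sub-averaging repetitions.
#' @param cost Soft-margin regularization parameter C of the linear SVM.
#' @param time_step Decimation factor over time points (1 = every sample);
#'   decimated analyses evaluate every `time_step`-th sample.
#' @param seed Integer seed for the random trial-to-group assignments.
#' @return A `decoding_config` list.
#' @export
decoding_config <- function(k = 5, n_repetitions = 100, cost = 1,
                            time_step = 1, seed = 1) {
  stopifnot(k >= 1, n_repetitions >= 1, cost > 0, time_step >= 1)
  structure(list(k = as.integer(k), n_repetitions = as.integer(n_repetitions),
                 cost = cost, time_step = as.integer(time_step),
                 seed = as.integer(seed)),
            class = "decoding_config")
}

#' Sub-average trials into pseudo-trials
#'
#' Randomly assigns the M rows of `x` to groups of `k` and averages each
#' group, yielding `floor(M/k)` pseudo-trials; leftover rows (`M %% k`) are
#' discarded for this assignment (a fresh assignment each repetition recycles
#' all trials in expectation).
#'
#' @param x Numeric matrix, trials x features.
#' @param k Group size.
#' @param seed Optional integer seed.
#' @return Matrix of pseudo-trials, `floor(nrow(x)/k)` x features.
#' @export
subaverage <- function(x, k, seed = NULL) {
  m <- nrow(x)
  if (m < k) rlang::abort("fewer trials than the sub-averaging group size")
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(m)
  p <- m %/% k
  out <- matrix(0, p, ncol(x))
  for (i in seq_len(p)) {
    out[i, ] <- colMeans(x[perm[((i - 1) * k + 1):(i * k)], , drop = FALSE])
  }
  out
}

# trials x repetitions matrix of fresh random assignments (1-based)
perm_matrix <- function(n, n_rep) {
  matrix(vapply(seq_len(n_rep), function(i) sample.int(n), integer(n)), n, n_rep)
}

# channels x trials x time cube for one condition (one subject's epochs)
condition_cube <- function(epochs, cond, t_idx) {
  rows <- which(epochs$info$condition_id == cond)
  aperm(epochs$data[rows, , t_idx, drop = FALSE], c(2, 1, 3))
}

new_rdm_series <- function(acc, times, conditions, subjects) {
  structure(list(acc = acc, times = times, conditions = conditions,
                 subjects = subjects),
            class = "rdm_series")
}

#' @export
print.rdm_series <- function(x, ...) {
  d <- dim(x$acc)
  cat(sprintf("<rdm_series> %d subject(s) x %d time point(s) x %d x %d conditions\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Time-resolved pairwise decoding into MEG RDMs
#'
#' For every subject, time point and pair of conditions, measures linear SVM
#' decoding accuracy with sub-averaging into pseudo-trials (groups of
#' `config$k`), leave-one-pseudotrial-out-per-class cross-validation, and
#' `config$n_repetitions` random re-assignments. Accuracies (% correct, 50%
#' chance) are stored symmetrically in a condition x condition decoding matrix
#' per time point — the MEG representational dissimilarity matrix (RDM). The
#' diagonal is undefined (`NA`).
#'
#' @param epochs A preprocessed `epoch_set` (all subjects).
#' @param config A [decoding_config()].
#' @return An `rdm_series`: accuracy array subject x time x condition x
#'   condition, the (decimated) time axis, condition ids and subject ids.
#' @export
pairwise_decoding_timecourse <- function(epochs, config = decoding_config()) {
  conds <- sort(unique(epochs$info$condition_id))
  n_cond <- length(conds)
  t_idx <- seq(1, length(epochs$times), by = config$time_step)
  per_subj <- split_subjects(epochs)
  subjects <- as.integer(names(per_subj))
  min_n <- min(table(epochs$info$condition_id))
  if (min_n < 2 * config$k) {
    rlang::abort("every condition needs at least 2k trials for leave-one-out decoding")
  }

  acc <- array(NA_real_, c(length(per_subj), length(t_idx), n_cond, n_cond))
  set.seed(config$seed)
  for (s in seq_along(per_subj)) {
    es <- per_subj[[s]]
    cubes <- lapply(conds, function(cc) condition_cube(es, cc, t_idx))
    for (i in seq_len(n_cond - 1)) {
      for (j in (i + 1):n_cond) {
        a <- cpp_pair_loo(cubes[[i]], cubes[[j]], config$k, config$cost,
                          perm_matrix(dim(cubes[[i]])[2], config$n_repetitions),
                          perm_matrix(dim(cubes[[j]])[2], config$n_repetitions))
        acc[s, , i, j] <- a
        acc[s, , j, i] <- a
      }
    }
  }
  new_rdm_series(acc, epochs$times[t_idx], conds, subjects)
}

#' Group time course container
#'
#' A tibble (`subject`, `time_ms`, `value`) carrying one statistic per subject
#' and time point, with the statistic label and its chance/null reference
#' value as attributes. This is the substrate of all group inference.
#'
#' @param df Tibble with columns `subject`, `time_ms`, `value`.
#' @param statistic Label of the statistic (e.g. "decoding accuracy (%)").
#' @param chance Null reference value (50 for accuracies, 0 for differences
#'   and correlations).
#' @return A `group_timecourse` tibble.
#' @export
group_timecourse <- function(df, statistic, chance) {
  stopifnot(all(c("subject", "time_ms", "value") %in% names(df)))
  structure(tibble::as_tibble(df),
            class = c("group_timecourse", class(tibble::tibble())),
            statistic = statistic, chance = chance)
}

# subjects x time matrix from a group_timecourse
tc_matrix <- function(tc) {
  wide <- tidyr::pivot_wider(dplyr::arrange(tibble::as_tibble(tc),
                                            .data$subject, .data$time_ms),
                             id_cols = "subject", names_from = "time_ms",
                             values_from = "value")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$subject
  m
}

tc_times <- function(tc) sort(unique(tc$time_ms))

matrix_to_tc <- function(m, times, statistic, chance) {
  df <- tibble::tibble(
    subject = rep(as.integer(rownames(m)), each = ncol(m)),
    time_ms = rep(times, times = nrow(m)),
    value = as.vector(t(m)))
  group_timecourse(df, statistic, chance)
}

#' Average matched-exemplar RDM cells into a single-image decoding time course
#'
#' Averages, per subject and time point, the RDM cells whose two conditions
#' agree on all four factor levels and differ only in exemplar — controlling
#' for size, clutter, contrast and luminance differences. The result measures
#' discriminability of individual scene images.
#'
#' @param rdms An `rdm_series`.
#' @param design The design tibble.
#' @return A `group_timecourse` (% decoding accuracy, 50% chance).
#' @export
factor_average_decoding <- function(rdms, design) {
  d <- design[match(rdms$conditions, design$condition_id), ]
  combo <- paste(d$size, d$clutter, d$contrast, d$luminance)
  n_cond <- length(rdms$conditions)
  pairs <- which(outer(combo, combo, "==") & lower.tri(diag(n_cond)), arr.ind = TRUE)
  if (nrow(pairs) == 0) rlang::abort("no matched-factor condition pairs in design")
  ns <- dim(rdms$acc)[1]; nt <- dim(rdms$acc)[2]
  m <- matrix(0, ns, nt, dimnames = list(rdms$subjects, NULL))
  for (p in seq_len(nrow(pairs))) {
    m <- m + matrix(rdms$acc[, , pairs[p, 1], pairs[p, 2]], ns, nt)
  }
  matrix_to_tc(m / nrow(pairs), rdms$times,
               "single-image decoding accuracy (%)", 50)
}

pooled_cube <- function(epochs, design, rows_filter, t_idx) {
  rows <- which(rows_filter)
  aperm(epochs$data[rows, , t_idx, drop = FALSE], c(2, 1, 3))
}

# train on set 1, test on set 2, then with reversed assignment; averaged.
# each set is list(cube class A, cube class B)
bidirectional_cross <- function(set1, set2, config) {
  pm <- function(cube) perm_matrix(dim(cube)[2], config$n_repetitions)
  a1 <- cpp_train_test(set1[[1]], set1[[2]], set2[[1]], set2[[2]],
                       config$k, config$cost,
                       pm(set1[[1]]), pm(set1[[2]]), pm(set2[[1]]), pm(set2[[2]]))
  a2 <- cpp_train_test(set2[[1]], set2[[2]], set1[[1]], set1[[2]],
                       config$k, config$cost,
                       pm(set2[[1]]), pm(set2[[2]]), pm(set1[[1]]), pm(set1[[2]]))
  (a1 + a2) / 2
}

#' Cross-classification of one factor across another
#'
#' Trains the classifier on trials from one level of `generalization_factor`
#' and tests it on the other level (and vice versa; the two directions are
#' averaged), classifying `target_factor`. Raw trials are pooled across all
#' images sharing the same target and generalization levels and sub-averaged
#' in groups of `config$k` (default 60). Above-chance accuracy indicates
#' target representations tolerant to the generalization factor.
#'
#' @param epochs A preprocessed `epoch_set`.
#' @param design The design tibble.
#' @param target_factor,generalization_factor Two distinct design factors.
#' @param config A [decoding_config()]; `k` defaults to 60 here.
#' @return A `group_timecourse` (% decoding accuracy, 50% chance).
#' @export
cross_decoding_timecourse <- function(epochs, design, target_factor,
                                      generalization_factor,
                                      config = decoding_config(k = 60)) {
  check_factor(design, target_factor)
  check_factor(design, generalization_factor)
  if (target_factor == generalization_factor) {
    rlang::abort("target and generalization factors must differ")
  }
  tlev <- sort(unique(design[[target_factor]]))
  glev <- sort(unique(design[[generalization_factor]]))
  t_idx <- seq(1, length(epochs$times), by = config$time_step)
  per_subj <- split_subjects(epochs)

  set.seed(config$seed)
  m <- matrix(0, length(per_subj), length(t_idx),
              dimnames = list(names(per_subj), NULL))
  for (s in seq_along(per_subj)) {
    es <- per_subj[[s]]
    dd <- design[match(es$info$condition_id, design$condition_id), ]
    cube <- function(tl, gl) {
      sel <- dd[[target_factor]] == tl & dd[[generalization_factor]] == gl
      if (!any(sel)) rlang::abort("empty target x generalization cell")
      pooled_cube(es, design, sel, t_idx)
    }
    m[s, ] <- bidirectional_cross(
      list(cube(tlev[1], glev[1]), cube(tlev[2], glev[1])),
      list(cube(tlev[1], glev[2]), cube(tlev[2], glev[2])), config)
  }
  matrix_to_tc(m, epochs$times[t_idx],
               sprintf("%s decoding across %s (%%)", target_factor,
                       generalization_factor), 50)
}

#' Cross-classification of a factor across scene image identity
#'
#' Trains on two of the three exemplars of every factor-level combination and
#' tests on the held-out exemplar (and with reversed assignment; directions
#' averaged). Above-chance accuracy indicates factor representations that
#' generalize across individual images.
#'
#' @param epochs A preprocessed `epoch_set`.
#' @param design The design tibble; must have exactly 3 exemplars.
#' @param target_factor The classified design factor.
#' @param config A [decoding_config()]; `k` defaults to 60.
#' @param holdout Which exemplar index forms the test set (default 3).
#' @return A `group_timecourse` (% decoding accuracy, 50% chance).
#' @export
identity_cross_decoding <- function(epochs, design, target_factor,
                                    config = decoding_config(k = 60),
                                    holdout = 3) {
  check_factor(design, target_factor)
  if (max(design$exemplar) != 3) {
    rlang::abort("identity cross-decoding requires exactly 3 exemplars per combination")
  }
  tlev <- sort(unique(design[[target_factor]]))
  t_idx <- seq(1, length(epochs$times), by = config$time_step)
  per_subj <- split_subjects(epochs)

  set.seed(config$seed)
  m <- matrix(0, length(per_subj), length(t_idx),
              dimnames = list(names(per_subj), NULL))
  for (s in seq_along(per_subj)) {
    es <- per_subj[[s]]
    dd <- design[match(es$info$condition_id, design$condition_id), ]
    cube <- function(tl, exemplars) {
      sel <- dd[[target_factor]] == tl & dd$exemplar %in% exemplars
      pooled_cube(es, design, sel, t_idx)
    }
    train_ex <- setdiff(1:3, holdout)
    m[s, ] <- bidirectional_cross(
      list(cube(tlev[1], train_ex), cube(tlev[2], train_ex)),
      list(cube(tlev[1], holdout), cube(tlev[2], holdout)), config)
  }
  matrix_to_tc(m, epochs$times[t_idx],
               sprintf("%s decoding across image identity (%%)", target_factor), 50)
}
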