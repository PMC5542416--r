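#' Sign-permutation cluster-size test on a group time course
#'
#' One-sample nonparametric test of a per-subject time course against its
#' null reference. Whole participant-specific time courses are randomly
#' multiplied by +1 or -1 (after centering at `null_value`); the permutation
#' distribution of the group mean yields two-sided empirical p-values per
#' time point, candidate clusters are maximal runs of `p < cluster_alpha`
#' with consistent sign, and multiple comparisons over time are controlled by
#' the permutation distribution of the maximal cluster size (cluster size =
#' number of time points). A cluster is significant when its size-based
#' p-value (plus-one convention) is at most `corrected_alpha`.
#'
#' @param tc A `group_timecourse`.
#' @param null_value Null reference; defaults to the time course's `chance`
#'   attribute (50 for accuracies, 0 for differences/correlations).
#' @param n_perm Number of sign permutations (exhaustive enumeration of all
#'   2^N sign patterns is used instead when it needs fewer draws).
#' @param cluster_alpha Two-sided cluster-definition threshold.
#' @param corrected_alpha Corrected significance level for cluster size.
#' @param seed Integer seed for the random sign flips.
#' @return A `cluster_result`: `clusters` tibble (`start_ms`, `end_ms`,
#'   `size`, `sign`, `p_value`, `significant`), per-timepoint p-values,
#'   the null maximal-cluster-size distribution, and the test parameters.
#' @export
sign_permutation_cluster_test <- function(tc, null_value = NULL, n_perm = 1000,
                                          cluster_alpha = 0.05,
                                          corrected_alpha = 0.05, seed = 1) {
  x <- tc_matrix(tc)
  if (nrow(x) < 2) rlang::abort("cluster test needs at least 2 subjects")
  if (is.null(null_value)) null_value <- attr(tc, "chance") %||% 0
  set.seed(seed)
  res <- cluster_test_core(x - null_value, n_perm, cluster_alpha,
                           corrected_alpha)
  times <- tc_times(tc)
  cl <- res$clusters
  clusters <- tibble::tibble(
    start_ms = times[cl$start], end_ms = times[cl$end],
    size = cl$size, sign = cl$sign, p_value = cl$p_value,
    significant = cl$significant)
  structure(list(clusters = clusters,
                 p_timepoint = tibble::tibble(time_ms = times, p = res$p_obs),
                 null_max_size = res$null_max,
                 group_mean = tibble::tibble(time_ms = times,
                                             value = res$gmean + null_value),
                 params = list(null_value = null_value, n_perm = res$n_perm,
                               exhaustive = res$exhaustive,
                               cluster_alpha = cluster_alpha,
                               corrected_alpha = corrected_alpha, seed = seed),
                 statistic = attr(tc, "statistic")),
            class = "cluster_result")
}

# x: subjects x time, already centered at the null. Uses the current RNG
# stream; set.seed() upstream governs reproducibility.
cluster_test_core <- function(x, n_perm, cluster_alpha, corrected_alpha) {
  ns <- nrow(x); nt <- ncol(x)
  exhaustive <- 2^ns <= n_perm
  if (exhaustive) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), ns)))
  } else {
    signs <- matrix(sample(c(-1, 1), n_perm * ns, replace = TRUE), n_perm, ns)
  }
  n_eff <- nrow(signs)
  if (1 / n_eff >= cluster_alpha) {
    rlang::abort("n_perm too small for the requested cluster-definition threshold")
  }
  gmean <- colMeans(x)
  perm <- (signs %*% x) / ns # n_eff x nt permutation group means

  # two-sided empirical p per time point, for the observed data and for every
  # permutation sample (each compared against the full permutation set)
  ap <- abs(perm)
  p_obs <- numeric(nt)
  p_perm <- matrix(0, n_eff, nt)
  for (t in seq_len(nt)) {
    p_obs[t] <- (1 + sum(ap[, t] >= abs(gmean[t]) - 1e-12)) / (1 + n_eff)
    r <- rank(ap[, t], ties.method = "min")
    p_perm[, t] <- (n_eff - r + 1) / n_eff
  }

  null_max <- vapply(seq_len(n_eff), function(m) {
    max_run_length(p_perm[m, ] < cluster_alpha)
  }, numeric(1))

  cl <- find_clusters(p_obs < cluster_alpha, sign(gmean))
  if (nrow(cl) > 0) {
    cl$p_value <- vapply(cl$size, function(sz) {
      (1 + sum(null_max >= sz)) / (1 + n_eff)
    }, numeric(1))
    cl$significant <- cl$p_value <= corrected_alpha
  } else {
    cl$p_value <- numeric(0)
    cl$significant <- logical(0)
  }
  list(clusters = cl, p_obs = p_obs, null_max = null_max, gmean = gmean,
       n_perm = n_eff, exhaustive = exhaustive)
}

max_run_length <- function(flags) {
  if (!any(flags)) return(0)
  r <- rle(flags)
  max(r$lengths[r$values])
}

# maximal runs of suprathreshold time points, split where the sign changes
find_clusters <- function(flags, signs) {
  out <- tibble::tibble(start = integer(), end = integer(), size = integer(),
                        sign = character())
  if (!any(flags)) return(out)
  grp <- cumsum(c(TRUE, diff(flags) != 0 | diff(signs) != 0))
  for (g in unique(grp[flags])) {
    idx <- which(grp == g & flags)
    if (length(idx) == 0) next
    out <- dplyr::bind_rows(out, tibble::tibble(
      start = min(idx), end = max(idx), size = length(idx),
      sign = if (signs[min(idx)] >= 0) "pos" else "neg"))
  }
  dplyr::arrange(out, .data$start)
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %s\n", x$statistic %||% ""))
  cat(sprintf("  null = %g, %d permutations%s\n", x$params$null_value,
              x$params$n_perm,
              if (x$params$exhaustive) " (exhaustive)" else ""))
  if (nrow(x$clusters) == 0) {
    cat("  no candidate clusters\n")
  } else {
    print(x$clusters)
  }
  invisible(x)
}

#' Bootstrap confidence intervals for cluster onset and peak latency
#'
#' Resamples subjects with replacement; for each bootstrap sample the cluster
#' test is rerun, the onset is the first time point of the earliest
#' significant cluster, and the peak is the argmax of the bootstrap-sample
#' mean over `peak_window`. 95% CIs are the 2.5/97.5 percentiles; bootstrap
#' samples without any significant cluster are excluded from the onset
#' distribution and counted.
#'
#' @param tc A `group_timecourse`.
#' @param n_boot Number of bootstrap resamples of the subject sample.
#' @param seed Integer seed.
#' @param peak_window Time window (ms) in which the peak is sought; defaults
#'   to the post-stimulus window (times >= 0).
#' @param level Confidence level.
#' @inheritParams sign_permutation_cluster_test
#' @return A `latency_estimate` with `onset`/`peak` point estimates (from the
#'   observed sample), their CIs, the bootstrap distributions and the number
#'   of clusterless samples.
#' @export
bootstrap_latency_ci <- function(tc, null_value = NULL, n_boot = 1000,
                                 n_perm = 1000, cluster_alpha = 0.05,
                                 corrected_alpha = 0.05, seed = 1,
                                 peak_window = NULL, level = 0.95) {
  x <- tc_matrix(tc)
  if (nrow(x) < 2) rlang::abort("bootstrap needs at least 2 subjects")
  if (is.null(null_value)) null_value <- attr(tc, "chance") %||% 0
  times <- tc_times(tc)
  if (is.null(peak_window)) peak_window <- c(0, max(times))
  pw <- which(times >= peak_window[1] & times <= peak_window[2])
  xc <- x - null_value

  set.seed(seed)
  obs <- cluster_test_core(xc, n_perm, cluster_alpha, corrected_alpha)
  sig <- obs$clusters[obs$clusters$significant, ]
  onset_pt <- if (nrow(sig)) times[min(sig$start)] else NA_real_
  peak_pt <- times[pw[which.max(colMeans(xc)[pw])]]

  onset_b <- peak_b <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(xc), replace = TRUE)
    rb <- cluster_test_core(xc[idx, , drop = FALSE], n_perm, cluster_alpha,
                            corrected_alpha)
    sb <- rb$clusters[rb$clusters$significant, ]
    if (nrow(sb)) onset_b[b] <- times[min(sb$start)]
    peak_b[b] <- times[pw[which.max(rb$gmean[pw])]]
  }
  a <- (1 - level) / 2
  onset_ci <- if (all(is.na(onset_b))) c(NA_real_, NA_real_) else
    unname(stats::quantile(onset_b, c(a, 1 - a), na.rm = TRUE))
  structure(list(onset = onset_pt, onset_ci = onset_ci,
                 peak = peak_pt,
                 peak_ci = unname(stats::quantile(peak_b, c(a, 1 - a))),
                 boot = tibble::tibble(onset_ms = onset_b, peak_ms = peak_b),
                 n_no_cluster = sum(is.na(onset_b)), n_boot = n_boot,
                 level = level, statistic = attr(tc, "statistic")),
            class = "latency_estimate")
}

#' @export
print.latency_estimate <- function(x, ...) {
  cat(sprintf("<latency_estimate> %s\n", x$statistic %||% ""))
  if (!is.null(x$onset)) {
    cat(sprintf("  onset %s ms (CI %s-%s), peak %s ms (CI %s-%s)\n",
                format(x$onset), format(x$onset_ci[1]), format(x$onset_ci[2]),
                format(x$peak), format(x$peak_ci[1]), format(x$peak_ci[2])))
    if (x$n_no_cluster > 0) {
      cat(sprintf("  %d/%d bootstrap samples without significant cluster\n",
                  x$n_no_cluster, x$n_boot))
    }
  }
  if (!is.null(x$difference)) {
    cat(sprintf("  peak latency difference %s ms (CI %s-%s), %ssignificant\n",
                format(x$difference), format(x$difference_ci[1]),
                format(x$difference_ci[2]),
                if (x$significant) "" else "not "))
  }
  invisible(x)
}

#' Bootstrap test of the peak-to-peak latency difference of two time courses
#'
#' For each bootstrap resample of the (shared) subject sample, computes the
#' difference of the two peak latencies (A minus B). The null hypothesis of
#' no latency difference is rejected when the CI excludes 0.
#'
#' @param tc_a,tc_b Two `group_timecourse`s over the same subjects and times.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param peak_window Window (ms) in which peaks are sought (default >= 0 ms).
#' @param level Confidence level.
#' @return A `latency_estimate` with `difference`, `difference_ci`,
#'   `significant` and the bootstrap distribution.
#' @export
peak_to_peak_difference_test <- function(tc_a, tc_b, n_boot = 1000, seed = 1,
                                         peak_window = NULL, level = 0.95) {
  xa <- tc_matrix(tc_a); xb <- tc_matrix(tc_b)
  ta <- tc_times(tc_a); tb <- tc_times(tc_b)
  if (!identical(dim(xa), dim(xb)) || !isTRUE(all.equal(ta, tb))) {
    rlang::abort("the two time courses must share subjects and time axis")
  }
  if (is.null(peak_window)) peak_window <- c(0, max(ta))
  pw <- which(ta >= peak_window[1] & ta <= peak_window[2])
  peak_of <- function(m) ta[pw[which.max(colMeans(m)[pw])]]
  set.seed(seed)
  diff_b <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(nrow(xa), replace = TRUE)
    peak_of(xa[idx, , drop = FALSE]) - peak_of(xb[idx, , drop = FALSE])
  }, numeric(1))
  a <- (1 - level) / 2
  ci <- unname(stats::quantile(diff_b, c(a, 1 - a)))
  structure(list(difference = peak_of(xa) - peak_of(xb), difference_ci = ci,
                 significant = ci[1] > 0 || ci[2] < 0,
                 boot = tibble::tibble(difference_ms = diff_b),
                 n_boot = n_boot, level = level,
                 statistic = paste(attr(tc_a, "statistic"), "vs",
                                   attr(tc_b, "statistic"))),
            class = "latency_estimate")
}

#' Condition-label permutation test for model RDM correspondence
#'
#' Tests the Spearman correlation between two model RDMs (lower triangles)
#' against a null built by simultaneously permuting the rows and columns of
#' the first RDM `n_perm` times (two-sided, plus-one convention).
#'
#' @param model,target `model_rdm`s on the same condition set.
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @return Tibble with `rho` (observed Spearman R) and `p_value`.
#' @export
label_permutation_test <- function(model, target, n_perm = 1000, seed = 1) {
  m <- unclass(model); tg <- unclass(target)
  if (!all(dim(m) == dim(tg))) rlang::abort("RDMs must match in size")
  tv <- rdm_lower(tg)
  if (stats::sd(rdm_lower(m)) == 0 || stats::sd(tv) == 0) {
    rlang::abort("constant RDM: correlation undefined")
  }
  obs <- stats::cor(rdm_lower(m), tv, method = "spearman")
  set.seed(seed)
  n <- nrow(m)
  null <- vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    stats::cor(rdm_lower(m[p, p]), tv, method = "spearman")
  }, numeric(1))
  tibble::tibble(rho = obs,
                 p_value = (1 + sum(abs(null) >= abs(obs) - 1e-12)) / (1 + n_perm))
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up false-discovery-rate control at level `q`.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param q FDR level.
#' @return Tibble with `p`, `p_adjusted` (monotone BH-adjusted values) and
#'   `significant`.
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  if (length(p_values) == 0) rlang::abort("empty p-value list")
  if (any(p_values < 0 | p_values > 1)) rlang::abort("p-values must be in [0, 1]")
  adj <- stats::p.adjust(p_values, method = "BH")
  tibble::tibble(p = p_values, p_adjusted = adj, significant = adj <= q)
}
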