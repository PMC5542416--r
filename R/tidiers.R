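#' Tidy a cluster test result
#'
#' @param x A `cluster_result`.
#' @param ... Ignored.
#' @return The clusters tibble (`start_ms`, `end_ms`, `size`, `sign`,
#'   `p_value`, `significant`).
#' @export
tidy.cluster_result <- function(x, ...) x$clusters

#' @rdname tidy.cluster_result
#' @return For `glance()`: a one-row summary (number of clusters, earliest
#'   significant onset, permutation count).
#' @export
glance.cluster_result <- function(x, ...) {
  sig <- x$clusters[x$clusters$significant, ]
  tibble::tibble(
    n_clusters = nrow(x$clusters), n_significant = nrow(sig),
    onset_ms = if (nrow(sig)) min(sig$start_ms) else NA_real_,
    n_perm = x$params$n_perm, exhaustive = x$params$exhaustive,
    cluster_alpha = x$params$cluster_alpha,
    corrected_alpha = x$params$corrected_alpha)
}

#' Tidy a latency estimate
#'
#' @param x A `latency_estimate`.
#' @param ... Ignored.
#' @return The bootstrap distribution tibble.
#' @export
tidy.latency_estimate <- function(x, ...) x$boot

#' @rdname tidy.latency_estimate
#' @return For `glance()`: point estimates and CI bounds in one row.
#' @export
glance.latency_estimate <- function(x, ...) {
  if (!is.null(x$difference)) {
    return(tibble::tibble(difference_ms = x$difference,
                          ci_lo = x$difference_ci[1], ci_hi = x$difference_ci[2],
                          significant = x$significant, n_boot = x$n_boot))
  }
  tibble::tibble(onset_ms = x$onset, onset_lo = x$onset_ci[1],
                 onset_hi = x$onset_ci[2], peak_ms = x$peak,
                 peak_lo = x$peak_ci[1], peak_hi = x$peak_ci[2],
                 n_no_cluster = x$n_no_cluster, n_boot = x$n_boot)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
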