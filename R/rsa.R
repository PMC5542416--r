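#' Model RDM container
#'
#' A condition x condition dissimilarity matrix from a computational model
#' layer or an explicit factor model, with condition ids as dimnames and a
#' source label.
#'
#' @param m Symmetric numeric matrix with zero (or `NA`) diagonal.
#' @param conditions Condition ids (defaults to existing dimnames or 1..n).
#' @param source Label (e.g. `"gist"`, `"size"`, `"hmax/C2"`).
#' @param semantics `"correlation"` (1 - Spearman, in \[0, 2\]) or `"binary"`.
#' @return A `model_rdm` matrix.
#' @export
model_rdm <- function(m, conditions = NULL, source = "model",
                      semantics = c("correlation", "binary")) {
  semantics <- match.arg(semantics)
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || max(abs(m - t(m)), na.rm = TRUE) > 1e-9) {
    rlang::abort("model RDM must be a symmetric square matrix")
  }
  if (semantics == "binary") {
    off <- m[lower.tri(m)]
    if (!all(off %in% c(0, 1))) rlang::abort("binary model RDM may contain only 0/1")
  }
  if (is.null(conditions)) conditions <- rownames(m) %||% seq_len(nrow(m))
  dimnames(m) <- list(conditions, conditions)
  structure(m, class = c("model_rdm", "matrix", "array"),
            source = source, semantics = semantics)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Lower-triangle vectorization of an RDM (diagonal excluded)
#' @param m A square matrix.
#' @return Numeric vector of the strictly-lower-triangular entries.
#' @export
rdm_lower <- function(m) m[lower.tri(m)]

#' Explicit binary factor model RDM
#'
#' Entries are 1 where the two conditions differ in the level of `factor` and
#' 0 otherwise — the explicit model of that factor's representation.
#'
#' @param design The design tibble.
#' @param factor One of the four design factors.
#' @return A binary `model_rdm`.
#' @export
factor_model_rdm <- function(design, factor) {
  check_factor(design, factor)
  lev <- design[[factor]]
  m <- outer(lev, lev, function(a, b) as.numeric(a != b))
  diag(m) <- 0
  model_rdm(m, conditions = design$condition_id, source = factor,
            semantics = "binary")
}

#' Feature set container
#'
#' @param x Numeric matrix, one row per condition (rownames = condition ids).
#' @param layer Layer label.
#' @return A `feature_set` matrix.
#' @export
feature_set <- function(x, layer = "features") {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- seq_len(nrow(x))
  structure(x, class = c("feature_set", "matrix", "array"), layer = layer)
}

#' Model RDM from per-condition feature vectors
#'
#' Pairwise dissimilarity 1 - Spearman rank correlation between the feature
#' vectors of every pair of conditions (average ranks on ties).
#'
#' @param features A [feature_set()] (conditions x feature dimensions).
#' @return A `model_rdm` with values in \[0, 2\] and zero diagonal.
#' @export
feature_rdm <- function(features) {
  if (nrow(features) < 2 || ncol(features) < 2) {
    rlang::abort("need at least 2 conditions and 2 feature dimensions")
  }
  sds <- apply(features, 1, stats::sd)
  if (any(sds == 0)) {
    rlang::abort(sprintf("constant feature vector for condition(s) %s",
                         paste(rownames(features)[sds == 0], collapse = ", ")))
  }
  rho <- stats::cor(t(features), method = "spearman")
  m <- 1 - rho
  diag(m) <- 0
  model_rdm(m, conditions = rownames(features),
            source = attr(features, "layer"), semantics = "correlation")
}

check_rdm_match <- function(rdms, model) {
  if (length(rdms$conditions) != nrow(model) ||
      !all(as.character(rdms$conditions) == rownames(model))) {
    rlang::abort("model RDM conditions do not match the MEG RDM series")
  }
}

#' Representational clustering time course (between minus within)
#'
#' Per subject and time point, the mean of RDM cells whose conditions differ
#' in the level of `factor` minus the mean of cells whose conditions share a
#' level (diagonal excluded). Positive values (% decoding accuracy
#' difference) indicate clustering of representations by the factor, i.e.
#' linearly readable factor information.
#'
#' @param rdms An `rdm_series`.
#' @param design The design tibble.
#' @param factor One of the four design factors.
#' @return A `group_timecourse` (% accuracy difference, null reference 0).
#' @export
clustering_timecourse <- function(rdms, design, factor) {
  check_factor(design, factor)
  lev <- design[[factor]][match(rdms$conditions, design$condition_id)]
  between <- outer(lev, lev, "!=") & lower.tri(diag(length(lev)))
  within <- outer(lev, lev, "==") & lower.tri(diag(length(lev)))
  ns <- dim(rdms$acc)[1]; nt <- dim(rdms$acc)[2]
  m <- matrix(0, ns, nt, dimnames = list(rdms$subjects, NULL))
  for (s in seq_len(ns)) {
    for (t in seq_len(nt)) {
      rdm <- rdms$acc[s, t, , ]
      m[s, t] <- mean(rdm[between]) - mean(rdm[within])
    }
  }
  matrix_to_tc(m, rdms$times,
               sprintf("%s clustering (%% accuracy difference)", factor), 0)
}

#' RSA time course: model RDM vs time-resolved MEG RDMs
#'
#' Per subject and time point, the Spearman correlation between the lower
#' triangles (diagonal excluded) of the MEG decoding RDM and the model RDM.
#' For a multi-layer model (a list of `model_rdm`s) the per-layer correlations
#' are computed and averaged across layers.
#'
#' @param rdms An `rdm_series`.
#' @param model A `model_rdm` or a list of them (layers).
#' @return A `group_timecourse` (Spearman R, null reference 0).
#' @export
rsa_timecourse <- function(rdms, model) {
  layers <- if (inherits(model, "model_rdm")) list(model) else model
  vecs <- lapply(layers, function(l) {
    check_rdm_match(rdms, l)
    v <- rdm_lower(unclass(l))
    if (stats::sd(v) == 0) {
      rlang::abort(sprintf("constant model RDM (%s): correlation undefined",
                           attr(l, "source") %||% "?"))
    }
    v
  })
  ns <- dim(rdms$acc)[1]; nt <- dim(rdms$acc)[2]
  m <- matrix(0, ns, nt, dimnames = list(rdms$subjects, NULL))
  for (s in seq_len(ns)) {
    for (t in seq_len(nt)) {
      meg <- rdm_lower(rdms$acc[s, t, , ])
      m[s, t] <- mean(vapply(vecs, function(v) {
        stats::cor(meg, v, method = "spearman")
      }, numeric(1)))
    }
  }
  src <- paste(unique(vapply(layers, function(l) attr(l, "source") %||% "model",
                             character(1))), collapse = "+")
  matrix_to_tc(m, rdms$times, sprintf("RSA: MEG ~ %s (Spearman R)", src), 0)
}

#' Partial Spearman correlation
#'
#' Rank-transforms all inputs (average ranks on ties), residualizes the ranks
#' of `x` and `y` on the ranks of the nuisance vectors by least squares, and
#' returns the Pearson correlation of the residuals. With no nuisance this
#' equals the plain Spearman correlation. Collinear nuisance columns are
#' dropped (with a message).
#'
#' @param x,y Numeric vectors.
#' @param nuisance A list of numeric vectors, a matrix (columns = nuisance
#'   variables), or `NULL`.
#' @return The partial rank correlation (scalar).
#' @export
partial_spearman <- function(x, y, nuisance = NULL) {
  if (is.list(nuisance)) nuisance <- do.call(cbind, nuisance)
  if (is.null(nuisance) || ncol(as.matrix(nuisance)) == 0) {
    return(stats::cor(x, y, method = "spearman"))
  }
  nuisance <- as.matrix(nuisance)
  n <- length(x)
  if (length(y) != n || nrow(nuisance) != n) {
    rlang::abort("all vectors must have the same length")
  }
  if (n <= ncol(nuisance) + 2) {
    rlang::abort("too few observations for the number of nuisance variables")
  }
  rx <- rank(x); ry <- rank(y)
  rz <- apply(nuisance, 2, rank)
  Z <- cbind(1, rz)
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z)) {
    keep <- qrz$pivot[seq_len(qrz$rank)]
    message("dropping ", ncol(Z) - qrz$rank, " collinear nuisance column(s)")
    qrz <- qr(Z[, keep, drop = FALSE])
  }
  ex <- rx - qr.fitted(qrz, rx)
  ey <- ry - qr.fitted(qrz, ry)
  # residuals that are numerically zero carry no correlation
  if (stats::sd(ex) < 1e-8 || stats::sd(ey) < 1e-8) return(0)
  stats::cor(ex, ey)
}

#' Partial-correlation RSA time course
#'
#' Per subject and time point, the partial Spearman correlation between the
#' MEG RDM and the target model RDM after partialling out the nuisance model
#' RDMs (e.g. all layer-specific RDMs of a computational model). A drop of
#' the target effect after partialling indicates that the nuisance model
#' carries the same representational structure.
#'
#' @param rdms An `rdm_series`.
#' @param target A `model_rdm` (e.g. the explicit size model).
#' @param nuisance_models List of `model_rdm`s to partial out.
#' @return A `group_timecourse` (partial Spearman R, null reference 0).
#' @export
partial_rsa_timecourse <- function(rdms, target, nuisance_models = list()) {
  check_rdm_match(rdms, target)
  tv <- rdm_lower(unclass(target))
  nv <- lapply(nuisance_models, function(l) {
    check_rdm_match(rdms, l)
    rdm_lower(unclass(l))
  })
  nz <- if (length(nv)) do.call(cbind, nv) else NULL
  ns <- dim(rdms$acc)[1]; nt <- dim(rdms$acc)[2]
  m <- matrix(0, ns, nt, dimnames = list(rdms$subjects, NULL))
  for (s in seq_len(ns)) {
    for (t in seq_len(nt)) {
      m[s, t] <- partial_spearman(rdm_lower(rdms$acc[s, t, , ]), tv, nz)
    }
  }
  matrix_to_tc(m, rdms$times,
               sprintf("partial RSA: MEG ~ %s | %d nuisance RDM(s)",
                       attr(target, "source") %||% "target", length(nv)), 0)
}

#' Round-trip a model RDM as CSV
#'
#' @param rdm A `model_rdm`.
#' @param path CSV path; condition ids form the header.
#' @return `write_model_rdm()` returns `path` invisibly; `read_model_rdm()`
#'   the `model_rdm`.
#' @export
write_model_rdm <- function(rdm, path) {
  df <- tibble::as_tibble(as.data.frame(unclass(rdm)), .name_repair = "minimal")
  names(df) <- rownames(rdm)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_model_rdm
#' @param semantics Value semantics of the stored RDM.
#' @param source Source label to attach on read.
#' @export
read_model_rdm <- function(path, source = "model",
                           semantics = c("correlation", "binary")) {
  df <- readr::read_csv(path, show_col_types = FALSE, name_repair = "minimal")
  m <- as.matrix(df)
  rownames(m) <- colnames(m)
  model_rdm(m, conditions = colnames(m), source = source,
            semantics = match.arg(semantics))
}
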