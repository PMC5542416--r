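#' Generate the factorial scene design
#'
#' Builds the full crossing of the four binary experimental factors — scene
#' size (small/large), clutter level (low/high), image contrast (low/high) and
#' image luminance (low/high) — with `n_exemplars` unique images per
#' factor-level combination. With the default `n_exemplars = 3` this yields the
#' 48-condition design (16 factor combinations x 3 exemplars).
#'
#' @param n_exemplars Number of unique images per factor-level combination.
#' @return A tibble with one row per condition: `condition_id` (dense, 1-based),
#'   the four factor columns, and `exemplar`.
#' @examples
#' generate_design()             # 48 conditions
#' generate_design(n_exemplars = 1) # the bare 2^4 crossing
#' @export
generate_design <- function(n_exemplars = 3) {
  if (!is.numeric(n_exemplars) || length(n_exemplars) != 1 ||
      n_exemplars < 1 || n_exemplars != round(n_exemplars)) {
    rlang::abort("`n_exemplars` must be a positive integer")
  }
  d <- tidyr::expand_grid(
    size      = c("small", "large"),
    clutter   = c("low", "high"),
    contrast  = c("low", "high"),
    luminance = c("low", "high"),
    exemplar  = seq_len(n_exemplars)
  )
  tibble::tibble(condition_id = seq_len(nrow(d)), d)
}

#' The four experimental factors of the scene design
#' @return Character vector of factor column names.
#' @export
design_factors <- function() c("size", "clutter", "contrast", "luminance")

check_factor <- function(design, factor) {
  if (!is.character(factor) || length(factor) != 1 ||
      !factor %in% design_factors()) {
    rlang::abort(paste0("unknown factor: ", paste(factor, collapse = ", "),
                        " (expected one of ",
                        paste(design_factors(), collapse = ", "), ")"))
  }
  if (!factor %in% names(design)) {
    rlang::abort(paste0("design has no column `", factor, "`"))
  }
  invisible(factor)
}

#' Round-trip a design table as CSV
#'
#' @param design A design tibble from [generate_design()].
#' @param path File path.
#' @return `write_design()` returns `path` invisibly; `read_design()` the tibble.
#' @export
write_design <- function(design, path) {
  readr::write_csv(design, path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    condition_id = readr::col_integer(),
                    exemplar = readr::col_integer(),
                    .default = readr::col_character()
                  ))
}
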