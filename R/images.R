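#' RMS contrast and RMS luminance of a grayscale image
#'
#' `rms_contrast()` is the relative RMS contrast, the standard deviation of
#' pixel intensities divided by their mean; `rms_luminance()` is the root mean
#' square of pixel intensities. Both are expressed in percent of full scale for
#' intensities in \[0, 1\].
#'
#' @param img Numeric matrix of intensities in \[0, 1\].
#' @return A scalar, in percent.
#' @export
rms_contrast <- function(img) 100 * stats::sd(img) / mean(img)

#' @rdname rms_contrast
#' @export
rms_luminance <- function(img) 100 * sqrt(mean(img^2))

# zero-mean, unit-sd smooth random texture with bounded excursions (about
# +/-1.87 after exact restandardization), so that the mean/sd rescaling for
# every factorial contrast x luminance cell stays inside [0, 1]
random_texture <- function(side, bound = 1.8) {
  z <- matrix(stats::rnorm(side^2), side, side)
  # isotropic low-pass in the Fourier domain: keeps coarse scene-like structure
  f <- stats::fft(z)
  fr <- c(0:(side %/% 2), rev(seq_len(side - side %/% 2 - 1))) / side
  r2 <- outer(fr^2, fr^2, "+")
  f <- f * exp(-r2 / (2 * 0.05^2))
  t0 <- Re(stats::fft(f, inverse = TRUE)) / side^2
  t0 <- (t0 - mean(t0)) / stats::sd(t0)
  t0 <- pmin(pmax(t0, -bound), bound)
  (t0 - mean(t0)) / stats::sd(t0)
}

#' Generate stimulus images with controlled RMS statistics
#'
#' Produces one smooth random texture per design condition and rescales it so
#' that the image meets its condition's RMS contrast and RMS luminance targets
#' exactly: an image is `mean + sd * texture` with the texture standardized to
#' zero mean and unit variance, and the (mean, sd) pair solved from the two
#' targets (`sd = c * mean`, `sqrt(mean^2 + sd^2) = L` with `c`, `L` the
#' fractional contrast/luminance targets). Should a target be unreachable
#' after clipping to \[0, 1\], the achieved value is reported with a warning.
#'
#' @param design Design tibble from [generate_design()].
#' @param side Image side length in pixels (square images).
#' @param seed Integer seed; the same seed reproduces identical pixels.
#' @param contrast_targets,luminance_targets Named vectors (`low`, `high`) of
#'   targets in percent. Defaults: contrast 34/50, luminance 34/51.
#' @return An `image_set` tibble: the design columns plus a list-column
#'   `image` (matrices in \[0,1\]) and the achieved `rms_contrast` /
#'   `rms_luminance` in percent.
#' @export
generate_images <- function(design, side = 128, seed = 1,
                            contrast_targets = c(low = 34, high = 50),
                            luminance_targets = c(low = 34, high = 51)) {
  if (side < 32) rlang::abort("`side` must be at least 32 pixels")
  set.seed(seed)
  out <- design
  imgs <- vector("list", nrow(design))
  ach_c <- ach_l <- numeric(nrow(design))
  for (i in seq_len(nrow(design))) {
    ct <- contrast_targets[[design$contrast[i]]] / 100
    lt <- luminance_targets[[design$luminance[i]]] / 100
    m <- lt / sqrt(1 + ct^2) # sqrt(mean^2 + sd^2) = lt with sd = ct * mean
    s <- ct * m
    tex <- random_texture(side)
    img <- m + s * tex
    if (any(img < 0 | img > 1)) {
      # clipping distorts the statistics: refit the affine map on the clipped
      # image by multiplicative feedback until the targets are met (or stuck)
      for (it in 1:40) {
        img <- pmin(pmax(m + s * tex, 0), 1)
        ca <- rms_contrast(img) / 100
        la <- rms_luminance(img) / 100
        if (abs(ca - ct) < 5e-4 && abs(la - lt) < 5e-4) break
        s <- s * ct / ca
        m <- m * lt / la
      }
      img <- pmin(pmax(m + s * tex, 0), 1)
      if (abs(rms_contrast(img) / 100 - ct) > 5e-3 ||
          abs(rms_luminance(img) / 100 - lt) > 5e-3) {
        rlang::warn(sprintf(
          "condition %d: RMS targets unreachable after clipping; achieved contrast %.2f%%, luminance %.2f%%",
          design$condition_id[i], rms_contrast(img), rms_luminance(img)))
      }
    }
    imgs[[i]] <- img
    ach_c[i] <- rms_contrast(img)
    ach_l[i] <- rms_luminance(img)
  }
  out$image <- imgs
  out$rms_contrast <- ach_c
  out$rms_luminance <- ach_l
  class(out) <- c("image_set", class(out))
  out
}

#' Round-trip an image set as PNG files plus a CSV table
#'
#' @param images An `image_set` from [generate_images()].
#' @param dir Directory (created if needed); one PNG per condition plus
#'   `images.csv` with the design columns and achieved RMS statistics.
#' @return `write_images()` returns `dir` invisibly; `read_images()` the set.
#' @export
write_images <- function(images, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- dplyr::select(tibble::as_tibble(images), -"image")
  readr::write_csv(tab, file.path(dir, "images.csv"))
  for (i in seq_len(nrow(images))) {
    png::writePNG(images$image[[i]],
                  file.path(dir, sprintf("condition_%02d.png", images$condition_id[i])))
  }
  invisible(dir)
}

#' @rdname write_images
#' @export
read_images <- function(dir) {
  tab <- readr::read_csv(file.path(dir, "images.csv"), show_col_types = FALSE)
  tab$image <- lapply(tab$condition_id, function(id) {
    png::readPNG(file.path(dir, sprintf("condition_%02d.png", id)))
  })
  class(tab) <- c("image_set", class(tab))
  tab
}
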