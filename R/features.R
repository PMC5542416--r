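#' A bank of complex Gabor filters
#'
#' Quadrature-pair Gabor kernels at `n_orientations` evenly spaced
#' orientations and `n_scales` octave-spaced spatial frequencies (the default
#' 8 x 4 = 32 filters). Kernels have an isotropic Gaussian envelope and are
#' mean-corrected so that constant images give zero response.
#'
#' @param n_orientations Number of orientations (evenly spaced over 180 deg).
#' @param n_scales Number of octave-spaced frequencies, starting at
#'   `base_frequency`.
#' @param base_frequency Highest center frequency, cycles/pixel.
#' @param bandwidth Envelope SD as a multiple of the wavelength.
#' @param max_half Cap on the kernel half-size in pixels.
#' @return A `gabor_bank`: list of complex kernels plus a parameter table
#'   (`scale`, `orientation_deg`, `frequency`).
#' @export
gabor_bank <- function(n_orientations = 8, n_scales = 4,
                       base_frequency = 0.25, bandwidth = 0.56,
                       max_half = 24) {
  params <- tidyr::expand_grid(scale = seq_len(n_scales),
                               orientation = seq_len(n_orientations))
  params$frequency <- base_frequency / 2^(params$scale - 1)
  params$orientation_deg <- (params$orientation - 1) * 180 / n_orientations
  kernels <- purrr::pmap(params, function(scale, orientation, frequency,
                                          orientation_deg) {
    sigma <- bandwidth / frequency
    h <- min(ceiling(2.5 * sigma), max_half)
    xy <- seq(-h, h)
    theta <- orientation_deg * pi / 180
    xr <- outer(xy * cos(theta), xy * sin(theta), "+") # x cos + y sin
    r2 <- outer(xy^2, xy^2, "+")
    k <- exp(-r2 / (2 * sigma^2)) * exp(2i * pi * frequency * xr)
    k - mean(k) # zero-mean: constant images map to zero
  })
  structure(list(kernels = kernels, params = params,
                 n_orientations = n_orientations, n_scales = n_scales),
            class = "gabor_bank")
}

# circular 2D convolution via FFT; kernel centered at the origin with wraparound
conv2_circular <- function(img, kernel) {
  n <- nrow(img); m <- ncol(img)
  h1 <- (nrow(kernel) - 1) / 2; h2 <- (ncol(kernel) - 1) / 2
  if (nrow(kernel) > n || ncol(kernel) > m) {
    rlang::abort("kernel larger than image")
  }
  kpad <- matrix(0 + 0i, n, m)
  ri <- ((-h1:h1) %% n) + 1
  ci <- ((-h2:h2) %% m) + 1
  kpad[ri, ci] <- kernel
  stats::fft(stats::fft(img) * stats::fft(kpad), inverse = TRUE) / (n * m)
}

bilinear_resize <- function(img, side) {
  n <- nrow(img); m <- ncol(img)
  if (n == side && m == side) return(img)
  # map output pixel centers onto input pixel centers
  xs <- (seq_len(side) - 0.5) * n / side + 0.5 - 1 # 0-based fractional rows
  ys <- (seq_len(side) - 0.5) * m / side + 0.5 - 1
  x0 <- pmin(pmax(floor(xs), 0), n - 1); x1 <- pmin(x0 + 1, n - 1)
  y0 <- pmin(pmax(floor(ys), 0), m - 1); y1 <- pmin(y0 + 1, m - 1)
  fx <- xs - x0; fy <- ys - y0
  a <- img[x0 + 1, y0 + 1] * outer(1 - fx, 1 - fy) +
    img[x1 + 1, y0 + 1] * outer(fx, 1 - fy) +
    img[x0 + 1, y1 + 1] * outer(1 - fx, fy) +
    img[x1 + 1, y1 + 1] * outer(fx, fy)
  a
}

#' GIST descriptor of a grayscale image
#'
#' Filters the image with a Gabor bank, pools the response magnitudes by
#' averaging within a `grid` x `grid` spatial grid, and concatenates the cell
#' means over filters. With the default 32-filter bank and 4x4 grid the
#' descriptor has 32 x 16 = 512 dimensions.
#'
#' @param image Square numeric matrix of intensities.
#' @param bank A [gabor_bank()].
#' @param grid Pooling grid resolution per side.
#' @param resize_to Side length the image is resized to before filtering
#'   (`NULL` keeps the native size); must be divisible by `grid`.
#' @return Numeric descriptor of length `length(bank$kernels) * grid^2`,
#'   ordered filter-major (cells column-major within each filter).
#' @export
gist_descriptor <- function(image, bank = gabor_bank(), grid = 4,
                            resize_to = 128) {
  if (nrow(image) != ncol(image)) rlang::abort("image must be square")
  if (!is.null(resize_to)) image <- bilinear_resize(image, resize_to)
  side <- nrow(image)
  if (side %% grid != 0) rlang::abort("image side must be divisible by the grid")
  if (side < 32) rlang::abort("image too small")
  cell <- side %/% grid
  idx <- rep(seq_len(grid), each = cell)
  out <- lapply(bank$kernels, function(k) {
    mag <- Mod(conv2_circular(image, k))
    pooled <- rowsum(t(rowsum(mag, idx)), idx) / cell^2 # grid x grid cell means
    as.vector(t(pooled)) # restore row-group x col-group, column-major
  })
  unlist(out, use.names = FALSE)
}

#' Compute GIST descriptors for an image set
#'
#' @param images An `image_set` (or list of matrices named by condition id).
#' @inheritParams gist_descriptor
#' @return A [feature_set()] (conditions x 512 by default), layer `"gist"`.
#' @export
gist_features <- function(images, bank = gabor_bank(), grid = 4,
                          resize_to = 128) {
  imgs <- if (inherits(images, "image_set")) {
    stats::setNames(images$image, images$condition_id)
  } else images
  x <- t(vapply(imgs, gist_descriptor,
                numeric(length(bank$kernels) * grid^2),
                bank = bank, grid = grid, resize_to = resize_to))
  feature_set(x, layer = "gist")
}

#' HMAX parameters
#'
#' Configuration of a 4-layer HMAX hierarchy (S1 -> C1 -> S2 -> C2): S1
#' convolves with Gabor filters at several sizes, C1 takes local maxima over
#' space and paired scales, S2 measures Gaussian radial-basis similarity to a
#' dictionary of C1 patches, and C2 is the global maximum per patch.
#'
#' @param n_orientations S1 Gabor orientations.
#' @param filter_half_sizes S1 kernel half-sizes; consecutive pairs form the
#'   C1 scale bands.
#' @param frequency S1 Gabor frequency in cycles/pixel.
#' @param c1_pool,c1_stride C1 spatial max-pooling neighborhood and stride.
#' @param patch_size S2 dictionary patch side (in C1 grid units).
#' @param s2_sigma S2 radial-basis width.
#' @param dictionary Patch dictionary from [hmax_dictionary()] (required for
#'   S2/C2).
#' @return An `hmax_params` list.
#' @export
hmax_params <- function(n_orientations = 4, filter_half_sizes = c(3, 4, 5, 6),
                        frequency = 0.25, c1_pool = 8, c1_stride = 4,
                        patch_size = 4, s2_sigma = 1, dictionary = NULL) {
  stopifnot(length(filter_half_sizes) %% 2 == 0)
  structure(list(n_orientations = n_orientations,
                 filter_half_sizes = filter_half_sizes, frequency = frequency,
                 c1_pool = c1_pool, c1_stride = c1_stride,
                 patch_size = patch_size, s2_sigma = s2_sigma,
                 dictionary = dictionary),
            class = "hmax_params")
}

hmax_s1 <- function(image, params) {
  lapply(params$filter_half_sizes, function(h) {
    sigma <- (2 * h + 1) / 4.5
    xy <- seq(-h, h)
    r2 <- outer(xy^2, xy^2, "+")
    lapply(seq_len(params$n_orientations), function(o) {
      theta <- (o - 1) * pi / params$n_orientations
      xr <- outer(xy * cos(theta), xy * sin(theta), "+")
      k <- exp(-r2 / (2 * sigma^2)) * exp(2i * pi * params$frequency * xr)
      k <- k - mean(k)
      k <- k / sqrt(sum(Mod(k)^2))
      Mod(conv2_circular(image, k))
    })
  })
}

max_pool <- function(m, pool, stride) {
  xs <- seq(1, nrow(m) - pool + 1, by = stride)
  ys <- seq(1, ncol(m) - pool + 1, by = stride)
  out <- matrix(0, length(xs), length(ys))
  for (i in seq_along(xs)) {
    for (j in seq_along(ys)) {
      out[i, j] <- max(m[xs[i]:(xs[i] + pool - 1), ys[j]:(ys[j] + pool - 1)])
    }
  }
  out
}

hmax_c1 <- function(s1, params) {
  n_bands <- length(s1) %/% 2
  lapply(seq_len(n_bands), function(b) {
    lapply(seq_len(params$n_orientations), function(o) {
      max_pool(pmax(s1[[2 * b - 1]][[o]], s1[[2 * b]][[o]]),
               params$c1_pool, params$c1_stride)
    })
  })
}

c1_windows <- function(c1_band, p) {
  n <- nrow(c1_band[[1]]); m <- ncol(c1_band[[1]])
  if (n < p || m < p) return(NULL)
  pos <- tidyr::expand_grid(i = seq_len(n - p + 1), j = seq_len(m - p + 1))
  list(pos = pos, get = function(i, j) {
    unlist(lapply(c1_band, function(o) o[i:(i + p - 1), j:(j + p - 1)]))
  })
}

#' Sample an S2 patch dictionary from C1 representations
#'
#' @param images An `image_set` or list of matrices to sample patches from.
#' @param params An [hmax_params()].
#' @param n_patches Dictionary size.
#' @param seed Integer seed fixing the dictionary.
#' @return List of patch vectors (length `patch_size^2 * n_orientations`).
#' @export
hmax_dictionary <- function(images, params = hmax_params(), n_patches = 100,
                            seed = 7) {
  imgs <- if (inherits(images, "image_set")) images$image else images
  set.seed(seed)
  pick <- sample.int(length(imgs), n_patches, replace = TRUE)
  c1_cache <- lapply(unique(pick), function(i) {
    hmax_c1(hmax_s1(imgs[[i]], params), params)
  })
  names(c1_cache) <- unique(pick)
  patches <- vector("list", n_patches)
  for (q in seq_len(n_patches)) {
    c1 <- c1_cache[[as.character(pick[q])]]
    b <- sample.int(length(c1), 1)
    w <- c1_windows(c1[[b]], params$patch_size)
    if (is.null(w)) rlang::abort("C1 maps smaller than the patch size")
    at <- w$pos[sample.int(nrow(w$pos), 1), ]
    patches[[q]] <- w$get(at$i, at$j)
  }
  patches
}

#' HMAX features of a grayscale image
#'
#' Runs the 4-layer hierarchy and returns one feature vector per layer:
#' flattened S1 and C1 maps, flattened S2 similarity maps, and the C2 vector
#' (global max per dictionary patch, length = dictionary size).
#'
#' @param image Square numeric matrix.
#' @param params An [hmax_params()] with a non-empty `dictionary`.
#' @return Named list of numeric vectors: `s1`, `c1`, `s2`, `c2`.
#' @export
hmax_features <- function(image, params = hmax_params()) {
  if (is.null(params$dictionary) || length(params$dictionary) == 0) {
    rlang::abort("empty S2 patch dictionary; build one with hmax_dictionary()")
  }
  minside <- 2 * max(params$filter_half_sizes) + 1
  if (nrow(image) < minside || ncol(image) < minside) {
    rlang::abort("image smaller than the largest S1 filter")
  }
  s1 <- hmax_s1(image, params)
  c1 <- hmax_c1(s1, params)
  p <- params$patch_size
  sig2 <- 2 * params$s2_sigma^2 * p^2 * params$n_orientations
  s2 <- lapply(c1, function(band) {
    w <- c1_windows(band, p)
    if (is.null(w)) return(NULL)
    pos <- as.matrix(w$pos)
    W <- t(apply(pos, 1, function(ij) w$get(ij[1], ij[2]))) # positions x len
    vapply(params$dictionary, function(pat) {
      exp(-colSums((t(W) - pat)^2) / sig2)
    }, numeric(nrow(W)))
  })
  s2 <- s2[!vapply(s2, is.null, logical(1))]
  if (length(s2) == 0) rlang::abort("no C1 band large enough for S2 patches")
  c2 <- apply(do.call(rbind, s2), 2, max)
  list(s1 = unlist(s1, use.names = FALSE),
       c1 = unlist(c1, use.names = FALSE),
       s2 = unlist(s2, use.names = FALSE),
       c2 = c2)
}

#' Per-layer HMAX feature sets for an image set
#'
#' @param images An `image_set`.
#' @param params An [hmax_params()] with a dictionary.
#' @return Named list of [feature_set()]s (`s1`, `c1`, `s2`, `c2`).
#' @export
hmax_feature_sets <- function(images, params = hmax_params()) {
  feats <- lapply(images$image, hmax_features, params = params)
  layers <- names(feats[[1]])
  stats::setNames(lapply(layers, function(l) {
    x <- do.call(rbind, lapply(feats, `[[`, l))
    rownames(x) <- images$condition_id
    feature_set(x, layer = paste0("hmax/", l))
  }), layers)
}

#' Load externally computed per-layer activation features
#'
#' Reads a CSV activation table (columns `condition_id`, `layer`, then one
#' column per feature dimension) — the plug-in point for features from any
#' externally run model, e.g. deep network layer activations. Rows are
#' aligned to the design's condition order; missing conditions or ragged
#' dimensionalities are errors.
#'
#' @param path CSV file.
#' @param design Design tibble used for condition alignment.
#' @param layers Optional layer subset/order (default: order of appearance).
#' @return Named list of [feature_set()]s, one per layer.
#' @export
load_activation_features <- function(path, design, layers = NULL) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("condition_id", "layer") %in% names(tab))) {
    rlang::abort("activation table needs `condition_id` and `layer` columns")
  }
  if (is.null(layers)) layers <- unique(tab$layer)
  feat_cols <- setdiff(names(tab), c("condition_id", "layer"))
  stats::setNames(lapply(layers, function(l) {
    sub <- tab[tab$layer == l, ]
    miss <- setdiff(design$condition_id, sub$condition_id)
    if (length(miss)) {
      rlang::abort(sprintf("layer %s: missing condition(s) %s", l,
                           paste(miss, collapse = ", ")))
    }
    sub <- sub[match(design$condition_id, sub$condition_id), ]
    x <- as.matrix(sub[, feat_cols])
    if (anyNA(x)) {
      rlang::abort(sprintf("layer %s: ragged feature dimensions (NA cells)", l))
    }
    rownames(x) <- sub$condition_id
    feature_set(x, layer = l)
  }), layers)
}

#' @rdname load_activation_features
#' @param features Named list of [feature_set()]s to write.
#' @export
write_activation_features <- function(features, path) {
  rows <- purrr::imap(features, function(fs, l) {
    df <- tibble::as_tibble(as.data.frame(unclass(fs)),
                            .name_repair = ~ paste0("f", seq_along(.x)))
    dplyr::bind_cols(tibble::tibble(condition_id = as.integer(rownames(fs)),
                                    layer = l), df)
  })
  readr::write_csv(dplyr::bind_rows(rows), path)
  invisible(path)
}
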