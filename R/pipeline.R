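#' Build a validated end-to-end run configuration
#'
#' Assembles all pipeline parameters with defaults taken from the chosen
#' scale profile (see [desk_profile()]); every analysis constant has a named
#' key. Overrides are supplied as nested lists and are checked strictly:
#' unknown keys are rejected.
#'
#' @param profile `"desk"` (reduced, minutes on one core) or `"full"`
#'   (306 channels, 1 ms sampling, 60 trials/condition, 15 subjects).
#' @param ... Nested overrides, e.g. `generator = list(n_subjects = 4)`,
#'   `signal = list(...)`, `analyses = list(cross_targets = "size")`.
#' @param seed Master seed; all stage seeds derive from it by fixed offsets.
#' @return A `run_config` nested list.
#' @export
run_config <- function(profile = c("desk", "full"), ..., seed = 1) {
  profile <- match.arg(profile)
  p <- if (profile == "desk") desk_profile() else full_profile()
  base <- list(
    profile = profile,
    seed = as.integer(seed),
    design = list(n_exemplars = 3),
    generator = list(
      n_channels = p$n_channels, times = p$times,
      n_trials_per_condition = p$n_trials_per_condition,
      n_subjects = p$n_subjects,
      noise = list(sd = 100, cov_rank = 5, shared_frac = 0.3, ar_coef = 0.8),
      subject_jitter_sd = 0.2),
    signal = list(effects = NULL), # NULL = pure-noise null generator
    artifacts = list(rate = 0, amplitude = 10000),
    preprocessing = list(p2p_threshold = 8000, baseline = c(-100, 0),
                         smoothing_ms = 20),
    decoding = list(k = p$decoding$k, n_repetitions = p$decoding$n_repetitions,
                    cost = 1, time_step = p$decoding$time_step),
    cross = list(k = p$cross_k, n_repetitions = p$decoding$n_repetitions),
    inference = list(n_perm = p$n_perm, n_boot = p$n_boot,
                     cluster_alpha = 0.05, corrected_alpha = 0.05),
    analyses = list(clustering_factors = design_factors(),
                    cross_targets = "size", identity = TRUE,
                    rsa_factors = "size"),
    models = list(gist = FALSE, hmax = FALSE, activations = NULL,
                  image_side = 64))
  merge_config(base, list(...))
}

merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    full <- paste0(path, key)
    if (!key %in% names(base)) {
      rlang::abort(paste0("unknown configuration key: ", full))
    }
    if (is.list(base[[key]]) && !is.null(names(base[[key]])) &&
        is.list(override[[key]])) {
      base[[key]] <- merge_config(base[[key]], override[[key]],
                                  paste0(full, "$"))
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' @rdname run_config
#' @param path YAML file of overrides; must contain at most the keys that
#'   [run_config()] knows (plus `profile`/`seed`).
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  profile <- y$profile %||% "desk"
  seed <- y$seed %||% 1
  y$profile <- NULL
  y$seed <- NULL
  do.call(run_config, c(list(profile = profile, seed = seed), y))
}

signal_from_config <- function(config) {
  eff <- config$signal$effects
  if (is.null(eff)) return(signal_spec(subject_jitter_sd = config$generator$subject_jitter_sd))
  if (is.data.frame(eff)) {
    return(signal_spec(eff, subject_jitter_sd = config$generator$subject_jitter_sd))
  }
  signal_spec(dplyr::bind_rows(lapply(eff, tibble::as_tibble)),
              subject_jitter_sd = config$generator$subject_jitter_sd)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the complete analysis graph: design and epoch generation,
#' artifact injection, trial rejection with the imbalance check, baseline
#' normalization, temporal smoothing, pairwise decoding into RDM time
#' series, single-image decoding, representational clustering per factor,
#' cross-classification (across factors and image identity), RSA against
#' explicit factor models (plus GIST/HMAX or loaded activation models when
#' enabled), and cluster/bootstrap inference on every group time course. All
#' artifacts are written as CSV under `out_dir` together with a JSON manifest
#' of seeds and parameters.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created; overwritten file by file).
#' @return Invisibly, a list with the in-memory results (`design`, `rdms`,
#'   `timecourses`, `cluster_tests`, `latencies`, `report`).
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "timecourses"), showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(paste0("pipeline stage [", name, "] failed: ",
                          conditionMessage(e)))
    })
  }

  design <- stage("design", generate_design(config$design$n_exemplars))
  write_design(design, file.path(out_dir, "design.csv"))

  g <- config$generator
  noise <- stage("noise", noise_spec(
    n_channels = g$n_channels, sd = g$noise$sd, cov_rank = g$noise$cov_rank,
    shared_frac = g$noise$shared_frac, ar_coef = g$noise$ar_coef))
  signal <- stage("signal", signal_from_config(config))
  epochs <- stage("generate_epochs", generate_epochs(
    design, signal, noise, n_trials_per_condition = g$n_trials_per_condition,
    n_subjects = g$n_subjects, times = g$times, master_seed = config$seed))
  if (config$artifacts$rate > 0) {
    epochs <- stage("inject_artifacts", inject_artifacts(
      epochs, config$artifacts$rate, config$artifacts$amplitude,
      seed = config$seed + 77L))
  }

  pp <- config$preprocessing
  rej <- stage("reject_trials", reject_trials(epochs, pp$p2p_threshold))
  readr::write_csv(rej$report, file.path(out_dir, "rejection_report.csv"))
  imb <- stage("imbalance", rejection_imbalance_test(
    rej$report, design, n_perm = config$inference$n_perm,
    seed = config$seed + 3L))
  readr::write_csv(imb, file.path(out_dir, "rejection_imbalance.csv"))

  epochs <- stage("baseline", baseline_normalize(rej$epochs, pp$baseline))
  epochs <- stage("smoothing", smooth_timecourse(epochs, pp$smoothing_ms))

  dec <- decoding_config(k = config$decoding$k,
                         n_repetitions = config$decoding$n_repetitions,
                         cost = config$decoding$cost,
                         time_step = config$decoding$time_step,
                         seed = config$seed + 11L)
  rdms <- stage("pairwise_decoding", pairwise_decoding_timecourse(epochs, dec))

  tcs <- list(image_decoding = stage("factor_average",
                                     factor_average_decoding(rdms, design)))
  for (f in config$analyses$clustering_factors) {
    tcs[[paste0("clustering_", f)]] <-
      stage(paste0("clustering_", f), clustering_timecourse(rdms, design, f))
  }
  xcfg <- decoding_config(k = config$cross$k,
                          n_repetitions = config$cross$n_repetitions,
                          cost = config$decoding$cost,
                          time_step = config$decoding$time_step,
                          seed = config$seed + 13L)
  for (tf in config$analyses$cross_targets) {
    for (gf in setdiff(design_factors(), tf)) {
      nm <- paste0("cross_", tf, "_by_", gf)
      tcs[[nm]] <- stage(nm, cross_decoding_timecourse(epochs, design, tf, gf, xcfg))
    }
    if (isTRUE(config$analyses$identity) && max(design$exemplar) == 3) {
      nm <- paste0("cross_", tf, "_by_identity")
      tcs[[nm]] <- stage(nm, identity_cross_decoding(epochs, design, tf, xcfg))
    }
  }

  for (f in config$analyses$rsa_factors) {
    tcs[[paste0("rsa_", f)]] <-
      stage(paste0("rsa_", f), rsa_timecourse(rdms, factor_model_rdm(design, f)))
  }
  model_layers <- list()
  if (isTRUE(config$models$gist) || isTRUE(config$models$hmax)) {
    images <- stage("images", generate_images(design, side = config$models$image_side,
                                              seed = config$seed + 23L))
    if (isTRUE(config$models$gist)) {
      model_layers$gist <- list(stage("gist", feature_rdm(gist_features(images))))
    }
    if (isTRUE(config$models$hmax)) {
      prm <- hmax_params(dictionary = hmax_dictionary(
        images, n_patches = 30, seed = config$seed + 29L))
      model_layers$hmax <- stage("hmax", lapply(
        hmax_feature_sets(images, prm), feature_rdm))
    }
  }
  if (!is.null(config$models$activations)) {
    feats <- stage("activations",
                   load_activation_features(config$models$activations, design))
    model_layers$activations <- lapply(feats, feature_rdm)
  }
  for (mn in names(model_layers)) {
    layers <- model_layers[[mn]]
    tcs[[paste0("rsa_", mn)]] <-
      stage(paste0("rsa_", mn), rsa_timecourse(rdms, layers))
    for (f in config$analyses$rsa_factors) {
      nm <- paste0("partial_rsa_", f, "_given_", mn)
      tcs[[nm]] <- stage(nm, partial_rsa_timecourse(
        rdms, factor_model_rdm(design, f), layers))
    }
  }

  inf <- config$inference
  tests <- list(); lats <- list()
  for (nm in names(tcs)) {
    tc <- tcs[[nm]]
    readr::write_csv(tibble::as_tibble(tc),
                     file.path(out_dir, "timecourses", paste0(nm, ".csv")))
    tests[[nm]] <- stage(paste0("cluster_test/", nm),
                         sign_permutation_cluster_test(
                           tc, n_perm = inf$n_perm,
                           cluster_alpha = inf$cluster_alpha,
                           corrected_alpha = inf$corrected_alpha,
                           seed = config$seed + 31L))
    lats[[nm]] <- stage(paste0("latency/", nm), bootstrap_latency_ci(
      tc, n_boot = inf$n_boot, n_perm = inf$n_perm,
      cluster_alpha = inf$cluster_alpha, corrected_alpha = inf$corrected_alpha,
      seed = config$seed + 37L))
  }

  clusters <- purrr::imap_dfr(tests, function(ct, nm) {
    dplyr::mutate(ct$clusters, analysis = nm, .before = 1)
  })
  readr::write_csv(clusters, file.path(out_dir, "clusters.csv"))
  latencies <- purrr::imap_dfr(lats, function(le, nm) {
    tc <- tcs[[nm]]
    gm <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(tc), .data$time_ms),
                           value = mean(.data$value))
    tibble::tibble(
      analysis = nm, statistic = attr(tc, "statistic"),
      onset_ms = le$onset, onset_lo = le$onset_ci[1], onset_hi = le$onset_ci[2],
      peak_ms = le$peak, peak_lo = le$peak_ci[1], peak_hi = le$peak_ci[2],
      max_effect = max(gm$value) - (attr(tc, "chance") %||% 0),
      significant = any(tests[[nm]]$clusters$significant),
      n_no_cluster = le$n_no_cluster)
  })
  readr::write_csv(latencies, file.path(out_dir, "latencies.csv"))

  manifest <- list(package = "megrsa",
                   version = as.character(utils::packageVersion("megrsa")),
                   seed = config$seed, profile = config$profile,
                   config = rapply(config, unclass, how = "replace"),
                   analyses = names(tcs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)

  invisible(list(design = design, rdms = rdms, timecourses = tcs,
                 cluster_tests = tests, latencies = lats,
                 report = latencies))
}

#' Summarize a completed pipeline run
#'
#' Reads the run directory and returns one row per analysis: onset and peak
#' latency with CIs, maximal effect size and cluster significance.
#'
#' @param out_dir A directory written by [run_pipeline()].
#' @return A tibble.
#' @export
pipeline_report <- function(out_dir) {
  need <- c("latencies.csv", "clusters.csv", "manifest.json")
  missing <- need[!file.exists(file.path(out_dir, need))]
  if (length(missing)) {
    rlang::abort(paste0("incomplete run; missing: ",
                        paste(missing, collapse = ", ")))
  }
  readr::read_csv(file.path(out_dir, "latencies.csv"), show_col_types = FALSE)
}
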