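#' Default end-to-end run configuration
#'
#' Bundles every setting of the phantom-to-decision pipeline: phantom recipe,
#' tissue properties, ambient conditions, camera noise, inverse-fit and
#' decision controls, and the validation batch description. The default
#' batch mirrors the clinical cohort's envelope at desk scale: 10
#' tumor-bearing phantoms with diameters sampled uniformly over 8-25 mm and
#' center depths over 10-40 mm (jointly rejection-sampled so the sphere lies
#' fully inside breast tissue), uniform azimuth, plus 10 tumor-free
#' phantoms, all observed with 0.02 degC camera noise.
#'
#' @param seed run-level seed; every stochastic element (truth sampling,
#'   per-case noise) derives from it.
#' @param ... named overrides of top-level config entries (lists are merged).
#' @return a `run_config`.
#' @examples
#' cfg <- default_run_config(seed = 7, batch = list(n_present = 2, n_absent = 1))
#' cfg$batch$n_present
#' @export
default_run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    phantom = list(breast_radius = 0.07, voxel_size = 0.0025,
                   gland_fraction = 0.5),
    props = default_tissue_properties(),
    ambient = default_ambient_conditions(),
    noise = list(sigma = 0.02),
    batch = list(n_present = 10L, n_absent = 10L,
                 diameter_range = c(0.008, 0.025),
                 depth_range = c(0.010, 0.040),
                 polar_max_deg = 60),
    inverse = list(multi_start = FALSE, control = list()),
    detection = list()
  )
  dots <- list(...)
  for (nm in names(dots)) {
    cfg[[nm]] <- if (is.list(dots[[nm]]) && is.list(cfg[[nm]]))
      modifyList(cfg[[nm]], dots[[nm]]) else dots[[nm]]
  }
  structure(cfg, class = "run_config")
}

config_hash <- function(config) {
  object_hash(unclass(config))
}

build_config_phantom <- function(config) {
  build_hemisphere_phantom(config$phantom$breast_radius,
                           config$phantom$voxel_size,
                           config$phantom$gland_fraction)
}

#' Sample ground-truth tumors for a validation batch
#'
#' Draws `n_present` tumor truths under the batch description: diameter and
#' center depth uniform over their configured ranges, rejection-sampled
#' jointly until the sphere fits fully below the skin
#' (`depth >= D/2 + voxel`), azimuth uniform, and polar angle uniform up to
#' the configured cap, further limited so the sphere clears the chest wall.
#'
#' @param config a [default_run_config()].
#' @return list of [tumor_params()] of length `config$batch$n_present`.
#' @export
sample_batch_truths <- function(config) {
  stop_if_not_class(config, "run_config")
  bt <- config$batch
  R <- config$phantom$breast_radius
  h <- config$phantom$voxel_size
  if (diff(bt$diameter_range) < 0 || diff(bt$depth_range) < 0 ||
      bt$depth_range[1] <= 0 ||
      bt$depth_range[2] < bt$diameter_range[1] / 2 + h ||
      bt$depth_range[1] > R - bt$diameter_range[1] / 2 - h) {
    stop("degenerate batch sampling ranges", call. = FALSE)
  }
  with_seed(config$seed, {
    lapply(seq_len(bt$n_present), function(i) {
      tries <- 0L
      repeat {
        d <- runif(1, bt$diameter_range[1], bt$diameter_range[2])
        depth <- runif(1, bt$depth_range[1], bt$depth_range[2])
        if (depth >= d / 2 + h && depth < R - d / 2 - h) break
        tries <- tries + 1L
        if (tries > 10000L) {
          stop("could not sample a feasible tumor under the batch ranges",
               call. = FALSE)
        }
      }
      r <- R - depth
      polar_cap <- min(bt$polar_max_deg * pi / 180, acos(min((d / 2 + h) / r, 1)))
      phi <- runif(1, 0, polar_cap)
      az <- runif(1, 0, 2 * pi)
      tumor_params(c(r * sin(phi) * cos(az), r * sin(phi) * sin(az),
                     r * cos(phi)), d)
    })
  })
}

#' Run one phantom case end to end
#'
#' Generates the observation (forward solve with the true tumor, or the
#' tumor-free solve, plus seeded camera noise), runs the Levenberg-Marquardt
#' inverse fit from the default initial guess, and classifies presence or
#' absence. Identical config and seeds reproduce the result exactly.
#'
#' @param config a [default_run_config()].
#' @param truth a [tumor_params()] ground truth, or `NULL` for a tumor-free
#'   case.
#' @param case_seed noise seed for this case; defaults to `config$seed`.
#' @param cache optional shared cache from [run_batch()] (phantom,
#'   discretization, tumor-free surface) to avoid recomputation.
#' @param outdir optional directory; when given, the observation (CSV), the
#'   classified result (JSON), and the run provenance are written there.
#' @return list with `truth`, `observed` (`surface_map`), and `result`
#'   (classified `inverse_result`).
#' @export
run_case <- function(config, truth = NULL, case_seed = NULL, cache = NULL,
                     outdir = NULL) {
  stop_if_not_class(config, "run_config")
  case_seed <- case_seed %||% config$seed
  if (is.null(cache)) cache <- make_run_cache(config)
  phantom <- cache$phantom
  geom <- cache$geom

  clean <- if (is.null(truth)) {
    cache$base_surface
  } else {
    forward_model(truth, phantom, config$props, config$ambient, geom = geom)
  }
  observed <- add_camera_noise(clean,
                               noise_model(config$noise$sigma, seed = case_seed))

  fit <- lma_fit(observed, phantom, config$props, config$ambient,
                 control = config$inverse$control, geom = geom,
                 multi_start = isTRUE(config$inverse$multi_start))
  result <- classify_detection(fit, phantom, noise_sigma = config$noise$sigma,
                               control = config$detection)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_surface_csv(observed, file.path(outdir, "observed_surface.csv"))
    write_inverse_result(result, file.path(outdir, "inverse_result.json"),
                         seed = case_seed, config_hash = config_hash(config))
  }
  list(truth = truth, observed = observed, result = result)
}

make_run_cache <- function(config) {
  phantom <- build_config_phantom(config)
  geom <- discretize_phantom(phantom)
  base_surface <- forward_model(NULL, phantom, config$props, config$ambient,
                                geom = geom)
  list(phantom = phantom, geom = geom, base_surface = base_surface)
}

#' Run a full validation batch
#'
#' Samples tumor truths per the batch description, runs [run_case()] for
#' every tumor-bearing and tumor-free case with per-case noise seeds derived
#' from the run seed, and aggregates the classified fits with
#' [score_validation()]. The phantom geometry, its discretization, and the
#' tumor-free forward solve are shared across cases.
#'
#' @param config a [default_run_config()].
#' @param progress print one line per case.
#' @return a `validation_report` with the run `$seed` and `$config_hash`
#'   attached.
#' @export
run_batch <- function(config, progress = FALSE) {
  stop_if_not_class(config, "run_config")
  bt <- config$batch
  n_total <- bt$n_present + bt$n_absent
  if (n_total < 1) stop("batch must contain at least one case", call. = FALSE)

  truths <- c(sample_batch_truths(config),
              rep(list(NULL), bt$n_absent))
  case_seeds <- with_seed(config$seed + 1L,
                          sample.int(.Machine$integer.max, n_total))
  cache <- make_run_cache(config)
  results <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    cs <- run_case(config, truth = truths[[i]], case_seed = case_seeds[i],
                   cache = cache)
    results[[i]] <- cs$result
    if (progress) {
      cat(sprintf("case %2d/%d: %s (%s), rms %.4f\n", i, n_total,
                  if (cs$result$detected) "present" else "absent",
                  cs$result$decision_reason, cs$result$residual_rms))
    }
  }
  report <- score_validation(truths, results)
  report$seed <- config$seed
  report$config_hash <- config_hash(config)
  report
}
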