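#' Configuration for a synthetic phase-contrast plate
#'
#' Bundles every parameter of the synthetic imaging experiment: the plate
#' design (wells, experiments, acquisition days, positions per well), the
#' image geometry, and the generative model linking the per-well
#' differentiation-efficiency score (MYF5+%, measured at the end of the
#' protocol) to what the images look like along the way.
#'
#' The defaults reproduce the design of a 34-well differentiation campaign
#' imaged on eight occasions between day 14 and day 38 at 21 positions per
#' well (34 x 8 x 21 = 5,712 images), but with 512 x 512 px frames so a
#' full plate can be rendered on a desktop; `image_height`/`image_width`
#' can be raised to the native 1440 x 1920 of a 4x phase-contrast camera.
#' Feature extraction works in dimensionless frequency units, so shell
#' profiles remain comparable across resolutions.
#'
#' @param n_wells Number of wells on the plate.
#' @param n_experiments Number of independent experimental batches the wells
#'   are split across (contiguous, near-equal blocks).
#' @param acquisition_days Integer vector of imaging days (days from the
#'   start of differentiation).
#' @param positions_per_well Number of imaging positions per well.
#' @param image_height,image_width Frame size in pixels.
#' @param density_link List linking (myf5_pct, day) to the expected number
#'   of rendered cell-like objects per `ref_dim` x `ref_dim` frame:
#'   `lambda = base + day_coef * dayfrac + myf5_day_coef * dayfrac * myf5_pct`,
#'   where `dayfrac` ramps linearly from 0 at `day_min` to 1 at `day_max`.
#'   The expectation scales with image area. Set all coefficients to 0 for
#'   a background-only plate.
#' @param texture_params List of object appearance parameters: `size_px`
#'   (median semi-minor axis in pixels, fixed across image sizes: a
#'   smaller frame is a sensor crop of the same field), `size_sdlog`
#'   (log-normal spread of sizes), `elong_day` and `elong_myf5`
#'   (aspect-ratio gain with day and with efficiency: round cells early,
#'   elongated myotube-like cells late and in efficient wells),
#'   `contrast` / `contrast_sd` (dark cell-body depth in gray levels),
#'   `halo` (bright phase-halo rim amplitude), `edge_soft` (anti-aliasing
#'   edge width in px), `ref_dim` (reference frame size whose area the
#'   `density_link` expectation refers to).
#' @param noise_sd Additive Gaussian camera-noise SD in gray levels,
#'   applied before 8-bit quantization.
#' @param illumination_gradient Amplitude (gray levels) of a smooth linear
#'   illumination field with a per-image random direction.
#' @param background Background gray level.
#' @param outcome_weights Mixture weights over the low (< 10), middle
#'   (10-20) and high (> 20) efficiency strata used when sampling well
#'   outcomes.
#' @param score_max Upper support bound for the efficiency score (the
#'   protocol's observed ceiling, 31).
#' @param seed Integer seed; every image derives its own sub-seed from
#'   this, so generation is fully reproducible.
#'
#' @return A list of class `"plate_config"`.
#' @seealso [sample_well_outcomes()], [render_image()], [generate_dataset()]
#' @examples
#' cfg <- plate_config(n_wells = 4, positions_per_well = 2,
#'                     acquisition_days = c(14, 38),
#'                     image_height = 96, image_width = 96)
#' cfg$n_wells
#' @export
plate_config <- function(n_wells = 34,
                         n_experiments = 6,
                         acquisition_days = c(14, 17, 21, 24, 28, 31, 34, 38),
                         positions_per_well = 21,
                         image_height = 512,
                         image_width = 512,
                         density_link = list(base = 60, day_coef = 90,
                                             myf5_day_coef = 9,
                                             day_min = 14, day_max = 38),
                         texture_params = list(size_px = 4, size_sdlog = 0.25,
                                               elong_day = 2, elong_myf5 = 1,
                                               contrast = 45, contrast_sd = 10,
                                               halo = 30, edge_soft = 1,
                                               ref_dim = 512),
                         noise_sd = 2,
                         illumination_gradient = 20,
                         background = 128,
                         outcome_weights = c(0.3, 0.4, 0.3),
                         score_max = 31,
                         seed = 1L) {
  check_count(n_wells, "n_wells")
  check_count(n_experiments, "n_experiments")
  check_count(positions_per_well, "positions_per_well")
  check_count(image_height, "image_height")
  check_count(image_width, "image_width")
  if (length(acquisition_days) < 1 || anyDuplicated(acquisition_days))
    stopf("`acquisition_days` must be a non-empty set of distinct days")
  if (image_height < 4 || image_width < 4)
    stopf("images must be at least 4 x 4 pixels")
  if (noise_sd < 0 || illumination_gradient < 0)
    stopf("noise and illumination amplitudes must be non-negative")
  if (length(outcome_weights) != 3 || any(outcome_weights < 0) ||
      sum(outcome_weights) <= 0)
    stopf("`outcome_weights` must be 3 non-negative weights")
  dl <- density_link
  needed <- c("base", "day_coef", "myf5_day_coef", "day_min", "day_max")
  if (!all(needed %in% names(dl)))
    stopf("`density_link` must contain %s", paste(needed, collapse = ", "))
  cfg <- list(n_wells = as.integer(n_wells),
              n_experiments = as.integer(n_experiments),
              acquisition_days = as.integer(sort(acquisition_days)),
              positions_per_well = as.integer(positions_per_well),
              image_height = as.integer(image_height),
              image_width = as.integer(image_width),
              density_link = dl,
              texture_params = texture_params,
              noise_sd = noise_sd,
              illumination_gradient = illumination_gradient,
              background = background,
              outcome_weights = outcome_weights / sum(outcome_weights),
              score_max = score_max,
              seed = as.integer(seed))
  class(cfg) <- "plate_config"
  cfg
}

#' @export
print.plate_config <- function(x, ...) {
  cat(sprintf("Synthetic plate: %d wells x %d days x %d positions (%d images)\n",
              x$n_wells, length(x$acquisition_days), x$positions_per_well,
              x$n_wells * length(x$acquisition_days) * x$positions_per_well))
  cat(sprintf("  frames %d x %d px, days {%s}, %d experiments, seed %d\n",
              x$image_height, x$image_width,
              paste(x$acquisition_days, collapse = ", "),
              x$n_experiments, x$seed))
  invisible(x)
}

# Day ramp of the generative model: 0 at day_min, 1 at day_max, clamped.
day_fraction <- function(day, dl) {
  if (dl$day_max <= dl$day_min) return(1)
  clamp((day - dl$day_min) / (dl$day_max - dl$day_min), 0, 1)
}

# Expected object count for a full frame of the configured size.
expected_object_count <- function(myf5_pct, day, cfg) {
  dl <- cfg$density_link
  f <- day_fraction(day, dl)
  lambda_ref <- dl$base + dl$day_coef * f + dl$myf5_day_coef * f * myf5_pct
  area_scale <- (cfg$image_height * cfg$image_width) / cfg$texture_params$ref_dim^2
  max(lambda_ref, 0) * area_scale
}
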