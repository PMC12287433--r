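#' Sample per-well differentiation outcomes
#'
#' Draws the per-well efficiency score (MYF5+% at the end of the
#' differentiation protocol) from a three-stratum mixture: low (< 10%),
#' middle (10-20%) and high (> 20%), uniform within each stratum and
#' bounded above by `score_max`. Whenever `n_wells >= 6` every stratum is
#' guaranteed at least one well (wells are reassigned from the modal
#' stratum if a random draw leaves one empty), mirroring a campaign in
#' which all outcome classes were observed.
#'
#' @param n_wells Number of wells.
#' @param n_experiments Number of experimental batches; wells are assigned
#'   to contiguous, near-equal blocks.
#' @param seed Integer seed (the caller's RNG state is untouched).
#' @param weights Mixture weights over the low/middle/high strata
#'   (normalized internally).
#' @param score_max Upper bound of the high stratum, default 31.
#' @return A data.frame with columns `well_id`, `experiment_id`,
#'   `myf5_pct` and `stratum` (`"low"`, `"middle"`, `"high"`).
#' @examples
#' out <- sample_well_outcomes(34, n_experiments = 6, seed = 7)
#' table(out$stratum)
#' range(out$myf5_pct)
#' @export
sample_well_outcomes <- function(n_wells, n_experiments = 1, seed = 1L,
                                 weights = c(0.3, 0.4, 0.3),
                                 score_max = 31) {
  check_count(n_wells, "n_wells")
  check_count(n_experiments, "n_experiments")
  if (length(weights) != 3 || any(weights < 0) || sum(weights) <= 0)
    stopf("`weights` must be 3 non-negative mixture weights")
  if (score_max <= 20) stopf("`score_max` must exceed the high-stratum threshold (20)")
  weights <- weights / sum(weights)
  local_seed(seed, {
    stratum <- sample.int(3, n_wells, replace = TRUE, prob = weights)
    if (n_wells >= 6) {
      for (s in which(tabulate(stratum, 3) == 0 & weights > 0)) {
        donor <- which.max(tabulate(stratum, 3))
        stratum[which(stratum == donor)[1]] <- s
      }
    }
    lo <- c(0, 10, 20)[stratum]
    hi <- c(10, 20, score_max)[stratum]
    myf5 <- stats::runif(n_wells, lo, hi)
    well_id <- sprintf("W%03d", seq_len(n_wells))
    exp_of <- rep(seq_len(n_experiments),
                  each = ceiling(n_wells / n_experiments))[seq_len(n_wells)]
    data.frame(well_id = well_id,
               experiment_id = sprintf("E%02d", exp_of),
               myf5_pct = myf5,
               stratum = c("low", "middle", "high")[stratum],
               stringsAsFactors = FALSE)
  })
}

# Sample the cell-like objects of one frame in unit coordinates.
# Returns a data.frame (possibly 0 rows): cx, cy in [0, 1); size = semi-minor
# axis in px at ref_dim resolution; aspect; theta; contrast; halo.
sample_objects <- function(myf5_pct, day, cfg) {
  tex <- cfg$texture_params
  lambda <- expected_object_count(myf5_pct, day, cfg)
  n <- if (lambda > 0) stats::rpois(1, lambda) else 0L
  f <- day_fraction(day, cfg$density_link)
  aspect_mean <- 1 + (tex$elong_day + tex$elong_myf5 * myf5_pct / cfg$score_max) * f
  data.frame(
    cx = stats::runif(n),
    cy = stats::runif(n),
    size = stats::rlnorm(n, log(tex$size_px), tex$size_sdlog),
    aspect = pmax(1, aspect_mean * stats::rlnorm(n, 0, 0.1)),
    theta = stats::runif(n, 0, pi),
    contrast = pmax(5, stats::rnorm(n, tex$contrast, tex$contrast_sd)),
    halo = pmax(0, stats::rnorm(n, tex$halo, tex$halo * 0.2))
  )
}

# Rasterize unit-coordinate objects onto an H x W canvas of additive
# intensity offsets (0 = background). Cells are anti-aliased filled
# ellipses: a dark body with a bright phase-halo rim just outside the
# edge, the standard appearance of adherent cells in low-magnification
# phase contrast. Sizes are in pixels at fixed magnification: a smaller
# canvas is a sensor crop of the same field (fewer objects, same object
# scale), which keeps shell profiles comparable across image sizes in
# the dimensionless cycles-per-pixel radius.
rasterize_objects <- function(objects, height, width, tex) {
  img <- matrix(0, nrow = height, ncol = width)
  if (nrow(objects) == 0) return(img)
  for (i in seq_len(nrow(objects))) {
    b <- objects$size[i]
    a <- b * objects$aspect[i]
    if (b < 0.5) next
    cx <- objects$cx[i] * width + 0.5
    cy <- objects$cy[i] * height + 0.5
    rmax <- 1.5 * a + 2 * tex$edge_soft + 1
    rows <- max(1L, floor(cy - rmax)):min(height, ceiling(cy + rmax))
    cols <- max(1L, floor(cx - rmax)):min(width, ceiling(cx + rmax))
    if (!length(rows) || !length(cols)) next
    dy <- rows - cy
    dx <- cols - cx
    ct <- cos(objects$theta[i]); st <- sin(objects$theta[i])
    # elliptical radius q: 1 on the cell boundary
    u <- outer(dy * st, dx * ct, "+")      # rotated major-axis coordinate
    v <- outer(dy * ct, -dx * st, "+")     # rotated minor-axis coordinate
    q <- sqrt((u / a)^2 + (v / b)^2)
    soft <- tex$edge_soft / b              # edge width in q units
    body <- clamp((1 + soft / 2 - q) / soft, 0, 1)
    rim_w <- max(soft, 0.18)
    rim <- exp(-0.5 * ((q - (1 + 1.2 * rim_w)) / rim_w)^2)
    img[rows, cols] <- img[rows, cols] -
      objects$contrast[i] * body + objects$halo[i] * rim
  }
  img
}

#' Render one synthetic phase-contrast frame
#'
#' Draws a seeded, fully deterministic image for one (well, day, position)
#' triple. The number of cell-like objects is Poisson with an expectation
#' that increases with both the well's efficiency score and the imaging
#' day (see [plate_config()]); objects become more elongated at later days
#' and in more efficient wells. A smooth linear illumination field and
#' Gaussian camera noise are added before quantization to 8-bit.
#'
#' @param outcome One row of [sample_well_outcomes()] output (or any list
#'   with `well_id`, `experiment_id`, `myf5_pct`).
#' @param day Imaging day; must belong to `cfg$acquisition_days`.
#' @param position Position index in `1:cfg$positions_per_well`.
#' @param cfg A [plate_config()].
#' @return An object of class `"image_record"`: a list with `pixels`
#'   (integer matrix in \[0, 255\]), the plate coordinates (`well_id`,
#'   `experiment_id`, `day`, `position`), `myf5_pct`, and `n_objects`
#'   (the generator's own object count, used for bookkeeping checks).
#' @examples
#' cfg <- plate_config(image_height = 128, image_width = 128)
#' out <- sample_well_outcomes(1, seed = 3)
#' img <- render_image(out[1, ], day = 38, position = 1, cfg)
#' range(img$pixels)
#' @export
render_image <- function(outcome, day, position, cfg) {
  stopifnot(inherits(cfg, "plate_config"))
  if (!day %in% cfg$acquisition_days)
    stopf("day %s is not in the configured acquisition days {%s}",
          format(day), paste(cfg$acquisition_days, collapse = ", "))
  if (!is_count(position) || position > cfg$positions_per_well)
    stopf("position must be in 1..%d, got %s",
          cfg$positions_per_well, format(position))
  seed <- derive_seed(cfg$seed, outcome$well_id, day, position)
  local_seed(seed, {
    h <- cfg$image_height; w <- cfg$image_width
    objects <- sample_objects(outcome$myf5_pct, day, cfg)
    canvas <- matrix(cfg$background, nrow = h, ncol = w)
    if (cfg$illumination_gradient > 0) {
      phi <- stats::runif(1, 0, 2 * pi)
      gy <- (seq_len(h) / h - 0.5) * sin(phi)
      gx <- (seq_len(w) / w - 0.5) * cos(phi)
      canvas <- canvas + cfg$illumination_gradient * outer(gy, gx, "+") * 2
    }
    canvas <- canvas + rasterize_objects(objects, h, w, cfg$texture_params)
    if (cfg$noise_sd > 0)
      canvas <- canvas + stats::rnorm(h * w, 0, cfg$noise_sd)
    pixels <- matrix(as.integer(clamp(round(canvas), 0, 255)), nrow = h)
    structure(list(pixels = pixels,
                   well_id = outcome$well_id,
                   experiment_id = outcome$experiment_id,
                   day = as.integer(day),
                   position = as.integer(position),
                   myf5_pct = outcome$myf5_pct,
                   n_objects = nrow(objects)),
              class = "image_record")
  })
}

#' @export
print.image_record <- function(x, ...) {
  cat(sprintf("<image_record %s day %d pos %d: %d x %d px, %d objects>\n",
              x$well_id, x$day, x$position,
              nrow(x$pixels), ncol(x$pixels), x$n_objects))
  invisible(x)
}

#' Enumerate the images a plate design implies
#'
#' Returns the full (well, day, position) layout of a configured plate as
#' a metadata table, without rendering any pixels: one row per image to
#' be generated, i.e. `n_wells * length(acquisition_days) *
#' positions_per_well` rows.
#'
#' @param cfg A [plate_config()].
#' @param outcomes Optional outcome table; sampled from `cfg` if missing.
#' @return A data.frame with columns `experiment_id`, `well_id`, `day`,
#'   `position`, `myf5_pct`.
#' @examples
#' nrow(plate_layout(plate_config()))  # 34 * 8 * 21 = 5712
#' @export
plate_layout <- function(cfg, outcomes = NULL) {
  stopifnot(inherits(cfg, "plate_config"))
  if (is.null(outcomes))
    outcomes <- sample_well_outcomes(cfg$n_wells, cfg$n_experiments,
                                     seed = derive_seed(cfg$seed, "outcomes"),
                                     weights = cfg$outcome_weights,
                                     score_max = cfg$score_max)
  grid <- expand.grid(position = seq_len(cfg$positions_per_well),
                      day = cfg$acquisition_days,
                      well_id = outcomes$well_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- match(grid$well_id, outcomes$well_id)
  data.frame(experiment_id = outcomes$experiment_id[idx],
             well_id = grid$well_id,
             day = as.integer(grid$day),
             position = as.integer(grid$position),
             myf5_pct = outcomes$myf5_pct[idx],
             stringsAsFactors = FALSE)
}

#' Generate a full synthetic plate dataset
#'
#' Renders every (well, day, position) frame of the configured plate.
#' With `dir` set, images are written as lossless 8-bit grayscale PNG
#' files named `{experiment}_{well}_{day}_{position}.png` together with a
#' `metadata.csv` table, and pixels are not kept in memory; otherwise the
#' rendered `image_record`s are returned in the `images` element.
#'
#' @param cfg A [plate_config()].
#' @param dir Optional output directory (created if needed).
#' @param render If `FALSE`, only the outcome table and image metadata are
#'   produced (useful to inspect a design without paying for rendering).
#' @param outcomes Optional pre-sampled outcome table.
#' @return A list of class `"plate_dataset"`: `images` (list of
#'   [render_image()] records, or `NULL`), `outcomes`, `metadata` (one row
#'   per image; includes `file_path` and realized `n_objects` when
#'   rendered), and `cfg`.
#' @examples
#' cfg <- plate_config(n_wells = 2, acquisition_days = c(14, 38),
#'                     positions_per_well = 2,
#'                     image_height = 64, image_width = 64)
#' ds <- generate_dataset(cfg)
#' nrow(ds$metadata)  # 2 * 2 * 2
#' @export
generate_dataset <- function(cfg, dir = NULL, render = TRUE, outcomes = NULL) {
  stopifnot(inherits(cfg, "plate_config"))
  if (is.null(outcomes))
    outcomes <- sample_well_outcomes(cfg$n_wells, cfg$n_experiments,
                                     seed = derive_seed(cfg$seed, "outcomes"),
                                     weights = cfg$outcome_weights,
                                     score_max = cfg$score_max)
  meta <- plate_layout(cfg, outcomes)
  keep_pixels <- is.null(dir)
  if (!is.null(dir)) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
      stopf("cannot create output directory '%s'", dir)
  }
  images <- NULL
  if (render) {
    meta$n_objects <- NA_integer_
    if (!is.null(dir)) meta$file_path <- NA_character_
    if (keep_pixels) images <- vector("list", nrow(meta))
    orows <- match(meta$well_id, outcomes$well_id)
    for (i in seq_len(nrow(meta))) {
      rec <- render_image(outcomes[orows[i], ], meta$day[i], meta$position[i], cfg)
      meta$n_objects[i] <- rec$n_objects
      if (!is.null(dir)) {
        fn <- sprintf("%s_%s_%d_%d.png", rec$experiment_id, rec$well_id,
                      rec$day, rec$position)
        path <- file.path(dir, fn)
        write_image_png(rec, path)
        meta$file_path[i] <- path
      }
      if (keep_pixels) images[[i]] <- rec
    }
    if (!is.null(dir))
      utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  }
  structure(list(images = images, outcomes = outcomes, metadata = meta,
                 cfg = cfg),
            class = "plate_dataset")
}

#' @export
print.plate_dataset <- function(x, ...) {
  cat(sprintf("<plate_dataset: %d wells, %d images%s>\n",
              nrow(x$outcomes), nrow(x$metadata),
              if (is.null(x$images)) " (metadata only in memory)" else ""))
  invisible(x)
}

#' Read and write 8-bit grayscale PNG images
#'
#' Lossless single-channel PNG I/O for `image_record` pixel grids.
#' `write_image_png()` stores the integer \[0, 255\] matrix at 8-bit
#' depth; `read_image_png()` restores it exactly (the first channel is
#' used if a multi-channel file is supplied).
#'
#' @param record An `image_record` or a plain integer matrix in \[0, 255\].
#' @param path File path.
#' @return `read_image_png()` returns an integer pixel matrix;
#'   `write_image_png()` returns `path` invisibly.
#' @export
write_image_png <- function(record, path) {
  pixels <- if (inherits(record, "image_record")) record$pixels else record
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stopf("pixels must be in [0, 255] to write '%s'", path)
  ok <- tryCatch({png::writePNG(pixels / 255, target = path); TRUE},
                 error = function(e) stopf("failed writing '%s': %s",
                                           path, conditionMessage(e)))
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  if (!file.exists(path)) stopf("image file '%s' does not exist", path)
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  matrix(as.integer(round(arr * 255)), nrow = nrow(arr))
}
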