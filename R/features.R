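#' Centered 2-D FFT power spectrum of an image
#'
#' Computes the squared magnitude of the discrete Fourier transform of an
#' image and recenters it so the zero-frequency (DC) term sits at the
#' middle of the grid. Each bin also carries a dimensionless frequency
#' radius `r = sqrt((u/H)^2 + (v/W)^2)`, where `u`, `v` are the signed
#' integer frequency indices and `H`, `W` the image dimensions; measuring
#' radius per axis in cycles-per-pixel keeps non-square images
#' rotation-comparable and makes shell profiles resolution-independent.
#'
#' The unnormalized transform is used, so the total power obeys the
#' discrete Parseval identity `sum(power) = H * W * sum(pixels^2)`.
#'
#' @param image An `image_record` or a numeric matrix (at least 4 x 4).
#' @param window If `TRUE`, apply a 2-D Hann window before the transform.
#'   Off by default: windowing trades a little spectral leakage for loss
#'   of the exact shift/brightness invariances.
#' @return An object of class `"centered_spectrum"`: list with `power`
#'   (non-negative matrix, DC central), `freq_radius` (matrix of the same
#'   shape), and `dim`.
#' @examples
#' sp <- power_spectrum(matrix(rnorm(64), 8, 8))
#' sp$freq_radius[5, 5]  # 0 at the central (DC) bin of an 8 x 8 grid
#' @export
power_spectrum <- function(image, window = FALSE) {
  pixels <- if (inherits(image, "image_record")) image$pixels else image
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stopf("`image` must be an image_record or a numeric matrix")
  h <- nrow(pixels); w <- ncol(pixels)
  if (h < 4 || w < 4)
    stopf("image too small for spectral analysis: %d x %d (need >= 4 x 4)", h, w)
  x <- pixels
  storage.mode(x) <- "double"
  if (window) {
    hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
    x <- x * outer(hann(h), hann(w))
  }
  pw <- Mod(stats::fft(x))^2
  # signed frequency index per axis and the permutation that centers DC
  signed <- function(n) {
    s <- 0:(n - 1)
    s[s >= ceiling(n / 2)] <- s[s >= ceiling(n / 2)] - n
    s
  }
  su <- signed(h); sv <- signed(w)
  ou <- order(su); ov <- order(sv)
  pw <- pw[ou, ov, drop = FALSE]
  r <- sqrt(outer((su[ou] / h)^2, (sv[ov] / w)^2, "+"))
  structure(list(power = pw, freq_radius = r, dim = c(h, w)),
            class = "centered_spectrum")
}

#' Rotation-invariant shell integration of a power spectrum
#'
#' Sums spectral power over concentric annuli ("shells") of the
#' dimensionless frequency radius, producing the radial power profile
#' that is invariant to image rotation and translation. Shell `k` of `n`
#' collects bins with radius in `((k-1) * R/n, k * R/n]` with `R = 0.5`,
#' the inscribed Nyquist radius; the DC bin (r = 0) is excluded and
#' corner bins with `r > R` are discarded so every direction contributes
#' equally. The profile is divided by the total retained power, so
#' components are non-negative and sum to 1 (all-zero when the image has
#' no non-DC power, e.g. a constant frame).
#'
#' @param spectrum A [power_spectrum()] result.
#' @param n_shells Number of shells (profile length), default 100.
#' @param log_power If `TRUE`, shell-integrate `log1p(power)` instead of
#'   raw power. Off by default.
#' @return An object of class `"spectral_feature"`: numeric vector of
#'   length `n_shells` (low to high frequency) with attributes `n_shells`
#'   and `retained_power`.
#' @examples
#' img <- matrix(rnorm(32 * 32), 32)
#' f <- shell_integrate(power_spectrum(img), n_shells = 100)
#' sum(f)  # 1
#' @export
shell_integrate <- function(spectrum, n_shells = 100, log_power = FALSE) {
  stopifnot(inherits(spectrum, "centered_spectrum"))
  check_count(n_shells, "n_shells")
  r <- spectrum$freq_radius
  p <- spectrum$power
  if (log_power) p <- log1p(p)
  keep <- r > 0 & r <= 0.5
  width <- 0.5 / n_shells
  # guard against r/width landing epsilon above an exact shell boundary
  idx <- pmax(1L, as.integer(ceiling(r[keep] / width - 1e-9)))
  vals <- numeric(n_shells)
  if (any(keep)) {
    agg <- rowsum(p[keep], group = idx)
    vals[as.integer(rownames(agg))] <- agg
  }
  tot <- sum(vals)
  if (tot > 0) vals <- vals / tot
  structure(vals, n_shells = as.integer(n_shells), retained_power = tot,
            class = "spectral_feature")
}

#' Extract the rotation-invariant spectral feature of an image
#'
#' Composition of [power_spectrum()] and [shell_integrate()]: the
#' 100-component normalized radial power profile used as the image's
#' feature vector. Deterministic; invariant to rotation, circular
#' translation and constant brightness offsets of the source image.
#'
#' @inheritParams power_spectrum
#' @inheritParams shell_integrate
#' @return A `"spectral_feature"` vector of length `n_shells`.
#' @examples
#' cfg <- plate_config(image_height = 96, image_width = 96)
#' out <- sample_well_outcomes(1, seed = 1)
#' f <- extract_features(render_image(out[1, ], 38, 1, cfg))
#' high_frequency_intensity(f)
#' @export
extract_features <- function(image, n_shells = 100, window = FALSE,
                             log_power = FALSE) {
  shell_integrate(power_spectrum(image, window = window),
                  n_shells = n_shells, log_power = log_power)
}

#' High-frequency intensity of a spectral feature
#'
#' The summed weight of all shells above a cutoff index (1-based;
#' "above the 30th" means shells 31..n). Under the profile normalization
#' the value lies in \[0, 1\] and serves as a scalar proxy for fine
#' texture and cell density.
#'
#' @param feature A [shell_integrate()] / [extract_features()] result, or
#'   a plain numeric profile.
#' @param cutoff Shell index above which power is summed; default 30.
#' @return A numeric scalar with attribute `cutoff`.
#' @examples
#' high_frequency_intensity(rep(0.01, 100))  # 70 shells * 0.01 = 0.7
#' @export
high_frequency_intensity <- function(feature, cutoff = 30) {
  vals <- as.numeric(feature)
  n <- length(vals)
  if (!is_count(cutoff) || cutoff < 1 || cutoff >= n)
    stopf("`cutoff` must be a shell index in 1..%d", n - 1)
  structure(sum(vals[(cutoff + 1):n]), cutoff = as.integer(cutoff))
}

#' Extract features for a batch of images
#'
#' Computes the spectral feature of every image in a list and assembles a
#' flat table: plate metadata columns followed by `shell_001` ..
#' `shell_<n>`. Images that fail to load or transform are skipped with a
#' warning (one per failure), never silently dropped; the failed inputs
#' are recorded in the `"failures"` attribute of the result.
#'
#' @param images A list of `image_record`s, a `plate_dataset`, or a
#'   character vector of PNG file paths.
#' @param metadata Optional metadata data.frame (one row per path) used
#'   when `images` are file paths; ignored for records.
#' @inheritParams extract_features
#' @return A data.frame with one row per successfully processed image.
#' @examples
#' cfg <- plate_config(n_wells = 2, acquisition_days = 14,
#'                     positions_per_well = 2,
#'                     image_height = 64, image_width = 64)
#' tab <- batch_extract(generate_dataset(cfg))
#' dim(tab)
#' @export
batch_extract <- function(images, metadata = NULL, n_shells = 100,
                          window = FALSE, log_power = FALSE) {
  if (inherits(images, "plate_dataset")) {
    if (is.null(images$images))
      stopf("plate_dataset holds no rendered images; pass file paths instead")
    images <- images$images
  }
  if (is.character(images)) {
    paths <- images
    images <- as.list(paths)
    loader <- function(i) read_image_png(paths[i])
    meta_of <- function(i) {
      if (!is.null(metadata)) as.list(metadata[i, , drop = FALSE])
      else list(file = paths[i])
    }
  } else {
    if (!is.list(images) || length(images) == 0)
      stopf("`images` must be a non-empty list of image records or file paths")
    loader <- function(i) images[[i]]
    meta_of <- function(i) {
      rec <- images[[i]]
      list(experiment_id = rec$experiment_id, well_id = rec$well_id,
           day = rec$day, position = rec$position,
           myf5_pct = rec$myf5_pct, n_objects = rec$n_objects)
    }
  }
  if (length(images) == 0) stopf("`images` must be non-empty")
  rows <- vector("list", length(images))
  failures <- character(0)
  for (i in seq_along(images)) {
    row <- tryCatch({
      f <- extract_features(loader(i), n_shells = n_shells,
                            window = window, log_power = log_power)
      c(meta_of(i), as.list(stats::setNames(
        as.numeric(f), sprintf("shell_%03d", seq_len(n_shells)))))
    }, error = function(e) {
      warning(sprintf("image %d skipped: %s", i, conditionMessage(e)),
              call. = FALSE)
      failures <<- c(failures, sprintf("image %d: %s", i, conditionMessage(e)))
      NULL
    })
    rows[[i]] <- row
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) stopf("no image could be processed")
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  out
}

#' Names of the shell feature columns in a feature table
#'
#' @param features A [batch_extract()] data.frame.
#' @return Character vector of `shell_*` column names.
#' @export
shell_columns <- function(features) {
  grep("^shell_[0-9]+$", names(features), value = TRUE)
}
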