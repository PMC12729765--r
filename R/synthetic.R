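# Synthetic CEUS video generator.
#
# Emulates the structure of clinical breast CEUS recordings: a bright
# device-annotation band across the top of the frame, black margins around a
# central imaging region, and an elliptical lesion whose echo intensity
# follows a class-dependent gamma-variate wash-in/wash-out enhancement curve
# with multiplicative speckle noise. Metastatic lesions enhance faster
# (shorter time to peak) and more strongly than non-metastatic ones, which is
# the perfusion signal the contrastive model is expected to learn.

#' Gamma-variate contrast enhancement curve
#'
#' Models lesion echo intensity after a bolus of microbubble contrast agent:
#' zero before the onset frame, a wash-in rising to a unique maximum of
#' exactly `peak`, then wash-out decaying back toward zero. The curve is the
#' gamma-variate form `peak * (u/tp)^shape * exp(shape * (1 - u/tp))` with
#' `u = t - onset` and time-to-peak `tp = shape / rate`, so doubling `rate`
#' halves the time to peak.
#'
#' @param t Frame index (vectorised), on the same scale as `onset`.
#' @param onset Frame at which contrast first arrives.
#' @param rate Wash-in rate (per frame); must be positive. Time to peak is
#'   `shape / rate` frames after onset.
#' @param peak Maximum intensity on the 8-bit scale, in (0, 255].
#' @param shape Gamma-variate shape parameter (default 2).
#' @return Numeric vector of intensities, same length as `t`.
#' @examples
#' enhancement_curve(0:100, onset = 20, rate = 0.1, peak = 200)
#' @export
enhancement_curve <- function(t, onset, rate, peak, shape = 2) {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a positive number")
  if (!is.numeric(peak) || length(peak) != 1L || peak <= 0 || peak > 255)
    stop("`peak` must lie in (0, 255]")
  tp <- shape / rate
  u <- t - onset
  out <- numeric(length(t))
  pos <- u > 0
  r <- u[pos] / tp
  out[pos] <- peak * r^shape * exp(shape * (1 - r))
  out
}

#' Configuration for the synthetic CEUS generator
#'
#' Defaults emulate 2-minute clinical recordings at one frame per second:
#' 120 frames of 128 x 128 pixels with a 16-pixel annotation band. The two
#' classes differ in wash-in kinetics: metastatic lesions (class 1) reach
#' peak enhancement in about 11 frames after onset versus about 20 for
#' non-metastatic (class 0), and enhance more strongly.
#'
#' @param n_patients Number of patients (one video per patient).
#' @param metastatic_fraction Fraction of class-1 (metastatic) patients.
#' @param n_frames Frames per video; must be at least 11 so a +/-5 keyframe
#'   window exists.
#' @param frame_height,frame_width Frame size in pixels.
#' @param band_height Height in pixels of the bright annotation band at the
#'   top of each frame.
#' @param lesion_params List with elements `class0` and `class1`, each a list
#'   with `rate_mean`, `rate_sd` (wash-in rate per frame), `peak_mean`,
#'   `peak_sd` (8-bit intensity), `onset_mean`, `onset_sd` (frames).
#' @param noise_sigma Standard deviation of the multiplicative speckle noise;
#'   0 disables noise.
#' @param seed Integer seed; the full dataset is reproducible from it.
#' @return An object of class `ceus_config`.
#' @export
synthetic_config <- function(n_patients = 60,
                             metastatic_fraction = 0.5,
                             n_frames = 120,
                             frame_height = 128,
                             frame_width = 128,
                             band_height = 16,
                             lesion_params = default_lesion_params(),
                             noise_sigma = 0.08,
                             seed = 1L) {
  if (n_patients < 2) stop("`n_patients` must be at least 2")
  if (metastatic_fraction <= 0 || metastatic_fraction >= 1)
    stop("`metastatic_fraction` must lie in (0, 1)")
  if (n_frames < 11) stop("`n_frames` must be at least 11 to admit a +/-5 keyframe window")
  if (is.null(lesion_params$class0) || is.null(lesion_params$class1))
    stop("`lesion_params` must provide both `class0` and `class1`")
  n1 <- round(n_patients * metastatic_fraction)
  if (n1 < 1 || n1 > n_patients - 1)
    stop("class counts implied by `metastatic_fraction` leave a class empty")
  structure(list(
    n_patients = as.integer(n_patients),
    metastatic_fraction = metastatic_fraction,
    n_frames = as.integer(n_frames),
    frame_height = as.integer(frame_height),
    frame_width = as.integer(frame_width),
    band_height = as.integer(band_height),
    lesion_params = lesion_params,
    noise_sigma = noise_sigma,
    seed = as.integer(seed)
  ), class = "ceus_config")
}

#' Default class-conditional lesion kinetics
#'
#' Class 1 (metastatic): wash-in rate ~0.18/frame (time to peak ~11 frames),
#' peak ~210. Class 0 (non-metastatic): rate ~0.10/frame (time to peak ~20
#' frames), peak ~170. Onset near frame 20.
#' @return Nested list of kinetic parameters keyed by class.
#' @export
default_lesion_params <- function() {
  list(
    class0 = list(rate_mean = 0.10, rate_sd = 0.020,
                  peak_mean = 170, peak_sd = 15,
                  onset_mean = 25, onset_sd = 4),
    class1 = list(rate_mean = 0.18, rate_sd = 0.030,
                  peak_mean = 210, peak_sd = 15,
                  onset_mean = 18, onset_sd = 4)
  )
}

# Class-conditional tables for the four clinical attribute categories.
# Placeholder vocabularies with class-dependent probabilities; values are
# short phrases suitable for appending to a training text.
clinical_attribute_tables <- function() {
  list(
    "Basic clinical data" = list(
      values = c("age under 50", "age 50 or over"),
      p0 = c(0.55, 0.45), p1 = c(0.45, 0.55)),
    "Histopathological biomarkers" = list(
      values = c("low ki67 index", "high ki67 index"),
      p0 = c(0.65, 0.35), p1 = c(0.35, 0.65)),
    "Contrast-enhanced ultrasound parameters" = list(
      values = c("slow mild enhancement", "rapid intense enhancement"),
      p0 = c(0.85, 0.15), p1 = c(0.15, 0.85)),
    "Conventional ultrasound parameters" = list(
      values = c("circumscribed margin", "irregular margin"),
      p0 = c(0.70, 0.30), p1 = c(0.30, 0.70))
  )
}

# Render one noiseless frame given lesion geometry and current lesion
# intensity. The imaging region interior is black; only the annotation band
# and the lesion carry signal, so threshold-based cropping recovers the
# lesion's bounding rectangle.
render_frame <- function(h, w, band_height, region, lesion, intensity) {
  f <- matrix(0, h, w)
  if (band_height > 0) f[seq_len(band_height), ] <- 230
  if (intensity > 0) {
    ys <- region$y0:region$y1
    xs <- region$x0:region$x1
    yy <- matrix(ys, length(ys), length(xs))
    xx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
    inside <- ((xx - lesion$cx) / lesion$rx)^2 + ((yy - lesion$cy) / lesion$ry)^2 <= 1
    block <- f[ys, xs]
    block[inside] <- intensity
    f[ys, xs] <- block
  }
  f
}

#' Generate a synthetic CEUS dataset
#'
#' Produces one labelled video per patient. Each frame has a bright
#' annotation band over rows `1:band_height`, black margins, and an
#' elliptical lesion inside a central imaging region whose intensity follows
#' [enhancement_curve()] with class-conditional parameters plus multiplicative
#' speckle noise. The keyframe is the frame of maximal mean lesion intensity.
#' Clinical attribute strings are drawn from class-conditional tables.
#'
#' @param config A [synthetic_config()] object.
#' @return A list of `ceus_sample` objects, each with fields `patient_id`,
#'   `frames` (list of integer matrices in 0..255), `keyframe_index`
#'   (0-based), `class_label` (0 or 1), `clinical_attributes` (named
#'   character), and `lesion` (geometry and kinetic metadata).
#' @examples
#' ds <- generate_dataset(synthetic_config(n_patients = 4, n_frames = 60, seed = 7))
#' length(ds)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "ceus_config"))
  n <- config$n_patients
  n1 <- round(n * config$metastatic_fraction)
  labels <- c(rep(1L, n1), rep(0L, n - n1))
  set.seed(config$seed)
  labels <- sample(labels)  # interleave classes across patient ids
  h <- config$frame_height; w <- config$frame_width
  bh <- config$band_height
  # central imaging region: below the band with a black margin all round
  region <- list(y0 = bh + 9L, y1 = h - 8L, x0 = 9L, x1 = w - 8L)
  attrs <- clinical_attribute_tables()
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    lab <- labels[i]
    lp <- if (lab == 1L) config$lesion_params$class1 else config$lesion_params$class0
    rate <- max(0.02, stats::rnorm(1, lp$rate_mean, lp$rate_sd))
    peak <- min(250, max(60, stats::rnorm(1, lp$peak_mean, lp$peak_sd)))
    onset <- max(2, round(stats::rnorm(1, lp$onset_mean, lp$onset_sd)))
    cy <- round((region$y0 + region$y1) / 2 + stats::runif(1, -4, 4))
    cx <- round((region$x0 + region$x1) / 2 + stats::runif(1, -4, 4))
    ry <- round(min(26 + stats::runif(1, -3, 3), (region$y1 - region$y0) / 2 - 2))
    rx <- round(min(32 + stats::runif(1, -3, 3), (region$x1 - region$x0) / 2 - 2))
    lesion <- list(cx = cx, cy = cy, rx = rx, ry = ry,
                   rate = rate, peak = peak, onset = onset)
    curve <- enhancement_curve(seq_len(config$n_frames) - 1L, onset, rate, peak)
    ys <- region$y0:region$y1; xs <- region$x0:region$x1
    yy <- matrix(ys, length(ys), length(xs))
    xx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
    inside <- ((xx - cx) / rx)^2 + ((yy - cy) / ry)^2 <= 1
    # linear indices of the only nonzero pixels: annotation band and lesion;
    # multiplicative speckle leaves everything else at zero, so noise is
    # drawn only where it can show
    band_idx <- if (bh > 0) as.vector(outer(seq_len(bh), (seq_len(w) - 1L) * h, `+`)) else integer(0)
    les_idx <- as.vector(outer(ys, (xs - 1L) * h, `+`))[as.vector(inside)]
    sig <- config$noise_sigma
    speckle <- function(v) {
      if (sig > 0) v <- v * (1 + stats::rnorm(length(v), 0, sig))
      as.integer(pmin(pmax(round(v), 0), 255))
    }
    frames <- vector("list", config$n_frames)
    lesion_mean <- numeric(config$n_frames)
    for (t in seq_len(config$n_frames)) {
      f <- matrix(0L, h, w)
      if (length(band_idx)) f[band_idx] <- speckle(rep(230, length(band_idx)))
      if (curve[t] > 0) f[les_idx] <- speckle(rep(curve[t], length(les_idx)))
      frames[[t]] <- f
      lesion_mean[t] <- mean(f[les_idx])
    }
    keyframe <- which.max(lesion_mean) - 1L
    ca <- vapply(attrs, function(a) {
      p <- if (lab == 1L) a$p1 else a$p0
      sample(a$values, 1, prob = p)
    }, character(1))
    samples[[i]] <- structure(list(
      patient_id = sprintf("P%03d", i),
      frames = frames,
      keyframe_index = keyframe,
      class_label = lab,
      clinical_attributes = ca,
      lesion = lesion
    ), class = "ceus_sample")
  }
  samples
}

#' Write a synthetic dataset to disk
#'
#' One directory per patient with numbered PNG frames and a JSON sidecar
#' (`patient_id`, `keyframe_index`, `class_label`, `clinical_attributes`),
#' plus a top-level `manifest.csv` (patient_id, path, label).
#'
#' @param samples List of `ceus_sample` objects from [generate_dataset()].
#' @param dir Output directory, created if missing.
#' @return Invisibly, the manifest data frame.
#' @export
write_ceus_dataset <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(samples, function(s) {
    pdir <- file.path(dir, s$patient_id)
    dir.create(pdir, showWarnings = FALSE)
    for (t in seq_along(s$frames)) {
      png::writePNG(s$frames[[t]] / 255,
                    file.path(pdir, sprintf("frame_%04d.png", t - 1L)))
    }
    jsonlite::write_json(list(
      patient_id = s$patient_id,
      keyframe_index = s$keyframe_index,
      class_label = s$class_label,
      clinical_attributes = as.list(s$clinical_attributes)
    ), file.path(pdir, "sample.json"), auto_unbox = TRUE)
    data.frame(patient_id = s$patient_id, path = pdir, label = s$class_label,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset written by [write_ceus_dataset()]
#'
#' @param dir Dataset directory containing `manifest.csv`.
#' @return List of `ceus_sample` objects.
#' @export
read_ceus_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    pdir <- manifest$path[i]
    meta <- jsonlite::read_json(file.path(pdir, "sample.json"))
    files <- sort(list.files(pdir, pattern = "^frame_\\d+\\.png$", full.names = TRUE))
    frames <- lapply(files, function(f) {
      m <- png::readPNG(f)
      if (length(dim(m)) == 3L) m <- m[, , 1]
      m <- round(m * 255)
      storage.mode(m) <- "integer"
      m
    })
    structure(list(
      patient_id = meta$patient_id,
      frames = frames,
      keyframe_index = as.integer(meta$keyframe_index),
      class_label = as.integer(meta$class_label),
      clinical_attributes = unlist(meta$clinical_attributes)
    ), class = "ceus_sample")
  })
}
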