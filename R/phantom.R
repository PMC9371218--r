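#' Generate a synthetic head-CT phantom slice
#'
#' Builds an ellipse-composite head phantom: a bright skull annulus, a mid-grey
#' brain with a gentle intensity gradient, two darker ventricle ellipses, and
#' quantum-like pixel noise inside the head. The ellipse geometry is a fixed
#' function of `region_label`, so slices sharing a region are geometrically
#' similar while different regions differ visibly; the seed adds small jitter
#' (sub-pixel axis/centre perturbations) and the noise realization.
#'
#' Intensities are quantized to integers on the 0--255 scale, the scale on
#' which the pixel-graph grey-difference gate operates. Background (air) stays
#' near 0.
#'
#' @param region_label Positive integer anatomical region label. Geometry
#'   (skull axes, ventricle size and position) is a deterministic function of
#'   this label.
#' @param size Image side length in pixels (square slice), at least 32.
#'   Default 128, the working resolution of the detector.
#' @param seed Integer seed controlling jitter and noise; fixed
#'   `(region_label, size, seed)` reproduces the image bit for bit.
#' @return An integer matrix of size `size x size` with values in `[0, 255]`.
#' @seealso [apply_motion_artifact()], [generate_dataset()]
#' @examples
#' img <- generate_phantom(1, size = 64, seed = 42)
#' range(img)
#' @export
generate_phantom <- function(region_label, size = 128, seed = 0) {
  region_label <- check_count(region_label, "region_label", min = 1)
  size <- check_count(size, "size", min = 1)
  if (size < 32) stop("`size` must be at least 32", call. = FALSE)

  g3 <- (region_label - 1L) %% 3L
  g4 <- (region_label - 1L) %% 4L

  with_seed(seed, {
    jit <- stats::runif(8, -0.015, 0.015)

    a_out <- 0.70 + 0.05 * g3 + jit[1]
    b_out <- 0.92 - 0.04 * g4 + jit[2]
    thick <- 0.09
    vent_dx <- 0.13 + 0.03 * g3 + jit[3]
    vent_a <- 0.07 + 0.02 * g4 + jit[4]
    vent_b <- 0.16 - 0.02 * g3 + jit[5]
    vent_cy <- -0.08 + 0.06 * g3 + jit[6]
    cx <- jit[7]
    cy <- jit[8]

    ax <- seq(-1, 1, length.out = size)
    xn <- matrix(ax, size, size, byrow = TRUE) - cx
    yn <- matrix(ax, size, size, byrow = FALSE) - cy

    img <- matrix(0, size, size)
    in_outer <- (xn / a_out)^2 + (yn / b_out)^2 <= 1
    in_inner <- (xn / (a_out - thick))^2 + (yn / (b_out - thick))^2 <= 1
    img[in_outer & !in_inner] <- 225
    brain <- 115 + 18 * yn
    img[in_inner] <- brain[in_inner]
    vl <- ((xn + vent_dx) / vent_a)^2 + ((yn - vent_cy) / vent_b)^2 <= 1
    vr <- ((xn - vent_dx) / vent_a)^2 + ((yn - vent_cy) / vent_b)^2 <= 1
    img[(vl | vr) & in_inner] <- 60

    # quantum-like noise in tissue; faint detector noise over air
    noise <- matrix(stats::rnorm(size^2, 0, 10), size, size)
    air <- !in_outer
    noise[air] <- stats::rnorm(sum(air), 0, 1.2)
    quantize_gray(img + noise)
  })
}

# Nearest-neighbour rigid resampling (rotation theta about the image centre
# plus translation), used for motion ghost copies. Out-of-frame samples are 0.
rigid_sample <- function(img, theta, dx, dy) {
  h <- nrow(img)
  w <- ncol(img)
  cy <- (h + 1) / 2
  cx <- (w + 1) / 2
  row0 <- matrix(seq_len(h), h, w)
  col0 <- matrix(seq_len(w), h, w, byrow = TRUE)
  yr <- row0 - cy
  xc <- col0 - cx
  src_r <- round(cy + cos(theta) * yr + sin(theta) * xc - dy)
  src_c <- round(cx - sin(theta) * yr + cos(theta) * xc - dx)
  out <- matrix(0, h, w)
  ok <- src_r >= 1 & src_r <= h & src_c >= 1 & src_c <= w
  out[ok] <- img[cbind(src_r[ok], src_c[ok])]
  out
}

#' Corrupt a slice with simulated motion artifacts
#'
#' Applies an image-domain motion-artifact model combining the phenomenology
#' seen in motion-degraded CT reconstructions:
#' \describe{
#'   \item{ghosting}{a weighted blend of the slice with copies displaced by
#'     small seeded rigid motions (rotation up to ~3 degrees, shifts up to a
#'     few pixels); blend weight grows with `severity`. Averaging displaced
#'     copies also suppresses high-frequency pixel noise, the smearing effect
#'     of patient motion.}
#'   \item{streaks}{additive narrow oriented line patterns through the object.}
#'   \item{shading}{a smooth low-frequency intensity field over the slice.}
#' }
#' The output is clipped to `[0, 255]` and re-quantized; the input matrix is
#' never modified. As `severity` approaches 0 the output converges to the
#' input.
#'
#' @param image Grayscale slice, numeric matrix with values in `[0, 255]`.
#' @param severity Artifact strength in `(0, 1]`; scales ghost weight, streak
#'   amplitude and shading amplitude.
#' @param seed Integer seed; fixed `(image, severity, seed)` reproduces the
#'   corrupted slice exactly.
#' @return An integer matrix of the same dimensions, values in `[0, 255]`.
#' @examples
#' clean <- generate_phantom(1, size = 64, seed = 1)
#' bad <- apply_motion_artifact(clean, severity = 0.8, seed = 7)
#' mean(abs(bad - clean))
#' @export
apply_motion_artifact <- function(image, severity, seed = 0) {
  check_gray_image(image)
  if (!is.numeric(severity) || length(severity) != 1L || is.na(severity) ||
      severity <= 0 || severity > 1) {
    stop("`severity` must be a single value in (0, 1]", call. = FALSE)
  }
  h <- nrow(image)
  w <- ncol(image)
  img <- image
  storage.mode(img) <- "double"

  with_seed(seed, {
    # (a) ghosting: blend with 4 rigidly displaced copies; averaging the
    # displaced copies suppresses high-frequency noise, the smearing that
    # patient motion produces in the reconstruction
    n_ghost <- 4L
    ghost <- matrix(0, h, w)
    for (i in seq_len(n_ghost)) {
      theta <- stats::runif(1, -1, 1) * 0.04 * severity
      ang <- stats::runif(1, 0, 2 * pi)
      mag <- stats::runif(1, 0.5, 1 + 2.5 * severity)
      ghost <- ghost + rigid_sample(img, theta, mag * cos(ang), mag * sin(ang))
    }
    ghost <- ghost / n_ghost
    wgt <- 0.65 * severity
    out <- (1 - wgt) * img + wgt * ghost

    # (c) low-frequency shading field
    ax <- seq(-1, 1, length.out = w)
    ay <- seq(-1, 1, length.out = h)
    xn <- matrix(ax, h, w, byrow = TRUE)
    yn <- matrix(ay, h, w, byrow = FALSE)
    u <- stats::runif(2, 0.5, 1.5)
    phi <- stats::runif(1, 0, 2 * pi)
    lin <- stats::runif(2, -1, 1)
    amp_s <- 12 * severity
    out <- out + amp_s * (0.6 * sin(pi * (u[1] * xn + u[2] * yn) + phi) +
                            0.4 * (lin[1] * xn + lin[2] * yn))

    # (b) directional streaks through the object
    n_str <- sample(2:4, 1)
    sc <- (min(h, w) - 1) / 2
    for (i in seq_len(n_str)) {
      ang <- stats::runif(1, 0, pi)
      px <- stats::runif(1, -0.3, 0.3) * sc
      py <- stats::runif(1, -0.3, 0.3) * sc
      width <- stats::runif(1, 0.7, 1.5)
      amp <- sample(c(-1, 1), 1) * 20 * severity
      d <- -sin(ang) * (xn * sc - px) + cos(ang) * (yn * sc - py)
      out <- out + amp * exp(-(d / width)^2)
    }
    quantize_gray(out)
  })
}

#' Generate a labeled synthetic head-CT dataset
#'
#' Writes clean and motion-corrupted phantom slices as 8-bit grayscale PNG
#' files plus a `manifest.csv` with columns
#' `slice_id,region_label,quality_label,image_path`. Clean slices cycle
#' round-robin through regions `1..n_regions`; artifact slices cycle through
#' a weighted region pattern in which lower-numbered regions appear more
#' often, emulating the uneven regional concentration of motion-degraded
#' slices seen in clinical head-CT datasets (which is what makes the
#' artifact-class slice-level graph denser than the clean-class one).
#' Artifact severities are drawn once, per corrupted slice, from a seeded
#' uniform distribution over `severity_range`. `quality_label` is 1 for
#' slices with motion artifacts (the positive class) and 0 for clean slices.
#'
#' @param n_clean,n_artifact Number of clean / artifact slices (each >= 1).
#' @param n_regions Number of anatomical region labels, cycled `1..n_regions`.
#' @param size Slice side length in pixels (>= 32).
#' @param seed Integer master seed; everything (phantoms, severities, artifact
#'   realizations) derives from it, so equal arguments reproduce a
#'   byte-identical dataset.
#' @param out_dir Output directory, created if needed.
#' @param severity_range Length-2 numeric range in `(0, 1]` from which each
#'   artifact slice's severity is drawn; default `c(0.4, 1)` keeps artifacts
#'   visible while letting mild cases approach the clean class.
#' @return The manifest as a `data.frame` (invisibly also written to
#'   `file.path(out_dir, "manifest.csv")`).
#' @examples
#' dir <- file.path(tempdir(), "ctnet-demo")
#' man <- generate_dataset(2, 2, n_regions = 2, size = 32, seed = 1,
#'                         out_dir = dir)
#' table(man$quality_label)
#' @export
generate_dataset <- function(n_clean, n_artifact, n_regions = 3, size = 128,
                             seed = 0, out_dir,
                             severity_range = c(0.4, 1)) {
  n_clean <- check_count(n_clean, "n_clean")
  n_artifact <- check_count(n_artifact, "n_artifact")
  n_regions <- check_count(n_regions, "n_regions")
  if (missing(out_dir) || !is.character(out_dir) || length(out_dir) != 1L) {
    stop("`out_dir` must be a single directory path", call. = FALSE)
  }
  if (length(severity_range) != 2L || severity_range[1] <= 0 ||
      severity_range[2] > 1 || severity_range[1] > severity_range[2]) {
    stop("`severity_range` must be an increasing range within (0, 1]",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop(sprintf("cannot create output directory '%s'", out_dir),
         call. = FALSE)
  }

  severities <- with_seed(derive_seed(seed, 0, 1),
                          stats::runif(n_artifact, severity_range[1],
                                       severity_range[2]))

  ids <- character(0)
  regions <- integer(0)
  labels <- integer(0)
  paths <- character(0)

  emit <- function(id, img) {
    path <- file.path(out_dir, paste0(id, ".png"))
    png::writePNG(img / 255, path)
    path
  }

  for (i in seq_len(n_clean)) {
    region <- ((i - 1L) %% n_regions) + 1L
    id <- sprintf("clean_%04d", i)
    img <- generate_phantom(region, size, derive_seed(seed, i, 2))
    ids <- c(ids, id)
    regions <- c(regions, region)
    labels <- c(labels, 0L)
    paths <- c(paths, emit(id, img))
  }
  # weighted cycle, e.g. 1,1,1,2,2,3 for 3 regions: artifact slices cluster
  # in low-numbered regions, as motion-degraded slices cluster in clinical data
  artifact_pattern <- rep(seq_len(n_regions), times = n_regions:1)
  for (j in seq_len(n_artifact)) {
    region <- artifact_pattern[((j - 1L) %% length(artifact_pattern)) + 1L]
    id <- sprintf("artifact_%04d", j)
    img <- generate_phantom(region, size, derive_seed(seed, j, 3))
    img <- apply_motion_artifact(img, severities[j], derive_seed(seed, j, 4))
    ids <- c(ids, id)
    regions <- c(regions, region)
    labels <- c(labels, 1L)
    paths <- c(paths, emit(id, img))
  }

  manifest <- data.frame(slice_id = ids, region_label = regions,
                         quality_label = labels, image_path = paths,
                         stringsAsFactors = FALSE)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}
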