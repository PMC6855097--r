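# Synthetic pseudo-CT thyroid phantoms.
#
# Each phantom is a 2D grayscale slice with a butterfly-shaped gland (two
# overlapping ellipse lobes joined by an isthmus bar), Gaussian-textured
# nodules inside the gland, organ-like distractor blobs in the background,
# and additive acquisition noise.  The ground-truth mask is exactly the set
# of pixels rendered as gland.  Class-conditional cues mirror what the two
# classifier streams are meant to exploit: malignant phantoms have an
# enlarged gland (both lobe half-axes scaled, so area scales with the square
# of the factor), stronger internal texture, and a blurred gland boundary.

#' Phantom generator configuration
#'
#' @param image_size Side length in pixels (square images).
#' @param gland_axes_range Length-4 vector `c(a_min, a_max, b_min, b_max)`:
#'   ranges of the horizontal (`a`) and vertical (`b`) lobe half-axes in
#'   pixels.  Defaults scale with `image_size`.
#' @param malignant_enlargement_factor Multiplier (`>= 1`) applied to both
#'   lobe half-axes of malignant glands, so gland area scales with its
#'   square.
#' @param nodule_count_range Integer range `c(min, max)` of nodules per
#'   phantom.
#' @param benign_texture_sd,malignant_texture_sd Standard deviation
#'   (intensity units) of the Gaussian nodule texture per class; the gland
#'   parenchyma receives the same texture at half amplitude.  Must satisfy
#'   `malignant_texture_sd > benign_texture_sd`.
#' @param malignant_edge_blur_sigma Gaussian sigma (pixels) of the boundary
#'   blur applied to malignant gland edges (0 disables).
#' @param background_organ_count Number of distractor blobs outside the
#'   gland.
#' @param noise_sd Additive Gaussian noise standard deviation (intensity
#'   units).
#' @param seed Default RNG seed used when generation functions are called
#'   without one.
#' @return A `phantom_config` object.
#' @export
phantom_config <- function(image_size = 256L,
                           gland_axes_range = NULL,
                           malignant_enlargement_factor = 1.15,
                           nodule_count_range = c(1L, 3L),
                           benign_texture_sd = 6,
                           malignant_texture_sd = 18,
                           malignant_edge_blur_sigma = 2.5,
                           background_organ_count = 3L,
                           noise_sd = 4,
                           seed = 1L) {
  image_size <- as.integer(image_size)
  if (image_size <= 0) stop("image_size must be positive")
  if (is.null(gland_axes_range)) {
    gland_axes_range <- image_size * c(0.12, 0.18, 0.19, 0.27)
  }
  if (length(gland_axes_range) != 4L || any(gland_axes_range <= 0) ||
      gland_axes_range[1] > gland_axes_range[2] ||
      gland_axes_range[3] > gland_axes_range[4])
    stop("gland_axes_range must be c(a_min, a_max, b_min, b_max), positive")
  if (malignant_enlargement_factor < 1)
    stop("malignant_enlargement_factor must be >= 1")
  if (malignant_texture_sd <= benign_texture_sd)
    stop("malignant_texture_sd must exceed benign_texture_sd")
  if (noise_sd < 0 || benign_texture_sd < 0) stop("sds must be non-negative")
  nodule_count_range <- as.integer(nodule_count_range)
  if (length(nodule_count_range) != 2L || nodule_count_range[1] < 0 ||
      nodule_count_range[1] > nodule_count_range[2])
    stop("nodule_count_range must be a non-decreasing pair of counts >= 0")
  structure(
    list(image_size = image_size, gland_axes_range = gland_axes_range,
         malignant_enlargement_factor = malignant_enlargement_factor,
         nodule_count_range = nodule_count_range,
         benign_texture_sd = benign_texture_sd,
         malignant_texture_sd = malignant_texture_sd,
         malignant_edge_blur_sigma = malignant_edge_blur_sigma,
         background_organ_count = as.integer(background_organ_count),
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "phantom_config"
  )
}

# pixel-centre coordinate grids, [row, col] = [y, x]: X[y, x] = x, Y[y, x] = y
coord_grids <- function(S) {
  list(X = matrix(rep(seq_len(S), each = S), S, S),
       Y = matrix(rep(seq_len(S), times = S), S, S))
}

in_ellipse <- function(g, cx, cy, a, b) {
  ((g$X - cx) / a)^2 + ((g$Y - cy) / b)^2 <= 1
}

runif1 <- function(lo, hi) stats::runif(1, lo, hi)

#' Generate one synthetic thyroid phantom
#'
#' @param config A [phantom_config()].
#' @param label `"benign"` or `"malignant"`.
#' @param seed Integer RNG seed; identical `(config, label, seed)` give
#'   bit-identical output.  Defaults to the config's seed.
#' @return A `ct_sample` list: `image` (integer matrix in `[0, 255]`),
#'   `mask` (0/1 matrix of the gland), `label`, `patient_id`.
#' @export
generate_phantom <- function(config = phantom_config(), label = "benign",
                             seed = config$seed) {
  stopifnot(inherits(config, "phantom_config"))
  if (length(label) != 1L || !label %in% CLASS_LABELS)
    stop("label must be one of: ", paste(CLASS_LABELS, collapse = ", "))
  with_seed(seed, render_phantom(config, label, patient_id = "synthetic"))
}

render_phantom <- function(config, label, patient_id) {
  S <- config$image_size
  g <- coord_grids(S)
  malignant <- label == "malignant"
  enlarge <- if (malignant) config$malignant_enlargement_factor else 1
  ax <- config$gland_axes_range

  # gland: two lobes left/right of the midline plus an isthmus bar
  cx <- S / 2 + stats::rnorm(1, 0, 0.01 * S)
  cy <- S / 2 + stats::rnorm(1, 0, 0.02 * S)
  dx <- runif1(0.18, 0.22) * S
  a1 <- runif1(ax[1], ax[2]) * enlarge
  a2 <- runif1(ax[1], ax[2]) * enlarge
  b1 <- runif1(ax[3], ax[4]) * enlarge
  b2 <- runif1(ax[3], ax[4]) * enlarge
  mask <- in_ellipse(g, cx - dx, cy, a1, b1) |
    in_ellipse(g, cx + dx, cy, a2, b2) |
    (abs(g$Y - cy) <= 0.05 * S & abs(g$X - cx) <= dx)

  # background level and distractor load vary widely between slices, so the
  # surroundings carry no label signal and the classifiers cannot anchor on
  # a fixed background statistic
  bg_level <- 0
  gland_level <- runif1(140, 160)
  img <- matrix(bg_level, S, S)

  # organ-like distractor blobs, clipped to the background
  n_org <- sample.int(config$background_organ_count + 1L, 1L) - 1L
  for (k in seq_len(n_org)) {
    ocx <- runif1(0.1, 0.9) * S
    ocy <- runif1(0.1, 0.9) * S
    oa <- runif1(0.03, 0.12) * S
    ob <- runif1(0.03, 0.12) * S
    blob <- in_ellipse(g, ocx, ocy, oa, ob) & !mask
    img[blob] <- runif1(30, 60)
  }

  texture_sd <- if (malignant) config$malignant_texture_sd
                else config$benign_texture_sd
  img[mask] <- gland_level +
    stats::rnorm(sum(mask), 0, 0.5 * texture_sd)

  # Gaussian-textured nodule discs inside the gland
  ncr <- config$nodule_count_range
  n_nod <- if (ncr[2] > ncr[1]) sample(ncr[1]:ncr[2], 1L) else ncr[1]
  gland_idx <- which(mask)
  for (k in seq_len(n_nod)) {
    centre <- gland_idx[sample.int(length(gland_idx), 1L)]
    ncy <- (centre - 1L) %% S + 1L
    ncx <- (centre - 1L) %/% S + 1L
    r <- runif1(0.03, 0.06) * S
    disc <- in_ellipse(g, ncx, ncy, r, r) & mask
    img[disc] <- gland_level + runif1(-25, 20) +
      stats::rnorm(sum(disc), 0, texture_sd)
    if (malignant) {
      # microcalcification speckles: bright in-nodule dots, a classic
      # malignancy sign and the dominant internal-texture cue
      di <- which(disc)
      n_spk <- max(1L, round(0.08 * length(di)))
      img[di[sample.int(length(di), n_spk)]] <- runif1(200, 255)
    }
  }

  # capsule rim straddling the gland boundary: a bright fascia-like
  # interface that encodes gland size/shape on both sides of the mask edge,
  # so the cue survives both mask-restriction and thyroid removal
  rim_brush <- EBImage::makeBrush(2L * max(1L, round(0.02 * S)) + 1L,
                                  shape = "disc")
  m_img <- EBImage::Image(mask * 1)
  rim <- (as.matrix(EBImage::dilate(m_img, rim_brush)) > 0.5) &
    !(as.matrix(EBImage::erode(m_img, rim_brush)) > 0.5)
  img[rim] <- runif1(45, 65)

  # malignant boundary blur: blend a smoothed copy inside a band around the
  # gland edge; the mask itself stays crisp (it is the ground truth)
  sigma <- config$malignant_edge_blur_sigma
  # the smoothing kernel (about 6 sigma wide) must fit inside the image
  if (malignant && sigma > 0 && S > 2L * ceiling(3 * sigma) + 1L) {
    blurred <- as.matrix(EBImage::gblur(img, sigma = sigma))
    brush <- EBImage::makeBrush(2L * ceiling(sigma) + 1L, shape = "disc")
    m <- EBImage::Image(mask * 1)
    band <- as.matrix(EBImage::dilate(m, brush)) > 0.5 &
      !(as.matrix(EBImage::erode(m, brush)) > 0.5)
    img[band] <- blurred[band]
  }

  img <- img + stats::rnorm(S * S, 0, config$noise_sd)
  img <- round_half_up(pmin(pmax(img, 0), 255))
  storage.mode(img) <- "integer"
  structure(
    list(image = img, mask = mask * 1L, label = label,
         patient_id = patient_id),
    class = "ct_sample"
  )
}

#' @export
print.ct_sample <- function(x, ...) {
  cat("ct_sample:", nrow(x$image), "x", ncol(x$image),
      if (!is.null(x$mask)) sprintf("(mask area %d)", sum(x$mask)) else "(no mask)",
      "label:", if (is.null(x$label)) "<none>" else x$label,
      "patient:", x$patient_id, "\n")
  invisible(x)
}

#' Generate a patient-grouped phantom cohort
#'
#' Every image of a patient carries the same label and patient id.  The
#' number of malignant patients is `malignant_fraction * n_patients`,
#' rounded half-up.
#'
#' @param config A [phantom_config()].
#' @param n_patients Number of synthetic patients.
#' @param images_per_patient Slices per patient.
#' @param malignant_fraction Fraction of patients with malignant nodules,
#'   strictly between 0 and 1.
#' @param seed Integer RNG seed.
#' @return List with `samples` (list of `ct_sample`) and `manifest`
#'   (data.frame with columns `path`, `mask_path`, `label`, `patient_id`;
#'   paths are filled by [write_cohort()]).
#' @export
generate_cohort <- function(config = phantom_config(), n_patients,
                            images_per_patient = 1L,
                            malignant_fraction = 73 / 398,
                            seed = config$seed) {
  stopifnot(inherits(config, "phantom_config"))
  if (malignant_fraction <= 0 || malignant_fraction >= 1)
    stop("malignant_fraction must lie strictly between 0 and 1")
  n_patients <- as.integer(n_patients)
  images_per_patient <- as.integer(images_per_patient)
  if (n_patients < 1 || images_per_patient < 1)
    stop("n_patients and images_per_patient must be positive")
  n_mal <- as.integer(round_half_up(n_patients * malignant_fraction))
  with_seed(seed, {
    labels <- sample(c(rep("malignant", n_mal),
                       rep("benign", n_patients - n_mal)))
    samples <- vector("list", n_patients * images_per_patient)
    rows <- vector("list", length(samples))
    idx <- 0L
    for (p in seq_len(n_patients)) {
      pid <- sprintf("P%04d", p)
      for (j in seq_len(images_per_patient)) {
        idx <- idx + 1L
        s <- render_phantom(config, labels[p], pid)
        samples[[idx]] <- s
        rows[[idx]] <- data.frame(
          path = sprintf("%s_img%02d.png", pid, j),
          mask_path = sprintf("%s_img%02d_mask.png", pid, j),
          label = labels[p], patient_id = pid,
          stringsAsFactors = FALSE)
      }
    }
    list(samples = samples, manifest = do.call(rbind, rows))
  })
}

#' Write a cohort to disk as PNG images plus a CSV manifest
#'
#' Images are written as 8-bit grayscale PNG; masks as PNG with values
#' \{0, 255\}.  The manifest (`manifest.csv`) has columns
#' `path,mask_path,label,patient_id` with paths relative to `dir`.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$manifest
  for (i in seq_along(cohort$samples)) {
    s <- cohort$samples[[i]]
    write_gray_png(s$image, file.path(dir, man$path[i]))
    write_gray_png(s$mask * 255L, file.path(dir, man$mask_path[i]))
  }
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(man, mp, row.names = FALSE, quote = FALSE)
  invisible(mp)
}
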