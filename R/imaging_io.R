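# Image/mask/manifest I/O and window-level normalisation.
#
# All images are integer matrices in [0, 255], row-major display convention
# (origin top-left); masks are 0/1 matrices.  On disk masks use {0, 255} and
# are thresholded at 128 on load, so they survive lossy viewing tools.

#' Window setting for intensity normalisation
#'
#' @param center Window centre (level), in raw intensity units.
#' @param width Window width, `> 0`.
#' @return A `window_setting` object.
#' @export
window_setting <- function(center, width) {
  if (width <= 0) stop("window width must be positive")
  structure(list(center = center, width = width), class = "window_setting")
}

#' Window-level normalisation of raw intensities to 8-bit grayscale
#'
#' Linearly maps `[center - width/2, center + width/2]` onto `[0, 255]`,
#' clips outside the window, and rounds half-up to integers.
#'
#' @param raw Numeric matrix (or vector) of raw intensities.
#' @param window A [window_setting()].
#' @return Integer matrix (same shape) with values in `[0, 255]`.
#' @export
window_normalize <- function(raw, window) {
  stopifnot(inherits(window, "window_setting"))
  lo <- window$center - window$width / 2
  g <- (raw - lo) / window$width * 255
  out <- round_half_up(pmin(pmax(g, 0), 255))
  storage.mode(out) <- "integer"
  out
}

check_mask <- function(image, mask) {
  if (!all(dim(image) == dim(mask)))
    stop("image is ", paste(dim(image), collapse = "x"), " but mask is ",
         paste(dim(mask), collapse = "x"))
  if (!all(mask %in% c(0, 1))) stop("mask must be binary (0/1)")
}

#' Restrict an image to a mask (ROI image)
#'
#' Keeps in-mask pixels and zeroes the rest; [remove_region()] is the
#' complement (zeroes in-mask pixels).  For any binary mask the two outputs
#' sum pixelwise to the original image.
#'
#' @param image Grayscale image matrix.
#' @param mask Binary mask of identical dimensions.
#' @return Image matrix of the same shape and storage mode.
#' @export
apply_mask <- function(image, mask) {
  check_mask(image, mask)
  out <- image * (mask == 1)
  storage.mode(out) <- storage.mode(image)
  out
}

#' @rdname apply_mask
#' @export
remove_region <- function(image, mask) {
  check_mask(image, mask)
  out <- image * (mask == 0)
  storage.mode(out) <- storage.mode(image)
  out
}

as_mat <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  if (length(dim(x)) > 2L) x <- x[, , 1L]
  x
}

#' Read a grayscale image from PNG or JPEG
#'
#' @param path File path.
#' @return Integer matrix with values in `[0, 255]` (rows = image rows).
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  im <- EBImage::readImage(path)
  # EBImage stores x (columns) as the first dimension
  m <- t(as_mat(im))
  out <- round_half_up(m * 255)
  storage.mode(out) <- "integer"
  out
}

#' @rdname read_gray_image
#' @param image Integer matrix in `[0, 255]`.
#' @export
write_gray_png <- function(image, path) {
  m <- t(pmin(pmax(image, 0), 255) / 255)
  EBImage::writeImage(EBImage::Image(m), path, type = "png")
  invisible(path)
}

#' Read a binary mask image
#'
#' On-disk masks use \{0, 255\}; values are thresholded at 128.
#'
#' @param path File path.
#' @return 0/1 integer matrix.
#' @export
read_mask <- function(path) {
  m <- read_gray_image(path)
  out <- (m >= 128) * 1L
  out
}

#' Load a cohort manifest and its images
#'
#' Reads a CSV manifest with columns `path`, `mask_path`, `label`,
#' `patient_id` (paths relative to the manifest's directory; `mask_path` and
#' `label` may be empty) and returns the corresponding samples.
#'
#' @param path Manifest CSV path.
#' @return List of `ct_sample` objects.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("no such manifest: ", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "patient_id")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(path)
  lapply(seq_len(nrow(man)), function(i) {
    mask <- NULL
    if (!is.null(man$mask_path) && !is.na(man$mask_path[i]) &&
        nzchar(man$mask_path[i]))
      mask <- read_mask(file.path(base, man$mask_path[i]))
    label <- NULL
    if (!is.null(man$label) && !is.na(man$label[i]) && nzchar(man$label[i]))
      label <- man$label[i]
    img <- read_gray_image(file.path(base, man$path[i]))
    if (!is.null(mask) && !all(dim(img) == dim(mask)))
      stop("image/mask dimension mismatch for ", man$path[i])
    structure(list(image = img, mask = mask, label = label,
                   patient_id = as.character(man$patient_id[i])),
              class = "ct_sample")
  })
}
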