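#' Binarize the superficial angiogram into a vessel mask
#'
#' Second quantification step, part one: the en-face OCTA image of the
#' superficial vascular slab is binarized with the same automatic global
#' threshold used for foci, yielding the vessel raster whose flow signal is
#' duplicated onto deeper hyperreflective material (the projection
#' artifact).
#'
#' @param superficial_angio an [extract_slab()] of the decorrelation channel
#'   with the superficial preset, or a bare matrix.
#' @param method `"isodata"` (default) or `"otsu"`.
#' @return A [binary_mask()] of vessel pixels.
#' @export
vessel_mask <- function(superficial_angio, method = c("isodata", "otsu")) {
  method <- match.arg(method)
  m <- global_threshold(superficial_angio, method)
  m$source <- "superficial angiogram"
  m
}

# dilate a logical matrix by a disc of the given pixel radius
dilate_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  r <- as.integer(ceiling(radius))
  out <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  for (dx in -r:r) for (dy in -r:r) {
    if (dx == 0 && dy == 0) next
    if (dx^2 + dy^2 > radius^2) next
    si <- max(1, 1 - dx):min(nr, nr - dx)
    sj <- max(1, 1 - dy):min(nc, nc - dy)
    out[si + dx, sj + dy] <- out[si + dx, sj + dy] | mask[si, sj]
  }
  out
}

#' Remove superficial-vessel projection from a foci mask
#'
#' Second quantification step, part two: retain only the foci pixels that do
#' not fall under superficial vessels. The composition of gradation
#' inversion of the vessel image with pixelwise conjunction reduces to the
#' set difference `foci AND NOT vessels`; an optional dilation of the vessel
#' mask widens the exclusion zone for projection tails broader than the
#' vessel caliber (default off).
#'
#' @param foci a [binary_mask()] of hyperreflective foci (structural slab).
#' @param vessels a [binary_mask()] of superficial vessels.
#' @param vessel_dilation_px dilation radius for the vessel mask in pixels
#'   (default 0, no dilation).
#' @return A [binary_mask()] of retained foci pixels (`method =
#'   "difference"`).
#' @export
remove_projection <- function(foci, vessels, vessel_dilation_px = 0) {
  stopifnot(inherits(foci, "binary_mask"), inherits(vessels, "binary_mask"))
  if (!identical(dim(foci$mask), dim(vessels$mask)))
    stop("foci and vessel masks differ in dimensions")
  excl <- dilate_mask(vessels$mask, vessel_dilation_px)
  binary_mask(foci$mask & !excl, "difference", NA_integer_,
              source = sprintf("%s minus %s", foci$source, vessels$source))
}

#' Decorrelation signal intensity over retained foci pixels
#'
#' Third quantification step: read the decorrelation grayscale of the HFL
#' OCTA slab at every retained foci pixel, accumulate the 256-bin grayscale
#' histogram, and return its mean — the decorrelation signal intensity of
#' the hyperreflective foci, the per-eye headline statistic. Eyes whose
#' retained mask is empty are an error (the caller flags the eye rather than
#' scoring it 0).
#'
#' @param angio_hfl an [extract_slab()] of the decorrelation channel with
#'   the HFL preset, or a bare matrix in `[0, 255]`.
#' @param retained a [binary_mask()] of foci pixels after projection
#'   removal.
#' @return An object of class `foci_decorrelation_result`: `intensity`
#'   (mean grayscale), `n_pixels`, `histogram` (counts for levels 0..255),
#'   and mask provenance.
#' @export
decorrelation_intensity <- function(angio_hfl, retained) {
  stopifnot(inherits(retained, "binary_mask"))
  img <- if (inherits(angio_hfl, "en_face_slab")) angio_hfl$image else angio_hfl
  if (!identical(dim(img), dim(retained$mask)))
    stop("slab and mask differ in dimensions")
  if (!any(retained$mask))
    stop("no foci pixels after projection removal")
  levels <- quantize255(img[retained$mask])
  h <- tabulate(levels + 1L, 256L)
  structure(
    list(intensity = sum((0:255) * h) / sum(h),
         n_pixels = as.integer(sum(h)),
         histogram = h,
         provenance = list(foci = retained$source)),
    class = "foci_decorrelation_result")
}

#' @export
print.foci_decorrelation_result <- function(x, ...) {
  cat(sprintf("decorrelation signal intensity: %.2f over %d foci pixels\n",
              x$intensity, x$n_pixels))
  invisible(x)
}

#' Display-oriented projection subtraction
#'
#' Pixelwise subtraction of the superficial angiogram from the HFL
#' angiogram, clipped at zero — the display route for projection-artifact
#' suppression. The quantification path uses [remove_projection()] (mask
#' algebra); this utility only produces a cleaned image for inspection.
#'
#' @param angio_hfl,superficial_angio slabs or matrices in `[0, 255]`.
#' @return A numeric matrix in `[0, 255]`.
#' @export
subtract_projection_image <- function(angio_hfl, superficial_angio) {
  a <- if (inherits(angio_hfl, "en_face_slab")) angio_hfl$image else angio_hfl
  b <- if (inherits(superficial_angio, "en_face_slab"))
    superficial_angio$image else superficial_angio
  if (!identical(dim(a), dim(b))) stop("images differ in dimensions")
  pmax(a - b, 0)
}
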