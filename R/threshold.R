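#' Binary mask container
#'
#' @param mask logical matrix.
#' @param method one of `"isodata"`, `"otsu"`, `"manual"`, `"difference"`.
#' @param threshold integer grayscale threshold, or `NA` for manual masks.
#' @param source provenance string (slab/source description).
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(mask, method, threshold = NA_integer_,
                        source = "unknown") {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!is.na(threshold) && (threshold < 0 || threshold > 255))
    stop("threshold must lie in [0, 255]")
  structure(list(mask = mask, method = method,
                 threshold = threshold, source = source),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask (%s%s): %d x %d px, %d foreground\n",
              x$method,
              if (is.na(x$threshold)) "" else sprintf(", t=%d", x$threshold),
              nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}

# 256-bin histogram of integer grayscale levels 0..255
hist256 <- function(image) {
  tabulate(quantize255(image) + 1L, nbins = 256L)
}

#' Automatic global threshold of a 256-bin histogram
#'
#' Computes a global threshold from an 8-bit grayscale histogram. Pixels at
#' levels strictly above the returned threshold are foreground; ties go to
#' the background.
#'
#' \describe{
#'   \item{`"isodata"`}{Ridler–Calvard iterative intermeans, the default
#'     auto-threshold of ImageJ: the threshold `t` is a fixed point of
#'     `t = floor((mean of levels <= t + mean of levels > t) / 2)`.
#'     Iteration starts at the midpoint of the occupied range.}
#'   \item{`"otsu"`}{Exhaustive maximization of the between-class variance
#'     `w0 * w1 * (mu0 - mu1)^2` over all 255 candidate splits; the lowest
#'     maximizing level is returned on ties.}
#' }
#'
#' @param counts integer vector of length 256, counts for levels 0..255.
#' @param method `"isodata"` (default) or `"otsu"`.
#' @return Integer threshold level in 0..254.
#' @export
threshold_histogram <- function(counts, method = c("isodata", "otsu")) {
  method <- match.arg(method)
  if (length(counts) != 256L || any(counts < 0))
    stop("'counts' must be 256 non-negative counts")
  counts <- as.double(counts)   # guard the cumulative sums against overflow
  levels <- 0:255
  occupied <- which(counts > 0) - 1L
  if (length(occupied) < 2L)
    stop("no threshold separates a constant image")
  if (method == "isodata") {
    lo <- occupied[1]; hi <- occupied[length(occupied)]
    t <- floor((lo + hi) / 2)
    t <- max(t, lo)           # keep both classes non-empty
    seen <- integer(0)
    repeat {
      below <- levels <= t
      mb <- sum(levels[below] * counts[below]) / sum(counts[below])
      ma <- sum(levels[!below] * counts[!below]) / sum(counts[!below])
      tn <- floor((mb + ma) / 2)
      tn <- min(max(tn, lo), hi - 1L)
      if (tn == t) return(as.integer(t))
      if (tn %in% seen) return(as.integer(tn))  # cycle guard
      seen <- c(seen, t)
      t <- tn
    }
  } else {
    n <- sum(counts)
    w0 <- cumsum(counts)[1:255]
    m0 <- cumsum(levels * counts)[1:255]
    mt <- sum(levels * counts)
    valid <- w0 > 0 & w0 < n
    sigma_b <- rep(-Inf, 255)
    sigma_b[valid] <- (mt * w0[valid] / n - m0[valid])^2 /
      (w0[valid] / n * (n - w0[valid]))
    as.integer(which.max(sigma_b) - 1L)
  }
}

#' Segment hyperreflective foci by automatic global thresholding
#'
#' Applies [threshold_histogram()] to the 8-bit histogram of an en-face slab
#' and returns the mask of pixels whose quantized grayscale level is
#' strictly above the threshold. This is the first quantification step:
#' confluent hyperreflective foci are much brighter than the slab background,
#' so a single global threshold separates them.
#'
#' @param image an [extract_slab()] result, or a bare numeric matrix in
#'   `[0, 255]`.
#' @param method `"isodata"` (default) or `"otsu"`.
#' @param min_component_px optional minimum connected-component size
#'   (4-connectivity); components smaller than this are dropped. Default 0
#'   (no morphological cleanup).
#' @return A [binary_mask()] recording the method and threshold used.
#' @export
global_threshold <- function(image, method = c("isodata", "otsu"),
                             min_component_px = 0L) {
  method <- match.arg(method)
  src <- "matrix"
  if (inherits(image, "en_face_slab")) {
    src <- paste0(image$source, " slab")
    image <- image$image
  }
  lev <- matrix(quantize255(image), nrow(image), ncol(image))
  t <- threshold_histogram(tabulate(lev + 1L, 256L), method)
  mask <- lev > t
  if (min_component_px > 0L)
    mask <- drop_small_components(mask, min_component_px)
  binary_mask(mask, method, t, src)
}

# 4-connected component labelling (iterative flood fill, no recursion)
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  current <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    current <- current + 1L
    queue <- start
    lab[start] <- current
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      i <- (p - 1L) %% nr + 1L
      j <- (p - 1L) %/% nr + 1L
      for (q in c(if (i > 1) p - 1L, if (i < nr) p + 1L,
                  if (j > 1) p - nr, if (j < nc) p + nr)) {
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- current
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

drop_small_components <- function(mask, min_px) {
  lab <- label_components(mask)
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_px)
  lab %in% keep & mask
}

#' Foci area from a binary mask
#'
#' @param mask a [binary_mask()] or logical matrix.
#' @param pixel_size area of one pixel in square micrometres.
#' @return List with `pixels` (exact integer count) and `area_um2`.
#' @export
foci_area <- function(mask, pixel_size) {
  if (inherits(mask, "binary_mask")) mask <- mask$mask
  n <- sum(mask)
  list(pixels = as.integer(n), area_um2 = n * pixel_size)
}

#' Read a manually traced mask from an image file
#'
#' Manual tracings (e.g. freehand selections exported as a binary image) are
#' ingested as masks: any nonzero pixel is foreground. The file must match
#' the dimensions of the slab it annotates.
#'
#' @param path a TIFF or PNG file, 1-bit or 8-bit.
#' @param dim expected `c(ny, nx)`; checked when supplied.
#' @return A [binary_mask()] with `method = "manual"`, no threshold.
#' @export
ingest_manual_mask <- function(path, dim = NULL) {
  img <- read_image_file(path)
  if (!is.null(dim) && !identical(base::dim(img), as.integer(dim)))
    stop(sprintf("mask dimensions %d x %d do not match expected %d x %d",
                 nrow(img), ncol(img), dim[1], dim[2]))
  binary_mask(img > 0, "manual", NA_integer_, source = basename(path))
}
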