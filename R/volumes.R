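#' Paired structural / decorrelation volume
#'
#' Container for a co-registered pair of 3-D grayscale volumes: a structural
#' OCT reflectance volume and an OCTA decorrelation volume, sharing one voxel
#' geometry. Volumes are numeric arrays with dimensions `c(ny, nx, nz)`;
#' values live on the 8-bit grayscale scale `[0, 255]`. Voxel `k` along the
#' axial (depth) axis spans the half-open depth interval
#' `[(k-1) * axial_step, k * axial_step)` micrometres, measured from the top
#' of the volume toward Bruch's membrane.
#'
#' @param structural numeric 3-D array `c(ny, nx, nz)` in `[0, 255]`.
#' @param decorrelation numeric 3-D array with identical dimensions.
#' @param axial_step axial voxel size in micrometres.
#' @param lateral_step lateral pixel size in micrometres.
#' @param id optional volume identifier used in provenance records.
#' @return An object of class `paired_volume`.
#' @export
paired_volume <- function(structural, decorrelation, axial_step, lateral_step,
                          id = "volume") {
  if (!is.array(structural) || length(dim(structural)) != 3L)
    stop("'structural' must be a 3-D array")
  if (!identical(dim(structural), dim(decorrelation)))
    stop("structural and decorrelation volumes must share dimensions")
  if (axial_step <= 0 || lateral_step <= 0)
    stop("voxel sizes must be positive")
  rng <- range(structural, decorrelation)
  if (rng[1] < 0 || rng[2] > 255)
    stop("volume values must lie in [0, 255]")
  structure(
    list(structural = structural, decorrelation = decorrelation,
         axial_step = axial_step, lateral_step = lateral_step, id = id),
    class = "paired_volume")
}

#' @export
print.paired_volume <- function(x, ...) {
  d <- dim(x$structural)
  cat(sprintf(
    "paired_volume '%s': %d x %d A-scans x %d depths (%.1f um/px lateral, %g um axial)\n",
    x$id, d[1], d[2], d[3], x$lateral_step, x$axial_step))
  invisible(x)
}

#' Retinal boundary surface set
#'
#' Holds the three reference surfaces used for en-face slab definition: the
#' internal limiting membrane (ILM), the posterior IPL/INL boundary, and
#' Bruch's membrane (BM). Each surface is a `ny x nx` matrix of depths in
#' micrometres from the volume top, one value per A-scan. Surfaces must be
#' strictly ordered ILM < IPL < BM at every lateral position and contain no
#' missing values.
#'
#' @param ilm,ipl,bm numeric matrices of depths (micrometres), same dims.
#' @param lateral_step lateral pixel size in micrometres.
#' @return An object of class `boundary_surfaces`.
#' @export
boundary_surfaces <- function(ilm, ipl, bm, lateral_step) {
  if (!identical(dim(ilm), dim(ipl)) || !identical(dim(ilm), dim(bm)))
    stop("surfaces must share dimensions")
  if (anyNA(ilm) || anyNA(ipl) || anyNA(bm))
    stop("surfaces must not contain missing values")
  if (any(ilm <= 0))
    stop("ILM depth must be positive everywhere")
  bad <- which(!(ilm < ipl & ipl < bm), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf(
      "crossed surfaces (need ILM < IPL < BM) at %d A-scan(s), first at (%d, %d)",
      nrow(bad), bad[1, 1], bad[1, 2]))
  structure(list(ilm = ilm, ipl = ipl, bm = bm, lateral_step = lateral_step),
            class = "boundary_surfaces")
}

#' @export
print.boundary_surfaces <- function(x, ...) {
  cat(sprintf(
    "boundary_surfaces: %d x %d A-scans; ILM %.0f-%.0f, IPL %.0f-%.0f, BM %.0f-%.0f um\n",
    nrow(x$ilm), ncol(x$ilm), min(x$ilm), max(x$ilm),
    min(x$ipl), max(x$ipl), min(x$bm), max(x$bm)))
  invisible(x)
}

#' Locate the foveal center from boundary surfaces
#'
#' The foveal pit is detected as the lateral position minimizing the
#' inner-retinal thickness (IPL depth minus ILM depth). An explicit center
#' can always be supplied to the consumers instead.
#'
#' @param surfaces a [boundary_surfaces()] object.
#' @return Integer vector `c(row, col)` of the pit position.
#' @export
find_fovea <- function(surfaces) {
  stopifnot(inherits(surfaces, "boundary_surfaces"))
  idx <- arrayInd(which.min(surfaces$ipl - surfaces$ilm), dim(surfaces$ilm))
  c(row = idx[1, 1], col = idx[1, 2])
}
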