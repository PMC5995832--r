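#' En-face slab specification
#'
#' A slab is the sub-volume between two offset copies of named reference
#' surfaces. Offsets are signed micrometres along the depth axis, positive
#' toward Bruch's membrane, so "91 um above Bruch's membrane" is written as
#' `outer_reference = "bm", outer_offset = -91`. The inner boundary must lie
#' strictly above the outer boundary at every A-scan. Most slabs use one
#' reference twice; the superficial vascular slab spans ILM to IPL.
#'
#' @param inner_reference,outer_reference one of `"ilm"`, `"ipl"`, `"bm"`.
#' @param inner_offset,outer_offset signed offsets in micrometres.
#' @param projection per-A-scan aggregation statistic, `"mean"` or `"max"`.
#' @return An object of class `slab_spec`.
#' @seealso [slab_preset()] for the named presets used throughout.
#' @export
slab_spec <- function(inner_reference, inner_offset,
                      outer_reference = inner_reference, outer_offset,
                      projection = c("mean", "max")) {
  inner_reference <- match.arg(inner_reference, c("ilm", "ipl", "bm"))
  outer_reference <- match.arg(outer_reference, c("ilm", "ipl", "bm"))
  projection <- match.arg(projection)
  structure(
    list(inner_reference = inner_reference, inner_offset = inner_offset,
         outer_reference = outer_reference, outer_offset = outer_offset,
         projection = projection),
    class = "slab_spec")
}

#' Named slab presets
#'
#' The three slabs of the quantification procedure:
#' \describe{
#'   \item{`"superficial"`}{ILM + 3 um to IPL + 15 um — the superficial
#'     vascular plexus slab used to detect vessels.}
#'   \item{`"inl"`}{IPL + 38 um to IPL + 47 um — a 9 um slab at the center
#'     of the inner nuclear layer.}
#'   \item{`"hfl"`}{BM - 100 um to BM - 91 um — a 9 um slab within Henle's
#'     fiber layer, referenced upward from Bruch's membrane.}
#' }
#'
#' @param name preset name.
#' @param projection aggregation statistic; defaults to `"mean"`.
#' @return A [slab_spec()].
#' @export
slab_preset <- function(name = c("superficial", "inl", "hfl"),
                        projection = c("mean", "max")) {
  name <- match.arg(name)
  projection <- match.arg(projection)
  switch(name,
    superficial = slab_spec("ilm", 3, "ipl", 15, projection = projection),
    inl = slab_spec("ipl", 38, "ipl", 47, projection = projection),
    hfl = slab_spec("bm", -100, "bm", -91, projection = projection))
}

# Axial voxel rows (1-based) overlapping the half-open depth interval
# [inner_um, outer_um) for voxels spanning [(k-1)*step, k*step).
slab_rows <- function(inner_um, outer_um, axial_step) {
  if (inner_um >= outer_um) stop("inner boundary must lie above outer boundary")
  i0 <- floor(inner_um / axial_step)
  i1 <- ceiling(outer_um / axial_step) - 1
  seq.int(i0 + 1L, i1 + 1L)
}

surface_depth <- function(surfaces, ref) {
  switch(ref, ilm = surfaces$ilm, ipl = surfaces$ipl, bm = surfaces$bm)
}

#' Extract an en-face slab from a volume channel
#'
#' Projects the voxels between the slab's micrometre-defined boundaries onto
#' a 2-D en-face image, one value per A-scan. At each lateral position the
#' boundary depths are `reference + offset` micrometres; voxels overlapping
#' the half-open depth interval (floor/ceiling rounding of the endpoints to
#' voxel rows) are aggregated by the spec's projection statistic. The
#' precondition that the slab stays inside the volume guarantees at least
#' one voxel per A-scan.
#'
#' @param volume a [paired_volume()] (select with `channel`) or a bare 3-D
#'   array in `[0, 255]`.
#' @param surfaces a [boundary_surfaces()] matching the lateral grid.
#' @param spec a [slab_spec()].
#' @param channel `"structural"` or `"decorrelation"` when `volume` is a
#'   [paired_volume()].
#' @param axial_step axial voxel size in micrometres; taken from the
#'   [paired_volume()] when available.
#' @return An object of class `en_face_slab` with fields `image` (`ny x nx`
#'   matrix in `[0, 255]`), `spec`, `source`, `lateral_step`, `provenance`.
#' @export
extract_slab <- function(volume, surfaces, spec,
                         channel = c("structural", "decorrelation"),
                         axial_step = NULL) {
  stopifnot(inherits(surfaces, "boundary_surfaces"), inherits(spec, "slab_spec"))
  channel <- match.arg(channel)
  if (inherits(volume, "paired_volume")) {
    arr <- volume[[channel]]
    axial_step <- volume$axial_step
    vol_id <- volume$id
  } else {
    arr <- volume
    vol_id <- "array"
    if (is.null(axial_step)) stop("'axial_step' required for bare arrays")
  }
  d <- dim(arr)
  if (!identical(d[1:2], dim(surfaces$ilm)))
    stop("surfaces do not match the lateral grid of the volume")

  inner <- surface_depth(surfaces, spec$inner_reference) + spec$inner_offset
  outer <- surface_depth(surfaces, spec$outer_reference) + spec$outer_offset
  if (any(inner >= outer)) {
    bad <- which(inner >= outer, arr.ind = TRUE)
    stop(sprintf("slab boundaries cross at %d A-scan(s), first at (%d, %d)",
                 nrow(bad), bad[1, 1], bad[1, 2]))
  }
  r0 <- floor(inner / axial_step) + 1
  r1 <- ceiling(outer / axial_step)
  if (any(r0 < 1) || any(r1 > d[3])) {
    bad <- which(r0 < 1 | r1 > d[3], arr.ind = TRUE)
    stop(sprintf("slab exits volume bounds at %d A-scan(s), first at (%d, %d)",
                 nrow(bad), bad[1, 1], bad[1, 2]))
  }

  img <- matrix(0, d[1], d[2])
  fun <- if (spec$projection == "mean") mean else max
  # group A-scans by identical row ranges so flat surfaces vectorize
  key <- paste(r0, r1)
  for (k in unique(key)) {
    sel <- key == k
    rows <- seq.int(r0[which(sel)[1]], r1[which(sel)[1]])
    flat <- matrix(arr[, , rows, drop = FALSE], nrow = d[1] * d[2])[sel, , drop = FALSE]
    img[sel] <- apply(flat, 1, fun)
  }

  structure(
    list(image = img, spec = spec, source = channel,
         lateral_step = surfaces$lateral_step,
         provenance = list(volume = vol_id, axial_step = axial_step)),
    class = "en_face_slab")
}

#' @export
print.en_face_slab <- function(x, ...) {
  cat(sprintf(
    "en_face_slab (%s, %s projection): %d x %d px, range %.1f-%.1f\n",
    x$source, x$spec$projection, nrow(x$image), ncol(x$image),
    min(x$image), max(x$image)))
  invisible(x)
}

#' Central subfield (CSF) thickness
#'
#' Mean full retinal thickness (Bruch's membrane depth minus ILM depth) over
#' the lateral pixels whose centers lie within a disc centered on the fovea,
#' by default the central 1 mm circle. Pixel-center inclusion: pixel (i, j)
#' is included when the Euclidean distance between its center and the center
#' pixel of the disc is at most `diameter / 2`.
#'
#' @param surfaces a [boundary_surfaces()].
#' @param fovea_center integer `c(row, col)`; defaults to [find_fovea()].
#' @param diameter disc diameter in micrometres (default 1000).
#' @return Mean thickness in micrometres (scalar).
#' @export
compute_csf_thickness <- function(surfaces, fovea_center = NULL,
                                  diameter = 1000) {
  stopifnot(inherits(surfaces, "boundary_surfaces"))
  if (is.null(fovea_center)) fovea_center <- find_fovea(surfaces)
  d <- dim(surfaces$ilm)
  step <- surfaces$lateral_step
  radius <- diameter / 2
  off <- floor(radius / step)   # furthest pixel offset that can be included
  if (fovea_center[1] - off < 1 || fovea_center[1] + off > d[1] ||
      fovea_center[2] - off < 1 || fovea_center[2] + off > d[2])
    stop("the measurement disc exceeds the lateral field")
  ii <- matrix(seq_len(d[1]), d[1], d[2])
  jj <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  dist <- step * sqrt((ii - fovea_center[1])^2 + (jj - fovea_center[2])^2)
  inside <- dist <= radius
  mean((surfaces$bm - surfaces$ilm)[inside])
}
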