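#' Write a 3-D volume as a multi-page 8-bit TIFF
#'
#' Pages run along the axial (depth) axis; grayscale values are stored as
#' 8-bit samples, so non-integer values are rounded on write.
#'
#' @param volume numeric 3-D array in `[0, 255]`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(volume, path) {
  stopifnot(is.array(volume), length(dim(volume)) == 3L)
  pages <- lapply(seq_len(dim(volume)[3]),
                  function(k) quantize255(volume[, , k]) / 255)
  pages <- lapply(pages, function(p) matrix(p, dim(volume)[1], dim(volume)[2]))
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a multi-page TIFF as a 3-D grayscale volume
#'
#' @param path a multi-page TIFF; RGB pages are converted to grayscale by
#'   channel averaging.
#' @return numeric array `c(ny, nx, nz)` with values in `[0, 255]`.
#' @export
read_volume_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- apply(p, c(1, 2), mean)
    round(p * 255)
  })
  array(unlist(pages), c(dim(pages[[1]]), length(pages)))
}

# read a single-page TIFF or PNG as a grayscale matrix in [0, 255]
read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop(sprintf("unsupported image format '%s'", ext)))
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  round(img * 255)
}

#' Write a binary mask or en-face slab as an 8-bit image
#'
#' Masks are stored with foreground 255 and background 0; slabs keep their
#' grayscale. Readers treat any nonzero pixel as foreground, so mask
#' round-trips are exact.
#'
#' @param x a [binary_mask()], [extract_slab()] result, or numeric matrix
#'   in `[0, 255]`.
#' @param path output file (`.tif`/`.tiff` or `.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  img <- if (inherits(x, "binary_mask")) x$mask * 255
  else if (inherits(x, "en_face_slab")) x$image
  else x
  img <- matrix(quantize255(img) / 255, nrow(img), ncol(img))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    png = png::writePNG(img, path),
    stop(sprintf("unsupported image format '%s'", ext)))
  invisible(path)
}

#' Write boundary surfaces as a long-format CSV
#'
#' Columns `row`, `col`, `surface` (`ilm`/`ipl`/`bm`), `depth_um`. The
#' lateral pixel size is recorded in a header comment line.
#'
#' @param surfaces a [boundary_surfaces()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_surfaces_csv <- function(surfaces, path) {
  stopifnot(inherits(surfaces, "boundary_surfaces"))
  d <- dim(surfaces$ilm)
  grid <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  long <- do.call(rbind, lapply(c("ilm", "ipl", "bm"), function(sfc)
    cbind(grid, surface = sfc, depth_um = as.vector(surfaces[[sfc]]))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# lateral_step_um=%.6f", surfaces$lateral_step), con)
  write.csv(long, con, row.names = FALSE)
  invisible(path)
}

#' Read boundary surfaces from a long-format CSV
#'
#' @param path CSV written by [write_surfaces_csv()] (or matching its
#'   layout); the lateral pixel size comes from the header comment or the
#'   `lateral_step` argument.
#' @param lateral_step lateral pixel size in micrometres, overriding the
#'   header.
#' @return A [boundary_surfaces()].
#' @export
read_surfaces_csv <- function(path, lateral_step = NULL) {
  first <- readLines(path, n = 1)
  if (grepl("^# lateral_step_um=", first) && is.null(lateral_step))
    lateral_step <- as.numeric(sub("^# lateral_step_um=", "", first))
  if (is.null(lateral_step))
    stop("lateral_step not in file header; supply it explicitly")
  long <- read.csv(path, comment.char = "#")
  d <- c(max(long$row), max(long$col))
  grab <- function(sfc) {
    sub <- long[long$surface == sfc, ]
    m <- matrix(NA_real_, d[1], d[2])
    m[cbind(sub$row, sub$col)] <- sub$depth_um
    m
  }
  boundary_surfaces(grab("ilm"), grab("ipl"), grab("bm"), lateral_step)
}

#' Write or read a cohort table as CSV
#'
#' @param cohort a cohort table (data.frame).
#' @param path CSV file.
#' @return `write_cohort_csv`: `path` invisibly; `read_cohort_csv`: a
#'   `cohort_table`.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  if ("dr_grade" %in% names(out))
    out$dr_grade <- factor(out$dr_grade,
                           levels = c("mild NPDR", "moderate NPDR",
                                      "severe NPDR", "PDR"))
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Write or read a configuration as YAML
#'
#' Serializes [phantom_config()] / [cohort_config()] objects (or any named
#' list) to a YAML key-value file and back.
#'
#' @param config configuration object or named list.
#' @param path YAML file.
#' @param type on read: `"phantom"`, `"cohort"`, or `"list"` (raw).
#' @return `write_config_yaml`: `path` invisibly; `read_config_yaml`: the
#'   reconstructed configuration.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path, type = c("list", "phantom", "cohort")) {
  type <- match.arg(type)
  raw <- yaml::read_yaml(path)
  switch(type,
    list = raw,
    phantom = do.call(phantom_config, raw[names(raw) %in%
                                            names(formals(phantom_config))]),
    cohort = do.call(cohort_config, raw[names(raw) %in%
                                          names(formals(cohort_config))]))
}

#' Write a volume as NIfTI
#'
#' Optional NIfTI route for the paired volumes (requires the RNifti
#' package).
#'
#' @param volume numeric 3-D array in `[0, 255]`.
#' @param path output `.nii` / `.nii.gz` file.
#' @param voxel_dims voxel sizes `c(y, x, z)` in micrometres, recorded as
#'   millimetres in the header.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(volume, path, voxel_dims = c(1, 1, 1)) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("the RNifti package is required for NIfTI output")
  img <- RNifti::asNifti(volume, pixdim = voxel_dims / 1000)
  RNifti::writeNifti(img, path)
  invisible(path)
}
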