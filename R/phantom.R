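#' Phantom configuration
#'
#' Parameters of the synthetic paired-volume phantom: a 3 x 3 mm macular
#' scan with a layered reflectance background, a smooth foveal pit,
#' hyperreflective foci placed uniformly at random in the INL band and in
#' radial arrays within the HFL band, superficial vessels whose flow signal
#' casts projection tails onto deeper hyperreflective material, and additive
#' Gaussian noise. All grayscale parameters are on the 8-bit scale.
#'
#' @param lateral_px lateral A-scans per side (square grid).
#' @param lateral_fov lateral field of view in micrometres (default 3000,
#'   a 3 x 3 mm square centered on the fovea).
#' @param axial_step axial voxel size in micrometres (default 3, the digital
#'   axial sampling of the emulated device).
#' @param depth_px axial voxels.
#' @param ilm_depth,ipl_depth,bm_depth surface depths (um) at the periphery.
#' @param pit_depth foveal-pit depression amplitude of the ILM (um).
#' @param pit_sigma Gaussian radius of the pit (um).
#' @param background_reflectance grayscale of the four background bands
#'   (vitreous, inner retina, outer retina, below BM).
#' @param n_foci_inl,n_foci_hfl foci counts per band.
#' @param foci_radius_range focus disc radius range (um).
#' @param foci_reflectance_mean,foci_reflectance_sd per-focus structural
#'   reflectance distribution.
#' @param foci_decorr_mean,foci_decorr_sd per-focus intrinsic decorrelation
#'   of HFL foci (INL foci carry none); may be 0.
#' @param n_rays number of rays for the radial HFL arrangement.
#' @param hfl_ecc_range eccentricity range of HFL foci centers from the
#'   foveal center (um).
#' @param vessel_density fraction of the superficial slab covered by
#'   vessels.
#' @param vessel_decorr_mean,vessel_decorr_sd vessel flow-signal grayscale.
#' @param projection_gain unitless factor mapping superficial decorrelation
#'   x (deep reflectance / 255) to projected decorrelation.
#' @param projection_gate_frac projection appears only where structural
#'   reflectance exceeds this fraction of `foci_reflectance_mean`.
#' @param noise_sd additive Gaussian noise SD (grayscale), applied to both
#'   channels and clipped to `[0, 255]`.
#' @param decorr_mode `"direct"` writes the decorrelation grayscale;
#'   `"frame_pair"` synthesizes two amplitude frames and computes the
#'   per-voxel amplitude decorrelation `1 - A1*A2 / (0.5*(A1^2 + A2^2))`
#'   scaled to 8-bit — a simplified surrogate of split-spectrum
#'   amplitude-decorrelation reconstruction, qualitative only.
#' @param seed integer seed; identical seed and config give bit-identical
#'   output.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(lateral_px = 128L, lateral_fov = 3000,
                           axial_step = 3, depth_px = 120L,
                           ilm_depth = 50, ipl_depth = 150, bm_depth = 350,
                           pit_depth = 60, pit_sigma = 350,
                           background_reflectance = c(vitreous = 10,
                                                      inner = 120,
                                                      outer = 70,
                                                      below = 25),
                           n_foci_inl = 15L, n_foci_hfl = 25L,
                           foci_radius_range = c(30, 80),
                           foci_reflectance_mean = 180,
                           foci_reflectance_sd = 10,
                           foci_decorr_mean = 120, foci_decorr_sd = 15,
                           n_rays = 8L, hfl_ecc_range = c(300, 1300),
                           vessel_density = 0.12,
                           vessel_decorr_mean = 200, vessel_decorr_sd = 15,
                           projection_gain = 0.5,
                           projection_gate_frac = 0.5,
                           noise_sd = 6,
                           decorr_mode = c("direct", "frame_pair"),
                           seed = 1L) {
  decorr_mode <- match.arg(decorr_mode)
  # tolerate list-valued vector fields (e.g. from YAML round-trips)
  background_reflectance <- unlist(background_reflectance)
  if (length(background_reflectance) != 4L)
    stop("background_reflectance needs 4 values (vitreous, inner, outer, below)")
  names(background_reflectance) <- c("vitreous", "inner", "outer", "below")
  foci_radius_range <- unname(unlist(foci_radius_range))
  hfl_ecc_range <- unname(unlist(hfl_ecc_range))
  cfg <- list(lateral_px = as.integer(lateral_px), lateral_fov = lateral_fov,
              axial_step = axial_step, depth_px = as.integer(depth_px),
              ilm_depth = ilm_depth, ipl_depth = ipl_depth,
              bm_depth = bm_depth, pit_depth = pit_depth,
              pit_sigma = pit_sigma,
              background_reflectance = background_reflectance,
              n_foci_inl = as.integer(n_foci_inl),
              n_foci_hfl = as.integer(n_foci_hfl),
              foci_radius_range = foci_radius_range,
              foci_reflectance_mean = foci_reflectance_mean,
              foci_reflectance_sd = foci_reflectance_sd,
              foci_decorr_mean = foci_decorr_mean,
              foci_decorr_sd = foci_decorr_sd,
              n_rays = as.integer(n_rays), hfl_ecc_range = hfl_ecc_range,
              vessel_density = vessel_density,
              vessel_decorr_mean = vessel_decorr_mean,
              vessel_decorr_sd = vessel_decorr_sd,
              projection_gain = projection_gain,
              projection_gate_frac = projection_gate_frac,
              noise_sd = noise_sd, decorr_mode = decorr_mode,
              seed = as.integer(seed))
  validate_phantom_config(cfg)
  class(cfg) <- "phantom_config"
  cfg
}

validate_phantom_config <- function(cfg) {
  with(cfg, {
    if (lateral_px < 8) stop("lateral_px too small")
    if (!(0 < ilm_depth && ilm_depth + pit_depth < ipl_depth &&
          ipl_depth < bm_depth && bm_depth <= depth_px * axial_step))
      stop("layer depths must satisfy 0 < ILM (+pit) < IPL < BM <= volume depth")
    grays <- c(background_reflectance, foci_reflectance_mean,
               foci_decorr_mean, vessel_decorr_mean)
    if (any(grays < 0 | grays > 255))
      stop("grayscale parameters must lie in [0, 255]")
    if (any(foci_radius_range <= 0) || diff(foci_radius_range) < 0)
      stop("foci radii must be positive and ordered")
    if (vessel_density < 0 || vessel_density > 1)
      stop("vessel_density must lie in [0, 1]")
    if (noise_sd < 0 || projection_gain < 0)
      stop("noise_sd and projection_gain must be non-negative")
  })
  invisible(cfg)
}

# deterministic sub-stream seeds derived from the master seed
substream_seed <- function(seed, k) (as.integer(seed) * 31L + k) %% 2147483647L

# rasterize a disc of radius_um centered at (ci, cj) on an ny x nx grid;
# returns linear indices, or NULL if the disc leaves the field
disc_pixels <- function(ci, cj, radius_um, step, ny, nx) {
  r_px <- radius_um / step
  if (ci - r_px < 0.5 || ci + r_px > ny + 0.5 ||
      cj - r_px < 0.5 || cj + r_px > nx + 0.5) return(NULL)
  ir <- max(1, floor(ci - r_px)):min(ny, ceiling(ci + r_px))
  jr <- max(1, floor(cj - r_px)):min(nx, ceiling(cj + r_px))
  ii <- rep(ir, times = length(jr))
  jj <- rep(jr, each = length(ir))
  keep <- (ii - ci)^2 + (jj - cj)^2 <= r_px^2
  (jj[keep] - 1L) * ny + ii[keep]
}

# grow random vessel paths until the target lateral density is reached
generate_vessel_raster <- function(ny, nx, density, max_iter = 10000L) {
  mask <- matrix(FALSE, ny, nx)
  target <- density * ny * nx
  iter <- 0L
  while (sum(mask) < target && iter < max_iter) {
    iter <- iter + 1L
    i <- runif(1, 1, ny); j <- runif(1, 1, nx)
    heading <- runif(1, 0, 2 * pi)
    width <- sample(1:2, 1)
    n_steps <- as.integer(runif(1, 0.4, 1.2) * max(ny, nx))
    for (s in seq_len(n_steps)) {
      heading <- heading + rnorm(1, 0, 0.25)
      i <- i + sin(heading); j <- j + cos(heading)
      if (i < 1 || i > ny || j < 1 || j > nx) break
      ir <- max(1, round(i) - width + 1):min(ny, round(i) + width - 1)
      jr <- max(1, round(j) - width + 1):min(nx, round(j) + width - 1)
      mask[ir, jr] <- TRUE
    }
  }
  mask
}

place_focus_centers <- function(n, mode, step, ny, nx, radius_range,
                                ecc_range = NULL, n_rays = NULL,
                                max_attempts = 200L) {
  centers <- vector("list", n)
  if (n == 0L) return(centers)
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  rot <- runif(1, 0, 2 * pi)
  for (f in seq_len(n)) {
    radius <- runif(1, radius_range[1], radius_range[2])
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      if (mode == "uniform") {
        ci <- runif(1, 1, ny); cj <- runif(1, 1, nx)
      } else {  # radial arrays toward the foveal center
        ray <- ((f - 1L) %% n_rays)
        theta <- rot + 2 * pi * ray / n_rays + rnorm(1, 0, 0.12)
        ecc <- runif(1, ecc_range[1], ecc_range[2]) / step
        ci <- cy + ecc * sin(theta); cj <- cx + ecc * cos(theta)
      }
      px <- disc_pixels(ci, cj, radius, step, ny, nx)
      if (!is.null(px)) {
        centers[[f]] <- list(row = ci, col = cj, radius_um = radius,
                             pixels = px)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf(
        "could not place focus %d (radius %.0f um) inside the lateral field after %d attempts",
        f, radius, max_attempts))
  }
  centers
}

# amplitude-frame surrogate: map an 8-bit decorrelation target to the
# frame ratio rho with 1 - 2*rho/(1+rho^2) = d/255, then recompute the
# decorrelation from the (optionally noisy) frame pair
frame_pair_decorrelation <- function(target, noise_sd) {
  d <- pmin(target / 255, 0.999)
  rho <- ifelse(d <= 0, 1, (1 - sqrt(d * (2 - d))) / (1 - d))
  a1 <- 100 + rnorm(length(d), 0, noise_sd / 4)
  a2 <- 100 * rho + rnorm(length(d), 0, noise_sd / 4)
  dec <- 1 - (a1 * a2) / (0.5 * (a1^2 + a2^2))
  clip255(255 * dec)
}

#' Generate a paired-volume phantom with exact ground truth
#'
#' Builds the structural and decorrelation volumes described by a
#' [phantom_config()], together with the ground truth every downstream stage
#' is validated against: the lateral foci masks of the INL and HFL bands,
#' the superficial vessel raster, the set of HFL-slab pixels contaminated by
#' projected vessel signal, per-focus true decorrelation values, and the
#' exact decorrelation signal intensity over the retained foci pixels
#' (foci minus vessel-projected pixels), computed from the noise-free
#' signal components.
#'
#' Foci span their band's full axial extent, so the 2-D ground-truth masks
#' describe the en-face slabs exactly. Projection tails run axially from
#' each vessel pixel down to Bruch's membrane wherever the structural
#' reflectance exceeds the configured gate, emulating the duplication of
#' flow signal onto hyperreflective material.
#'
#' @param config a [phantom_config()].
#' @return List with `volume` (a [paired_volume()]), `surfaces`
#'   (a [boundary_surfaces()]), and `truth` (class `phantom_truth`).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  validate_phantom_config(config)
  ny <- config$lateral_px; nx <- config$lateral_px
  nz <- config$depth_px
  step <- config$lateral_fov / config$lateral_px
  s <- config$axial_step

  # --- geometry ------------------------------------------------------------
  ii <- matrix(seq_len(ny), ny, nx)
  jj <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  r_um <- step * sqrt((ii - cy)^2 + (jj - cx)^2)
  ilm <- config$ilm_depth + config$pit_depth * exp(-r_um^2 / (2 * config$pit_sigma^2))
  ipl <- matrix(config$ipl_depth, ny, nx)
  bm <- matrix(config$bm_depth, ny, nx)
  surfaces <- boundary_surfaces(ilm, ipl, bm, lateral_step = step)

  # --- layered structural background --------------------------------------
  voxel_top <- (seq_len(nz) - 1) * s
  bg <- config$background_reflectance
  structural <- array(0, c(ny, nx, nz))
  for (k in seq_len(nz)) {
    layer <- matrix(bg[["below"]], ny, nx)
    layer[voxel_top[k] < bm] <- bg[["outer"]]
    layer[voxel_top[k] < ipl] <- bg[["inner"]]
    layer[voxel_top[k] < ilm] <- bg[["vitreous"]]
    structural[, , k] <- layer
  }
  decorr <- array(0, c(ny, nx, nz))

  plane <- ny * nx
  rows_inl <- slab_rows(config$ipl_depth + 38, config$ipl_depth + 47, s)
  rows_hfl <- slab_rows(config$bm_depth - 100, config$bm_depth - 91, s)

  # --- foci ---------------------------------------------------------------
  set.seed(substream_seed(config$seed, 1L))
  inl_centers <- place_focus_centers(config$n_foci_inl, "uniform", step,
                                     ny, nx, config$foci_radius_range)
  set.seed(substream_seed(config$seed, 2L))
  hfl_centers <- place_focus_centers(config$n_foci_hfl, "radial", step,
                                     ny, nx, config$foci_radius_range,
                                     ecc_range = config$hfl_ecc_range,
                                     n_rays = config$n_rays)
  set.seed(substream_seed(config$seed, 3L))
  per_focus <- list()
  foci_mask_inl <- matrix(FALSE, ny, nx)
  foci_mask_hfl <- matrix(FALSE, ny, nx)
  # per-pixel noise-free decorrelation value of the HFL band (overwritten by
  # overlapping foci, exactly as in the volume)
  hfl_decorr_px <- matrix(0, ny, nx)
  paint <- function(centers, rows, layer) {
    for (f in seq_along(centers)) {
      cc <- centers[[f]]
      refl <- round(clip255(rnorm(1, config$foci_reflectance_mean,
                                  config$foci_reflectance_sd)))
      dec <- if (layer == "hfl")
        round(clip255(rnorm(1, config$foci_decorr_mean,
                            config$foci_decorr_sd))) else 0
      for (k in rows) structural[cc$pixels + (k - 1L) * plane] <<- refl
      if (layer == "hfl") {
        for (k in rows) decorr[cc$pixels + (k - 1L) * plane] <<- dec
        foci_mask_hfl[cc$pixels] <<- TRUE
        hfl_decorr_px[cc$pixels] <<- dec
      } else {
        foci_mask_inl[cc$pixels] <<- TRUE
      }
      per_focus[[length(per_focus) + 1L]] <<- data.frame(
        id = sprintf("%s_%02d", layer, f), layer = layer,
        row = cc$row, col = cc$col, radius_um = cc$radius_um,
        reflectance = refl, decorrelation = dec)
    }
  }
  paint(inl_centers, rows_inl, "inl")
  paint(hfl_centers, rows_hfl, "hfl")

  # --- superficial vessels -------------------------------------------------
  set.seed(substream_seed(config$seed, 4L))
  vessel_raster <- generate_vessel_raster(ny, nx, config$vessel_density)
  vessel_value <- matrix(0, ny, nx)
  nves <- sum(vessel_raster)
  if (nves > 0) {
    vessel_value[vessel_raster] <-
      round(clip255(rnorm(nves, config$vessel_decorr_mean,
                          config$vessel_decorr_sd)))
  }
  gate <- config$projection_gate_frac * config$foci_reflectance_mean
  projection_mask_hfl <- matrix(FALSE, ny, nx)
  if (nves > 0) {
    vidx <- which(vessel_raster)
    for (p in vidx) {
      i <- (p - 1L) %% ny + 1L
      j <- (p - 1L) %/% ny + 1L
      sup_rows <- slab_rows(ilm[i, j] + 3, ipl[i, j] + 15, s)
      decorr[i, j, sup_rows] <- vessel_value[p]
      bm_row <- min(nz, ceiling(bm[i, j] / s))
      below <- seq.int(max(sup_rows) + 1L, bm_row)
      refl <- structural[i, j, below]
      hit <- refl > gate
      if (any(hit)) {
        decorr[i, j, below[hit]] <- decorr[i, j, below[hit]] +
          round(config$projection_gain * vessel_value[p] * refl[hit] / 255)
        if (any(below[hit] %in% rows_hfl)) projection_mask_hfl[p] <- TRUE
      }
    }
  }

  # --- exact truth from the noise-free components --------------------------
  retained <- foci_mask_hfl & !vessel_raster
  true_intensity <- if (any(retained)) {
    # per-pixel en-face value of the retained set: mean over band rows of a
    # per-column constant equals that constant; quantized as the pipeline does
    mean(round(hfl_decorr_px[retained]))
  } else NA_real_
  truth <- structure(
    list(foci_mask_inl = foci_mask_inl, foci_mask_hfl = foci_mask_hfl,
         vessel_mask = vessel_raster,
         projection_mask_hfl = projection_mask_hfl,
         per_focus = do.call(rbind, per_focus),
         true_intensity = true_intensity,
         rows_inl = rows_inl, rows_hfl = rows_hfl),
    class = "phantom_truth")

  # --- decorrelation rendering and noise ----------------------------------
  decorr <- clip255(decorr)
  if (config$decorr_mode == "frame_pair") {
    set.seed(substream_seed(config$seed, 5L))
    decorr <- array(frame_pair_decorrelation(decorr, config$noise_sd),
                    c(ny, nx, nz))
    if (config$noise_sd > 0) {
      set.seed(substream_seed(config$seed, 6L))
      structural <- clip255(structural + rnorm(length(structural), 0, config$noise_sd))
    }
  } else if (config$noise_sd > 0) {
    set.seed(substream_seed(config$seed, 5L))
    structural <- clip255(structural + rnorm(length(structural), 0, config$noise_sd))
    set.seed(substream_seed(config$seed, 6L))
    decorr <- clip255(decorr + rnorm(length(decorr), 0, config$noise_sd))
  }

  vol <- paired_volume(structural, decorr, axial_step = s,
                       lateral_step = step,
                       id = sprintf("phantom_seed%d", config$seed))
  list(volume = vol, surfaces = surfaces, truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(
    "phantom_truth: %d INL / %d HFL foci px, %d vessel px, %d projected px; true intensity %.2f\n",
    sum(x$foci_mask_inl), sum(x$foci_mask_hfl), sum(x$vessel_mask),
    sum(x$projection_mask_hfl), x$true_intensity))
  invisible(x)
}

#' Simulate a manual tracing of a mask
#'
#' Produces a synthetic stand-in for a manual freehand tracing by randomly
#' dilating or eroding each connected boundary of the reference mask:
#' boundary pixels flip with the given probability. Used to exercise the
#' manual-vs-automatic agreement statistics without real tracings.
#'
#' @param mask a [binary_mask()] or logical matrix (e.g. ground-truth foci).
#' @param flip_prob probability that a boundary pixel is flipped.
#' @param seed integer seed.
#' @return A [binary_mask()] with `method = "manual"`.
#' @export
simulate_manual_tracing <- function(mask, flip_prob = 0.3, seed = 1L) {
  m <- if (inherits(mask, "binary_mask")) mask$mask else mask
  set.seed(substream_seed(seed, 7L))
  grown <- dilate_mask(m, 1)
  shrunk <- !dilate_mask(!m, 1)
  boundary <- grown & !shrunk
  flips <- boundary & matrix(runif(length(m)) < flip_prob, nrow(m), ncol(m))
  out <- m
  out[flips] <- !out[flips]
  binary_mask(out, "manual", NA_integer_, source = "simulated manual tracing")
}
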