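# shared fixtures: tiny phantoms, flat-retina surfaces, histogram images

small_phantom_config <- function(seed = 1L, ...) {
  args <- list(lateral_px = 64L, n_foci_inl = 8L, n_foci_hfl = 12L,
               seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_config, args)
}

# flat retina: constant surfaces over an ny x nx grid
flat_surfaces <- function(ny = 20, nx = 20, ilm = 50, ipl = 150, bm = 350,
                          lateral_step = 50) {
  boundary_surfaces(matrix(ilm, ny, nx), matrix(ipl, ny, nx),
                    matrix(bm, ny, nx), lateral_step)
}

# build an image whose 256-bin histogram equals `counts`
image_from_hist <- function(counts) {
  v <- rep(0:255, counts)
  n <- length(v)
  nr <- max(1, floor(sqrt(n)))
  while (n %% nr != 0) nr <- nr - 1
  matrix(v, nr, n / nr)
}

# independent Otsu oracle: exhaustive between-class variance scan,
# written from first principles on probabilities
otsu_bruteforce <- function(counts) {
  p <- counts / sum(counts)
  mu_t <- sum((0:255) * p)
  best <- -1; best_t <- NA
  for (t in 0:254) {
    w0 <- sum(p[1:(t + 1)])
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum((0:t) * p[1:(t + 1)]) / w0
    mu1 <- (mu_t - w0 * mu0) / w1
    s <- w0 * w1 * (mu0 - mu1)^2
    if (s > best + 1e-12) { best <- s; best_t <- t }
  }
  best_t
}

# isodata fixed-point predicate: t == floor((mean below + mean above)/2)
isodata_is_fixed_point <- function(counts, t) {
  lev <- 0:255
  below <- lev <= t
  mb <- sum(lev[below] * counts[below]) / sum(counts[below])
  ma <- sum(lev[!below] * counts[!below]) / sum(counts[!below])
  t == floor((mb + ma) / 2)
}
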