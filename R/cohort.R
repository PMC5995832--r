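#' Cohort configuration
#'
#' Parameters of the synthetic per-eye clinical table that stands in for a
#' study cohort. Intensities are drawn per ellipsoid-zone (EZ) group; logMAR
#' visual acuity is a linear function of intensity and EZ status plus
#' Gaussian noise whose SD is solved analytically so that the population
#' Pearson correlation between intensity and logMAR VA equals `target_r`;
#' central subfield (CSF) thickness is correlated with intensity at `csf_r`.
#' DR severity grade, DME status, signal strength index (SSI) and axial
#' length are drawn independently.
#'
#' @param n_eyes number of eyes (default 102).
#' @param n_patients number of patients; each contributes at most two eyes
#'   (default 66).
#' @param ez_disrupted_fraction fraction of eyes with a disrupted foveal EZ
#'   line (default 32/102); group sizes are fixed at `round(n_eyes *
#'   fraction)`.
#' @param group_means intensity grayscale means `c(intact, disrupted)`
#'   (defaults 72.3 and 88.3).
#' @param intensity_sd within-group intensity SD (default 22).
#' @param va_slope logMAR per grayscale unit (default 0.00372).
#' @param ez_va_effect direct logMAR offset of EZ disruption (default
#'   0.163).
#' @param target_r intended population Pearson correlation between
#'   intensity and logMAR VA (default 0.553). The residual VA noise SD is
#'   derived from it; an incompatible combination (implied noise variance
#'   negative, or slopes of the wrong sign) is an error.
#' @param logmar_mean population mean logMAR VA (default 0.061).
#' @param csf_mean,csf_sd CSF thickness distribution in micrometres
#'   (defaults 320, 99).
#' @param csf_r correlation between CSF thickness and intensity (default
#'   0.408).
#' @param dr_grade_probs probabilities of (mild NPDR, moderate NPDR, severe
#'   NPDR, PDR); must sum to 1 (defaults 8/47/23/24 out of 102).
#' @param dme_prob probability of center-involved DME (default 42/102).
#' @param ssi_mean,ssi_sd signal strength index distribution (68, 5.4).
#' @param axial_mean,axial_sd axial length distribution in mm (23.8, 0.9).
#' @param seed integer seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_eyes = 102L, n_patients = 66L,
                          ez_disrupted_fraction = 32 / 102,
                          group_means = c(intact = 72.3, disrupted = 88.3),
                          intensity_sd = 22,
                          va_slope = 0.00372, ez_va_effect = 0.163,
                          target_r = 0.553, logmar_mean = 0.061,
                          csf_mean = 320, csf_sd = 99, csf_r = 0.408,
                          dr_grade_probs = c(8, 47, 23, 24) / 102,
                          dme_prob = 42 / 102,
                          ssi_mean = 68, ssi_sd = 5.4,
                          axial_mean = 23.8, axial_sd = 0.9,
                          seed = 1L) {
  group_means <- unlist(group_means)
  if (length(group_means) != 2L)
    stop("group_means needs 2 values (intact, disrupted)")
  names(group_means) <- c("intact", "disrupted")
  dr_grade_probs <- unname(unlist(dr_grade_probs))
  cfg <- list(n_eyes = as.integer(n_eyes), n_patients = as.integer(n_patients),
              ez_disrupted_fraction = ez_disrupted_fraction,
              group_means = group_means, intensity_sd = intensity_sd,
              va_slope = va_slope, ez_va_effect = ez_va_effect,
              target_r = target_r, logmar_mean = logmar_mean,
              csf_mean = csf_mean, csf_sd = csf_sd, csf_r = csf_r,
              dr_grade_probs = dr_grade_probs, dme_prob = dme_prob,
              ssi_mean = ssi_mean, ssi_sd = ssi_sd,
              axial_mean = axial_mean, axial_sd = axial_sd,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    if (n_eyes < 1 || n_patients < 1) stop("counts must be positive")
    if (n_eyes > 2L * n_patients)
      stop("each patient contributes at most two eyes")
    if (n_patients > n_eyes) stop("more patients than eyes")
    if (abs(sum(dr_grade_probs) - 1) > 1e-8)
      stop("dr_grade_probs must sum to 1")
    if (any(dr_grade_probs < 0) || dme_prob < 0 || dme_prob > 1 ||
        ez_disrupted_fraction < 0 || ez_disrupted_fraction > 1)
      stop("probabilities must lie in [0, 1]")
    if (intensity_sd < 0 || csf_sd < 0 || ssi_sd < 0 || axial_sd < 0)
      stop("SDs must be non-negative")
    if (target_r < 0 || target_r > 1) stop("target_r must lie in [0, 1]")
    if (abs(csf_r) > 1) stop("csf_r must lie in [-1, 1]")
  })
  invisible(cfg)
}

# population moments of the intensity mixture and the VA noise SD implied
# by target_r; errors when the target is unattainable
cohort_calibration <- function(cfg) {
  p <- cfg$ez_disrupted_fraction
  mu <- c(cfg$group_means[[1]], cfg$group_means[[2]])
  delta <- mu[2] - mu[1]
  mu_i <- mu[1] + p * delta
  var_i <- cfg$intensity_sd^2 + p * (1 - p) * delta^2
  cov_ie <- p * (1 - p) * delta
  b <- cfg$va_slope; cc <- cfg$ez_va_effect
  cov_iva <- b * var_i + cc * cov_ie
  signal_var <- b^2 * var_i + cc^2 * p * (1 - p) + 2 * b * cc * cov_ie
  if (cfg$target_r == 0) {
    if (cov_iva != 0)
      stop("target_r = 0 is incompatible with nonzero slopes")
    return(list(mu_i = mu_i, var_i = var_i, noise_sd = 0.211,
                intercept = cfg$logmar_mean - b * mu_i - cc * p))
  }
  if (cov_iva <= 0)
    stop("target_r > 0 is incompatible with the sign of va_slope")
  var_va <- (cov_iva / (cfg$target_r * sqrt(var_i)))^2
  noise_var <- var_va - signal_var
  if (noise_var < -1e-12)
    stop(sprintf(
      "target_r = %.3f is unattainable with these slopes (implied noise variance %.3g < 0)",
      cfg$target_r, noise_var))
  list(mu_i = mu_i, var_i = var_i, noise_sd = sqrt(max(noise_var, 0)),
       intercept = cfg$logmar_mean - b * mu_i - cc * p)
}

#' Generate a synthetic per-eye cohort table
#'
#' @param config a [cohort_config()].
#' @return A `data.frame` of class `cohort_table` with one row per eye:
#'   `eye_id`, `patient_id`, `intensity` (decorrelation signal intensity,
#'   grayscale), `logmar_va`, `csf_thickness` (um), `dr_grade` (factor),
#'   `dme`, `ez_disrupted`, `ssi`, `axial_length` (mm),
#'   `foci_present_inl`, `foci_present_hfl`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  cal <- cohort_calibration(config)
  n <- config$n_eyes
  set.seed(substream_seed(config$seed, 11L))

  n_pairs <- n - config$n_patients
  patient_id <- c(rep(seq_len(n_pairs), each = 2),
                  seq.int(n_pairs + 1, length.out = config$n_patients - n_pairs))
  patient_id <- sprintf("P%03d", patient_id[seq_len(n)])

  n_dis <- round(n * config$ez_disrupted_fraction)
  ez <- rep(FALSE, n)
  ez[sample.int(n, n_dis)] <- TRUE

  mu <- ifelse(ez, config$group_means[[2]], config$group_means[[1]])
  intensity <- clip255(rnorm(n, mu, config$intensity_sd))
  logmar_va <- cal$intercept + config$va_slope * intensity +
    config$ez_va_effect * ez + rnorm(n, 0, cal$noise_sd)
  csf <- config$csf_mean +
    config$csf_r * config$csf_sd * (intensity - cal$mu_i) / sqrt(cal$var_i) +
    config$csf_sd * sqrt(1 - config$csf_r^2) * rnorm(n)
  csf <- pmax(csf, 50)

  grades <- c("mild NPDR", "moderate NPDR", "severe NPDR", "PDR")
  out <- data.frame(
    eye_id = sprintf("E%03d", seq_len(n)),
    patient_id = patient_id,
    intensity = intensity,
    logmar_va = logmar_va,
    csf_thickness = csf,
    dr_grade = factor(sample(grades, n, replace = TRUE,
                             prob = config$dr_grade_probs), levels = grades),
    dme = runif(n) < config$dme_prob,
    ez_disrupted = ez,
    ssi = rnorm(n, config$ssi_mean, config$ssi_sd),
    axial_length = rnorm(n, config$axial_mean, config$axial_sd),
    foci_present_inl = TRUE,
    foci_present_hfl = TRUE,
    stringsAsFactors = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  attr(out, "provenance") <- "generated"
  out
}

#' Simulate two raters grading foci presence at a target agreement
#'
#' Emulates two specialists independently grading the presence or absence of
#' hyperreflective foci across a population of eyes. Both raters read the
#' true status but independently misread each eye with a common flip
#' probability, which is calibrated numerically so that the population
#' Cohen's kappa equals `kappa_target` at the given prevalence.
#'
#' @param n number of graded eyes.
#' @param prevalence true fraction of eyes with foci present.
#' @param kappa_target intended population kappa in (0, 1].
#' @param seed integer seed.
#' @return List with `rater_a`, `rater_b`, `truth` (logical vectors) and
#'   `flip_prob` (the calibrated misreading probability).
#' @export
simulate_rater_gradings <- function(n, prevalence, kappa_target, seed = 1L) {
  if (kappa_target <= 0 || kappa_target > 1)
    stop("kappa_target must lie in (0, 1]")
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie in (0, 1)")
  expected_kappa <- function(q) {
    po <- 1 - 2 * q * (1 - q)
    m <- prevalence * (1 - q) + (1 - prevalence) * q
    pe <- m^2 + (1 - m)^2
    (po - pe) / (1 - pe)
  }
  q <- if (kappa_target == 1) 0 else
    uniroot(function(q) expected_kappa(q) - kappa_target,
            c(1e-9, 0.49), tol = 1e-10)$root
  set.seed(substream_seed(seed, 13L))
  truth <- runif(n) < prevalence
  rater_a <- xor(truth, runif(n) < q)
  rater_b <- xor(truth, runif(n) < q)
  list(rater_a = rater_a, rater_b = rater_b, truth = truth, flip_prob = q)
}
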