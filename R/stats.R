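#' Eligibility filter for a cohort table
#'
#' Retains eyes meeting the study's quantitative inclusion criteria: axial
#' length within `[22.0, 26.0]` mm (only eyes shorter than 22.0 or longer
#' than 26.0 are excluded), signal strength index strictly greater than 60
#' (a score of 60 or less is excluded), and hyperreflective foci present in
#' both the INL and the HFL slab. Every exclusion is logged with its
#' reason(s); an eye failing several criteria is logged once per reason.
#'
#' @param cohort a `cohort_table` / data.frame with columns `eye_id`,
#'   `axial_length`, `ssi`, `foci_present_inl`, `foci_present_hfl`.
#' @return List with `retained` (eligible rows), `excluded` (the rest), and
#'   `log` (data.frame `eye_id`, `reason`).
#' @export
eligibility_filter <- function(cohort) {
  required <- c("eye_id", "axial_length", "ssi",
                "foci_present_inl", "foci_present_hfl")
  for (f in required) {
    if (!f %in% names(cohort))
      stop(sprintf("cohort is missing required field '%s'", f))
    bad <- which(is.na(cohort[[f]]))
    if (length(bad))
      stop(sprintf("missing value in field '%s' for eye %s",
                   f, cohort$eye_id[bad[1]]))
  }
  reasons <- list(
    "axial length shorter than 22.0 mm" = cohort$axial_length < 22.0,
    "axial length longer than 26.0 mm" = cohort$axial_length > 26.0,
    "SSI of 60 or less" = cohort$ssi <= 60,
    "no hyperreflective foci in the INL slab" = !cohort$foci_present_inl,
    "no hyperreflective foci in the HFL slab" = !cohort$foci_present_hfl)
  log <- do.call(rbind, lapply(names(reasons), function(r) {
    idx <- which(reasons[[r]])
    if (!length(idx)) return(NULL)
    data.frame(eye_id = cohort$eye_id[idx], reason = r,
               stringsAsFactors = FALSE)
  }))
  if (is.null(log))
    log <- data.frame(eye_id = character(0), reason = character(0))
  drop <- Reduce(`|`, reasons)
  list(retained = cohort[!drop, , drop = FALSE],
       excluded = cohort[drop, , drop = FALSE],
       log = log)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length, n >= 3, finite, with nonzero
#'   variance.
#' @return List with `r`, `p` (two-sided t-test), and `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (var(x) == 0 || var(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' One-way ANOVA with Bonferroni-corrected pairwise comparisons
#'
#' Fits a one-way ANOVA of `values` on `groups` and runs all pairwise
#' two-sample t-tests (pooled SD), multiplying each raw p-value by the
#' number of pairs and capping at 1 (Bonferroni).
#'
#' @param values numeric vector.
#' @param groups factor (or coercible); at least 2 levels with at least 2
#'   observations each.
#' @return List with `F`, `p`, `df`, and `pairwise` (data.frame `group1`,
#'   `group2`, `p_raw`, `p_adj`, with `n_pairs` attribute).
#' @export
anova_bonferroni <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  sizes <- table(groups)
  if (any(sizes < 2))
    stop(sprintf("group '%s' has fewer than 2 observations",
                 names(sizes)[which(sizes < 2)[1]]))
  fit <- aov(values ~ groups)
  tab <- anova(fit)
  raw <- pairwise.t.test(values, groups, p.adjust.method = "none",
                         pool.sd = TRUE)$p.value
  pairs <- which(!is.na(raw), arr.ind = TRUE)
  m <- nrow(pairs)
  pw <- data.frame(
    group1 = rownames(raw)[pairs[, 1]],
    group2 = colnames(raw)[pairs[, 2]],
    p_raw = raw[pairs],
    p_adj = pmin(1, raw[pairs] * m),
    stringsAsFactors = FALSE)
  attr(pw, "n_pairs") <- m
  list(F = tab[["F value"]][1], p = tab[["Pr(>F)"]][1],
       df = tab[["Df"]], pairwise = pw)
}

#' Two-group comparison of a continuous measure
#'
#' Welch's unequal-variance two-sample t-test by default (Student's pooled
#' test via `var_equal = TRUE`), reporting group means and SDs in the
#' conventional "m1 +/- sd1 vs. m2 +/- sd2" form.
#'
#' @param values numeric vector.
#' @param group logical or two-level factor.
#' @param var_equal use the pooled-variance test (default `FALSE`).
#' @return List with `means`, `sds`, `ns`, `t`, `df`, `p`, `formatted`.
#' @export
two_group_compare <- function(values, group, var_equal = FALSE) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2)
    stop("need exactly 2 groups with observations")
  sizes <- table(group)
  if (any(sizes < 2)) stop("both groups need at least 2 observations")
  sp <- split(values, group)
  tt <- t.test(sp[[2]], sp[[1]], var.equal = var_equal)
  means <- vapply(sp, mean, 0)
  sds <- vapply(sp, sd, 0)
  list(means = means, sds = sds, ns = as.vector(sizes),
       t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       formatted = sprintf("%.1f ± %.1f vs. %.1f ± %.1f",
                           means[2], sds[2], means[1], sds[1]))
}

#' Forced-entry multiple regression with standardized coefficients
#'
#' Ordinary least squares of the z-scored outcome on the z-scored
#' predictors (binary predictors are z-scored too); all predictors are
#' entered and none dropped. Exact or near collinearity (condition number
#' of the standardized design above `max_condition`) is an error.
#'
#' @param data data.frame holding outcome and predictors.
#' @param outcome outcome column name.
#' @param predictors character vector of predictor column names.
#' @param max_condition condition-number bound (default 1e8).
#' @return data.frame with one row per predictor: `predictor`, `beta`
#'   (standardized coefficient), `se`, `t`, `p`.
#' @export
forced_entry_regression <- function(data, outcome = "logmar_va",
                                    predictors = c("intensity",
                                                   "ez_disrupted",
                                                   "csf_thickness"),
                                    max_condition = 1e8) {
  cols <- c(outcome, predictors)
  missing <- setdiff(cols, names(data))
  if (length(missing))
    stop(sprintf("missing columns: %s", paste(missing, collapse = ", ")))
  d <- data[cols]
  d[] <- lapply(d, function(v) as.numeric(v))
  if (!all(complete.cases(d))) stop("missing values in model variables")
  n <- nrow(d)
  if (n <= length(predictors) + 1)
    stop("need n > number of predictors + 1")
  if (any(vapply(d, sd, 0) == 0))
    stop("a model variable has zero variance")
  z <- as.data.frame(scale(d))
  X <- as.matrix(z[predictors])
  if (kappa(cbind(1, X), exact = TRUE) > max_condition)
    stop("predictors are collinear (condition number above bound)")
  fit <- lm(z[[outcome]] ~ X)
  cf <- summary(fit)$coefficients[-1, , drop = FALSE]
  data.frame(predictor = predictors,
             beta = unname(cf[, 1]), se = unname(cf[, 2]),
             t = unname(cf[, 3]), p = unname(cf[, 4]),
             stringsAsFactors = FALSE)
}

#' Cohen's kappa for two binary raters
#'
#' Chance-corrected agreement `kappa = (po - pe) / (1 - pe)` with the
#' standard marginal-product expected agreement.
#'
#' @param ratings_a,ratings_b vectors of equal length >= 2 (logical, or any
#'   two-category codes).
#' @return List with `kappa`, `po` (observed agreement), `pe` (expected),
#'   and `n`.
#' @export
cohen_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b)) stop("ratings differ in length")
  n <- length(ratings_a)
  if (n < 2) stop("need at least 2 rated items")
  lev <- sort(unique(c(as.character(ratings_a), as.character(ratings_b))))
  a <- factor(as.character(ratings_a), levels = lev)
  b <- factor(as.character(ratings_b), levels = lev)
  po <- mean(a == b)
  pe <- sum(table(a) / n * table(b) / n)
  if (pe >= 1)
    stop("both raters are constant: kappa undefined (expected agreement 1)")
  list(kappa = (po - pe) / (1 - pe), po = po, pe = pe, n = n)
}

#' Intraclass correlation for absolute agreement, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation for method-comparison tables (eyes x methods), with the
#' F-distribution confidence interval.
#'
#' @param measurements numeric matrix or data.frame, rows = subjects (>= 5),
#'   columns = methods/raters (>= 2).
#' @param conf_level confidence level (default 0.95).
#' @return List with `icc`, `ci` (lower, upper), `n`, `k`, and the ANOVA
#'   mean squares (`msr`, `msc`, `mse`).
#' @export
icc_agreement <- function(measurements, conf_level = 0.95) {
  m <- as.matrix(measurements)
  if (!is.numeric(m) || anyNA(m)) stop("measurements must be numeric, no NA")
  n <- nrow(m); k <- ncol(m)
  if (n < 5) stop("need at least 5 subjects")
  if (k < 2) stop("need at least 2 methods")
  grand <- mean(m)
  if (all(m == grand)) stop("zero total variance: ICC undefined")
  ssr <- k * sum((rowMeans(m) - grand)^2)
  ssc <- n * sum((colMeans(m) - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))

  alpha <- 1 - conf_level
  fj <- msc / mse
  vn <- (k - 1) * (n - 1) *
    (k * icc * fj + n * (1 + (k - 1) * icc) - k * icc)^2
  vd <- (n - 1) * k^2 * icc^2 * fj^2 +
    (n * (1 + (k - 1) * icc) - k * icc)^2
  v <- vn / vd
  fl <- qf(1 - alpha / 2, n - 1, v)
  fu <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  list(icc = icc, ci = c(lower = lower, upper = upper), n = n, k = k,
       msr = msr, msc = msc, mse = mse)
}
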