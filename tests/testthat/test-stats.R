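make_eye <- function(eye_id = "E1", axial = 24, ssi = 70,
                     inl = TRUE, hfl = TRUE) {
  data.frame(eye_id = eye_id, axial_length = axial, ssi = ssi,
             foci_present_inl = inl, foci_present_hfl = hfl,
             stringsAsFactors = FALSE)
}

test_that("eligibility boundaries follow the inclusion rules exactly", {
  cohort <- rbind(
    make_eye("ssi_60", ssi = 60),            # "60 or less" -> excluded
    make_eye("ssi_61", ssi = 60.5),          # retained
    make_eye("al_22", axial = 22.0),         # boundary retained
    make_eye("al_26", axial = 26.0),         # boundary retained
    make_eye("al_short", axial = 21.9),      # excluded
    make_eye("al_long", axial = 26.1),       # excluded
    make_eye("hfl_only", inl = FALSE),       # excluded: needs both layers
    make_eye("inl_only", hfl = FALSE),       # excluded
    make_eye("ok"))
  out <- eligibility_filter(cohort)
  expect_setequal(out$retained$eye_id,
                  c("ssi_61", "al_22", "al_26", "ok"))
  expect_setequal(out$excluded$eye_id,
                  c("ssi_60", "al_short", "al_long", "hfl_only", "inl_only"))
  expect_true(all(out$log$eye_id %in% out$excluded$eye_id))
  expect_match(out$log$reason[out$log$eye_id == "ssi_60"], "60 or less")
})

test_that("eligibility filtering is idempotent and partitions the input", {
  co <- generate_cohort(cohort_config(seed = 2L))
  out <- eligibility_filter(co)
  expect_identical(nrow(out$retained) + nrow(out$excluded), nrow(co))
  again <- eligibility_filter(out$retained)
  expect_identical(again$retained, out$retained)
  expect_identical(nrow(again$excluded), 0L)
})

test_that("missing eligibility fields are reported by eye and field", {
  co <- make_eye("E9")
  co$ssi <- NA
  expect_error(eligibility_filter(co), "'ssi'.*E9")
  expect_error(eligibility_filter(co[, -3]), "missing required field")
})

test_that("pearson_r handles exact linearity, orthogonality, and degeneracy", {
  x <- 1:20
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  set.seed(9)
  y <- rnorm(20)
  y_orth <- residuals(lm(y ~ x))           # orthogonalized against x
  expect_lt(abs(pearson_r(x, y_orth)$r), 1e-12)
  expect_error(pearson_r(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("sample correlations of calibrated cohorts respect the Fisher-z interval", {
  z <- atanh(0.55)
  band <- tanh(z + c(-1, 1) * qnorm(0.975) / sqrt(102 - 3))
  inside <- vapply(1:100, function(s) {
    co <- generate_cohort(cohort_config(target_r = 0.55, seed = 300L + s))
    r <- pearson_r(co$intensity, co$logmar_va)$r
    r > band[1] && r < band[2]
  }, TRUE)
  # nominal coverage 95%; allow 3 binomial SEs around it
  expect_gte(mean(inside), 0.95 - 3 * sqrt(0.95 * 0.05 / 100))
})

test_that("near-null groups give F near 0 and saturated adjusted p", {
  values <- rep(c(10, 20, 30), 4) + rep(c(0, 1e-6, -1e-6, 2e-6), each = 3)
  groups <- rep(c("a", "b", "c", "d"), each = 3)
  out <- anova_bonferroni(values, groups)
  expect_lt(out$F, 1e-3)
  expect_true(all(out$pairwise$p_adj == 1))
})

test_that("Bonferroni adjustment multiplies raw pairwise p-values by the pair count", {
  set.seed(12)
  values <- rnorm(40, rep(c(0, 1, 2, 3), each = 10))
  groups <- factor(rep(letters[1:4], each = 10))
  out <- anova_bonferroni(values, groups)
  expect_identical(nrow(out$pairwise), 6L)
  expect_equal(out$pairwise$p_adj, pmin(1, out$pairwise$p_raw * 6))
  # raw pairwise p agrees with a pooled-SD two-sample t computed by hand
  sp <- split(values, groups)
  s2 <- sum(vapply(sp, function(v) sum((v - mean(v))^2), 0)) / (40 - 4)
  tstat <- (mean(sp$a) - mean(sp$b)) / sqrt(s2 * (1 / 10 + 1 / 10))
  p_ab <- 2 * pt(-abs(tstat), 40 - 4)
  row_ab <- out$pairwise[out$pairwise$group1 == "b" &
                           out$pairwise$group2 == "a", ]
  expect_equal(row_ab$p_raw, p_ab, tolerance = 1e-12)
  expect_error(anova_bonferroni(rnorm(3), c("a", "a", "b")), "fewer than 2")
})

test_that("two-group comparison reports means, SDs, and a Welch test", {
  v <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c(FALSE, TRUE), each = 3)
  out <- two_group_compare(v, g)
  expect_equal(out$t, 0)
  expect_equal(out$p, 1)
  expect_equal(unname(out$means), c(2, 2))
  set.seed(3)
  v2 <- c(rnorm(10, 0), rnorm(10, 5))
  g2 <- rep(c("x", "y"), each = 10)
  ref <- t.test(v2[11:20], v2[1:10])
  out2 <- two_group_compare(v2, g2)
  expect_equal(out2$t, unname(ref$statistic))
  expect_equal(out2$p, ref$p.value)
  expect_error(two_group_compare(v, rep(TRUE, 6)), "2 groups")
})

test_that("EZ-group rejection rate matches the noncentral-t power oracle", {
  rejections <- vapply(1:200, function(s) {
    co <- generate_cohort(cohort_config(seed = 5000L + s))
    two_group_compare(co$intensity, co$ez_disrupted)$p < 0.001
  }, TRUE)
  # analytic Welch power at the generator's effect size (delta 16, SD 22,
  # groups 70/32, alpha 0.001 two-sided)
  n1 <- 70; n2 <- 32; s <- 22
  se <- s * sqrt(1 / n1 + 1 / n2)
  nc <- (88.3 - 72.3) / se
  v1 <- s^2 / n1; v2 <- s^2 / n2
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  crit <- qt(1 - 0.0005, df)
  power <- 1 - pt(crit, df, ncp = nc) + pt(-crit, df, ncp = nc)
  mc_se <- sqrt(power * (1 - power) / 200)
  expect_lt(abs(mean(rejections) - power), 3 * mc_se + 0.02)
})

test_that("standardized betas reduce to correlations in the classic identities", {
  set.seed(21)
  n <- 200
  d <- data.frame(x1 = rnorm(n))
  d$y <- 0.6 * d$x1 + rnorm(n)
  fit1 <- forced_entry_regression(d, "y", "x1")
  expect_equal(fit1$beta, cor(d$x1, d$y), tolerance = 1e-12)
  # orthogonal standardized predictors: each beta is its marginal correlation
  # (orthogonalize against the intercept too, so centering preserves it)
  x <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, -1]
  d2 <- data.frame(x1 = x[, 1], x2 = x[, 2], x3 = x[, 3])
  d2$y <- 1.5 * d2$x1 - 0.8 * d2$x2 + rnorm(n, 0, 0.5)
  d2[] <- lapply(d2, function(v) (v - mean(v)) / sd(v))
  fit2 <- forced_entry_regression(d2, "y", c("x1", "x2", "x3"))
  expect_equal(fit2$beta, vapply(d2[1:3], cor, 0, y = d2$y),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("regression matches a hand-rolled normal-equations solver", {
  co <- generate_cohort(cohort_config(seed = 31L))
  fit <- forced_entry_regression(co, "logmar_va",
                                 c("intensity", "ez_disrupted",
                                   "csf_thickness"))
  z <- scale(data.frame(y = co$logmar_va, i = co$intensity,
                        e = as.numeric(co$ez_disrupted),
                        c = co$csf_thickness))
  X <- cbind(1, z[, 2:4])
  beta <- solve(t(X) %*% X, t(X) %*% z[, 1])
  resid <- z[, 1] - X %*% beta
  sigma2 <- sum(resid^2) / (nrow(X) - ncol(X))
  se <- sqrt(diag(sigma2 * solve(t(X) %*% X)))
  p <- 2 * pt(-abs(beta / se), nrow(X) - ncol(X))
  expect_equal(fit$beta, unname(beta[-1]), tolerance = 1e-10)
  expect_equal(fit$se, unname(se[-1]), tolerance = 1e-10)
  expect_equal(fit$p, unname(p[-1]), tolerance = 1e-10)
})

test_that("collinear predictors are refused", {
  co <- generate_cohort(cohort_config(seed = 4L))
  co$dup <- co$intensity * 2
  expect_error(
    forced_entry_regression(co, "logmar_va", c("intensity", "dup")),
    "collinear")
})

test_that("Cohen's kappa spans its reference points", {
  a <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  expect_equal(cohen_kappa(a, a)$kappa, 1)
  # observed agreement equal to chance by construction: kappa = 0
  b <- c(TRUE, FALSE, TRUE, FALSE)
  c2 <- c(TRUE, TRUE, FALSE, FALSE)
  k0 <- cohen_kappa(b, c2)
  expect_equal(k0$po, k0$pe)
  expect_equal(k0$kappa, 0)
  # 2x2 table a=40 b=5 c=10 d=45: po=0.85, pe=0.5, kappa=0.7
  ra <- rep(c(TRUE, TRUE, FALSE, FALSE), c(40, 5, 10, 45))
  rb <- rep(c(TRUE, FALSE, TRUE, FALSE), c(40, 5, 10, 45))
  expect_equal(cohen_kappa(ra, rb)$kappa, 0.7, tolerance = 1e-12)
  expect_error(cohen_kappa(rep(TRUE, 5), rep(TRUE, 5)), "constant")
})

test_that("ICC(2,1) spans its reference points and matches an ANOVA oracle", {
  set.seed(6)
  a <- rnorm(10, 50, 10)
  expect_equal(icc_agreement(cbind(a, a))$icc, 1, tolerance = 1e-12)
  noisy <- cbind(a, a + rnorm(10, 0, 100))
  expect_lt(icc_agreement(noisy)$icc, 0.2)
  # from-scratch oracle via the two-way ANOVA decomposition in aov()
  m <- cbind(a, a + rnorm(10, 0, 5))
  long <- data.frame(v = as.vector(m),
                     row = factor(rep(1:10, 2)),
                     col = factor(rep(1:2, each = 10)))
  ms <- anova(aov(v ~ row + col, data = long))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- 10; k <- 2
  icc_oracle <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  got <- icc_agreement(m)
  expect_equal(got$icc, icc_oracle, tolerance = 1e-12)
  expect_lt(got$ci["lower"], got$icc)
  expect_gt(got$ci["upper"], got$icc)
  expect_error(icc_agreement(matrix(5, 6, 2)), "zero total variance")
  expect_error(icc_agreement(matrix(rnorm(8), 4, 2)), "at least 5")
})
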