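#' Quantify one eye: slabs, masks, decorrelation signal intensity
#'
#' Runs the three-step quantification on one paired volume: (1) global
#' thresholding of the structural HFL slab to delineate hyperreflective
#' foci, (2) binarization of the superficial angiogram and exclusion of
#' vessel-projection pixels from the foci mask, (3) histogram averaging of
#' the HFL decorrelation grayscale over the retained pixels.
#'
#' @param volume a [paired_volume()].
#' @param surfaces a [boundary_surfaces()].
#' @param threshold_method `"isodata"` (default) or `"otsu"`.
#' @param vessel_dilation_px vessel-mask dilation radius (default 0).
#' @param projection slab projection statistic (default `"mean"`).
#' @return List with the three slabs (`hfl_structural`, `hfl_angio`,
#'   `superficial_angio`), the three masks (`foci`, `vessels`, `retained`),
#'   and `result` (a `foci_decorrelation_result`).
#' @export
quantify_eye <- function(volume, surfaces, threshold_method = "isodata",
                         vessel_dilation_px = 0, projection = "mean") {
  hfl_struct <- extract_slab(volume, surfaces,
                             slab_preset("hfl", projection), "structural")
  hfl_angio <- extract_slab(volume, surfaces,
                            slab_preset("hfl", projection), "decorrelation")
  sup_angio <- extract_slab(volume, surfaces,
                            slab_preset("superficial", projection),
                            "decorrelation")
  foci <- global_threshold(hfl_struct, threshold_method)
  vessels <- vessel_mask(sup_angio, threshold_method)
  retained <- remove_projection(foci, vessels, vessel_dilation_px)
  result <- decorrelation_intensity(hfl_angio, retained)
  list(hfl_structural = hfl_struct, hfl_angio = hfl_angio,
       superficial_angio = sup_angio,
       foci = foci, vessels = vessels, retained = retained,
       result = result)
}

#' Run the quantification pipeline over a batch of eyes
#'
#' Accepts either phantom configurations (volumes are generated on the fly
#' with known ground truth) or measured inputs (`list(volume =, surfaces =)`
#' pairs). A stage failure aborts that eye with a logged reason; the run
#' continues for the remaining eyes. With an output directory, all
#' intermediate slabs and masks, per-eye results, and a manifest (file
#' hashes, seed, package version) sufficient to reproduce the run are
#' written.
#'
#' @param eyes a [phantom_config()], a list of them, or a list of
#'   `list(volume =, surfaces =)` inputs. List names become eye ids.
#' @param out_dir optional output directory; created if needed.
#' @param threshold_method,vessel_dilation_px,projection passed to
#'   [quantify_eye()].
#' @param write_intermediates write slabs and masks (default `TRUE` when
#'   `out_dir` is given).
#' @return data.frame with one row per eye: `eye_id`, `status`,
#'   `intensity`, `n_pixels`, `foci_pixels`, `excluded_pixels`,
#'   `foci_threshold`, `vessel_threshold`, `true_intensity` (phantom eyes,
#'   else `NA`), `reason` (on error).
#' @export
run_quantify <- function(eyes, out_dir = NULL,
                         threshold_method = "isodata",
                         vessel_dilation_px = 0, projection = "mean",
                         write_intermediates = !is.null(out_dir)) {
  if (inherits(eyes, "phantom_config")) eyes <- list(eyes)
  if (is.null(names(eyes)))
    names(eyes) <- sprintf("E%03d", seq_along(eyes))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  manifest_files <- character(0)

  rows <- lapply(names(eyes), function(id) {
    eye <- eyes[[id]]
    row <- data.frame(eye_id = id, status = "ok", intensity = NA_real_,
                      n_pixels = NA_integer_, foci_pixels = NA_integer_,
                      excluded_pixels = NA_integer_,
                      foci_threshold = NA_integer_,
                      vessel_threshold = NA_integer_,
                      true_intensity = NA_real_, reason = "",
                      stringsAsFactors = FALSE)
    out <- tryCatch({
      if (inherits(eye, "phantom_config")) {
        ph <- generate_phantom(eye)
        volume <- ph$volume; surfaces <- ph$surfaces
        row$true_intensity <- ph$truth$true_intensity
      } else {
        volume <- eye$volume; surfaces <- eye$surfaces
      }
      q <- quantify_eye(volume, surfaces, threshold_method,
                        vessel_dilation_px, projection)
      row$intensity <- q$result$intensity
      row$n_pixels <- q$result$n_pixels
      row$foci_pixels <- sum(q$foci$mask)
      row$excluded_pixels <- sum(q$foci$mask) - q$result$n_pixels
      row$foci_threshold <- q$foci$threshold
      row$vessel_threshold <- q$vessels$threshold
      if (!is.null(out_dir) && write_intermediates) {
        for (nm in c("hfl_structural", "hfl_angio", "superficial_angio",
                     "foci", "vessels", "retained")) {
          f <- file.path(out_dir, sprintf("%s_%s.tif", id, nm))
          write_image(q[[nm]], f)
          manifest_files <<- c(manifest_files, f)
        }
        if (inherits(eye, "phantom_config")) {
          f <- file.path(out_dir, sprintf("%s_config.yaml", id))
          write_config_yaml(eye, f)
          manifest_files <<- c(manifest_files, f)
        }
      }
      row
    }, error = function(e) {
      row$status <- "error"
      row$reason <- conditionMessage(e)
      row
    })
    out
  })
  results <- do.call(rbind, rows)

  if (!is.null(out_dir)) {
    res_file <- file.path(out_dir, "results.csv")
    write.csv(results, res_file, row.names = FALSE)
    manifest_files <- c(manifest_files, res_file)
    manifest <- list(
      package = "octafoci",
      version = as.character(packageVersion("octafoci")),
      threshold_method = threshold_method,
      vessel_dilation_px = vessel_dilation_px,
      projection = projection,
      files = lapply(manifest_files, function(f)
        list(path = basename(f), md5 = unname(tools::md5sum(f)))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  results
}

run_safely <- function(expr) {
  tryCatch(expr, error = function(e)
    list(error = conditionMessage(e)))
}

#' Cohort-level statistics report
#'
#' Runs the full statistics layer on a per-eye table: descriptive summary,
#' correlations of the decorrelation signal intensity with logMAR VA (all
#' eyes and within DME strata) and CSF thickness, EZ-status group
#' comparison, ANOVA across DR severity grades with Bonferroni-corrected
#' pairwise comparisons, forced-entry multiple regression of logMAR VA on
#' intensity, EZ status and CSF thickness, and — when the columns are
#' present — rater agreement (`rater_a_*` / `rater_b_*` binary columns via
#' Cohen's kappa) and method agreement (`area_auto` / `area_manual` via
#' ICC). Analyses that fail (e.g. degenerate groups) are reported as error
#' strings; the run always completes.
#'
#' @param cohort a cohort table (e.g. [generate_cohort()] output) with an
#'   `intensity` column, or one to be joined with `results`.
#' @param results optional [run_quantify()] output; its `intensity`
#'   replaces the cohort's, joined on `eye_id`. Join failures are listed in
#'   the report.
#' @return A list of class `stats_report`.
#' @export
run_stats <- function(cohort, results = NULL) {
  join_failures <- character(0)
  if (!is.null(results)) {
    ok <- results$status == "ok" & !is.na(results$intensity)
    matched <- match(cohort$eye_id, results$eye_id[ok])
    join_failures <- cohort$eye_id[is.na(matched)]
    cohort <- cohort[!is.na(matched), , drop = FALSE]
    cohort$intensity <- results$intensity[ok][matched[!is.na(matched)]]
  }

  report <- list(join_failures = join_failures)
  report$descriptive <- run_safely(list(
    n_eyes = nrow(cohort),
    n_patients = if ("patient_id" %in% names(cohort))
      length(unique(cohort$patient_id)) else NA_integer_,
    intensity = c(mean = mean(cohort$intensity), sd = sd(cohort$intensity)),
    logmar_va = c(mean = mean(cohort$logmar_va), sd = sd(cohort$logmar_va)),
    csf_thickness = c(mean = mean(cohort$csf_thickness),
                      sd = sd(cohort$csf_thickness)),
    dr_grade = if ("dr_grade" %in% names(cohort))
      table(cohort$dr_grade) else NULL,
    ez_disrupted = sum(cohort$ez_disrupted),
    dme = if ("dme" %in% names(cohort)) sum(cohort$dme) else NA_integer_))

  report$r_intensity_va <-
    run_safely(pearson_r(cohort$intensity, cohort$logmar_va))
  report$r_intensity_csf <-
    run_safely(pearson_r(cohort$intensity, cohort$csf_thickness))
  if ("dme" %in% names(cohort)) {
    report$r_intensity_va_dme <- run_safely(
      pearson_r(cohort$intensity[cohort$dme],
                cohort$logmar_va[cohort$dme]))
    report$r_intensity_va_no_dme <- run_safely(
      pearson_r(cohort$intensity[!cohort$dme],
                cohort$logmar_va[!cohort$dme]))
  }
  report$ez_comparison <-
    run_safely(two_group_compare(cohort$intensity, cohort$ez_disrupted))
  if ("dr_grade" %in% names(cohort))
    report$dr_anova <-
      run_safely(anova_bonferroni(cohort$intensity, cohort$dr_grade))
  report$regression <- run_safely(forced_entry_regression(
    cohort, "logmar_va", c("intensity", "ez_disrupted", "csf_thickness")))

  for (layer in c("inl", "hfl")) {
    a <- paste0("rater_a_", layer); b <- paste0("rater_b_", layer)
    if (all(c(a, b) %in% names(cohort)))
      report[[paste0("kappa_", layer)]] <-
        run_safely(cohen_kappa(cohort[[a]], cohort[[b]]))
  }
  if (all(c("area_auto", "area_manual") %in% names(cohort)))
    report$icc_area <- run_safely(
      icc_agreement(cbind(cohort$area_auto, cohort$area_manual)))

  class(report) <- "stats_report"
  report
}

is_error <- function(x) is.list(x) && !is.null(x$error)

#' @export
print.stats_report <- function(x, ...) {
  fmt_r <- function(a) {
    if (is_error(a)) return(paste("error:", a$error))
    sprintf("R = %.3f, P %s (n = %d)", a$r,
            if (a$p < 0.001) "< 0.001" else sprintf("= %.3f", a$p), a$n)
  }
  cat("Cohort statistics report\n")
  if (!is_error(x$descriptive)) {
    d <- x$descriptive
    cat(sprintf("  eyes/patients: %d/%s\n", d$n_eyes, d$n_patients))
    cat(sprintf("  intensity: %.1f ± %.1f; logMAR VA: %.3f ± %.3f; CSF: %.0f ± %.0f um\n",
                d$intensity[1], d$intensity[2], d$logmar_va[1],
                d$logmar_va[2], d$csf_thickness[1], d$csf_thickness[2]))
  }
  cat("  intensity vs logMAR VA:   ", fmt_r(x$r_intensity_va), "\n")
  cat("  intensity vs CSF:         ", fmt_r(x$r_intensity_csf), "\n")
  if (!is.null(x$r_intensity_va_dme))
    cat("  intensity vs VA (DME):    ", fmt_r(x$r_intensity_va_dme), "\n")
  if (!is.null(x$r_intensity_va_no_dme))
    cat("  intensity vs VA (no DME): ", fmt_r(x$r_intensity_va_no_dme), "\n")
  if (!is_error(x$ez_comparison))
    cat(sprintf("  EZ disrupted vs intact: %s; P %s\n",
                x$ez_comparison$formatted,
                if (x$ez_comparison$p < 0.001) "< 0.001"
                else sprintf("= %.3f", x$ez_comparison$p)))
  if (!is.null(x$dr_anova) && !is_error(x$dr_anova))
    cat(sprintf("  DR grade ANOVA: F = %.2f, P = %.3f (%d pairwise, Bonferroni)\n",
                x$dr_anova$F, x$dr_anova$p, nrow(x$dr_anova$pairwise)))
  if (!is_error(x$regression)) {
    cat("  forced-entry regression (outcome logMAR VA):\n")
    for (i in seq_len(nrow(x$regression)))
      cat(sprintf("    %-14s beta = %6.3f, P %s\n",
                  x$regression$predictor[i], x$regression$beta[i],
                  if (x$regression$p[i] < 0.001) "< 0.001"
                  else sprintf("= %.3f", x$regression$p[i])))
  }
  for (layer in c("inl", "hfl")) {
    k <- x[[paste0("kappa_", layer)]]
    if (!is.null(k) && !is_error(k))
      cat(sprintf("  kappa (%s): %.3f\n", toupper(layer), k$kappa))
  }
  if (!is.null(x$icc_area) && !is_error(x$icc_area))
    cat(sprintf("  ICC auto vs manual area: %.3f [%.3f-%.3f]\n",
                x$icc_area$icc, x$icc_area$ci[1], x$icc_area$ci[2]))
  errs <- names(x)[vapply(x, is_error, TRUE)]
  if (length(errs))
    cat("  analyses with errors:", paste(errs, collapse = ", "), "\n")
  invisible(x)
}

#' Write a statistics report as JSON
#'
#' @param report a [run_stats()] result.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_stats_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  invisible(path)
}
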