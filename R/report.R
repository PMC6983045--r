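#' Run the full cosolvency analysis
#'
#' End-to-end pipeline on one dataset: ideal solubility and activity
#' coefficients from the fusion properties, apparent dissolution
#' thermodynamics at the harmonic-mean temperature, enthalpy-entropy
#' compensation, and the five cosolvency model fits with their RMSD
#' summaries. Every number in the report is recomputed from the inputs; no
#' cached constants.
#'
#' @param dataset a [solubility_dataset()].
#' @param fusion a [fusion_properties()] object.
#' @param R molar gas constant, J mol^-1 K^-1.
#' @param ja_terms maximum interaction-term count for the Jouyban-Acree
#'   models (see [fit_jouyban_acree()]).
#' @param rmsd_overall overall-RMSD aggregation used for the pass/fail
#'   flags, `"mean"` or `"pooled"`.
#' @param threshold overall-RMSD adequacy bound, percent.
#' @param strict if `TRUE`, error when any model's overall RMSD is at or
#'   above `threshold`.
#' @return object of class `cosolv_report`: list with `dataset`, `ideal`,
#'   `activity`, `thermo`, `compensation`, `fits` (named list of five
#'   `cosolv_fit`s), `evaluation` (per-model summaries), and `config`.
#' @examples
#' \donttest{
#' rep <- run_full_analysis(ppd_dataset(), ppd_fusion())
#' rep$evaluation$jouyban_acree$overall_rmsd
#' }
#' @export
run_full_analysis <- function(dataset, fusion, R = GAS_CONSTANT,
                              ja_terms = 3,
                              rmsd_overall = c("mean", "pooled"),
                              threshold = 2.0, strict = FALSE) {
  stopifnot(inherits(dataset, "solubility_dataset"),
            inherits(fusion, "fusion_properties"))
  rmsd_overall <- match.arg(rmsd_overall)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  ideal <- stage("ideal_solubility",
                 ideal_solubility_curve(fusion, dataset_temperatures(dataset),
                                        R = R))
  activity <- stage("activity_coefficients",
                    activity_coefficients(dataset, ideal))
  thermo <- stage("solution_thermodynamics",
                  solution_thermodynamics(dataset, R = R))
  compensation <- stage("compensation_analysis", compensation_analysis(thermo))
  # Model fits are isolated: a failed precondition (e.g. a grid without a
  # neat series, which the mixture models require) is recorded against that
  # model and leaves the remaining stages intact.
  fit_stage <- function(expr) {
    tryCatch(expr, error = function(e)
      structure(list(message = conditionMessage(e)),
                class = "cosolv_fit_error"))
  }
  fits <- list(
    vant_hoff = fit_stage(fit_vant_hoff(dataset)),
    apelblat = fit_stage(fit_apelblat(dataset)),
    yalkowsky = fit_stage(fit_yalkowsky(dataset)),
    jouyban_acree = fit_stage(fit_jouyban_acree(dataset,
                                                n_terms = ja_terms)),
    ja_vant_hoff = fit_stage(fit_ja_vant_hoff(dataset,
                                              n_terms = ja_terms)))
  ok <- !vapply(fits, inherits, logical(1), "cosolv_fit_error")
  evaluation <- lapply(fits[ok], evaluate_model, threshold = threshold,
                       overall = rmsd_overall)
  if (strict) {
    bad <- c(names(fits)[!ok],
             names(Filter(function(e) !e$passes, evaluation)))
    if (length(bad) > 0)
      stop("strict mode: failed fit or overall RMSD at or above ",
           threshold, "% for model(s): ", paste(bad, collapse = ", "))
  }
  structure(list(dataset = dataset, fusion = fusion, ideal = ideal,
                 activity = activity, thermo = thermo,
                 compensation = compensation, fits = fits,
                 evaluation = evaluation,
                 config = list(R = R, ja_terms = ja_terms,
                               rmsd_overall = rmsd_overall,
                               threshold = threshold)),
            class = "cosolv_report")
}

#' @export
print.cosolv_report <- function(x, ...) {
  print(x$dataset)
  cat(sprintf("Ideal solubility: %.3g (%.1f K) to %.3g (%.1f K)\n",
              x$ideal$x_idl[1], x$ideal$T_K[1],
              x$ideal$x_idl[nrow(x$ideal)], x$ideal$T_K[nrow(x$ideal)]))
  print(x$compensation)
  cat(sprintf("Model fits (overall RMSD %%, %s aggregation; threshold %.1f%%):\n",
              x$config$rmsd_overall, x$config$threshold))
  for (nm in names(x$fits)) {
    if (inherits(x$fits[[nm]], "cosolv_fit_error")) {
      cat(sprintf("  %-14s failed: %s\n", nm, x$fits[[nm]]$message))
    } else {
      e <- x$evaluation[[nm]]
      cat(sprintf("  %-14s %6.3f%%  %s\n", nm, e$overall_rmsd,
                  if (e$passes) "ok" else "EXCEEDS THRESHOLD"))
    }
  }
  invisible(x)
}

#' Write the analysis report to a directory of CSV tables and JSON
#'
#' Emits `table2_activity.csv`, `table3_thermo.csv`, `table4_vanthoff.csv`,
#' `table5_apelblat.csv`, `table6_yalkowsky.csv`, `table7_ja.csv` and a
#' machine-readable `report.json` (parameters, RMSDs, compensation,
#' config).
#'
#' @param report a `cosolv_report` from [run_full_analysis()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_analysis_report <- function(report, dir) {
  stopifnot(inherits(report, "cosolv_report"))
  errored <- Filter(function(f) inherits(f, "cosolv_fit_error"), report$fits)
  if (length(errored) > 0)
    stop("cannot write report: failed fit(s): ",
         paste(names(errored), collapse = ", "))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, file)
    write.csv(df, file.path(dir, file), row.names = FALSE)
  w(report$activity, "table2_activity.csv")
  thermo_out <- data.frame(m = report$thermo$m,
                           dH0_kJ_mol = report$thermo$dH0 / 1000,
                           dG0_kJ_mol = report$thermo$dG0 / 1000,
                           dS0_J_mol_K = report$thermo$dS0,
                           r2 = report$thermo$r2)
  w(thermo_out, "table3_thermo.csv")
  vh <- report$fits$vant_hoff
  w(cbind(vh$params, rmsd = unname(vh$rmsd_per_m)), "table4_vanthoff.csv")
  ap <- report$fits$apelblat
  w(cbind(ap$params, rmsd = unname(ap$rmsd_per_m)), "table5_apelblat.csv")
  yal <- report$fits$yalkowsky
  yal_tab <- data.frame(m = yal$predictions$m, T_K = yal$predictions$T_K,
                        log10_x_calc = log10(yal$predictions$x_calc))
  w(yal_tab, "table6_yalkowsky.csv")
  ja <- report$fits$jouyban_acree
  javh <- report$fits$ja_vant_hoff
  ja_tab <- data.frame(
    model = c(sprintf("jouyban_acree_J%d", seq_along(ja$params$J) - 1L),
              "jouyban_acree_overall_rmsd",
              "ja_vant_hoff_A1", "ja_vant_hoff_B1",
              "ja_vant_hoff_A2", "ja_vant_hoff_B2",
              sprintf("ja_vant_hoff_J%d", seq_along(javh$params$J) - 1L),
              "ja_vant_hoff_overall_rmsd"),
    value = c(ja$params$J, ja$overall_rmsd,
              javh$params$A1, javh$params$B1, javh$params$A2,
              javh$params$B2, javh$params$J, javh$overall_rmsd))
  w(ja_tab, "table7_ja.csv")

  json <- list(
    dataset = list(solute = report$dataset$solute_name,
                   cosolvent = report$dataset$cosolvent_name,
                   solvent = report$dataset$solvent_name,
                   n_records = nrow(report$dataset$data)),
    T_hm = attr(report$thermo, "T_hm"),
    compensation = report$compensation[c("slope", "intercept", "r2",
                                         "slope_reversed")],
    models = lapply(report$evaluation, function(e)
      list(overall_rmsd = e$overall_rmsd,
           overall_rmsd_pooled = e$overall_rmsd_pooled,
           passes = e$passes)),
    config = report$config)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
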