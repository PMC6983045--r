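#' Harmonic-mean temperature
#'
#' `n / sum(1/T_i)`, the reference temperature of the apparent dissolution
#' analysis.
#'
#' @param temps temperatures (K), non-empty, all positive.
#' @return scalar, K.
#' @examples
#' harmonic_mean_temperature(c(298.2, 303.2, 308.2, 313.2, 318.2))
#' @export
harmonic_mean_temperature <- function(temps) {
  if (length(temps) == 0) stop("empty temperature list")
  if (any(!is.finite(temps)) || any(temps <= 0))
    stop("temperatures must be positive and finite")
  length(temps) / sum(1 / temps)
}

#' Apparent dissolution thermodynamics from one solubility series
#'
#' Ordinary least squares of `ln x_e` on `(1/T - 1/T_hm)`. The slope gives
#' the apparent standard dissolution enthalpy `dH0 = -R * slope` (slope is
#' invariant to the choice of `T_hm`, which only shifts the intercept); the
#' intercept gives the apparent standard Gibbs energy
#' `dG0 = -R * T_hm * intercept`; the entropy follows from the Gibbs
#' relation `dS0 = (dH0 - dG0) / T_hm`, which holds to machine precision by
#' construction.
#'
#' @param T temperatures (K), at least 3 distinct values.
#' @param x_e mole-fraction solubilities, all positive.
#' @param T_hm harmonic-mean reference temperature (K); defaults to
#'   [harmonic_mean_temperature()] of `T`.
#' @param R molar gas constant, J mol^-1 K^-1.
#' @return object of class `thermo_result`: list with `dH0`, `dG0` (J mol^-1),
#'   `dS0` (J mol^-1 K^-1), `r2` of the regression, `T_hm`, `n`.
#' @examples
#' s <- dataset_series(ppd_dataset(), 0)
#' fit_solution_thermo(s$T_K, s$x_e)
#' @export
fit_solution_thermo <- function(T, x_e, T_hm = harmonic_mean_temperature(T),
                                R = GAS_CONSTANT) {
  if (length(T) != length(x_e)) stop("T and x_e lengths differ")
  if (length(T) < 3) stop("need at least 3 temperature points, got ", length(T))
  if (any(x_e <= 0)) stop("x_e must be positive")
  if (any(T <= 0)) stop("temperatures must be positive")
  if (length(unique(T)) < 2) stop("zero temperature variance: singular fit")
  u <- 1 / T - 1 / T_hm
  fit <- lm(log(x_e) ~ u)
  b <- coef(fit)
  dH0 <- -R * unname(b[2])
  dG0 <- -R * T_hm * unname(b[1])
  # squared Pearson correlation of fitted vs observed ln x_e; identical to
  # the OLS R^2 with intercept, without summary.lm's perfect-fit warning
  r2 <- cor(log(x_e), fitted(fit))^2
  structure(list(dH0 = dH0, dG0 = dG0, dS0 = (dH0 - dG0) / T_hm,
                 r2 = r2, T_hm = T_hm, n = length(T)),
            class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf(
    "dH0 = %.2f kJ/mol, dG0 = %.2f kJ/mol, dS0 = %.2f J/(mol K), R2 = %.4f (T_hm = %.2f K, n = %d)\n",
    x$dH0 / 1000, x$dG0 / 1000, x$dS0, x$r2, x$T_hm, x$n))
  invisible(x)
}

#' Apparent dissolution thermodynamics per composition
#'
#' Runs [fit_solution_thermo()] on the temperature series of every
#' composition in the grid, at a common harmonic-mean reference temperature.
#'
#' @param dataset a [solubility_dataset()].
#' @param T_hm reference temperature; defaults to the harmonic mean of the
#'   dataset's temperature grid.
#' @param R molar gas constant.
#' @return data frame of class `thermo_table` with columns `m`, `dH0`, `dG0`
#'   (J mol^-1), `dS0` (J mol^-1 K^-1), `r2`; attribute `T_hm`.
#' @export
solution_thermodynamics <- function(dataset, T_hm = NULL, R = GAS_CONSTANT) {
  stopifnot(inherits(dataset, "solubility_dataset"))
  if (is.null(T_hm))
    T_hm <- harmonic_mean_temperature(dataset_temperatures(dataset))
  ms <- dataset_compositions(dataset)
  rows <- lapply(ms, function(m) {
    s <- dataset_series(dataset, m)
    th <- fit_solution_thermo(s$T_K, s$x_e, T_hm = T_hm, R = R)
    data.frame(m = m, dH0 = th$dH0, dG0 = th$dG0, dS0 = th$dS0, r2 = th$r2)
  })
  out <- do.call(rbind, rows)
  attr(out, "T_hm") <- T_hm
  class(out) <- c("thermo_table", "data.frame")
  out
}

#' @export
print.thermo_table <- function(x, ...) {
  cat(sprintf("Apparent dissolution thermodynamics at T_hm = %.2f K\n",
              attr(x, "T_hm")))
  show <- data.frame(m = x$m, `dH0 (kJ/mol)` = round(x$dH0 / 1000, 2),
                     `dG0 (kJ/mol)` = round(x$dG0 / 1000, 2),
                     `dS0 (J/mol/K)` = round(x$dS0, 2),
                     R2 = round(x$r2, 4), check.names = FALSE)
  print.data.frame(show, row.names = FALSE)
  invisible(x)
}

#' Enthalpy-entropy compensation analysis
#'
#' Ordinary least squares of the apparent dissolution enthalpy on the
#' apparent Gibbs energy across compositions. A slope above 1 on the
#' enthalpy-vs-Gibbs plot is conventionally read as enthalpy-driven
#' solvation; below 1, entropy-driven. Because the regression orientation is
#' a known source of ambiguity in the compensation literature, the slope of
#' the reversed regression (`dG0` on `dH0`) is also reported as
#' `slope_reversed`.
#'
#' @param thermo a `thermo_table` from [solution_thermodynamics()], or any
#'   data frame with columns `dH0` and `dG0` (at least 3 rows).
#' @return object of class `compensation_result`: `slope`, `intercept`
#'   (J mol^-1), `r2`, `slope_reversed`, `n`.
#' @export
compensation_analysis <- function(thermo) {
  stopifnot(is.data.frame(thermo), all(c("dH0", "dG0") %in% names(thermo)))
  if (nrow(thermo) < 3)
    stop("need at least 3 compositions, got ", nrow(thermo))
  fit <- lm(dH0 ~ dG0, data = thermo)
  rev_fit <- lm(dG0 ~ dH0, data = thermo)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r2 = cor(thermo$dH0, thermo$dG0)^2,
                 slope_reversed = unname(coef(rev_fit)[2]),
                 n = nrow(thermo)),
            class = "compensation_result")
}

#' @export
print.compensation_result <- function(x, ...) {
  cat(sprintf(
    "Enthalpy-entropy compensation (n = %d): slope = %.3f, intercept = %.3g kJ/mol, R2 = %.4f\n",
    x$n, x$slope, x$intercept / 1000, x$r2))
  cat(sprintf("  reversed orientation (dG0 ~ dH0): slope = %.3f\n",
              x$slope_reversed))
  invisible(x)
}
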