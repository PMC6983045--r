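#' Specification for a synthetic solubility surface
#'
#' Generative twin of the Jouyban-Acree-van't Hoff surface: the mean
#' log-solubility is
#' `ln x(m,T) = m1 (A1 + B1/T) + m2 (A2 + B2/T) + (m1 m2 / T) sum_i J_i (m1-m2)^i`
#' and measurement error is multiplicative log-normal on `x_e` (additive
#' Gaussian on `ln x_e`), matching where the fitting happens. Defaults are
#' the PPD/DMSO/water study conditions: the fitted neat-solvent van't Hoff
#' parameters, a single interaction term, the 11 x 5 grid, and a 1.38
#' percent relative measurement uncertainty.
#'
#' @param A1,B1 neat-cosolvent van't Hoff intercept and slope (B in K).
#' @param A2,B2 neat-water van't Hoff intercept and slope (K).
#' @param J interaction coefficients, length 1-3 (K).
#' @param temps temperature grid (K).
#' @param m_grid mass-fraction grid; must include 0 and 1 for the mixture
#'   models to be fittable on the result.
#' @param noise_cv coefficient of variation of the multiplicative noise on
#'   `x_e` (0 = noiseless).
#' @param seed integer seed; generation is bit-reproducible for a fixed
#'   spec.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(A1 = 1.54, B1 = -733.05, A2 = 0.55, B2 = -3765.7,
                           J = 25.32,
                           temps = c(298.2, 303.2, 308.2, 313.2, 318.2),
                           m_grid = seq(0, 1, by = 0.1),
                           noise_cv = 0.0138, seed = 1L) {
  stopifnot(length(J) >= 1, length(J) <= 3, all(is.finite(J)),
            is.finite(A1), is.finite(B1), is.finite(A2), is.finite(B2))
  if (length(temps) == 0 || length(m_grid) == 0) stop("empty grid")
  if (any(temps <= 0)) stop("temperatures must be positive")
  if (any(m_grid < 0 | m_grid > 1)) stop("m_grid must lie in [0, 1]")
  if (noise_cv < 0) stop("noise_cv must be non-negative")
  structure(list(A1 = A1, B1 = B1, A2 = A2, B2 = B2, J = J,
                 temps = sort(unique(temps)), m_grid = sort(unique(m_grid)),
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Mean log-solubility surface of the generative model.
synthetic_mean_log <- function(spec, m, T) {
  m2 <- 1 - m
  jsum <- rowSums(vapply(seq_along(spec$J) - 1L,
                         function(k) spec$J[k + 1] * (m - m2)^k,
                         numeric(length(m))))
  m * (spec$A1 + spec$B1 / T) + m2 * (spec$A2 + spec$B2 / T) +
    m * m2 * jsum / T
}

#' Generate a synthetic solubility dataset
#'
#' Draws `x_e(m, T) = exp(mean surface) * eps` with
#' `ln eps ~ N(0, sigma^2)`, `sigma = sqrt(log(1 + noise_cv^2))` (the exact
#' log-normal CV relation; for small CV, `sigma ~ noise_cv`). The caller's
#' RNG state is left untouched.
#'
#' @param spec a [synthetic_spec()].
#' @return a [solubility_dataset()] over the spec's grid.
#' @examples
#' d <- generate_surface(synthetic_spec(noise_cv = 0, seed = 7))
#' @export
generate_surface <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  grid <- expand.grid(T_K = spec$temps, m = spec$m_grid)[, c("m", "T_K")]
  mu <- synthetic_mean_log(spec, grid$m, grid$T_K)
  if (spec$noise_cv > 0) {
    sigma <- sqrt(log(1 + spec$noise_cv^2))
    eps <- local_rng(spec$seed, rnorm(nrow(grid), 0, sigma))
  } else {
    eps <- 0
  }
  x <- exp(mu + eps)
  bad <- which(x <= 0 | x >= 1)
  if (length(bad) > 0)
    stop("generated x_e outside (0, 1) at (m = ", grid$m[bad[1]],
         ", T = ", grid$T_K[bad[1]], "): ", format(x[bad[1]]),
         "; adjust the generative parameters")
  grid$x_e <- x
  suppressWarnings(solubility_dataset(
    grid, solute_name = "synthetic solute",
    cosolvent_name = "synthetic cosolvent"))
}

# Evaluate `expr` under a temporarily seeded RNG, restoring the caller's
# RNG state afterwards.
local_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Parameter-recovery study over synthetic replicates
#'
#' Generates `n_reps` noisy surfaces from `spec` (replicate r uses seed
#' `spec$seed + r`), fits all five cosolvency models to each, and
#' summarizes per-parameter bias and RMSE against the generating values.
#' True values are known exactly for every model here because the
#' generative surface is van't Hoff in T at fixed m: the per-composition
#' van't Hoff truth is `(a_m, b_m)` read off the mean surface, the Apelblat
#' truth is `(a_m, b_m, 0)`, and the interaction-model truth is the spec's
#' own parameter vector. The Yalkowsky model has no parameters and
#' contributes only its overall RMSD.
#'
#' @param spec a [synthetic_spec()].
#' @param n_reps number of replicates (>= 1).
#' @param n_terms interaction terms used when fitting the Jouyban-Acree
#'   models; defaults to the length of `spec$J` so the fitted model matches
#'   the generative one.
#' @return object of class `recovery_report`: list with `params` (data
#'   frame: model, parameter, truth, mean estimate, bias, rmse), `rmsd`
#'   (mean overall RMSD per model), `failures` (count of failed fits),
#'   `n_reps`.
#' @export
recovery_report <- function(spec, n_reps, n_terms = length(spec$J)) {
  stopifnot(inherits(spec, "synthetic_spec"), n_reps >= 1)
  m2 <- 1 - spec$m_grid
  jsum <- rowSums(vapply(seq_along(spec$J) - 1L,
                         function(k) spec$J[k + 1] * (spec$m_grid - m2)^k,
                         numeric(length(spec$m_grid))))
  truth <- list(
    vant_hoff = c(
      setNames(spec$m_grid * spec$A1 + m2 * spec$A2,
               sprintf("a[m=%g]", spec$m_grid)),
      setNames(spec$m_grid * spec$B1 + m2 * spec$B2 +
                 spec$m_grid * m2 * jsum,
               sprintf("b[m=%g]", spec$m_grid))),
    jouyban_acree = setNames(spec$J, sprintf("J%d", seq_along(spec$J) - 1L)),
    ja_vant_hoff = c(A1 = spec$A1, B1 = spec$B1, A2 = spec$A2, B2 = spec$B2,
                     setNames(spec$J,
                              sprintf("J%d", seq_along(spec$J) - 1L))))

  estimates <- list()
  rmsds <- list()
  failures <- 0L
  for (r in seq_len(n_reps)) {
    rep_spec <- spec
    rep_spec$seed <- spec$seed + r
    d <- tryCatch(generate_surface(rep_spec), error = function(e) NULL)
    if (is.null(d)) { failures <- failures + 1L; next }
    fits <- tryCatch(list(
      vant_hoff = fit_vant_hoff(d),
      apelblat = suppressWarnings(fit_apelblat(d)),
      yalkowsky = fit_yalkowsky(d),
      jouyban_acree = fit_jouyban_acree(d, n_terms = n_terms,
                                        drop_tol = -Inf),
      ja_vant_hoff = fit_ja_vant_hoff(d, n_terms = n_terms,
                                      drop_tol = -Inf)),
      error = function(e) NULL)
    if (is.null(fits)) { failures <- failures + 1L; next }
    vh <- fits$vant_hoff$params
    est <- list(
      vant_hoff = c(setNames(vh$a, sprintf("a[m=%g]", vh$m)),
                    setNames(vh$b, sprintf("b[m=%g]", vh$m))),
      jouyban_acree = setNames(fits$jouyban_acree$params$J,
                               sprintf("J%d",
                                       seq_along(fits$jouyban_acree$params$J) - 1L)),
      ja_vant_hoff = with(fits$ja_vant_hoff$params,
                          c(A1 = A1, B1 = B1, A2 = A2, B2 = B2,
                            setNames(J, sprintf("J%d", seq_along(J) - 1L)))))
    estimates[[length(estimates) + 1L]] <- est
    rmsds[[length(rmsds) + 1L]] <-
      vapply(fits, function(f) f$overall_rmsd, numeric(1))
  }
  if (length(estimates) == 0) stop("every replicate failed")

  param_rows <- do.call(rbind, lapply(names(truth), function(model) {
    tr <- truth[[model]]
    est_mat <- do.call(rbind, lapply(estimates, function(e) e[[model]][names(tr)]))
    data.frame(model = model, parameter = names(tr), truth = unname(tr),
               estimate = colMeans(est_mat),
               bias = colMeans(est_mat) - unname(tr),
               rmse = sqrt(colMeans(sweep(est_mat, 2, tr)^2)),
               se = apply(est_mat, 2, stats::sd) / sqrt(nrow(est_mat)),
               row.names = NULL)
  }))
  rmsd_mat <- do.call(rbind, rmsds)
  structure(list(params = param_rows,
                 rmsd = colMeans(rmsd_mat),
                 failures = failures,
                 n_reps = n_reps),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery over %d replicates (%d failed)\n",
              x$n_reps, x$failures))
  print.data.frame(format(x$params, digits = 4), row.names = FALSE)
  cat("mean overall RMSD (%):\n")
  print(round(x$rmsd, 4))
  invisible(x)
}
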