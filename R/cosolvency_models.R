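#' Percent root-mean-square deviation
#'
#' Relative form, `100 * sqrt(mean(((x_obs - x_calc) / x_obs)^2))`. The
#' relative (not absolute) residual is essential here: solubilities across a
#' water-to-cosolvent grid span several orders of magnitude, and an absolute
#' RMSD would be dominated entirely by the cosolvent-rich points.
#'
#' @param x_obs observed mole fractions, all positive.
#' @param x_calc model mole fractions, same length.
#' @return percent RMSD (scalar, >= 0).
#' @examples
#' rmsd_percent(c(1, 2), c(1.01, 1.96)) # 1.5811...
#' @export
rmsd_percent <- function(x_obs, x_calc) {
  if (length(x_obs) == 0) stop("empty input")
  if (length(x_obs) != length(x_calc)) stop("length mismatch")
  if (any(x_obs <= 0)) stop("x_obs must be positive")
  100 * sqrt(mean(((x_obs - x_calc) / x_obs)^2))
}

# Assemble a fitted-model container with per-composition and overall fit
# statistics from a prediction table (m, T_K, x_obs, x_calc).
new_cosolv_fit <- function(model_name, params, predictions) {
  stopifnot(all(c("m", "T_K", "x_obs", "x_calc") %in% names(predictions)))
  by_m <- split(predictions, predictions$m)
  rmsd_per_m <- vapply(by_m, function(s) rmsd_percent(s$x_obs, s$x_calc),
                       numeric(1))
  r2_per_m <- vapply(by_m, function(s) {
    if (nrow(s) < 3 || stats::sd(s$x_obs) == 0) return(NA_real_)
    cor(log(s$x_obs), log(s$x_calc))^2
  }, numeric(1))
  structure(list(
    model_name = model_name, params = params, predictions = predictions,
    rmsd_per_m = rmsd_per_m,
    overall_rmsd = mean(rmsd_per_m),
    overall_rmsd_pooled = rmsd_percent(predictions$x_obs, predictions$x_calc),
    r2_per_m = r2_per_m), class = "cosolv_fit")
}

#' @export
print.cosolv_fit <- function(x, digits = 4, ...) {
  cat("Cosolvency model fit:", x$model_name, "\n")
  if (is.data.frame(x$params)) {
    print.data.frame(format(x$params, digits = digits), row.names = FALSE)
  } else if (length(x$params)) {
    str(x$params, give.attr = FALSE)
  }
  cat(sprintf("per-m RMSD (%%): %s\n",
              paste(sprintf("%.2f", x$rmsd_per_m), collapse = " ")))
  cat(sprintf("overall RMSD: %.3f%% (mean of per-m), %.3f%% (pooled)\n",
              x$overall_rmsd, x$overall_rmsd_pooled))
  invisible(x)
}

# OLS of log solubility on a design matrix; returns coefficients,
# predictions on the mole-fraction scale and R^2 of the log-space fit.
fit_log_linear <- function(X, x_e) {
  if (nrow(X) < ncol(X))
    stop("insufficient data: ", nrow(X), " points for ", ncol(X),
         " parameters")
  q <- qr(X)
  if (q$rank < ncol(X)) stop("singular design matrix")
  beta <- qr.coef(q, log(x_e))
  eta <- drop(X %*% beta)
  list(coef = beta, x_calc = exp(eta),
       r2 = cor(log(x_e), eta)^2)
}

#' Fit the van't Hoff model per composition
#'
#' For each composition the two-parameter correlation
#' `ln x = a + b / T` is fitted by ordinary least squares of `ln x_e` on
#' `1/T`.
#'
#' @param dataset a [solubility_dataset()] with at least 3 temperatures.
#' @return object of class `cosolv_fit`; `$params` is a data frame with
#'   columns `m`, `a`, `b` (K), `r2`.
#' @examples
#' fit_vant_hoff(ppd_dataset())
#' @export
fit_vant_hoff <- function(dataset) {
  stopifnot(inherits(dataset, "solubility_dataset"))
  ms <- dataset_compositions(dataset)
  params <- NULL
  preds <- NULL
  for (m in ms) {
    s <- dataset_series(dataset, m)
    if (nrow(s) < 3) stop("need >= 3 temperature points at m = ", m)
    f <- fit_log_linear(cbind(1, 1 / s$T_K), s$x_e)
    params <- rbind(params, data.frame(m = m, a = unname(f$coef[1]),
                                       b = unname(f$coef[2]), r2 = f$r2))
    preds <- rbind(preds, data.frame(m = m, T_K = s$T_K, x_obs = s$x_e,
                                     x_calc = f$x_calc))
  }
  new_cosolv_fit("vant_hoff", params, preds)
}

#' Fit the Apelblat model per composition
#'
#' The three-parameter correlation `ln x = A + B / T + C * ln T`, solved as
#' a linear-in-parameters least-squares problem on the design
#' `(1, 1/T, ln T)` — the exact optimum of the log-space objective, with no
#' iterative optimizer. Over a narrow temperature window `1/T` and `ln T`
#' are nearly collinear, so the individual parameter values are weakly
#' identified (tiny data perturbations move them a lot) while the fitted
#' curve and its RMSD are stable; a warning notes this. Predictions, not
#' parameter triplets, are the quantity to compare between sources.
#'
#' @param dataset a [solubility_dataset()] with at least 4 temperatures.
#' @param warn_collinear warn when `1/T` and `ln T` are nearly collinear
#'   over the dataset's temperature range.
#' @return object of class `cosolv_fit`; `$params` has columns `m`, `A`,
#'   `B` (K), `C`, `r2`.
#' @export
fit_apelblat <- function(dataset, warn_collinear = TRUE) {
  stopifnot(inherits(dataset, "solubility_dataset"))
  temps <- dataset_temperatures(dataset)
  if (warn_collinear && length(temps) >= 3 &&
      cor(1 / temps, log(temps))^2 > 0.9999)
    warning("1/T and ln T are nearly collinear over this temperature range; ",
            "Apelblat parameters are weakly identified (predictions are stable)")
  ms <- dataset_compositions(dataset)
  params <- NULL
  preds <- NULL
  for (m in ms) {
    s <- dataset_series(dataset, m)
    if (nrow(s) < 4)
      stop("need >= 4 temperature points at m = ", m,
           " for the 3-parameter model")
    f <- fit_log_linear(cbind(1, 1 / s$T_K, log(s$T_K)), s$x_e)
    params <- rbind(params, data.frame(m = m, A = unname(f$coef[1]),
                                       B = unname(f$coef[2]),
                                       C = unname(f$coef[3]), r2 = f$r2))
    preds <- rbind(preds, data.frame(m = m, T_K = s$T_K, x_obs = s$x_e,
                                     x_calc = f$x_calc))
  }
  new_cosolv_fit("apelblat", params, preds)
}

#' Yalkowsky-Roseman log-linear blend
#'
#' Algebraic (fit-free) prediction of mixture solubility from the neat
#' solubilities: `log10 x = m1 * log10 x1 + m2 * log10 x2` with
#' `m2 = 1 - m1`. Note the decadic logarithm.
#'
#' @param x1 neat-cosolvent solubility at the temperature of interest.
#' @param x2 neat-water solubility at the same temperature.
#' @param m1 cosolvent mass fraction(s) in `[0, 1]`.
#' @return `log10` of the predicted mole-fraction solubility.
#' @examples
#' yalkowsky_predict(0.400, 5.82e-6, 0.5) # -2.8165
#' @export
yalkowsky_predict <- function(x1, x2, m1) {
  if (any(x1 <= 0) || any(x2 <= 0)) stop("neat solubilities must be positive")
  if (any(m1 < 0 | m1 > 1)) stop("m1 must lie in [0, 1]")
  m1 * log10(x1) + (1 - m1) * log10(x2)
}

# Experimental neat-solvent series (m = 0 and m = 1) keyed by temperature;
# precondition for the mixture models.
neat_series <- function(dataset) {
  ms <- dataset_compositions(dataset)
  if (!(0 %in% ms) || !(1 %in% ms))
    stop("dataset must contain both neat series (m = 0 and m = 1)")
  if (length(ms) < 3) stop("dataset has no mixture compositions")
  list(x1 = dataset_series(dataset, 1), x2 = dataset_series(dataset, 0))
}

#' Evaluate the Yalkowsky-Roseman model over a solubility grid
#'
#' Applies [yalkowsky_predict()] at every mixture composition
#' (`0 < m < 1`), using the dataset's own neat-solvent series as inputs.
#' The neat compositions are inputs to the blend, not predictions, so they
#' are excluded from the prediction grid and the RMSD.
#'
#' @param dataset a [solubility_dataset()] containing both neat series.
#' @return object of class `cosolv_fit` with `$params = NULL` (the model has
#'   no fitted parameters).
#' @export
fit_yalkowsky <- function(dataset) {
  stopifnot(inherits(dataset, "solubility_dataset"))
  neat <- neat_series(dataset)
  ms <- setdiff(dataset_compositions(dataset), c(0, 1))
  preds <- NULL
  for (m in ms) {
    s <- dataset_series(dataset, m)
    x1 <- neat$x1$x_e[match(s$T_K, neat$x1$T_K)]
    x2 <- neat$x2$x_e[match(s$T_K, neat$x2$T_K)]
    preds <- rbind(preds, data.frame(
      m = m, T_K = s$T_K, x_obs = s$x_e,
      x_calc = 10^yalkowsky_predict(x1, x2, m)))
  }
  new_cosolv_fit("yalkowsky", NULL, preds)
}

# Jouyban-Acree interaction design: column i is m1*m2*(m1-m2)^(i-1) / T.
ja_design <- function(m1, T, n_terms) {
  m2 <- 1 - m1
  vapply(seq_len(n_terms) - 1L,
         function(k) m1 * m2 * (m1 - m2)^k / T,
         numeric(length(m1)))
}

#' Fit the Jouyban-Acree model
#'
#' The mixture solubility surface
#' `ln x(m,T) = m1 ln x1(T) + m2 ln x2(T) + (m1 m2 / T) * sum_i J_i (m1-m2)^i`
#' is fitted by no-intercept least squares: the response is the excess
#' `ln x_e - m1 ln x1 - m2 ln x2` on the mixture rows (neat solubilities
#' `x1`, `x2` taken from the dataset's own neat series at matching
#' temperatures), regressed on the interaction terms
#' `m1 m2 (m1 - m2)^i / T`, i = 0..(n_terms-1).
#'
#' Starting from `n_terms`, trailing interaction terms are dropped while
#' removal worsens the pooled RMSD by no more than `drop_tol` percentage
#' points, so over-parameterized tails are pruned automatically; set
#' `drop_tol = -Inf` to keep exactly `n_terms` terms.
#'
#' @param dataset a [solubility_dataset()] containing both neat series and
#'   at least one mixture composition.
#' @param n_terms maximum number of interaction terms (1-3).
#' @param drop_tol pooled-RMSD tolerance (percentage points) for dropping
#'   the highest-order term.
#' @return object of class `cosolv_fit`; `$params` is a list with the
#'   retained coefficient vector `J` (K).
#' @examples
#' fit_jouyban_acree(ppd_dataset())
#' @export
fit_jouyban_acree <- function(dataset, n_terms = 3, drop_tol = 0.01) {
  stopifnot(inherits(dataset, "solubility_dataset"),
            n_terms >= 1, n_terms <= 3)
  neat <- neat_series(dataset)
  mix <- dataset$data[!(dataset$data$m %in% c(0, 1)), , drop = FALSE]
  lx1 <- log(neat$x1$x_e[match(mix$T_K, neat$x1$T_K)])
  lx2 <- log(neat$x2$x_e[match(mix$T_K, neat$x2$T_K)])
  y <- log(mix$x_e) - mix$m * lx1 - (1 - mix$m) * lx2
  fit_k <- function(k) {
    X <- ja_design(mix$m, mix$T_K, k)
    J <- qr.coef(qr(X), y)
    preds <- data.frame(m = mix$m, T_K = mix$T_K, x_obs = mix$x_e,
                        x_calc = exp(mix$m * lx1 + (1 - mix$m) * lx2 +
                                       drop(X %*% J)))
    list(J = unname(J), preds = preds,
         pooled = rmsd_percent(preds$x_obs, preds$x_calc))
  }
  cur <- fit_k(n_terms)
  while (length(cur$J) > 1) {
    cand <- fit_k(length(cur$J) - 1L)
    if (cand$pooled - cur$pooled > drop_tol) break
    cur <- cand
  }
  new_cosolv_fit("jouyban_acree", list(J = cur$J), cur$preds)
}

#' Fit the Jouyban-Acree-van't Hoff model
#'
#' A full `(m, T)` surface built in two stages. Stage 1: van't Hoff fits of
#' the two neat series give `(A1, B1)` for the neat cosolvent and
#' `(A2, B2)` for neat water. Stage 2: the interaction coefficients `J` are
#' estimated by no-intercept least squares exactly as in
#' [fit_jouyban_acree()], but with the experimental neat terms replaced by
#' their van't Hoff smooths:
#' `ln x(m,T) = m1 (A1 + B1/T) + m2 (A2 + B2/T) + (m1 m2 / T) sum_i J_i (m1-m2)^i`.
#' Predictions cover the full grid, neat compositions included (there the
#' surface is the pure van't Hoff smooth).
#'
#' @inheritParams fit_jouyban_acree
#' @return object of class `cosolv_fit`; `$params` is a list with `A1`,
#'   `B1`, `A2`, `B2`, and the retained vector `J` (K).
#' @export
fit_ja_vant_hoff <- function(dataset, n_terms = 3, drop_tol = 0.01) {
  stopifnot(inherits(dataset, "solubility_dataset"),
            n_terms >= 1, n_terms <= 3)
  neat <- neat_series(dataset)
  vh1 <- fit_log_linear(cbind(1, 1 / neat$x1$T_K), neat$x1$x_e)$coef
  vh2 <- fit_log_linear(cbind(1, 1 / neat$x2$T_K), neat$x2$x_e)$coef
  A1 <- unname(vh1[1]); B1 <- unname(vh1[2])
  A2 <- unname(vh2[1]); B2 <- unname(vh2[2])

  d <- dataset$data
  mix <- d[!(d$m %in% c(0, 1)), , drop = FALSE]
  base_mix <- mix$m * (A1 + B1 / mix$T_K) + (1 - mix$m) * (A2 + B2 / mix$T_K)
  y <- log(mix$x_e) - base_mix
  fit_k <- function(k) {
    X <- ja_design(mix$m, mix$T_K, k)
    J <- unname(qr.coef(qr(X), y))
    base <- d$m * (A1 + B1 / d$T_K) + (1 - d$m) * (A2 + B2 / d$T_K)
    Xall <- ja_design(d$m, d$T_K, k)
    preds <- data.frame(m = d$m, T_K = d$T_K, x_obs = d$x_e,
                        x_calc = exp(base + drop(Xall %*% J)))
    list(J = J, preds = preds,
         pooled = rmsd_percent(preds$x_obs, preds$x_calc))
  }
  cur <- fit_k(n_terms)
  while (length(cur$J) > 1) {
    cand <- fit_k(length(cur$J) - 1L)
    if (cand$pooled - cur$pooled > drop_tol) break
    cur <- cand
  }
  new_cosolv_fit("ja_vant_hoff",
                 list(A1 = A1, B1 = B1, A2 = A2, B2 = B2, J = cur$J),
                 cur$preds)
}

#' Goodness-of-fit summary for a cosolvency model
#'
#' @param fit a `cosolv_fit`.
#' @param threshold overall-RMSD acceptance threshold in percent (the
#'   conventional adequacy bound for cosolvency correlations is 2 percent).
#' @param overall which overall-RMSD aggregation to judge against the
#'   threshold: `"mean"` (arithmetic mean of per-composition RMSDs, the
#'   convention of the solubility-correlation literature) or `"pooled"`
#'   (RMSD of all residuals pooled).
#' @return list with `table` (per-composition RMSD and R^2),
#'   `overall_rmsd`, `overall_rmsd_pooled`, `threshold`, and logical
#'   `passes`.
#' @export
evaluate_model <- function(fit, threshold = 2.0,
                           overall = c("mean", "pooled")) {
  stopifnot(inherits(fit, "cosolv_fit"))
  overall <- match.arg(overall)
  ov <- if (overall == "mean") fit$overall_rmsd else fit$overall_rmsd_pooled
  list(model_name = fit$model_name,
       table = data.frame(m = as.numeric(names(fit$rmsd_per_m)),
                          rmsd = unname(fit$rmsd_per_m),
                          r2 = unname(fit$r2_per_m)),
       overall_rmsd = fit$overall_rmsd,
       overall_rmsd_pooled = fit$overall_rmsd_pooled,
       threshold = threshold,
       passes = ov < threshold)
}
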