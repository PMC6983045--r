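test_that("percent RMSD matches hand computation and rejects bad input", {
  expect_identical(rmsd_percent(c(1, 2, 3), c(1, 2, 3)), 0)
  # deviations (-1%, +2%) -> 100*sqrt((1e-4 + 4e-4)/2)
  expect_equal(rmsd_percent(c(1, 2), c(1.01, 1.96)), 1.58113883,
               tolerance = 1e-8)
  expect_error(rmsd_percent(numeric(0), numeric(0)), "empty")
  expect_error(rmsd_percent(c(1, 2), 1), "mismatch")
  expect_error(rmsd_percent(c(0, 1), c(1, 1)), "positive")
})

test_that("van't Hoff fits reproduce the published neat-solvent parameters", {
  fit <- fit_vant_hoff(ppd_dataset())
  p1 <- fit$params[fit$params$m == 1, ]
  expect_equal(p1$a, 1.54, tolerance = 0.02 / 1.54)
  expect_equal(p1$b, -733.05, tolerance = 5 / 733.05)
  p0 <- fit$params[fit$params$m == 0, ]
  expect_equal(p0$b, -3765.70, tolerance = 0.005)
  expect_true(all(fit$params$r2 > 0.98))
  # parameter b grows monotonically with cosolvent fraction
  expect_true(all(diff(fit$params$b) > 0))
})

test_that("noiseless log-linear data are recovered exactly by every fitter", {
  temps <- seq(298, 318, by = 5)
  # van't Hoff: ln x = a + b/T
  g <- expand.grid(m = c(0, 1), T_K = temps)
  ab <- list(`0` = c(-9, -1500), `1` = c(2, -1500))
  g$x_e <- vapply(seq_len(nrow(g)), function(i) {
    p <- ab[[as.character(g$m[i])]]
    exp(p[1] + p[2] / g$T_K[i])
  }, numeric(1))
  d <- suppressWarnings(solubility_dataset(g))
  fit <- fit_vant_hoff(d)
  expect_equal(fit$params$a, c(-9, 2), tolerance = 1e-10)
  expect_equal(fit$params$b, c(-1500, -1500), tolerance = 1e-10)
  expect_equal(unname(fit$rmsd_per_m), c(0, 0), tolerance = 1e-10)

  # Apelblat: ln x = A + B/T + C ln T, generated then recovered in prediction
  g$x_e <- exp(-100 + 4000 / g$T_K + 15 * log(g$T_K)) *
    ifelse(g$m == 0, 1e-4, 1)
  d <- suppressWarnings(solubility_dataset(g))
  fit <- suppressWarnings(fit_apelblat(d))
  expect_equal(fit$predictions$x_calc, fit$predictions$x_obs,
               tolerance = 1e-9)
  expect_equal(fit$overall_rmsd, 0, tolerance = 1e-8)
})

test_that("Apelblat fit warns about collinearity but yields stable predictions", {
  expect_warning(fit <- fit_apelblat(ppd_dataset()), "collinear")
  expect_true(all(fit$rmsd_per_m < 1.5))
  expect_true(all(fit$r2_per_m > 0.997))
  expect_true(fit$overall_rmsd < fit_vant_hoff(ppd_dataset())$overall_rmsd)
})

test_that("every least-squares fit matches the closed-form normal equations", {
  d <- ppd_dataset()
  s <- dataset_series(d, 0.3)

  vh <- fit_vant_hoff(d)$params
  beta <- normal_equations(cbind(1, 1 / s$T_K), log(s$x_e))
  expect_equal(unlist(vh[vh$m == 0.3, c("a", "b")]), beta,
               tolerance = 1e-10, ignore_attr = TRUE)

  # the normal-equations oracle itself loses digits on the near-collinear
  # Apelblat design, so the agreement bound is correspondingly looser
  ap <- suppressWarnings(fit_apelblat(d))$params
  beta <- normal_equations(cbind(1, 1 / s$T_K, log(s$T_K)), log(s$x_e))
  expect_equal(unlist(ap[ap$m == 0.3, c("A", "B", "C")]), beta,
               tolerance = 1e-6, ignore_attr = TRUE)

  # Jouyban-Acree no-intercept regression (3 terms)
  ja <- fit_jouyban_acree(d, n_terms = 3, drop_tol = -Inf)
  mix <- d$data[!(d$data$m %in% c(0, 1)), ]
  x1 <- dataset_series(d, 1); x2 <- dataset_series(d, 0)
  y <- log(mix$x_e) -
    mix$m * log(x1$x_e[match(mix$T_K, x1$T_K)]) -
    (1 - mix$m) * log(x2$x_e[match(mix$T_K, x2$T_K)])
  X <- sapply(0:2, function(k)
    mix$m * (1 - mix$m) * (mix$m - (1 - mix$m))^k / mix$T_K)
  expect_equal(ja$params$J, normal_equations(X, y), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("Yalkowsky log-linear blend matches published predictions", {
  expect_equal(yalkowsky_predict(4.00e-1, 5.82e-6, 0.5), -2.81,
               tolerance = 0.01 / 2.81)
  expect_equal(yalkowsky_predict(4.67e-1, 1.30e-5, 0.9), -0.78,
               tolerance = 0.01 / 0.78)
  expect_identical(yalkowsky_predict(0.4, 5.82e-6, 1), log10(0.4))
  expect_error(yalkowsky_predict(-0.1, 1e-5, 0.5), "positive")
  expect_error(yalkowsky_predict(0.4, 1e-5, 1.5), "m1")

  fit <- fit_yalkowsky(ppd_dataset())
  # predictions cover exactly the mixture grid
  expect_setequal(unique(fit$predictions$m), (1:9) / 10)
  lg <- log10(fit$predictions$x_calc)
  ref <- mapply(function(m, T) ref_yalkowsky_log10[as.character(m),
                                                   as.character(T)],
                fit$predictions$m, fit$predictions$T_K)
  expect_lt(max(abs(lg - ref)), 0.015) # published values carry 2 decimals
})

test_that("Jouyban-Acree reduces to the log-linear blend when J = 0", {
  set.seed(31)
  for (i in 1:10) {
    x1 <- runif(1, 1e-3, 0.5); x2 <- runif(1, 1e-6, 1e-3)
    m1 <- runif(1)
    ja0 <- exp(m1 * log(x1) + (1 - m1) * log(x2)) # J terms vanish
    expect_equal(log10(ja0), yalkowsky_predict(x1, x2, m1),
                 tolerance = 1e-12)
  }
})

test_that("noiseless Jouyban-Acree surfaces give exact parameter recovery", {
  temps <- c(298.2, 303.2, 308.2, 313.2, 318.2)
  ms <- seq(0, 1, by = 0.1)
  J <- c(30, -5, 2)
  g <- expand.grid(m = ms, T_K = temps)
  x1 <- exp(1.54 - 733.05 / temps)
  x2 <- exp(0.55 - 3765.7 / temps)
  g$x_e <- vapply(seq_len(nrow(g)), function(i) {
    m1 <- g$m[i]; m2 <- 1 - m1; T <- g$T_K[i]
    l1 <- log(x1[match(T, temps)]); l2 <- log(x2[match(T, temps)])
    exp(m1 * l1 + m2 * l2 +
          m1 * m2 / T * sum(J * (m1 - m2)^(0:2)))
  }, numeric(1))
  d <- solubility_dataset(g)
  fit <- fit_jouyban_acree(d, n_terms = 3, drop_tol = -Inf)
  expect_equal(fit$params$J, J, tolerance = 1e-8)
  expect_equal(fit$overall_rmsd, 0, tolerance = 1e-8)
})

test_that("single-term Jouyban-Acree matches a brute-force grid-search oracle", {
  d <- ppd_dataset()
  fit <- fit_jouyban_acree(d, n_terms = 1, drop_tol = -Inf)
  mix <- d$data[!(d$data$m %in% c(0, 1)), ]
  x1 <- dataset_series(d, 1); x2 <- dataset_series(d, 0)
  y <- log(mix$x_e) -
    mix$m * log(x1$x_e[match(mix$T_K, x1$T_K)]) -
    (1 - mix$m) * log(x2$x_e[match(mix$T_K, x2$T_K)])
  p <- mix$m * (1 - mix$m) / mix$T_K
  sse <- function(Jgrid)
    colSums((matrix(y, length(y), length(Jgrid)) - outer(p, Jgrid))^2)
  coarse <- seq(0, 60, by = 0.01)
  J_best <- coarse[which.min(sse(coarse))]
  fine <- seq(J_best - 0.02, J_best + 0.02, by = 1e-4)
  J_best <- fine[which.min(sse(fine))]
  expect_equal(fit$params$J, J_best, tolerance = 1e-4 / abs(J_best))
})

test_that("term pruning keeps all three interaction terms on the fixture", {
  fit <- fit_jouyban_acree(ppd_dataset()) # default drop_tol = 0.01
  expect_length(fit$params$J, 3)
  fit1 <- fit_jouyban_acree(ppd_dataset(), n_terms = 1)
  expect_length(fit1$params$J, 1)
  expect_gte(fit1$overall_rmsd_pooled, fit$overall_rmsd_pooled)
})

test_that("two-stage Jouyban-Acree-van't Hoff inherits the neat van't Hoff fits", {
  d <- ppd_dataset()
  vh <- fit_vant_hoff(d)$params
  fit <- fit_ja_vant_hoff(d)
  expect_equal(fit$params$A1, vh$a[vh$m == 1], tolerance = 1e-12)
  expect_equal(fit$params$B1, vh$b[vh$m == 1], tolerance = 1e-12)
  expect_equal(fit$params$A2, vh$a[vh$m == 0], tolerance = 1e-12)
  expect_equal(fit$params$B2, vh$b[vh$m == 0], tolerance = 1e-12)
  # published two-stage parameters (rounded to Table precision)
  expect_equal(fit$params$A1, 1.54, tolerance = 0.02 / 1.54)
  expect_equal(fit$params$B1, -733.05, tolerance = 5 / 733.05)
  expect_equal(fit$params$B2, -3765.7, tolerance = 0.005)

  # predictions cover the full grid; neat ends equal the van't Hoff smooths
  expect_equal(nrow(fit$predictions), 55)
  neat1 <- fit$predictions[fit$predictions$m == 1, ]
  expect_equal(neat1$x_calc,
               exp(fit$params$A1 + fit$params$B1 / neat1$T_K),
               tolerance = 1e-12)
})

test_that("noiseless two-stage surfaces recover all five parameters exactly", {
  spec <- synthetic_spec(A1 = 2, B1 = -800, A2 = -1, B2 = -3500,
                         J = c(20, 4), noise_cv = 0)
  d <- generate_surface(spec)
  fit <- fit_ja_vant_hoff(d, n_terms = 2, drop_tol = -Inf)
  expect_equal(fit$params$A1, 2, tolerance = 1e-8)
  expect_equal(fit$params$B1, -800, tolerance = 1e-8)
  expect_equal(fit$params$A2, -1, tolerance = 1e-8)
  expect_equal(fit$params$B2, -3500, tolerance = 1e-8)
  expect_equal(fit$params$J, c(20, 4), tolerance = 1e-7)
  expect_equal(fit$overall_rmsd, 0, tolerance = 1e-8)
})

test_that("overall RMSD aggregations are consistent with hand-pooled residuals", {
  fit <- fit_vant_hoff(ppd_dataset())
  pooled <- 100 * sqrt(mean(((fit$predictions$x_obs - fit$predictions$x_calc) /
                               fit$predictions$x_obs)^2))
  expect_equal(fit$overall_rmsd_pooled, pooled, tolerance = 1e-12)
  expect_equal(fit$overall_rmsd, mean(fit$rmsd_per_m), tolerance = 1e-12)
  # pooled >= mean here (Jensen direction for these data)
  expect_gt(fit$overall_rmsd_pooled, fit$overall_rmsd)
})

test_that("mixture models require both neat series", {
  g <- make_toy_grid(n_m = 4, n_T = 4)
  g <- g[g$m < 1, ]
  d <- solubility_dataset(g)
  expect_error(fit_yalkowsky(d), "neat")
  expect_error(fit_jouyban_acree(d), "neat")
  expect_error(fit_ja_vant_hoff(d), "neat")
})

test_that("model evaluation summarizes per-composition fit quality", {
  fit <- fit_vant_hoff(ppd_dataset())
  ev <- evaluate_model(fit)
  expect_equal(nrow(ev$table), 11)
  expect_true(ev$passes)
  expect_false(evaluate_model(fit, threshold = 1.0)$passes)
  expect_equal(ev$overall_rmsd, fit$overall_rmsd)
})
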