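#' Ideal mole-fraction solubility from fusion properties
#'
#' Computes the ideal solubility of a crystalline solute at temperature(s)
#' `T` below its melting point from
#' \deqn{\ln x^{idl} = -\frac{\Delta H_{fus}(T_{fus}-T)}{R\,T_{fus}\,T}
#'   + \frac{\Delta C_p}{R}\left[\frac{T_{fus}-T}{T}
#'   + \ln\frac{T}{T_{fus}}\right].}
#' At `T = T_fus` both bracketed terms vanish and the result is exactly 1.
#' With `dCp = 0` the expression reduces to the classic van't Hoff ideal
#' solubility.
#'
#' @param fusion a [fusion_properties()] object.
#' @param T absolute temperature(s), K; must satisfy `0 < T <= T_fus`.
#' @param R molar gas constant, J mol^-1 K^-1.
#' @return numeric vector of ideal mole fractions, same length as `T`.
#' @examples
#' ideal_solubility(ppd_fusion(), c(298.2, 318.2))
#' @export
ideal_solubility <- function(fusion, T, R = GAS_CONSTANT) {
  stopifnot(inherits(fusion, "fusion_properties"), is.numeric(T))
  if (any(T <= 0)) stop("temperature must be positive")
  if (any(T > fusion$T_fus))
    stop("temperature above the melting point (", fusion$T_fus,
         " K); the crystalline ideal-solubility expression does not apply")
  with(fusion,
       exp(-dH_fus * (T_fus - T) / (R * T_fus * T) +
             dCp / R * ((T_fus - T) / T + log(T / T_fus))))
}

#' Ideal solubility curve over a set of temperatures
#'
#' @inheritParams ideal_solubility
#' @param temps temperatures (K).
#' @return data frame with columns `T_K` and `x_idl`, sorted by temperature.
#' @export
ideal_solubility_curve <- function(fusion, temps, R = GAS_CONSTANT) {
  temps <- sort(unique(temps))
  data.frame(T_K = temps, x_idl = ideal_solubility(fusion, temps, R = R))
}

#' Activity coefficients over a solubility grid
#'
#' The activity coefficient of the solute in each solvent mixture is the
#' ratio of ideal to experimental solubility, `gamma = x_idl(T) / x_e(m, T)`.
#' Values above 1 indicate weaker solute-solvent interaction than the ideal
#' solution; below 1, stronger (the experimental solubility exceeds the
#' ideal one). Unrounded `x_idl` is used throughout.
#'
#' @param dataset a [solubility_dataset()].
#' @param ideal either a [fusion_properties()] object (the curve is computed
#'   at the dataset temperatures) or a data frame from
#'   [ideal_solubility_curve()] covering every dataset temperature.
#' @param R molar gas constant, used only when `ideal` is a
#'   `fusion_properties` object.
#' @return data frame with columns `m`, `T_K`, `x_e`, `x_idl`, `gamma`.
#' @examples
#' head(activity_coefficients(ppd_dataset(), ppd_fusion()))
#' @export
activity_coefficients <- function(dataset, ideal, R = GAS_CONSTANT) {
  stopifnot(inherits(dataset, "solubility_dataset"))
  if (inherits(ideal, "fusion_properties"))
    ideal <- ideal_solubility_curve(ideal, dataset_temperatures(dataset),
                                    R = R)
  stopifnot(is.data.frame(ideal), all(c("T_K", "x_idl") %in% names(ideal)))
  d <- dataset$data
  idx <- match(d$T_K, ideal$T_K)
  if (anyNA(idx))
    stop("ideal curve is missing temperature(s): ",
         paste(unique(d$T_K[is.na(idx)]), collapse = ", "))
  d$x_idl <- ideal$x_idl[idx]
  d$gamma <- d$x_idl / d$x_e
  d
}
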