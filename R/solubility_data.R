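#' Construct a validated solubility dataset
#'
#' A solubility dataset is a complete rectangular grid of experimental
#' mole-fraction solubilities `x_e` over cosolvent mass fractions `m`
#' (0 = neat water, 1 = neat cosolvent) and absolute temperatures `T_K`.
#' Construction enforces the grid contract every downstream fit relies on:
#' each (m, T) cell present exactly once, at least two distinct temperatures
#' and two distinct compositions, all `x_e` strictly inside (0, 1).
#'
#' Solubility is physically expected to increase with both temperature and
#' cosolvent fraction in a cosolvency system; violations on user data are
#' reported as warnings (real measurements may cross), never as errors.
#'
#' @param data data frame with numeric columns `m`, `T_K`, `x_e`.
#' @param solute_name,cosolvent_name,solvent_name character metadata.
#' @param pressure_MPa numeric, metadata only (no pressure dependence is
#'   modeled anywhere in the package).
#' @return An object of class `solubility_dataset`: a list with elements
#'   `data` (the validated long-format data frame, sorted by `m` then `T_K`),
#'   the three name fields and `pressure_MPa`.
#' @examples
#' d <- solubility_dataset(
#'   data.frame(m = rep(c(0, 1), each = 2), T_K = rep(c(298, 308), 2),
#'              x_e = c(1e-5, 2e-5, 0.40, 0.44)),
#'   solute_name = "demo")
#' @export
solubility_dataset <- function(data, solute_name = "unknown",
                               cosolvent_name = "cosolvent",
                               solvent_name = "water",
                               pressure_MPa = NA_real_) {
  required <- c("m", "T_K", "x_e")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0)
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  data <- as.data.frame(data)[required]
  for (col in required) {
    if (!is.numeric(data[[col]]) || anyNA(data[[col]]) ||
        any(!is.finite(data[[col]])))
      stop("column '", col, "' must be finite numeric")
  }
  if (any(data$m < 0 | data$m > 1)) stop("mass fraction m must lie in [0, 1]")
  if (any(data$T_K <= 0)) stop("temperature T_K must be positive (kelvin)")
  if (any(data$x_e <= 0 | data$x_e >= 1))
    stop("mole-fraction solubility x_e must lie strictly in (0, 1)")

  key <- paste(format(data$m, digits = 15), format(data$T_K, digits = 15))
  if (anyDuplicated(key))
    stop("duplicate (m, T) cell(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))

  temps <- sort(unique(data$T_K))
  comps <- sort(unique(data$m))
  if (length(temps) < 2)
    stop("need at least 2 distinct temperatures, got ", length(temps))
  if (length(comps) < 2)
    stop("need at least 2 distinct compositions, got ", length(comps))
  if (nrow(data) != length(temps) * length(comps))
    stop("records do not form a complete ", length(comps), " x ", length(temps),
         " grid: expected ", length(temps) * length(comps), " rows, got ",
         nrow(data))

  data <- data[order(data$m, data$T_K), , drop = FALSE]
  rownames(data) <- NULL

  ds <- structure(
    list(data = data, solute_name = solute_name,
         cosolvent_name = cosolvent_name, solvent_name = solvent_name,
         pressure_MPa = pressure_MPa),
    class = "solubility_dataset")

  mono <- check_monotonicity(ds)
  if (!mono$in_T)
    warning("x_e is not strictly increasing in T within every composition")
  if (!mono$in_m)
    warning("x_e is not strictly increasing in m within every temperature")
  ds
}

#' Monotonicity diagnostics for a solubility grid
#'
#' Checks whether `x_e` increases strictly with temperature within each
#' composition and with cosolvent fraction within each temperature.
#'
#' @param dataset a [solubility_dataset()].
#' @return list with logical elements `in_T` and `in_m`.
#' @export
check_monotonicity <- function(dataset) {
  d <- dataset$data
  in_T <- all(vapply(split(d, d$m), function(s)
    !is.unsorted(s$x_e[order(s$T_K)], strictly = TRUE), logical(1)))
  in_m <- all(vapply(split(d, d$T_K), function(s)
    !is.unsorted(s$x_e[order(s$m)], strictly = TRUE), logical(1)))
  list(in_T = in_T, in_m = in_m)
}

#' @export
print.solubility_dataset <- function(x, ...) {
  d <- x$data
  cat("Solubility dataset:", x$solute_name, "in",
      paste0(x$cosolvent_name, " + ", x$solvent_name), "\n")
  cat(sprintf("  %d compositions x %d temperatures (%d records)\n",
              length(unique(d$m)), length(unique(d$T_K)), nrow(d)))
  cat(sprintf("  m in [%g, %g]; T in [%g, %g] K; x_e in [%.3g, %.3g]\n",
              min(d$m), max(d$m), min(d$T_K), max(d$T_K),
              min(d$x_e), max(d$x_e)))
  invisible(x)
}

#' Temperatures and compositions of a dataset
#' @param dataset a [solubility_dataset()].
#' @return sorted numeric vector.
#' @export
dataset_temperatures <- function(dataset) sort(unique(dataset$data$T_K))

#' @rdname dataset_temperatures
#' @export
dataset_compositions <- function(dataset) sort(unique(dataset$data$m))

#' Extract the (T, x_e) series at one composition
#' @param dataset a [solubility_dataset()].
#' @param m composition to extract (must be present in the grid).
#' @return data frame with columns `T_K`, `x_e`, sorted by temperature.
#' @export
dataset_series <- function(dataset, m) {
  s <- dataset$data[dataset$data$m == m, c("T_K", "x_e")]
  if (nrow(s) == 0) stop("no records at m = ", m)
  s[order(s$T_K), , drop = FALSE]
}

#' Read a solubility dataset from CSV
#'
#' Expects long format with one row per (m, T) cell. Lines starting with `#`
#' are treated as comments; comments of the form `# key: value` written by
#' [write_solubility_csv()] are parsed back into metadata.
#'
#' @param path file path.
#' @param columns named character map from the canonical names `m`, `T_K`,
#'   `x_e` to the column names used in the file.
#' @param ... metadata passed on to [solubility_dataset()]; overrides any
#'   metadata parsed from file comments.
#' @return a [solubility_dataset()].
#' @export
read_solubility_csv <- function(path, columns = c(m = "m", T_K = "T_K",
                                                  x_e = "x_e"), ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- grep("^#", readLines(path, n = 50L), value = TRUE)
  meta <- list()
  for (ln in header) {
    mt <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+):\\s*(.*)$", ln))[[1]]
    if (length(mt) == 3) meta[[mt[2]]] <- mt[3]
  }
  raw <- read.csv(path, comment.char = "#", check.names = FALSE)
  for (canon in c("m", "T_K", "x_e")) {
    src <- if (canon %in% names(columns)) columns[[canon]] else canon
    if (!src %in% names(raw))
      stop("column '", src, "' (for ", canon, ") not found in ", path)
    names(raw)[names(raw) == src] <- canon
  }
  args <- list(data = raw)
  for (fld in c("solute_name", "cosolvent_name", "solvent_name"))
    if (!is.null(meta[[fld]])) args[[fld]] <- meta[[fld]]
  if (!is.null(meta$pressure_MPa))
    args$pressure_MPa <- if (meta$pressure_MPa == "NA") NA_real_
                         else as.numeric(meta$pressure_MPa)
  user <- list(...)
  args[names(user)] <- user
  do.call(solubility_dataset, args)
}

#' Write a solubility dataset to CSV
#'
#' Writes long-format `m,T_K,x_e` with 17 significant digits so that
#' `read_solubility_csv(write_solubility_csv(d))` round-trips every value to
#' full double precision. Metadata go into `# key: value` comment lines.
#'
#' @param dataset a [solubility_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_solubility_csv <- function(dataset, path) {
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(
    paste0("# solute_name: ", dataset$solute_name),
    paste0("# cosolvent_name: ", dataset$cosolvent_name),
    paste0("# solvent_name: ", dataset$solvent_name),
    paste0("# pressure_MPa: ", format(dataset$pressure_MPa, digits = 17))),
    con)
  writeLines("m,T_K,x_e", con)
  d <- dataset$data
  writeLines(paste(format(d$m, digits = 17, trim = TRUE),
                   format(d$T_K, digits = 17, trim = TRUE),
                   format(d$x_e, digits = 17, trim = TRUE), sep = ","), con)
  invisible(path)
}

#' The bundled PPD in DMSO + water solubility dataset
#'
#' Experimental mole-fraction solubility of 6-phenylpyridazin-3(2H)-one
#' (PPD) on the full 11 x 5 grid: mass fractions of DMSO m = 0.0, 0.1, ...,
#' 1.0 and temperatures 298.2, 303.2, 308.2, 313.2, 318.2 K at 0.1 MPa.
#'
#' @return a [solubility_dataset()] with 55 records.
#' @examples
#' d <- ppd_dataset()
#' dataset_series(d, 1.0)
#' @export
ppd_dataset <- function() {
  path <- system.file("extdata", "ppd_dmso_water.csv", package = "cosolvr",
                      mustWork = TRUE)
  read_solubility_csv(path)
}

#' Fusion properties of a solute
#'
#' Melting temperature, molar fusion enthalpy and the solid-liquid molar
#' heat-capacity difference; the inputs that determine ideal solubility.
#'
#' @param T_fus melting temperature (K), > 0.
#' @param dH_fus molar fusion enthalpy (J mol^-1), > 0.
#' @param dCp solid-liquid molar heat-capacity difference (J mol^-1 K^-1),
#'   >= 0.
#' @return object of class `fusion_properties`.
#' @export
fusion_properties <- function(T_fus, dH_fus, dCp = 0) {
  stopifnot(is.numeric(T_fus), length(T_fus) == 1, is.finite(T_fus),
            is.numeric(dH_fus), length(dH_fus) == 1, is.finite(dH_fus),
            is.numeric(dCp), length(dCp) == 1, is.finite(dCp))
  if (T_fus <= 0) stop("T_fus must be positive")
  if (dH_fus <= 0) stop("dH_fus must be positive")
  if (dCp < 0) stop("dCp must be non-negative")
  structure(list(T_fus = T_fus, dH_fus = dH_fus, dCp = dCp),
            class = "fusion_properties")
}

#' @export
print.fusion_properties <- function(x, ...) {
  cat(sprintf(
    "Fusion properties: T_fus = %.2f K, dH_fus = %.4g kJ/mol, dCp = %.4g J/(mol K)\n",
    x$T_fus, x$dH_fus / 1000, x$dCp))
  invisible(x)
}

#' Fusion properties of PPD
#'
#' The differential-scanning-calorimetry values for
#' 6-phenylpyridazin-3(2H)-one: T_fus = 476.43 K, fusion enthalpy
#' 24.51 kJ mol^-1, heat-capacity difference 51.44 J mol^-1 K^-1.
#'
#' @return a [fusion_properties()] object.
#' @export
ppd_fusion <- function() fusion_properties(476.43, 24510, 51.44)
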