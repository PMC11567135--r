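#' Pipeline configuration: physical constants and conventions
#'
#' All physical constants used by the DLW equations live in one configuration
#' object so that every stage of the pipeline draws on the same values and so
#' that the user-overridable ones (food quotient, hydration constant) can be
#' changed in a single place.
#'
#' The defaults are the standard two-pool DLW constants: isotopic
#' overestimation factors of the body water pool (deuterium dilution space
#' exceeds body water by ~4.3%, oxygen-18 space by ~0.7%), 0.01802 kg of water
#' per mol, hydration of fat-free mass 0.732, the 2.078 and 0.0246 x 1.05
#' terms of the two-pool CO2 production equation, 22.26 L of CO2 per mol, the
#' Weir-type energy equivalent 1.106 + 3.94/FQ kcal per litre CO2, a food
#' quotient of 0.86, and the 0.99 fractionation correction in the water
#' turnover equation.
#'
#' @param fq food quotient (diet-level CO2/O2 ratio), must lie in (0.7, 1).
#'   0.86 corresponds to fats contributing roughly 30% of energy intake; with
#'   a lower dietary fat fraction computed TEE falls by a few percent.
#' @param hydration hydration constant of fat-free mass (kg TBW per kg FFM).
#' @param enrichment_unit unit in which enrichment time series are expressed:
#'   \code{"mole_fraction"} (canonical internal unit, tracer mole fraction in
#'   excess of baseline) or \code{"ppm_excess"} (parts per million, converted
#'   by 1e-6).
#' @param negative_fm_policy what to do when computed fat mass is negative:
#'   \code{"warn"} (pass the value through with a warning, the default) or
#'   \code{"clamp"} (set FM to 0 with a warning).
#' @param ... override any other constant by name (e.g. \code{d_space_factor}).
#'
#' @return A list of class \code{"dlw_config"} with elements:
#'   \code{d_space_factor} (1.043), \code{o_space_factor} (1.007),
#'   \code{kg_per_mol_water} (0.01802), \code{hydration} (0.732),
#'   \code{rco2_pool_divisor} (2.078), \code{frac_gas_coef} (0.0246),
#'   \code{frac_gas_space} (1.05), \code{l_per_mol_co2} (22.26),
#'   \code{weir_a} (1.106), \code{weir_b} (3.94), \code{fq} (0.86),
#'   \code{wt_fractionation} (0.99), \code{enrichment_unit},
#'   \code{negative_fm_policy}, and molar masses of the two labelled water
#'   species (\code{mm_2h2o}, \code{mm_h218o}, g/mol).
#' @examples
#' cfg <- dlw_config()
#' cfg$fq
#' dlw_config(fq = 0.80)$fq
#' @export
dlw_config <- function(fq = 0.86, hydration = 0.732,
                       enrichment_unit = c("mole_fraction", "ppm_excess"),
                       negative_fm_policy = c("warn", "clamp"), ...) {
  enrichment_unit <- match.arg(enrichment_unit)
  negative_fm_policy <- match.arg(negative_fm_policy)
  if (!is.numeric(fq) || length(fq) != 1L || fq <= 0.7 || fq >= 1.0)
    stop("'fq' must be a single number in (0.7, 1.0), got ", fq)
  if (!is.numeric(hydration) || hydration <= 0 || hydration >= 1)
    stop("'hydration' must lie in (0, 1)")
  cfg <- list(
    d_space_factor   = 1.043,
    o_space_factor   = 1.007,
    kg_per_mol_water = 0.01802,
    hydration        = hydration,
    rco2_pool_divisor = 2.078,
    frac_gas_coef    = 0.0246,
    frac_gas_space   = 1.05,
    l_per_mol_co2    = 22.26,
    weir_a           = 1.106,
    weir_b           = 3.94,
    fq               = fq,
    wt_fractionation = 0.99,
    mm_2h2o          = 20.0231,   # 2 x 2.014102 + 15.994915
    mm_h218o         = 20.0148,   # 2 x 1.007825 + 17.999160
    enrichment_unit  = enrichment_unit,
    negative_fm_policy = negative_fm_policy
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      stop("unknown configuration constant(s): ", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  num <- vapply(cfg[!names(cfg) %in% c("enrichment_unit", "negative_fm_policy")],
                function(x) is.numeric(x) && x > 0, logical(1))
  if (!all(num))
    stop("all physical constants must be positive numbers")
  structure(cfg, class = "dlw_config")
}

#' @export
print.dlw_config <- function(x, ...) {
  cat("DLW pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# energy equivalent of CO2 (kcal per litre) under the Weir-type conversion
energy_equiv_kcal_per_l <- function(config = dlw_config()) {
  config$weir_a + config$weir_b / config$fq
}
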