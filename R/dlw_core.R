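#' Deuterium-to-oxygen-18 dilution space ratio
#'
#' The ratio ND/NO is a routine data-quality check in DLW work: because
#' deuterium exchanges with non-aqueous hydrogen, its apparent dilution space
#' exceeds the oxygen-18 space, and the ratio typically falls between 1.00 and
#' 1.08 in healthy adults. Values outside that band usually indicate an
#' analytical problem and trigger a warning.
#'
#' @param nd deuterium dilution space (mol).
#' @param no oxygen-18 dilution space (mol).
#' @return ND/NO (unrounded; round only for display).
#' @examples
#' dilution_space_ratio(1539.2, 1476.1)  # ~1.043
#' @export
dilution_space_ratio <- function(nd, no) {
  if (any(!is.finite(no)) || any(no <= 0)) stop("NO must be positive")
  if (any(!is.finite(nd)) || any(nd <= 0)) stop("ND must be positive")
  r <- nd / no
  out <- which(r < 1.00 | r > 1.08)
  if (length(out))
    warning("dilution space ratio outside [1.00, 1.08] for ",
            length(out), " record(s); check isotope analyses")
  r
}

#' Corrected dilution space
#'
#' Averages the two isotope dilution spaces after removing their known
#' overestimation of the body water pool: Ncorr = (ND/1.043 + NO/1.007)/2.
#' Ncorr is the working estimate of the body water pool size (mol) used by
#' the CO2 production and total-body-water equations.
#'
#' @inheritParams dilution_space_ratio
#' @param config a [dlw_config()] object supplying the 1.043 and 1.007 factors.
#' @return corrected dilution space Ncorr (mol).
#' @examples
#' corrected_dilution_space(1539.2, 1476.1)  # ~1470.8 mol
#' @export
corrected_dilution_space <- function(nd, no, config = dlw_config()) {
  if (any(!is.finite(nd)) || any(nd <= 0) || any(!is.finite(no)) || any(no <= 0))
    stop("ND and NO must be positive")
  (nd / config$d_space_factor + no / config$o_space_factor) / 2
}

#' Body composition from isotope dilution
#'
#' Total body water follows from the corrected dilution space
#' (TBW = Ncorr x 0.01802 kg/mol); fat-free mass assumes a constant hydration
#' of lean tissue (FFM = TBW/0.732); fat mass is the remainder of body mass
#' and fat percent its share. A negative fat mass (possible when the
#' hydration assumption fails for an individual) is passed through with a
#' warning by default, or clamped to zero under
#' \code{negative_fm_policy = "clamp"}.
#'
#' @param body_mass_kg body mass (kg).
#' @inheritParams corrected_dilution_space
#' @return A data.frame with one row per input: \code{ncorr_mol},
#'   \code{tbw_kg}, \code{ffm_kg}, \code{fm_kg}, \code{fat_pct}.
#' @examples
#' body_composition(48, 1539.2, 1476.1)  # FFM ~36.2 kg
#' @export
body_composition <- function(body_mass_kg, nd, no, config = dlw_config()) {
  if (any(!is.finite(body_mass_kg)) || any(body_mass_kg <= 0))
    stop("body mass must be positive")
  ncorr <- corrected_dilution_space(nd, no, config)
  tbw <- ncorr * config$kg_per_mol_water
  bad <- which(tbw >= body_mass_kg)
  if (length(bad))
    stop("total body water >= body mass for record(s) ",
         paste(bad, collapse = ", "), "; inputs are inconsistent")
  ffm <- tbw / config$hydration
  fm <- body_mass_kg - ffm
  neg <- which(fm < 0)
  if (length(neg)) {
    if (config$negative_fm_policy == "clamp") {
      warning("negative fat mass clamped to 0 for ", length(neg), " record(s)")
      fm[neg] <- 0
    } else {
      warning("negative fat mass for ", length(neg),
              " record(s); passed through (hydration assumption may not hold)")
    }
  }
  data.frame(ncorr_mol = ncorr, tbw_kg = tbw, ffm_kg = ffm, fm_kg = fm,
             fat_pct = 100 * fm / body_mass_kg)
}

#' CO2 production rate from two-pool isotope kinetics
#'
#' The two-pool equation: with the rate difference
#' \eqn{\Delta = 1.007 k_O - 1.043 k_D} (the flux leaving as CO2 plus
#' fractionated gaseous water), CO2 production in mol/day is
#' \deqn{rCO_2 = \frac{N_{corr}}{2.078}\Delta - 0.0246 \cdot 1.05 N_{corr} \Delta,}
#' where the second term removes the fractionated gaseous water loss
#' (evaporative water leaving through breath and skin, assumed to turn over
#' a 1.05 x Ncorr pool at 2.46% of the flux). Requires
#' \eqn{1.007 k_O > 1.043 k_D}; equality means zero apparent CO2 production
#' and a reversed inequality is physiologically impossible and raises an
#' error naming both rates.
#'
#' @param kd deuterium elimination rate (per day).
#' @param ko oxygen-18 elimination rate (per day).
#' @param ncorr_mol corrected dilution space (mol), from
#'   [corrected_dilution_space()].
#' @inheritParams corrected_dilution_space
#' @return A data.frame with \code{rco2_mol_day} and \code{rco2_l_day}
#'   (conversion 22.26 L/mol).
#' @examples
#' bc <- corrected_dilution_space(1539.2, 1476.1)
#' co2_production(0.2269, 0.2604, bc)
#' @export
co2_production <- function(kd, ko, ncorr_mol, config = dlw_config()) {
  if (any(kd <= 0) || any(ko <= 0)) stop("elimination rates must be positive")
  if (any(ncorr_mol <= 0)) stop("Ncorr must be positive")
  delta <- config$o_space_factor * ko - config$d_space_factor * kd
  # exact boundary (1.007 kO = 1.043 kD) legitimately gives zero production;
  # tolerate rounding there, error on genuinely reversed rates
  bad <- which(delta < -1e-10)
  delta[delta < 0 & delta >= -1e-10] <- 0
  if (length(bad))
    stop(sprintf(
      "physiologically invalid rates: %.4g*kO <= %.4g*kD (kO=%s, kD=%s)",
      config$o_space_factor, config$d_space_factor,
      paste(signif(ko[bad], 4), collapse = ","),
      paste(signif(kd[bad], 4), collapse = ",")))
  r_gf <- config$frac_gas_space * ncorr_mol * delta
  rmol <- (ncorr_mol / config$rco2_pool_divisor) * delta -
    config$frac_gas_coef * r_gf
  data.frame(rco2_mol_day = rmol, rco2_l_day = config$l_per_mol_co2 * rmol)
}

#' Total energy expenditure from CO2 production
#'
#' Weir-type conversion of CO2 volume to energy at a fixed food quotient:
#' TEE (kcal/day) = rCO2 (L/day) x (1.106 + 3.94/FQ). At the default
#' FQ = 0.86 the energy equivalent is 5.687 kcal per litre of CO2.
#'
#' @param rco2_l_day CO2 production (litres/day), as returned by
#'   [co2_production()].
#' @inheritParams corrected_dilution_space
#' @return TEE in kcal/day.
#' @examples
#' tee_from_co2(381.2)  # ~2168 kcal/day
#' @export
tee_from_co2 <- function(rco2_l_day, config = dlw_config()) {
  if (any(rco2_l_day < 0)) stop("rCO2 must be non-negative")
  rco2_l_day * energy_equiv_kcal_per_l(config)
}

#' Water turnover from deuterium kinetics
#'
#' Water turnover (litres/day) from the deuterium dilution space and
#' elimination rate: WT = 0.01802 x 1.043 x kD x ND / 0.99, where 0.99 is
#' the fractionation correction for evaporative water loss.
#'
#' @inheritParams co2_production
#' @param nd_mol deuterium dilution space (mol).
#' @return water turnover (litres/day).
#' @examples
#' water_turnover(0.2269, 1539.2)  # ~6.63 L/day
#' @export
water_turnover <- function(kd, nd_mol, config = dlw_config()) {
  if (any(kd <= 0) || any(nd_mol <= 0)) stop("kD and ND must be positive")
  config$kg_per_mol_water * config$d_space_factor * kd * nd_mol /
    config$wt_fractionation
}

#' Run the full DLW computation over a cohort
#'
#' Joins a participant table to an isotope summary table and computes, per
#' participant, the corrected dilution space, body composition, CO2
#' production, total energy expenditure and water turnover. Rows whose
#' isotope values are invalid (non-positive spaces or rates, or a rate pair
#' implying non-positive CO2 production) are rejected individually; the rest
#' of the cohort is processed. Rejected rows and their reasons are attached
#' as the \code{"rejected"} attribute.
#'
#' @param participants data.frame (or path to a CSV) with columns
#'   \code{participant_id}, \code{community}, \code{age_y}, \code{sex}
#'   (\code{"F"}/\code{"M"}), \code{body_mass_kg}.
#' @param isotopes data.frame (or path to a CSV) with columns
#'   \code{participant_id}, \code{nd_mol}, \code{no_mol}, \code{kd_perday},
#'   \code{ko_perday}.
#' @inheritParams corrected_dilution_space
#' @return A data.frame with one row per successfully processed participant:
#'   the participant columns plus \code{nd_no}, \code{ncorr_mol},
#'   \code{tbw_kg}, \code{ffm_kg}, \code{fm_kg}, \code{fat_pct},
#'   \code{rco2_mol_day}, \code{rco2_l_day}, \code{tee_kcal_day},
#'   \code{wt_l_day} and \code{fq}. Attributes: \code{"rejected"} (data.frame
#'   of participant_id + reason) and \code{"constants"} (the config used).
#' @examples
#' coh <- daasanach_cohort()
#' derived <- process_cohort(
#'   coh[, c("participant_id", "community", "age_y", "sex", "body_mass_kg")],
#'   coh[, c("participant_id", "nd_mol", "no_mol", "kd_perday", "ko_perday")])
#' head(derived[, c("participant_id", "ffm_kg", "tee_kcal_day", "wt_l_day")])
#' @export
process_cohort <- function(participants, isotopes, config = dlw_config()) {
  participants <- read_table_arg(participants,
    c("participant_id", "community", "age_y", "sex", "body_mass_kg"),
    "participants")
  isotopes <- read_table_arg(isotopes,
    c("participant_id", "nd_mol", "no_mol", "kd_perday", "ko_perday"),
    "isotopes")
  if (anyDuplicated(participants$participant_id))
    stop("duplicated participant_id in participants table")
  if (anyDuplicated(isotopes$participant_id))
    stop("duplicated participant_id in isotopes table")
  dat <- merge(participants, isotopes, by = "participant_id", sort = FALSE)
  missing_iso <- setdiff(participants$participant_id, isotopes$participant_id)
  if (length(missing_iso))
    warning("no isotope record for participant(s): ",
            paste(missing_iso, collapse = ", "))
  if (nrow(dat) == 0L) {
    warning("empty cohort: no joinable rows")
    out <- dat
    attr(out, "rejected") <- data.frame(participant_id = character(),
                                        reason = character())
    attr(out, "constants") <- config
    return(out)
  }

  rejected <- data.frame(participant_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  rows <- vector("list", nrow(dat))
  for (i in seq_len(nrow(dat))) {
    r <- dat[i, ]
    res <- tryCatch({
      bc <- body_composition(r$body_mass_kg, r$nd_mol, r$no_mol, config)
      co2 <- co2_production(r$kd_perday, r$ko_perday, bc$ncorr_mol, config)
      cbind(r,
            nd_no = r$nd_mol / r$no_mol,
            bc, co2,
            tee_kcal_day = tee_from_co2(co2$rco2_l_day, config),
            wt_l_day = water_turnover(r$kd_perday, r$nd_mol, config),
            fq = config$fq)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rejected <- rbind(rejected, data.frame(
        participant_id = r$participant_id, reason = conditionMessage(res)))
    } else {
      rows[[i]] <- res
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (nrow(rejected))
    warning(nrow(rejected), " row(s) rejected: ",
            paste(rejected$participant_id, collapse = ", "))
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  attr(out, "constants") <- config
  out
}

#' Write a derived cohort table to CSV
#'
#' Internal computation keeps full double precision; this writer applies
#' display rounding (4 significant figures by default, matching the precision
#' of published DLW tables) at output only.
#'
#' @param x derived cohort data.frame from [process_cohort()].
#' @param path output CSV path.
#' @param digits significant digits for numeric columns.
#' @return \code{path}, invisibly.
#' @export
write_cohort_csv <- function(x, path, digits = 4) {
  y <- x
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], signif, digits = digits)
  utils::write.csv(y, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Accept a data.frame or a CSV path; validate required columns.
read_table_arg <- function(x, required, what) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop(what, " file not found: ", x)
    x <- utils::read.csv(x, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(x)) stop(what, " must be a data.frame or a CSV path")
  miss <- setdiff(required, names(x))
  if (length(miss))
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
  x
}
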