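#' Fit isotope elimination kinetics by the slope-intercept method
#'
#' Isotope washout after a DLW dose is mono-exponential: excess enrichment
#' (enrichment above the pre-dose baseline) decays as
#' \eqn{E(t) = A e^{-kt}}. The slope-intercept method fits ordinary least
#' squares of \eqn{\ln E} on time; the elimination rate is minus the slope
#' and the zero-time intercept \eqn{A = e^{intercept}} carries the dilution
#' space information (filled in by [dilution_space_from_dose()]).
#'
#' Exactly one pre-dose baseline sample per participant x isotope is
#' expected; if several are present they are averaged with a warning. All
#' post-dose samples must lie strictly above baseline (otherwise the offending
#' sample is named in an error) and at strictly positive times.
#'
#' @param samples data.frame for one participant and one isotope with columns
#'   \code{time_days}, \code{enrichment}, \code{is_baseline} (logical or 0/1).
#'   An optional \code{isotope} column (all equal, \code{"2H"} or
#'   \code{"18O"}) is carried into the result.
#' @return An object of class \code{"elimination_fit"}: list with
#'   \code{isotope}, \code{k} (per day), \code{intercept_excess} (excess
#'   enrichment at t = 0, same unit as the input), \code{baseline},
#'   \code{N_mol} (NA until [dilution_space_from_dose()]), \code{n_points},
#'   \code{fit_r2}.
#' @examples
#' t <- c(0.1, 1:7)
#' s <- data.frame(time_days = c(0, t), enrichment = c(10, 10 + 500 * exp(-0.25 * t)),
#'                 is_baseline = c(TRUE, rep(FALSE, 8)))
#' fit_elimination(s)$k  # 0.25
#' @export
fit_elimination <- function(samples) {
  stopifnot(is.data.frame(samples))
  need <- c("time_days", "enrichment", "is_baseline")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("samples missing column(s): ", paste(miss, collapse = ", "))
  isotope <- if ("isotope" %in% names(samples)) {
    u <- unique(samples$isotope)
    if (length(u) != 1L) stop("samples mix isotopes: ", paste(u, collapse = ", "))
    u
  } else NA_character_
  bl <- samples[as.logical(samples$is_baseline), , drop = FALSE]
  post <- samples[!as.logical(samples$is_baseline), , drop = FALSE]
  if (nrow(bl) == 0L) stop("no baseline sample present")
  if (nrow(bl) > 1L) warning("multiple baseline samples; using their mean")
  baseline <- mean(bl$enrichment)
  if (nrow(post) < 2L)
    stop("insufficient data: need >= 2 post-dose samples, got ", nrow(post))
  if (any(post$time_days <= 0))
    stop("post-dose times must be strictly positive")
  excess <- post$enrichment - baseline
  bad <- which(excess <= 0)
  if (length(bad))
    stop("invalid sample(s): non-positive excess enrichment at t = ",
         paste(post$time_days[bad], collapse = ", "), " days")
  fit <- stats::lm(log(excess) ~ post$time_days)
  y <- log(excess)
  ss_tot <- sum((y - mean(y))^2)
  # exact or degenerate fits have ss_tot ~ ss_res ~ 0; report R2 = 1
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else 1
  k <- -unname(stats::coef(fit)[2])
  if (!is.finite(k) || k <= 0)
    warning("fitted elimination rate is not positive (k = ", signif(k, 4),
            "); enrichment does not decay over the sampling window")
  structure(list(
    isotope = isotope,
    k = k,
    intercept_excess = exp(unname(stats::coef(fit)[1])),
    baseline = baseline,
    N_mol = NA_real_,
    n_points = nrow(post),
    fit_r2 = r2
  ), class = "elimination_fit")
}

#' @export
print.elimination_fit <- function(x, ...) {
  cat(sprintf(
    "Elimination fit%s: k = %.4f /day, intercept excess = %.4g, N = %s mol (n = %d, R2 = %.4f)\n",
    if (is.na(x$isotope)) "" else paste0(" [", x$isotope, "]"),
    x$k, x$intercept_excess,
    if (is.na(x$N_mol)) "unset" else format(signif(x$N_mol, 6)),
    x$n_points, x$fit_r2))
  invisible(x)
}

#' Dose record for a DLW administration
#'
#' @param dose_g grams of dose water administered.
#' @param frac_2h2o mass fraction of 2H2O in the dose (default 0.06).
#' @param frac_h218o mass fraction of H2-18O in the dose (default 0.10).
#' @return list of class \code{"dose_record"}.
#' @examples
#' dose_record(80)
#' @export
dose_record <- function(dose_g, frac_2h2o = 0.06, frac_h218o = 0.10) {
  if (!is.numeric(dose_g) || dose_g <= 0) stop("dose_g must be positive")
  for (f in c(frac_2h2o, frac_h218o))
    if (!is.numeric(f) || f <= 0 || f >= 1) stop("dose fractions must lie in (0,1)")
  structure(list(dose_g = dose_g, frac_2h2o = frac_2h2o,
                 frac_h218o = frac_h218o), class = "dose_record")
}

#' Dilution space from dose and zero-time intercept
#'
#' Converts the fitted zero-time intercept into the dilution space N: the
#' moles of labelled water administered divided by the intercept excess
#' expressed as a mole fraction. With enrichment measured as tracer mole
#' fraction above baseline, \eqn{N = n_{dose} / A}. The enrichment unit of
#' the fit must be declared in the configuration (\code{"mole_fraction"} or
#' \code{"ppm_excess"}); ppm values are converted by 1e-6.
#'
#' @param fit an \code{"elimination_fit"} from [fit_elimination()]; its
#'   \code{isotope} field selects the labelled species unless \code{species}
#'   is given.
#' @param dose a [dose_record()].
#' @param species which labelled water species the fit tracks:
#'   \code{"2H2O"} or \code{"H218O"}; defaults from \code{fit$isotope}.
#' @param config a [dlw_config()]; supplies molar masses and the declared
#'   enrichment unit.
#' @return the fit with \code{N_mol} filled in.
#' @examples
#' t <- 1:7
#' s <- data.frame(time_days = c(0, t),
#'                 enrichment = c(0.00015, 0.00015 + 1.6e-4 * exp(-0.25 * t)),
#'                 is_baseline = c(TRUE, rep(FALSE, 7)),
#'                 isotope = "2H")
#' dilution_space_from_dose(fit_elimination(s), dose_record(80))
#' @export
dilution_space_from_dose <- function(fit, dose,
                                     species = NULL,
                                     config = dlw_config()) {
  stopifnot(inherits(fit, "elimination_fit"), inherits(dose, "dose_record"))
  if (is.null(species)) {
    if (is.na(fit$isotope))
      stop("species not given and fit carries no isotope label")
    species <- switch(fit$isotope, "2H" = "2H2O", "18O" = "H218O",
                      stop("unknown isotope label: ", fit$isotope))
  }
  species <- match.arg(species, c("2H2O", "H218O"))
  if (!is.finite(fit$intercept_excess) || fit$intercept_excess <= 0)
    stop("zero-time intercept excess must be positive")
  moles <- switch(species,
    "2H2O"  = dose$dose_g * dose$frac_2h2o / config$mm_2h2o,
    "H218O" = dose$dose_g * dose$frac_h218o / config$mm_h218o)
  intercept_mf <- switch(config$enrichment_unit,
    mole_fraction = fit$intercept_excess,
    ppm_excess    = fit$intercept_excess * 1e-6)
  fit$N_mol <- moles / intercept_mf
  fit
}

#' Read an enrichment time-series CSV
#'
#' Schema: \code{participant_id}, \code{isotope} (\code{2H}/\code{18O}),
#' \code{time_days}, \code{enrichment}, \code{is_baseline} (0/1). An optional
#' \code{enrichment_unit} column must match the configured unit.
#'
#' @param path CSV path.
#' @param config a [dlw_config()] declaring the expected enrichment unit.
#' @return data.frame, validated.
#' @export
read_enrichment_csv <- function(path, config = dlw_config()) {
  d <- read_table_arg(path, c("participant_id", "isotope", "time_days",
                              "enrichment", "is_baseline"), "enrichment")
  if (!all(d$isotope %in% c("2H", "18O")))
    stop("isotope must be one of '2H', '18O'")
  if ("enrichment_unit" %in% names(d)) {
    u <- unique(d$enrichment_unit)
    if (!identical(u, config$enrichment_unit))
      stop("enrichment unit mismatch: file declares ",
           paste(u, collapse = ","), " but config expects ",
           config$enrichment_unit)
  }
  d
}
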