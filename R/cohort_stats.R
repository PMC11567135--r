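#' Build the model frame for cohort regressions
#'
#' Prepares the derived cohort table for the regression stage: natural-log
#' transforms of TEE, FFM and FM (which must be strictly positive), factors
#' with fixed reference levels (sex = F, community = Illeret,
#' population = Daasanach), and pass-through of age, steps and MVPA where
#' present.
#'
#' @param derived data.frame from [process_cohort()] (columns
#'   \code{tee_kcal_day}, \code{ffm_kg}, \code{fm_kg}, \code{sex},
#'   \code{age_y}; optional \code{community}, \code{population},
#'   \code{wt_l_day}, \code{steps_day}, \code{mvpa_min_day}).
#' @param reference_levels named list overriding the default reference level
#'   of any factor.
#' @return data.frame with columns \code{participant_id}, \code{lnTEE},
#'   \code{lnFFM}, \code{lnFM}, \code{TEE}, \code{FFM}, \code{FM},
#'   \code{age}, \code{sex}, and any of \code{community}, \code{population},
#'   \code{WT}, \code{steps}, \code{MVPA} available.
#' @examples
#' inp <- cohort_inputs()
#' derived <- process_cohort(inp$participants, inp$isotopes)
#' head(cohort_model_frame(derived))
#' @export
cohort_model_frame <- function(derived,
                               reference_levels = list(sex = "F",
                                                       community = "Illeret",
                                                       population = "Daasanach")) {
  need <- c("participant_id", "tee_kcal_day", "ffm_kg", "fm_kg", "sex", "age_y")
  miss <- setdiff(need, names(derived))
  if (length(miss)) stop("derived table missing column(s): ",
                         paste(miss, collapse = ", "))
  for (v in c("tee_kcal_day", "ffm_kg", "fm_kg")) {
    bad <- which(!is.finite(derived[[v]]) | derived[[v]] <= 0)
    if (length(bad))
      stop("cannot log-transform ", v, ": non-positive value in row(s) ",
           paste(derived$participant_id[bad], collapse = ", "))
  }
  out <- data.frame(
    participant_id = derived$participant_id,
    lnTEE = log(derived$tee_kcal_day),
    lnFFM = log(derived$ffm_kg),
    lnFM  = log(derived$fm_kg),
    TEE = derived$tee_kcal_day,
    FFM = derived$ffm_kg,
    FM  = derived$fm_kg,
    age = derived$age_y,
    stringsAsFactors = FALSE
  )
  add_factor <- function(out, nm) {
    if (nm %in% names(derived)) {
      lev <- unique(derived[[nm]])
      ref <- reference_levels[[nm]]
      if (!is.null(ref)) {
        if (!ref %in% lev)
          stop("reference level '", ref, "' not observed in ", nm)
        lev <- c(ref, setdiff(lev, ref))
      }
      out[[nm]] <- factor(derived[[nm]], levels = lev)
    }
    out
  }
  out <- add_factor(out, "sex")
  out <- add_factor(out, "community")
  out <- add_factor(out, "population")
  if ("wt_l_day" %in% names(derived)) out$WT <- derived$wt_l_day
  if ("steps_day" %in% names(derived)) out$steps <- derived$steps_day
  if ("mvpa_min_day" %in% names(derived)) out$MVPA <- derived$mvpa_min_day
  out
}

#' Specify a cohort regression model
#'
#' @param response \code{"lnTEE"} or \code{"WT"}.
#' @param predictors character vector, an ordered subset of
#'   \code{lnFFM, lnFM, FFM, FM, age, sex, community, population, TEE,
#'   steps, MVPA}.
#' @return list of class \code{"model_spec"}.
#' @examples
#' model_spec("lnTEE", c("lnFFM", "lnFM", "sex"))
#' @export
model_spec <- function(response = c("lnTEE", "WT"), predictors) {
  response <- match.arg(response)
  allowed <- c("lnFFM", "lnFM", "FFM", "FM", "age", "sex", "community",
               "population", "TEE", "steps", "MVPA")
  if (!length(predictors)) stop("predictors must be non-empty")
  bad <- setdiff(predictors, allowed)
  if (length(bad)) stop("unknown predictor(s): ", paste(bad, collapse = ", "))
  structure(list(response = response, predictors = predictors),
            class = "model_spec")
}

#' Fit a cohort regression by ordinary least squares
#'
#' Fits the specified linear model with treatment (dummy) coding at the
#' reference levels fixed by [cohort_model_frame()]. Reports coefficient
#' estimates, standard errors and two-sided t-test p-values, R-squared and
#' adjusted R-squared, and residuals keyed by participant for the
#' residual-adjustment stage.
#'
#' @param spec a [model_spec()].
#' @param frame model frame from [cohort_model_frame()].
#' @return object of class \code{"cohort_fit"}: list with \code{spec},
#'   \code{coefficients} (data.frame term/estimate/se/t/p),
#'   \code{r_squared}, \code{adj_r_squared}, \code{sigma}, \code{n},
#'   \code{residuals} (named by participant_id), and \code{lm} (the
#'   underlying fit).
#' @examples
#' inp <- cohort_inputs()
#' fr <- cohort_model_frame(process_cohort(inp$participants, inp$isotopes))
#' fit_cohort_model(model_spec("lnTEE", c("lnFFM", "lnFM", "sex")), fr)
#' @export
fit_cohort_model <- function(spec, frame) {
  stopifnot(inherits(spec, "model_spec"))
  miss <- setdiff(c(spec$response, spec$predictors), names(frame))
  if (length(miss))
    stop("model frame missing variable(s): ", paste(miss, collapse = ", "))
  vars <- c(spec$response, spec$predictors)
  cc <- stats::complete.cases(frame[, vars, drop = FALSE])
  frame <- frame[cc, , drop = FALSE]
  p <- length(spec$predictors)
  if (nrow(frame) < p + 2L)
    stop("need at least ", p + 2L, " complete rows, got ", nrow(frame))
  form <- stats::reformulate(spec$predictors, response = spec$response)
  fit <- stats::lm(form, data = frame)
  if (fit$rank < length(stats::coef(fit))) {
    dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  sm <- summary(fit)
  co <- sm$coefficients
  res <- stats::residuals(fit)
  names(res) <- frame$participant_id
  structure(list(
    spec = spec,
    coefficients = data.frame(term = rownames(co), estimate = co[, 1],
                              se = co[, 2], t = co[, 3], p = co[, 4],
                              row.names = NULL),
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    sigma = sm$sigma,
    n = nrow(frame),
    residuals = res,
    lm = fit
  ), class = "cohort_fit")
}

#' @export
print.cohort_fit <- function(x, ...) {
  cat(sprintf("%s ~ %s  (n = %d)\n", x$spec$response,
              paste(x$spec$predictors, collapse = " + "), x$n))
  print(transform(x$coefficients,
                  estimate = signif(estimate, 3), se = signif(se, 3),
                  t = signif(t, 3), p = signif(p, 3)), row.names = FALSE)
  cat(sprintf("R2 = %.3f, adjusted R2 = %.3f\n", x$r_squared, x$adj_r_squared))
  invisible(x)
}

#' One-way ANOVA on regression residuals
#'
#' Uses the residuals of a fitted cohort model as covariate-adjusted values
#' (e.g. body-mass- and sex-adjusted TEE) and tests for group differences
#' with a one-way ANOVA.
#'
#' @param fit a \code{"cohort_fit"}.
#' @param groups vector of group labels, either named by participant_id or
#'   in the order of the rows the model was fitted on.
#' @return list: \code{F}, \code{df_between}, \code{df_within}, \code{p}.
#' @examples
#' inp <- cohort_inputs()
#' fr <- cohort_model_frame(process_cohort(inp$participants, inp$isotopes))
#' fit <- fit_cohort_model(model_spec("lnTEE", c("lnFFM", "lnFM", "sex")), fr)
#' residual_anova(fit, stats::setNames(fr$community, fr$participant_id))
#' @export
residual_anova <- function(fit, groups) {
  stopifnot(inherits(fit, "cohort_fit"))
  res <- fit$residuals
  if (!is.null(names(groups))) {
    miss <- setdiff(names(res), names(groups))
    if (length(miss))
      stop("no group label for participant(s): ", paste(miss, collapse = ", "))
    groups <- groups[names(res)]
  } else if (length(groups) != length(res)) {
    stop("groups must be named by participant_id or match the fitted rows")
  }
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  small <- names(which(table(g) < 2L))
  if (length(small))
    stop("group(s) with fewer than 2 members: ", paste(small, collapse = ", "))
  a <- stats::anova(stats::lm(res ~ g))
  list(F = a$`F value`[1], df_between = a$Df[1], df_within = a$Df[2],
       p = a$`Pr(>F)`[1])
}

#' Kruskal-Wallis rank test
#'
#' Thin wrapper around [stats::kruskal.test()] (tie-corrected H) that
#' validates the grouping and returns H = 0 with a warning when all values
#' are identical (where the rank statistic is undefined).
#'
#' @param values numeric vector.
#' @param groups group labels, same length.
#' @return list: \code{H}, \code{df}, \code{p}.
#' @examples
#' kruskal_wallis(c(1, 5, 2, 8, 9, 11), rep(c("a", "b"), each = 3))
#' @export
kruskal_wallis <- function(values, groups) {
  if (length(values) != length(groups)) stop("values and groups differ in length")
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(groups[keep])
  if (nlevels(droplevels(groups)) < 2L) stop("need at least 2 non-empty groups")
  groups <- droplevels(groups)
  if (length(unique(values)) == 1L) {
    warning("all values identical; H = 0")
    return(list(H = 0, df = nlevels(groups) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Reference regression model for prediction-interval screening
#'
#' A reference model (typically fitted elsewhere on a large comparison
#' sample) is serialised as its coefficient vector plus enough design
#' information to form 95% prediction intervals: either the full
#' \eqn{(X'X)^{-1}} matrix, or, as an approximation, just the residual SD
#' and sample size (prediction SE then \eqn{\sigma\sqrt{1 + 1/n}}, which
#' ignores leverage and is slightly anti-conservative far from the
#' covariate mean).
#'
#' @param coefficients named numeric vector; must include
#'   \code{"(Intercept)"}. Names of the remaining terms must match columns
#'   of the screening data (factor dummies spelt out, e.g. \code{sexM}).
#' @param sigma residual standard deviation.
#' @param n training sample size.
#' @param df_residual residual degrees of freedom (default \code{n} minus
#'   the number of coefficients).
#' @param xtx_inv optional \eqn{(X'X)^{-1}} with rows/columns matching
#'   \code{coefficients}.
#' @param log_scale if TRUE, the model predicts the natural log of the
#'   response and predictions/intervals are exponentiated before reporting.
#' @return list of class \code{"reference_model"}.
#' @export
reference_model <- function(coefficients, sigma, n,
                            df_residual = n - length(coefficients),
                            xtx_inv = NULL, log_scale = FALSE) {
  if (!"(Intercept)" %in% names(coefficients))
    stop("coefficients must include '(Intercept)'")
  if (sigma < 0) stop("sigma must be non-negative")
  if (df_residual <= 0) stop("df_residual must be positive")
  if (!is.null(xtx_inv)) {
    stopifnot(is.matrix(xtx_inv),
              identical(dim(xtx_inv), rep(length(coefficients), 2L)))
    if (is.null(rownames(xtx_inv))) {
      dimnames(xtx_inv) <- list(names(coefficients), names(coefficients))
    } else {
      xtx_inv <- xtx_inv[names(coefficients), names(coefficients)]
    }
  }
  structure(list(coefficients = coefficients, sigma = sigma, n = n,
                 df_residual = df_residual, xtx_inv = xtx_inv,
                 log_scale = log_scale), class = "reference_model")
}

#' Extract a reference model from an lm fit
#'
#' @param fit an \code{lm} object.
#' @param log_scale whether the response of \code{fit} is on the log scale.
#' @return a [reference_model()] carrying the full covariance information.
#' @export
as_reference_model <- function(fit, log_scale = FALSE) {
  stopifnot(inherits(fit, "lm"))
  sm <- summary(fit)
  qr_r <- qr.R(fit$qr)
  xtx_inv <- chol2inv(qr_r)
  dimnames(xtx_inv) <- list(names(stats::coef(fit)), names(stats::coef(fit)))
  reference_model(stats::coef(fit), sm$sigma, length(stats::resid(fit)),
                  df_residual = fit$df.residual, xtx_inv = xtx_inv,
                  log_scale = log_scale)
}

#' Screen observations against a reference model's prediction intervals
#'
#' For each row, forms the reference model's point estimate and two-sided
#' prediction interval at the given level and flags whether the observed
#' value lies inside, below or above it. Rows missing a required covariate
#' are skipped with a warning.
#'
#' @param ref a [reference_model()].
#' @param newdata data.frame containing the model's covariate columns.
#' @param observed numeric vector of observed responses (response scale,
#'   i.e. already exponentiated if \code{ref$log_scale}).
#' @param level coverage of the prediction interval (default 0.95).
#' @return data.frame: \code{predicted}, \code{pi_lo}, \code{pi_hi},
#'   \code{status} (\code{inside}/\code{below}/\code{above}), one row per
#'   retained input row, with a \code{"summary"} attribute of status counts.
#' @examples
#' ref <- reference_model(c("(Intercept)" = 1, x = 2), sigma = 0.5, n = 100)
#' predict_with_interval(ref, data.frame(x = c(0, 1)), observed = c(1.2, 9))
#' @export
predict_with_interval <- function(ref, newdata, observed, level = 0.95) {
  stopifnot(inherits(ref, "reference_model"))
  if (nrow(newdata) != length(observed))
    stop("newdata and observed differ in length")
  terms <- setdiff(names(ref$coefficients), "(Intercept)")
  miss_col <- setdiff(terms, names(newdata))
  if (length(miss_col))
    stop("newdata missing covariate column(s): ",
         paste(miss_col, collapse = ", "))
  X <- cbind(`(Intercept)` = 1,
             as.matrix(newdata[, terms, drop = FALSE]))
  ok <- stats::complete.cases(X) & is.finite(observed)
  if (any(!ok))
    warning(sum(!ok), " row(s) skipped: missing covariate or observation")
  X <- X[ok, , drop = FALSE]
  observed <- observed[ok]
  eta <- drop(X %*% ref$coefficients[colnames(X)])
  se_pred <- if (!is.null(ref$xtx_inv)) {
    lev <- rowSums((X %*% ref$xtx_inv[colnames(X), colnames(X)]) * X)
    ref$sigma * sqrt(1 + lev)
  } else {
    rep(ref$sigma * sqrt(1 + 1 / ref$n), length(eta))
  }
  tq <- stats::qt(1 - (1 - level) / 2, ref$df_residual)
  lo <- eta - tq * se_pred
  hi <- eta + tq * se_pred
  if (ref$log_scale) {
    eta <- exp(eta); lo <- exp(lo); hi <- exp(hi)
  }
  status <- ifelse(observed < lo, "below",
                   ifelse(observed > hi, "above", "inside"))
  out <- data.frame(predicted = eta, pi_lo = lo, pi_hi = hi,
                    observed = observed, status = status)
  if (!is.null(rownames(newdata))) rownames(out) <- rownames(newdata)[ok]
  attr(out, "summary") <- table(factor(status,
                                       c("below", "inside", "above")))
  out
}

#' Group means and standard deviations
#'
#' @param data data.frame.
#' @param value name of the numeric column to summarise.
#' @param by character vector of grouping columns (e.g. \code{"sex"},
#'   \code{c("community", "sex")}).
#' @param na.rm drop missing values before summarising (default TRUE).
#' @return data.frame with the grouping columns plus \code{n}, \code{mean},
#'   \code{sd} (NA for singleton groups).
#' @examples
#' group_summaries(daasanach_cohort(), "tee_kcal_day", "sex")
#' @export
group_summaries <- function(data, value, by, na.rm = TRUE) {
  stopifnot(value %in% names(data), all(by %in% names(data)))
  v <- data[[value]]
  if (na.rm) {
    keep <- !is.na(v)
    data <- data[keep, , drop = FALSE]
    v <- v[keep]
  }
  key <- interaction(data[by], drop = TRUE, sep = "\r")
  if (!length(v)) stop("no non-missing values to summarise")
  agg <- data.frame(
    do.call(rbind, strsplit(levels(key), "\r", fixed = TRUE)),
    n = as.integer(tapply(v, key, length)),
    mean = as.numeric(tapply(v, key, mean)),
    sd = as.numeric(tapply(v, key, stats::sd)),
    stringsAsFactors = FALSE
  )
  names(agg)[seq_along(by)] <- by
  rownames(agg) <- NULL
  agg
}
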