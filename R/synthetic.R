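#' Simulation settings for synthetic cohorts
#'
#' Distribution parameters emulating a small, lean, physically active adult
#' cohort: sex-stratified body mass (means 52.5 kg men / 49.2 kg women) and
#' body-fat percent (14 +/- 6% men, 25 +/- 8% women, truncated to [3, 45]),
#' a log-log linear model generating true TEE from body composition and sex
#' (intercept 3.35, lnFFM slope 1.33, lnFM slope -0.16, male offset -0.22,
#' residual SD 0.12 on the log scale), and water turnover linear in TEE
#' (3.07 + 0.002 x TEE, residual SD 1.3 L/day, floored at 2.5). The
#' deuterium/oxygen-18 dilution-space ratio is drawn from N(1.041, 0.008)
#' truncated to [1.00, 1.07].
#'
#' @param ... override any element by name (e.g. \code{sd_lntee = 0},
#'   \code{sd_wt = 0} for a noise-free cohort).
#' @return list of class \code{"cohort_sim_config"}.
#' @export
cohort_sim_config <- function(...) {
  cfg <- list(
    p_female = 19 / 34,
    mass_mean = c(F = 49.2, M = 52.5), mass_sd = c(F = 6, M = 4.5),
    mass_range = c(38, 70),
    fat_mean = c(F = 25, M = 14), fat_sd = c(F = 8, M = 6),
    fat_range = c(3, 45),
    age_range = c(20, 56),
    communities = c("Illeret", "El Bokoch", "Roto"),
    lntee_coef = c(intercept = 3.35, lnFFM = 1.33, lnFM = -0.16,
                   sexM = -0.22),
    sd_lntee = 0.12,
    wt_coef = c(intercept = 3.07, tee = 0.002),
    sd_wt = 1.3,
    wt_floor = 2.5,
    ratio_mean = 1.041, ratio_sd = 0.008, ratio_range = c(1.00, 1.07)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown simulation setting(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (cfg$fat_range[1] >= cfg$fat_range[2] ||
      cfg$mass_range[1] >= cfg$mass_range[2])
    stop("infeasible truncation range")
  structure(cfg, class = "cohort_sim_config")
}

# truncated-normal draws by rejection (ranges used here are wide, so the
# acceptance rate is high)
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (any(lo >= hi)) stop("infeasible truncation: empty interval")
  out <- stats::rnorm(n, mean, sd)
  for (iter in 1:1000) {
    bad <- which(out < lo | out > hi)
    if (!length(bad)) return(out)
    out[bad] <- stats::rnorm(length(bad),
                             if (length(mean) > 1) mean[bad] else mean,
                             if (length(sd) > 1) sd[bad] else sd)
  }
  stop("truncated-normal sampler failed to converge; check the range")
}

#' Stable per-participant seed
#'
#' Fans a single global seed out to per-participant substreams by a stable
#' polynomial hash of the participant id, so that each participant's
#' synthetic series is reproducible in isolation.
#'
#' @param seed integer global seed.
#' @param participant_id character id.
#' @return integer seed below 2^31.
#' @export
participant_seed <- function(seed, participant_id) {
  h <- 0
  for (ch in utf8ToInt(as.character(participant_id)))
    h <- (h * 131 + ch) %% 2147483647
  as.integer((h + as.numeric(seed)) %% 2147483647)
}

#' Generate a synthetic cohort with exactly invertible isotope inputs
#'
#' Draws per-participant truth (body mass, fat percent, TEE, water turnover)
#' from the configured distributions, then back-solves the isotope summary
#' (ND, NO, kD, kO) through the frozen DLW equations so that running
#' [process_cohort()] on the generated inputs reproduces the truth exactly
#' (to machine precision): the dilution-space ratio fixes ND and NO from the
#' body-water pool, kD is solved from water turnover, and kO from the CO2
#' production implied by TEE.
#'
#' @param n cohort size (>= 1).
#' @param seed integer seed; the output is a pure function of
#'   \code{(seed, sim, config)}.
#' @param sim a [cohort_sim_config()].
#' @param config a [dlw_config()] (the same constants the analysis uses).
#' @return list with \code{truth} (all true quantities plus the back-solved
#'   isotope columns), \code{participants} and \code{isotopes} (the two
#'   input tables in the [process_cohort()] schemas).
#' @examples
#' g <- generate_cohort(20, seed = 1)
#' derived <- process_cohort(g$participants, g$isotopes)
#' max(abs(derived$tee_kcal_day - g$truth$tee_kcal_day))  # ~1e-12 relative
#' @export
generate_cohort <- function(n, seed, sim = cohort_sim_config(),
                            config = dlw_config()) {
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  id <- sprintf("S%04d", seq_len(n))
  sex <- ifelse(stats::runif(n) < sim$p_female, "F", "M")
  community <- sample(sim$communities, n, replace = TRUE)
  age <- round(stats::runif(n, sim$age_range[1], sim$age_range[2]))
  mass <- rnorm_trunc(n, sim$mass_mean[sex], sim$mass_sd[sex],
                      sim$mass_range[1], sim$mass_range[2])
  fat <- rnorm_trunc(n, sim$fat_mean[sex], sim$fat_sd[sex],
                     sim$fat_range[1], sim$fat_range[2])
  ffm <- mass * (1 - fat / 100)
  fm <- mass - ffm
  b <- sim$lntee_coef
  lntee <- b["intercept"] + b["lnFFM"] * log(ffm) + b["lnFM"] * log(fm) +
    b["sexM"] * (sex == "M") + stats::rnorm(n, 0, sim$sd_lntee)
  tee <- exp(unname(lntee))
  wt <- sim$wt_coef["intercept"] + sim$wt_coef["tee"] * tee +
    stats::rnorm(n, 0, sim$sd_wt)
  wt <- pmax(unname(wt), sim$wt_floor)
  ratio <- rnorm_trunc(n, sim$ratio_mean, sim$ratio_sd,
                       sim$ratio_range[1], sim$ratio_range[2])

  # invert the DLW equations
  tbw <- config$hydration * ffm
  ncorr <- tbw / config$kg_per_mol_water
  no <- 2 * ncorr / (ratio / config$d_space_factor + 1 / config$o_space_factor)
  nd <- ratio * no
  kd <- wt * config$wt_fractionation /
    (config$kg_per_mol_water * config$d_space_factor * nd)
  rco2_mol <- tee / energy_equiv_kcal_per_l(config) / config$l_per_mol_co2
  delta <- rco2_mol / (ncorr * (1 / config$rco2_pool_divisor -
                                  config$frac_gas_coef * config$frac_gas_space))
  ko <- (delta + config$d_space_factor * kd) / config$o_space_factor

  truth <- data.frame(
    participant_id = id, community = community, age_y = age, sex = sex,
    body_mass_kg = mass, fat_pct = fat, ffm_kg = ffm, fm_kg = fm,
    tee_kcal_day = tee, wt_l_day = wt, nd_no = ratio,
    nd_mol = nd, no_mol = no, kd_perday = kd, ko_perday = ko,
    seed = vapply(id, participant_seed, integer(1), seed = seed),
    stringsAsFactors = FALSE
  )
  list(
    truth = truth,
    participants = truth[, c("participant_id", "community", "age_y", "sex",
                             "body_mass_kg")],
    isotopes = truth[, c("participant_id", "nd_mol", "no_mol", "kd_perday",
                         "ko_perday")]
  )
}

#' Generate a mono-exponential enrichment washout series
#'
#' Builds the enrichment time series implied by a dose and a true dilution
#' space: the zero-time intercept (mole-fraction excess) is the moles of
#' labelled species administered divided by N, and excess decays as
#' \eqn{A e^{-kt}}. Measurement noise is multiplicative log-normal on the
#' excess; the baseline sample is reported noise-free at t = 0.
#'
#' @param k true elimination rate (per day).
#' @param n_mol true dilution space (mol).
#' @param dose a [dose_record()].
#' @param isotope \code{"2H"} or \code{"18O"} (selects the labelled species
#'   and its natural-abundance baseline).
#' @param schedule post-dose sampling times in days (>= 2 values).
#' @param noise_sd log-scale SD of the multiplicative measurement noise
#'   (0 = noiseless).
#' @param seed integer seed.
#' @param baseline baseline tracer mole fraction; defaults to natural
#'   abundance (1.56e-4 for 2H, 2.005e-3 for 18O).
#' @param config a [dlw_config()].
#' @return list with \code{samples} (data.frame in the [fit_elimination()]
#'   schema, baseline row first) and \code{dose}.
#' @examples
#' g <- generate_enrichment_series(0.25, 1500, dose_record(80), "2H",
#'                                 schedule = 1:7, noise_sd = 0, seed = 1)
#' fit_elimination(g$samples)$k  # 0.25
#' @export
generate_enrichment_series <- function(k, n_mol, dose, isotope = c("2H", "18O"),
                                       schedule, noise_sd = 0.01, seed = 1,
                                       baseline = NULL,
                                       config = dlw_config()) {
  isotope <- match.arg(isotope)
  stopifnot(inherits(dose, "dose_record"), k > 0, n_mol > 0)
  if (length(schedule) < 2L) stop("schedule needs >= 2 post-dose times")
  if (any(schedule <= 0)) stop("post-dose times must be positive")
  if (is.null(baseline))
    baseline <- switch(isotope, "2H" = 1.56e-4, "18O" = 2.005e-3)
  moles <- switch(isotope,
    "2H"  = dose$dose_g * dose$frac_2h2o / config$mm_2h2o,
    "18O" = dose$dose_g * dose$frac_h218o / config$mm_h218o)
  a0 <- moles / n_mol  # mole-fraction excess at t = 0
  set.seed(as.integer(seed))
  excess <- a0 * exp(-k * schedule)
  if (noise_sd > 0)
    excess <- excess * exp(stats::rnorm(length(schedule), 0, noise_sd))
  samples <- data.frame(
    isotope = isotope,
    time_days = c(0, schedule),
    enrichment = c(baseline, baseline + excess),
    is_baseline = c(TRUE, rep(FALSE, length(schedule)))
  )
  list(samples = samples, dose = dose)
}

#' Generate a bout-structured synthetic accelerometer stream
#'
#' Builds a 10-s triaxial count stream whose per-day class minutes and step
#' totals match the requested profile exactly. Each day is assembled from
#' 10-minute bouts assigned (in seeded random order) to MVPA, light or
#' sedentary time; per-minute axis counts are drawn inside ranges that
#' guarantee the class's vector-magnitude band (MVPA >= 2690, light
#' [200, 2690), sedentary < 200 with a 30% chance of an all-zero minute).
#' An optional non-wear block of exact zeros is inserted as one contiguous
#' run per day. Daily steps are split across active minutes (MVPA minutes
#' weighted 3x light) and minute counts are split evenly across the six
#' 10-s epochs, so reintegration recovers the minute values exactly.
#'
#' @param days number of days (>= 1).
#' @param profile list: \code{mvpa_min}, \code{light_min}, \code{steps}
#'   per day, optional \code{nonwear_min} (default 0) and
#'   \code{nonwear_start} (minute of day, default 60).
#' @param seed integer seed.
#' @param start_date first day (Date), default 2022-06-20.
#' @return list with \code{stream} (10-s epochs: timestamp, axis1-3, steps),
#'   \code{truth} (per-day class minutes and steps) and \code{minute_truth}
#'   (per-minute class and wear flags, for recovery checks).
#' @export
generate_accel_stream <- function(days, profile, seed = 1,
                                  start_date = as.Date("2022-06-20")) {
  stopifnot(days >= 1)
  mv <- profile$mvpa_min %||% 0
  lt <- profile$light_min %||% 0
  nw <- profile$nonwear_min %||% 0
  nw_start <- profile$nonwear_start %||% 60
  steps <- profile$steps %||% 0
  if (mv + lt + nw > 1440)
    stop("profile exceeds 1440 minutes/day (",
         mv, " MVPA + ", lt, " light + ", nw, " non-wear)")
  if (nw > 0 && nw_start + nw > 1440)
    stop("non-wear block extends past midnight")
  set.seed(as.integer(seed))

  day_list <- vector("list", days)
  minute_cls <- character(0); minute_wear <- logical(0)
  for (d in seq_len(days)) {
    cls <- rep("sedentary_nonwear", 1440)
    wear <- rep(TRUE, 1440)
    if (nw > 0) {
      idx <- nw_start + seq_len(nw) - 1L
      wear[idx] <- FALSE
    }
    free <- which(wear)  # assign activity outside the non-wear block
    # 10-minute bouts in random order
    bouts <- split(free, (seq_along(free) - 1L) %/% 10L)
    bouts <- bouts[sample(length(bouts))]
    quota <- c(mvpa = mv, light = lt)
    for (b in bouts) {
      if (quota["mvpa"] > 0) {
        take <- min(length(b), quota["mvpa"])
        cls[b[seq_len(take)]] <- "mvpa"
        quota["mvpa"] <- quota["mvpa"] - take
      } else if (quota["light"] > 0) {
        take <- min(length(b), quota["light"])
        cls[b[seq_len(take)]] <- "light"
        quota["light"] <- quota["light"] - take
      } else break
    }
    # per-minute axis counts inside the class's VM band
    ax <- matrix(0L, nrow = 1440, ncol = 3)
    i_mv <- which(cls == "mvpa"); i_lt <- which(cls == "light")
    i_sed <- which(cls == "sedentary_nonwear" & wear)
    if (length(i_mv)) {
      ax[i_mv, 1] <- sample(2800:6000, length(i_mv), replace = TRUE)
      ax[i_mv, 2] <- sample(500:2000, length(i_mv), replace = TRUE)
      ax[i_mv, 3] <- sample(500:2000, length(i_mv), replace = TRUE)
    }
    if (length(i_lt)) {
      ax[i_lt, 1] <- sample(400:1500, length(i_lt), replace = TRUE)
      ax[i_lt, 2] <- sample(0:600, length(i_lt), replace = TRUE)
      ax[i_lt, 3] <- sample(0:600, length(i_lt), replace = TRUE)
    }
    if (length(i_sed)) {
      nonzero <- stats::runif(length(i_sed)) > 0.3
      ax[i_sed[nonzero], 1] <- sample(1:120, sum(nonzero), replace = TRUE)
      ax[i_sed[nonzero], 2] <- sample(0:80, sum(nonzero), replace = TRUE)
      ax[i_sed[nonzero], 3] <- sample(0:80, sum(nonzero), replace = TRUE)
    }
    # exact integer step allocation: MVPA minutes weighted 3, light 1
    st <- integer(1440)
    w <- integer(1440); w[i_mv] <- 3L; w[i_lt] <- 1L
    if (steps > 0 && sum(w) > 0) {
      base <- floor(steps * w / sum(w))
      rem <- steps - sum(base)
      active <- which(w > 0)
      if (rem > 0) base[active[seq_len(rem)]] <- base[active[seq_len(rem)]] + 1L
      st <- base
    }
    day_list[[d]] <- list(ax = ax, st = st)
    minute_cls <- c(minute_cls, cls)
    minute_wear <- c(minute_wear, wear)
  }

  # expand minutes to six 10-s epochs with exact integer splits
  split6 <- function(v) {
    q <- v %/% 6L; r <- v %% 6L
    out <- matrix(q, nrow = length(v), ncol = 6)
    for (j in seq_len(5L)) out[r >= j, j] <- out[r >= j, j] + 1L
    as.integer(t(out))
  }
  ax_all <- do.call(rbind, lapply(day_list, `[[`, "ax"))
  st_all <- unlist(lapply(day_list, `[[`, "st"))
  stream <- data.frame(
    timestamp = as.POSIXct(start_date, tz = "UTC") +
      seq(0, by = 10, length.out = days * 8640),
    axis1 = split6(ax_all[, 1]),
    axis2 = split6(ax_all[, 2]),
    axis3 = split6(ax_all[, 3]),
    steps = split6(st_all)
  )
  truth <- data.frame(
    date = seq(start_date, by = "day", length.out = days),
    steps = steps,
    mvpa_min = mv, light_min = lt,
    sed_nonwear_min = 1440 - mv - lt,
    nonwear_min = nw
  )
  list(stream = stream,
       truth = truth,
       minute_truth = data.frame(
         class = factor(minute_cls,
                        c("sedentary_nonwear", "light", "mvpa")),
         wear = minute_wear))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
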