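# Seeded synthetic UGIB cohort generator. Two independent standard-normal
# latent axes drive everything: bleeding severity (vitals, labs, bleeding
# symptoms, need of intervention) and frailty (age, comorbidity, 30-day
# death). This crossed design is the minimal structure under which the
# hemodynamic/laboratory scores discriminate intervention while the
# age/comorbidity score discriminates mortality.

# Marginal prevalence of plogis(a + b * Z), Z standard normal
.logit_marginal <- function(a, b) {
  stats::integrate(function(z) stats::plogis(a + b * z) * stats::dnorm(z),
                   -8, 8, rel.tol = 1e-10)$value
}

# Intercept giving a target marginal prevalence for a fixed latent slope
solve_logit_intercept <- function(target, slope) {
  stats::uniroot(function(a) .logit_marginal(a, slope) - target,
                 c(-20, 20), tol = 1e-9)$root
}

#' Default synthetic-cohort specification
#'
#' Returns the generator configuration calibrated to the study cohort's
#' marginal frequencies: cohort size 590; female fraction 0.364; age
#' distribution with 49.3% aged 80 or over; flag prevalences melena 0.488,
#' syncope 0.034, hepatic disease 0.069, cardiac disease 0.571; intervention
#' prevalence 280/590; 30-day mortality 0.042. Logistic intercepts are solved
#' numerically against these targets given the latent slopes, so large-n
#' cohorts hit the marginals by construction. Vital-sign maps are monotone
#' linear (log-linear for BUN) links from the severity axis with Gaussian
#' noise, truncated to physiologic ranges (pulse 40-180 beats/min, SBP 60-220
#' mmHg, BUN 5-150 mg/dL, Hb 4-18 g/dL). Intervention loads on severity only;
#' death loads mainly on frailty, weakly on severity.
#'
#' @param n Cohort size (default 590, the study cohort).
#' @return A list of class `cohort_spec`; see [generate_cohort()].
#' @export
default_spec <- function(n = 590) {
  targets <- c(female = 0.364, age80 = 0.493, melena = 0.488,
               syncope = 0.034, hepatic_disease = 0.069,
               cardiac_failure = 0.571, intervention = 280 / 590,
               death30 = 0.042)
  flag_slopes <- c(melena = 0.6, syncope = 0.8, hepatic_disease = 0.5,
                   cardiac_failure = 0.8)
  flag_axis <- c(melena = "severity", syncope = "severity",
                 hepatic_disease = "severity", cardiac_failure = "frailty")
  flag_logits <- lapply(names(flag_slopes), function(f) {
    list(axis = flag_axis[[f]], slope = flag_slopes[[f]],
         intercept = solve_logit_intercept(targets[[f]], flag_slopes[[f]]))
  })
  names(flag_logits) <- names(flag_slopes)

  com_slope <- 1.2
  spec <- list(
    n = n,
    severity_sd = 1,
    frailty_sd = 1,
    female_p = targets[["female"]],
    # age = mu + sd * (loading * frailty + sqrt(1 - loading^2) * noise),
    # mu chosen so P(age >= 80) matches the target before truncation
    age_map = list(mu = 80 - stats::qnorm(1 - targets[["age80"]]) * 25,
                   sd = 25, loading = 0.8, range = c(18, 100)),
    vital_maps = list(
      pulse = list(base = 86, slope = 22, noise_sd = 13,
                   range = c(40, 180), log = FALSE, digits = 0),
      sbp = list(base = 112, slope = -20, noise_sd = 16,
                 range = c(60, 220), log = FALSE, digits = 0),
      bun_mg_dl = list(base = 3.42, slope = 0.55, noise_sd = 0.40,
                       range = c(5, 150), log = TRUE, digits = 1),
      hb_g_dl = list(base = 9.2, slope = -2.0, noise_sd = 1.5,
                     range = c(4, 18), log = FALSE, digits = 1)
    ),
    flag_logits = flag_logits,
    # proportional-odds comorbidity on the frailty axis:
    # P(major or severe), P(severe) marginals 0.334 / 0.084
    comorbidity_logits = list(
      slope = com_slope,
      t_major = -solve_logit_intercept(0.334, com_slope),
      t_severe = -solve_logit_intercept(0.084, com_slope)
    ),
    # endoscopy sooner for sicker patients; lognormal hours
    delay_map = list(meanlog = 2.2, slope = -0.4, sdlog = 0.8,
                     range = c(0.5, 120)),
    outcome_logits = list(
      intervention = list(
        slope_severity = 1.6, slope_frailty = 0,
        intercept = solve_logit_intercept(targets[["intervention"]], 1.6)
      ),
      death30 = list(
        slope_severity = 0.3, slope_frailty = 2.2,
        intercept = solve_logit_intercept(targets[["death30"]],
                                          sqrt(0.3^2 + 2.2^2))
      )
    ),
    marginal_targets = targets
  )
  class(spec) <- "cohort_spec"
  spec
}

validate_spec <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    stop("`spec` must be a cohort_spec (see default_spec())", call. = FALSE)
  }
  if (!is.numeric(spec$n) || spec$n < 2) {
    stop("cohort size n must be at least 2", call. = FALSE)
  }
  sds <- c(spec$severity_sd, spec$frailty_sd,
           vapply(spec$vital_maps, function(m) m$noise_sd, numeric(1)))
  if (any(sds <= 0)) stop("all spec standard deviations must be positive",
                          call. = FALSE)
  invisible(spec)
}

clamp <- function(x, range) pmin(pmax(x, range[1]), range[2])

# Run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic patient cohort
#'
#' Draws `spec$n` patient records from the two-latent-axis model described in
#' [default_spec()]. Deterministic given `(spec, seed)`; the caller's RNG
#' state is left untouched. Every record satisfies the patient-record
#' invariants (positive vitals/labs, age >= 18, valid factor levels), so the
#' output feeds directly into [score_patients()] and [score_cohort()]. The
#' latent axes are attached as `attr(, "latents")` (columns `severity`,
#' `frailty`) so generator calibration can be checked by re-fitting the
#' outcome models.
#'
#' @param spec A `cohort_spec`, e.g. [default_spec()].
#' @param seed Integer seed governing all draws.
#' @return A validated patient-record data frame in the flat CSV schema.
#' @export
generate_cohort <- function(spec = default_spec(), seed = 1L) {
  validate_spec(spec)
  n <- as.integer(spec$n)
  with_seed(seed, {
    severity <- stats::rnorm(n, 0, spec$severity_sd)
    frailty <- stats::rnorm(n, 0, spec$frailty_sd)

    sex <- ifelse(stats::runif(n) < spec$female_p, "female", "male")

    am <- spec$age_map
    age_lat <- am$loading * frailty +
      sqrt(1 - am$loading^2) * stats::rnorm(n)
    age <- round(clamp(am$mu + am$sd * age_lat, am$range))

    vital <- function(map) {
      x <- map$base + map$slope * severity + stats::rnorm(n, 0, map$noise_sd)
      if (map$log) x <- exp(x)
      round(clamp(x, map$range), map$digits)
    }
    pulse <- vital(spec$vital_maps$pulse)
    sbp <- vital(spec$vital_maps$sbp)
    bun <- vital(spec$vital_maps$bun_mg_dl)
    hb <- vital(spec$vital_maps$hb_g_dl)

    axes <- list(severity = severity, frailty = frailty)
    flag <- function(fl) {
      as.integer(stats::runif(n) < stats::plogis(fl$intercept +
                                                   fl$slope * axes[[fl$axis]]))
    }
    flags <- lapply(spec$flag_logits, flag)

    cl <- spec$comorbidity_logits
    u <- stats::runif(n)
    p_severe <- stats::plogis(cl$slope * frailty - cl$t_severe)
    p_major_up <- stats::plogis(cl$slope * frailty - cl$t_major)
    comorbidity <- ifelse(u < p_severe, "severe",
                          ifelse(u < p_major_up, "major", "none"))

    dm <- spec$delay_map
    delay <- round(clamp(stats::rlnorm(n, dm$meanlog + dm$slope * severity,
                                       dm$sdlog), dm$range), 1)

    outcome <- function(ol) {
      as.integer(stats::runif(n) < stats::plogis(
        ol$intercept + ol$slope_severity * severity +
          ol$slope_frailty * frailty))
    }

    records <- data.frame(
      age = age, sex = sex, pulse = pulse, sbp = sbp,
      bun_mg_dl = bun, hb_g_dl = hb,
      melena = flags$melena, syncope = flags$syncope,
      hepatic_disease = flags$hepatic_disease,
      cardiac_failure = flags$cardiac_failure,
      rockall_comorbidity = comorbidity,
      endoscopy_delay_h = delay,
      intervention = outcome(spec$outcome_logits$intervention),
      death30 = outcome(spec$outcome_logits$death30)
    )
    records <- validate_patients(records)
    attr(records, "latents") <- data.frame(severity = severity,
                                           frailty = frailty)
    records
  })
}
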