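#' Parameters of the synthetic cohort generator
#'
#' Marginal covariate distributions, length-of-stay model and safety-event
#' model used to simulate patient-level stepped-wedge trial data. Defaults
#' emulate a large unselected emergency-department population with suspected
#' acute coronary syndrome: mean age 59 (SD 17), 45% women, a log-normal
#' length of stay with geometric mean near 10 hours reduced multiplicatively
#' by the early rule-out pathway, and a rare binary safety endpoint with a
#' baseline rate of 0.4% and negligible between-site variability.
#'
#' @param age_mean,age_sd age distribution (years).
#' @param prop_female probability a patient is female.
#' @param simd_probs probabilities of deprivation quintiles 1-5 (sum to 1).
#' @param history_prevalences named prevalences for the ten history flags
#'   (prior ischaemic heart disease, myocardial infarction, cerebrovascular
#'   disease, diabetes, PCI, CABG, aspirin, lipid-lowering drugs, beta
#'   blockers, ACE inhibitors).
#' @param los_log_mean,los_log_sd location and scale of log length of stay
#'   (log hours).
#' @param los_intervention_multiplier multiplicative intervention effect on
#'   length of stay (a geometric mean ratio; < 1 shortens stay).
#' @param los_season_multipliers named multipliers for Winter, Spring,
#'   Summer, Autumn (Winter is the reference, 1).
#' @param los_secular_slope per-day change in log length of stay.
#' @param los_missing_frac fraction of records with missing length of stay.
#' @param safety_baseline_logit logit of the control-condition event
#'   probability at the enrolment midpoint for an average patient.
#' @param safety_site_sd SD of site random intercepts on the logit scale.
#'   Defaults to 0: in a trial of this kind between-cluster variability in a
#'   rare endpoint is effectively zero; raise it for stress tests.
#' @param safety_intervention_log_or log odds ratio of the intervention on
#'   the safety event (0 = null).
#' @param safety_secular_slope per-day change in the event logit.
#' @param safety_age_log_or log odds ratio per year of age (centred at
#'   `age_mean`); nonzero values make age an outcome predictor so that
#'   covariate-adjustment methods have something to correct.
#' @param confounding_drift per-day drift in the mean age (years/day);
#'   combined with `safety_age_log_or` this induces time-varying
#'   confounding of the intervention effect.
#' @param site_weights relative site sizes (default equal).
#' @return a list of class `sw_cohort_params`.
#' @export
sw_cohort_params <- function(age_mean = 59, age_sd = 17,
                             prop_female = 0.45,
                             simd_probs = rep(0.2, 5),
                             history_prevalences = c(
                               hx_ihd = 0.15, hx_mi = 0.08, hx_cvd = 0.05,
                               hx_diabetes = 0.12, hx_pci = 0.05, hx_cabg = 0.03,
                               hx_aspirin = 0.20, hx_lipid = 0.25,
                               hx_betablocker = 0.18, hx_acei = 0.15),
                             los_log_mean = log(10.1), los_log_sd = 1.0,
                             los_intervention_multiplier = 0.78,
                             los_season_multipliers = c(Winter = 1, Spring = 0.97,
                                                        Summer = 0.95, Autumn = 0.97),
                             los_secular_slope = log(0.9) / 730,
                             los_missing_frac = 0,
                             safety_baseline_logit = stats::qlogis(0.004),
                             safety_site_sd = 0,
                             safety_intervention_log_or = 0,
                             safety_secular_slope = 0,
                             safety_age_log_or = 0,
                             confounding_drift = 0,
                             site_weights = rep(1, 7)) {
  p <- list(age_mean = age_mean, age_sd = age_sd, prop_female = prop_female,
            simd_probs = simd_probs, history_prevalences = history_prevalences,
            los_log_mean = los_log_mean, los_log_sd = los_log_sd,
            los_intervention_multiplier = los_intervention_multiplier,
            los_season_multipliers = los_season_multipliers,
            los_secular_slope = los_secular_slope,
            los_missing_frac = los_missing_frac,
            safety_baseline_logit = safety_baseline_logit,
            safety_site_sd = safety_site_sd,
            safety_intervention_log_or = safety_intervention_log_or,
            safety_secular_slope = safety_secular_slope,
            safety_age_log_or = safety_age_log_or,
            confounding_drift = confounding_drift,
            site_weights = site_weights)
  probs <- c(p$prop_female, p$simd_probs, p$history_prevalences, p$los_missing_frac)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (abs(sum(p$simd_probs) - 1) > 1e-8)
    stop("simd_probs must sum to 1", call. = FALSE)
  if (p$los_log_sd <= 0) stop("los_log_sd must be positive", call. = FALSE)
  if (p$safety_site_sd < 0) stop("safety_site_sd must be non-negative", call. = FALSE)
  if (length(p$history_prevalences) != 10L)
    stop("history_prevalences must have 10 entries", call. = FALSE)
  names(p$history_prevalences) <- hx_cols
  class(p) <- "sw_cohort_params"
  p
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  expr
}

# covariates + LOS + (optionally) safety outcomes for records at given
# site/day; the outcome models mirror the documented generator structure
fill_parametric <- function(site, day, design, params, timing = "actual",
                            site_u = NULL, draw_safety = TRUE) {
  n <- length(day)
  mid <- (design$study_start_day + design$study_end_day) / 2
  age <- stats::rnorm(n, params$age_mean + params$confounding_drift * (day - mid),
                      params$age_sd)
  sex <- stats::rbinom(n, 1L, params$prop_female)
  simd <- sample(1:5, n, replace = TRUE, prob = params$simd_probs)
  hx <- vapply(params$history_prevalences,
               function(pr) stats::rbinom(n, 1L, pr), integer(n))
  if (n == 1L) hx <- matrix(hx, nrow = 1L, dimnames = list(NULL, hx_cols))
  cross <- crossover_days(design, timing)[as.character(site)]
  interv <- as.integer(day >= cross)
  season <- season_of(as.POSIXlt(day_to_date(day, design))$mon + 1L)
  los_mu <- params$los_log_mean +
    log(params$los_intervention_multiplier) * interv +
    log(params$los_season_multipliers)[as.integer(season)] +
    params$los_secular_slope * day
  los <- exp(stats::rnorm(n, los_mu, params$los_log_sd))
  if (params$los_missing_frac > 0)
    los[stats::runif(n) < params$los_missing_frac] <- NA_real_
  out <- data.frame(site = as.character(site), day = as.integer(day),
                    age = age, sex = sex, simd = simd,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(hx))
  out$los_hours <- los
  if (draw_safety) {
    if (is.null(site_u)) site_u <- stats::setNames(rep(0, 7), design$site_ids)
    logit <- params$safety_baseline_logit +
      site_u[as.character(site)] +
      params$safety_secular_slope * day +
      params$safety_intervention_log_or * interv +
      params$safety_age_log_or * (age - params$age_mean)
    out$safety_event <- stats::rbinom(n, 1L, stats::plogis(unname(logit)))
  } else {
    out$safety_event <- 0L
  }
  out$synthetic <- 0L
  out
}

#' Generate a parametric synthetic trial cohort
#'
#' Simulates `n` presentations with continuous (uniform) recruitment over
#' the study window, covariates drawn from the marginals in `params`,
#' log-normal length of stay with multiplicative intervention, season and
#' secular effects, and a Bernoulli safety event on the logit scale with
#' site random intercepts, a secular slope and an intervention log odds
#' ratio. Fixed seed gives byte-identical output.
#'
#' @param design an [sw_design].
#' @param params an [sw_cohort_params].
#' @param n number of presentations.
#' @param seed integer seed.
#' @param timing whether outcomes respond to the actual or planned
#'   crossover dates.
#' @return data frame in the standard trial-data schema.
#' @export
generate_parametric <- function(design, params = sw_cohort_params(), n,
                                seed = NULL, timing = "actual") {
  stopifnot(n > 0)
  with_seed(seed, {
    site <- sample(design$site_ids, n, replace = TRUE,
                   prob = params$site_weights)
    day <- sample(seq(design$study_start_day, design$study_end_day), n,
                  replace = TRUE)
    site_u <- stats::setNames(
      stats::rnorm(7, 0, params$safety_site_sd), design$site_ids)
    fill_parametric(site, day, design, params, timing, site_u)
  })
}

#' Published phase-level count margins for the replica generator
#'
#' The count identities the replica mode reproduces exactly: per-phase
#' denominators and safety-event totals, and the split of the
#' randomisation phase by condition. Defaults are the margins of the
#' 31,492-patient trial the package emulates (113 events overall).
#'
#' @param phase_denoms named integer vector of presentations per phase.
#' @param phase_events named integer vector of safety events per phase.
#' @param rand_intervention,rand_control events and denominators of the
#'   randomisation phase by condition, as `c(events =, n =)`.
#' @param spike optional `list(site =, month =, events =)` placing a single
#'   high-count cluster period in the randomisation phase (see
#'   [default_spike]).
#' @return a list of class `sw_replica_counts`.
#' @export
sw_replica_counts <- function(phase_denoms = c(validation = 10724L,
                                               randomisation = 9336L,
                                               implementation = 11432L),
                              phase_events = c(validation = 49L,
                                               randomisation = 37L,
                                               implementation = 27L),
                              rand_intervention = c(events = 29L, n = 5248L),
                              rand_control = c(events = 8L, n = 4088L),
                              spike = NULL) {
  x <- list(phase_denoms = phase_denoms, phase_events = phase_events,
            rand_intervention = rand_intervention, rand_control = rand_control,
            spike = spike)
  if (rand_intervention[["n"]] + rand_control[["n"]] !=
      phase_denoms[["randomisation"]])
    stop("inconsistent counts: rand_intervention n + rand_control n != randomisation denominator",
         call. = FALSE)
  if (rand_intervention[["events"]] + rand_control[["events"]] !=
      phase_events[["randomisation"]])
    stop("inconsistent counts: rand_intervention events + rand_control events != randomisation events",
         call. = FALSE)
  if (any(phase_events > phase_denoms))
    stop("inconsistent counts: events exceed denominators", call. = FALSE)
  if (!is.null(spike) && spike$events > rand_intervention[["events"]])
    stop("inconsistent counts: spike events exceed randomisation-phase intervention events",
         call. = FALSE)
  class(x) <- "sw_replica_counts"
  x
}

#' Default spiked cluster period
#'
#' The first full calendar month after the earliest actual crossover, at
#' the earliest-crossing site: the cluster period nearest a treatment
#' switch, where event-rate anomalies are most influential.
#'
#' @param design an [sw_design].
#' @param events event count for the cell (default 7).
#' @return `list(site, month, events)`.
#' @export
default_spike <- function(design, events = 7L) {
  s <- which.min(design$actual_crossover_day)
  list(site = design$site_ids[s],
       month = month_index(design$actual_crossover_day[s], design) + 1L,
       events = as.integer(events))
}

# largest-remainder apportionment of n into weights w (integer, sums to n)
apportion <- function(n, w) {
  q <- n * w / sum(w)
  k <- floor(q)
  r <- n - sum(k)
  if (r > 0) {
    o <- order(q - k, decreasing = TRUE)
    k[o[seq_len(r)]] <- k[o[seq_len(r)]] + 1
  }
  as.integer(k)
}

#' Generate a replica cohort reproducing printed count margins exactly
#'
#' Builds a patient-level dataset whose phase denominators, phase event
#' totals and randomisation-phase condition split match `counts` exactly.
#' Within each phase, records are spread over sites in proportion to the
#' time each site spends in the relevant condition (so every site
#' contributes to both sides of the randomisation phase according to its
#' crossover date) and presentation days are uniform within the allowed
#' interval; events are then assigned to records by seeded simple random
#' sampling, which induces a multinomial allocation of events over
#' cluster periods proportional to their denominators. If a spike is
#' configured, that site-month cell receives exactly `spike$events` of the
#' randomisation-phase intervention events. Covariates and length of stay
#' are filled parametrically from `params`. Conditions follow the actual
#' crossover days.
#'
#' @inheritParams generate_parametric
#' @param counts an [sw_replica_counts].
#' @return data frame in the standard trial-data schema.
#' @export
generate_replica <- function(design, counts = sw_replica_counts(),
                             params = sw_cohort_params(), seed = NULL) {
  cross <- crossover_days(design, "actual")
  vend <- design$validation_end_day
  rend <- design$randomisation_end_day
  with_seed(seed, {
    draw_days <- function(n_total, site_weights, lo, hi) {
      # lo/hi per site, half-open [lo, hi); returns site + day vectors
      per_site <- apportion(n_total, site_weights)
      site <- rep(design$site_ids, per_site)
      day <- unlist(lapply(seq_len(7), function(s) {
        if (per_site[s] == 0L) return(integer(0))
        days <- seq(lo[s], hi[s] - 1L)
        days[sample.int(length(days), per_site[s], replace = TRUE)]
      }))
      list(site = site, day = as.integer(day))
    }
    w <- params$site_weights
    val <- draw_days(counts$phase_denoms[["validation"]], w,
                     rep(design$study_start_day, 7), rep(vend, 7))
    imp <- draw_days(counts$phase_denoms[["implementation"]], w,
                     rep(rend, 7), rep(design$study_end_day + 1L, 7))
    # randomisation phase: control records live in [vend, crossover),
    # intervention records in [crossover, rend); site allocation follows
    # interval length (x site size) so empty intervals get no records
    ctl <- draw_days(counts$rand_control[["n"]], w * (cross - vend),
                     rep(vend, 7), cross)
    int <- draw_days(counts$rand_intervention[["n"]], w * (rend - cross),
                     cross, rep(rend, 7))
    rec <- fill_parametric(c(val$site, ctl$site, int$site, imp$site),
                           c(val$day, ctl$day, int$day, imp$day),
                           design, params, draw_safety = FALSE)
    nv <- length(val$day); nc <- length(ctl$day); ni <- length(int$day)
    idx_val <- seq_len(nv)
    idx_ctl <- nv + seq_len(nc)
    idx_int <- nv + nc + seq_len(ni)
    idx_imp <- nv + nc + ni + seq_len(length(imp$day))
    ev <- integer(nrow(rec))
    ev[sample(idx_val, counts$phase_events[["validation"]])] <- 1L
    ev[sample(idx_ctl, counts$rand_control[["events"]])] <- 1L
    ev[sample(idx_imp, counts$phase_events[["implementation"]])] <- 1L
    n_int_ev <- counts$rand_intervention[["events"]]
    if (!is.null(counts$spike)) {
      sp <- counts$spike
      cell <- idx_int[rec$site[idx_int] == sp$site &
                        month_index(rec$day[idx_int], design) == sp$month]
      if (length(cell) < sp$events)
        stop("spike cell has fewer records (", length(cell),
             ") than requested events (", sp$events, ")", call. = FALSE)
      ev[sample(cell, sp$events)] <- 1L
      rest <- setdiff(idx_int, cell)
      ev[sample(rest, n_int_ev - sp$events)] <- 1L
    } else {
      ev[sample(idx_int, n_int_ev)] <- 1L
    }
    rec$safety_event <- ev
    rownames(rec) <- NULL
    rec
  })
}

#' Set the event count of one cluster period (spike injection)
#'
#' Relabels `safety_event` within a single site-by-month cell so that the
#' cell carries exactly `target_events` events; all other cells are
#' untouched. Used to create or remove a localised event-rate spike.
#'
#' @inheritParams generate_parametric
#' @param data trial data frame.
#' @param site,month cluster-period address (calendar month index since
#'   study start, as in [tabulate_cluster_periods]).
#' @param target_events desired event count for the cell.
#' @return the modified data frame.
#' @export
inject_spike <- function(data, design, site, month, target_events, seed = NULL) {
  set_cluster_period_events(data, design, site, month, target_events, seed)
}
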