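#' Scenario for simulating MORS event logs with known ground truth
#'
#' The generator emulates what a set of monitoring services would record
#' over an observation period: per-service emergency event counts (Poisson
#' around the stated rates), repeat use by the same clients, a fraction of
#' false-alarm callouts, and — the part no real service can observe — a
#' latent counterfactual fatality flag per true emergency, set with the
#' scenario's true fatality rate. The flagged events are the ground-truth
#' deaths averted that the estimator is later asked to recover.
#'
#' Defaults mirror the observed North American service table: event rates
#' equal to the seven strictly positive known counts (sum 299), the true
#' rate re-drawn from the fatality-rate model each replicate, moderate
#' repeat-client concentration and a 20% false-alarm fraction.
#'
#' @param event_rates Positive per-service expected emergency-response
#'   counts (named or not).
#' @param true_fatality_rate A probability, or `"random"` to draw the rate
#'   once per simulated cohort from the fatality-rate model.
#' @param repeat_client_dispersion Non-negative real; 0 gives every event a
#'   distinct client, larger values concentrate events on fewer clients
#'   (size-biased assignment).
#' @param false_callout_fraction Expected fraction of logged events that
#'   are false alarms (never counterfactually fatal), in `[0, 1)`.
#' @param seed Integer seed.
#' @return An object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(event_rates = NULL,
                                true_fatality_rate = "random",
                                repeat_client_dispersion = 0.5,
                                false_callout_fraction = 0.2,
                                seed = 2023) {
  if (is.null(event_rates)) {
    counts <- known_counts(mors_table1())
    event_rates <- stats::setNames(counts$n_events, counts$name)
    event_rates <- event_rates[event_rates > 0]
  }
  if (!is.numeric(event_rates) || length(event_rates) < 1 ||
      anyNA(event_rates) || any(event_rates <= 0)) {
    abort_validation("`event_rates` must be positive numbers (at least one service).")
  }
  if (is.null(names(event_rates))) {
    names(event_rates) <- paste0("service_", seq_along(event_rates))
  }
  if (!identical(true_fatality_rate, "random")) {
    if (!is.numeric(true_fatality_rate) || length(true_fatality_rate) != 1 ||
        is.na(true_fatality_rate) || true_fatality_rate < 0 || true_fatality_rate > 1) {
      abort_validation("`true_fatality_rate` must be \"random\" or a probability in [0, 1].")
    }
  }
  if (!is.numeric(repeat_client_dispersion) || length(repeat_client_dispersion) != 1 ||
      is.na(repeat_client_dispersion) || repeat_client_dispersion < 0) {
    abort_validation("`repeat_client_dispersion` must be a single non-negative number.")
  }
  if (!is.numeric(false_callout_fraction) || length(false_callout_fraction) != 1 ||
      is.na(false_callout_fraction) || false_callout_fraction < 0 ||
      false_callout_fraction >= 1) {
    abort_validation("`false_callout_fraction` must lie in [0, 1).")
  }
  structure(
    list(
      event_rates = event_rates,
      n_services = length(event_rates),
      true_fatality_rate = true_fatality_rate,
      repeat_client_dispersion = repeat_client_dispersion,
      false_callout_fraction = false_callout_fraction,
      seed = as.integer(seed)
    ),
    class = "simulation_scenario"
  )
}

#' @export
print.simulation_scenario <- function(x, ...) {
  cat(sprintf(
    "<simulation_scenario> %d services (total rate %g), true rate %s, dispersion %g, false-callout fraction %g, seed %d\n",
    x$n_services, sum(x$event_rates),
    if (identical(x$true_fatality_rate, "random")) "drawn from model" else format(x$true_fatality_rate),
    x$repeat_client_dispersion, x$false_callout_fraction, x$seed
  ))
  invisible(x)
}

# events allocated to clients sequentially: event i starts a new client with
# probability 1 / (1 + d * (i - 1)), otherwise joins an existing client with
# probability proportional to the client's current event count (size-biased);
# d = 0 makes every event its own client
assign_clients <- function(n_events, dispersion) {
  if (n_events == 0) return(character(0))
  ids <- integer(n_events)
  counts <- integer(0)
  for (i in seq_len(n_events)) {
    if (i == 1 || stats::runif(1) < 1 / (1 + dispersion * (i - 1))) {
      counts <- c(counts, 1L)
      ids[i] <- length(counts)
    } else {
      j <- sample.int(length(counts), 1, prob = counts)
      counts[j] <- counts[j] + 1L
      ids[i] <- j
    }
  }
  ids
}

#' Simulate one cohort of MORS events with latent counterfactual outcomes
#'
#' Per service, the number of true emergencies is Poisson with the
#' scenario's rate and the number of false-alarm callouts Poisson with mean
#' `rate * f / (1 - f)` (so false alarms are an `f` fraction of the log in
#' expectation). Each true emergency is counterfactually fatal with the
#' scenario's true fatality rate, independently; false alarms never are.
#' Events are assigned to clients with the scenario's dispersion. All
#' true-event and fatality draws precede the false-alarm draws so the
#' ground truth is unchanged by the false-callout fraction under a shared
#' seed.
#'
#' @param scenario A [simulation_scenario()].
#' @param model A [fatality_rate_model()], used when
#'   `true_fatality_rate = "random"`.
#' @return An object of class `synthetic_cohort`: an `events` tibble
#'   (`service`, `client_id`, `is_true_emergency`, `counterfactual_fatal`),
#'   per-service `observed_counts` (true emergencies only, what a real
#'   service would report), `true_averted`, `true_unique_lives`, and the
#'   `true_rate` used.
#' @export
#' @examples
#' cohort <- simulate_cohort(simulation_scenario(seed = 7))
#' cohort$true_averted
simulate_cohort <- function(scenario, model = fatality_rate_model()) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  check_model(model)
  rates <- scenario$event_rates
  f <- scenario$false_callout_fraction

  withr::with_seed(scenario$seed, {
    rate <- if (identical(scenario$true_fatality_rate, "random")) {
      stats::runif(1, model$lower, model$upper)
    } else {
      scenario$true_fatality_rate
    }
    n_true <- stats::rpois(length(rates), rates)
    fatal <- lapply(n_true, function(m) stats::rbinom(m, 1, rate) == 1)
    n_false <- if (f > 0) {
      stats::rpois(length(rates), rates * f / (1 - f))
    } else {
      integer(length(rates))
    }
    events <- lapply(seq_along(rates), function(s) {
      m <- n_true[s] + n_false[s]
      clients <- assign_clients(m, scenario$repeat_client_dispersion)
      # true emergencies and false alarms interleaved in log order
      is_true <- rep(FALSE, m)
      if (m > 0 && n_true[s] > 0) {
        is_true[sample.int(m, n_true[s])] <- TRUE
      }
      cf <- rep(FALSE, m)
      cf[is_true] <- fatal[[s]]
      tibble::tibble(
        service = names(rates)[s],
        client_id = if (m > 0) sprintf("%s_c%03d", names(rates)[s], clients) else character(0),
        is_true_emergency = is_true,
        counterfactual_fatal = cf
      )
    })
  })
  events <- dplyr::bind_rows(events)

  observed <- stats::setNames(n_true, names(rates))
  fatal_events <- events[events$counterfactual_fatal, ]
  structure(
    list(
      events = events,
      observed_counts = observed,
      true_averted = nrow(fatal_events),
      true_unique_lives = length(unique(fatal_events$client_id)),
      true_rate = rate,
      scenario = scenario
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d events across %d services (%d true emergencies); true rate %.3f, %d deaths averted among %d unique clients\n",
    nrow(x$events), length(x$observed_counts), sum(x$observed_counts),
    x$true_rate, x$true_averted, x$true_unique_lives
  ))
  invisible(x)
}

#' Overstatement fraction when events are equated with lives
#'
#' Services report events, but repeat clients mean events overstate unique
#' lives saved. For a simulated cohort, returns
#' `1 - true_unique_lives / true_averted`: the fraction by which "deaths
#' averted" overstates "unique lives saved".
#'
#' @param cohort A [simulate_cohort()] result.
#' @return A value in `[0, 1]`; 0 when every counterfactually fatal event
#'   belongs to a distinct client.
#' @export
uniqueness_gap <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (cohort$true_averted == 0) {
    abort_domain("`true_averted` is zero; the uniqueness gap is undefined.")
  }
  1 - cohort$true_unique_lives / cohort$true_averted
}

#' Interval-coverage and bias experiment for the averted-death estimator
#'
#' Repeatedly simulates a cohort, runs the Monte Carlo estimator on the
#' observed per-service counts, and records whether the credible interval
#' contains the cohort's true number of deaths averted. With the true rate
#' re-drawn from the fatality-rate model each replicate (the regime in
#' which the interval has a calibration claim), empirical coverage should
#' sit near the nominal mass. The report also tracks
#' `point / total observed events`, whose mean converges to the model's
#' mean rate — not to any fixed true rate — quantifying that the estimator
#' propagates assumed uncertainty rather than learning the rate from data.
#'
#' @param scenario A [simulation_scenario()]; replicate `i` uses seed
#'   `scenario$seed + i`.
#' @param config An [estimation_config()].
#' @param model A [fatality_rate_model()].
#' @param n_replicates Number of simulated cohorts (>= 1).
#' @return An object of class `coverage_report`: `coverage`, a 95%
#'   binomial confidence interval on it (exact, Clopper-Pearson),
#'   `mean_point_over_events`, and the per-replicate tibble.
#' @export
#' @examples
#' coverage_experiment(simulation_scenario(seed = 1), n_replicates = 20,
#'                     config = estimation_config(n_draws = 2000))
coverage_experiment <- function(scenario, config = estimation_config(),
                                model = fatality_rate_model(),
                                n_replicates) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  if (!is.numeric(n_replicates) || length(n_replicates) != 1 || n_replicates < 1) {
    abort_domain("`n_replicates` must be a single integer >= 1.")
  }
  reps <- lapply(seq_len(n_replicates), function(i) {
    sc <- scenario
    sc$seed <- scenario$seed + i
    cohort <- simulate_cohort(sc, model)
    obs <- cohort$observed_counts[cohort$observed_counts > 0]
    if (length(obs) == 0) {
      # no recorded emergencies: the only honest estimate is zero
      covered <- cohort$true_averted == 0
      return(tibble::tibble(
        replicate = i, true_rate = cohort$true_rate, total_events = 0,
        true_averted = cohort$true_averted, point = 0,
        ci_lower = 0, ci_upper = 0, covered = covered,
        point_over_events = NA_real_
      ))
    }
    cfg <- config
    cfg$seed <- config$seed + i
    mc <- mc_estimate(obs, config = cfg, model = model)
    tibble::tibble(
      replicate = i, true_rate = cohort$true_rate,
      total_events = sum(cohort$observed_counts),
      true_averted = cohort$true_averted,
      point = mc$total$point, ci_lower = mc$total$ci_lower,
      ci_upper = mc$total$ci_upper,
      covered = mc$total$ci_lower <= cohort$true_averted &
        cohort$true_averted <= mc$total$ci_upper,
      point_over_events = mc$total$point / sum(cohort$observed_counts)
    )
  })
  reps <- dplyr::bind_rows(reps)
  n_cov <- sum(reps$covered)
  ci <- as.numeric(stats::binom.test(n_cov, n_replicates)$conf.int)
  structure(
    list(
      coverage = n_cov / n_replicates,
      coverage_ci = ci,
      nominal = config$interval_mass,
      n_replicates = n_replicates,
      mean_point_over_events = mean(reps$point_over_events, na.rm = TRUE),
      prior_mean_rate = (model$lower + model$upper) / 2,
      replicates = reps
    ),
    class = "coverage_report"
  )
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf(
    "<coverage_report> %d replicates: empirical coverage %.3f (95%% CI %.3f-%.3f) at nominal %.2f; mean point/events %.3f (model mean rate %.3f)\n",
    x$n_replicates, x$coverage, x$coverage_ci[1], x$coverage_ci[2],
    x$nominal, x$mean_point_over_events, x$prior_mean_rate
  ))
  invisible(x)
}
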