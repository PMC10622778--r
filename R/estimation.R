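#' Configuration of the Monte Carlo estimator
#'
#' @param n_draws Number of fatality-rate draws per estimate (default
#'   10,000).
#' @param seed Integer seed for the draws (default 2023; an arbitrary,
#'   documented constant so that default runs are reproducible).
#' @param draw_mode `"shared"` (default): each iteration draws one fatality
#'   rate applied to every service, so per-service and total estimates are
#'   comonotone and the total credible interval equals the pooled count
#'   times the rate quantiles. `"independent"`: one rate per service per
#'   iteration; the total interval is narrower because independent rate
#'   errors partially cancel.
#' @param interval_mass Mass of the equal-tailed credible interval
#'   (default 0.95).
#' @param range_rounding Rounding policy for deterministic endpoint ranges
#'   (default `"ceiling"`).
#' @param mc_rounding Rounding policy for Monte Carlo point estimates and
#'   interval bounds (default `"nearest"`, half away from zero).
#' @param sampler Rate sampler passed to [draw_rates()] (default
#'   `"systematic"`).
#' @return An object of class `estimation_config`.
#' @export
estimation_config <- function(n_draws = 10000, seed = 2023,
                              draw_mode = c("shared", "independent"),
                              interval_mass = 0.95,
                              range_rounding = "ceiling",
                              mc_rounding = "nearest",
                              sampler = c("systematic", "stratified", "iid")) {
  draw_mode <- match.arg(draw_mode)
  sampler <- match.arg(sampler)
  range_rounding <- match.arg(range_rounding, rounding_policies)
  mc_rounding <- match.arg(mc_rounding, rounding_policies)
  if (!is.numeric(n_draws) || length(n_draws) != 1 || n_draws < 1 ||
      n_draws != trunc(n_draws)) {
    abort_domain("`n_draws` must be a single integer >= 1.")
  }
  if (!is.numeric(interval_mass) || length(interval_mass) != 1 ||
      interval_mass <= 0 || interval_mass >= 1) {
    abort_domain("`interval_mass` must lie strictly between 0 and 1.")
  }
  structure(
    list(
      n_draws = as.integer(n_draws), seed = as.integer(seed),
      draw_mode = draw_mode, interval_mass = interval_mass,
      range_rounding = range_rounding, mc_rounding = mc_rounding,
      sampler = sampler
    ),
    class = "estimation_config"
  )
}

#' @export
print.estimation_config <- function(x, ...) {
  cat(sprintf(
    "<estimation_config> %d draws, seed %d, %s mode, %g%% interval, sampler %s\n",
    x$n_draws, x$seed, x$draw_mode, 100 * x$interval_mass, x$sampler
  ))
  invisible(x)
}

#' Deterministic averted-death range at the fatality-rate endpoints
#'
#' Evaluates `deaths = n_events * rate` at the two endpoints of the
#' fatality-rate model. With the default ceiling policy a fraction of a
#' death counts as one more potential death averted, which is how the
#' published per-service ranges are tabulated (e.g. 33 events give
#' `ceiling(3.3) = 4` to `ceiling(26.4) = 27`).
#'
#' @param n_events Known non-negative integer event count. Unknown (`NA`)
#'   counts are an error: filter with [known_counts()] first.
#' @param model A [fatality_rate_model()].
#' @param rounding `"ceiling"` (default), `"nearest"`, or `"none"`.
#' @return An object of class `mors_range` with fields `lower`, `upper`,
#'   `rounding`.
#' @export
#' @examples
#' range_estimate(77) # 8 to 62
range_estimate <- function(n_events, model = fatality_rate_model(),
                           rounding = c("ceiling", "nearest", "none")) {
  check_model(model)
  rounding <- match.arg(rounding)
  if (length(n_events) != 1 || is.na(n_events)) {
    abort_unknown_count(
      "`n_events` is unknown; drop unknown-count services with known_counts() before estimating."
    )
  }
  n_events <- check_count_scalar(n_events, "n_events")
  new_range(
    apply_rounding(n_events * model$lower, rounding),
    apply_rounding(n_events * model$upper, rounding),
    rounding
  )
}

new_range <- function(lower, upper, rounding) {
  stopifnot(lower <= upper, lower >= 0)
  structure(list(lower = lower, upper = upper, rounding = rounding),
            class = "mors_range")
}

#' @export
print.mors_range <- function(x, ...) {
  cat(sprintf("<mors_range> %g to %g deaths averted (%s rounding)\n",
              x$lower, x$upper, x$rounding))
  invisible(x)
}

#' Monte Carlo estimate of deaths averted, per service and in total
#'
#' Propagates the fatality-rate uncertainty through
#' `deaths = n_events * rate`: for each of `n_draws` iterations a rate is
#' drawn from `model` and multiplied by every service count and by their
#' sum. Point estimates are the rounded means of the draws; credible
#' intervals are rounded equal-tailed percentile intervals
#' (midpoint-interpolated order statistics, quantile type 5).
#'
#' In the default `"shared"` draw mode one rate per iteration drives all
#' services, so the total's draws are exactly the sum of the per-service
#' draws and its interval equals the pooled count times the rate quantiles.
#'
#' @param counts A tibble with columns `name` and `n_events` (as returned
#'   by [known_counts()]), or a named numeric vector of known counts.
#' @param config An [estimation_config()].
#' @param model A [fatality_rate_model()].
#' @param keep_draws Keep the draw matrix in the result (for diagnostics).
#' @return An object of class `mc_estimate`: tibbles `per_service` and
#'   `total` with rounded (`point`, `ci_lower`, `ci_upper`) and raw
#'   (`raw_mean`, `raw_lower`, `raw_upper`) fields, plus provenance
#'   (`n_draws`, `seed`, `draw_mode`, `sampler`, `interval_mass`).
#' @export
#' @examples
#' mc_estimate(known_counts(mors_table1()))
mc_estimate <- function(counts, config = estimation_config(),
                        model = fatality_rate_model(), keep_draws = FALSE) {
  check_model(model)
  stopifnot(inherits(config, "estimation_config"))
  counts <- as_counts(counts)
  n <- counts$n_events

  if (config$draw_mode == "shared") {
    r <- draw_rate_matrix(model, config$n_draws, 1L, config$seed, config$sampler)[, 1]
    draws <- outer(r, n)
  } else {
    rmat <- draw_rate_matrix(model, config$n_draws, length(n), config$seed, config$sampler)
    draws <- sweep(rmat, 2, n, `*`)
  }
  total_draws <- if (length(n) == 1) draws[, 1] else rowSums(draws)

  probs <- c((1 - config$interval_mass) / 2, 1 - (1 - config$interval_mass) / 2)
  summarise_draws <- function(x) {
    qs <- unname(stats::quantile(x, probs = probs, type = 5, names = FALSE))
    raw <- c(mean(x), qs)
    rounded <- apply_rounding(raw, config$mc_rounding)
    tibble::tibble(
      point = rounded[1], ci_lower = rounded[2], ci_upper = rounded[3],
      raw_mean = raw[1], raw_lower = raw[2], raw_upper = raw[3]
    )
  }

  per_service <- dplyr::bind_cols(
    counts,
    dplyr::bind_rows(lapply(seq_along(n), function(j) summarise_draws(draws[, j])))
  )
  total <- dplyr::bind_cols(
    tibble::tibble(name = "TOTAL", n_events = sum(n)),
    summarise_draws(total_draws)
  )

  out <- structure(
    list(
      per_service = per_service, total = total,
      n_draws = config$n_draws, seed = config$seed,
      draw_mode = config$draw_mode, sampler = config$sampler,
      interval_mass = config$interval_mass, mc_rounding = config$mc_rounding
    ),
    class = "mc_estimate"
  )
  if (keep_draws) {
    out$draws <- draws
    out$total_draws <- total_draws
  }
  stopifnot(
    all(per_service$ci_lower <= per_service$point),
    all(per_service$point <= per_service$ci_upper),
    total$ci_lower <= total$point, total$point <= total$ci_upper
  )
  out
}

as_counts <- function(counts) {
  if (is.numeric(counts)) {
    nm <- names(counts)
    if (is.null(nm)) nm <- paste0("service_", seq_along(counts))
    counts <- tibble::tibble(name = nm, n_events = as.numeric(counts))
  } else if (is.data.frame(counts)) {
    if (!all(c("name", "n_events") %in% names(counts))) {
      abort_schema("`counts` needs columns `name` and `n_events`.")
    }
    counts <- tibble::tibble(
      name = as.character(counts$name),
      n_events = as.numeric(counts$n_events)
    )
  } else {
    abort_schema("`counts` must be a data frame or a numeric vector.")
  }
  if (nrow(counts) == 0) {
    abort_domain("`counts` is empty; nothing to estimate.")
  }
  if (anyNA(counts$n_events)) {
    abort_unknown_count(sprintf(
      "Unknown counts present (%s); select known counts with known_counts() first.",
      paste(counts$name[is.na(counts$n_events)], collapse = ", ")
    ))
  }
  bad <- counts$n_events < 0 | counts$n_events != trunc(counts$n_events)
  if (any(bad)) {
    abort_validation(sprintf(
      "Event counts must be non-negative integers; offending record(s): %s.",
      paste(counts$name[bad], collapse = ", ")
    ))
  }
  counts
}

#' @export
print.mc_estimate <- function(x, ...) {
  cat(sprintf(
    "<mc_estimate> %d draws (%s, %s sampler, seed %d), %g%% equal-tailed interval\n",
    x$n_draws, x$draw_mode, x$sampler, x$seed, 100 * x$interval_mass
  ))
  shown <- dplyr::bind_rows(x$per_service, x$total)
  cat(paste0(
    sprintf("  %-18s %8s  %s\n", "service", "events", "averted [interval]"),
    paste(sprintf(
      "  %-18s %8d  %d [%d, %d]", shown$name, as.integer(shown$n_events),
      as.integer(shown$point), as.integer(shown$ci_lower), as.integer(shown$ci_upper)
    ), collapse = "\n"), "\n"
  ))
  invisible(x)
}
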