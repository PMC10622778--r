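#' Summed deterministic range over several services
#'
#' Computes each service's ceiling range with [range_estimate()] and sums
#' the lower and upper bounds component-wise. Because the ceiling is applied
#' per service before summing, the result dominates the pooled range on the
#' same counts (e.g. the nine known published counts give 33 to 243 summed
#' versus 29.9 to 239.2 pooled).
#'
#' @param counts A tibble with `name`/`n_events` columns or a numeric
#'   vector of known counts; may be empty.
#' @param model A [fatality_rate_model()].
#' @return A `mors_range` (rounding `"ceiling"`); `(0, 0)` for empty input.
#' @export
#' @examples
#' summed_range(known_counts(mors_table1())) # 33 to 243
summed_range <- function(counts, model = fatality_rate_model()) {
  check_model(model)
  if ((is.data.frame(counts) && nrow(counts) == 0) || length(counts) == 0) {
    return(new_range(0, 0, "ceiling"))
  }
  counts <- as_counts(counts)
  per <- lapply(counts$n_events, range_estimate, model = model, rounding = "ceiling")
  new_range(
    sum(vapply(per, `[[`, numeric(1), "lower")),
    sum(vapply(per, `[[`, numeric(1), "upper")),
    "ceiling"
  )
}

#' Deterministic range on the pooled event count
#'
#' Applies `total * rate` at the model endpoints with a single rounding at
#' the end, the calculation behind pooled statements such as "between 30
#' and 240 potential deaths averted" for 299 pooled events.
#'
#' @param total_count Pooled non-negative integer event count.
#' @param model A [fatality_rate_model()].
#' @param rounding `"nearest"` (default), `"ceiling"`, or `"none"`.
#' @return A `mors_range`.
#' @export
#' @examples
#' pooled_range(299)                    # 30 to 239
#' pooled_range(299, rounding = "none") # 29.9 to 239.2
pooled_range <- function(total_count, model = fatality_rate_model(),
                         rounding = c("nearest", "ceiling", "none")) {
  check_model(model)
  rounding <- match.arg(rounding)
  total_count <- check_count_scalar(total_count, "total_count")
  new_range(
    apply_rounding(total_count * model$lower, rounding),
    apply_rounding(total_count * model$upper, rounding),
    rounding
  )
}

#' Ratio of non-fatal to fatal drug poisonings
#'
#' Given the total number of emergency responses and the number of deaths
#' assumed averted (i.e. events expected to have been fatal), returns
#' `(total_events - averted) / averted` rounded to `decimals` places —
#' e.g. 299 events and 135 averted give 1.21 (1.21 non-fatal poisonings per
#' expected fatality).
#'
#' @param total_events Positive integer total event count.
#' @param averted Positive integer deaths averted, at most `total_events`.
#' @param decimals Decimal places kept (default 2).
#' @return The rounded ratio.
#' @export
nonfatal_fatal_ratio <- function(total_events, averted, decimals = 2) {
  total_events <- check_count_scalar(total_events, "total_events")
  averted <- check_count_scalar(averted, "averted")
  if (averted == 0) {
    abort_domain("`averted` is zero; the non-fatal:fatal ratio is undefined.")
  }
  if (averted > total_events) {
    abort_domain("`averted` cannot exceed `total_events`.")
  }
  round_half_away((total_events - averted) / averted, digits = decimals)
}

#' Ratios at the rate floor, the Monte Carlo point, and the rate ceiling
#'
#' The denominators are nearest-rounded pooled averted counts at the two
#' rate endpoints plus the Monte Carlo point estimate; with the default
#' model and 299 events this yields 8.97, 1.21 and 0.25.
#'
#' @param total_events Positive integer total event count.
#' @param mc_point Rounded Monte Carlo point estimate of deaths averted.
#' @param model A [fatality_rate_model()].
#' @param decimals Decimal places kept (default 2).
#' @return A list of class `ratio_report` with `ratio_at_floor`,
#'   `ratio_at_mc`, `ratio_at_ceiling` and `denominator_policy`.
#' @export
ratio_report <- function(total_events, mc_point, model = fatality_rate_model(),
                         decimals = 2) {
  check_model(model)
  floor_averted <- round_half_away(total_events * model$lower)
  ceiling_averted <- round_half_away(total_events * model$upper)
  out <- list(
    ratio_at_floor = nonfatal_fatal_ratio(total_events, floor_averted, decimals),
    ratio_at_mc = nonfatal_fatal_ratio(total_events, mc_point, decimals),
    ratio_at_ceiling = nonfatal_fatal_ratio(total_events, ceiling_averted, decimals),
    averted_at_floor = floor_averted,
    averted_at_ceiling = ceiling_averted,
    denominator_policy = "nearest-rounded pooled averted count at each rate endpoint; rounded MC point at the centre"
  )
  structure(out, class = "ratio_report")
}

#' @export
print.ratio_report <- function(x, ...) {
  cat(sprintf(
    "<ratio_report> non-fatal:fatal %0.2f:1 (rate floor), %0.2f:1 (MC), %0.2f:1 (rate ceiling)\n",
    x$ratio_at_floor, x$ratio_at_mc, x$ratio_at_ceiling
  ))
  invisible(x)
}

#' Societal cost of a death by drug poisoning
#'
#' The per-death value covers life lost to society and potential productive
#' life years lost. The default constant is defined as the exact rational
#' CAD 3,487,836,040/18 cents per death (about $1,937,686.69), the value
#' implied by a societal saving of $34,878,360.40 for 18 averted Canadian
#' deaths; it is stored as a numerator/denominator pair so money arithmetic
#' stays exact to the cent.
#'
#' @param per_death_value Value of one averted death in currency units, or
#'   `NULL` (default) for the built-in Canadian constant.
#' @param currency Currency tag (default `"CAD"`).
#' @return An object of class `cost_model`.
#' @export
cost_model <- function(per_death_value = NULL, currency = "CAD") {
  if (is.null(per_death_value)) {
    cents_num <- 3487836040
    cents_den <- 18
  } else {
    if (!is.numeric(per_death_value) || length(per_death_value) != 1 ||
        is.na(per_death_value) || per_death_value <= 0) {
      abort_domain("`per_death_value` must be a single positive number.")
    }
    cents_num <- round(per_death_value * 100)
    cents_den <- 1
  }
  structure(
    list(
      cents_num = cents_num, cents_den = cents_den,
      per_death_value = cents_num / cents_den / 100, currency = currency
    ),
    class = "cost_model"
  )
}

#' @export
print.cost_model <- function(x, ...) {
  cat(sprintf("<cost_model> %s %s per averted death\n",
              x$currency, format_money(round_cents(1, x))))
  invisible(x)
}

# deaths * cents_num / cents_den, rounded half away to whole cents using
# exact integer arithmetic (products stay far below 2^53)
round_cents <- function(deaths, cost) {
  num <- deaths * cost$cents_num
  q <- num %/% cost$cents_den
  r <- num %% cost$cents_den
  q + as.numeric(2 * r >= cost$cents_den)
}

format_money <- function(cents) {
  sprintf("%s.%02d",
          formatC(cents %/% 100, format = "d", big.mark = ","),
          as.integer(cents %% 100))
}

#' Societal cost savings over an averted-death range
#'
#' Multiplies both bounds of an averted-death range by the per-death value,
#' exactly to the cent.
#'
#' @param averted_range A `mors_range` (integer bounds).
#' @param cost A [cost_model()].
#' @return An object of class `cost_savings` with numeric `lower`/`upper`
#'   (currency units), exact `lower_cents`/`upper_cents`, and formatted
#'   strings.
#' @export
#' @examples
#' cost_savings(summed_range(known_counts(mors_table1(), "canada")))
cost_savings <- function(averted_range, cost = cost_model()) {
  stopifnot(inherits(averted_range, "mors_range"), inherits(cost, "cost_model"))
  lo <- round_cents(averted_range$lower, cost)
  hi <- round_cents(averted_range$upper, cost)
  structure(
    list(
      lower = lo / 100, upper = hi / 100,
      lower_cents = lo, upper_cents = hi,
      lower_formatted = format_money(lo), upper_formatted = format_money(hi),
      currency = cost$currency
    ),
    class = "cost_savings"
  )
}

#' @export
print.cost_savings <- function(x, ...) {
  cat(sprintf("<cost_savings> %s $%s to $%s\n",
              x$currency, x$lower_formatted, x$upper_formatted))
  invisible(x)
}
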