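#' Build the full deaths-averted report for a service table
#'
#' Runs the whole pipeline on one table: per-service deterministic ranges
#' and shared-draw Monte Carlo estimates (unknown-count services are kept
#' and marked, never dropped), the TOTAL row, summed and pooled ranges,
#' non-fatal:fatal ratios, the Canada-exclusive subset with its societal
#' cost savings, and full provenance (every default made explicit) so any
#' number in the report can be re-derived from the report alone.
#'
#' @param table A [service_table()] (default: the built-in published
#'   table).
#' @param config An [estimation_config()].
#' @param model A [fatality_rate_model()].
#' @param cost A [cost_model()].
#' @param canada_scopes Country scopes counted as "Canada-exclusive"
#'   (default `"canada"`, which excludes cross-border and global services).
#' @return An object of class `mors_report`.
#' @export
#' @examples
#' report <- build_report()
#' report$total
build_report <- function(table = mors_table1(), config = estimation_config(),
                         model = fatality_rate_model(), cost = cost_model(),
                         canada_scopes = "canada") {
  stopifnot(inherits(table, "mors_service_table"))
  known <- known_counts(table)
  if (nrow(known) == 0) {
    abort_unknown_count("Every service count in the table is unknown; nothing to estimate.")
  }
  mc <- mc_estimate(known, config = config, model = model)

  ranges <- lapply(known$n_events, range_estimate, model = model,
                   rounding = config$range_rounding)
  known_rows <- tibble::tibble(
    name = known$name,
    range_lower = vapply(ranges, `[[`, numeric(1), "lower"),
    range_upper = vapply(ranges, `[[`, numeric(1), "upper")
  )
  known_rows <- dplyr::left_join(
    known_rows,
    dplyr::select(mc$per_service, "name", "point", "ci_lower", "ci_upper",
                  "raw_mean", "raw_lower", "raw_upper"),
    by = "name"
  )
  services <- dplyr::left_join(
    tibble::as_tibble(table)[c("name", "modality", "jurisdiction",
                               "country_scope", "n_events")],
    known_rows,
    by = "name"
  )
  services$known <- !is.na(services$n_events)

  total_events <- sum(known$n_events)
  summed <- summed_range(known, model)
  pooled_nearest <- pooled_range(total_events, model, rounding = "nearest")
  pooled_raw <- pooled_range(total_events, model, rounding = "none")
  ratios <- ratio_report(total_events, mc$total$point, model)

  canada <- known_counts(table, canada_scopes)
  canada_range <- summed_range(canada, model)
  canada_cost <- cost_savings(canada_range, cost)

  structure(
    list(
      services = services,
      total = mc$total,
      total_events = total_events,
      summed_range = summed,
      pooled_range = pooled_nearest,
      pooled_range_raw = pooled_raw,
      ratios = ratios,
      canada = list(
        scopes = canada_scopes, counts = canada,
        summed_range = canada_range, cost = canada_cost
      ),
      provenance = list(
        package = "morsaverted",
        version = as.character(utils::packageVersion("morsaverted")),
        table_label = attr(table, "label"),
        n_services = nrow(table),
        n_known = nrow(known),
        n_draws = config$n_draws, seed = config$seed,
        draw_mode = config$draw_mode, sampler = config$sampler,
        interval_mass = config$interval_mass,
        range_rounding = config$range_rounding,
        mc_rounding = config$mc_rounding,
        rate_family = model$family,
        rate_lower = model$lower, rate_upper = model$upper,
        cost_per_death = cost$per_death_value,
        cost_cents_num = cost$cents_num, cost_cents_den = cost$cents_den,
        currency = cost$currency
      )
    ),
    class = "mors_report"
  )
}

format_range_cell <- function(lo, hi) {
  ifelse(is.na(lo), "unknown", sprintf("%d–%d", as.integer(lo), as.integer(hi)))
}

format_mc_cell <- function(point, lo, hi) {
  ifelse(is.na(point), "unknown",
         sprintf("%d [%d, %d]", as.integer(point), as.integer(lo), as.integer(hi)))
}

report_rows <- function(report) {
  s <- report$services
  tot <- report$total
  tibble::tibble(
    service = c(s$name, "TOTAL"),
    modality = c(s$modality, "-"),
    country_scope = c(s$country_scope, "-"),
    events = c(ifelse(s$known, as.character(s$n_events), "unknown"),
               as.character(report$total_events)),
    averted_range = c(
      format_range_cell(s$range_lower, s$range_upper),
      format_range_cell(report$summed_range$lower, report$summed_range$upper)
    ),
    averted_mc = c(
      format_mc_cell(s$point, s$ci_lower, s$ci_upper),
      format_mc_cell(tot$point, tot$ci_lower, tot$ci_upper)
    )
  )
}

#' @export
print.mors_report <- function(x, ...) {
  p <- x$provenance
  cat(sprintf(
    "<mors_report> %d services (%d known counts, %d events); %d draws, %s mode, seed %d\n\n",
    p$n_services, p$n_known, x$total_events, p$n_draws, p$draw_mode, p$seed
  ))
  rows <- report_rows(x)
  widths <- vapply(rows, function(col) max(nchar(c(col))), numeric(1))
  widths <- pmax(widths, nchar(names(rows)))
  line <- function(vals) {
    cat(paste(mapply(formatC, vals, width = widths, flag = "-"), collapse = "  "), "\n")
  }
  line(names(rows))
  for (i in seq_len(nrow(rows))) line(unlist(rows[i, ]))
  cat(sprintf(
    "\nSummed range %d–%d; pooled range %g–%g (nearest) / %g–%g (raw)\n",
    as.integer(x$summed_range$lower), as.integer(x$summed_range$upper),
    x$pooled_range$lower, x$pooled_range$upper,
    x$pooled_range_raw$lower, x$pooled_range_raw$upper
  ))
  cat(sprintf(
    "Non-fatal:fatal ratio %0.2f:1 (floor) / %0.2f:1 (MC) / %0.2f:1 (ceiling)\n",
    x$ratios$ratio_at_floor, x$ratios$ratio_at_mc, x$ratios$ratio_at_ceiling
  ))
  cat(sprintf(
    "Canada-exclusive: %d–%d deaths averted, %s $%s to $%s saved\n",
    as.integer(x$canada$summed_range$lower), as.integer(x$canada$summed_range$upper),
    x$canada$cost$currency, x$canada$cost$lower_formatted, x$canada$cost$upper_formatted
  ))
  invisible(x)
}

provenance_lines <- function(report, prefix = "# ") {
  p <- report$provenance
  paste0(prefix, names(p), ": ", vapply(p, as.character, character(1)))
}

#' Write a report to CSV, JSON and/or Markdown
#'
#' Every file embeds the report's full effective configuration: CSV files
#' carry it as leading `#` comment lines (readable back with
#' `read.csv(comment.char = "#")`), the Markdown file as a provenance
#' section, and the JSON file verbatim. A Figure-style data file
#' (`service, range lower, range upper, MC point`) is also written for
#' external plotting.
#'
#' @param report A [build_report()] result.
#' @param outdir Output directory (created if missing).
#' @param formats Subset of `c("csv", "json", "markdown")`.
#' @param basename Stem for the output file names.
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(report, outdir,
                         formats = c("csv", "json", "markdown"),
                         basename = "mors_report") {
  stopifnot(inherits(report, "mors_report"))
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  rows <- report_rows(report)

  if ("csv" %in% formats) {
    path <- file.path(outdir, paste0(basename, ".csv"))
    con <- textConnection("csv_body", "w", local = TRUE)
    utils::write.csv(rows, con, row.names = FALSE)
    close(con)
    writeLines(c(provenance_lines(report), csv_body), path)
    written <- c(written, path)

    fig <- file.path(outdir, paste0(basename, "_figure_data.csv"))
    s <- report$services[report$services$known, ]
    con <- textConnection("fig_body", "w", local = TRUE)
    utils::write.csv(
      data.frame(service = s$name, range_lower = s$range_lower,
                 range_upper = s$range_upper, mc_point = s$point),
      con, row.names = FALSE
    )
    close(con)
    writeLines(c(provenance_lines(report), fig_body), fig)
    written <- c(written, fig)
  }
  if ("json" %in% formats) {
    path <- file.path(outdir, paste0(basename, ".json"))
    payload <- list(
      provenance = report$provenance,
      services = report$services,
      total = report$total,
      total_events = report$total_events,
      summed_range = unclass(report$summed_range),
      pooled_range = unclass(report$pooled_range),
      pooled_range_raw = unclass(report$pooled_range_raw),
      ratios = unclass(report$ratios),
      canada = list(
        scopes = report$canada$scopes,
        counts = report$canada$counts,
        summed_range = unclass(report$canada$summed_range),
        cost = unclass(report$canada$cost)
      )
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(written, path)
  }
  if ("markdown" %in% formats) {
    path <- file.path(outdir, paste0(basename, ".md"))
    md_row <- function(vals) paste0("| ", paste(vals, collapse = " | "), " |")
    lines <- c(
      "# Potential drug-poisoning deaths averted",
      "",
      md_row(c("Service", "Modality", "Scope", "Events",
               "Averted (range)", "Averted (Monte Carlo)")),
      md_row(rep("---", 6)),
      vapply(seq_len(nrow(rows)), function(i) md_row(unlist(rows[i, ])), character(1)),
      "",
      sprintf("Summed range: %d–%d. Pooled range: %g–%g (nearest).",
              as.integer(report$summed_range$lower),
              as.integer(report$summed_range$upper),
              report$pooled_range$lower, report$pooled_range$upper),
      sprintf("Non-fatal:fatal ratios: %0.2f:1 / %0.2f:1 / %0.2f:1 (floor / MC / ceiling).",
              report$ratios$ratio_at_floor, report$ratios$ratio_at_mc,
              report$ratios$ratio_at_ceiling),
      sprintf("Canada-exclusive services: %d–%d deaths averted; %s $%s to $%s saved.",
              as.integer(report$canada$summed_range$lower),
              as.integer(report$canada$summed_range$upper),
              report$canada$cost$currency,
              report$canada$cost$lower_formatted,
              report$canada$cost$upper_formatted),
      "",
      "## Provenance",
      "",
      provenance_lines(report, prefix = "- ")
    )
    writeLines(lines, path)
    written <- c(written, path)
  }
  invisible(written)
}
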