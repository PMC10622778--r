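service_modalities <- c("hotline", "app", "hybrid")
service_scopes <- c("canada", "usa", "both", "global")

required_columns <- c("name", "modality", "country_scope", "n_events")
optional_columns <- c("jurisdiction", "period_start", "period_end", "source_note")
all_columns <- c(
  "name", "modality", "jurisdiction", "country_scope",
  "period_start", "period_end", "n_events", "source_note"
)

#' Build and validate a table of mobile overdose response services
#'
#' A service table holds one row per service: the service name, its
#' modality (`hotline`, `app`, or `hybrid`), where it operates, the
#' observation period, and the number of emergency drug-poisoning/overdose
#' responses it recorded over that period. Counts that a service could not
#' or did not report are carried as `NA` ("unknown"): they stay in the
#' table, are flagged in reports, and are excluded from every sum and
#' estimate — never imputed, never coerced to zero.
#'
#' @param x A data frame with at least the columns `name`, `modality`,
#'   `country_scope`, `n_events`. `n_events` may be integer, or character
#'   with `"unknown"` / empty for missing counts. Optional columns:
#'   `jurisdiction`, `period_start`, `period_end`, `source_note`.
#' @param label A short label for the table.
#' @return A tibble of class `mors_service_table`.
#' @export
#' @examples
#' service_table(data.frame(
#'   name = "NORS", modality = "hotline",
#'   country_scope = "canada", n_events = 77
#' ))
service_table <- function(x, label = "service table") {
  if (!is.data.frame(x)) {
    abort_schema("A service table must be built from a data frame.")
  }
  missing_cols <- setdiff(required_columns, names(x))
  if (length(missing_cols) > 0) {
    abort_schema(sprintf(
      "Missing required column%s: %s.",
      if (length(missing_cols) > 1) "s" else "", paste(missing_cols, collapse = ", ")
    ))
  }
  x <- tibble::as_tibble(x)
  for (col in optional_columns) {
    if (!col %in% names(x)) x[[col]] <- NA_character_
  }
  x <- x[all_columns]
  x$name <- as.character(x$name)
  x$modality <- tolower(as.character(x$modality))
  x$country_scope <- tolower(as.character(x$country_scope))
  for (col in optional_columns) x[[col]] <- as.character(x[[col]])
  x$n_events <- parse_counts(x$n_events, x$name)

  validate_service_table(x, label)
  structure(x, label = label, class = c("mors_service_table", class(x)))
}

# "unknown" (any case) and blank/NA are the unknown state; everything else
# must parse as a non-negative integer
parse_counts <- function(n_events, names) {
  if (is.numeric(n_events)) {
    raw <- n_events
  } else {
    chr <- trimws(as.character(n_events))
    unknown <- is.na(chr) | chr == "" | tolower(chr) == "unknown"
    raw <- suppressWarnings(as.numeric(chr))
    bad <- !unknown & is.na(raw)
    if (any(bad)) {
      abort_validation(sprintf(
        "Non-numeric event count for record(s): %s.",
        paste(names[bad], collapse = ", ")
      ))
    }
    raw[unknown] <- NA_real_
  }
  ok <- is.na(raw) | (raw >= 0 & raw == trunc(raw))
  if (!all(ok)) {
    abort_validation(sprintf(
      "Event counts must be non-negative integers or \"unknown\"; offending record(s): %s.",
      paste(names[!ok], collapse = ", ")
    ))
  }
  as.integer(raw)
}

validate_service_table <- function(x, label) {
  if (nrow(x) < 1) {
    abort_schema("A service table needs at least one record.")
  }
  dup <- unique(x$name[duplicated(x$name)])
  if (length(dup) > 0) {
    abort_validation(sprintf(
      "Service names must be unique; duplicated: %s.", paste(dup, collapse = ", ")
    ))
  }
  bad_mod <- !x$modality %in% service_modalities
  if (any(bad_mod)) {
    abort_validation(sprintf(
      "Unknown modality for record(s) %s (allowed: %s).",
      paste(x$name[bad_mod], collapse = ", "),
      paste(service_modalities, collapse = ", ")
    ))
  }
  bad_scope <- !x$country_scope %in% service_scopes
  if (any(bad_scope)) {
    abort_validation(sprintf(
      "Unknown country_scope for record(s) %s (allowed: %s).",
      paste(x$name[bad_scope], collapse = ", "),
      paste(service_scopes, collapse = ", ")
    ))
  }
  invisible(x)
}

#' @export
print.mors_service_table <- function(x, ...) {
  known <- sum(!is.na(x$n_events))
  cat(sprintf(
    "<mors_service_table> \"%s\": %d services (%d with known counts, total %d events)\n",
    attr(x, "label"), nrow(x), known, sum(x$n_events, na.rm = TRUE)
  ))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Read a service table from CSV or JSON
#'
#' CSV files are comma-separated UTF-8 with a header row; JSON files are an
#' array of objects keyed by field name. Unknown counts are written and read
#' as the literal string `"unknown"` (or JSON `null`) and survive a
#' write/read round trip exactly.
#'
#' @param path Path to the file.
#' @param format `"csv"`, `"json"`, or `"auto"` (default: infer from the
#'   file extension).
#' @param label Table label; defaults to the file name.
#' @return A validated [service_table()].
#' @export
read_service_table <- function(path, format = c("auto", "csv", "json"),
                               label = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort_schema(sprintf("File not found: %s.", path))
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", json = "json",
      abort_schema(sprintf("Cannot infer format from extension \".%s\"; pass `format`.", ext))
    )
  }
  df <- if (format == "csv") {
    out <- tryCatch(
      utils::read.csv(path, colClasses = "character", check.names = FALSE,
                      comment.char = "#", fileEncoding = "UTF-8"),
      error = function(e) abort_schema(sprintf("Failed to parse CSV: %s.", conditionMessage(e)))
    )
    if (nrow(out) == 0 && ncol(out) == 0) {
      abort_schema("CSV file is empty (no header row).")
    }
    out
  } else {
    out <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
      error = function(e) abort_schema(sprintf("Failed to parse JSON: %s.", conditionMessage(e)))
    )
    if (!is.data.frame(out)) {
      abort_schema("JSON service table must be an array of objects.")
    }
    out
  }
  service_table(df, label = label)
}

#' Write a service table to CSV or JSON
#'
#' @param table A [service_table()].
#' @param path Output path.
#' @param format `"csv"`, `"json"`, or `"auto"` (infer from extension).
#' @return `path`, invisibly.
#' @export
write_service_table <- function(table, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(table, "mors_service_table"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)), csv = "csv", json = "json",
      abort_schema("Cannot infer format from extension; pass `format`.")
    )
  }
  out <- as.data.frame(table)
  out$n_events <- ifelse(is.na(out$n_events), "unknown", as.character(out$n_events))
  if (format == "csv") {
    utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(out, path, auto_unbox = FALSE, pretty = TRUE, na = "null")
  }
  invisible(path)
}

#' The published service table of North American MORS
#'
#' The 11 mobile overdose response / virtual overdose monitoring services
#' identified across Canada and the USA, with the number of emergency
#' drug-poisoning/overdose responses each had recorded by mid-2023. Two
#' services (iKeepr, The Canary) could not report counts; their rows carry
#' the unknown state. The nine known counts sum to 299 events. The same
#' table ships as a CSV file at
#' `system.file("extdata", "mors_services.csv", package = "morsaverted")`.
#'
#' @return A [service_table()] with 11 records.
#' @export
#' @examples
#' tab <- mors_table1()
#' sum(tab$n_events, na.rm = TRUE) # 299
mors_table1 <- function() {
  service_table(tibble::tibble(
    name = c(
      "NORS", "DORS", "Lifeguard", "Better App", "iKeepr", "OPL",
      "BeSafe Brave", "Never Use Alone", "The Canary", "UnityPhilly",
      "Naxos Neighbors"
    ),
    modality = c(
      "hotline", "app", "app", "app", "app", "hotline",
      "hybrid", "hotline", "app", "app", "app"
    ),
    jurisdiction = c(
      "Canada (national)", "Alberta", "British Columbia", "Canada", "Canada",
      "Ontario", "Global", "USA (national)", "USA", "Philadelphia, PA", "USA"
    ),
    country_scope = c(
      "canada", "canada", "canada", "canada", "canada", "canada",
      "global", "usa", "usa", "usa", "usa"
    ),
    period_start = c(
      "2020-12", "2021-01", "2021-01", "2020-01", "2022-01", "2020-01",
      "2020-01", "2019-01", "2018-01", "2019-03", "unknown"
    ),
    period_end = c(
      "2023-04", "2023-02", "2023-05", "2020-12", "2022-12", "2020-12",
      "2020-12", "2021-12", "2018-12", "2020-02", "unknown"
    ),
    n_events = c("77", "18", "66", "0", "unknown", "3", "33", "28", "unknown", "74", "0"),
    source_note = c(
      "Call-log data: drug poisonings with emergency response initiated",
      "Provincial app statistics",
      "News brief",
      "Founders report no emergency responses initiated to date",
      "Correspondence with developers; count not available",
      "Discontinued; replaced by NORS",
      "Public call-log data; operates across Canada and the USA",
      "2021 statistics",
      "Developers do not record this yet",
      "Published pilot evaluation",
      "0 responses; 214 downloads, 108 trained responders"
    )
  ), label = "North American MORS, observed to mid-2023")
}

#' Known event counts, optionally filtered by country scope
#'
#' Drops records with unknown counts and, when `subset` is not `"all"`,
#' keeps only services whose `country_scope` is in `subset`. Services
#' operating across borders (scope `"both"` or `"global"`) are only
#' retained when those scopes are named explicitly, so
#' `subset = "canada"` selects the Canada-exclusive services.
#'
#' @param table A [service_table()].
#' @param subset `"all"` or a character vector of scopes from
#'   `c("canada", "usa", "both", "global")`.
#' @return A tibble with columns `name`, `n_events` (all known), in the
#'   table's order. Empty when nothing matches.
#' @export
#' @examples
#' known_counts(mors_table1(), "canada") # the 5 Canada-exclusive services
known_counts <- function(table, subset = "all") {
  stopifnot(inherits(table, "mors_service_table"))
  subset <- tolower(subset)
  if (!(identical(subset, "all") || all(subset %in% service_scopes))) {
    abort_domain(sprintf(
      "`subset` must be \"all\" or values from: %s.",
      paste(service_scopes, collapse = ", ")
    ))
  }
  keep <- !is.na(table$n_events)
  if (!identical(subset, "all")) {
    keep <- keep & table$country_scope %in% subset
  }
  tibble::tibble(name = table$name[keep], n_events = as.integer(table$n_events[keep]))
}
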