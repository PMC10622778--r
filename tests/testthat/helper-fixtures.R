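# Published per-service counts and result cells, used across tests.
table1_counts <- c(
  NORS = 77, DORS = 18, Lifeguard = 66, `Better App` = 0, OPL = 3,
  `BeSafe Brave` = 33, `Never Use Alone` = 28, UnityPhilly = 74,
  `Naxos Neighbors` = 0
)

# ceiling ranges and Monte Carlo cells as tabulated for each known-count
# service (point [lower, upper] of the 95% interval)
table1_cells <- tibble::tibble(
  name = names(table1_counts),
  n_events = unname(table1_counts),
  range_lower = c(8, 2, 7, 0, 1, 4, 3, 8, 0),
  range_upper = c(62, 15, 53, 0, 3, 27, 23, 60, 0),
  mc_point = c(35, 8, 30, 0, 1, 15, 13, 33, 0),
  mc_lower = c(9, 2, 8, 0, 0, 4, 3, 9, 0),
  mc_upper = c(60, 14, 52, 0, 2, 26, 22, 58, 0)
)

# internal helpers exercised directly in tests
new_range <- morsaverted:::new_range
report_rows_for_test <- morsaverted:::report_rows

strip_label <- function(tab) {
  attr(tab, "label") <- NULL
  tab
}

tiny_table_df <- function() {
  data.frame(
    name = c("A", "B", "C"),
    modality = c("hotline", "app", "hybrid"),
    country_scope = c("canada", "usa", "global"),
    n_events = c("10", "unknown", "0"),
    stringsAsFactors = FALSE
  )
}
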