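# Display-column names (as shown in the result table) -> tibble column names.
# These are the five filterable columns plus the sortable numeric ones.
column_map <- c(
  Query       = "query_id",
  Subject     = "subject_id",
  Organism    = "organism",
  Product     = "product",
  Replicon    = "replicon_id",
  RelPosition = "x",
  BitScore    = "bitscore",
  Evalue      = "evalue",
  Y           = "y"
)

resolve_column <- function(column) {
  if (column %in% names(column_map)) {
    return(unname(column_map[[column]]))
  }
  if (column %in% unname(column_map)) {
    return(column)
  }
  abort(paste0("unknown column '", column, "'"))
}

# Columns every plotted-result tibble carries, in canonical order.
result_columns <- c(
  "query_id", "subject_id", "organism", "product", "replicon_id",
  "x", "y", "vector_deg", "strand", "seg_offset_deg", "seg_len_deg",
  "bitscore", "color_value", "evalue", "s_start", "s_end"
)

check_results <- function(results, arg = "results") {
  if (!is.data.frame(results)) {
    abort(paste0("`", arg, "` must be a data frame of plotted results"))
  }
  missing <- setdiff(result_columns, names(results))
  if (length(missing) > 0) {
    abort(paste0(
      "`", arg, "` is missing plotted-result column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(results)
}

# Stable significance-first ordering used for caps and the *_Sorted export:
# bitscore desc, then evalue asc, then replicon index, then position, then
# original input order (dplyr::arrange is stable, so input order is the
# implicit final key).
canonical_order <- function(results) {
  dplyr::arrange(
    results,
    dplyr::desc(.data$bitscore), .data$evalue, .data$y, .data$x
  )
}

fmt_num <- function(x, digits = 10) {
  # Fixed-notation-or-scientific formatting with enough significant digits
  # to round-trip doubles we produce; deterministic across runs.
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v == floor(v) && abs(v) < 1e15) {
      sprintf("%.0f", v)
    } else {
      formatC(v, digits = digits, format = "g")
    }
  }, character(1))
}
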