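#' Specify a "contains" filter
#'
#' Filters are case-sensitive exact-substring matches, mirroring the
#' underscore-suffix naming convention used to tag query headers (e.g.
#' `"SSI_"` matches `SSI_HlyD` but not `SSII_GspC`). Multiple filters
#' compose with AND.
#'
#' @param column One of `Query`, `Subject`, `Organism`, `Product`,
#'   `Replicon` (display names) or the underlying column name.
#' @param needle Non-empty substring to search for.
#' @return A `blastxy_filter` object.
#' @export
filter_spec <- function(column, needle) {
  col <- resolve_column(column)
  if (!col %in% c("query_id", "subject_id", "organism", "product", "replicon_id")) {
    abort(paste0("column '", column, "' is not filterable"))
  }
  if (!is.character(needle) || length(needle) != 1 || !nzchar(needle)) {
    abort("filter needle must be a non-empty string")
  }
  structure(list(column = col, mode = "contains", needle = needle),
            class = "blastxy_filter")
}

as_filter_list <- function(filters) {
  if (is.null(filters)) return(list())
  if (inherits(filters, "blastxy_filter")) return(list(filters))
  lapply(filters, function(f) {
    if (inherits(f, "blastxy_filter")) return(f)
    if (is.character(f) && length(f) == 1) {
      # "COLUMN:NEEDLE" shorthand used by the command line
      parts <- stringr::str_split_fixed(f, stringr::fixed(":"), 2)
      if (!nzchar(parts[2])) abort(paste0("bad filter '", f, "', want COLUMN:NEEDLE"))
      return(filter_spec(parts[1], parts[2]))
    }
    abort("filters must be filter_spec objects or 'COLUMN:NEEDLE' strings")
  })
}

#' Filter a result table by substring containment
#'
#' A row survives iff every filter's needle is a case-sensitive substring of
#' that row's column. Row order is preserved and the input is not modified.
#'
#' @param results Plotted-result tibble.
#' @param filters A [filter_spec()], a list of them, or `"COLUMN:NEEDLE"`
#'   strings. An empty list returns all rows.
#' @return The surviving rows, original order preserved.
#' @export
filter_results <- function(results, filters) {
  filters <- as_filter_list(filters)
  if (length(filters) == 0) return(results)
  keep <- rep(TRUE, nrow(results))
  for (f in filters) {
    if (!f$column %in% names(results)) {
      abort(paste0("unknown column '", f$column, "'"))
    }
    keep <- keep & stringr::str_detect(results[[f$column]],
                                       stringr::fixed(f$needle))
  }
  results[keep, , drop = FALSE]
}

#' Sort a result table on one column
#'
#' Stable sort: ties keep their prior relative order. Numeric columns sort
#' numerically, text columns lexicographically (C locale).
#'
#' @param results Plotted-result tibble.
#' @param column Display or internal column name.
#' @param direction `"asc"` or `"desc"`.
#' @return The reordered rows.
#' @export
sort_results <- function(results, column, direction = c("asc", "desc")) {
  direction <- match.arg(direction)
  col <- resolve_column(column)
  if (!col %in% names(results)) {
    abort(paste0("unknown column '", column, "'"))
  }
  v <- results[[col]]
  if (is.character(v)) {
    ord <- order(v, method = "radix", decreasing = (direction == "desc"))
  } else {
    ord <- order(if (direction == "desc") -xtfrm(v) else xtfrm(v),
                 method = "radix")
  }
  results[ord, , drop = FALSE]
}

#' Cap a result table at its most significant rows
#'
#' The plot is limited to 50,000 results by default because more saturate
#' it; raw exports carry up to one million. When the cap binds, the most
#' significant rows are retained under the ordering: bit score descending,
#' e-value ascending, replicon index, relative position, input order.
#'
#' @param results Plotted-result tibble.
#' @param cap Positive integer.
#' @return At most `cap` rows in that canonical order, with attribute
#'   `n_discarded` giving the number dropped (also reported via a message
#'   when non-zero).
#' @export
apply_result_cap <- function(results, cap = 50000) {
  if (!is.numeric(cap) || length(cap) != 1 || cap < 1) {
    abort("cap must be a positive integer")
  }
  n <- nrow(results)
  out <- canonical_order(results)
  if (n > cap) {
    out <- out[seq_len(cap), , drop = FALSE]
    inform(paste0(n - cap, " result(s) beyond the cap of ", cap, " discarded"))
  }
  attr(out, "n_discarded") <- max(0L, n - as.integer(cap))
  out
}

#' Group nearby results into proximity clusters
#'
#' Runs of hits at nearby relative positions on one replicon are the visual
#' signature of an operon or gene cluster. This groups results per replicon
#' by single linkage on `x`: sorted by position, a new cluster starts
#' whenever the gap to the previous position exceeds `window_deg`. Clusters
#' never span replicons and every row belongs to exactly one cluster.
#'
#' @param results Plotted-result tibble.
#' @param window_deg Maximum gap, in degrees, between consecutive cluster
#'   members. The default of 5 degrees resolves clusters within the
#'   ~25-degree zoom window typically used for browsing.
#' @return A tibble with one row per cluster: `replicon_id`, `cluster`,
#'   `n_members`, `x_min`, `x_max`, and `members` (list column of the
#'   member rows, ordered by `x`).
#' @export
detect_clusters <- function(results, window_deg = 5) {
  if (!is.numeric(window_deg) || window_deg <= 0) {
    abort("window_deg must be > 0")
  }
  if (nrow(results) == 0) {
    return(tibble::tibble(
      replicon_id = character(), cluster = integer(), n_members = integer(),
      x_min = double(), x_max = double(), members = list()
    ))
  }
  tbl <- tibble::as_tibble(results)
  per_replicon <- split(tbl, tbl$replicon_id)
  purrr::map(per_replicon, function(rows) {
    rows <- rows[order(rows$x), , drop = FALSE]
    gap <- c(0, diff(rows$x))
    cl <- cumsum(gap > window_deg) + 1L
    members <- split(rows, cl)
    tibble::tibble(
      replicon_id = rows$replicon_id[1],
      cluster = as.integer(names(members)),
      n_members = unname(vapply(members, nrow, integer(1))),
      x_min = unname(vapply(members, function(m) min(m$x), double(1))),
      x_max = unname(vapply(members, function(m) max(m$x), double(1))),
      members = unname(members)
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$replicon_id, .data$cluster)
}
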