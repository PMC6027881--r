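#' Write and read the results JSON bundle
#'
#' Results are recorded in a plain-text JSON file with a fixed schema:
#' a top-level object with `job` (title and parameters), `replicons`
#' (id, organism, length, y index) and `results` (the plotted-result rows).
#' Numbers are serialized at full precision, so `read_results_json()`
#' after `write_results_json()` is the identity on the result table.
#'
#' @param results Plotted-result tibble.
#' @param path Output path.
#' @param job_title Job title recorded in the file.
#' @param parameters Named list of job parameters recorded in the file.
#' @param replicons Replicon tibble; defaults to the `replicons` attribute
#'   of `results` when present.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(results, path, job_title = "",
                               parameters = list(), replicons = NULL) {
  check_results(results)
  replicons <- replicons %||% attr(results, "replicons")
  rep_block <- if (is.null(replicons) || nrow(replicons) == 0) {
    list()
  } else {
    purrr::pmap(
      dplyr::select(replicons, "replicon_id", "organism", "length_bp",
                    "replicon_index"),
      function(replicon_id, organism, length_bp, replicon_index) {
        list(replicon_id = replicon_id, organism = organism,
             length_bp = length_bp, replicon_index = replicon_index)
      }
    )
  }
  res_block <- purrr::pmap(
    tibble::as_tibble(results)[, result_json_fields],
    function(...) as.list(list(...))
  )
  obj <- list(
    job = list(title = job_title, parameters = parameters),
    replicons = rep_block,
    results = res_block
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

# field order of one result object in the JSON schema
result_json_fields <- c(
  "x", "y", "vector_deg", "strand", "seg_offset_deg", "seg_len_deg",
  "bitscore", "color_value", "evalue", "query_id", "subject_id",
  "organism", "product", "replicon_id", "s_start", "s_end"
)

#' @rdname write_results_json
#' @return `read_results_json()` returns the plotted-result tibble in file
#'   order, with the `job` (list) and `replicons` (tibble) attributes
#'   restored.
#' @export
read_results_json <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("results JSON not found: ", path))
  }
  obj <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) abort(paste0("invalid results JSON: ", conditionMessage(e)))
  )
  for (key in c("job", "replicons", "results")) {
    if (is.null(obj[[key]])) abort(paste0("missing field ", key))
  }
  parse_result <- function(r, i) {
    for (f in result_json_fields) {
      if (is.null(r[[f]])) {
        abort(paste0("result ", i, ": missing field ", f))
      }
    }
    r[result_json_fields]
  }
  rows <- purrr::imap(obj$results, parse_result)
  if (length(rows) == 0) {
    out <- tibble::as_tibble(
      stats::setNames(
        lapply(result_json_fields, function(f) {
          if (f %in% c("query_id", "subject_id", "organism", "product",
                       "replicon_id", "strand")) character() else double()
        }),
        result_json_fields
      )
    )
  } else {
    out <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  }
  out$y <- as.integer(out$y)
  out$s_start <- as.integer(out$s_start)
  out$s_end <- as.integer(out$s_end)
  out <- out[, result_columns]
  reps <- if (length(obj$replicons) > 0) {
    dplyr::bind_rows(lapply(obj$replicons, tibble::as_tibble)) |>
      dplyr::mutate(length_bp = as.integer(.data$length_bp),
                    replicon_index = as.integer(.data$replicon_index))
  } else {
    NULL
  }
  new_blastxy_results(out, replicons = reps)
}

#' Write the spreadsheet-style TSV export
#'
#' Two variants mirror the downloadable job bundle: `sorted_raw`
#' (`*_Sorted`) holds every capped result in canonical significance order;
#' `sorted_scored` (`*_Sorted_Scored`) holds only the rows surviving the
#' active filters. Columns: Query, Subject, Organism, Replicon,
#' RelPosition, BitScore, Evalue, Product.
#'
#' @param results Plotted-result tibble (already capped for `sorted_raw`).
#' @param path Output path.
#' @param variant `"sorted_raw"` or `"sorted_scored"`.
#' @param filters Active filters (see [filter_results()]); applied only for
#'   the `sorted_scored` variant.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(results, path,
                            variant = c("sorted_raw", "sorted_scored"),
                            filters = NULL) {
  variant <- match.arg(variant)
  check_results(results)
  rows <- canonical_order(tibble::as_tibble(results))
  if (variant == "sorted_scored") {
    rows <- filter_results(rows, filters)
  }
  out <- tibble::tibble(
    Query = rows$query_id,
    Subject = rows$subject_id,
    Organism = rows$organism,
    Replicon = rows$replicon_id,
    RelPosition = fmt_num(rows$x),
    BitScore = fmt_num(rows$bitscore),
    Evalue = formatC(rows$evalue, format = "e", digits = 4),
    Product = rows$product
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
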