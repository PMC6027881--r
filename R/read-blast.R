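#' Read BLAST tabular output (outfmt 6 or 7)
#'
#' Parses the standard 12-column tab-separated BLAST output into a tibble,
#' one row per hit, preserving input order. Comment lines starting with `#`
#' (the outfmt 7 dialect) are skipped, so either format can be passed
#' unchanged. Lines may carry more than 12 fields (custom outfmt 6 with
#' extra columns); only the first 12 are used.
#'
#' @param path Path to a BLAST tabular file.
#' @param unit Coordinate unit of the subject: `"nucleotide"` (blastn-style,
#'   where `s_start > s_end` encodes a minus-strand alignment) or
#'   `"protein"` (blastp/tblastn-style residue coordinates). Stored as the
#'   `unit` attribute of the result and consulted by [project_hits()].
#' @return A tibble with the 12 standard columns: `query_id`, `subject_id`,
#'   `pct_identity`, `aln_length`, `mismatches`, `gap_opens`, `q_start`,
#'   `q_end`, `s_start`, `s_end`, `evalue`, `bitscore`.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines("capA\tBTH_II1227\t100.00\t141\t0\t0\t1\t141\t1\t141\t3e-70\t262", f)
#' read_blast_tabular(f)
#' @export
read_blast_tabular <- function(path, unit = c("nucleotide", "protein")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) {
    abort(paste0("BLAST tabular file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  is_comment <- startsWith(lines, "#")
  keep <- which(!is_comment & nzchar(trimws(lines)))

  empty <- tibble::tibble(
    query_id = character(), subject_id = character(),
    pct_identity = double(), aln_length = integer(), mismatches = integer(),
    gap_opens = integer(), q_start = integer(), q_end = integer(),
    s_start = integer(), s_end = integer(), evalue = double(),
    bitscore = double()
  )
  if (length(keep) == 0) {
    attr(empty, "unit") <- unit
    return(empty)
  }

  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12)) {
    bad <- keep[which(nf < 12)[1]]
    abort(paste0("line ", bad, ": expected >=12 fields, got ", nf[which(nf < 12)[1]]))
  }

  m <- vapply(fields, function(f) f[1:12], character(12))
  parse_num <- function(i, what, as_int = FALSE) {
    v <- suppressWarnings(as.numeric(m[i, ]))
    if (anyNA(v)) {
      bad <- keep[which(is.na(v))[1]]
      abort(paste0("line ", bad, ": cannot parse ", what, " '",
                   m[i, which(is.na(v))[1]], "'"))
    }
    if (as_int) as.integer(v) else v
  }

  out <- tibble::tibble(
    query_id     = m[1, ],
    subject_id   = m[2, ],
    pct_identity = parse_num(3, "percent identity"),
    aln_length   = parse_num(4, "alignment length", as_int = TRUE),
    mismatches   = parse_num(5, "mismatch count", as_int = TRUE),
    gap_opens    = parse_num(6, "gap open count", as_int = TRUE),
    q_start      = parse_num(7, "query start", as_int = TRUE),
    q_end        = parse_num(8, "query end", as_int = TRUE),
    s_start      = parse_num(9, "subject start", as_int = TRUE),
    s_end        = parse_num(10, "subject end", as_int = TRUE),
    evalue       = parse_num(11, "e-value"),
    bitscore     = parse_num(12, "bit score")
  )
  if (any(out$aln_length < 1)) {
    abort("alignment length must be >= 1")
  }
  if (any(out$evalue < 0)) {
    abort("e-value must be >= 0")
  }
  attr(out, "unit") <- unit
  out
}

#' Write hits back out in outfmt 6
#'
#' Re-serializes a hit tibble as 12-column BLAST tabular text with canonical
#' number formatting (identity to two decimals, e-value in scientific
#' notation). Mainly used by the simulator and round-trip tests.
#'
#' @param hits A tibble as returned by [read_blast_tabular()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_tabular <- function(hits, path) {
  lines <- sprintf(
    "%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%s",
    hits$query_id, hits$subject_id, hits$pct_identity, hits$aln_length,
    hits$mismatches, hits$gap_opens, hits$q_start, hits$q_end,
    hits$s_start, hits$s_end,
    formatC(hits$evalue, format = "e", digits = 2),
    fmt_num(hits$bitscore)
  )
  writeLines(lines, path)
  invisible(path)
}
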