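#' Read query sequences from a multi-FASTA file
#'
#' Query files carry one record per query sequence; informative headers
#' (e.g. `capA`..`capD` for a four-gene bacteriocin locus, or the
#' `SSI_`/`SSII_` prefix convention for secretion-system components) are
#' what the table filters later match against.
#'
#' @param path FASTA file path.
#' @return A tibble with `query_id` (first word of the header) and
#'   `length` (sequence length).
#' @export
read_query_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("query FASTA not found: ", path))
  }
  seqs <- Biostrings::readBStringSet(path)
  tibble::tibble(
    query_id = sub("\\s.*$", "", names(seqs)),
    length = Biostrings::width(seqs)
  )
}
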