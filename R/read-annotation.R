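#' Read genome annotation: GFF3 features plus replicon lengths
#'
#' Parses gene/CDS records from a GFF3 file and replicon metadata from
#' either a FASTA file (sequence lengths) or a tab-separated replicon table
#' (`replicon_id<TAB>length_bp[<TAB>organism[<TAB>topology]]`). Coordinates
#' are 1-based inclusive throughout, per the GFF3 convention; conversion to
#' degrees happens only at projection time.
#'
#' Origin-spanning features of circular replicons -- annotated in the source
#' with end < start -- are normalized to `end_bp = end + length_bp` with
#' `wraps_origin = TRUE`, which keeps `start_bp <= end_bp` while preserving
#' the true feature length.
#'
#' @param gff_path Path to a GFF3 file; records of type `gene` or `CDS`
#'   carrying an `ID` (or `locus_tag`) attribute are used.
#' @param fasta_or_tsv_path Path to a FASTA file or a replicon TSV.
#' @return A list with elements `replicons` (tibble: `replicon_id`,
#'   `organism`, `length_bp`, `topology`, `replicon_index`) and `features`
#'   (tibble: `replicon_id`, `feature_id`, `start_bp`, `end_bp`, `strand`,
#'   `locus_tag`, `product`, `wraps_origin`).
#' @export
read_annotation <- function(gff_path, fasta_or_tsv_path) {
  if (!file.exists(gff_path)) {
    abort(paste0("annotation file not found: ", gff_path))
  }
  if (!file.exists(fasta_or_tsv_path)) {
    abort(paste0("replicon metadata file not found: ", fasta_or_tsv_path))
  }
  replicons <- read_replicon_metadata(fasta_or_tsv_path)
  features <- read_gff3_features(gff_path)

  unknown <- setdiff(unique(features$replicon_id), replicons$replicon_id)
  if (length(unknown) > 0) {
    abort(paste0("unknown replicon ", unknown[1]))
  }

  lens <- stats::setNames(replicons$length_bp, replicons$replicon_id)
  L <- unname(lens[features$replicon_id])

  # end < start in the source marks an origin-spanning circular feature
  wraps <- features$end_bp < features$start_bp
  features$end_bp[wraps] <- features$end_bp[wraps] + L[wraps]
  features$wraps_origin <- wraps

  over <- !wraps & (features$end_bp > L)
  if (any(over)) {
    i <- which(over)[1]
    abort(paste0(
      "feature ", features$feature_id[i], " ends at ", features$end_bp[i],
      " beyond replicon ", features$replicon_id[i], " length ", L[i]
    ))
  }
  dup <- features |>
    dplyr::count(.data$replicon_id, .data$feature_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate feature id ", dup$feature_id[1],
                 " on replicon ", dup$replicon_id[1]))
  }

  list(replicons = replicons, features = features)
}

read_replicon_metadata <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) > 0 && startsWith(first, ">")) {
    seqs <- Biostrings::readDNAStringSet(path)
    ids <- sub("\\s.*$", "", names(seqs))
    out <- tibble::tibble(
      replicon_id = ids,
      organism = "",
      length_bp = Biostrings::width(seqs),
      topology = "circular"
    )
  } else {
    raw <- readr::read_tsv(
      path,
      col_names = FALSE, col_types = readr::cols(.default = readr::col_character()),
      comment = "#", progress = FALSE
    )
    if (ncol(raw) < 2) {
      abort("replicon TSV needs at least 2 columns: replicon_id, length_bp")
    }
    len <- suppressWarnings(as.numeric(raw[[2]]))
    if (anyNA(len)) {
      abort(paste0("replicon TSV: cannot parse length '", raw[[2]][which(is.na(len))[1]], "'"))
    }
    out <- tibble::tibble(
      replicon_id = raw[[1]],
      organism = if (ncol(raw) >= 3) dplyr::coalesce(raw[[3]], "") else "",
      length_bp = as.integer(len),
      topology = if (ncol(raw) >= 4) dplyr::coalesce(raw[[4]], "circular") else "circular"
    )
  }
  if (any(out$length_bp < 1)) {
    abort("replicon length_bp must be >= 1")
  }
  if (anyDuplicated(out$replicon_id)) {
    abort(paste0("duplicate replicon_id ",
                 out$replicon_id[anyDuplicated(out$replicon_id)]))
  }
  bad_topo <- setdiff(unique(out$topology), c("circular", "linear"))
  if (length(bad_topo) > 0) {
    abort(paste0("unknown topology '", bad_topo[1], "' (circular or linear)"))
  }
  out$replicon_index <- NA_integer_
  out
}

gff3_attr <- function(attrs, key) {
  pat <- paste0("(?:^|;)\\s*", key, "=([^;]*)")
  m <- regmatches(attrs, regexec(pat, attrs))
  vapply(m, function(x) if (length(x) == 2) utils::URLdecode(x[2]) else NA_character_,
         character(1))
}

read_gff3_features <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fasta_at <- which(lines == "##FASTA")
  if (length(fasta_at) > 0) lines <- lines[seq_len(fasta_at[1] - 1L)]
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(
      replicon_id = character(), feature_id = character(),
      start_bp = integer(), end_bp = integer(), strand = character(),
      locus_tag = character(), product = character()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9)) {
    abort(paste0("GFF3 line ", which(nf < 9)[1], ": expected 9 fields"))
  }
  m <- vapply(fields, function(f) f[1:9], character(9))
  type <- m[3, ]
  keep <- type %in% c("gene", "CDS")
  m <- m[, keep, drop = FALSE]
  if (ncol(m) == 0) {
    return(tibble::tibble(
      replicon_id = character(), feature_id = character(),
      start_bp = integer(), end_bp = integer(), strand = character(),
      locus_tag = character(), product = character()
    ))
  }
  start <- suppressWarnings(as.integer(m[4, ]))
  end <- suppressWarnings(as.integer(m[5, ]))
  if (anyNA(start) || anyNA(end)) {
    abort("GFF3: unparseable start/end coordinate")
  }
  strand <- m[7, ]
  if (!all(strand %in% c("+", "-"))) {
    abort(paste0("GFF3: strand must be '+' or '-', got '",
                 strand[which(!strand %in% c("+", "-"))[1]], "'"))
  }
  attrs <- m[9, ]
  id <- gff3_attr(attrs, "ID")
  locus <- gff3_attr(attrs, "locus_tag")
  feature_id <- dplyr::coalesce(id, locus)
  if (anyNA(feature_id)) {
    abort("GFF3: feature without ID or locus_tag attribute")
  }
  if (any(start < 1)) {
    abort("GFF3: start coordinate must be >= 1")
  }
  tibble::tibble(
    replicon_id = m[1, ],
    feature_id = feature_id,
    start_bp = start,
    end_bp = end,
    strand = strand,
    locus_tag = dplyr::coalesce(locus, ""),
    product = dplyr::coalesce(gff3_attr(attrs, "product"), "")
  )
}
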