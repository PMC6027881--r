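#' Map a base-pair position to the 0-360 relative coordinate axis
#'
#' Every replicon, whatever its size, is drawn as a line of fixed length 360
#' (the degrees of a circle). Base `b` of a length-`L` replicon occupies the
#' half-open degree interval `[360 (b-1) / L, 360 b / L)`, so the first
#' base's start maps to exactly 0 and the final base's end to exactly 360,
#' and the map is measure-preserving.
#'
#' Positions beyond `L` (produced by origin-wrap normalization of circular
#' features) are reduced modulo `L` before mapping.
#'
#' @param pos_bp Integer position(s), 1-based.
#' @param replicon_length_bp Replicon length(s) in bp.
#' @param boundary `"start"` for the left edge of the base, `"end"` for its
#'   right edge.
#' @return Degrees in `[0, 360]` (double, vectorized).
#' @examples
#' relative_coordinate(1, 4641652, "start") # 0
#' relative_coordinate(4641652, 4641652, "end") # 360
#' @export
relative_coordinate <- function(pos_bp, replicon_length_bp,
                                boundary = c("start", "end")) {
  boundary <- match.arg(boundary)
  if (any(replicon_length_bp < 1)) {
    abort("replicon_length_bp must be >= 1")
  }
  if (any(pos_bp < 1)) {
    abort("pos_bp must be >= 1")
  }
  pos <- ((pos_bp - 1) %% replicon_length_bp) + 1
  if (boundary == "start") {
    360 * (pos - 1) / replicon_length_bp
  } else {
    360 * pos / replicon_length_bp
  }
}

#' Assign y-axis indices to replicons
#'
#' The y axis counts the replicons used as the search database, from 1 (a
#' single replicon) to N. The ordering is canonical and reproducible:
#' organisms alphabetically; within an organism, replicons by decreasing
#' length (which puts chromosomes before plasmids), ties broken by
#' `replicon_id`.
#'
#' @param replicons Replicon tibble (`replicon_id`, `organism`,
#'   `length_bp`, ...).
#' @return The same tibble, reordered canonically, with `replicon_index`
#'   set to `1..N`.
#' @export
assign_replicon_indices <- function(replicons) {
  if (anyDuplicated(replicons$replicon_id)) {
    dup <- replicons$replicon_id[duplicated(replicons$replicon_id)][1]
    abort(paste0("duplicate replicon_id ", dup))
  }
  out <- dplyr::arrange(
    replicons,
    .data$organism, dplyr::desc(.data$length_bp), .data$replicon_id
  )
  out$replicon_index <- seq_len(nrow(out))
  out
}

#' Construct a bit-score colour scale
#'
#' Colours encode significance as defined by the BLAST bit score, from dark
#' blue `rgb(0, 0, 139)` for the most significant down to yellow
#' `rgb(255, 255, 0)` for the least, linearly interpolated per channel.
#' Normalization is over the full (capped) result set of a job, so colours
#' stay stable while panning and zooming.
#'
#' @param min_bitscore,max_bitscore Scale endpoints in bits.
#' @return An object of class `blastxy_color_scale`.
#' @export
color_scale <- function(min_bitscore, max_bitscore) {
  if (!is.finite(min_bitscore) || !is.finite(max_bitscore)) {
    abort("colour scale endpoints must be finite")
  }
  if (min_bitscore > max_bitscore) {
    abort("min_bitscore must be <= max_bitscore")
  }
  structure(
    list(
      min_bitscore = min_bitscore,
      max_bitscore = max_bitscore,
      low_color = c(255L, 255L, 0L),   # yellow
      high_color = c(0L, 0L, 139L)     # dark blue
    ),
    class = "blastxy_color_scale"
  )
}

#' Map bit scores to the yellow-to-dark-blue significance scale
#'
#' @param bitscore Bit score(s).
#' @param scale A [color_scale()].
#' @return A tibble with `color_value` in `[0, 1]` (1 = most significant),
#'   integer channels `r`, `g`, `b`, and `hex`. When the scale is degenerate
#'   (`min == max`) every score maps to 1 (dark blue).
#' @export
bitscore_to_color <- function(bitscore, scale) {
  if (any(!is.finite(bitscore))) {
    abort("bitscore must be finite")
  }
  rng <- scale$max_bitscore - scale$min_bitscore
  v <- if (rng <= 0) {
    rep(1, length(bitscore))
  } else {
    pmin(1, pmax(0, (bitscore - scale$min_bitscore) / rng))
  }
  lerp <- function(a, b) as.integer(round(a + (b - a) * v))
  r <- lerp(scale$low_color[1], scale$high_color[1])
  g <- lerp(scale$low_color[2], scale$high_color[2])
  b <- lerp(scale$low_color[3], scale$high_color[3])
  tibble::tibble(
    color_value = v, r = r, g = g, b = b,
    hex = sprintf("#%02X%02X%02X", r, g, b)
  )
}

#' Project BLAST hits onto the 0-360 coordinate system
#'
#' Joins each hit's subject to an annotated gene (exact `feature_id` match
#' first, then `locus_tag`), and converts it to a plotted result: `x` is the
#' relative coordinate of the gene's transcription start (lower genomic
#' boundary for `+` features, upper for `-`); `y` the replicon index;
#' `vector_deg` the signed gene length in degrees, pointing in the
#' transcription sense; `seg_offset_deg` / `seg_len_deg` locate the aligned
#' region along the vector; `color_value` encodes the bit score.
#'
#' For `unit = "protein"` subjects the alignment segment is mapped by
#' residue fraction of the protein length (taken as gene length in bp
#' divided by 3) onto the gene's degree vector.
#'
#' Unresolvable subject ids are never silently dropped: they are counted in
#' the `n_unresolved` attribute (with ids in `unresolved_ids`) and reported
#' via a message.
#'
#' @param hits Hit tibble from [read_blast_tabular()].
#' @param features Feature tibble from [read_annotation()].
#' @param replicons Replicon tibble with indices assigned (or not -- indices
#'   are assigned canonically when absent).
#' @param scale Optional [color_scale()]; defaults to the bit-score range of
#'   the resolvable hits.
#' @param unit `"nucleotide"` or `"protein"`; defaults to the `unit`
#'   attribute of `hits`.
#' @return A plotted-result tibble (class `blastxy_results`) with one row
#'   per resolvable hit and columns `query_id`, `subject_id`, `organism`,
#'   `product`, `replicon_id`, `x`, `y`, `vector_deg`, `strand`,
#'   `seg_offset_deg`, `seg_len_deg`, `bitscore`, `color_value`, `evalue`,
#'   `s_start`, `s_end`, plus attributes `n_unresolved`, `unresolved_ids`
#'   and `replicons`.
#' @export
project_hits <- function(hits, features, replicons, scale = NULL, unit = NULL) {
  unit <- unit %||% attr(hits, "unit") %||% "nucleotide"
  unit <- match.arg(unit, c("nucleotide", "protein"))
  if (!"replicon_index" %in% names(replicons) ||
      all(is.na(replicons$replicon_index))) {
    replicons <- assign_replicon_indices(replicons)
  }

  # two-stage subject resolution: feature_id, then locus_tag
  feat <- features
  feat$.subject_len_bp <- feat$end_bp - feat$start_bp + 1L
  by_id <- dplyr::inner_join(
    dplyr::mutate(hits, .hit_row = dplyr::row_number()),
    feat,
    by = c(subject_id = "feature_id")
  )
  unresolved1 <- !(hits$subject_id %in% features$feature_id)
  by_locus <- dplyr::inner_join(
    dplyr::mutate(hits[unresolved1, , drop = FALSE],
                  .hit_row = which(unresolved1)),
    dplyr::filter(feat, nzchar(.data$locus_tag)),
    by = c(subject_id = "locus_tag")
  )
  by_id$feature_id <- by_id$subject_id
  if (nrow(by_locus) > 0) {
    by_locus$locus_tag <- by_locus$subject_id
    by_locus <- by_locus[, names(by_id)]
    joined <- dplyr::bind_rows(by_id, by_locus)
  } else {
    joined <- by_id
  }
  joined <- dplyr::arrange(joined, .data$.hit_row)

  unresolved_ids <- unique(hits$subject_id[!(seq_len(nrow(hits)) %in% joined$.hit_row)])
  n_unresolved <- sum(!(seq_len(nrow(hits)) %in% joined$.hit_row))
  if (n_unresolved > 0) {
    inform(paste0(n_unresolved, " hit(s) with unresolvable subject id (",
                  paste(utils::head(unresolved_ids, 5), collapse = ", "),
                  if (length(unresolved_ids) > 5) ", ..." else "", ")"))
  }

  joined <- dplyr::left_join(
    joined,
    dplyr::select(replicons, "replicon_id", "organism", "length_bp",
                  "replicon_index"),
    by = "replicon_id"
  )
  if (anyNA(joined$replicon_index)) {
    abort(paste0("feature on replicon without an assigned index: ",
                 joined$replicon_id[which(is.na(joined$replicon_index))[1]]))
  }

  if (is.null(scale)) {
    scale <- if (nrow(joined) == 0) {
      color_scale(0, 0)
    } else {
      color_scale(min(joined$bitscore), max(joined$bitscore))
    }
  }

  gene_len_bp <- joined$end_bp - joined$start_bp + 1L
  subject_len <- if (unit == "protein") gene_len_bp %/% 3L else gene_len_bp
  s_lo <- pmin(joined$s_start, joined$s_end)
  s_hi <- pmax(joined$s_start, joined$s_end)
  if (any(s_lo < 1) || any(s_hi > subject_len)) {
    i <- which(s_lo < 1 | s_hi > subject_len)[1]
    abort(paste0(
      "subject coordinates ", joined$s_start[i], "..", joined$s_end[i],
      " outside subject length ", subject_len[i],
      " for ", joined$subject_id[i]
    ))
  }

  plus <- joined$strand == "+"
  L <- joined$length_bp
  x <- ifelse(
    plus,
    relative_coordinate(joined$start_bp, L, "start"),
    relative_coordinate(joined$end_bp, L, "end")
  )
  vec_mag <- 360 * gene_len_bp / L
  vector_deg <- ifelse(plus, vec_mag, -vec_mag)
  seg_offset_deg <- (s_lo - 1) / subject_len * vec_mag
  seg_len_deg <- (s_hi - s_lo + 1) / subject_len * vec_mag
  col <- bitscore_to_color(joined$bitscore, scale)

  out <- tibble::tibble(
    query_id = joined$query_id,
    subject_id = joined$subject_id,
    organism = joined$organism,
    product = joined$product,
    replicon_id = joined$replicon_id,
    x = x,
    y = joined$replicon_index,
    vector_deg = vector_deg,
    strand = joined$strand,
    seg_offset_deg = seg_offset_deg,
    seg_len_deg = seg_len_deg,
    bitscore = joined$bitscore,
    color_value = col$color_value,
    evalue = joined$evalue,
    s_start = joined$s_start,
    s_end = joined$s_end
  )
  new_blastxy_results(out, replicons = replicons, scale = scale,
                      n_unresolved = n_unresolved,
                      unresolved_ids = unresolved_ids)
}

#' Project hits against whole-replicon subjects (genome database mode)
#'
#' When BLAST runs against whole replicons rather than extracted genes there
#' is no annotation to join: the subject id is the replicon id, `x` comes
#' from the alignment's lower subject coordinate, the vector magnitude is
#' the aligned span, its sign the alignment orientation, and the segment
#' covers the whole vector.
#'
#' @inheritParams project_hits
#' @return A `blastxy_results` tibble, as [project_hits()].
#' @export
project_hits_genome <- function(hits, replicons, scale = NULL) {
  if (!"replicon_index" %in% names(replicons) ||
      all(is.na(replicons$replicon_index))) {
    replicons <- assign_replicon_indices(replicons)
  }
  joined <- dplyr::inner_join(
    dplyr::mutate(hits, .hit_row = dplyr::row_number()),
    dplyr::select(replicons, "replicon_id", "organism", "length_bp",
                  "replicon_index"),
    by = c(subject_id = "replicon_id")
  )
  n_unresolved <- nrow(hits) - nrow(joined)
  unresolved_ids <- setdiff(hits$subject_id, replicons$replicon_id)
  if (n_unresolved > 0) {
    inform(paste0(n_unresolved, " hit(s) on unknown replicon(s)"))
  }
  if (is.null(scale)) {
    scale <- if (nrow(joined) == 0) color_scale(0, 0) else
      color_scale(min(joined$bitscore), max(joined$bitscore))
  }
  s_lo <- pmin(joined$s_start, joined$s_end)
  s_hi <- pmax(joined$s_start, joined$s_end)
  if (any(s_hi > joined$length_bp)) {
    abort("subject coordinates outside replicon length")
  }
  forward <- joined$s_end >= joined$s_start
  L <- joined$length_bp
  vec_mag <- 360 * (s_hi - s_lo + 1) / L
  x <- ifelse(
    forward,
    relative_coordinate(s_lo, L, "start"),
    relative_coordinate(s_hi, L, "end")
  )
  col <- bitscore_to_color(joined$bitscore, scale)
  out <- tibble::tibble(
    query_id = joined$query_id,
    subject_id = joined$subject_id,
    organism = joined$organism,
    product = "",
    replicon_id = joined$subject_id,
    x = x,
    y = joined$replicon_index,
    vector_deg = ifelse(forward, vec_mag, -vec_mag),
    strand = ifelse(forward, "+", "-"),
    seg_offset_deg = 0,
    seg_len_deg = vec_mag,
    bitscore = joined$bitscore,
    color_value = col$color_value,
    evalue = joined$evalue,
    s_start = joined$s_start,
    s_end = joined$s_end
  )
  new_blastxy_results(out, replicons = replicons, scale = scale,
                      n_unresolved = n_unresolved,
                      unresolved_ids = unresolved_ids)
}

new_blastxy_results <- function(tbl, replicons = NULL, scale = NULL,
                                n_unresolved = 0L,
                                unresolved_ids = character()) {
  structure(
    tbl,
    replicons = replicons,
    scale = scale,
    n_unresolved = n_unresolved,
    unresolved_ids = unresolved_ids,
    class = c("blastxy_results", class(tibble::as_tibble(tbl)))
  )
}
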