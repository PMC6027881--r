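#' Configure a job
#'
#' Mirrors the job form of the original web tool: a title, the query or a
#' precomputed hit file, the annotation, the BLAST flavour, and the caps.
#' When both a query FASTA and a hits file are given, the hits file wins
#' (no silent re-BLAST).
#'
#' @param job_title Job title; sanitized into the output-file prefix.
#' @param hits_path Precomputed BLAST tabular file (outfmt 6/7).
#' @param query_fasta Query FASTA; used only when `hits_path` is absent and
#'   BLAST binaries are installed.
#' @param subject_fasta Subject FASTA for the optional local BLAST run.
#' @param gff_path,replicon_path Annotation inputs (see
#'   [read_annotation()]). Not needed for `blast_type = "genomes"`.
#' @param blast_type `"genes"`, `"proteins"` or `"genomes"` -- the database
#'   flavour searched. `genes`/`proteins` join hits to annotated features;
#'   `genomes` maps whole-replicon subjects directly.
#' @param evalue_cutoff Significance cutoff; hits above it are dropped
#'   (default 1e-08).
#' @param max_results Cap applied right after parsing (default 30,000).
#' @param display_cap Maximum results rendered at once (default 50,000).
#' @param raw_cap Maximum results exported raw (default 1,000,000).
#' @param filters Filters for the `*_Sorted_Scored` export (see
#'   [filter_results()]).
#' @param out_dir Output directory for the job folder.
#' @return A `blastxy_job_config` object.
#' @export
job_config <- function(job_title, hits_path = NULL, query_fasta = NULL,
                       subject_fasta = NULL,
                       gff_path = NULL, replicon_path = NULL,
                       blast_type = c("genes", "proteins", "genomes"),
                       evalue_cutoff = 1e-08, max_results = 30000,
                       display_cap = 50000, raw_cap = 1000000,
                       filters = NULL, out_dir = tempfile("job")) {
  blast_type <- match.arg(blast_type)
  if (evalue_cutoff <= 0) abort("evalue_cutoff must be > 0")
  for (cap in c(max_results, display_cap, raw_cap)) {
    if (!is.numeric(cap) || cap < 1) abort("caps must be >= 1")
  }
  if (is.null(hits_path) && is.null(query_fasta)) {
    abort("either hits_path or query_fasta is required")
  }
  structure(
    list(job_title = job_title, hits_path = hits_path,
         query_fasta = query_fasta, subject_fasta = subject_fasta,
         gff_path = gff_path, replicon_path = replicon_path,
         blast_type = blast_type, evalue_cutoff = evalue_cutoff,
         max_results = max_results, display_cap = display_cap,
         raw_cap = raw_cap, filters = as_filter_list(filters),
         out_dir = out_dir),
    class = "blastxy_job_config"
  )
}

title_prefix <- function(title) {
  gsub("[^A-Za-z0-9._-]+", "_", trimws(title))
}

#' Run a complete job
#'
#' Parses the hits (or runs local BLAST), joins them to the annotation,
#' projects onto the 0-360 axis, applies the e-value cutoff and the raw,
#' result and display caps, applies filters, and writes the output bundle
#' into the job folder: `<title>_Sorted.tsv` (raw, canonical order),
#' `<title>_Sorted_Scored.tsv` (filtered), `<title>_results.json`,
#' `graph.html` (interactive), `graph.svg` (static) and `table.html`, plus
#' `run_log.txt` with the pipeline counts. A failed run removes the
#' partially written folder.
#'
#' @param config A [job_config()].
#' @return A `blastxy_job` object: `config`, `results` (displayed rows),
#'   `raw_results`, `log` (named counts), `paths` (artifact paths).
#' @export
run_job <- function(config) {
  stopifnot(inherits(config, "blastxy_job_config"))
  for (p in c(config$hits_path, config$gff_path, config$replicon_path,
              config$query_fasta, config$subject_fasta)) {
    if (!is.null(p) && !file.exists(p)) {
      abort(paste0("input file not found: ", p))
    }
  }
  created <- !dir.exists(config$out_dir)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- FALSE
  if (created) {
    on.exit(if (!ok) unlink(config$out_dir, recursive = TRUE), add = TRUE)
  }

  unit <- if (config$blast_type == "proteins") "protein" else "nucleotide"
  hits_path <- config$hits_path
  if (is.null(hits_path)) {
    hits_path <- run_blast(
      config$query_fasta, config$subject_fasta,
      program = switch(config$blast_type, genes = "blastn",
                       proteins = "blastp", genomes = "blastn"),
      evalue_cutoff = config$evalue_cutoff,
      max_results = config$max_results
    )
  }
  hits <- read_blast_tabular(hits_path, unit = unit)
  n_parsed <- nrow(hits)
  hits <- hits[hits$evalue <= config$evalue_cutoff, , drop = FALSE]
  n_cutoff <- nrow(hits)
  if (nrow(hits) > config$max_results) {
    hits <- canonical_order_hits(hits)[seq_len(config$max_results), ]
  }

  if (config$blast_type == "genomes") {
    if (is.null(config$replicon_path)) {
      abort("replicon_path is required for genome mode")
    }
    replicons <- assign_replicon_indices(read_replicon_metadata(config$replicon_path))
    projected <- project_hits_genome(hits, replicons)
  } else {
    if (is.null(config$gff_path) || is.null(config$replicon_path)) {
      abort("gff_path and replicon_path are required for gene/protein mode")
    }
    ann <- read_annotation(config$gff_path, config$replicon_path)
    replicons <- assign_replicon_indices(ann$replicons)
    projected <- project_hits(hits, ann$features, replicons, unit = unit)
  }
  n_resolved <- nrow(projected)
  n_unresolved <- attr(projected, "n_unresolved")

  raw <- apply_result_cap(projected, config$raw_cap)
  raw <- new_blastxy_results(raw, replicons = replicons,
                             scale = attr(projected, "scale"))
  filtered <- filter_results(raw, config$filters)
  if (nrow(filtered) == 0 && n_resolved > 0) {
    warn("active filters retain 0 results")
  }
  displayed <- apply_result_cap(filtered, config$display_cap)
  displayed <- new_blastxy_results(displayed, replicons = replicons,
                                   scale = attr(projected, "scale"))

  prefix <- title_prefix(config$job_title)
  paths <- list(
    sorted = file.path(config$out_dir, paste0(prefix, "_Sorted.tsv")),
    sorted_scored = file.path(config$out_dir, paste0(prefix, "_Sorted_Scored.tsv")),
    json = file.path(config$out_dir, paste0(prefix, "_results.json")),
    graph_html = file.path(config$out_dir, "graph.html"),
    graph_svg = file.path(config$out_dir, "graph.svg"),
    table_html = file.path(config$out_dir, "table.html"),
    log = file.path(config$out_dir, "run_log.txt")
  )
  parameters <- list(
    blast_type = config$blast_type, evalue_cutoff = config$evalue_cutoff,
    max_results = config$max_results, display_cap = config$display_cap,
    raw_cap = config$raw_cap
  )
  write_table_tsv(raw, paths$sorted, "sorted_raw")
  write_table_tsv(raw, paths$sorted_scored, "sorted_scored",
                  filters = config$filters)
  write_results_json(raw, paths$json, job_title = config$job_title,
                     parameters = parameters, replicons = replicons)
  render_interactive(displayed, view_spec(), paths$graph_html,
                     display_cap = config$display_cap,
                     title = config$job_title)
  render_static(displayed, view_spec(y_range = c(1, max(1, nrow(replicons)))),
                paths$graph_svg)
  render_table_html(displayed, paths$table_html, title = config$job_title)

  log <- c(
    parsed = n_parsed,
    passed_evalue_cutoff = n_cutoff,
    resolved = n_resolved,
    unresolved = n_unresolved,
    raw_exported = nrow(raw),
    filtered = nrow(filtered),
    displayed = nrow(displayed)
  )
  writeLines(paste(names(log), log, sep = "\t"), paths$log)
  ok <- TRUE
  structure(
    list(config = config, results = displayed, raw_results = raw,
         replicons = replicons, log = as.list(log), paths = paths),
    class = "blastxy_job"
  )
}

# significance ordering for raw hits (before projection)
canonical_order_hits <- function(hits) {
  dplyr::arrange(hits, dplyr::desc(.data$bitscore), .data$evalue)
}

#' @export
print.blastxy_job <- function(x, ...) {
  cat("blastxy job: ", x$config$job_title, "\n", sep = "")
  cat("  replicons: ", nrow(x$replicons), "\n", sep = "")
  counts <- unlist(x$log)
  cat(paste0("  ", names(counts), ": ", counts, collapse = "\n"), "\n")
  cat("  folder: ", x$config$out_dir, "\n", sep = "")
  invisible(x)
}

#' Tidy a job into its displayed result rows
#'
#' @param x A `blastxy_job`.
#' @param ... Unused.
#' @return The displayed plotted-result tibble.
#' @method tidy blastxy_job
#' @export
tidy.blastxy_job <- function(x, ...) {
  tibble::as_tibble(x$results)
}

#' One-row summary of a job's pipeline counts
#'
#' @param x A `blastxy_job`.
#' @param ... Unused.
#' @return A one-row tibble: job title, replicon count and the run-log
#'   counts (parsed, resolved, unresolved, raw_exported, filtered,
#'   displayed).
#' @method glance blastxy_job
#' @export
glance.blastxy_job <- function(x, ...) {
  tibble::as_tibble(c(
    list(job_title = x$config$job_title, n_replicons = nrow(x$replicons)),
    x$log
  ))
}

#' @rdname autoplot.blastxy_results
#' @method autoplot blastxy_job
#' @export
autoplot.blastxy_job <- function(object, view = NULL, ...) {
  autoplot.blastxy_results(object$results, view = view, ...)
}
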