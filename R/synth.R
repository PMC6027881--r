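#' Describe a synthetic genome set
#'
#' Captures the shape of a simulated multi-organism genome collection:
#' organisms, replicons per organism (with lengths and topologies), genes
#' per replicon and the mean gene length. All randomness is driven by the
#' mandatory seed, so identical specs give byte-identical files.
#'
#' @param n_organisms Number of organisms.
#' @param replicons_per_organism Replicons per organism.
#' @param replicon_length_bp Replicon length(s) in bp, recycled across
#'   replicons within an organism.
#' @param genes_per_replicon Genes placed on each replicon.
#' @param mean_gene_length_bp Mean gene length in bp (gene lengths are
#'   drawn uniformly between half and one-and-a-half times this).
#' @param organism_names Optional explicit organism names; defaults to
#'   `Organism_01 ...`.
#' @param topology `"circular"` or `"linear"`, recycled.
#' @param seed Integer seed (mandatory; no global RNG state is touched).
#' @return A `genome_sim_spec` list.
#' @export
genome_sim_spec <- function(n_organisms = 1, replicons_per_organism = 1,
                            replicon_length_bp = 1e5,
                            genes_per_replicon = 50,
                            mean_gene_length_bp = 900,
                            organism_names = NULL,
                            topology = "circular",
                            seed) {
  if (missing(seed)) abort("seed is mandatory")
  if (n_organisms < 1 || replicons_per_organism < 1 ||
      any(genes_per_replicon < 1) || any(replicon_length_bp < 1)) {
    abort("all counts and lengths must be >= 1")
  }
  if (is.null(organism_names)) {
    organism_names <- sprintf("Organism_%02d", seq_len(n_organisms))
  }
  if (length(organism_names) != n_organisms) {
    abort("organism_names must have length n_organisms")
  }
  structure(
    list(
      n_organisms = as.integer(n_organisms),
      replicons_per_organism = as.integer(replicons_per_organism),
      replicon_length_bp = as.integer(replicon_length_bp),
      genes_per_replicon = as.integer(genes_per_replicon),
      mean_gene_length_bp = as.integer(mean_gene_length_bp),
      organism_names = organism_names,
      topology = topology,
      seed = as.integer(seed)
    ),
    class = "genome_sim_spec"
  )
}

# non-overlapping placement: sorted random starts, re-drawn until feasible
place_genes <- function(n, lengths, L, max_tries = 200) {
  if (sum(lengths + 1) > L) {
    abort(paste0("infeasible packing: ", n, " genes totalling ",
                 sum(lengths), " bp cannot fit a ", L, " bp replicon"))
  }
  for (i in seq_len(max_tries)) {
    starts <- sort(sample.int(L - max(lengths), n))
    ends <- starts + lengths - 1L
    if (all(starts[-1] > ends[-n] + 1) || n == 1) {
      return(list(start = starts, end = ends))
    }
  }
  # deterministic fallback: evenly spaced
  gap <- (L - sum(lengths)) %/% (n + 1)
  starts <- cumsum(c(gap + 1L, lengths[-n] + gap))
  list(start = as.integer(starts), end = as.integer(starts + lengths - 1L))
}

#' Generate a synthetic annotated genome set
#'
#' Writes a GFF3 annotation file and a replicon metadata TSV emulating the
#' inputs a real job would take, and returns the parsed tibbles. Strands
#' are assigned at random; genes never overlap. Members of planted clusters
#' get a role-tagged product, a shared strand, and operon-like geometry
#' (consecutive genes separated by ~50 bp) so the cluster is a genuine
#' tight run on the replicon.
#'
#' Deterministic: the same spec (including seed) produces byte-identical
#' files.
#'
#' @param spec A [genome_sim_spec()].
#' @param dir Output directory (created if needed).
#' @param planted Optional list of planted-cluster descriptors, each a list
#'   with `replicon_id`, `first_gene` (1-based gene index on that
#'   replicon), `n_genes`, and `tag` (product label prefix).
#' @return A list: `replicons` and `features` tibbles (as
#'   [read_annotation()]), plus `gff_path` and `replicon_tsv_path`.
#' @export
generate_genome <- function(spec, dir = tempfile("genome"), planted = NULL) {
  stopifnot(inherits(spec, "genome_sim_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  withr::with_seed(spec$seed, {
    reps <- list()
    feats <- list()
    for (o in seq_len(spec$n_organisms)) {
      for (r in seq_len(spec$replicons_per_organism)) {
        rid <- sprintf("%s_rep%02d", gsub("[^A-Za-z0-9_]", "_",
                                          spec$organism_names[o]), r)
        L <- spec$replicon_length_bp[((r - 1) %% length(spec$replicon_length_bp)) + 1]
        topo <- spec$topology[((r - 1) %% length(spec$topology)) + 1]
        n_genes <- spec$genes_per_replicon[((r - 1) %% length(spec$genes_per_replicon)) + 1]
        lens <- as.integer(round(stats::runif(
          n_genes, 0.5 * spec$mean_gene_length_bp,
          1.5 * spec$mean_gene_length_bp
        )))
        pos <- place_genes(n_genes, lens, L)
        strand <- sample(c("+", "-"), n_genes, replace = TRUE)
        reps[[rid]] <- tibble::tibble(
          replicon_id = rid, organism = spec$organism_names[o],
          length_bp = L, topology = topo
        )
        feats[[rid]] <- tibble::tibble(
          replicon_id = rid,
          feature_id = sprintf("%s_g%04d", rid, seq_len(n_genes)),
          start_bp = pos$start, end_bp = pos$end, strand = strand,
          locus_tag = sprintf("%s_g%04d", rid, seq_len(n_genes)),
          product = "hypothetical protein",
          wraps_origin = FALSE
        )
      }
    }
    replicons <- dplyr::bind_rows(reps)
    features <- dplyr::bind_rows(feats)

    for (pc in planted %||% list()) {
      idx <- which(features$replicon_id == pc$replicon_id)
      if (length(idx) == 0) abort(paste0("unknown replicon ", pc$replicon_id))
      take <- idx[seq(pc$first_gene, length.out = pc$n_genes)]
      if (anyNA(take) || max(pc$first_gene + pc$n_genes - 1) > length(idx)) {
        abort("planted cluster extends beyond the genes on its replicon")
      }
      features$product[take] <- sprintf("%s cluster protein %d", pc$tag,
                                        seq_len(pc$n_genes))
      # operon-like geometry: compact the cluster genes into a tight run
      # (~50 bp intergenic gaps). Compacting only shrinks the span, so the
      # block cannot collide with the next gene.
      if (length(take) > 1) {
        lens <- features$end_bp[take] - features$start_bp[take] + 1L
        starts <- features$start_bp[take[1]] +
          cumsum(c(0L, lens[-length(lens)] + 50L))
        features$start_bp[take] <- starts
        features$end_bp[take] <- starts + lens - 1L
        features$strand[take] <- features$strand[take[1]]
      }
    }

    gff_path <- file.path(dir, "annotation.gff3")
    tsv_path <- file.path(dir, "replicons.tsv")
    gff <- c(
      "##gff-version 3",
      sprintf(
        "%s\tblastxy_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;locus_tag=%s;product=%s",
        features$replicon_id, features$start_bp, features$end_bp,
        features$strand, features$feature_id, features$locus_tag,
        gsub(";", "%3B", features$product)
      )
    )
    writeLines(gff, gff_path)
    writeLines(
      sprintf("%s\t%d\t%s\t%s", replicons$replicon_id, replicons$length_bp,
              replicons$organism, replicons$topology),
      tsv_path
    )
    replicons$replicon_index <- NA_integer_
    list(replicons = replicons, features = features,
         gff_path = gff_path, replicon_tsv_path = tsv_path)
  })
}

#' Describe a synthetic BLAST hit set
#'
#' Planted clusters emit one strong hit per (query, consecutive gene) pair
#' -- the signature of a conserved operon such as a four-gene bacteriocin
#' locus -- over a sparse background of weak hits. Bit scores are uniform
#' in `[200, 400]` for planted and `[40, 80]` for background hits, with
#' e-value `10^(-bitscore/10)` as a monotone stand-in; the pipeline needs
#' ordering, not BLAST statistics.
#'
#' @param query_names Query header names.
#' @param hit_rate Probability of a background hit per (query, gene) pair.
#' @param planted_clusters List of descriptors: `replicon_id`,
#'   `first_gene`, `queries` (character vector mapped in order onto
#'   consecutive genes).
#' @param bitscore_planted,bitscore_background Length-2 uniform ranges.
#' @param seed Integer seed (mandatory).
#' @return A `hit_sim_spec` list.
#' @export
hit_sim_spec <- function(query_names, hit_rate = 0.001,
                         planted_clusters = list(),
                         bitscore_planted = c(200, 400),
                         bitscore_background = c(40, 80),
                         seed) {
  if (missing(seed)) abort("seed is mandatory")
  if (hit_rate < 0 || hit_rate > 1) abort("hit_rate must be in [0, 1]")
  structure(
    list(query_names = query_names, hit_rate = hit_rate,
         planted_clusters = planted_clusters,
         bitscore_planted = bitscore_planted,
         bitscore_background = bitscore_background,
         seed = as.integer(seed)),
    class = "hit_sim_spec"
  )
}

#' Simulate a BLAST tabular hit file against a synthetic genome
#'
#' @param genome Output of [generate_genome()] (or a list with `replicons`
#'   and `features` tibbles).
#' @param spec A [hit_sim_spec()].
#' @param path Output path for the outfmt-6 file.
#' @return `path` invisibly, with attributes `n_planted` and
#'   `n_background`.
#' @export
simulate_hits <- function(genome, spec, path = tempfile(fileext = ".tsv")) {
  stopifnot(inherits(spec, "hit_sim_spec"))
  features <- genome$features
  withr::with_seed(spec$seed, {
    planted <- list()
    for (pc in spec$planted_clusters) {
      idx <- which(features$replicon_id == pc$replicon_id)
      if (length(idx) == 0) abort(paste0("unknown replicon ", pc$replicon_id))
      k <- length(pc$queries)
      if (pc$first_gene + k - 1 > length(idx)) {
        abort("planted cluster references genes beyond its replicon")
      }
      genes <- features[idx[seq(pc$first_gene, length.out = k)], ]
      glen <- genes$end_bp - genes$start_bp + 1L
      bs <- stats::runif(k, spec$bitscore_planted[1], spec$bitscore_planted[2])
      planted[[length(planted) + 1]] <- tibble::tibble(
        query_id = pc$queries,
        subject_id = genes$feature_id,
        pct_identity = round(stats::runif(k, 80, 100), 2),
        aln_length = glen,
        mismatches = 0L, gap_opens = 0L,
        q_start = 1L, q_end = glen,
        s_start = 1L, s_end = glen,
        evalue = 10^(-bs / 10),
        bitscore = round(bs, 1)
      )
    }
    n_feat <- nrow(features)
    background <- list()
    if (spec$hit_rate > 0 && n_feat > 0 && length(spec$query_names) > 0) {
      for (q in spec$query_names) {
        hit <- which(stats::runif(n_feat) < spec$hit_rate)
        if (length(hit) == 0) next
        genes <- features[hit, ]
        glen <- genes$end_bp - genes$start_bp + 1L
        # partial alignments somewhere inside the subject
        alen <- pmax(30L, as.integer(round(glen * stats::runif(length(hit), 0.2, 0.8))))
        smax <- pmax(1L, glen - alen + 1L)
        s0 <- as.integer(1 + floor(stats::runif(length(hit)) * smax))
        bs <- stats::runif(length(hit), spec$bitscore_background[1],
                           spec$bitscore_background[2])
        background[[length(background) + 1]] <- tibble::tibble(
          query_id = q,
          subject_id = genes$feature_id,
          pct_identity = round(stats::runif(length(hit), 60, 85), 2),
          aln_length = alen,
          mismatches = as.integer(round(alen * 0.2)), gap_opens = 0L,
          q_start = 1L, q_end = alen,
          s_start = s0, s_end = pmin(glen, s0 + alen - 1L),
          evalue = 10^(-bs / 10),
          bitscore = round(bs, 1)
        )
      }
    }
    hits <- dplyr::bind_rows(c(planted, background))
    if (nrow(hits) == 0) {
      file.create(path)
    } else {
      write_blast_tabular(hits, path)
    }
    out <- invisible(path)
    attr(out, "n_planted") <- sum(vapply(planted, nrow, integer(1)))
    attr(out, "n_background") <- sum(vapply(background, nrow, integer(1)))
    out
  })
}

# ---- optional wrapper over locally installed BLAST ------------------------

#' Build the command lines for a local BLAST run
#'
#' Pure helper behind [run_blast()]: returns the `makeblastdb` and search
#' program argument vectors without executing anything, so parameter
#' forwarding (the default e-value cutoff of 1e-08, the default result cap
#' of 30000) is testable without binaries.
#'
#' @param query_fasta,subject_fasta Input FASTA paths.
#' @param program `"blastn"`, `"blastp"` or `"tblastn"`.
#' @param evalue_cutoff E-value threshold (default 1e-08).
#' @param max_results Maximum target sequences (default 30000).
#' @param db Database prefix path.
#' @param out Output path for the tabular results.
#' @return A list with `makeblastdb` and `search` character vectors
#'   (program + args).
#' @export
blast_command <- function(query_fasta, subject_fasta,
                          program = c("blastn", "blastp", "tblastn"),
                          evalue_cutoff = 1e-08, max_results = 30000,
                          db = tempfile("blastdb"), out = tempfile(fileext = ".tsv")) {
  program <- match.arg(program)
  dbtype <- if (program == "blastp") "prot" else "nucl"
  list(
    makeblastdb = c("makeblastdb", "-in", subject_fasta, "-dbtype", dbtype,
                    "-out", db),
    search = c(program, "-query", query_fasta, "-db", db,
               "-outfmt", "6", "-evalue", format(evalue_cutoff, scientific = TRUE),
               "-max_target_seqs", format(max_results, scientific = FALSE),
               "-out", out),
    out = out
  )
}

#' Run a local BLAST search into outfmt 6
#'
#' Optional convenience wrapper over locally installed NCBI BLAST+
#' binaries: builds a database from the subject FASTA and runs the chosen
#' program with `-outfmt 6`. Absent binaries give a clear
#' "blast not installed" error, distinguishable from a BLAST runtime
#' failure.
#'
#' @inheritParams blast_command
#' @return Path of the outfmt-6 output file.
#' @export
run_blast <- function(query_fasta, subject_fasta,
                      program = c("blastn", "blastp", "tblastn"),
                      evalue_cutoff = 1e-08, max_results = 30000,
                      out = tempfile(fileext = ".tsv")) {
  program <- match.arg(program)
  if (Sys.which("makeblastdb") == "" || Sys.which(program) == "") {
    abort("blast not installed")
  }
  cmd <- blast_command(query_fasta, subject_fasta, program,
                       evalue_cutoff, max_results, out = out)
  run1 <- function(argv) {
    res <- suppressWarnings(system2(argv[1], argv[-1], stdout = TRUE, stderr = TRUE))
    status <- attr(res, "status") %||% 0L
    if (status != 0) {
      abort(paste0(argv[1], " failed (exit ", status, "): ",
                   paste(res, collapse = "\n")))
    }
  }
  run1(cmd$makeblastdb)
  run1(cmd$search)
  cmd$out
}
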