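test_that("relative coordinates pin the axis: start(1) = 0, end(L) = 360, midpoint = 180", {
  for (L in c(1, 1234567, 4641652)) {
    expect_identical(relative_coordinate(1, L, "start"), 0)
    expect_identical(relative_coordinate(L, L, "end"), 360)
  }
  expect_identical(relative_coordinate(2000000, 4000000, "end"), 180)
})

test_that("relative_coordinate is monotone and measure-preserving", {
  withr::with_seed(42, {
    for (L in c(17, 1000, 999983)) {
      pos <- sort(sample.int(L, min(L, 200)))
      s <- relative_coordinate(pos, L, "start")
      e <- relative_coordinate(pos, L, "end")
      expect_true(all(diff(s) > 0))  # strictly increasing across bases
      expect_true(all(diff(e) > 0))
      expect_true(all(e > s))        # a base has positive degree width
      expect_equal(e - s, rep(360 / L, length(pos)), tolerance = 1e-9)
    }
  })
})

test_that("positions beyond L (origin wrap) reduce modulo the replicon length", {
  expect_equal(relative_coordinate(5200, 5000, "end"),
               relative_coordinate(200, 5000, "end"))
  expect_error(relative_coordinate(0, 100), "pos_bp")
  expect_error(relative_coordinate(5, 0), "replicon_length_bp")
})

test_that("replicon indices are 1..N, gap-free, in the canonical order", {
  one <- tibble::tibble(replicon_id = "c1", organism = "X", length_bp = 100L)
  expect_equal(assign_replicon_indices(one)$replicon_index, 1L)

  reps <- tibble::tibble(
    replicon_id = c("b_chr", "b_pls", "a_chr", "a_pls"),
    organism = c("Org_B", "Org_B", "Org_A", "Org_A"),
    length_bp = c(4000000L, 100000L, 3000000L, 50000L)
  )
  out <- assign_replicon_indices(reps)
  expect_equal(out$replicon_index, 1:4)
  # organisms alphabetical; within one, the chromosome (longest) first
  expect_equal(out$replicon_id, c("a_chr", "a_pls", "b_chr", "b_pls"))
  expect_error(assign_replicon_indices(reps[c(1, 1, 2), ]), "duplicate")
})

test_that("canonical replicon order is stable across shuffled input", {
  reps <- tibble::tibble(
    replicon_id = sprintf("r%02d", 1:8),
    organism = rep(c("OrgA", "OrgB"), each = 4),
    length_bp = as.integer(c(5e6, 2e5, 2e5, 1e4, 7e6, 3e5, 1e5, 1e5))
  )
  a <- assign_replicon_indices(reps)
  b <- assign_replicon_indices(reps[withr::with_seed(3, sample(8)), ])
  expect_equal(a, b)
})

test_that("bitscore colour scale endpoints and monotonicity", {
  sc <- color_scale(40, 400)
  top <- bitscore_to_color(400, sc)
  bot <- bitscore_to_color(40, sc)
  expect_equal(top$color_value, 1)
  expect_equal(c(top$r, top$g, top$b), c(0, 0, 139))   # dark blue, most significant
  expect_equal(bot$color_value, 0)
  expect_equal(c(bot$r, bot$g, bot$b), c(255, 255, 0)) # yellow, least
  # monotone in bitscore, clipped outside the scale
  bs <- seq(0, 500, by = 7)
  v <- bitscore_to_color(bs, sc)$color_value
  expect_true(all(diff(v) >= 0))
  expect_true(all(v >= 0 & v <= 1))
  # idempotent under re-scaling with the same endpoints
  expect_equal(bitscore_to_color(bs, sc), bitscore_to_color(bs, sc))
  expect_error(bitscore_to_color(NaN, sc), "finite")
})

test_that("a degenerate scale (all bitscores equal) maps everything to dark blue", {
  sc <- color_scale(262, 262)
  col <- bitscore_to_color(c(262, 262), sc)
  expect_equal(col$color_value, c(1, 1))
  expect_equal(col$hex, rep("#00008B", 2))
})

test_that("project_hits reproduces the worked plus/minus-strand example", {
  reps <- tibble::tibble(replicon_id = "R", organism = "Org",
                         length_bp = 360000L)
  feats <- tibble::tibble(
    replicon_id = "R", feature_id = c("gp", "gm"),
    start_bp = c(1L, 1L), end_bp = c(1000L, 1000L),
    strand = c("+", "-"), locus_tag = "", product = "p",
    wraps_origin = FALSE
  )
  hits <- tibble::tibble(
    query_id = "q", subject_id = c("gp", "gm"), pct_identity = 99,
    aln_length = 500L, mismatches = 0L, gap_opens = 0L,
    q_start = 1L, q_end = 500L, s_start = 101L, s_end = 600L,
    evalue = 1e-30, bitscore = c(200, 100)
  )
  res <- project_hits(hits, feats, reps)
  # 1000 bp gene on a 360 kb replicon spans exactly 1 degree
  expect_equal(abs(res$vector_deg), c(1, 1), tolerance = 1e-12)
  # + strand: dot at the start boundary of base 1; vector positive
  expect_equal(res$x[1], 0)
  expect_equal(res$vector_deg[1], 1)
  # - strand: dot at the end boundary of base 1000; vector negative
  expect_equal(res$x[2], relative_coordinate(1000, 360000, "end"))
  expect_equal(res$vector_deg[2], -1)
  # alignment 101..600 of a 1000 bp subject: offset 0.1 deg, span 0.5 deg
  expect_equal(res$seg_offset_deg, c(0.1, 0.1), tolerance = 1e-12)
  expect_equal(res$seg_len_deg, c(0.5, 0.5), tolerance = 1e-12)
  # colour: higher bitscore is the dark-blue end
  expect_equal(res$color_value, c(1, 0))
})

test_that("a full-span alignment covers the whole vector", {
  reps <- tibble::tibble(replicon_id = "R", organism = "O", length_bp = 10000L)
  feats <- tibble::tibble(replicon_id = "R", feature_id = "g",
                          start_bp = 501L, end_bp = 1500L, strand = "+",
                          locus_tag = "", product = "", wraps_origin = FALSE)
  hits <- tibble::tibble(query_id = "q", subject_id = "g", pct_identity = 100,
                         aln_length = 1000L, mismatches = 0L, gap_opens = 0L,
                         q_start = 1L, q_end = 1000L, s_start = 1L,
                         s_end = 1000L, evalue = 0, bitscore = 500)
  res <- project_hits(hits, feats, reps)
  expect_equal(res$seg_offset_deg, 0)
  expect_equal(res$seg_len_deg, abs(res$vector_deg), tolerance = 1e-12)
})

test_that("projected segments match an independent integer-arithmetic oracle", {
  g <- generate_genome(genome_sim_spec(n_organisms = 2, genes_per_replicon = 40,
                                       seed = 77))
  h <- simulate_hits(g, hit_sim_spec(paste0("q", 1:5), hit_rate = 0.3, seed = 78))
  hits <- read_blast_tabular(h)
  res <- project_hits(hits, g$features, assign_replicon_indices(g$replicons))
  expect_equal(nrow(res), nrow(hits)) # every resolvable hit, exactly once

  # brute force per hit: integer bp arithmetic then one division
  feat <- g$features
  reps <- assign_replicon_indices(g$replicons)
  for (i in seq_len(nrow(hits))) {
    f <- feat[feat$feature_id == hits$subject_id[i], ]
    L <- reps$length_bp[reps$replicon_id == f$replicon_id]
    glen <- f$end_bp - f$start_bp + 1L
    s0 <- min(hits$s_start[i], hits$s_end[i])
    s1 <- max(hits$s_start[i], hits$s_end[i])
    expect_equal(res$seg_offset_deg[i],
                 360 * glen / L * ((s0 - 1) / glen), tolerance = 1e-9)
    expect_equal(res$seg_len_deg[i],
                 360 * glen / L * ((s1 - s0 + 1) / glen), tolerance = 1e-9)
    expect_equal(abs(res$vector_deg[i]), 360 * glen / L, tolerance = 1e-9)
    expect_equal(res$y[i], reps$replicon_index[reps$replicon_id == f$replicon_id])
  }
})

test_that("segment invariants hold on simulated data", {
  g <- generate_genome(genome_sim_spec(genes_per_replicon = 60, seed = 5))
  h <- simulate_hits(g, hit_sim_spec(paste0("q", 1:8), hit_rate = 0.4, seed = 6))
  res <- project_hits(read_blast_tabular(h), g$features,
                      assign_replicon_indices(g$replicons))
  expect_true(all(res$seg_offset_deg >= 0))
  expect_true(all(res$seg_len_deg <= abs(res$vector_deg) + 1e-9))
  expect_true(all(res$seg_offset_deg + res$seg_len_deg <=
                    abs(res$vector_deg) + 1e-9))
  expect_true(all(res$x >= 0 & res$x <= 360))
})

test_that("features tiling a replicon sum to 360 vector degrees", {
  L <- 12345L
  cuts <- withr::with_seed(8, c(0L, sort(sample.int(L - 1, 30)), L))
  lens <- diff(cuts)
  expect_equal(sum(360 * lens / L), 360, tolerance = 1e-6)
})

test_that("unresolvable subjects are counted, not dropped; locus_tag is a fallback", {
  ann <- tiny_annotation()
  parsed <- read_annotation(ann$gff, ann$tsv)
  reps <- assign_replicon_indices(parsed$replicons)
  hits <- tibble::tibble(
    query_id = c("a", "b", "c"),
    subject_id = c("g1", "LT_0002", "nosuch"),
    pct_identity = 99, aln_length = 50L, mismatches = 0L, gap_opens = 0L,
    q_start = 1L, q_end = 50L, s_start = 1L, s_end = 50L,
    evalue = 1e-10, bitscore = 100
  )
  expect_message(res <- project_hits(hits, parsed$features, reps),
                 "unresolvable")
  expect_equal(nrow(res), 2) # g1 direct, LT_0002 via locus_tag
  expect_equal(attr(res, "n_unresolved"), 1)
  expect_equal(attr(res, "unresolved_ids"), "nosuch")
})

test_that("subject coordinates beyond the subject length error", {
  reps <- tibble::tibble(replicon_id = "R", organism = "O", length_bp = 10000L)
  feats <- tibble::tibble(replicon_id = "R", feature_id = "g",
                          start_bp = 1L, end_bp = 300L, strand = "+",
                          locus_tag = "", product = "", wraps_origin = FALSE)
  hits <- tibble::tibble(query_id = "q", subject_id = "g", pct_identity = 100,
                         aln_length = 400L, mismatches = 0L, gap_opens = 0L,
                         q_start = 1L, q_end = 400L, s_start = 1L,
                         s_end = 400L, evalue = 0, bitscore = 100)
  expect_error(project_hits(hits, feats, reps), "outside subject length")
})

test_that("protein subjects map segments by residue fraction", {
  reps <- tibble::tibble(replicon_id = "R", organism = "O", length_bp = 36000L)
  feats <- tibble::tibble(replicon_id = "R", feature_id = "g",
                          start_bp = 1L, end_bp = 300L, strand = "+",
                          locus_tag = "", product = "", wraps_origin = FALSE)
  # 300 bp gene -> 100 residues; alignment over residues 26..75 = middle half
  hits <- tibble::tibble(query_id = "q", subject_id = "g", pct_identity = 100,
                         aln_length = 50L, mismatches = 0L, gap_opens = 0L,
                         q_start = 1L, q_end = 50L, s_start = 26L,
                         s_end = 75L, evalue = 0, bitscore = 100)
  res <- project_hits(hits, feats, reps, unit = "protein")
  expect_equal(res$seg_offset_deg, 0.25 * abs(res$vector_deg), tolerance = 1e-12)
  expect_equal(res$seg_len_deg, 0.5 * abs(res$vector_deg), tolerance = 1e-12)
})

test_that("genome-database mode projects whole-replicon subjects without a join", {
  reps <- tibble::tibble(replicon_id = "chr1", organism = "O",
                         length_bp = 3600L)
  hits <- tibble::tibble(query_id = "q", subject_id = "chr1",
                         pct_identity = 95, aln_length = 360L,
                         mismatches = 5L, gap_opens = 0L, q_start = 1L,
                         q_end = 360L, s_start = c(1001L, 1360L),
                         s_end = c(1360L, 1001L), evalue = 1e-40,
                         bitscore = 300)
  res <- project_hits_genome(hits, reps)
  expect_equal(res$y, c(1L, 1L))
  expect_equal(abs(res$vector_deg), c(36, 36), tolerance = 1e-12)
  expect_equal(res$vector_deg[2], -36) # reversed coordinates = minus strand
  expect_equal(res$seg_len_deg, abs(res$vector_deg))
  expect_equal(res$x[1], relative_coordinate(1001, 3600, "start"))
  expect_equal(res$x[2], relative_coordinate(1360, 3600, "end"))
})
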