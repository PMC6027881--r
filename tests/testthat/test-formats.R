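test_that("outfmt 6 lines map field-for-field onto hit rows", {
  f <- tiny_hits_file()
  hits <- read_blast_tabular(f)
  expect_equal(nrow(hits), 3)
  expect_equal(hits$query_id[1], "capA")
  expect_equal(hits$subject_id[1], "g1")
  expect_equal(hits$pct_identity[1], 100)
  expect_equal(hits$aln_length[1], 141L)
  expect_equal(hits$evalue[1], 3e-70)
  expect_equal(hits$bitscore[1], 262)
  # the paper-style Capistruin example line
  d <- withr::local_tempdir()
  writeLines("capA\tBTH_II1227\t100.00\t141\t0\t0\t1\t141\t1\t141\t3e-70\t262",
             file.path(d, "cap.tsv"))
  one <- read_blast_tabular(file.path(d, "cap.tsv"))
  expect_equal(one$subject_id, "BTH_II1227")
  expect_equal(one$bitscore, 262)
})

test_that("outfmt 7 comment lines are skipped and comments-only input is empty", {
  d <- withr::local_tempdir()
  f <- file.path(d, "h.tsv")
  writeLines(c("# BLASTN 2.12.0+", "# Query: capA", "# 0 hits found"), f)
  expect_equal(nrow(read_blast_tabular(f)), 0)

  writeLines(c("# BLASTN 2.12.0+",
               "capA\tg1\t100.00\t141\t0\t0\t1\t141\t1\t141\t3e-70\t262"), f)
  expect_equal(nrow(read_blast_tabular(f)), 1)
})

test_that("malformed tabular lines error with the line number", {
  d <- withr::local_tempdir()
  f <- file.path(d, "bad.tsv")
  writeLines("capA\tg1\t100.00\t141\t0\t0\t1\t141\t1\t141\t3e-70", f)
  expect_error(read_blast_tabular(f), "line 1: expected >=12 fields")
  writeLines(c("capA\tg1\t100.00\t141\t0\t0\t1\t141\t1\t141\t3e-70\t262",
               "capB\tg2\tNOTNUM\t141\t0\t0\t1\t141\t1\t141\t3e-70\t262"), f)
  expect_error(read_blast_tabular(f), "line 2")
})

test_that("record conservation: one hit per non-comment line", {
  d <- withr::local_tempdir()
  f <- file.path(d, "mix.tsv")
  body <- sprintf("q%d\ts%d\t99.00\t100\t1\t0\t1\t100\t1\t100\t1e-20\t%d",
                  1:37, 1:37, 100 + 1:37)
  writeLines(c("# comment", body[1:10], "# another", body[11:37]), f)
  expect_equal(nrow(read_blast_tabular(f)), 37)
})

test_that("re-serializing parsed hits preserves all 12 fields (naive-split oracle)", {
  g <- generate_genome(genome_sim_spec(genes_per_replicon = 20, seed = 31))
  h <- simulate_hits(g, hit_sim_spec(paste0("q", 1:4), hit_rate = 0.2, seed = 32))
  hits <- read_blast_tabular(h)
  d <- withr::local_tempdir()
  f2 <- file.path(d, "rt.tsv")
  write_blast_tabular(hits, f2)
  a <- do.call(rbind, strsplit(readLines(h), "\t"))
  b <- do.call(rbind, strsplit(readLines(f2), "\t"))
  expect_equal(dim(a), dim(b))
  # text fields identical, numeric fields equal as numbers
  expect_identical(a[, 1:2], b[, 1:2])
  for (j in 3:12) {
    expect_equal(as.numeric(a[, j]), as.numeric(b[, j]), tolerance = 1e-9)
  }
})

test_that("GFF3 + replicon TSV parse into consistent features and replicons", {
  ann <- tiny_annotation()
  parsed <- read_annotation(ann$gff, ann$tsv)
  expect_equal(nrow(parsed$replicons), 2)
  expect_equal(nrow(parsed$features), 3)
  g1 <- parsed$features[parsed$features$feature_id == "g1", ]
  expect_equal(g1$start_bp, 101L)
  expect_equal(g1$end_bp, 700L)
  expect_equal(g1$strand, "+")
  expect_equal(g1$product, "hypothetical protein")
  # minus-strand feature keeps start <= end with strand preserved
  g2 <- parsed$features[parsed$features$feature_id == "g2", ]
  expect_true(g2$start_bp <= g2$end_bp)
  expect_equal(g2$strand, "-")
})

test_that("annotation errors: unknown replicon, overlong feature; wrap flag works", {
  d <- withr::local_tempdir()
  tsv <- file.path(d, "rep.tsv")
  writeLines("repA\t5000\tOrg\tcircular", tsv)
  gff <- file.path(d, "bad.gff3")
  writeLines(c("##gff-version 3",
               "repZ\tt\tgene\t1\t10\t.\t+\t.\tID=g9"), gff)
  expect_error(read_annotation(gff, tsv), "unknown replicon repZ")

  writeLines(c("##gff-version 3",
               "repA\tt\tgene\t100\t9000\t.\t+\t.\tID=g9"), gff)
  expect_error(read_annotation(gff, tsv), "beyond replicon")

  # origin-spanning circular feature: end < start normalizes with flag
  writeLines(c("##gff-version 3",
               "repA\tt\tgene\t4800\t200\t.\t+\t.\tID=gw"), gff)
  parsed <- read_annotation(gff, tsv)
  expect_true(parsed$features$wraps_origin)
  expect_equal(parsed$features$start_bp, 4800L)
  expect_equal(parsed$features$end_bp, 5200L)
})

test_that("replicon lengths can come from FASTA", {
  d <- withr::local_tempdir()
  fa <- file.path(d, "g.fasta")
  writeLines(c(">repA some organism", strrep("ACGT", 25),
               ">repB", strrep("A", 77)), fa)
  gff <- file.path(d, "a.gff3")
  writeLines(c("##gff-version 3",
               "repA\tt\tgene\t1\t60\t.\t+\t.\tID=g1"), gff)
  parsed <- read_annotation(gff, fa)
  expect_equal(parsed$replicons$length_bp, c(100L, 77L))
})

test_that("results JSON round trip is the identity (property over random tables)", {
  d <- withr::local_tempdir()
  for (seed in 1:100) {
    r <- random_results(sample(1:30, 1), seed = seed)
    p <- file.path(d, "r.json")
    write_results_json(r, p, job_title = "t")
    back <- read_results_json(p)
    expect_equal(tibble::as_tibble(back), tibble::as_tibble(r),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("empty result list round-trips to an empty array", {
  d <- withr::local_tempdir()
  p <- file.path(d, "empty.json")
  r <- random_results(5, seed = 1)[0, ]
  write_results_json(r, p)
  expect_match(paste(readLines(p), collapse = ""), "\"results\":\\[\\]")
  expect_equal(nrow(read_results_json(p)), 0)
})

test_that("JSON with a result missing a field errors naming the field", {
  d <- withr::local_tempdir()
  p <- file.path(d, "r.json")
  write_results_json(random_results(2, seed = 3), p)
  obj <- jsonlite::fromJSON(p, simplifyVector = FALSE)
  obj$results[[1]]$x <- NULL
  jsonlite::write_json(obj, p, auto_unbox = TRUE)
  expect_error(read_results_json(p), "missing field x")
})

test_that("TSV export row counts follow the active variant and filters", {
  r <- random_results(4, seed = 9)
  r$query_id <- c("SSI_HlyD", "SSI_TolC", "SSII_GspC", "other")
  d <- withr::local_tempdir()
  p <- file.path(d, "t.tsv")
  write_table_tsv(r, p, "sorted_raw")
  expect_length(readLines(p), 5) # header + 4

  flt <- filter_spec("Query", "SSI_")
  # by-hand: SSI_HlyD and SSI_TolC contain "SSI_"; SSII_GspC does not
  write_table_tsv(r, p, "sorted_scored", filters = flt)
  expect_length(readLines(p), 3)

  write_table_tsv(r[0, ], p, "sorted_raw")
  expect_length(readLines(p), 1)
})
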