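# Fixture builders shared across test files. Everything is generated in
# code; files only ever land in tempdirs.

# A random but internally consistent plotted-result table.
random_results <- function(n, seed, n_replicons = 3) {
  withr::with_seed(seed, {
    L <- 1e6
    len_bp <- sample(300:3000, n, replace = TRUE)
    start <- sample.int(L - 3000, n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    vec <- 360 * len_bp / L * ifelse(strand == "+", 1, -1)
    y <- sample.int(n_replicons, n, replace = TRUE)
    x <- ifelse(strand == "+",
                360 * (start - 1) / L,
                360 * (start + len_bp - 1) / L)
    frac0 <- runif(n, 0, 0.5)
    frac1 <- runif(n, 0, 1 - frac0)
    bs <- round(runif(n, 40, 400), 1)
    tibble::tibble(
      query_id = paste0("q", sample.int(20, n, replace = TRUE), "_",
                        sample(c("SSI_", "SSII_", "cap"), n, replace = TRUE)),
      subject_id = sprintf("s%05d", seq_len(n)),
      organism = sample(c("Burkholderia_thailandensis", "Burkholderia_gladioli",
                          "Escherichia_coli"), n, replace = TRUE),
      product = sample(c("hypothetical protein", "transporter",
                         "bacteriocin precursor"), n, replace = TRUE),
      replicon_id = paste0("rep", y),
      x = x, y = y, vector_deg = vec, strand = strand,
      seg_offset_deg = frac0 * abs(vec),
      seg_len_deg = frac1 * abs(vec),
      bitscore = bs,
      color_value = (bs - min(bs)) / max(max(bs) - min(bs), 1e-9),
      evalue = 10^(-bs / 10),
      s_start = as.integer(round(frac0 * len_bp) + 1),
      s_end = as.integer(pmin(len_bp, round((frac0 + frac1) * len_bp) + 1))
    )
  })
}

# A tiny two-replicon annotation with hand-chosen coordinates.
tiny_annotation <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  gff <- file.path(dir, "ann.gff3")
  writeLines(c(
    "##gff-version 3",
    "repA\ttest\tgene\t101\t700\t.\t+\t.\tID=g1;locus_tag=LT_0001;product=hypothetical protein",
    "repA\ttest\tgene\t1001\t4000\t.\t-\t.\tID=g2;locus_tag=LT_0002;product=exporter",
    "repB\ttest\tgene\t1\t1000\t.\t+\t.\tID=g3;product=bacteriocin precursor"
  ), gff)
  tsv <- file.path(dir, "rep.tsv")
  writeLines(c(
    "repA\t5000\tOrganism_A\tcircular",
    "repB\t360000\tOrganism_B\tcircular"
  ), tsv)
  list(gff = gff, tsv = tsv)
}

# One outfmt-6 line joined against tiny_annotation().
tiny_hits_file <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                           lines = NULL) {
  path <- file.path(dir, "hits.tsv")
  writeLines(lines %||% c(
    "capA\tg1\t100.00\t141\t0\t0\t1\t141\t1\t141\t3e-70\t262",
    "capB\tg2\t95.00\t300\t10\t2\t1\t300\t501\t800\t1e-50\t180",
    "capC\tg3\t90.00\t500\t30\t5\t1\t500\t101\t600\t1e-30\t120"
  ), path)
  path
}

`%||%` <- rlang::`%||%`

# tag a plain tibble as a blastxy_results object with its natural scale
new_results_for_test <- function(r) {
  blastxy:::new_blastxy_results(
    r, scale = color_scale(min(r$bitscore), max(r$bitscore))
  )
}
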