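# blastxy

Large-scale BLAST searches across whole-genome-sequenced bacteria and
archaea — "is this operon present, complete, and where, in every genome I
care about?" — return tens of thousands to a million hits. blastxy is an R
package for genome miners who run such searches locally and need to *see*
all the results at once: it projects every hit onto a coordinate system in
which gene clusters pop out visually, and provides the spreadsheet-style
sorting, substring filtering, caps and exports needed to drill down from
the full result set to a single gene.

## The method

Circular bacterial replicons (chromosomes and plasmids) are projected as
horizontal lines of **fixed length 360** — the degrees of a circle — so
any replicon occupies the same x extent regardless of its real size. With
`L` the replicon length in bp, base `b` occupies the degree interval
`[360(b−1)/L, 360b/L)`, so the first base starts at exactly 0 and the last
base ends at exactly 360. Each BLAST hit against an annotated gene becomes:

- a **dot** at `(x, y)` — x the *relative position* (degrees) of the
  gene's transcription start, y the replicon index (1..N over the searched
  database);
- a **vector** of signed length `360 · gene_length/L` degrees pointing in
  the transcription sense;
- a thicker **alignment segment** over the vector spanning the aligned
  region, coloured by BLAST bit score from yellow (least significant) to
  dark blue `rgb(0,0,139)` (most significant).

Hits at nearby degrees on one track are candidate operons/gene clusters; a
single-linkage pass (`detect_clusters()`, default 5° window) makes those
runs explicit. Display is capped at 50,000 results (more saturates the
plot); raw exports carry up to 1,000,000.

## Worked example

Simulate two organisms (chromosome + plasmid each), plant a four-gene
capABCD-style bacteriocin locus, simulate a BLAST run of the four queries,
and run the job:

```r
library(blastxy)

g <- generate_genome(
  genome_sim_spec(n_organisms = 2, replicons_per_organism = 2,
                  replicon_length_bp = c(300000, 60000),
                  genes_per_replicon = c(60, 15), seed = 41),
  dir = "genome",
  planted = list(list(replicon_id = "Organism_01_rep01", first_gene = 20,
                      n_genes = 4, tag = "capistruin")))
hits <- simulate_hits(
  g, hit_sim_spec(c("capA", "capB", "capC", "capD"), hit_rate = 0.01,
                  planted_clusters = list(
                    list(replicon_id = "Organism_01_rep01", first_gene = 20,
                         queries = c("capA", "capB", "capC", "capD"))),
                  seed = 42),
  path = "hits.tsv")

job <- run_job(job_config("Search for Capistruin cluster",
                          hits_path = hits, gff_path = g$gff_path,
                          replicon_path = g$replicon_tsv_path,
                          evalue_cutoff = 1, out_dir = "job"))
job
#> blastxy job: Search for Capistruin cluster
#>   replicons: 4
#>   parsed: 15
#>   passed_evalue_cutoff: 15
#>   resolved: 15
#>   unresolved: 0
#>   raw_exported: 15
#>   filtered: 15
#>   displayed: 15
#>   folder: job
```

All 15 simulated hits parse, resolve against the annotation and get
projected; the job folder now contains
`Search_for_Capistruin_cluster_Sorted.tsv` (raw, significance-sorted),
`..._Sorted_Scored.tsv` (filtered), `..._results.json`, `graph.svg`
(static), `graph.html` (interactive, self-contained) and `table.html`.

The three strongest projected results:

```r
tidy(job)[1:3, c("query_id", "subject_id", "x", "y", "vector_deg",
                 "bitscore", "color_value")]
#>   query_id subject_id                  x     y vector_deg bitscore color_value
#> 1 capB     Organism_01_rep01_g0021  119.     1      0.662     387.       1
#> 2 capA     Organism_01_rep01_g0020  118.     1      0.654     383        0.987
#> 3 capD     Organism_01_rep01_g0023  121.     1      0.841     366.       0.938
```

Each is a dot at ~118–121° on replicon track 1 (the genes sit around
position `118/360 × 300000 ≈ 98 kb`), a vector of ~0.7° (the gene length in
degrees, pointing `+`), and a segment coloured near dark blue
(`color_value` ≈ 1: these are the job's most significant bit scores).
Clustering the high-scoring results returns the planted locus intact as a
single four-member cluster at 118–121°:

```r
detect_clusters(tidy(job)[tidy(job)$bitscore > 150, ])[, 1:5]
#>   replicon_id       cluster n_members x_min  x_max
#> 1 Organism_01_rep01       1         4  118.   121.
```

`ggplot2::autoplot(job)` draws the projection in R; the `graph.html`
artifact offers zoom, drag, hover popups (relative position, BitScore,
query, organism, product) and click-through detail, and
`inst/cli/blastxy` exposes `run` / `simulate` / `render` subcommands for
shell use.

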