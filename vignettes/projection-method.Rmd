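---
title: "Projecting large-scale BLAST results onto a fixed 0-360 replicon axis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting large-scale BLAST results onto a fixed 0-360 replicon axis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blastxy)
```

## The problem and the model

A genome-mining search — "where, across hundreds of bacterial or archaeal
genomes, do the genes of this operon occur?" — produces BLAST result sets far
too large to read as a table. blastxy visualizes them all at once by giving
every replicon (chromosome or plasmid) the same drawing space: a horizontal
line of fixed length 360, the degrees of a circle. A position `b` on a
replicon of `L` bp maps to its *relative position* in degrees; the y axis
simply counts replicons, 1..N. Each BLAST hit then becomes:

* a **dot** at `(x, y)`: the transcription start of the subject gene on its
  replicon's track;
* a **vector** from the dot, of signed length `360 * gene_length / L`
  degrees, pointing in the transcription sense (`+` toward increasing
  degrees);
* a thicker **alignment segment** drawn over the vector, spanning the
  aligned part of the subject, coloured by significance: BLAST bit score
  normalized over the job, linearly interpolated from yellow
  `rgb(255,255,0)` (least significant) to dark blue `rgb(0,0,139)` (most).

Because the x axis is relative, replicons of any size share one window, and
gene clusters — operons, biosynthetic loci — appear as tight runs of marks
at nearby degrees on one track, recognizable at a glance even among tens of
thousands of results.

## The degree convention

Base `b` of a length-`L` replicon occupies the half-open interval
`[360(b-1)/L, 360 b/L)`. Three consequences motivate this choice:

* `start(1) = 0` and `end(L) = 360` hold *exactly*, for every `L`
  (including `L = 1`);
* the map is measure-preserving: every base gets the same degree width
  `360/L`, and features tiling a replicon have vector lengths summing to
  exactly 360;
* positions normalized past `L` (origin-spanning features of circular
  replicons) reduce modulo `L` without special cases.

```{r}
relative_coordinate(1, 4641652, "start")
relative_coordinate(4641652, 4641652, "end")
relative_coordinate(2000000, 4000000, "end")
```

Origin-spanning features (annotated with end < start) are normalized at
parse time to `end + L` with a `wraps_origin` flag, which preserves the true
gene length; rendering splits the vector at the 360/0 seam while `x` stays
at the transcription start.

## Which end carries the dot

The dot marks the *origin of the subject gene*, which we define
strand-awarely: the lower genomic boundary for `+` genes and the upper
boundary for `-` genes, so that the vector always points in the
transcription sense. The alternative (always the lower boundary, with the
vector flipping) would draw minus-strand vectors pointing away from their
gene body.

## The y axis

The y index ranges from 1 (a single replicon searched) to N. Download or
database order is not reproducible, so the ordering here is canonical and
deterministic: organisms alphabetically; within an organism, replicons by
decreasing length, ties broken by id. Since bacterial chromosomes are
essentially always longer than their plasmids, length-descending order
realizes "chromosome(s) first, then plasmids" without needing a
chromosome/plasmid type column that neither GFF3 nor a plain replicon table
carries.

## Colour normalization

`color_value = (bitscore - min) / (max - min)`, clipped to `[0, 1]`, with
min and max taken over the full (capped) result set of the job — not per
zoomed view — so colours are stable while panning. A degenerate job whose
results all share one bit score maps everything to 1 (dark blue): a single
significance class is best shown as uniformly significant. RGB interpolation
is linear per channel between the two endpoint hues.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `evalue_cutoff` | 1e-08 | — | job significance cutoff; hits above it are dropped before projection |
| `max_results` | 30,000 | results | cap applied right after parsing, most significant kept |
| `display_cap` | 50,000 | results | maximum rendered at once; more saturates the plot |
| `raw_cap` | 1,000,000 | results | maximum exported in the raw `*_Sorted` file |
| `window_deg` | 5 | degrees | single-linkage gap threshold for cluster detection |
| zoom preset | 25 | degrees | typical browsing window width |

When a cap binds, retention follows the canonical significance order — bit
score descending, e-value ascending, then replicon index, position, input
order — matching the significance-centric colour semantics: what you lose
first is what would have been yellowest. The 5-degree cluster window is a
quarter of the 25-degree browsing window: runs that merge at 5 degrees are
exactly the runs a user would perceive as one cluster in such a view. On a
4 Mb chromosome, 5 degrees is about 55 kb — generous for one operon, which
is why clustering is a browsing aid, not an operon caller.

## Filtering semantics

Table filters are case-sensitive, literal substring matches ("contains"),
AND-composed. This is deliberate: the recommended query-naming convention
(`SSI_HlyD`, `SSII_GspC`, ...) relies on literal substring semantics —
`"SSI_"` must match `SSI_HlyD` but not `SSII_GspC`, which regex or
case-folding variants would break. Sorting is a stable single-key sort;
multi-key orders compose by sorting on the minor key first.

## Subject resolution

A hit's subject id is matched to the annotation in two stages: exact
`feature_id` match first, then `locus_tag`, because gene/protein FASTA
headers vary between the two styles. Unresolvable subjects are counted and
reported (message plus the `n_unresolved` attribute), never silently
dropped. For protein subjects (blastp/tblastn), alignment coordinates are
residues; the segment is mapped by residue fraction of the protein length,
taken as `floor(gene_bp / 3)` — at 360-unit resolution this is visually
indistinguishable from codon-exact arithmetic and avoids CDS-phase
bookkeeping. In genome-database mode (subjects are whole replicons) no join
is needed: `x` comes from the alignment's subject coordinates, orientation
from their order, and the segment covers the whole vector.

## What the synthetic generator emulates — and what it does not

`generate_genome()` and `simulate_hits()` build the study conditions for
every test: multi-organism, multi-replicon genome sets with non-overlapping
genes placed uniformly at random (defaults: 100 kb replicons, 50 genes of
mean length 900 bp — intergenic spacing comparable to gene-dense bacterial
chromosomes), and hit sets made of planted clusters (one strong hit per
consecutive gene, bit scores uniform in [200, 400], operon-like ~50 bp
intergenic gaps and a shared strand) over a sparse uniform background (bit
scores in [40, 80]). E-values are the monotone stand-in
`10^(-bitscore/10)`: the pipeline consumes only their ordering.

The generator does **not** emulate sequence evolution, alignment statistics,
paralogy, horizontal transfer, or annotation errors. Passing tests therefore
demonstrate that parsing, projection, filtering, capping, clustering and
rendering are correct on well-formed inputs of realistic shape and volume —
not that BLAST results from real genomes will be biologically
interpretable. All randomness flows through mandatory per-operation seeds
(`withr::with_seed`), so identical specs give byte-identical files and the
global RNG state is never touched.

## Numerical and degenerate-input choices

* Projection agrees with integer bp arithmetic to 1e-9 relative tolerance;
  invariants (`start(1)=0`, `end(L)=360`, degree-width `360/L`) are exact.
* An empty BLAST file is an empty result set, not an error; a malformed
  line errors with its line number.
* Ties in sorting keep their prior relative order (stable radix sort, C
  locale for text).
* JSON round trips are the identity: numbers are serialized at full
  precision.
* SVG and HTML outputs are deterministic byte-for-byte for fixed input:
  fixed-format number printing, no timestamps.

## Problem sizes used in the test-suite

The property suites run on generated tables of 30-1,000 rows across 100
seeds; the cap checks run once at the full stated sizes (60,000 results
against the display cap; 1,200,000 against the raw export cap). End-to-end
job tests use 2-3 organisms with 60-100 genes per replicon — large enough
to exercise every pipeline stage, small enough to iterate quickly.

## Known limitations

* Interactivity (zoom, drag, hover, range selection) is implemented as a
  self-contained HTML document with an embedded data island; the *data
  contract* (embedded table equals the capped result set; hover carries
  relative position, bit score, query, organism, product; click adds
  subject id, replicon, e-value, subject coordinates) is what is tested —
  browser behaviour is not exercised in the test-suite.
* No polar rendering: the method is precisely the linearization of circular
  replicons.
* Cluster detection is single-linkage on projected degrees; it does not
  consult strand or intergenic distance in bp, and does not split clusters
  at replicon-scale gene deserts smaller than the window.
* The overview panels summarize density (counts per 1-degree bin; counts
  per replicon) rather than drawing every mark, to stay responsive at the
  50,000-result display cap.

## A worked example

```{r, message = FALSE}
dir <- tempfile("vignette")
g <- generate_genome(
  genome_sim_spec(n_organisms = 2, replicons_per_organism = 2,
                  replicon_length_bp = c(300000, 60000),
                  genes_per_replicon = c(60, 15), seed = 41),
  dir = file.path(dir, "genome"),
  planted = list(list(replicon_id = "Organism_01_rep01", first_gene = 20,
                      n_genes = 4, tag = "capistruin"))
)
hits <- simulate_hits(
  g, hit_sim_spec(c("capA", "capB", "capC", "capD"), hit_rate = 0.01,
                  planted_clusters = list(
                    list(replicon_id = "Organism_01_rep01", first_gene = 20,
                         queries = c("capA", "capB", "capC", "capD"))),
                  seed = 42),
  path = file.path(dir, "hits.tsv"))

job <- run_job(job_config("Search for Capistruin cluster",
                          hits_path = hits, gff_path = g$gff_path,
                          replicon_path = g$replicon_tsv_path,
                          evalue_cutoff = 1, out_dir = file.path(dir, "job")))
glance(job)
detect_clusters(tidy(job)[tidy(job)$bitscore > 150, ])[, 1:5]
```

The high-scoring planted locus comes back as one four-member cluster; the
job folder now holds the sorted/filtered TSVs, the results JSON, the static
SVG and the interactive graph and table pages.

```{r, fig.width = 7, fig.height = 3}
ggplot2::autoplot(job)
```
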