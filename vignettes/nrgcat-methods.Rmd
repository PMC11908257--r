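---
title: "Methods: catalog construction, profiling, and the synthetic validation world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: catalog construction, profiling, and the synthetic validation world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope

`nrgcat` implements the two halves of a reference-free gene-catalog
workflow for microbiome shotgun data:

1. **Catalog construction** — coding sequences from many sources (MAGs,
   un-binned contigs, isolate genomes) are collapsed into *non-redundant
   genes* (NRGs) by greedy identity clustering, cleaned by a four-stage
   filter cascade, and labeled by a five-rule taxonomy decision tree.
2. **Profiling** — shotgun metagenome or metatranscriptome reads are mapped
   end-to-end against the NRG sequences; per-gene coverage (aligned bases
   divided by gene length) is aggregated into taxon relative abundances,
   TPM expression values, and mycobiome/phageome/CAZy sub-profiles.

Upstream steps (assembly, binning, CDS calling, source-genome
classification, functional annotation, phage prediction) are out of scope:
their outputs are inputs here, carried by a source manifest and annotation
tables.

## The clustering model

Genes are clustered at **95% identity over 90% of the shorter sequence**,
the `cd-hit-est -n 8 -c 0.95 -aS 0.9` convention:

* *identity* = matching alignment columns / length of the shorter sequence;
* *coverage* = aligned span of the shorter sequence / its length;
* alignment is semi-global ("overlap": free end gaps on both sequences),
  computed with `Biostrings::pairwiseAlignment`.

The greedy order is fixed for reproducibility: length descending, ties by
lexicographically smallest `gene_id`, first-fit against representatives in
creation order. The representative of a cluster is therefore always a
longest member. Before any alignment, a shared-word prefilter discards
candidate pairs that cannot reach the identity threshold: a query of length
`L` within 5% substitution divergence of a candidate destroys at most
`8` words per substitution, so a true match shares at least
`(L - 7) - 8 * floor(0.05 L)` 8-mers. The bound is admissible for
substitution-only divergence; indels can defeat it, which matches the
tool convention the thresholds come from.

## The filter cascade

Applied in fixed order, each stage logging its removals:

1. **Host screen** — local alignment against host/contaminant genomes
   (both strands); a gene is removed at identity ≥ 0.75 over ≥ 50% of its
   length. Identity here is matches/alignment-columns (the blastn
   convention), coverage is over the gene. Screening against any other
   unwanted genome (e.g. a viral control) is the same operation with a
   different FASTA.
2. **N filter** — any gene containing at least one `N` is removed.
3. **Containment deduplication** — if two genes share an exact substring of
   ≥ 100 bp, the shorter is removed (ties: lexicographically larger id).
   A ≥ 100 bp exact common substring exists iff a 100-mer is shared, so the
   scan hashes 100-mers. Removal is a *single pass against the original
   set*: an already-removed gene still witnesses removals (the upstream
   convention is unstated; this choice is deterministic and
   order-independent).
4. **Anomaly screen** — within each species (≥ 20 genes), three per-gene
   statistics: cosine distance of the tetranucleotide frequency vector to
   the species centroid; log10 median depth across the samples containing
   the species; prevalence among those samples. Each is converted to a
   robust z-score (median/MAD) within the species and a gene is removed
   when any |z| > 5. The published pipeline states this criterion only
   qualitatively; the z cutoff and the support guard are parameters, and
   all scores are returned so users can re-threshold. Without a per-sample
   presence table the screen runs on the tetramer statistic alone (with a
   warning) — that is the situation in the synthetic validation, where
   sources are isolates rather than per-sample assemblies.

The anomaly screen needs species labels, which only exist after taxonomy
propagation; the build therefore propagates provisional labels over the
post-containment clusters, applies the screen, and recomputes final labels
on the surviving set.

## Taxonomy propagation

Per cluster, member species/genus votes are tallied (a species vote also
votes its genus; a genus-only vote abstains at species rank; untaxed
members abstain entirely). Rules fire in order:

1. uniform species-level taxonomy → that species;
2. a strict majority (> 50%) of one species among species voters → that
   species;
3. otherwise a strict genus majority among taxed members → that genus;
4. otherwise → `MULTIGENERA`;
5. no taxonomic information at all → `UNASSIGNED`.

Exactly 50% is *not* a majority. The majority denominator is the number of
members carrying taxonomy at the relevant rank — untaxed members abstain,
which is consistent with rule 5 existing as a separate terminal state.

## The read mapper

Reads are aligned **end-to-end** (no clipping, no gaps) against NRG
sequences. Candidates come from exact 20-mer seed matches taken at read
offsets `0, 10, 20, …` plus the final offset; each candidate diagonal is
scored by full-length Hamming comparison, alignments below 90% identity
are dropped, and only the best-score stratum (up to `k = 10` alignments)
is reported. With the default stride every base lies in two seed windows,
so any placement of a 150 bp read with up to ~7 substitutions is found;
reads more divergent than that may be missed, the usual seed-heuristic
blind spot. `min_identity = 0.90` stands in for the unstated score floor of
the upstream aligner and is configurable.

Multi-mapping resolution: each read contributes total weight 1, split
equally among its best-score alignments. This is deterministic and
mass-conserving; the upstream pipeline reports up to 10 alignments without
stating a resolution rule, so the rule here is the package's own. Depth
("gene coverage") is weighted aligned bases / gene length; a taxon's
relative abundance is the sum of its genes' depths over the total. TPM is
`reads/(length/kb)` rescaled to 1e6. A SAM import path accepts external
alignments (gap-free CIGAR subset) and produces identical profiles to the
internal mapper on identical alignment sets.

## The synthetic validation world

`make_genomes()` builds uniform-random root genomes; children are parent
copies with `Poisson(L × divergence)` substitutions. Genes tile each
genome as 900 bp windows separated by 100 bp spacers, so cluster-level
ground truth is exact. `simulate_reads()` draws species with probability
proportional to `proportion × genome length` (so a species' expected
per-base depth share equals its stated proportion), uniform start
positions, i.i.d. substitution errors, constant quality, forward strand
only (this keeps "an error-free read is an exact substring of its genome"
true; the mapper searches both strands regardless).

The default panel has eight species in six genera with one sister pair at
2% and one at 6% divergence, 50 kb genomes with 50 genes each. The default
communities are three single-dominant designs, one even community, three
gradients over the 2% pair, one over the 6% pair, and two seeded random
assortments floored at 1%. Reads: 200,000 per community, 150 bp (the
short-read instrument convention), 0.2% substitution error — a deliberate
desk-scale stand-in for the published validation's 10 M NovaSeq-model
reads per mock.

What the generator does *not* emulate: indels, quality-dependent errors,
paired ends, GC bias, strand sampling, gene-length variation, and real
genomes' heterogeneous per-gene divergence. A green validation therefore
establishes that clustering, labeling, mapping and quantification are
mutually consistent and unbiased under substitution-only divergence — not
that the pipeline is robust to assembler- or instrument-specific artifacts.

### Why the regression is scored at catalog resolution

With uniform per-site divergence, a 900 bp ortholog pair at 2% divergence
has essentially zero probability of falling below 95% identity, so the
sister species share *all* their clusters and every one of their genes is
labeled at genus level. Their species-level observed abundance is then ~0
by construction — not a quantification error but the catalog's honest
resolution limit (the published validation shows the same effect as
genus-level buckets and a slight underestimate of species with close
relatives). The validation therefore regresses observed against *expected
composition at catalog resolution*: each species' truth mass is
distributed over its genes' cluster labels (length-weighted) and
renormalized. At 6% divergence about 90% of ortholog pairs split into
separate species-level clusters and the rest merge to genus, and the
expected vector accounts for both. One further effect is modeled
explicitly: when containment deduplication removes one copy of a
6%-divergent ortholog pair (substitution gaps of ≥ 100 bp occur in a
fraction of such pairs), reads of the removed species still map to the
surviving witness copy at ~94% identity and are attributed to its label —
so the expected vector redirects a contained-removed gene's mass to its
witness's taxon (the catalog records the witness per removal), while
genes removed by the other filter stages drop their mass. Residual error
after this accounting reflects mapping and sampling noise only. The
redirection assumes the witness is within the mapper's identity floor of
the removed gene, which holds by construction here (an exact ≥ 100 bp
shared block between 900 bp genes implies high overall identity in this
world) but is not guaranteed for arbitrary inputs.

## Analytics choices

* **Accumulation curves** average cumulative distinct-feature counts over
  100 seeded random sample orders (whether the published curves were
  order-averaged is unstated; averaging with a reported spread is the
  conservative choice).
* **Co-occurrence** is Pearson correlation of CLR-transformed abundances
  (per-sample pseudocount: half the smallest nonzero share), over samples
  where either taxon is present, with coefficients zeroed when |r| < 0.3
  (the hard threshold) or the correlation-test p ≥ 0.001. This is a stated
  concretization of the sparse compositional-correlation tool the upstream
  analysis used; its bias-correction machinery is not reimplemented.
* **Detection thresholds** are strict (`>`) at both 1% (congeneric species
  counting) and 1e-4 (mycobiome detection); the boundary is measure-zero.
* **AUC** uses the midrank Mann–Whitney identity,
  `P(pos > neg) + 0.5 P(tie)`.
* **Species transcriptome extraction** refuses below a minimum of species-
  mapped reads; the upstream description uses 100,000 in its methods and
  250,000 in the corresponding figure, so the threshold is a parameter
  with 100,000 as default and both values supported. Both whole-sample and
  species-renormalized TPM variants are emitted because the upstream
  choice is unstated.

## Numerical and degenerate-input conventions

* Zero mapped reads: composition/TPM return empty, flagged tables rather
  than dividing by zero.
* A temperate-phage depth of zero flags the virulent:temperate ratio as
  undefined (`NA`) instead of `Inf`.
* MAD of zero in the anomaly screen: genes equal to the median get z = 0,
  any deviation gets infinite z (a constant statistic plus one deviant is
  exactly the anomaly the screen exists for).
* Sequence alphabet is strict `{A,C,G,T,N}`; IUPAC ambiguity codes are
  rejected at parse time (N-containing genes are dropped by the cascade
  anyway, so permissiveness buys nothing). `N` never matches anything,
  including another `N`, in alignment or mapping.
* All randomized operations take explicit integer seeds and restore the
  caller's RNG state; builds and validations are byte-identical across
  reruns at a fixed seed.

## Known limitations

* The clustering prefilter bound is not admissible under indels —
  acceptable for CDS inputs whose divergence is substitution-dominated,
  and consistent with the word-filter convention it mirrors.
* The mapper's gap-free end-to-end model cannot represent indel alignments
  a general aligner would report; the SAM import path accepts only the
  matching (gap-free) subset.
* Catalog updates are rebuild-only; there is no incremental append.
* The anomaly screen's published removal count cannot be reproduced since
  the original thresholds and exact statistics are unpublished; the screen
  is parameterized and auditable instead.
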