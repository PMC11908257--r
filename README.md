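# nrgcat

Non-redundant gene catalogs for metagenome and metatranscriptome profiling.

## The problem

Reference-based analysis of microbiome shotgun data needs a *gene catalog*:
a de-duplicated set of coding sequences drawn from many sources
(metagenome-assembled genomes, un-binned assembly contigs, isolate
genomes), each carrying a taxonomic label, against which reads from new
samples can be mapped and quantified. `nrgcat` implements both halves of
that workflow for anyone building a catalog for a body site or environment
of interest:

* **Catalog construction.** Coding sequences are clustered greedily at
  95% identity over ≥ 90% of the shorter sequence (the
  `cd-hit-est -c 0.95 -aS 0.9` convention, with an admissible shared
  8-mer prefilter), each cluster represented by its longest member — a
  *non-redundant gene* (NRG). A four-stage filter cascade then removes
  host-matching genes (local identity ≥ 75% over ≥ 50% of the gene),
  genes containing `N`, genes sharing an exact substring of ≥ 100 bp with
  a longer gene, and genes whose tetranucleotide composition, abundance or
  prevalence is a robust-z outlier (|z| > 5) within their species.
  Cluster taxonomy is propagated from member labels by a five-rule
  decision tree: uniform species → species; strict species majority
  (> 50%) → species; strict genus majority → genus; otherwise
  `MultiGenera`; no information → unassigned.

* **Profiling.** Reads are mapped end-to-end (20 bp exact seeds, gap-free
  scoring, ≥ 90% identity, up to 10 best-score alignments per read with
  equal fractional weight). Per-gene *coverage* is weighted aligned bases
  divided by gene length; a taxon's relative abundance is the sum of its
  genes' coverages over the total; expression is reported as TPM.
  Sub-profiles: mycobiome (fungal fraction, detected when > 10⁻⁴),
  phageome (phage share and virulent:temperate coverage ratio), CAZy
  family expression matrices with per-taxon contributions, and
  single-species transcriptome extraction gated on a minimum of
  species-mapped reads.

* **Validation.** A seeded generator builds synthetic species genomes
  (including sister species at controlled divergence), mock communities of
  known proportions, and substitution-error reads; `cmd_validate()` runs
  the whole pipeline end-to-end and regresses observed against expected
  relative abundance.

Statistics for catalog/profile interpretation are included: gene
accumulation curves, strict-threshold species counting (1% detection),
CLR-based co-occurrence with a hard correlation floor (|r| ≥ 0.3,
p < 0.001), and single-feature ROC AUC.

## Worked example

```r
library(nrgcat)

# a synthetic world: 8 species incl. sister pairs at 2% and 6% divergence
specs   <- default_mock_species(genome_length = 10000L, n_genes = 10L)
genomes <- make_genomes(specs, seed = 7)
genes   <- cds_from_genomes(genomes)

catalog <- build_catalog(genes, build_params(), seed = 7)
catalog
#> Non-redundant gene catalog: 67 NRGs
#>   taxonomy: 54 species-level, 13 genus-level, 0 multi-genera, 0 unassigned
#>   pipeline: input_genes=80, clusters=67, after_host_screen=67,
#>             after_n_filter=67, after_containment=67, after_anomaly=67

# profile a mock community against it
comm  <- default_mock_communities(vapply(specs, `[[`, "", "species"),
                                  seed = 11)[[3]]          # even: 0.125 x 8
truth <- simulate_reads(genomes, comm, n_reads = 20000, read_length = 150,
                        error_rate = 0.002, seed = 13)
prof  <- quantify(map_reads(truth$reads, catalog), catalog)
compose(prof, catalog$entries)
#>                  taxon    rank      share
#> 1:      Mockibacterium   GENUS 0.25275235
#> 2:       Artificia eta SPECIES 0.12680727
#> 3:     Imaginella zeta SPECIES 0.12534819
#> 4:  Synthetica epsilon SPECIES 0.12289428
#> 5:    Fabricatus theta SPECIES 0.12123624
#> 6: Fictibacillus gamma SPECIES 0.08767741
#> 7: Fictibacillus delta SPECIES 0.08681523
#> 8:       Fictibacillus   GENUS 0.07646903
```

Reading the output: every species was seeded at 0.125. The 2%-divergent
sister pair (`Mockibacterium alpha`/`beta`) clusters together, so the
catalog reports their combined mass (0.25) at genus level — the expected
resolution limit for near-identical species. The 6% pair is resolved at
species level except for the ~10% of ortholog clusters that merged (the
`Fictibacillus` genus bucket). All shares match the catalog-resolution
expectation within a few tenths of a percentage point.

Full-scale validation (10 communities × 200k reads at 0.2% error):

```r
res <- cmd_validate(seed = 1)
res$r2     #> 0.99998
res$slope  #> 0.9998
```

## Command line

```sh
Rscript inst/cli/nrgcat.R build    --manifest manifest.tsv --out catalog/
Rscript inst/cli/nrgcat.R profile  --input reads.fastq --catalog catalog/ --out prof/
Rscript inst/cli/nrgcat.R validate --seed 1 --out report/
```

The manifest is a TSV with columns `fasta_path`, `source_type`
(`MAG`/`UNBINNED`/`ISOLATE`), `source_id`, `sample_id`, `species`,
`genus`. The catalog directory holds one FASTA plus numbered TSV tables
(taxonomy, cluster map, removal log, annotations, phage) and a provenance
file; see `vignettes/nrgcat-methods.Rmd` for the model, parameter
rationale, and known limitations.
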