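---
title: "Methods: curating a CTCF variant catalog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curating a CTCF variant catalog}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(ctcfcat)
```

This vignette walks through the methods implemented by `ctcfcat`: how
heterogeneous genotype–phenotype database exports are harmonized into a
single deduplicated catalog of *CTCF* variants associated with
neurodevelopmental disorders (NDD), and how every stage is made
testable.

## 1. Coordinate conventions

All genomic intervals are **1-based closed**; a span of one base has
length 1. UCSC chain files, which are 0-based half-open, are converted
at the parser boundary and nowhere else.

```{r}
interval_length(genomic_interval("chr16", 67596310, 67673088))
```

## 2. Transcript model and coordinate mapping

A `transcript_model` carries exon spans, the genomic CDS start/end and
(optionally) the spliced CDS sequence; the constructor validates exon
ordering and, when a sequence is present, that it starts with ATG, ends
with a single stop, has no internal stop, and matches the coding-exon
overlap length.

Genomic positions map to cDNA coordinates in HGVS style: coding bases
(`c.N`), 5'/3' UTR bases (`c.-N`, `c.*N`) and intronic offsets
(`c.N+M` / `c.N-M`, anchored at the nearer exon edge; ties anchor 5').
The mapping is exercised by exhaustive round-trip tests over every
position of toy and random transcripts.

```{r}
model <- generate_transcript(42, n_exons = 4, cds_codons = 250, utr3_len = 120)
genomic_to_cdna(model, 1031)
codon_of(1456)  # CDS base 1456 sits in residue 486
```

## 3. Liftover

The chain parser enforces the format's extent invariants (block sizes
plus gaps must sum to the declared source and target spans). Position
mapping is offset arithmetic inside aligned blocks; positions inside
alignment gaps report `in_gap`, positions outside every chain report
`no_chain`, and intervals whose ends map through different chains
report `split` rather than a silently stitched interval. Minus-strand
targets are reflected per the chain specification. Tests cross-check
the mapper against a brute-force per-base expansion of random chains
and against `rtracklayer::liftOver`, and verify that a chain composed
with its reciprocal is the identity.

## 4. HGVS parsing and 3'-rule normalization

The parser supports the catalog's variant vocabulary: substitutions,
deletions, duplications, insertions and deletion–insertions at coding,
UTR and intronic positions. Deletions, duplications and insertions in
repetitive sequence are ambiguous; `normalize_3prime` right-shifts them
to the most 3' representation (and rewrites an insertion that exactly
duplicates its upstream neighbor as a `dup`), which is what makes
cross-source deduplication sound. Normalization provably preserves the
edited sequence: property tests apply the raw and normalized variants
independently and compare results.

```{r}
cds <- model$cds_sequence
format_c(normalize_3prime(cds, parse_c("c.604dup")))
```

## 5. Protein consequences

`call_consequence` applies the normalized variant to the CDS,
translates both alleles (standard code, via Biostrings) and classifies
by residue-wise diff: synonymous, missense, nonsense, in-frame
del/ins, start-lost, stop-lost, or frameshift with the `fs*N`
termination offset (first changed residue counts as 1). UTR and
intronic variants get a region label only; no splice prediction is
attempted. The classifier is tested for equivalence against an
independent brute-force oracle (own hand-written codon table) on more
than 10^4 random variants.

```{r}
call_consequence(model, parse_c("c.604dup"))
```

## 6. Harmonization and deduplication

Source exports arrive in per-database schema dialects (TSV/CSV column
namings plus a minimal VCF reader). `standardize_records` brings every
record to one assembly (lifting GRCh38 coordinates down with the
supplied chain), reconstructs the missing representation (coordinates
from HGVS or vice versa), validates stated reference bases against the
transcript, and computes one canonical key per variant:
`chrom:normalized-HGVS`. Records that cannot be standardized are
excluded with a machine-readable reason (`ambiguous`,
`liftover_no_chain`, `hgvs_parse_error`, `reference_mismatch`,
`unsupported_kind`, `inconsistent`, ...), and a conservation invariant
is asserted at every stage: records in = records out + exclusions, and
after dedup, records = distinct + duplicates.

`deduplicate` merges same-key records, keeping full provenance (source
list, per-field conflicts pipe-merged and flagged) and producing the
per-source overlap table.

## 7. Phenotype and pathogenicity curation

Free-text conditions are classified by a config-driven terminology rule
table (normalized substring matching with word boundaries); among all
matches the highest-priority category wins, and categories CRD, ASD,
DD, EP, ID, IGD and ANS qualify as NDD. Records without phenotype data
classify `NO_PHENOTYPE_DATA` and never count as NDD.

Pathogenicity recuration applies a small ordered rule set — synonymous
variants are excluded from the catalog; missense at a
zinc-coordinating Cys/His is at least likely pathogenic;
benign-reported missense carried by an NDD phenotype becomes VUS;
unreported classes default to VUS. Every change is logged with its rule
id. The mapping is idempotent and never downgrades (property-tested
over the full input grid). Origin (`de_novo` / `inherited`) is accepted
only with trio confirmation.

## 8. CNVs

CNVs deduplicate on exact `(chrom, start, end, dosage)` coordinates;
gains and losses over the same interval stay distinct. Sizes print in
bp/kb/Mb, and `gene_overlap` classifies containment versus partial
overlap of the gene locus.

```{r}
cnv_size(65347298, 90148393)$text
```

## 9. Synthetic ground truth and parameter recovery

Because the upstream databases are live services, the pipeline is
validated against a synthetic generator instead: a truth ledger of
distinct variants is placed on a toy transcript (each variant's
consequence class is verified with the real engine at generation time),
then emitted as messy multi-source export files — schema dialects,
mixed assemblies with a matching chain file, HGVS-only and
coordinate-only representations, messy phenotype wording, and duplicate
records sampled with replacement. Running the full pipeline over these
files must recover the ledger's expected counts **exactly** — distinct
variants, per-category phenotype counts, consequence classes, origins
and the CNV distinct count. The defaults reproduce the aggregate
structure of the published *CTCF* catalog (538 records / 311 distinct
SNVs; 73 records / 62 distinct CNVs; 225 exonic variants of which 149,
i.e. 66%, NDD-associated).

```{r, eval = FALSE}
truth <- generate_catalog_truth(42)
ex <- emit_source_exports(truth, 42, n_records = 538)
st <- standardize_records(ex$records, ex$chains, attr(truth, "model"))
dd <- deduplicate(st$records)
bundle <- build_catalog(dd, attr(truth, "model"), excluded = st$excluded,
                        n_source_records = nrow(ex$records))
summarize_catalog(bundle)$ndd_share
```
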