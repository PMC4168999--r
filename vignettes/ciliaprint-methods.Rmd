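---
title: "Methods: motility fingerprints, splice consequences and co-conservation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motility fingerprints, splice consequences and co-conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliaprint)
```

# The scientific problem

Genes of the ciliary motility programme — the dynein arms, their assembly
factors, and associated axonemal machinery — are transcriptionally marked by
a recognisable promoter signature: RFX-bound X-boxes near the transcription
start, usually accompanied by forkhead (FOX) binding sites.  A candidate
motility gene can therefore be interrogated on three independent axes:

1. does its upstream region carry the RFX/FOX *motility fingerprint*, and
   is that fingerprint conserved across orthologous promoters?
2. if a patient variant hits a splice acceptor, what is the predicted
   transcript- and protein-level consequence?
3. is the gene *co-conserved* across eukaryotes with the motile-cilia
   machinery itself (present where motile cilia exist, lost where they were
   lost)?

`ciliaprint` implements all three, plus the small exact statistics that
accompany them, and seeded simulators that generate every input class with
known ground truth.

# Motif model

An X-box is modelled as two 6-bp IUPAC half-sites separated by a variable
1–3 bp spacer.  Two published renderings of the 5' half-site circulate,
`RYYRYY` and the more degenerate `RYYNYY`; the package defaults to
`RYYRYY` (the form applied in tabulated cross-species analyses) and ships
`RYYNYY` as a named alternative (`default_motif_set(xbox_form =
"RYYNYY")`), surfacing the discrepancy rather than hiding it.  The FOX
component defaults to the consensus core used by the majority of forkhead
proteins, `RYMAAYA`; the two stringent FOXJ1 sites (`WDTGTTTGTTTA`,
`KTTTGTTGTTKTW`) are available via `include_strict = TRUE` but typically
recover nothing close to the start site, which is itself informative.

Matching is set membership per position: no position-weight scoring, no
enrichment statistics.  Three deliberate choices:

* **`N` never matches.**  A masked subject base fails every motif letter,
  including motif `N` and spacer positions.  This is the conservative
  behaviour for masked or low-quality sequence.
* **Mismatch tolerance is asymmetric.**  The 3' half-site of reported
  X-boxes is consistently well matched while the 5' half-site is "more
  degenerate"; no publication quantifies that degeneracy.  We classify a
  hit *canonical* when both half-sites are exact and *relaxed* when the 3'
  half is exact and the 5' half carries 1–`max_mm5` mismatches.
  `max_mm5 = 2` is a configurable operating default, not ground truth.
* **All matches are reported**, overlapping and multi-spacer alike;
  downstream consumers deduplicate.  Lossless primary output makes the
  scanner directly comparable to a brute-force oracle.

## Window and coordinates

`fingerprint_window()` scans the terminal `window` bases (default 500 bp, a
1000 bp option for expanded analyses) of an upstream sequence supplied
5'→3' ending at its anchor.  The anchor is the TSS, or the ATG where a
sizeable 5'UTR makes the TSS unreliable — the anchor choice is recorded per
species.  Published positions such as "−16" do not state whether they
measure the motif's 5' or 3' end, so hits carry both (`offset5`,
`offset3`; the base just 5' of the anchor is −1).  Pairwise X-box
separations are start-to-start distances; the FOX-to-X-box distance is the
end-to-start gap, clamped to 0 for overlapping motifs.  A window is called
*positive* iff it holds at least one X-box hit (canonical or relaxed) and
at least one FOX hit.

## Conservation across species

`build_conservation_table()` runs the fingerprint per species and reports,
per motif class, the fraction of species with at least one hit.  No
cross-species alignment is attempted: the comparison is presence and
position per species, exactly as such tables are published.  How syntenic
windows are chosen in each genome is not algorithmically specified
anywhere; the module takes the windows as given input.

# Splice-acceptor consequence model

U2-type introns end in an invariant `AG`.  A substitution that destroys it
(`apply_acceptor_variant()` flags the intron *disrupted* iff the terminal
dinucleotide no longer reads `AG`) can force the spliceosome onto a
*cryptic* acceptor.  The model searches **3'-ward only** (exonic), taking
the nearest `AG` within `search_window` (default 50 nt) and resuming the
transcript immediately after it, so the deleted base count is the AG's
exon offset plus 2.  An exon that itself begins `AG` therefore loses
exactly 2 nt.  Intronic cryptic sites, exon skipping, branch-point effects
and splice-strength scoring are out of scope: modelling them from a single
substitution would be speculation.

From the mutant transcript the pipeline translates wild type and mutant
(the mutant with 3'UTR readthrough, since a frameshift abolishes the
annotated stop) and derives the full outcome.  Conventions:

* `first_altered_codon` is the first residue that differs.
* `replaced_count` counts wild-type residues from the first altered codon
  to the wild-type C-terminus **inclusive**; `novel_count` counts mutant
  residues from the first altered codon to the residue before the new
  stop, so `ter_codon = first_altered_codon + novel_count` always.
* The HGVS frameshift ordinal counts the first altered residue as 1:
  `p.<Wt><pos><Mut>fsTer<novel_count + 1>`.  Initiator-codon changes are
  outside this nomenclature and rejected.
* The deleted-bases effect is printed in the `c.<first>-<last>del<SEQ>`
  style used in clinical reports of such deletions.
* The predicted size shift is the difference of average (ExPASy-style)
  protein masses — the appropriate scale for gel mobility, where such
  shifts are observed.
* Cryptic usage shortens RT-PCR amplicons only by the deleted count (−2 nt
  in the AG-initial case), which is why such events look size-neutral on
  gels; the report carries this as `rt_pcr_size_delta`.

A variant that leaves the `AG` readable round-trips to a wild-type
transcript (`acceptor_intact`); a deletion divisible by 3 is reported as an
in-frame deletion with no frameshift fields.

# Co-conservation model

Orthology is called by reciprocal best hit (RBH): the query's top-scoring
hit in the target proteome must return the query as its own top hit.  The
desk-scale aligner is exact local alignment (Smith–Waterman) under BLOSUM62
with affine gaps, open 11 / extend 1 — the BLASTP operating point, so
heuristic search tools rank by the same score at genome scale.  Score ties
are broken by lexicographic record id and flagged `ambiguous`
(determinism with honesty).  `min_score` has no published default and must
be configured per dataset; raising it can only remove calls, never add
them.

Percent identity to the reference is computed by pairwise **global**
alignment rather than from a multiple alignment; report headers flag this
methodological substitution.

`build_presence_matrix()` collapses calls to `full`/`half`/`absent`: a
category (e.g. ODA markers DNAH9/DNAH5/DNAL1; IDA markers
DNAH3/DNAH1/DNAH2) is `full` when every member is present, `half` when at
least one is, `absent` otherwise.  `coconservation_concordance()` then
scores agreement between a gene column and a category column and attaches
a two-sided Fisher exact p; a single-valued column gives a degenerate
table whose only arrangement has probability 1, hence p = 1.

# Exact statistics

* **Fisher exact (2×2)** uses the minimum-likelihood two-sided convention
  (sum of all hypergeometric probabilities not exceeding the observed
  table's), matching mainstream statistical software.  It is validated in
  the test suite against both exhaustive enumeration over all tables with
  margins ≤ 8 and `stats::fisher.test`.
* **Count reconstruction** from printed percentages rounds half away from
  zero and always reports a consistency flag: e.g. 91.50% of 63 is not
  reachable as k/63 for any integer k (57/63 = 90.48%, 58/63 = 92.06%);
  the flag records this rather than silently accepting the reprint.  The
  Fisher bound is insensitive to ±1 in any reconstructed count, which the
  acceptance tests verify explicitly.
* **Exclusion power** is the analytic tail probability
  `1 − (1 − q)^n_chr` of seeing an allele of frequency `q` at least once
  among `n_chr` chromosomes; with 13,358 control chromosomes and
  q = 0.1% this exceeds 0.95, the basis of "greater than 95% power to
  exclude" statements.

# Synthetic data: what it emulates, and what it does not

Every generator derives its RNG stream from one top-level seed hashed with
a generator label, so outputs are byte-identical under a fixed seed and
adding a generator never perturbs existing fixtures.

* **Promoter sets** (`simulate_promoter_set()`): i.i.d. background at a
  configurable GC content, motif instances sampled uniformly from their
  consensus sets, planted at stated anchor offsets, then diverged by
  per-site substitution.  Defaults (6 species, 500 bp windows, an X-box
  whose 3' end sits at −16 with a FOX core upstream) mirror the tabulated
  cross-species configuration.  Not emulated: indels, local duplication,
  phylogenetic correlation between species, and real promoter base
  composition — so passing recovery tests demonstrates scanner
  correctness, not expected sensitivity on real genomes.
* **Mini-genes** (`simulate_minigene()`): two-exon genes with a canonical
  `GT..AG` intron and a mode switch controlling the exon-2 start
  (`ag_initial` reproduces the final-exon configuration that loses 2 nt;
  `inframe` plants the first AG at offset 1, deleting 3 nt).  A
  stop-in-every-frame cassette near the exon end guarantees termination.
  Truth comes from `naive_splice_truth()`, a string-operations oracle that
  shares no code with the consequence pipeline.
* **Full-scale surrogate locus** (`simulate_heatr2_like_locus()`): a fully
  synthetic 13-exon model engineered base-by-base so that an 854-residue
  wild type with an AG-initial final exon (first exonic base = coding
  position 2432, codon 811 `GAG` spanning the junction) yields, under the
  acceptor substitution `c.2432-1G>C`, a 2-nt deletion, 44 replaced and 77
  novel residues, and a stop at codon 888 (`p.Glu811GlyfsTer78`).  The
  constrained construction (sampling bases while forbidding stop codons in
  both reading frames between the junction and the planted stops) is
  re-verified against the naive oracle at generation time.  This is a
  synthetic stand-in with the published *configuration*; it is not the
  human sequence, which users can supply as FASTA + gene model to run the
  identical pipeline on the real transcript.
* **Proteomes** (`simulate_proteomes()`): present orthologues are
  per-site-diverged copies of random reference proteins; absences are
  unrelated random sequences; decoys pad each proteome.  Not emulated:
  site-rate heterogeneity, domain structure, paralogy — so RBH recovery at
  5% divergence tests the calling logic, not remote-homology sensitivity.
* **Doublet counts** (`simulate_doublet_counts()`): binomial draws at the
  published group sizes (63 control, 126 knock-down doublets).

# Numerical and degenerate-input choices

Internal coordinates are 0-based half-open; HGVS and report coordinates
are 1-based.  GFF3 (1-based inclusive) is converted on ingest; a JSON gene
model schema is documented in `read_gene_model_json()`.  Codons containing
`N` translate to `X`; a frame with no stop raises an explicit
`ciliaprint_no_stop` condition rather than truncating silently.  An empty
protein has mass equal to one water.  Fisher probability comparisons use a
`1 + 1e-7` relative tolerance so that exact ties are not lost to floating
point.  The all-zero contingency table and the empty promoter set are
errors; an empty scan input returns an empty hit table.  A frameshift
whose shifted frame happens to re-encode the wild-type residues up to the
shorter protein's end has no substitution to report and is returned as
`synonymous` (equal lengths) or `stop_shift` (stop relocation only)
rather than forced into fs nomenclature.

# Problem sizes in the test suite

The suite runs entirely from seeded generators: 1000 random sequences (15–
300 nt) for scanner/oracle equivalence, 200 seeded mini-genes for the
splice oracle sweep, every 2×2 table with margins ≤ 8 for Fisher
enumeration, 3–4 species × 4 genes with 5% divergence for RBH recovery,
and 25–50 species for recall curves.  These sizes were chosen to exercise
each property densely at desk scale while keeping the default suite fast.

# Known limitations

* Promoter windows must be supplied; the package does not locate syntenic
  regions or integrate epigenomic tracks.
* The splice model predicts neither acceptor strength nor
  nonsense-mediated decay; it assumes the nearest exonic AG is used
  efficiently, which is an empirical observation for the motivating class
  of variants, not a general rule.
* RBH is a heuristic for orthology: it does not detect paralogy swaps,
  does not search six-frame nucleotide assemblies, and its `min_score`
  requires dataset-specific calibration.
* Variant application supports plus-strand gene models; minus-strand loci
  should be reverse-complemented first.
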