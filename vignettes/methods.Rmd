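---
title: "Models and methods behind lncmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lncmir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncmir)
```

`lncmir` reimplements, as a tested R package, a transcriptome-based
discovery workflow for regulatory non-coding RNAs in developing seed and
pod tissues: lncRNA identification by a filter cascade, homology-seeded
miRNA prediction with thermodynamic hairpin validation, target linking
(miRNA/UTR expectation scan, cis windows, duplex-energy trans targets),
endogenous-target-mimic (eTM) detection, and expression-layer statistics.
This vignette explains each model, its assumptions, the tunable parameters,
and the choices made where the design was genuinely open.

## The lncRNA filter cascade

Candidates pass, in order: length ≥ 200 nt; FPKM > 1 in at least one
sample; longest forward-frame ORF < 100 amino acids; coding-potential score
below a cutoff; absence from a protein-homology exclusion list; absence
from a housekeeping-ncRNA exclusion list. Each stage is a pure predicate on
the transcript, so the surviving set is invariant under stage order; the
recorded `first_fail` column depends on the canonical order above. At
exactly 200 nt the bound is inclusive (`min_length = 200`, configurable),
the stricter of the two readings of "above 200 bp".

External coding-potential classifiers (CPC/CNCI-class tools) are
unversioned external binaries, so the cascade exposes two routes:

* an **internal score**, CPAT-like: `combined = 2 * hexamer_llr +
  orf_coverage`, where `hexamer_llr` is the mean per-hexamer log2
  likelihood ratio between coding and noncoding hexamer tables (trained on
  labelled sets, pseudocount 1 over the full hexamer space) and
  `orf_coverage` is the fraction of the transcript inside its longest ORF.
  Transcripts scoring below 0 are kept. The weights make the composition
  term dominant while letting a genuine long ORF veto; on fixture data the
  score separates coding transcripts from their composition-shuffled decoys
  in ≥ 90 of 100 pairs.
* **pass-through scores**: a named vector of externally computed scores
  with the published keep-if-below −0.5 semantics.

Protein-homology and ncRNA-family removal are exclusion-list inputs, not
reimplemented database searches: the result of such searches depends on
database versions, which a reproducible package cannot pin.

Locus classes follow position and strand: `lncNAT` for exon overlap with a
gene on the opposite strand, `intragenic` for containment in a gene span on
the same strand, `lincRNA` otherwise, with ties resolved in that priority
order. Strand-less transcripts cannot be antisense calls and are flagged.
A 10 kb window plays no role in classification; it belongs to cis-target
assignment (`lncrna_cis_targets`), where any gene within 10 kb of a lncRNA
span, strand-agnostic, is a potential cis target.

## The RNA thermodynamics engine

All structure filters are driven by an internal engine rather than an
external folding binary, so every computation is reproducible and testable
against an exact oracle.

**Energy model.** Nested secondary structures are scored by nearest-
neighbour stacking only: each adjacent pair stack (i,j)/(i+1,j-1)
contributes `-(s_outer + s_inner)/2`, with pair strengths `GC = 2.0,
AU = 1.2, GU = 0.6` (model units on a kcal/mol-like scale). Isolated pairs
contribute nothing, the empty structure has energy 0, and hairpin loops
must enclose at least 3 unpaired nucleotides. G:U wobbles are allowed
everywhere. The published screening thresholds all act on normalized
indices (MFEI, NQ, ND, Npb), not raw energies, which makes the simplified
model appropriate: what matters is the contrast between hairpin-like and
arbitrary sequences, which the stacking term captures.

**Algorithms.** Minimum free energy structures come from a Zuker-style
dynamic program over an unambiguous grammar (`W = Wn + V`), with a
deterministic traceback (ties prefer the paired branch, then the smallest
5' index, then stacked continuations). The same grammar, with sums in
place of minima, yields a McCaskill-style inside/outside partition
function with exact base-pair probabilities. Ensemble indices follow the
pre-miRNA screening literature, which names but rarely defines them:

* `NQ = -(1/L) * sum over i<j of p_ij log2 p_ij` (normalized Shannon entropy),
* `ND = (1/L) * sum over i<j of p_ij (1 - p_ij)` (normalized base-pair distance),
* `Npb` = pairs in the MFE structure / L (base-pairing propensity),
* `AMFE = 100 |MFE| / L` and `MFEI = AMFE / GC%`.

Both DPs are verified against exhaustive enumeration of all nested
structures (`enumerate_structures`), energy-exactly for folding and to
1e-9 relative for the partition function; the enumeration itself is
cross-checked by an independent recursion count. A true symmetry of the
model — invariance of the ensemble under sequence reversal — is asserted
numerically. (Reverse *complement* is not a symmetry once wobbles are
allowed: a G:U maps to A:C, which cannot pair.)

**Duplexes.** Intermolecular hybridization (used for trans targets) is an
RNAplex-like alignment DP: stacks score the same table, interior
loops/bulges cost 1 model unit per unpaired nucleotide, with at most 10
unpaired per strand between consecutive pairs. The trans-target cutoff of
−50 model units is configurable; the scale of the published cutoff is tool
specific, so the value is recorded in run metadata rather than asserted as
physically meaningful. Under the internal model, −50 corresponds to a
duplex of roughly 30+ contiguous pairs, which the ≥ 50 nt / ≥ 95% identity
candidate gate comfortably exceeds.

## miRNA prediction

**Homology scan.** Known matures (14–25 nt) are matched ungapped and
full-length against both strands with fewer than 3 substitutions. Seeding
uses exact words of length `min(7, floor(len/3))`: the pigeonhole principle
then guarantees the seeded scan finds exactly the hits of a full Hamming
scan (asserted against a brute-force oracle). The BLAST e-value cutoff of
the original protocol has no analogue in an exact scanner and is absorbed
by the mismatch bound.

**Precursor windows.** The protocol does not state precursor extraction
windows; the package emits up to four windows per hit
(up/downstream flanks 0/60, 20/60, 60/20, 60/0 nt, clipped at transcript
bounds) and lets best-candidate selection arbitrate. All sizes are
configurable.

**Hairpin screen.** Each window is folded and checked against the
published criteria: single terminal loop across the mature/star region;
MFEI ≥ 0.41; AU content 22–77%; mature entirely within one arm; intact
miRNA\*; at most 6 mature:star mismatches; NQ ≤ 0.45; ND ≤ 0.15;
Npb ≥ 0.25. The star is derived from the MFE structure as the region
pairing the mature, extended by the canonical 2-nt 3' overhang.
"Mismatches" are mature positions unpaired or paired outside the star.
"No loop or break in miRNA\*" is made precise as: paired star positions
must keep a constant register against the mature arm — symmetric internal
loops (mismatches) are tolerated, asymmetric bulges are a break. Without
the register condition, a fold can absorb a heavily mutated star as bulges
and undercount mismatches.

**SSR signature.** The protocol's family signature value R has no
published formula. The package documents its stand-in: R = observed count
of the family's modal 3-mer in the mature / expected count under the
mature's mononucleotide composition, with R = 0 when the motif is absent;
the threshold R ≥ 2.5 is applied at the prediction-driver level against
the matched family. This is flagged as an artifact-specific definition in
the function documentation.

**Selection.** Among all-pass candidates at a locus, maximum MFEI wins;
ties break by maximum R, then shortest precursor, then lexicographic id.

## Target linking and eTM detection

**miRNA/UTR expectation scan.** The penalty scheme of plant target
predictors is reimplemented with documented constants: mismatch +1, G:U
+0.5, single-nucleotide target bulge +2, all doubled at miRNA positions
2–13; at most 2 target bulges; a site is a hit at expectation ≤ 5. Scores
are labelled "expectation-like" — they follow the published scheme but are
not the output of the external tool. Non-overlapping best sites are
reported per miRNA/target pair. The region label (5'UTR/3'UTR) is carried
through so either a joint or a per-region view is recoverable.

**eTM rules.** Positions are counted from the miRNA 5' end (position 1 =
first nucleotide); the one ambiguous phrase in the source protocol is
resolved in favour of the convention that makes its own rule i coherent.
A site must have: exactly one bulge, on the lncRNA side, between the
partners of miRNA positions p and p+1 with p in 9–12 (a bulge-free perfect
duplex is a cleavage site, not a mimic; a no-bulge mode exists for
sensitivity analyses); bulge length 1–3 nt by default ("only for three
nucleotides" is ambiguous between exactly-3 and at-most-3; a strict mode
requires 3); Watson–Crick pairing at positions 2–8 with G:U disallowed
there; and fewer than 3 mismatches + G:U pairs elsewhere. One physical
site can satisfy the rules under several adjacent bulge placements; the
detector reports all of them (matching the literal brute-force oracle) and
offers a collapsed one-row-per-site view used by the pipeline driver.

## Expression statistics

Fold changes are `log2((FPKM_b + c)/(FPKM_a + c))` with pseudocount c.
The DE gate is `|log2FC| ≥ 1` (2-fold) with p < 0.005 and BH-adjusted
q < 0.01; whether the published fold gate means 2-fold or log2-units-2 is
ambiguous, so `fc_thresh` is exposed (set 2 for the literal reading).
P-values may be supplied externally (assembly-level DE models are out of
scope); for replicate-free fixtures the package provides a clearly
labelled stand-in, an exact Poisson rate test on FPKM-scaled
pseudo-counts, which is *not* equivalent to an assembly-level dispersion
model and is used only to exercise the filter logic. Pair correlations are
Pearson r over per-stage log2 fold changes relative to the 0 DAA
reference; zero-variance profiles are flagged undefined and excluded from
binning (fractions at |r| ≥ 0.8 / 0.6 / 0.5 and sign split). The
comparative-Ct utility computes `2^(-ΔΔCt)`.

## The synthetic-data generator

The generator defines the study conditions under which everything is
tested; its defaults emulate the ten-sample design (leaf; bud at 0 days
after anthesis; seed and pod tissues at four later stages each).

* **Coding transcripts**: a strongly biased-codon ORF of 120–250 codons
  (≥ 100 aa by construction) with short UTRs. The codon bias (one
  GC-ending codon class preferred 10:1) gives coding sequences a hexamer
  signature that survives comparison with composition-matched shuffles.
* **lncRNAs**: AU-rich (A/U 0.35 each), 300–1200 nt, resampled until every
  ORF is < 100 aa.
* **Decoys**: mononucleotide shuffles of coding transcripts. Their planted
  FPKM of 0.5 gives each decoy a deterministic designed fate in the
  cascade (the `fpkm` stage); an ORF-stage fate would not be deterministic
  because a shuffle can contain a long ORF by chance.
* **Precursors**: 5' flank (8 nt) + mature + loop (6 nt) + star + 3' flank,
  where the star is the reverse complement of the mature with a configured
  number of substitutions that always break pairing (never create a
  wobble), so the planted mismatch count is exact. Every planted precursor
  is re-validated through the package's own hairpin screen (plus the SSR
  gate) at generation time and resampled up to 50 times; persistent
  failure is an error, never silent.
* **eTM sites**: the reverse complement of a miRNA with the configured
  bulge (default 3 nt between positions 10/11) spliced into a lncRNA host,
  re-detected at generation time.
* **Expression**: lognormal multiplicative noise (σ = 0.25 by default)
  around a 100-FPKM baseline; DE-designated transcripts carry a planted
  log2 fold change of 2 at the contrast stage; correlation-designated
  pairs draw per-stage log2 profiles with planted correlation 0.9 over the
  eight seed/pod stages. The source study gives no distributional account
  of its expression data; lognormal FPKM is a stand-in choice, not an
  inference about the study.

What passing tests show — and what they do not: fixtures plant exactly the
structure each stage is designed to detect, with none of the alignment
artifacts, chimeric assemblies, positional biases, or overdispersed counts
of real RNA-seq. Recovery rates on fixtures validate the *logic* of the
cascade and screens, not their field performance on real transcriptomes.

## Numerical and reproducibility choices

Problem sizes for the oracle suites were chosen to keep exhaustive
enumeration exact and the whole suite quick: folding is checked on 200
sequences up to 18 nt, the partition function on 100 sequences up to
15 nt (1e-9 relative), eTM equivalence on random 21-nt/200-nt pairs, and
recovery on fixtures of 30 precursors among 300 decoys and 100 planted eTM
sites. All generators and the pipeline driver are deterministic given
their seeds; pipeline outputs embed a hash of the configuration
(excluding the output directory) and are byte-identical across reruns.
Configuration lives in R lists serialized to JSON inside run metadata; no
separate config-file dialect is introduced, since the package's users
drive it from R and `scripts/acceptance.R` is the command-line entry
point for reproducing the headline numbers.

## Known limitations

* The energy model omits loop-sequence terms, dangling ends and
  temperature dependence; absolute energies are model units, and only
  normalized indices should be compared to published thresholds.
* Pseudoknots are out of scope throughout.
* The coding-potential score is a stand-in for external classifiers; with
  real data, supplying external scores through the pass-through route is
  preferable.
* The Poisson DE stand-in ignores biological dispersion; with replicates,
  use a dedicated DE package and feed its p-values to the filter.
* Small-RNA-seq evidence (read stacks, star expression) is not used; the
  miRNA branch is homology-only, as in the source protocol.
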