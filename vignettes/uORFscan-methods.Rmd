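---
title: "uORFscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{uORFscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uORFscan)
```

# The problem

Translation of most mRNAs initiates at the first AUG encountered by the
scanning 40S subunit. A variant in the 5' untranslated region (5'UTR) can
therefore rewire translation without touching the protein sequence: an
SNV or small deletion that creates an upstream AUG (uAUG), or one that
removes the stop codon of an existing upstream open reading frame (uORF),
redirects initiation away from the canonical start. The most damaging
configurations are those in which the upstream reading frame has no stop
codon within the UTR, so the ribosome runs into the coding sequence —
out of frame (an overlapping ORF, oORF) or in frame (a CDS elongation).
`uORFscan` provides the machinery to enumerate and classify every such
variant on a set of transcript models, to quantify the negative selection
acting on each variant class in population data through the
mutability-adjusted proportion of singletons (MAPS), to compare base-level
conservation at functional UTR positions, and to triage genes by how
likely a uORF-perturbing variant is to be deleterious.

# Data model and coordinates

A `TranscriptSet` holds, per transcript, the spliced 5'UTR sequence
(sense strand, 5' to 3') and a CDS prefix beginning with the canonical
ATG. All coordinates are 1-based positions into the concatenation
`UTR + CDS prefix`; the UTR occupies `1..L` and the CDS starts at
`L + 1`. The distance from a uAUG at position `a` to the CDS is
`d = L - a + 1` and its reading frame relative to the CDS is `d mod 3`
(frame 0 means an unterminated upstream frame reads the CDS in frame,
i.e. CDS elongation). Genomic strand handling is confined to the
readers: the GFF3 reader reverse-complements and splices minus-strand
features so that all downstream annotation is done on the sense-strand
spliced sequence, which is also how transcript sequences exported from
annotation databases arrive. Variants spanning the UTR/CDS junction are
rejected rather than guessed; windows containing N are skipped during
enumeration because the codon identity cannot be asserted.

# Consequence classification

For every candidate variant the post-edit sequence is scanned for the
first in-frame stop codon (TAA, TGA, TAG) lying entirely within the UTR
(`stop_start + 3 <= L + 1` in 1-based terms; codons straddling the
junction do not count). The consequence vocabulary is fixed to four
machine-joinable terms:

* `uORF_created` — a new uAUG with an in-frame UTR stop;
* `uORF_elongated` — a uORF stop removed, but a downstream in-frame UTR
  stop exists;
* `oORF_out_of_frame` — no in-frame UTR stop and frame != 0;
* `CDS_elongation` — no in-frame UTR stop and frame 0.

Kozak context strength is scored from the two most informative
positions: strong when the base 3 nt upstream of the A is A or G *and*
the base immediately after the G is G; moderate when exactly one
condition holds; weak otherwise. An absent upstream base (uAUG within
the first three transcript bases) counts as non-matching. Whether the
downstream context base is the one directly after the G (offset +3 from
the A) or the classical +4 column is a genuine ambiguity; we adopt
offset +3 and expose it as the `plusOffset` argument rather than hard-coding
a guess. When several uAUGs converge on one stop codon the uORF is
annotated with the strongest Kozak among them, and stop-removing SNVs
are emitted once per distinct stop codon using the 5'-most converging
start for distance/frame (all converging starts share the same frame, so
only `d` depends on this choice).

A variant is *high-impact* when it yields an oORF or CDS elongation
from a strong/moderate-Kozak start (for uAUG creation) or from a uORF
with strong/moderate Kozak or documented translation evidence (for stop
removal and frameshift). Translation evidence is matched by stop-codon
coordinate against a user-supplied catalogue (ribosome-profiling
repositories such as sorfs.org provide these in practice).

Three enumeration operations cover the variant space: all uAUG-creating
SNVs (every UTR trinucleotide one substitution away from ATG), all
stop-removing SNVs (exactly 7 for TAA and 8 each for TGA/TAG — the
combinatorics are asserted in the tests), and all uAUG-creating
deletions of 1-5 bp. Insertions are not enumerated (the space is
unbounded) but supplied insertions are annotated by `annotateVariant()`,
which diffs the uORF structure before and after applying the variant and
therefore also recognises the frameshift mechanism in which an indel
inside a uORF changes its frame so that the stop is bypassed and an
out-of-frame oORF results — the mechanism of the recurrent pathogenic
NF2 5'UTR insertion. A deletion is credited with a *new* uAUG only when
the post-edit ATG spans the deletion junction and the pre-edit window at
the same left-aligned position was not already ATG; deletions that
merely shift an existing ATG are excluded.

# MAPS

MAPS compares the observed number of singletons (allele count 1) in a
variant class against the number expected from mutability alone:

MAPS = (observed singletons − expected singletons) / observed variants.

Highly mutable sites (CpG transitions above all) recur in a cohort and
are less often singletons, so a raw proportion of singletons confounds
selection with mutability. The adjustment has three steps:

1. **Mutability table.** For each substitution in one base of flanking
   context (e.g. `ACG>ATG`), with C>T at CpG sites split into three
   methylation bins, the proportion of possible sites observed as
   variants in a neutral corpus (intergenic/intronic, autosomal,
   passing coverage 15-60x and −3.9885 < GERP < 2.6607 filters) is
   computed and rescaled so the possible-site-weighted mean equals the
   human per-base per-generation rate, 1.2e-8. Classes with zero
   observed counts get a 0.5 pseudocount so no rate is zero; classes
   with zero possible sites are excluded with a warning.
2. **Calibration.** The per-(context, bin) proportion of singletons
   among synonymous variants — neutral with respect to UTR biology but
   disjoint from the bases used to build the table — is regressed on
   the scaled rate. We use unweighted ordinary least squares by default
   with a `weighted` (by group size) option, since the choice is not
   forced by anything in the method; predictions are clipped to [0, 1].
3. **Expectation.** Each observed variant in the class under test
   contributes its predicted singleton probability; the sum is the
   expected singleton count in the MAPS formula.

Uncertainty is by case resampling: the n observed variants are resampled
with replacement (10,000 replicates by default) and the 5th/95th
percentiles of the recomputed MAPS form a 90% interval. The p-value for
"class B is under stronger selection than class A" resamples *both*
classes per permutation and reports the fraction of permutations with
MAPS(B) − MAPS(A) < 0 (whether one or both sets should be resampled is
not forced; we resample both, which treats the two sampling errors
symmetrically). A p of 0 is reported as `< 1/n_perm`. All resampling is
driven by a single integer seed and results are bit-reproducible.

# Conservation and enrichment

Per-base conservation scores (phyloP-like) are compared as the
proportion of bases at or above a threshold of 2, with Clopper-Pearson
95% intervals. The threshold uses `>=` by default with a `strict` flag,
since both conventions appear in practice and only boundary scores
differ. To control for gene context and distance to the CDS, uORF stop
bases are compared against *matched controls*: the 3 bases immediately
upstream and downstream of each stop, clipped at UTR bounds and
deduplicated, never including the stop itself. Contrasts use Fisher's
exact test (two-sided; odds ratio with Haldane correction when a cell is
zero) and the Wilcoxon rank-sum test (two-sided; exact below 50
observations without ties). Enrichment of a property among
disease-ascertained variants relative to the background of all possible
variants uses the one-sided binomial tail P(X >= k | n, pi) with pi the
background proportion — one-sided because the direction (enrichment of
severe configurations among pathogenic variants) is specified in
advance.

# Gene triage

Genes are assigned to nine classes by the first matching rule, in the
order 0, 1, 2, 3, 4, 5, 8, 7, 6 (see `?classifyGenes`). The order
matters and is asserted in the tests: known haploinsufficient / dominant-LoF
disease genes (class 8) are claimed before LOEUF-intolerant genes
(class 7), and a common high-impact variant (class 4, allele count
above 15, i.e. allele frequency above 0.1% at a ~15,708-genome cohort
scale — configurable because cohorts differ) is claimed before LoF
tolerance (class 5). A "high-confidence oORF" for class 3 is an
existing uAUG with no in-frame UTR stop and strong/moderate Kozak or
translation evidence. Classes group into likelihood bands: low (2-5),
moderate (6), high (7-8), unclassified (0-1). LOEUF sextiles, curation
flags and ClinVar counts are consumed as inputs; the package does not
recompute them.

# The synthetic-data generator

Real inputs for this analysis are large, licensed or version-pinned
(population variant databases, conservation score releases, clinical
variant databases), so the package ships a generator that emulates every
input at desk scale and makes the whole pipeline testable end to end.

**Transcripts.** UTR lengths are log-normal (meanlog = log 150,
sdlog = 0.6 — a median of ~150 nt with a heavy right tail, typical of
human 5'UTRs), GC content 0.6 (5'UTRs are GC-rich), a 5% fraction of
genes with no UTR (gene class 0 fodder). uORFs of a requested Kozak
class are planted by writing the context bases, ATG, a non-stop spacer
codon and TGA explicitly; existing oORFs are planted near the UTR end
with downstream in-frame stops scrubbed. Everything planted is
re-detected by the annotation module — the generator is not allowed to
disagree with the annotator, and a test asserts this.

**Population corpus.** Selection is modelled phenomenologically as an
inflation delta of the singleton probability — exactly the quantity MAPS
estimates — rather than through an explicit population-genetic model;
this makes parameter recovery an exact acceptance surface (MAPS of a
class with inflation delta should equal delta up to sampling noise).
Each possible site draws a context from the rate table (CpG contexts
down-weighted in abundance, as in real genomes); it is observed with
probability `min(presenceScale * mu, 0.99)` with presenceScale = 4e6, so
that a 1.2e-8 site is observed ~5% of the time and the fastest CpG bin
~48% — comparable to the saturation pattern of a ~15,000-genome cohort,
and linear in mu so the observed/possible proportion is an unbiased
readout of the true rate. Observed sites are singletons with probability
`plogis(0.2 − 0.05 * mu/1e-8) + delta`: a logit-linear decline from
~0.55 at the genome-average rate to ~0.40 at the fastest CpG bin
reproduces the mutability confounder the calibration must remove, and
the mild slope keeps the relationship near-linear so unweighted OLS
calibration closes (in-sample MAPS of the calibration class is ~0, which
a test asserts at |MAPS| < 0.005). Default true rates: transversions
5e-9, transitions 1.2e-8, each modulated ±25% by flanking GC; CpG C>T
bins 3e-8 / 6e-8 / 1.2e-7. Coverage ~ N(30, 8), GERP ~ N(0, 1.5), 3%
sex-chromosome sites and 2% QC failures give the filters realistic work
to do without starving any class.

**What the generator does not emulate:** linkage, demography, coverage
heterogeneity along the genome, correlated conservation scores, isoform
structure, and context composition tied to the actual simulated
sequences (class corpora draw contexts from the table's abundance
weights). Passing tests therefore demonstrate the *statistical
machinery* — enumeration exactness, calibration closure, signal
recovery, resampling calibration, rule order — not distributional
realism of human variation data.

# Numerical and testing choices

* Degenerate inputs: empty observation sets error after filtering;
  calibration requires at least two distinct rates; `conservedProportion`
  and the rank-sum test reject empty inputs; a variant whose `ref` does
  not match errors with expected-vs-found.
* Ties: the first (5'-most) in-frame stop defines a uORF; later ones are
  kept as alternative stops. Stop-removal records tie-break to the
  5'-most converging start and strongest Kozak.
* Determinism: every stochastic stage takes an explicit seed; fixed seed
  gives bit-identical results (asserted for the bootstrap and the
  pipeline manifest).
* Problem sizes used by the test suite: oracle equivalence on 500 random
  UTRs of length 10-300; MAPS neutrality/recovery at ~50,000 observed
  variants per class (tolerance ±0.02); bootstrap coverage over 200
  replicates of n = 2,000 with 1,000 bootstrap replicates (accepted at
  85-95%); permutation-null uniformity over 200 repeats of 400
  permutations (Kolmogorov-Smirnov at alpha = 0.01); statistical tests
  against exact enumeration oracles for all instances with n <= 10.
  These sizes make the full suite run in a couple of minutes while
  leaving the binomial/bootstrap noise floors well inside the stated
  tolerances.

# Limitations

The package classifies *potential* translational consequences; it does
not model reinitiation, leaky scanning or translation-efficiency
effects, does not resolve multi-isoform annotation (one transcript model
per gene is assumed the canonical one), does not enumerate insertions,
and treats 3'UTRs as out of scope. MAPS is a rank statistic for relative
selection strength between classes, not an estimate of fitness effects.
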