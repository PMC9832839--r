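---
title: "Core InDel marker design with subgenome specificity screening"
author: "coreindel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core InDel marker design with subgenome specificity screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coreindel)
```

## The problem

Autopolyploid crops such as hexaploid sweetpotato carry six near-identical
copies of every chromosome. Resequencing cohorts against one subgenome copy
yields millions of SNPs and InDels, but turning those calls into
*usable PCR markers* is dominated by two failure modes:

* **Population-genetic uselessness.** A marker whose minor allele is rare,
  whose length difference is too small to resolve on a gel, or whose
  heterozygosity is inflated by collapsed paralogs distinguishes almost
  nothing.
* **Off-target amplification.** A primer pair designed against one
  subgenome copy will usually also bind the five homologous copies — that
  is expected and tolerable (the "allelic loci") — but in a
  repeat-rich genome many pairs additionally bind unrelated loci and
  amplify garbage.

`coreindel` implements the full path from a multi-sample InDel VCF plus a
multi-subgenome reference to a screened, co-dominant core marker set and
per-sample molecular IDs, with every filtering rule and design constraint
explicit, parameterized and tested.

## Pipeline model

The pipeline is a pure function of its inputs; every stage is exposed on
its own:

1. **Variant quality control.** GATK-style hard filters per variant class
   (SNP: `QD < 2.0`, `FS > 60.0`, `MQ < 40.0`, `MQRankSum < -12.5`,
   `ReadPosRankSum < -8.0`; InDel: `QD < 2.0`, `FS > 200.0`,
   `ReadPosRankSum < -20.0`; an absent metric skips its clause, the GATK
   convention, because low-complexity sites legitimately lack rank-sum
   annotations), then vcftools-style cohort site filters
   (`--max-missing 0.5 --mac 3 --minQ 30 --maf 0.05 --minDP 3`), where
   `max-missing` is a minimum call-rate fraction and the depth mask is
   applied to genotypes *before* site statistics. Whether marker statistics
   should be computed before or after depth masking is genuinely open; we
   mask first (a genotype supported by fewer than 3 reads in a hexaploid
   is noise) and expose `mask_depth = FALSE` to disable it.
2. **Marker candidacy** (`marker_candidate_filter()`): keep bi-allelic
   InDels with length difference `>= 5` bp, heterozygosity `<= 0.80` and
   MAF `>= 0.2`. All bounds are closed on the retained side: the rules are
   stated as strict filters ("more than 80%", "less than 0.2"), so
   boundary values survive. Multi-allelic records are rejected outright
   rather than split — splitting would manufacture markers whose gel
   interpretation is ambiguous.
3. **Primer design** (`design_primers()`): 200 bp flanks on each side of
   the InDel are the template; forward primers are enumerated exhaustively
   in the upstream flank and reverse primers in the downstream flank over
   lengths 20–26 bp, and a pair is emitted only if product length (on the
   REF allele) lies in [100, 200] bp, both Tm in [58, 64] °C,
   `|ΔTm| < 2` °C (strict), GC in [35, 65] % (inclusive), the product
   spans the InDel (guaranteed by construction), and self/cross dimer
   screens pass. The ALT product length is
   `product_len_ref + (|alt| - |ref|)`.
4. **Specificity screening** (`screen_pairs()`): every primer is aligned
   against *all* subgenome copies; a pair survives only if all of its
   binding sites are the designed target or its allelic loci.
5. **Core set and molecular IDs** (`assemble_core_set()`,
   `select_discriminating_set()`, `encode_ids()`): best pair per marker,
   density summary, in-silico PAGE bands per sample, and a minimal
   discriminating marker subset.

## The melting-temperature engine

The tool the printed parameters come from reports acceptance windows, not
a thermodynamic model, so the engine is a documented package choice: the
unified nearest-neighbor parameter set (ΔH, ΔS per dinucleotide stack,
with terminal initiation terms), entropic monovalent-salt correction

$$\Delta S' = \Delta S + 0.368\,(n-1)\ln[\mathrm{Na}^+]$$

and, for a non-self-complementary oligo at total strand concentration
$C_T$,

$$T_m = \frac{1000\,\Delta H}{\Delta S' + R\ln(C_T/4)} - 273.15 .$$

Defaults are 50 mM monovalent cation and 50 nM oligo, the conventional
defaults of mainstream primer-design software. The engine is deterministic
and is cross-checked in the test suite against an independently coded
term-by-term summation oracle to within 0.01 °C, and for monotonicity in
GC content and salt. The penalty used for ranking pairs,

$$\mathrm{penalty} = |T_{m,f} - 61| + |T_{m,r} - 61|
  + 0.5\,(|L_f - 23| + |L_r - 23|) + |\Delta T_m|,$$

is an invented, isolated scoring rule (optimum at the window centers);
ties are broken lexicographically by
`(penalty, fwd_start, product_len_ref, fwd_seq)` so ranked output is
reproducible bit for bit. Primers with homopolymer runs of 5+ bases are
rejected as a stability heuristic. The dimer screen computes the longest
ungapped antiparallel complementary run between two oligos — equivalently
the longest common substring of one primer and the reverse complement of
the other — and fails at a run of 8 anywhere or 5 anchored at either 3'
end.

## What "matched" means in the specificity screen

The six subgenome copies are collinear at chromosome scale but diverge by
point substitutions, so primer matching must tolerate mismatches away from
the 3' end (polymerase extension requires a matched 3' terminus). A *hit*
is an ungapped full-length alignment with at most `max_mismatch = 2`
mismatches overall and none in the 3'-terminal `three_prime_exact = 5`
bases. All three knobs are exposed.

Hits are found with a positional k-mer index (`k = 12`, plus strand;
minus-strand queries go through the reverse-complement k-mer). Seeding
from the 3'-terminal k-mer alone would be lossy — a legitimate hit may
carry a mismatch inside the terminal k-mer but outside the exact zone — so
the search queries the whole Hamming neighborhood of the terminal k-mer
(every k-mer within `max_mismatch` substitutions of it, holding the exact
zone fixed; 211 lookups at the defaults) and verifies every candidate base
by base. Any valid hit agrees with the terminal k-mer in all but at most
`max_mismatch` positions, so its genomic k-mer is in that neighborhood:
the seeding is provably lossless, and the test suite asserts exact hit-set
equality with an exhaustive per-offset aligner.

Hit classification: `TARGET` is the designed binding position and strand
on the marker's own contig; `ALLELIC` is a hit on another contig of the
same homology group within `window = 1` Mb of the designed position
projected by contig-length ratio. The copies emitted by the synthetic
generator are exactly collinear, making the projection the identity and
the classification exactly testable; the window absorbs modest structural
drift in real assemblies and is configurable. Everything else — including
contigs absent from the subgenome map — is `OFF_TARGET`.

Two screening modes exist. `strict` (default) rejects a pair if *any* hit
of either primer is off-target, the conservative reading of a per-primer
retention rule. `amplicon` mode instead predicts products from convergent
hit pairs (forward-plus, reverse-minus, ≤ 2 kb) and rejects only pairs
with an off-target *product*; it is useful because isolated single hits
cannot amplify, and strict mode over-rejects them. Strict retention
provably implies amplicon retention, which the suite asserts. In both
modes a pair must actually hit its own target with both primers in the
designed orientation; a missing target hit indicates an inconsistency and
rejects (`NO_TARGET_HIT`).

## Molecular IDs

A band-state matrix (samples × markers over `R`/`A`/`H`/`N`) is predicted
from genotypes: the markers are co-dominant, so heterozygotes show both
product sizes. Markers whose REF/ALT product difference is below the PAGE
resolution (5 bp, a parameter inherited from candidacy rule ii) are
excluded from band prediction rather than silently kept.

The minimal discriminating subset is a greedy set cover over unordered
sample pairs: repeatedly pick the marker that resolves the most
currently-unresolved pairs, where a pair is resolved when its two samples
differ in state and *neither is `N`* — a missing band on a gel is not
reliable evidence of difference, so `NULL` never resolves. Selection stops
at closure (every pair the full panel can resolve is resolved), ties break
by genome order, and inherently indistinguishable pairs are reported. The
selection algorithm behind published marker panels is typically unprinted;
greedy set cover is the standard auditable choice, and on small instances
the suite compares it against an exhaustive optimum (greedy is within the
classical `1 + ln(#pairs)` factor and equals the optimum on the shipped
structured fixtures).

A lower bound worth knowing: with at most $s$ observed states per marker,
distinguishing $N$ samples needs at least $\lceil \log_s N \rceil$
markers.

## The synthetic generator

Real hexaploid resequencing data is terabyte-scale; the package instead
ships a deterministic generator (`sim_config()`, `simulate_reference()`,
`simulate_variants()`, `spike_off_target()`) that emulates the features
the pipeline actually exercises:

* homology groups of near-identical copies (default 6, divergence 1 %
  substitutions per base per copy, no inter-copy indels so coordinates
  stay collinear);
* bi-allelic InDels implanted on the reference copies at disjoint
  template slots (≥ 450 bp apart), with controlled length difference,
  target MAF/heterozygosity (genotype model
  `P(het) = h`, `P(hom-alt) = m - h/2`), and missingness (default 5 %);
* planned violations of each candidacy rule (20 % each by default) so
  every filter branch is populated;
* off-target spiking: whole 450 bp templates copied onto a contig of a
  different homology group, giving markers that *must* be rejected.

The truth table's candidacy decision is computed from the *realized*
emitted genotypes by direct counting — with 50 samples a marker aimed at
MAF 0.25 can realize 0.19, and the truth is what the VCF contains, not
what was planned. Genotypes are diploid-style throughout, mirroring a
diploid caller run on a polyploid; allele dosage is a documented model
simplification, not something the generator tries to emulate. Likewise
absent from the generator: repeat families and transposons (off-target
hits in it arise only from spiking or rare chance k-mer collisions), read
errors and mapping artifacts, and recombination or pedigree structure.
Passing tests on this fixture therefore demonstrate the *logic* of the
pipeline — filter exactness, constraint compliance, screen soundness —
not recall/precision on a real repeat-rich genome.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere (VCF convention); any
  exported BED would be 0-based half-open.
* `N` bases are legal in genomes but any template flank or primer
  containing `N` is skipped/rejected (undefined thermodynamics); k-mers
  containing `N` are not indexed.
* Soft-masked (lowercase) input is uppercased on load; masking is not
  retained.
* Records with zero called genotypes have undefined statistics and fail
  every threshold filter.
* Homology between chromosome copies is declared explicitly in a
  subgenome-map TSV (`group_id`, `contig_id`, `is_reference`) rather than
  inferred from naming conventions.
* Raising `max_mismatch` never removes hits; shrinking the allelic window
  never converts `OFF_TARGET` to `ALLELIC` (monotonicity, tested).

## Problem sizes used by the test suite

The suite validates at deliberately desk-scale sizes chosen to exercise
every code path with tight oracles: a 3-group × 6-copy × 1 Mb genome with
5 000 InDels and 50 samples for the end-to-end run; 1 000 random templates
for constraint compliance; 1 000 random oligos for the Tm oracle; 200
primers against a 6 × 100 kb genome for hit-set equality; 50 markers with
10 spiked for screen soundness; 64 samples for molecular IDs. Headline
counts from any real cohort (tens of thousands of eligible InDels, a few
thousand retained pairs) depend on the organism, the repeat content and
the sequencing depth and are not reproduced by the fixture.

## Known limitations

* Ungapped primer matching only; an off-target site with an internal
  indel relative to the primer is not found (rare for 20–26-mers, but
  real).
* No thermodynamic secondary-structure folding, probe design or multiplex
  grouping.
* The allelic-locus rule is geometric (length-ratio projection within a
  window); highly rearranged subgenomes would need anchor-based
  projection.
* Amplicon prediction considers the canonical convergent orientation
  (forward on plus, reverse on minus); a pair binding with swapped roles
  is only caught by strict mode.
* InDel normalization (left-alignment) is assumed done by the caller.
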