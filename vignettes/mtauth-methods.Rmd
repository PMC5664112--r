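---
title: "Authenticating ancient mitochondrial genomes with mtauth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Authenticating ancient mitochondrial genomes with mtauth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

DNA surviving in archaeological bone is fragmented to well under 100 bp,
chemically damaged, and always at risk of being swamped by modern human DNA
introduced during excavation, handling, or laboratory work. Before an
ancient mitochondrial genome can be interpreted, three quantitative checks
are standard:

1. **Damage profiling.** Post-mortem deamination converts cytosine to
   uracil, which sequencing reads as thymine. Because single-stranded
   overhangs at fragment ends deaminate fastest, authentic ancient libraries
   show an elevated C→T rate at the 5′ terminal read position (and,
   symmetrically, G→A at the 3′ end) decaying into the read. Treating the
   extract with uracil-DNA-glycosylase (UDG) excises uracils and strongly
   attenuates the signal.
2. **Phylogenetic consistency.** The consensus haplotype should carry the
   defining variants of a single haplogroup lineage, with few unexplained
   ("private") mutations.
3. **Contamination estimation.** At positions that define the sample's
   haplogroup, reads from a contaminating individual of another lineage show
   non-consensus bases; their pooled frequency estimates the contaminant
   fraction.

`mtauth` implements these checks as a reusable, tested pipeline, together
with a read simulator that generates data with known truth so every stage
can be validated without external downloads.

## The simulator: the stated world

`simulate_reads()` draws `n` fragments from a sample genome built by
applying a haplotype to a circular reference. Its parameters and defaults:

| parameter | meaning | default | why |
|---|---|---|---|
| `frag_len_mean`, `frag_len_sd` | log-normal fragment length (bp), rounded and truncated to `[25, 150]` | 68, 15 | mapped-fragment means just under 70 bp are typical of well-preserved ancient material |
| `contamination` | probability a fragment comes from the contaminant genome | 0 | experiment-specific |
| `delta5`, `delta3` | terminal C→T / G→A deamination probability | 0.25 | the observed terminal rate of an untreated ancient library (~23%) rounded to the conventional simulation value |
| `rho` | geometric decay of deamination per base from the end | 0.6 | no quantitative decay curve is printed in the motivating study; 0.6 gives the fast few-base decay seen in empirical MapDamage tables, and the recovery tests treat it as a parameter to estimate, not a constant |
| `udg_residual` | multiplier on both deltas for UDG-treated libraries | 1 | UDG is modelled as a single residual factor because the treated/untreated contrast is binary in practice |
| `seq_error` | per-base miscall probability, uniform to the three other bases | 0.001 | Q30-scale error |
| `duplication_rate` | expected PCR duplicate copies per fragment (Poisson) | 4 | gives the ~80% duplicate fraction of heavily amplified capture libraries |

Damage is applied before sequencing error (lesion, then miscall), in read
orientation: a C at 5′ offset `k` becomes T with probability
`u·δ5·ρ^k`, symmetrically G→A from the 3′ end. Reverse-strand reads are
emitted in reference orientation; the damage channels map accordingly.
Fragments spanning the circular origin are emitted as two SAM segments
sharing a read id with an `XC` tag, which downstream stages re-join; this
keeps the SAM standard-conformant without a shifted reference. Duplicates
are exact copies (they share the molecule, including its damage and
errors). Identical inputs and seed give bit-identical output.

**What the generator does not emulate:** base-quality variation (constant
Q30), adapter artifacts, mapping ambiguity or reference bias, indel
sequencing errors, heteroplasmy, and CpG-specific UDG survival. A green test
therefore establishes the correctness of the statistical machinery on an
idealized library, not robustness to alignment artifacts.

## Synthetic fixtures

The true human mitochondrial reference and the published haplogroup tree
cannot be redistributed here, so the package ships deterministic synthetic
stand-ins (`synthetic_reference()`, `inst/extdata/*_synthetic.*`) that
reproduce the structural facts of the motivating analysis:

* a 16,569 bp circular reference with the placeholder N at position 3107;
* a haplogroup tree whose U1a1a-like path carries **50 substitution
  defining positions plus one insertion (3158.1T)**. Nineteen of the 50 lie
  above the reference's own branch point, so their expected allele *equals*
  the reference base — this is how a haplogroup can have 50 defining
  positions while the sample differs from the reference at only 35;
* an endogenous haplotype of **38 tokens, 35 after the conventional
  exclusions** (the 3107 placeholder and the 309.1/309.2 C-stretch slots),
  including three private mutations (5480G, 8573A, 16129A);
* a deep-rooting contaminant lineage that differs from the endogenous
  genome at **all 50** diagnostic positions. This matters: the pooled
  estimator counts contaminant bases only where lineages differ, so a
  contaminant sharing alleles at some sites biases the estimate downward in
  proportion to the shared fraction. The packaged world models the fully
  discriminating case; with a partially overlapping contaminant the
  diagnostic estimate is a lower bound.

## Consensus calling

Majority rule over {A, C, G, T, deletion} with N-masked bases excluded from
the vote: call iff depth ≥ `min_cov` (default 10) and majority fraction ≥
`min_frac` (default 0.7), else N. A fraction exactly at the threshold calls
the allele; an exact count tie calls N. Insertion slots are called against
the anchor position's depth, in ascending slot order, stopping at the first
failure. The defaults are exposed configuration, not claims about any
particular commercial caller's thresholds, which are undocumented. Deletion
calls compete in the same vote; C-stretch slots are called by the same rule,
a simplification relative to full forensic length-heteroplasmy alignment
rules (out of scope).

## Haplogroup scoring

Every node of the tree is scored by `matched/expected` over the cumulative
defining variants of its root-to-node path. A defining variant whose
expected allele equals the reference base is matched when the query has *no*
substitution there (this is why the scorer takes the reference as an
argument); otherwise the query must carry the expected allele. Back-mutation
tokens (`...!`) expect their recorded ancestral allele. **Ranking is by
matched count, then score fraction, then name**: a deeper node explaining
more of the haplotype outranks a fully matched but shallow ancestor, while a
fully matched node outranks a deeper child missing a variant — which is the
behaviour that reports "U1a1a, all variants present; U1a1a1 missing
11467G". (Ranking by fraction alone would let any fully-matched ancestor of
a near-complete node win, which contradicts how haplogroups are actually
called.)

## Contamination estimation

**Diagnostic (pooled) estimator.** At the diagnostic sites,
`ĉ = Σ non-consensus bases / Σ depth`, deletions counted as non-consensus,
N-masked bases excluded. "Non-consensus" means *any* base other than the
expected allele, not only the alternative-lineage allele. The default
interval is the Wilson score on the pooled counts (boundary cases pinned at
exactly 0/1 so floating-point jitter cannot exclude the boundary); a seeded
position-level bootstrap (2,000 resamples) is available for users worried
about site-level clustering. Exact reproduction of any published interval is
not promised, since published intervals rarely state their procedure.

**Damage filter.** A site is excluded iff its expected allele is C or G
*and* at least one observation of the damage product (T under C, A under G)
is present — presence, not a rate threshold, following the method's
published wording; the threshold is configurable (`min_obs`) for sensitivity
analysis. On a damaged library this removes the positions where deamination
masquerades as contamination, and the filtered estimate drops accordingly —
the structural analogue of a published ~1.9% → ~1.0% drop when 50 positions
were reduced to 29.

**Mixture estimator.** Per read, `L_g = (1−ε)^n (ε/3)^m` over aligned
non-N positions against the endogenous genome and each panel genome;
`ĉ` maximizes `Σ_r log[(1−p)·L_endo + p·mean_g L_g]` over a 1,001-point
grid, with a 95% profile-likelihood interval (log-likelihood within
`qchisq(0.95, 1)/2 ≈ 1.92` of the maximum). Reads overlapping no
discriminating site contribute a constant. Genomes are compared in
reference-coordinate substitution space: insertions are ignored and deleted
positions skipped, a deliberate simplification (indels contribute almost no
discriminating sites on mtDNA and keeping the likelihood per-position keeps
the estimator transparent). This is a grid-ML cross-check of the diagnostic
method, not a re-implementation of the full Bayesian mixture-with-MCMC
machinery, which is out of scope.

## Numerical and design choices

* **Coverage target.** The acceptance experiments check that the filtered
  estimator's 95% CI covers the *dataset's realized* contaminant fraction
  (recorded in the simulation truth), not the nominal mixing parameter: the
  nominal value additionally carries the binomial noise of the mixture draw
  itself (sd ≈ 0.001 at c = 0.05, n = 50,000), which no read-level estimator
  can cover and which is not estimator error.
* **Noise in calibration runs.** The coverage and damage-confound
  experiments simulate with `seq_error = 0`: a uniform miscall rate ε adds a
  known ≈ ε upward bias to the pooled non-consensus rate (visible in the
  README example), which is a property of the measurement, not of the
  estimator; with it, CI coverage of c = 0 would be impossible by
  construction.
* **Duplicate definition.** Fragments are grouped by both endpoints plus
  strand (merged single-end fragments make both ends informative);
  representative = highest total base quality, ties to the smallest read id.
  At 10,000 fragments on a 16.6 kb circle, coincidental endpoint collisions
  inflate the duplicate fraction by ≈ 0.1–0.3 percentage points over the
  Poisson expectation λ/(1+λ); the tests account for this.
* **Offsets.** Damage-table offsets are 0-based from each read end, and a
  published "frequency at the 5′ end" is interpreted as the offset-0 rate.
* **Ignore-set matching.** Ignore entries may be full tokens (`16129A`) or
  position slots (`3107`, `309.1`); the default set is
  `{3107, 309.1, 309.2}`, matching the convention of quoting 35 differences
  "(38 if 3107, 309.1 and 309.2 are included)".
* **Degenerate inputs.** A reference shorter than the maximum fragment is a
  parameter error; zero-coverage diagnostic sites are an error (not a rate
  of 0); an estimator fed only non-discriminating reads flags the result
  `uninformative`; grid maximizers on the boundary are flagged `boundary`.

## Known limitations

* The fixtures are synthetic; position numbers echo the real phylotree
  where convenient, but alleles are constrained by the synthetic reference.
  Analyses of real data must supply the real reference, tree, and panel.
* The mixture estimator's ε is a single global error rate; damage is not
  modelled in its likelihood, so it should be run on UDG-treated data or
  with damage-affected positions removed.
* Length-heteroplasmy (C-stretch) calling is simplified to per-slot
  majority votes; forensic alignment conventions around 309.x/16193.x are
  not fully implemented.
* The benchmark against the motivating study's deposited sequencing data
  requires downloading those accessions and is not run offline; the
  analysis-only pipeline path it would use (`run_pipeline(list(sam = ...))`)
  is exercised on synthetic SAMs instead.
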