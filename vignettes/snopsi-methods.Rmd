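---
title: "Models and methods in snopsi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in snopsi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snopsi)
```

`snopsi` analyzes three data modalities around snoRNA biology in paired
tumor/normal designs — Ψ-seq (pseudouridine mapping by reverse-transcriptase
termination), snoRNA-seq counts, and pooled CRISPR screen counts — and ships
synthetic generators with known ground truth for all three. This vignette is
the package's account of its models, the choices behind them, and what the
bundled benchmarks do and do not establish.

## The termination model and the Ψ-ratio

Ψ-seq chemistry leaves an adduct at pseudouridines that stalls the reverse
transcriptase, so the 5′ ends of cDNA reads accumulate at modified sites.
The per-site statistic is the **Ψ-ratio**: reads beginning at the site
divided by reads overlapping it. Two conventions needed fixing because the
phrase "reads overlapping it" is ambiguous and published implementations
differ:

* **Denominator.** A read that begins at a site also overlaps it, so
  `n_overlap` includes beginning reads and the ratio is a proper fraction
  in [0, 1], interpretable as the termination fraction among site-covering
  reads. The alternative (excluding beginning reads from the denominator)
  is an odds, not a fraction, and is unbounded.
* **Offset.** By default a stalled read's 5′-most base *is* the site
  (`offset = 0`); `offset = 1` selects the convention in which the RT
  stops one nucleotide 3′ of the adduct. Both the simulator and
  `psi_ratio()` take the same knob, and the unit tests verify that the
  pile-up moves accordingly.

The generator models cDNA synthesis 3′→5′ from a uniformly placed 3′ start.
Walking toward the 5′ end, synthesis stops at a pseudouridine of
stoichiometry $f$ with probability $f \cdot e$ (termination efficiency $e$),
at any other base with the background rate $b$, and everywhere with the
geometric length hazard $1/L$ (mean read length $L$). These hazards act
independently per position, which yields a closed form used throughout the
tests: conditional on a read covering a position, it *starts* there with
probability equal to the combined stop hazard, so

$$E[\hat\Psi] = 1 - (1 - f e)(1 - 1/L)$$

at a site, and the same expression with $b$ in place of $fe$ at background
positions (`expected_psi_ratio()`). Two consequences worth knowing: even a
fully unmodified site shows the baseline $\approx 1/L$ (uniform-start
pile-up), and sites 5′ of a strongly modified site sit in its coverage
shadow. The simulator sizes the read count so that realized mean coverage
matches the requested target under these hazards (verified to within 10%).

Defaults: termination efficiency 0.8 (efficient but imperfect chemistry),
background 0.01 stops/nt (capped at 0.05 — spurious stops are rare), mean
read length 80 nt (small-fragment libraries), coverage 2000× (deep rRNA
sequencing), all overridable per `sim_psi_config()`.

`build_profile()` accepts SAM/BAM (via Rsamtools; SAM is converted on the
fly) or an alignment tibble; start counts use the reference 5′-most aligned
base and overlap uses the CIGAR reference span. rRNA references are
single-stranded, so reverse-strand alignments are discarded and counted.
`psi_ratio()` reports a site as missing below `min_coverage` (default 20
overlapping reads: the binomial standard error of a ratio near 0.5 is then
below 0.12); the threshold is exposed because the appropriate filter
depends on sequencing depth.

## Paired differential pseudouridylation

Three levels of contrast, all built on a paired design table
(`unit`, `sample_a`, `sample_b`):

* `site_tests()` — per-site paired two-sided *t*-test (Wilcoxon available),
  mean paired difference, and a log2 fold change of mean ratios with
  pseudocount $10^{-3}$ to guard fully unmodified sites. Sites are flagged
  on the raw p-value at 0.05 — per-site Ψ analyses in this field are
  conventionally reported on raw p — and BH q-values are always reported
  alongside for FDR-aware use. Zero-variance differences are flagged
  degenerate with p = 1 rather than erroring.
* `hotspot_test()` — regions of adjacent modified uridines (e.g. an
  18S-like 105/109/119 triplet, a 28S-like 3700–3732 stretch) are
  summarized per sample by the *sum* of site ratios (`region_sum()`), then
  compared by paired *t*. A sample missing any region site drops its whole
  pair, so sums are always over the same sites.
* `global_shift_test()` — a transcriptome-level Wilcoxon signed-rank over
  per-site condition means, restrictable to a site subset. This is how a
  snoRNP-knockdown signature is dissociated: H/ACA-guided sites shift,
  unguided sites do not.

Wilcoxon details are pinned down because implementations differ: zero
differences are dropped (the classical convention), the exact null is used
for up to 25 informative pairs when there are no ties among absolute
differences, and the normal approximation with continuity correction
otherwise.

## snoRNA quantification and paired DE

`count_snornas()` assigns a read to a snoRNA when at least half of its
aligned length overlaps the annotated interval on the same strand
(`min_overlap_frac = 0.5`); multi-hits go to the larger overlap and exact
ties are discarded and counted. The rule is deliberately simple and fully
stated, since small-RNA protocols rarely publish theirs; the conservation
`assigned + unassigned + ties = total` is tested. Annotation intervals
follow the BED convention (0-based half-open).

`class_fractions()` divides class read sums by **total mapped reads** (not
snoRNA-only totals), so the shares are comparable to pie-chart style
library composition summaries; the remainder is reported as `unassigned`
and shares sum to one.

`paired_de()` normalizes to CPM of total mapped reads, takes
`log2(cpm + 0.5)`, and tests each snoRNA across pairs with the paired
Wilcoxon (paired *t* by flag). The volcano flags use log2 FC > 1.5 with
p < 0.05 (`enriched`; `depleted` symmetric). At n = 7 pairs the exact
Wilcoxon can reach p = 2/128 ≈ 0.016, so the joint flag is attainable but
demands near-complete concordance across patients — an intentional
property of the small-cohort design.

### What the count generator emulates

`simulate_snorna_counts()` draws negative-binomial counts around
log-normal baseline abundances calibrated so C/D and H/ACA class totals
take configurable shares of total mapped reads (defaults 16% and 4.4%,
typical of lung tissue libraries; 242 and 67 members, the scale of an
annotated human snoRNA capture). Its variance decomposition mirrors what
makes matched designs powerful: a global per-patient effect (library/
tissue scale, log-normal sd 0.3) and a **gene-by-patient** effect (that
patient's biological level of each snoRNA, log-normal sd 0.3) are both
shared by the tumor and normal sample of a pair and therefore cancel in
paired contrasts, while the residual NB dispersion (0.05) represents
technical and sampling noise that does not cancel. Early drafts lumped all
biological variation into independent per-sample dispersion, which
systematically understates the power of a paired design; the decomposition
above is the faithful emulation. Both patient effects are drawn mean-one
so the class-share calibration stays unbiased. A designated set of H/ACA
snoRNAs (default 9) carries a common true tumor/normal fold change
(default 4).

## Screen analysis

The screen generator evolves each gRNA's relative abundance as
$w_0 (1+s)^{d}$ with $d$ doublings elapsed and $s$ the per-doubling fitness
effect of its target's knockout ($|s| < 1$; non-targeting controls have
$s = 0$), then draws a fixed number of reads per sample multinomially —
counts conserve depth exactly, and replicates share $w_0$ and $s$ but not
sampling noise. Defaults mirror a dropout screen sampled at days 0/3/5/9
with two replicates.

Analysis is deliberately transparent rather than model-based:
counts-per-million per sample, `log2((cpm_t + 0.5)/(cpm_0 + 0.5))` against
the day-0 library, and target aggregation by the median gRNA LFC within
each replicate averaged over replicates. The null is built by drawing
size-matched gRNA sets from the whole library (non-targeting guides
included) and aggregating them identically; one-sided permutation p-values
(floored at $1/(n_{perm}+1)$) are computed for depletion and enrichment,
each direction forming its own BH family across targets — the convention
of established screen tools, and the shape of the output table (separate
depletion/enrichment p and FDR columns). Consequently the FDR guarantee is
per direction: on a global-null screen, each family's probability of any
call at threshold q is about q (verified empirically at q = 0.25), and an
any-direction call rate approaching 2q is expected, not a defect. The
default call threshold FDR ≤ 0.8 is deliberately permissive, as screen
hit-calling often is; it is a flag, not a recommendation. Targets with a
single gRNA are reported untested; composition effects (strong depleters
inflating everyone else's CPM) are visible as a small positive shift of
null LFCs and are absorbed by the permutation null, which is drawn from
the same library.

## Guide–target integration

`join_results()` links the snoRNA volcano table to per-site differential-Ψ
statistics through a guide→site map; a site may carry several guides
(shared targets are common), and unmapped entries on either side pass
through flagged rather than vanishing. `concordance_test()` reduces the
linked table to distinct sites — a site is "guide-up" if *any* of its
guides is enriched, "hyper-Ψ" if its raw p < 0.05 with positive delta (the
red-point convention of volcano displays; a q-value variant is a flag
away) — and tests the 2×2 association. The default is the Fisher exact
test; the permutation mode shuffles which sites are hyper-Ψ while holding
both margins fixed, a one-sided enrichment test that agrees with the
hypergeometric upper tail. The Fisher p itself is computed by a vectorized
conditional exact routine (`fisher_exact_p()`, dhyper-based, with the
customary `1 + 1e-7` two-sided tie tolerance); it matches
`stats::fisher.test` on random tables and an exhaustive log-binomial
enumeration over every margin class with table total ≤ 60 to below 1e-9.
Degenerate margins (all sites hyper, or none) return p = 1 with a status
flag. The sample (cross-product) odds ratio is reported as the effect
descriptor.

## Pipeline, configuration, determinism

`run_pipeline()` executes simulate → quantify → test → integrate on a
bundled synthetic scenario: two mock rRNA molecules (1800 and 4500 nt)
carrying 32 annotated sites — including the 105/109/119 hotspot triplet,
a 3700–3732 hotspot stretch, one shared two-guide site and one
single-guide site — five Ψ-seq tumor/normal pairs in which sites guided
by the truly up-regulated snoRNAs gain +0.15 stoichiometry, a
seven-pair count cohort (9 up-regulated H/ACA snoRNAs at fold change 4),
and a 60-target screen with three depleted targets (s = −0.3) among
nulls and non-targeting controls. Demo coverage is 500× per sample, a
desk-scale compromise that still gives per-site binomial noise well below
the simulated effects.

Configuration is a validated YAML-round-trippable object
(`init_config()`, `validate_config()`); validation collects *all*
violations — unknown keys included — into one report. Every stochastic
stage derives a labeled child seed from the master seed (FNV-1a over
`label + seed`), so adding a stage never perturbs another's stream and a
rerun with the same config is byte-identical (verified by hashing all
outputs). Interchange files are TSV with `#` provenance headers (package
version, seed, config hash); a JSON run report records stage status,
record counts and warnings. A failed stage halts only its dependents,
which the report marks `skipped`.

## Benchmark problem sizes

The test suite and `scripts/acceptance.R` use: 20 simulated read sets
(≤10⁴ reads) for exact oracle equivalence of profiles and ratios; the
stoichiometry grid f ∈ {0, 0.25, 0.5, 0.75, 1} × b ∈ {0, 0.01} at 2000×;
100 seeds for each power study (knockdown dissociation, DE sensitivity,
screen recovery); 30–60 seeds for the null calibrations; and the
exhaustive Fisher enumeration to table total 60 (~635k tables). These
sizes keep the full suite around two minutes on one core while leaving
Monte-Carlo error well inside the asserted margins.

## Limitations

The read simulator emits pre-mapped, error-free, forward-strand reads: no
sequencing error, adapters, alignment ambiguity, or CMC-treatment/mock
library pairing (no input-control subtraction is modeled, so assays that
require mock subtraction need upstream handling). Passing benchmarks show
the statistics recover the generative model's truth — they cannot certify
behavior under artifacts the generator does not emulate (mappability,
RT sequence bias, snoRNA cross-mapping). The screen aggregation is a
transparent stand-in, not a reimplementation of model-based screen tools,
and its FDRs are not comparable to theirs. The concordance test formalizes
an association that descriptive analyses usually present qualitatively;
with few linked sites its power is limited and the degenerate-margin guard
matters.
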