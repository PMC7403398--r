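---
title: "Scanning genotype data for recessive lethal haplotypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning genotype data for recessive lethal haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lethscan)
```

## The model

A recessive embryonic lethal removes homozygotes before birth. If the
haplotype segregates at frequency $q$ in the gamete pool, zygotes form at
Hardy–Weinberg proportions $p^2 : 2pq : q^2$ and the $q^2$ class dies, so
among survivors

$$\Pr(\text{carrier}) = \frac{2pq}{1-q^2} = \frac{2q}{1+q}, \qquad
  \hat q_{\text{surv}} = \frac{q}{1+q},$$

and every surviving copy of the allele sits in a heterozygote: the carrier
fraction is exactly twice the survivor allele frequency. A cohort of $n$
genotyped survivors should therefore show $E = n\,\hat q^2$ minor
homozygotes under neutrality but zero under lethality; at $n = 526$ and
$\hat q \approx 0.17$ that is an expectation of $\approx 16$ against an
observation of 0. `survivor_carrier_fraction()` is this closed form, and the
simulator draws survivors from exactly this conditional law.

## The deficit scan

`scan_deficit()` tests every variant with the conditional exact
Hardy–Weinberg test: given the observed allele counts, all heterozygote
counts $h$ with the right parity are enumerated with weight

$$P(h) \propto \frac{n!\, 2^h}{n_0(h)!\, h!\, n_2(h)!},$$

computed in log space for numerical range. The two-sided p-value sums
$P(h')$ over tables no more probable than the observed one (the convention
of the standard genotype-QC tools, kept as the default so published
significance calls reproduce); the one-sided `"deficit"` mode sums the
heterozygote-excess tail $h' \ge h_{\text{obs}}$, the direction a lethal
pushes the genotype distribution. Monomorphic tables and variants below the
MAF floor (default 0.01) get $p = 1$ and can never be candidates — a lethal
at detectable carrier frequency cannot be monomorphic. The implementation is
checked against an independent brute-force enumerator (direct factorial
arithmetic, no log-space recurrence) on every genotype table up to $n = 30$.

Multiplicity is handled once across the merged panel, by Benjamini–Hochberg
or (default) Storey q-values with $\pi_0$ estimated on the grid
$\lambda = 0.05, 0.10, \dots, 0.95$ and a cubic smoothing spline read off at
$\lambda = 0.95$, clamped to $(0, 1]$; with genome-wide panels that are
overwhelmingly null the two differ little, but the Storey estimate is the
behaviour of the established q-value implementation this column mirrors.
Per-population summary rows report raw exact p-values (the per-breed stars
of the published table are per-population, not FDR-adjusted).

A candidate must satisfy *both* criteria: q-value below $\alpha$ (default
0.05) **and** observed minor homozygotes at most `max_observed_minor_hom`
(default 0, strict absence — so a linked marker showing 22 homozygotes is
representable as a non-candidate). Because an isolated zero-homozygote SNP
is as easily a clustering artifact as a lethal, `cluster_adjacent()` keeps
only maximal runs of $\ge 2$ flagged variants consecutive in the tested
panel on one chromosome; "adjacent" means neighbouring panel markers, with
an optional base-pair gap cap (default unlimited) for sparse panels.

## LD shortlisting

Two-locus haplotype frequencies are estimated from unphased genotypes by EM
over the double-heterozygote phase ambiguity, then $D = p_{11}p_{00} -
p_{01}p_{10}$, $D' = |D|/D_{\max}$ and $r^2 = D^2 / (p_A p_a p_B p_b)$, with
$D = 0 \Rightarrow D' = 0$ by convention and $D'$ reported unsigned (the
shortlist thresholds are magnitude-based). The likelihood in the
double-heterozygote count can be bimodal (one mode at positive, one at
negative $D$), and the product-of-marginals starting point sits between
them; the EM therefore runs from that point *and* from both endpoints of the
admissible $p_{11}$ range, keeping the best log-likelihood. This is the one
deliberate departure from a pure single-start EM, and it is what makes the
estimate match a global grid-search maximizer on an exhaustive set of small
tables (the packaged tests verify this at $10^{-4}$ grid resolution).
Thresholds are strict — $r^2 > 0.8$ and $D' > 0.9$ — and the window is ±5 Mb
around the index variant; a boundary value is excluded.

## Genotype re-calling

Suspect calls are re-examined on the raw two-channel intensities. The pair
$(x, y)$ is projected to the contrast coordinate $\theta = (2/\pi)\,
\mathrm{atan2}(y, x) \in [0, 1]$ and a one-dimensional Gaussian mixture is
fitted for $K \in \{1, 2, 3\}$ by EM: means initialised at $K$ evenly spaced
quantiles (with a seeded $10^{-6}$ jitter only if quantiles coincide),
variances floored at $10^{-6}$ against duplicate intensities, convergence at
$10^{-8}$ log-likelihood improvement or 500 iterations; $K$ is chosen by
BIC. $K$ must be selectable because a variant whose minor-homozygote class
is lethal genuinely has at most two clusters. Components are mapped to
genotype codes by greedy nearest assignment to the canonical cluster
positions $\{0, 0.5, 1\}$ with distinct codes enforced — deliberately not by
positional order, so that two components straddling one true cluster (e.g.
a skewed homozygote cloud) cannot hijack the heterozygote label. Samples
whose maximum posterior falls below the call threshold (default 0.95) are
no-calls. The pipeline re-calls any flagged variant that has intensities and
re-tests it, so a deficit created by a calling artifact clears itself.

## The synthetic cohort generator

`simulate_lethal_population()` is first-class, tested code that generates
the statistical structure the analysis assumes, with defaults set to the
study conditions the package targets: $n = 526$ survivors at pre-selection
frequency $q = 0.21$, i.e. $\approx 35\%$ carriers — a pooled
Thoroughbred-scale cohort.

- **Lethal block**: all `n_lethal_snps` (default 2) markers carry identical
  survivor genotypes in perfect coupling at adjacent positions; survivor
  genotypes are drawn from the conditional law above, so the
  minor-homozygote count is exactly zero by construction.
- **Neutral background**: independent SNPs at HWE with MAFs uniform on
  [0.01, 0.5] — a flat, featureless null panel.
- **Linked marker**: a forward simulation of `n_pop` (default 1000) diploids
  over `n_generations` (default 20) of discrete random mating. Haplotypes
  carry (causal, marker) alleles, gametes recombine with probability $c$,
  and causal homozygotes die. One modelling decision matters here: complete
  lethal selection alone drives the allele down as $q/(1+q)$ per generation
  ($0.21 \to 0.04$ in 20 generations), which would extinguish exactly the
  phenomenon the simulator exists to show. Real populations carried the
  haplotype at high frequency through drift and popular-sire effects, so
  the simulator holds the pre-selection zygote frequency at `q_pre` each
  generation by drawing gametes stratified on the causal allele. The result
  is the published pattern: the causal column keeps zero homozygotes while
  the recombined marker accumulates a small positive number of them, and
  its $r^2$ with the causal locus decays with generations. When a linked
  marker is requested, the emitted lethal block reuses the forward
  simulation's causal genotypes so block and marker are genuinely in LD.
- **Intensities**: per-genotype clusters on the contrast coordinate with
  centres 0.1/0.5/0.9 (sd 0.03) and a signal radius around 1. Centres are
  kept off the [0, 1] boundary and $\theta$ is sampled from a *truncated*
  normal, because a boundary point mass makes a variance-floored mixture
  split the cluster. Miscalls are injected by corrupting the recorded call
  (not the intensity) for a random fraction of samples, which is the error
  mode re-calling can fix.

What the generator does **not** emulate: pedigree structure and sire-usage
skew, genotyping batch effects, strand-ambiguous assay design, LD among the
neutral background SNPs, and mutation. Passing tests therefore demonstrate
the method's behaviour under clean HWE nulls with an idealised lethal
signature, not robustness to population structure (which inflates
homozygosity and makes this scan *conservative* for lethals, but can hide
weak signals).

## Numerical and design choices

- Expected-count rounding is half-away-from-zero; this reproduces every
  printed value of the published breed table from its genotype counts.
- Minor-allele ties ($q = 0.5$ exactly) resolve to `allele_B`, so results
  are deterministic.
- Thresholds quoted as "over 10" / "over 20" (VCF depth/quality) and "over
  0.8" / "> 0.9" (LD) are strict inequalities.
- Merging harmonises only label swaps; a palindromic or otherwise
  conflicting allele set raises an error rather than guessing strand.
- Missing genotypes are excluded from all counts; no imputation anywhere.
- All randomness flows from explicit integer seeds through a
  save-and-restore RNG wrapper, so simulators are pure functions of their
  configuration; identical config + seed gives byte-identical outputs.

Problem sizes in the packaged tests were chosen to give stable Monte-Carlo
estimates at interactive runtimes: 200 replicates × 5,002 variants for the
power study, $10^5$ survivors for the closed-form carrier check, exhaustive
enumeration to $n = 30$ for the exact-test oracle, exhaustive two-locus
tables to $n = 5$ (plus random tables to $n = 12$) for the EM-LD oracle,
and 100 seeded panels of 200 samples for recall accuracy. Recall accuracy
is measured among called samples; abstentions (no-calls) are reported
separately, as is standard for array genotype callers.

## Known limitations

- The scan is genotype-based; phased-haplotype approaches (as used for
  cattle lethal screens) can detect lethals whose individual SNPs all have
  minor homozygotes, which this design will miss.
- Storey $\pi_0$ estimation is unstable for very small panels; the `"bh"`
  method is the conservative fallback there.
- The PED text format carries no allele orientation, so a write/read round
  trip is exact only for matrices whose allele labels are already in the
  reader's lexicographic orientation.
- The forward simulator's stationary-frequency assumption is a modelling
  choice, not an inference about any real breed's history; it isolates the
  recombination phenomenon from frequency decay.
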