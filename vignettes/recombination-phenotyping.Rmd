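---
title: "Phenotyping individual meiotic recombination in large full-sib families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping individual meiotic recombination in large full-sib families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In species with genotyped multi-generation pedigrees, each offspring
genotype records the outcome of one meiosis in each of its parents.  When
a sire-by-dam pair (the *focal individuals*, FIDs) has many full-sib
offspring, the parental haplotypes can be phased from the offspring alone,
and every transmitted gamete can be labelled, marker by marker, with the
parental haplotype (ultimately, grandparental chromosome) it came from.
Two phenotypes are then defined per meiosis and assigned to the FID in
which that meiosis took place:

* **Crossover count (CC)** — the number of origin switches along the
  gamete, summed over chromosomes;
* **Intra-chromosomal shuffling** \(\bar r = \sum_k 2 p_k (1-p_k) L_k^2\),
  the probability that a randomly chosen pair of loci on the same
  chromosome received different grandparental origins, where \(p_k\) is
  the fraction of chromosome \(k\) carrying one origin label and
  \(L_k\) its physical length as a fraction of the genome.

CC measures how often crossovers happen; \(\bar r\) additionally measures
*where* they happen — a crossover at the middle of a chromosome shuffles
far more allelic combinations than one at a telomere.  Atlantic salmon is
the motivating system: male crossovers are confined to sub-telomeric
regions while female crossovers sit closer to the centromeres, so females
shuffle linked variation several times more than males even though their
crossover counts differ much less.

This package implements the full chain — family construction, gamete
phasing, phenotype extraction, sex-specific linkage maps, variance
components, and a weighted leave-one-chromosome-out GWAS — together with a
meiosis simulator that provides exact ground truth for every stage.

## The simulator

Chiasmata are simulated at the **bivalent** level:

1. per chromosome, a chiasma count \(N_k \sim \text{Poisson}(\lambda
   w_k\, m_i)\), optionally replaced by \(\max(N_k, 1)\) (the obligate
   rule); \(w_k\) are per-chromosome weights (default: proportional to
   physical length) and \(m_i\) is the individual's rate multiplier;
2. chiasma positions are i.i.d. draws from a sex-specific piecewise-linear
   positional density over relative position (inverse-CDF sampling);
3. each chiasma reaches the sampled gamete independently with probability
   1/2 (two of four chromatids, no chromatid interference), toggling the
   copied strand at its position.

The two-step construction matters: one obligate chiasma per bivalent
yields an expected *gamete* crossover count of 1/2 and hence a 50 cM
minimum map length.  A gamete-level Poisson shortcut would give 100 cM and
contradict that prediction.  Crossover interference is deliberately not
modelled; counts are Poisson and positions independent.

`calibrate_lambda()` solves \(\sum_k (\lambda w_k + e^{-\lambda w_k})/2 =
\text{target}\) so that landscape intensities are stated in the unit
users observe (mean gamete crossovers per meiosis).  Under the obligate
rule the reachable floor is \(n_\text{chrom}/2\); the published Atlantic
salmon male mean (12.1 crossovers over 29 chromosomes) sits *below* that
floor of 14.5, consistent with undetected male crossovers in sparsely
covered sub-telomeric regions.  The paper-like preset therefore emulates
the observed counts without the obligate rule, while the desk preset
keeps it.

Default positional densities: male crossovers are restricted to the
distal ~10% of each chromosome arm; female densities are broad with a
pericentromeric peak and little mass at the telomere.  Individual
variation acts multiplicatively on \(\lambda\) through a log link,
\(m_i = \exp(a_i + pe_i)\), with \(a_i\) an additive polygenic score over
`n_causal` (default 100) marker loci whose female and male effect sizes
are drawn with a configurable cross-sex correlation (default 0), scaled
to \(\sigma^2_{a}\) (default 0.005 per sex), and \(pe_i \sim N(0,
\sigma^2_{pe})\) (default 0.003).  On the paper-like scale (mean CC
19.6) these defaults give \(V_a \approx \mu^2\sigma^2_a \approx 1.9\)
against a within-meiosis variance near the Poisson value, i.e.
\(h^2 \approx 0.09\) and low cross-sex genetic correlation — the regime
the package is designed to detect.  On the desk scale (mean CC ~4) the
same relative variance translates into \(h^2 \approx 0.03\), so the desk
preset demonstrates the machinery rather than its power.

Genotyping error is a symmetric per-allele flip (default 0.001) and
missingness is applied per genotype (default 0.003, matching a 0.997
call rate).  What the simulator does **not** emulate: linkage
disequilibrium among founders (founder haplotypes are independent across
markers), recombination hotspots, tetrasomic/quadrivalent pairing and
homeologous exchange, array-merging artefacts, and a sex-determining
region.  Passing tests on simulated data therefore validate the
estimators under the stated generative model, not the genotyping
platform or residual-pairing biology of real salmon data.

## Phasing

Families are one per distinct sire-by-dam pair with both parents
genotyped; grandparents are used opportunistically.  Within a family and
for one focal parent, markers where the parent is heterozygous are
informative; for each offspring the transmitted parental allele is
resolved when the offspring is homozygous or the other parent is
homozygous (a double-heterozygous offspring at a double-heterozygous
marker stays missing for that offspring only).  Phasing is a binary
orientation chain along the chromosome: at each informative marker the
orientation is chosen so that the majority of offspring keep the origin
they carried at their previous resolved marker; ties keep the previous
orientation.  With family sizes in the tens to hundreds this greedy
majority vote reaches the global minimum-recombination solution (tested
against exhaustive enumeration up to 12 markers).  Families below
`min_offspring` (default 4) are skipped: with 1–3 offspring the majority
vote degenerates and phase errors masquerade as crossovers.  The default
is configurable down to 1.

Mendelian-impossible offspring genotypes are masked first, and a
per-family chi-square segregation-distortion filter (default
\(\alpha = 0.01\)) masks markers whose offspring genotype ratios are
incompatible with the parental genotypes, mirroring standard multi-family
linkage-mapping practice.  Haplotype labels are anchored to grandparental
origin where the focal parent's parents are genotyped; otherwise labels
are arbitrary per chromosome, which is harmless because CC and \(\bar r\)
are invariant to label flips.

## Phenotypes

`detect_crossovers()` removes interior runs of identical origin shorter
than `min_support` markers (default 3) flanked by the opposite origin —
the signature of an isolated genotyping error, which would otherwise
create two spurious crossovers — then emits one event per remaining
origin switch, localised to the bracketing informative-marker interval.
Terminal short runs cannot be distinguished from real distal crossovers
and are kept; this leaves a small residual inflation at chromosome ends
on error-prone data.  For truth-table equivalence testing `min_support =
1` disables the mask.

For \(\bar r\), each chromosome is segmented by placing a breakpoint at
the physical midpoint of each crossover interval (the true breakpoint is
uniformly distributed within the interval, so the midpoint minimises the
expected error, which is bounded by half the informative-marker spacing);
chromosome ends extend the nearest observed origin.  \(p_k\) is
physical-length-weighted by default, matching the definition of \(\bar r\)
over physical locus pairs; a marker-count mode is provided for
sensitivity analysis.  Chromosomes with no informative marker contribute
zero shuffling and raise a per-gamete coverage flag rather than dropping
the gamete.  The formula is verified against a direct Monte-Carlo
locus-pair oracle (uniform genome positions, same-chromosome indicator).

## Linkage maps

Marker order is fixed to genome order.  The spec of the estimator is the
classical one — per adjacent informative-marker interval, \(\hat r\) =
recombinant meioses / informative meioses, mapped through Haldane
\(d = -50\ln(1-2\hat r)\) cM and accumulated — but with family-specific
informative sets the union of informative markers is much denser than any
single meiosis's resolved set, leaving adjacent-interval denominators of
1–2 meioses where a single recombinant saturates the estimator.  The
implementation therefore allocates each meiosis's consecutive resolved
pair to every union interval it spans: coverage counts add 1 per spanned
interval, and a recombinant pair adds recombination mass proportional to
physical length.  When all meioses resolve the same markers this reduces
exactly to the classical \(\hat r\).  Interval fractions above 0.49 are
capped with a warning (Haldane diverges at 0.5); markers never
informative get cM interpolated by physical position.  Unbiasedness is
tested against Poisson landscapes (total cM within Monte-Carlo error of
100 × expected gamete crossovers) and the obligate-chiasma 50 cM
prediction.

Fine-scale landscapes use half-open 1 Mb bins; the rate is the cM
difference over the Mb difference between the first and last marker in
the bin, missing with fewer than 2 markers.  The relative-position
profile maps bin midpoints of acrocentric chromosomes onto [0, 1] with 0
at the centromere, averaging across chromosomes in 40 relative bins; no
smoothing is applied (smoothing is presentation, not inference).

## Variance components

The repeatability animal model for per-meiosis records of an FID is
\(y = Xb + a + pe + e\) with \(a \sim N(0, G\,V_a)\) on the VanRaden
(method 1) GRM, \(pe \sim N(0, I\,V_{pe})\), \(e \sim N(0, I\,V_e)\), and
\(X\) holding an intercept and the method-of-moments inbreeding
coefficient F.  Sexes are fitted separately: the source analyses report
sex-specific variance components, and separate fits are the unambiguous
reading (a joint fit with a sex fixed effect would force shared
components).  Because the random effects are indexed by FID, the
restricted likelihood factorises exactly into a within-FID chi-square
(carrying \(N - q\) degrees of freedom for \(V_e\)) and a between-FID
multivariate normal on FID means with covariance \(V_a G + V_{pe} I +
V_e\,\mathrm{diag}(1/n_i)\), so all matrix work is \(q \times q\).

The optimiser is AI-REML with a 3-iteration EM warm-up; AI steps use the
minimum-norm pseudo-inverse of the average-information matrix (which is
singular when parameters are confounded, e.g. identical traits), with
step-halving so the restricted likelihood is non-decreasing along the
iterate path (asserted in tests) and an EM fall-back when the AI
direction fails.  Convergence is \(|\Delta \log L| < 10^{-8}\) or 200
iterations; variances are floored at \(10^{-10}\); the GRM receives a
\(10^{-6}\) ridge when not positive definite.  Standard errors come from
the inverse AI matrix, with delta-method errors for \(h^2 = V_a/V_p\),
repeatability \(t = (V_a+V_{pe})/V_p\) and genetic correlations.
Bivariate fits add a 2×2 additive (co)variance across the GRM and
trait-specific \(pe\) and residual variances with no residual covariance
— exact for cross-sex pairs, where no individual carries both traits;
the genetic covariance is clamped inside the Cauchy–Schwarz bound and
\(r_g\) is reported as undefined when either additive variance sits at
the floor.  Phenotypic correlations between traits are Pearson
correlations of FID means.

## GWAS

Per-FID means \(\bar y_n\) are tested under \(\bar y_n = a + b x + g +
e\), \(g \sim N(0, G_{-c}\,\sigma^2_a)\) with the focal SNP's chromosome
left out of the GRM, and \(e \sim N(0, D\,\sigma^2_e)\).  The residual
weight derives from the repeatability decomposition
\(\mathrm{Var}(\bar y) = V_a + V_{pe} + V_e/n\):

\[ d_i = \frac{(t - h^2) + (1 - t)/n_i}{1 - h^2}, \]

normalised so \(d = 1\) for a single observation and decreasing to
\((t-h^2)/(1-h^2)\) as \(n \to \infty\).  The weights enter the residual
covariance (the natural place for record-count heterogeneity; the
alternative GRM-side weighting is not implemented).  Null variance
components are re-estimated by REML for every left-out chromosome; each
SNP is then a generalised least-squares fixed effect with a 1-df Wald
chi-square, and Bonferroni control uses the actual number of tested
markers.  Calibration is checked under a polygenic null on a
29-chromosome genome (the per-chromosome polygenic share left in the
residual by LOCO is then negligible; with very few chromosomes a mild,
structural type-I inflation is visible and expected).

## Problem sizes and reproducibility

The bundled test and acceptance runs use desk-scale designs chosen to
exercise every code path with tight Monte-Carlo error: 3–5 chromosomes of
20–40 Mb, 30–1000 markers per chromosome, families of 6–100 offspring,
300–500 FIDs for REML/GWAS simulations, 2,000 gametes for the
obligate-chiasma map check, and 4×10⁵ locus pairs per gamete for the
\(\bar r\) oracle.  The analysis drivers default to the desk preset
(5 × 40 Mb chromosomes, 200 markers each, 60 sire–dam pairs × 20
offspring) and provide a paper-like preset (29 salmon chromosomes with
published physical lengths, ~3.5K markers, 100 families × 30 offspring).
Every stochastic entry point takes the session seed; the analysis
drivers echo the resolved configuration, and stage outputs are plain
TSV so each stage can be re-run independently.

## Known limitations

* Phase errors at chromosome ends and terminal short runs are not
  distinguishable from real distal crossovers; on error-prone data map
  totals retain a small residual inflation after cleaning.
* Two true crossovers inside one informative interval cancel; CC is
  exact only up to interval parity, with the discrepancy controlled by
  marker density (quantified against the truth table in the analysis
  drivers).
* The simulator's founders carry no linkage disequilibrium, so imputation
  or LD-aware methods cannot be benchmarked with it.
* Crossover interference, tetrasomic pairing and hotspot fine structure
  are out of scope; desk-scale REML estimates of weakly heritable traits
  are honest but noisy, and the drivers flag non-converged or floored
  fits rather than hiding them.
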