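---
title: "Methods: building and evaluating ancestry-informative SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and evaluating ancestry-informative SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

aimkit implements the computational pipeline behind small forensic
ancestry-informative marker (AIM) SNP panels: scoring and balancing marker
informativeness, naive-Bayes ancestry classification with Bayes likelihood
ratios, supervised co-ancestry (admixture) proportion estimation, genotype
call-set concordance auditing, and a synthetic-population generator that
makes the whole pipeline testable end to end without any external genotype
resources. This vignette describes the statistical models, the tunable
parameters, the numerical choices, and what the synthetic experiments do
and do not demonstrate.

## Marker informativeness and panel balance

Rosenberg's *informativeness for assignment* is the mutual information
between a random allele and the population it was drawn from. For K
populations with allele-frequency vectors $p_i$ over a shared allele set,

$$I_n = \sum_a \Big[ -\bar p_a \ln \bar p_a
        + \frac{1}{K}\sum_{i=1}^{K} p_{ia} \ln p_{ia} \Big],$$

with $0 \ln 0 := 0$ and $\bar p$ the unweighted mean across populations.
We use natural logarithms throughout (nats); only rankings and ratios
matter downstream, so the base is a pure convention. $I_n$ is zero iff all
populations share the same frequencies and is bounded by $\ln K$.

The *population-specific divergence* (PSD) of a marker for group $g$ is the
two-group $I_n$ between $g$ and the unweighted pooled mean of all remaining
groups (`population_specific_divergence()`). Pooling is over populations,
not samples: reference sets deliberately balance group sizes, and equal
weighting keeps the statistic independent of panel sampling depth. The
*delta differential* (`delta_differential()`) is the simpler screening
statistic: the largest allele-frequency difference between the target and a
comparator mean. For South-Asian-informative markers the natural comparator
is Europe alone, and for Europe-vs-Asia contrast markers a pooled
South/East-Asian (and, with real data, Middle-Eastern) mean; the comparator
set is therefore an explicit argument.

`cumulative_psd()` accumulates PSD over a panel in two modes. The
`"panel"` mode sums each group's PSD over *every* marker in the subset;
this is the panel-wide accumulation plotted when a finished panel's balance
is assessed, and it is the scale on which a balanced ~100-SNP panel reaches
per-group totals around 10-14, with South Asia far lower (its
differentiation from Europe is intrinsically weak). The `"assigned"` mode
credits each marker only to its assigned target group, which is the
quantity a curator balances when deciding which group's marker to add or
drop: the two modes answer different questions and both are exposed.
(Per-group totals of member PSDs cannot exceed
$n_{\text{members}} \ln 2$, so panel-wide totals above ~5 for a group with
few assigned markers are necessarily panel-wide accumulations.)

`balance_panel()` replaces manual curation with a deterministic greedy
procedure: fill each group's budget by repeatedly giving the group with the
lowest cumulative (assigned) PSD its best unused candidate, then apply
within-group swaps while any swap strictly reduces the max-minus-min
spread, with all ties broken by ascending rsID. Determinism matters more
than optimality here — the procedure is a reproducible stand-in for a
judgement call, and the test suite only requires it to beat a
1000-draw random search, which it does comfortably.

## Naive-Bayes classification and cross-validation

Within each reference population, genotypes are modelled by Hardy-Weinberg
proportions ($p_a^2$, $2 p_a p_b$); no inbreeding correction is applied.
A profile's log-likelihood for a population is the sum of per-locus
genotype log-probabilities over non-missing loci plus the log prior
(uniform by default, configurable). Missing loci are skipped, not imputed:
imputation would leak information between reference and query. The strength
of an assignment is the Bayes likelihood ratio between the best and
second-best population, rendered verbosely with the conventional
1,000 / 1 million / 1 billion phrasing thresholds alongside the numeric
value; exact ties are reported as such with LR 1.

Reference allele frequencies are estimated with a pseudo-count per allele,
$\hat p_a = (c_a + s) / (2N + sA)$ with $A$ the number of declared alleles.
The default is $s = 1$ for classification — any $s > 0$ keeps every called
genotype's likelihood finite and preserves rankings at fixed $N$ — and
$s = 0$ (the plain MLE) when frequencies are reported as data.

`loo_crossval()` re-estimates the left-out sample's own population
frequencies without its two allele copies at every locus (other
populations' estimates are unaffected by construction) and classifies it
against the reduced reference; results are tallied into a confusion matrix
with per-group and overall correct-classification percentages. The
procedure is exact, not approximate, and deterministic.

## Co-ancestry estimation

`supervised_admixture()` estimates a per-individual co-ancestry simplex
$q$ over $K$ reference groups by maximizing
$\sum_{\text{allele copies}} \ln \sum_k q_k f_{k}(\text{allele})$
with the reference frequencies held fixed. This is the supervised analogue
of reference-anchored model-based clustering: the quantity being compared
downstream is the per-individual proportion vector, which supervised
maximum likelihood estimates consistently, deterministically, and at desk
scale — no MCMC is involved, so there is no burn-in, no label switching and
no seed. The EM update sets $q_k$ to the mean posterior origin probability
over allele copies; iteration stops when the log-likelihood improves by
less than `tol` (default 1e-6, default cap 1000 iterations; the
monotonicity of the EM objective is asserted at every step). Initialization
is uniform; the likelihood is concave in $q$, so the optimum is global.

`gda_coancestry()` is the quick distance-based screen: the mean
allele-sharing distance to each reference group,
$d_k = \text{mean}_\ell\, (1 - \tfrac12\sum_{\text{copies}} f_k)$, is
converted to proportions $q_k \propto d_k^{-\gamma}$, truncating components
below 0.01 and renormalizing; a zero distance takes all the weight. The
published algorithm it emulates is not printed anywhere we could reimplement
it from, so this transform is a declared stand-in calibrated to the
*reported behaviour* of the original: with the default exponent
$\gamma = 4$, synthetic African-Caribbean-like cohorts show systematic
underestimation of the minor European component relative to EM (to the
point of frequent non-detection below ~10%) together with spurious East
Asian attribution when the American and East Asian references lie close.
An inverse-square transform ($\gamma = 2$) was evaluated first and does
*not* reproduce that direction — it slightly overestimates the minor
component at $K = 4$ — which is why the exponent is a parameter with a
calibrated default rather than a fixed constant. Exact numerical agreement
with the original implementation is out of scope.

`allele_distance_matrix()` gives the pairwise allele-sharing distance
(2 minus the number of shared alleles, summed over jointly non-missing
loci) used for ordination and neighbour-joining trees; the plotting itself
is standard and left to the user.

## Concordance auditing

`compare_callsets()` matches two call sets by sample and locus id, compares
cells that are non-missing in both, and counts a discordance whenever the
unordered allele multisets differ — phase is ignored, and half-calls are
treated as no-calls. Percentages are kept at full precision and rounded
half-up to two decimals only for display. Samples or loci present in only
one set are excluded and listed. `flag_outlier_loci()` ranks loci at or
above a discordance-count threshold. The synthetic error injector
(`inject_errors()`) has an exact count mode precisely so that audit
fixtures with known printed counts (e.g. 17 discordances among
272 x 151 comparisons, which is 99.96% concordance) can be reconstructed
and the arithmetic checked end to end; its ledger of every perturbed cell
must be recovered exactly by the audit, and the tests assert that.

## Percentile comparison, detection, delta-K, diplotypes

`percentile_compare()` sorts individuals by one method's proportion for a
chosen component (the cohort's expected major co-ancestry by default —
the sort key is configurable because different cohorts call for different
anchors), splits them into 10 near-equal bins (remainders to the earliest
bins), and reports per-bin mean proportion vectors under both methods
together with a per-component goodness-of-fit, the r² of the OLS
regression of method B on method A over individuals (identically the
squared Pearson correlation). `detection_summary()` tabulates, per
component, the fraction of individuals whose estimate reaches 5% within
true-proportion bins (<5%, 5-10%, >=10%): the >=10% bin is where a
balanced ~100-SNP panel is expected to report co-ancestry reliably, and
the synthetic experiments reproduce exactly that pattern (near-100%
detection at >=10%, falling off steeply below).

`evanno_delta_k()` implements the standard second-difference heuristic for
choosing the number of clusters from replicate log-probabilities:
$\Delta K = |L''(K)| / \mathrm{sd}\,L(K)$, defined for interior K with
positive replicate spread, computed from the per-K means; it is invariant
to adding a constant to all log-probabilities, and degenerate zero-spread
replicates are flagged rather than silently divided by.

`diplotype_encode()` recodes a phased 2-SNP microhaplotype as a single
pseudo-SNP: the haplotype combinations are sorted alphabetically and
mapped onto A, C, G, T in order (AA→A, AG→C, CA→G, CG→T for allele sets
(A,C)×(A,G)), so existing SNP-profile machinery can consume the combined
marker. The map is a bijection, pairs with a tri-allelic member extend the
alphabet with a warning, and unphased input is rejected — phase must come
from the sequence reads.

## The synthetic-population generator

`simulate_frequencies()` uses the Balding-Nichols model: each locus draws
an ancestral frequency vector (biallelic $p \sim U(0.1, 0.9)$; tri-allelic
Dirichlet bounded away from fixation), and each population's vector from a
Dirichlet with mean the ancestral vector and concentration $(1-F)/F$, so
$\mathrm{Var}(p_{\text{pop}}) = F\,p(1-p)$. $F$ is per-group. Markers
assigned to a target group are additionally pushed toward fixation of
their informative allele until a per-group PSD floor is met (bounded
rejection sampling; Europe-vs-Asia contrast markers apply the floor to the
two-group $I_n$ between Europe and the South/East-Asian mean, since their
job is that specific contrast, not target-vs-rest divergence).

The default configuration is the package's standing model of the study
conditions and is deliberately fixed: six groups (AFR, EUR, EAS, SAS, OCE,
AMR); a panel of 88 group-assigned binary markers (7/15/16/20/13/17),
12 Europe-vs-Asia contrast markers and 15 tri-allelic markers (115 loci);
and reference sizes 108/99/103/103/28/79 (520 profiles). The per-group
drift parameters (AFR 0.45, EUR 0.25, EAS 0.22, SAS 0.05, OCE 0.36,
AMR 0.27) and PSD floors were calibrated once so that the panel-wide
cumulative PSD per group lands on the scale of a real balanced forensic
AIM panel — roughly 9-12 per continental group with South Asia near 3 —
and were not revisited afterwards. These $F$ values are much larger than
genome-wide fixation indices because an AIM panel is, by construction, an
extreme tail sample of the genome's divergence distribution; they describe
the panel's loci, not the populations.

What the generator does *not* emulate: linkage between markers (loci are
independent, consistent with the naive-Bayes assumption — real panels
enforce this by design), realistic demographic history or migration
(drift is a one-parameter caricature), genotyping error structure (errors
are exchangeable random genotype swaps), and within-group substructure.
Consequently the synthetic 100% cross-validation result demonstrates that
the pipeline's arithmetic and the panel's divergence budget deliver the
expected separation under the model, not that any real panel achieves
100% on real populations; conversely the concordance and audit figures are
pure counting and carry over exactly.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full 520-profile
leave-one-out cross-validation (~2 s), 200-individual EM recovery
(~7 s), and 100-individual EM/GDA comparisons; the whole pipeline is a
sub-minute desk computation by design. Frequencies are validated to sum to
one within 1e-9; EM declares convergence below 1e-6 log-likelihood
improvement; co-ancestry simplexes are renormalized each EM step to absorb
rounding; greedy balancing treats spreads within 1e-12 as ties. Genotype
strings are canonicalized alphabetically ("AG" ≡ "GA"), missing is "NN" in
the grid serialization and `NA` internally, and all genotype comparisons
are on unordered multisets. Coordinates are 1-based; VCF records are
matched to panel loci by chromosome and position first, rsID as a
fallback, and alleles outside the declared set are flagged and dropped
rather than strand-flipped (A/T and C/G markers cannot be disambiguated
without strand metadata, so silent complementing would be worse than a
loud missing value).

## Known limitations

The GDA stand-in matches the original's reported direction, not its
values. The Evanno calculator requires balanced replicate counts over a
consecutive K range. The supervised EM assumes the reference frequencies
are exact; with very small reference groups its proportions inherit that
sampling noise (visible as the slightly lower detection rates when the
reference is scaled down). Unsupervised clustering, MCMC admixture
models, coalescent simulation and liftover are out of scope.
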