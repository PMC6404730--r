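---
title: "From promoter SNPs to dominance/subordination candidate markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From promoter SNPs to dominance/subordination candidate markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tatadom)
```

## The scientific question

Most regulatory SNPs with clinically verified effects sit in the ~70 bp of
core promoter immediately upstream of the transcription start site (TSS),
where the TATA-binding protein (TBP) must bind before RNA polymerase II can
initiate. Experimental work has established a simple direction rule: variants
that tighten TBP binding (lower the dissociation constant $K_D$) tend to
cause overexpression of the downstream gene; variants that loosen it cause
underexpression. If, additionally, an excess of the encoded protein is a
known physiological correlate of dominance-like behaviour (low pain
sensitivity, fast post-injury recovery, risk seeking, ...), then a promoter
SNP predicted to cause overexpression is a *candidate marker of the tendency
in social dominance*, underexpression of subordination — and vice versa for
proteins whose excess marks subordination-like phenotypes.

`tatadom` implements that chain end to end: affinity estimation for both
alleles, a Z-score significance test, the marker decision rule, the
population-level dichotomy statistics, and the mouse-contest analysis used
to show that dominance tendencies are heritable at all.

## The three-step affinity model

TBP reaches its site in three physical steps: it (i) slides along the double
helix, (ii) stops at a putative TBP-binding site, and (iii) is locked in
place by bending the DNA by roughly a right angle. The model mirrors these
steps with three window-level terms for every 15 bp window $w$ of the
promoter:

* **stop**: an additive position-weight-matrix (PWM) score of the TATA
  motif, $f_{stop}(w) = \sum_j W[b_j, j]$;
* **slide**: the mean of a dinucleotide step-flexibility scale over the 14
  overlapping dinucleotide steps of the window;
* **bend**: the mean of a dinucleotide bending-propensity scale, likewise.

Each raw term is mapped onto the $-\ln K_D$ scale (with $K_D$ in mol/L) by a
linear calibration $E_i(w) = a_i + b_i f_i(w)$. The combined window score is
the unweighted mean of the three calibrated estimates; the promoter's
affinity is the maximum over all windows (ties go to the most upstream
window), and its uncertainty is

$$\delta = \mathrm{sd}\{E_{slide}, E_{stop}, E_{bend}\} / \sqrt{3},$$

the standard error of the combined mean at the maximizing window: the three
steps act as three semi-independent measurements of the same site, and their
disagreement is the natural uncertainty of the estimate. $\delta = 0$
exactly when the three step estimates coincide.

### The shipped default parameterization

All coefficients are configuration (`inst/extdata/tbp_model.cfg`, a flat
key-value file), never hard-coded; `default_model_config()` loads the
defaults and `read_model_config()` any alternative. The defaults were chosen
once, as follows:

* **PWM** — a 15-position TATA-box matrix written as log2-odds of a
  consensus probability matrix against uniform base composition. Its
  consensus `GTTATAAAAGGGCCG` carries the canonical `TATAAA` core with the
  G/C-rich downstream flank typical of TATA sites. The strong-information
  "core" columns (weight range ≥ 4 bits) are positions 3–8.
* **slide / bend scales** — dimensionless per-dinucleotide values in
  $[0, 1]$, with every dinucleotide step that occurs in the consensus site
  fixed at the maximum 1.0 and the six remaining steps well below it. This
  normalization makes the consensus site optimal under *all three* steps
  simultaneously, which has two consequences worth stating explicitly:
  the three calibrated estimates agree exactly at a consensus site (so
  $\delta \to 0$ there, and allele differences at strong sites are sharply
  resolved), and the combined score of *any* window is bounded by the
  consensus score — embedding the consensus into any background can never
  lower a promoter's affinity estimate, which the test suite checks as an
  invariant rather than a tendency.
* **calibrations** — every step is anchored so the consensus maps to
  $-\ln K_D = 20.8$ ($K_D \approx 0.9$ nM, a typical strong TATA box).
  The slopes (0.30 per bit for the PWM, 8.0 per property unit for slide and
  bend) balance the three steps' responses to a single core substitution,
  which is what powers the Z-score: $Z$ grows with the *agreement* of the
  three per-step changes, so comparably scaled responses give substitutions
  in real sites large Z while background substitutions, whose step changes
  are small and discordant, stay insignificant.

Only the gene strand is scanned, 5'→3', over TSS-relative offsets
$[-70, -1]$: TBP-site orientation relative to the TSS is functional, and
the region convention already contains every TBP-binding site of interest.
IUPAC ambiguity codes are rejected by default (`lenient = TRUE` resolves
them to the alphabetically first compatible base with a warning).

## Allele comparison

For a SNP with ancestral (wt) and minor (min) alleles the two affinity
estimates are compared by Fisher's Z-score,

$$Z = \frac{\left|\ln\left(K_D^{min} / K_D^{wt}\right)\right|}
           {\sqrt{\delta_{min}^2 + \delta_{wt}^2}},$$

whose numerator is just the difference of the two $-\ln K_D$ values. The
p-value is the two-tailed standard-normal tail probability — the
conservative convention, consistent with the $\alpha \ge 0.95$
significance threshold at $Z \ge 1.96$ — and results are reported as
$\alpha = 1 - p$. Decisions: `insignificant` below the threshold, otherwise
`overexpression` when the minor allele binds tighter and `underexpression`
when it binds weaker. A heuristic rank compresses $\alpha$ into A–E bins
(A ≥ 0.9999, B ≥ 0.999, C ≥ 0.99, D ≥ 0.95, E otherwise); the bins are a
documented default, chosen to subdivide the significant range by decades.

Indel variants are supported by re-anchoring the $[-70, -1]$ frame at the
TSS: insertions shed their most upstream bases, deletions pull bases in
from an upstream flank (an error if no flank is available).

```{r}
cfg <- default_model_config()
prom <- promoter_record("DEMO", paste0(strrep("C", 30), pwm_consensus(cfg),
                                       strrep("C", 25)))
wt <- estimate_affinity(prom, cfg)
mn <- estimate_affinity(apply_variant(prom, -36L, "T", "C"), cfg)
c(z = z_score(wt, mn), alpha = significance(z_score(wt, mn))$alpha)
```

## The marker rule and the dichotomy statistics

Gene-level polarity annotations (`excess_marks_dominance` or
`excess_marks_subordination`, with free-text evidence) externalize the
literature curation step, which is not computable. `classify_marker()`
crosses them with the expression decision; `tally_markers()` counts, per
body system (neuropeptidergic / non-neuropeptidergic / neurotrophinergic)
and in total: $N_{RES}$ significant SNPs, the expression split
$N_> / N_<$, and the marker split $N_\uparrow / N_\downarrow$. Genes with
no significant SNP simply contribute zero. Conservation
($N_{RES} = N_> + N_< = N_\uparrow + N_\downarrow$) and polarity-flip
symmetry are tested invariants.

Three test statistics summarize the dichotomies:

* `binom_equal_test()` — exact binomial at $p = 1/2$; the two-sided p-value
  uses the **doubling method** (twice the smaller tail, capped at 1), which
  is straightforward to verify by direct enumeration, rather than the
  minimum-likelihood method of `binom.test()`.
* `binom_neutral_test()` — exact binomial at $p = 1/5$, the genome-wide
  neutral-drift expectation that site-damaging SNPs outnumber
  site-improving ones about 4:1; a significant excess of improving variants
  signals natural selection.
* `chi2_equal_split()` — goodness-of-fit $\chi^2$ with 1 df and **no
  continuity correction**; the published per-strain contest values
  (e.g. 13 vs 7 → 1.80) reproduce only without Yates' correction.
* `concordance_prob()` — the one-sided probability $0.5^n$ that all $n$
  independent concordance checks of predictions against clinical
  annotations succeed by chance.

## Mouse contests and inheritance

Dominance tendencies can only be under natural selection if they are
heritable, hence the diallel validation design: five maternal strains
(31/20/21/20/23 pairs) crossed with the two analytic paternal strains
BALB/cLac (dominance-prone) and CBA/Lac (subordination-prone); each pair of
F1 males is observed 14 times. `score_contest()` pools the observations and
calls a male dominant only under the strict conjunctive rule — more attacks
*and* fewer submissive poses — because those are exactly the two asymmetry
measures the protocol names; an `attacks_only` switch is provided.
Ambiguous patterns are `unresolved`, excluded from counts and reported.
`tabulate_crosses()` builds the per-maternal-strain cross table with
`chi2_equal_split()` on every row and on the totals.

## What the synthetic data emulate — and what they do not

The generators replace the genome-database extractions so that every stage
is testable offline. Defaults are the study conditions: 231 genes,
Poisson(21.9) SNPs per gene (the screen's 5,052/231), three body systems at
27:109:95, the contest design above, and `p_dom = 79/115` (the observed
dominance rate; the type-I simulation in the acceptance material sets 0.5
explicitly).

Choices that needed making, and why:

* **GC content 0.6** — human core promoters are GC-rich; it also reflects
  how rarely spurious AT-rich windows should compete with a real site.
* **motif_fraction 0.5** — half the promoters carry an embedded consensus
  site; this is deliberately higher than the genome-wide TATA frequency so
  both promoter classes are well represented at test sizes.
* **latent sites** — single-base "motif-creating" SNPs are only physically
  possible where a near-consensus site exists, so each motif-free promoter
  carries two non-overlapping latent sites (consensus with one core
  mismatch, the mismatch being the substitution most damaging under the
  full model). A creating SNP restores such a mismatch; a disrupting SNP
  applies one to an embedded site; background SNPs avoid planted sites
  entirely.
* **effect_mix (0.04, 0.04, 0.92)** — symmetric creating/disrupting
  fractions keep the expression dichotomy balanced by construction, and the
  implied ~8% significant fraction is of the order of the screen's 22%
  while respecting the small per-gene pool of distinct latent variants.
* **contests** — the drawn winner's identity is the only asserted quantity;
  observation counts are Poisson (attacks 3.0 vs 0.5 per observation,
  submissive poses 0.3 vs 2.5), redrawn per pair until the totals realize
  the drawn winner under the strict rule.

Each generator seeds its own substream (`seed + 1` … `seed + 4`), so a
fixed `sim_spec` seed gives bit-identical outputs and partial regeneration
is reproducible.

The generators do **not** emulate real human promoter base composition
beyond GC content, linkage between variants, allele frequencies, indels, or
any behavioural time-course structure within contest observations. Passing
recovery tests therefore demonstrates that the pipeline's inferences are
correct *for the model that generated the data*, not that the default
parameterization reproduces any particular laboratory $K_D$ value — matching
published nM figures is explicitly out of scope.

## Numerical conventions and edge cases

* Argmax ties across windows resolve to the most upstream window.
* $Z$ with both $\delta = 0$: defined as 0 when the estimates are equal
  (identical alleles), an explicit error when they differ.
* Offsets are 1-based TSS-relative negative integers everywhere; FASTA
  headers carry `gene|transcript` ids with optional `offset=` and `flank=`
  tags; TSV is the tabular dialect throughout, and readers validate enums,
  ancestral alleles and referential integrity at load with line numbers in
  error messages.
* Test problem sizes: brute-force window-oracle comparisons run on ≤ 30 bp
  sequences; recovery checks use ~60 genes × 9 SNPs (≈ 500 variants); the
  type-I contest calibration uses 1,000 replicate 115-pair studies. These
  sizes give stable rates while keeping the default suite fast.

## Known limitations

The model scores TBP only; promoters regulated through other core elements
(Inr, DPE) are outside its scope. The calibration's absolute $-\ln K_D$
scale is a convention anchored at one point, so only *differences* between
alleles carry meaning. Polarity annotations are taken at gene level; if a
protein's excess has opposite behavioural readings in different tissues the
single-polarity assumption breaks down. The contest rule is a pooled-count
simplification of a richer ethological protocol whose full criteria are
not public.
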