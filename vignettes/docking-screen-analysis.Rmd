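---
title: "Quantitative analysis of competitive docking-site selection screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative analysis of competitive docking-site selection screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsitescreen)
```

## The experimental system

ERK2 recruits its activators, substrates and phosphatases through the
docking recruitment site (DRS), a groove opposite the catalytic cleft that
reads short linear docking motifs (D-sites) in disordered regions of partner
proteins. Recurrent cancer mutations cluster at the common-docking (CD)
acidic patch within the DRS, and a central question is how these mutations
rewire docking specificity: which interactions are lost, which persist, and
whether any are gained.

The measurement this package analyses is a pooled competitive yeast
two-hybrid (Y2H) selection. A library of thousands of candidate 14-mer
docking peptides, each fused to a transcription-factor prey and encoded by a
defined 42-nt insert, competes for growth under histidine-dropout selection
that rewards binding to an ERK2 bait (wild type or a CD mutant). Cultures
are sampled repeatedly over about seven population doublings, the variable
insert is PCR-amplified and sequenced, and each member's trajectory of read
frequencies carries its selective advantage.

## The enrichment-score model

For member $i$ in sample $t$, the frequency is
$F_{i,t} = c_{i,t} / \sum_j c_{j,t}$ with $c$ the read counts. The
enrichment score is the slope of

$$y_{i,t} = \ln\left(F_{i,t} / F_{i,0}\right)$$

regressed by ordinary least squares on cumulative population doublings
$D_t$. Under exponential competitive growth
$N_i(\tau) = N_i(0)\,e^{g_i \tau}$ this slope converges to
$\ln 2\,(g_i/\bar g - 1)$, i.e. the member's growth-rate excess over the
population mean, in natural-log units per doubling — which is why ES values
are comparable across screens sampled on different clocks.

Concrete modelling choices, each exposed as an argument:

* **Pseudocount 0.5**, added uniformly to every cell before normalisation,
  keeps $\ln F$ finite. Members whose *raw* count at the $D=0$ baseline is
  zero in a replicate are excluded from that replicate (reported as `NA`,
  never as 0): a slope anchored at an imputed baseline measures the
  imputation, not the member.
* **Free intercept**, with the point $(0, 0)$ entering the regression as
  data. The intercept absorbs baseline sampling error instead of forcing it
  into the slope.
* **Replicates are averaged unweighted** over the replicates where an ES is
  defined, and **Z-scores are computed on the replicate-averaged ES** within
  one (genotype, condition) screen using the sample standard deviation.
  Per-replicate Z-scores are also emitted for "hit in every replicate"
  consistency filters.
* Selective and nonselective scores are reported in parallel; no
  subtraction is performed.

Hits are members with $Z > 3$ (strict inequality; an inclusive flag is
available). Across two mutant screens and wild type, hits are categorised as
*lost* (wild-type-unique), *common* (shared with at least one mutant) and
*gained* (hit in both mutants but not wild type), plus all seven Venn cells,
so both "either-mutant" and "both-mutant" overlap conventions can be read
off directly. A relaxed membership — the top 3% of members by mean ES, size
$\lceil pN/100 \rceil$ with boundary ties broken by member id — supports the
observation that most apparent gained hits are near-threshold wild-type
binders. Wild-type-selective candidates are ranked by
$\Delta_i = \mathrm{ES}^{WT}_i - \tfrac12(\mathrm{ES}^{m_1}_i +
\mathrm{ES}^{m_2}_i)$; the mutant mean is a declared convention (the
maximum is available as an alternative) since no canonical differential
metric exists for three-screen designs.

## The synthetic screen generator

Real screens of this kind are only reproducible from deposited sequencing
data, so the package carries a first-class generator that emulates the
statistical structure the analysis assumes; every downstream stage is
exercised end to end on it.

* **Library.** `build_synthetic_library()` draws unique 14-mers conforming
  to the library consensus `[R/K]-x(0-2)-[R/K]-x(3-5)-[ILV]-x-[FILMV]` (a
  basic patch, variable linker, and hydrophobic phi-x-phi module). A
  configurable fraction carries an I/L-x-x-R-R (HEPTP-type) match starting
  within the first four positions — the motif class whose binding is
  selective for wild-type ERK2 — with the di-arginine doubling as the
  consensus basic pair. Reverse translation uses one fixed preferred yeast
  codon per residue, so libraries are byte-reproducible for a seed.
* **Fitness link.** Binding enters growth through fractional bait occupancy
  $\theta_i = C/(C + K_{d,i})$ and $g_i = r_0 (1 + s\,\theta_i)$ under
  selection ($g_i = r_0$ otherwise). The saturating link is deliberate: very
  strong binders plateau, while affinity losses around the half-saturation
  point translate efficiently into growth differences. Defaults:
  $r_0 = 0.35\,\mathrm{h^{-1}}$ (a ~2 h doubling time), $s = 1$,
  $C = 5\,\mu M$. Non-motif members draw wild-type $K_d$ log-uniformly from
  0.5–500 µM (a realistic peptide-affinity span); in mutant genotypes,
  HEPTP-type members have their $K_d$ multiplied by a log-uniform 3–40-fold
  penalty, the range measured for validated lost interactors.
* **HEPTP affinity band.** HEPTP-type members draw wild-type $K_d$ from a
  narrow band just below $C$ (0.4–0.9 µM). This follows from the occupancy
  algebra rather than taste: if $K_d \ll C$, even a 10-fold penalty leaves
  $\theta$ near saturation and the member remains a mutant hit; if
  $K_d \gtrsim C$, the member is not a confident wild-type hit to begin
  with. Only a band near the saturation knee lets a 3–40-fold loss separate
  the genotypes — and it matches the validated wild-type-selective peptides,
  which bind wild-type kinase with similar, low-micromolar affinity.
* **Growth and sampling.** Abundances grow deterministically and
  exponentially; chronological time is solved from the cumulative-doubling
  grid (default $\{0, 1.75, 3.5, 5.25, 7\}$, five samples over ~7
  doublings) by a monotone root-find. Reads are multinomial at fixed depth;
  an optional Dirichlet-multinomial knob adds PCR-like overdispersion but
  defaults to off, the simplest model consistent with the slope estimator.
  Replicates share the true fitness and differ only through independent
  sampling substreams, matching independently grown screens of one library.
  An optional Poisson founding bottleneck (colonies per member) is exposed;
  it defaults to off because no value is constrained by data.
* **FASTQ emission.** `emit_fastq()` writes each counted read as
  `anchor5 + insert + anchor3` with constant quality, so the counting stage
  can be round-trip tested against the simulated truth exactly.

What the generator does **not** emulate: PCR amplification chemistry,
base-call errors, paired-end structure, yeast lag phase or His3 enzymology,
and library synthesis bias. Passing recovery tests on synthetic screens
therefore demonstrates the estimator and classification logic, not
robustness to those artefacts.

## Choosing the hit threshold for recovery studies

One self-consistency study deserves its own note. To measure end-to-end
recovery we simulate screens in which 20% of members are HEPTP-type,
wild-type-selective binders and ask how many land in the wild-type-unique
category. A $Z > 3$ threshold cannot work in that design — not because of
noise, but arithmetic: by the one-sided Chebyshev (Cantelli) inequality at
most $1/(1+t^2)$ of any distribution lies more than $t$ standard deviations
above its mean, so at most 10% of members can ever satisfy $Z > 3$, and a
20%-prevalence class can never reach 80% recovery through it. Flagging a
20% tail requires $t \le 2$; the recovery studies therefore use $Z > 1$,
which leaves margin for sampling noise while still rejecting the bulk of
the distribution. The published-data convention of $Z > 3$ is unaffected:
real screens call ~1% of the library as hits, far inside the feasible
region. This is a useful reminder that standard-score thresholds embed an
assumption about hit prevalence.

## Amplicon counting

Reads are assigned by extracting the substring strictly between the first
occurrence of the 5' anchor and the first subsequent occurrence of the 3'
anchor (exact matching, forward strand only — exactness keeps counts
auditable; a k-mismatch extension point is documented in the code), then
matched against the library whitelist by exact DNA first and exact
translated peptide second. The DNA-first rule tolerates synonymous
PCR/sequencing artefacts without inventing an error model. Discarded reads
are tallied by reason (`no_anchor`, `bad_length`, `stop_or_ambiguous`,
`not_in_whitelist`) and matched + discarded always equals reads processed.
A missing doublings-0 sample for any series is a hard error, because the ES
baseline is undefined without it. Quality trimming, UMIs and demultiplexing
are out of scope.

## Motif scanning and probability logos

Motifs are ordered residue classes separated by bounded variable spacers,
written in a compact grammar (`"[RK]x{0,2}[RK]x{3,5}[ILV]x[FILMV]"`), with
an optional start window for the first element. The scanner enumerates all
spacing combinations (shortest first at equal starts); it is tested for
exact agreement with an independent regular-expression oracle. The
HEPTP-type motif is `[IL]x{2,2}[R][R]` with start window 1–4 — "near the
N-terminus" made concrete and configurable; position 1 is {I, L}, not
{I, L, V}, following the motif's structural definition.

Positional overrepresentation compares a foreground set of equal-length
peptides against a background by exact binomial tails:
$p_{over} = P(X \ge k)$, $p_{under} = P(X \le k)$ with
$X \sim \mathrm{Bin}(n, p_0)$ and $p_0$ the background frequency of that
residue at that position. Letter heights are $-\log_{10} p$ of the favoured
tail, signed, exactly zero when $k/n = p_0$; significance is Bonferroni at
$\alpha = 0.05$ over $20 \times L$ tests, the convention of published
probability logos. No normal approximation is used anywhere. Because all
library members share one length, no alignment is performed. The default
background is the screened library itself — this corrects for the built-in
consensus bias (arginine is common at basic-patch positions by
construction); a proteome background would conflate library design with
selection.

## Dose-response fitting

Competitive-inhibition series are fitted with the four-parameter logistic
$y = bottom + (top - bottom)/(1 + (c/IC_{50})^h)$ by nonlinear least
squares on a log10 concentration grid, all four parameters free (a 3PL
variant with fixed bottom is available). Start values come from the data:
asymptotes from the extreme-concentration quartiles, $IC_{50}$ from the
half-maximal crossing, $h = 1$. Zero-concentration points enter only the
normalisation `(raw - min)/(max - min)`, never the logistic fit. The
reported $IC_{50}$ is the mean of per-replicate fits with a t-based 95%
interval across replicates — the convention used when assays are summarised
as "mean and 95% CI of three independent replicates" — rather than a
single-fit asymptotic interval. Fits are flagged (never silently dropped)
when the optimiser fails, the $IC_{50}$ falls outside the tested range, or
the curve rises with dose (negative Hill slope or inverted asymptotes).
Fold changes between kinase variants are reported as mutant/wild-type
ratios with a delta-method interval on the log scale. Mechanistic $K_i$
extraction (Cheng–Prusoff) is out of scope.

## Numerical choices and degenerate inputs

* Slopes are computed by the closed-form least-squares expression,
  vectorised across members; tests pin agreement with `lm()` to $10^{-10}$.
* The doubling-to-time root-find brackets $[0, D\ln 2 / \min g]$ and
  tightens to $10^{-12}$; a non-growing population is an internal error.
* Z-scores require at least two scored members and positive standard
  deviation; degenerate screens error rather than emit zeros.
* Empty libraries, empty FASTQs, all-zero columns, boundary Z values and
  tie-breaks all have defined, tested behaviour (see the test suite).
* All randomness flows from one integer seed through fixed substreams;
  identical configurations produce byte-identical outputs.

## Problem sizes

The package's own verification studies use libraries of 1,000 members at
read depth $10^5$, three replicates, five timepoints over seven doublings —
large enough that multinomial noise behaves as in deep screens
(counts of ~100 per member per sample) while a full simulate–score–compare
cycle stays in seconds. The generator defaults to $10^4$ members, the scale
of the real library; unit tests use 10–300 members.

## Limitations

Estimation is plain OLS per member — no shrinkage, no mixed-effects
replicate model, no variance-stabilising transform; members near zero
frequency therefore have noisy scores, mitigated only by the baseline
filter. Hit calling by standard score inherits the prevalence assumption
discussed above. The comparison stage assumes exactly one wild-type and two
mutant screens. Published screen tables can be re-analysed via
`reproduce_published_comparison()`, but the deposited data must be supplied
by the user; nothing in this package re-derives those numbers from raw
reads.
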