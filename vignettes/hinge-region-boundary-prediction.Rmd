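---
title: "Hinge-region domain boundary prediction: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hinge-region domain boundary prediction: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Protein chains often fold into several compact domains joined by short
linkers. Given only a sequence, we want to call, per residue, whether it
belongs to a domain interior or to a boundary. Residue-level boundary
calling is heavily imbalanced: in domain-annotated chains roughly one
residue in fifteen is a boundary residue (a residue outside all domains,
or the first/last residue of a domain segment). The hinge-region strategy
attacks the imbalance, and the fact that most prediction errors cluster
around domain termini, by inserting a third label class between the two:

* **domain (0)** — interior residues of a domain segment;
* **boundary (1)** — residues outside all domains, plus every segment's
  first and last residue (so two touching domains contribute two adjacent
  boundary residues);
* **hinge (2)** — for each domain-segment terminus, a window of `2R`
  residues straddling it, `R` on the domain side and `R` on the boundary
  side (default `R = 10`, so a 20-residue window). Windows truncate at
  chain ends and overlapping windows take their union; hinge overrides
  the other two codes.

The index convention is fixed so each full window really has `R` residues
per side: an N-terminus at `t` covers `t-R .. t+R-1`, a C-terminus at `t`
covers `t-R+1 .. t+R`. For discontinuous (multi-segment) domains we apply
the terminus rule to *every* segment, because segment ends are exactly
where the chain leaves or re-enters a domain region; the alternative
(whole-domain extremes only) would leave internal re-entry points
unlabeled.

### DHB profiles

The informative feature is homology: a query is locally aligned against a
reference database of chains with known three-state labels
(`local_align_search()`), keeping alignments with e-value at most 0.1,
ranked ascending, top 10 (`search_params()`). For query position $p$ and
state $s$, with $A_l(p,s) = 1$ when hit $l$ aligns $p$ to a subject
residue labeled $s$,

$$\mathrm{profile}(p,s) \;=\; \frac{\sum_l A_l(p,s)}
{\sum_{s'} \sum_l A_l(p,s')},$$

an L×3 row-stochastic matrix (columns: domain, hinge, boundary) on
covered positions. Two interpretation choices are deliberate:

* the denominator counts *hits aligning p*, not all kept hits, so the
  profile is a well-defined frequency even at partially covered
  positions;
* positions no hit aligns get the all-zero row and a `covered = FALSE`
  flag — zero encodes "no homology evidence" and the feature binning
  maps it to its own category, rather than pretending a uniform 1/3.

### Features and the chain CRF

Four observation columns enter the model: the three profile columns and a
one-character-per-residue shape string (8-symbol backbone alphabet from
Ramachandran-space clustering; `-` when unknown, which lets profile-only
models run). A unigram template walks offsets −4…+4 for every column, so
each position carries 36 categorical features; out-of-range offsets emit
`_BOS_`/`_EOS_` sentinels. Numeric profile values are discretized
round-half-up on a 0.1 grid (`template_config(bin_width = )` makes the
grid finer), mirroring how CRF toolkits treat feature strings as opaque
categories.

The sequence model is a linear-chain conditional random field over the
three labels, written from scratch because it is the computational core:
log-space forward–backward and Viterbi in C++, emission weights tied per
feature id, plus 3×3 observation-independent transition weights. Training
maximizes the L2-penalized conditional log-likelihood (Gaussian prior,
`l2_sigma = 1` by default) with L-BFGS from a zero start; the objective
is concave, so no random restarts are needed and the seed in
`train_config()` is reserved for callers that shuffle data. Feature ids
unseen at training time contribute nothing at prediction time.

### Decoding

`argmax_regions()` segments the posterior marginals into maximal runs of
the per-position argmax state (ties toward the lower label code). The
final two-state call applies the region-specific decision rules of
`decide_two_state()`:

* argmax-boundary regions are always boundary;
* argmax-hinge regions: boundary iff `P_hinge > t_hinge`
  (default 0.4, the value at which the weighted score peaks in
  threshold sweeps);
* argmax-domain regions: domain, unless `mode` is `domain_only`/`both`,
  where the call is domain iff `P_domain > t_domain` (default 0.75).

"Predicted hinge region" is operationalized as an argmax-marginal run;
Viterbi runs are an equally defensible reading, and `viterbi_path()` is
exported for callers who prefer it. In `domain_only` mode the hinge rule
is inactive; hinge-region residues then fall back to comparing domain
mass against hinge+boundary mass. The default mode is `hinge_only`,
matching the operating point used for large-scale runs. The per-residue
ROC score is `1 − P_domain`, i.e. hinge and boundary mass pooled as
boundary evidence; this is a documented convention of this package — any
monotone combination could underlie a reported AUC, and this one uses
all three states without an extra parameter.

## Alignment back end

Hit generation is pluggable. The default is single-pass Smith–Waterman
with affine gaps (BLOSUM62, gap open 11 / extend 1) executed by
Biostrings, with Karlin–Altschul e-values
$E = K m n e^{-\lambda S}$ using the standard gapped constants for this
scoring system ($\lambda = 0.267$, $K = 0.041$) and the database residue
count as $n$; e-values are floored at 1e−300 against exp underflow on
near-identical long hits. One alignment — the best — is kept per subject.
Iterated profile search (PSSM) is out of scope; externally computed hits
(e.g. from BLAST) can be supplied through `import_tabular_hits()`, which
applies the same e-value ceiling / ranking / top-S contract, so the
profile stage is agnostic to where hits came from. Ties in e-value break
by bit score then subject id, keeping hit lists reproducible.

## The synthetic generator

`generate_dataset()` plants homologous families so every stage is
testable offline: each family is a random prototype (length 120–220 by
default); a domain instance is its prototype trimmed uniformly by
0–8 residues at each end (`boundary_jitter`, emulating the fuzziness of
real domain-boundary assignment — and the reason alignment-derived hinge
profiles are graded rather than binary) and point-mutated at
`mutation_rate` (default 0.05). Chains carry 1–3 domains (weights
0.5/0.35/0.15) joined by 6–18-residue random linkers with 0–7-residue
terminal tails; shape strings emit `A/T/G/K` inside domains and
`R/S/U/V` elsewhere, randomized per residue with probability
`shape_noise` (default 0.1). The linker/tail/domain length defaults were
computed analytically, once, to land the boundary:domain residue ratio
near the 1:15 imbalance of real annotated chains. Mutated copies make
query–reference exact matches essentially impossible; the generator
nevertheless resamples on collision so the exact-match exclusion filter
is a no-op on its own output.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: indels within domains (alignment coordinates
stay exact), domain architectures beyond three domains, composition bias
and low-complexity regions, families with internal repeats, and shape
strings with realistic prediction-error structure. Synthetic profiles
are therefore much cleaner than PSI-BLAST-derived ones; posterior
marginals saturate, and the weighted-score-versus-threshold curve,
while still peaking at an interior threshold, is flatter than on real
data, with its peak pushed toward high thresholds.

A related caveat: within the generator's allowed substitution range
(`mutation_rate` ≤ 0.5), homology between realistic-length domain copies
never becomes undetectable — at rate 0.45 two copies still share ~31%
identity, which local alignment finds with overwhelming significance —
so profiles stay informative and pipeline AUC stays high even with
fully randomized shape strings. Destroying the signal end to end
requires *short* domains (so alignment genuinely drops below the
e-value ceiling), which is how the signal-controllability test in the
suite is constructed.

## Problem sizes and numerics

The test suite exercises the full pipeline at the scale of the synthetic
study fixture: 3 families, 300 reference chains, 100 training and 50
held-out query chains (about 13,000 evaluated residues), which keeps a
complete synth → align → train → predict → evaluate cycle under two
minutes on one CPU. Exact-inference checks run at chain lengths ≤ 8
against enumeration over all $3^L$ label paths (tolerance 1e−9), the
analytic gradient against central differences (relative 1e−5), and the
built-in alignment against an independent Gotoh dynamic program on
≤ 12-residue sequences. Bootstrap standard errors resample 80% of
targets with replacement, 1000 times, under a fixed seed; "bootstrap"
is meant literally — with-replacement resampling is also what makes the
estimate match binomial sampling theory on a Bernoulli construction.
Metrics with zero denominators are reported as undefined (`NA`), never
silently as zero. The weighted score is computed as
`Sw = Sn + Sp − 1` (twice the balanced accuracy minus one), the reading
consistent with published hinge-size tables up to rounding.

## Known limitations

* Single-pass Smith–Waterman is weaker than an iterated profile search;
  on real data, supply external hits via `import_tabular_hits()` for
  full fidelity.
* Multi-domain queries whose families differ greatly in alignment
  strength can have their weaker domain crowded out of the global top-S
  hit list, leaving it uncovered; the shape column then carries the
  signal there.
* Residue-level evaluation only; no event-level matching with a
  tolerance window, and no assembly of boundary calls into domain
  architectures.
* The CRF uses unigram observation features plus label-pair transitions;
  no observation-dependent transition features.
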