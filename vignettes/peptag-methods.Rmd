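---
title: "peptag: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{peptag: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its science: the models and
their assumptions, the parameters that matter, what the synthetic data
generator does and does not emulate, and the places where the design was
genuinely open and a choice had to be made. It states no empirical result
that the test suite does not itself compute.

## 1. The identification model

`peptag` identifies peptides from CID tandem mass spectra by combining two
evidence streams per spectrum: a *de novo* stream (how well a candidate's
sequence agrees with sequence tags read directly off the spectrum) and a
*database* stream (how well the candidate's predicted fragment ions match
the observed peaks). The final score is a weighted sum of the two after
per-spectrum min-max normalisation.

### Preprocessing

Two intensity views are kept. The *continuous* view divides every raw
intensity by a baseline — the median of the nonzero intensities, a robust
choice when a handful of peaks dominate — and feeds ion matching. The
*discrete* view bins the normalised intensity into four levels (no, low,
medium, strong signal) at thresholds 1, 3 and 10, and feeds the Bayesian
fragmentation model. A level is the number of thresholds strictly below
the value, so the baseline itself discretises to "no signal": peaks at or
below the noise floor are deliberately dropped before graph construction.
Denoising keeps the 6 most intense peaks of at least one 100 Th window
centred on a peak. Each peak finally gets one of five equal-width m/z
regions spanning zero to the singly protonated precursor mass; regions let
the model learn that, e.g., low-m/z noise behaves differently from
mid-range noise. Whether the original five regions were equal-width or
quantile-based is not documented anywhere we could rely on; equal width is
the simpler choice and is configurable.

### The spectrum graph and its scoring

Every kept peak is given both a b-ion and a y-ion interpretation as a
prefix residue mass; terminals for the empty and intact peptide are added,
and edges connect vertices one residue mass apart (within the fragment
tolerance, 0.5 Da by default). Leucine/isoleucine are exactly isobaric and
collapse to one edge label; glutamine/lysine differ by 0.036 Da and are
collapsed whenever the tolerance cannot resolve them.

Two details took actual debugging to get right and are worth recording:

* **Mirror vertices and conflict sets.** The y-interpretation of a b-ion
  peak and the b-interpretation of the matching y-ion peak land on the
  *same* mirrored mass, and that mirror vertex sees genuine peaks at both
  its b- and y-positions — it is indistinguishable from a true vertex by
  position evidence alone. Vertices closer than the tolerance are merged,
  and the merged vertex records the *union* of contributing peaks. A path
  may use at most one vertex per recorded peak (the antisymmetry
  constraint), which is exactly what prevents chimeric paths that stitch
  true and mirrored ladder segments together.
* **The random-match null.** A vertex is scored by the log likelihood
  ratio of "these intensities arise from a real cleavage here" against
  "these matches are random". The null is estimated from the density of
  *all* kept peaks per region, not only of peaks that failed annotation
  during training: under the null the candidate mass is wrong, so hitting
  a genuine fragment peak is precisely as coincidental as hitting noise.
  Estimating the null from noise peaks alone understates it in
  fragment-rich regions and makes isolated coincidental hits look like
  evidence (the classic symptom is a doubly charged peak's singly charged
  misinterpretation spawning a well-scored phantom vertex).

The fragmentation network models nine ion types. b+ and y+ are parents;
a+, the water/ammonia losses and the doubly charged ions each depend on
their primary ion. Every conditional table is additionally indexed by
region and by coarse chemical classes of the residues flanking the
cleavage ({K/R, H, P, G, other} — basic residues, histidine, the proline
effect, glycine, rest). The class partition keeps tables estimable from a
few hundred annotated spectra; when the flanking residues are unknown (as
during de novo scoring) the "other" class is used. Tables are Laplace
smoothed (pseudo-count 1), so every score is finite. Doubly charged
positions are matched at half the mass tolerance, because a neutral-mass
tolerance shrinks per charge in m/z space.

### From paths to tags

The k best antisymmetric source-to-sink paths (k = 20) are enumerated
exactly by best-first search with an admissible bound (the unconstrained
best suffix score from a reverse topological sweep); ties break
lexicographically so results are deterministic. The paths are aligned
progressively (match +1, mismatch −1, gap −2, guide order by path score),
and tags are extracted as runs of columns where enough paths agree.

Column support is weighted, and this is the one place the package departs
from the obvious equal-vote reading. Path scores are sums of
log-likelihood-ratio vertex scores, so each path is weighted by
`exp((score - best_score)/T)` with temperature `T = 10` — a tempered
posterior over candidate interpretations. The failure mode of equal votes
is easy to reproduce: the sub-optimal space contains whole families of
near-duplicate low-scoring variants (often mirror readings), and twenty
equal votes let that swarm outvote a clearly better family. With weighted
votes a dominant family keeps its consensus, while genuine near-ties (two
readings within a few log units) dilute support and correctly mark the
region as ambiguous. The temperature trades these off: `T → 0` degenerates
to "tags are segments of the single best path", `T → ∞` restores equal
voting; `T = 10` lets variants differing by one dubious vertex (a few log
units) share the vote while keeping 20+ log-unit families negligible.
Support is thresholded at half the total weight
(`tag_min_support = 0.5`), and the reported `support` column remains the
plain count of agreeing paths.

Each tag is by construction a contiguous segment of one candidate path, so
its flanking prefix/suffix mass gaps come from that path's vertex masses
and satisfy `prefix_gap + residue masses + suffix_gap = precursor neutral
mass` (the suffix gap absorbs the terminal water). Tags are bounded to
3–7 residues — longer consensus runs are clipped to the best-scoring
window — because beyond 7–8 residues tag errors grow faster than the
added search power.

### Querying tags and rescoring candidates

Tags search the tryptic peptide index (cleavage after K/R except before P,
up to 2 missed cleavages, length 6–30, coordinates 0-based half-open) with
an affine-gap Smith–Waterman (gap open 11, extend 1) over a modified
BLOSUM62: L/I and Q/K are made *fully* interchangeable (mutual and
diagonal scores from the averaged diagonals, rows/columns against everyone
else averaged likewise), X scores zero everywhere (an unknown tag position
should neither reward nor punish), and a cleavage-anchor symbol `^`
scoring the K/R diagonal average lets a tag that starts at the peptide
N-terminus collect a bonus for the preceding tryptic cleavage. Full
interchangeability is a slightly stronger modification than averaging the
diagonals alone, but it is what makes the similarity score provably
invariant under L&harr;I and Q&harr;K swaps — without full row averaging a
swap could still change off-diagonal terms. It also makes any special
"internal lysine" recoding a no-op, since an internal K already scores as
its isobaric twin. Candidates are prefiltered to ±2.5 Da around the
spectrum's neutral mass (disable with `mass_window = Inf` for open
searches), hits merge per peptide keeping the best similarity score Ss,
and at most 50 hits per spectrum go forward.

Each hit is fragmented in silico (the nine ion types with empirical
intensities 100 for b/y, 50 for b2/y2, 20 for the rest) and matched
greedily closest-pair-first within tolerance. The correlation score is the
factorial-weighted dot product `Nb!·Ny!·Σ I·P`, evaluated via log-gamma
because the factorials overflow for long peptides while any strictly
monotone transform preserves ranking. `Nb` and `Ny` count distinct
cleavage sites with an assigned b-series or y-series ion; neutral losses
support the match through the dot product but are not counted as assigned
ions.

### Final score, delta and FDR

The printed combination rule of the source method is a pure product of
weighted Ss and Sc; in that form the weight multiplies every candidate by
the same constant `W(1−W)` and cannot change relative ranking (the test
suite asserts this as a regression test). The default is therefore the
weighted *sum* of per-spectrum min-max normalised scores, `S = W·Ss_norm +
(1−W)·Sc_norm` with `W = 0.5`, which actually lets the de novo weight
matter; the literal product stays available behind
`score_mode = "literal_product"`. The delta score `D = (S_max −
S_2nd)/S_max` is taken over distinct peptides; a lone candidate gets
`D = 1`, and `D` is undefined when `S_max ≤ 0`. FDR control is standard
target-decoy with whole-protein reversal: `FDR(t) = #decoys/#targets`
above `t` among rank-1 PSMs, made monotone by the cumulative-minimum
q-value transform.

## 2. Parameters at a glance

| key | default | unit | why |
|---|---|---|---|
| `discretize_thresholds` | 1, 3, 10 | × baseline | four levels; baseline itself maps to "no signal" |
| `window_width` / `window_top_n` | 100 Th / 6 | | common denoising practice |
| `n_regions` | 5 | | position-dependent fragment/noise statistics |
| `fragment_tolerance` | 0.5 | Da | ion-trap CID scale; halved per charge in m/z |
| `top_k` | 20 | paths | sub-optimal space to expose ambiguity |
| `tag_min_len` / `tag_max_len` | 3 / 7 | residues | tags beyond 7–8 accumulate errors |
| `tag_min_support` | 0.5 | weight fraction | half of the tempered path posterior |
| `tag_support_temperature` | 10 | log-units | vertex-level score scale of one dubious swap |
| `mass_window` | 2.5 | Da | precursor prefilter; `Inf` = open search |
| `max_hits` | 50 | | caps candidates per spectrum |
| `gap_open` / `gap_extend` | 11 / 1 | | BLAST protein defaults |
| `W_denovo` | 0.5 | | equal weighting of evidence streams |
| `missed_cleavages`, `digest_min_len`, `digest_max_len` | 2, 6, 30 | | common tryptic search practice |

## 3. The synthetic world

The generator exists so that training, tag inference, search and
evaluation run with no external data, and it emulates precisely the
structure the method assumes: tryptic peptides sampled from a random
protein database (K/R boosted to a combined 11% so tryptic peptides
average ~9 residues), b/y fragment ladders with per-ion-type detection
probabilities and discrete intensity levels, Gaussian m/z jitter
(sd 0.01 Da), and Poisson-distributed uniform noise peaks (mean 30).

Three deliberate design points:

* **Levels are emitted in the discretiser's own bins.** Intensity bands
  are placed so that, after the pipeline re-estimates the baseline as the
  median, level-2 and level-3 peaks land inside their intended bins with
  margin. Level 1 sits *at* the baseline — as weak fragments do in real
  spectra — so part of its mass is absorbed into level 0 on
  renormalisation. Consequently, trained marginals of the primary and
  doubly charged ions recover the generator's marginals closely (the
  acceptance suite asserts total variation below 0.1 for b and y), while
  the weak minor ions (a, neutral losses) land slightly above that bound;
  this is a property of median renormalisation, not of the estimator.
* **b is weaker than y.** Detection 0.85 vs 0.95 and a softer level
  distribution, matching tryptic CID where C-terminal fragments retain
  the basic residue. This is not cosmetic: a perfectly b/y-symmetric
  spectrum is two-fold ambiguous — the mirrored ladder reads the reversed
  peptide and no scoring function can orient it. The b/y asymmetry is the
  signal that lets the trained network distinguish the likely ion
  combinations from their mirror images.
* **The noise-free world is the degenerate limit**, not a separate code
  path: detection 1, jitter 0, zero noise peaks, deterministic bin-centre
  intensities (y strong, b medium, b2/y2 medium, minors at the dropped
  level). End-to-end recovery tests run there.

What the generator does *not* emulate — and hence what a green test does
not establish: isotope envelopes, chemical noise with structure,
co-isolation, charge states beyond 2, post-translational modifications,
instrument-specific intensity response, retention time. Results on
synthetic spectra bound what the pipeline can do when its model matches
the data-generating process; they say nothing about model mismatch on
real instruments.

## 4. Numerical choices and degenerate inputs

* Monoisotopic masses throughout; proton 1.007276, water 18.010565,
  ammonia 17.026549, CO 27.994915 Da.
* All probability tables are smoothed, every score finite; `p_real` and
  `p_random` are products in (0, 1], compared in natural log.
* Path ties break by lexicographic residue string; PSM ties by `Sc_log`,
  then peptide string — all outputs are deterministic given inputs, and
  the only randomness in the package lives in the generator behind a
  seed.
* Empty inputs are contracts, not errors: an empty MGF gives an empty PSM
  table; a spectrum with no kept peaks or no source-sink path yields a
  `no_tags` row; a tag list without hits yields `no_hits`.
* An all-zero spectrum, a non-ascending threshold vector, a single-residue
  peptide, and W outside [0, 1] are errors by contract.
* The k-best search carries a 50 000-expansion safety cap; on the graph
  sizes the pipeline builds (a few hundred vertices) the exact enumeration
  finishes far below it.

## 5. Known limitations

* Tolerance 0.5 Da cannot distinguish Q/K, nor a residue from certain
  two-residue splits (e.g. K vs G+A at 0.036 Da); tags inherit these
  ambiguities by design and the substitution matrix absorbs them at query
  time.
* Only singly charged b/y interpretations build the graph; charge-3+
  precursors are accepted but their doubly charged fragments are modelled
  only in ion matching, not as graph vertices.
* The noise model is per-region level frequencies; it has no notion of
  correlated chemical noise.
* mzML input is not implemented (no reader available in the target
  environment); the `Spectrum` contract isolates formats, so adding one
  later does not touch the pipeline.
* Protein-level inference is a best-peptide roll-up, not a parsimony
  model.
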