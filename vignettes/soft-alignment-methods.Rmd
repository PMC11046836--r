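---
title: "Soft alignment of protein embeddings: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soft alignment of protein embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(softalign)
```

## The problem

Functional annotation of viral proteins is hard for classical homology
search: viral sequences diverge quickly, and substitution-matrix scores
(PAM/BLOSUM) judge each residue pair out of context. Protein language models
offer an alternative similarity signal: a per-residue embedding vector that
encodes the residue *in its sequence context*, so that two residues playing
the same structural or functional role score as similar even when the
letters differ. This package implements a residue-level alignment built
entirely on that signal.

## The model

For a query $q = q_1 \ldots q_n$ and subject $s = s_1 \ldots s_m$ with
residue embedding matrices $E(q) \in \mathbb{R}^{n \times d}$ and
$E(s) \in \mathbb{R}^{m \times d}$, the similarity matrix $D$ is the
$n \times m$ matrix of cosine similarities
$D_{ij} = \cos\!\big(E(q)_i, E(s)_j\big)$.

1. **Match classification.** For each query residue, the top-3 subject
   residues by cosine form its candidate list (and vice versa). A pair
   $(i, j)$ is a **mutual match** when each residue is the other's single
   best partner; mutual matches are therefore a one-to-one partial mapping.
   A pair is a **secondary match** when it is not mutual, each residue sits
   in the other's top-3 list, and neither residue participates in any
   mutual pair.
2. **Diagonal filtering.** Genuine gap-free homology is co-linear: matched
   pairs share a diagonal offset $d = j - i$. A diagonal is kept when it
   carries at least 5 mutual matches, or lies within 5 offsets of a
   diagonal carrying strictly more than 5 (the asymmetric thresholds are
   deliberate and kept literal). Every match on a discarded diagonal is
   removed. Filtering never adds matches.
3. **Single-gap rescue.** A lone missing cell on a retained diagonal whose
   two diagonal neighbours are matches is promoted to a **rescued** match
   when query and subject carry the identical amino acid there (X equals
   X). Runs of two or more missing cells are never rescued.
4. **Chaining and score.** The alignment is the subset of surviving matches
   with maximum total cosine similarity that is strictly increasing in both
   coordinates, found by an $O(M^2)$ dynamic program over the $M$ matches
   (the weight structure makes crossing pairs mutually exclusive; no gap
   penalty is applied — diagonal filtering is the only anti-gap mechanism).
   The score is the sum of the chained cosines, so a perfect gap-free
   alignment of $L$ residues scores $L$. An alignment is **significant**
   when its score reaches `min_score = 20`, a threshold calibrated against
   a conventional aligner's stringent e-value regime.

Around the core sit a pooled-embedding retrieval step (mean over residues,
L2-normalised, exact cosine k-nearest-neighbour search), an annotation
pipeline that transfers the functional category of the best significant hit,
and a combinatorial null model.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `t` | 3 | candidate-list depth for secondary matches |
| `min_mutual` | 5 | mutual matches a diagonal needs to stand alone |
| `neighbor_window` | 5 | max offset distance for neighbour rescue |
| `min_score` | 20 | significance threshold on the summed cosine score |
| `knn_k` | 5 | pooled-retrieval candidates soft-aligned per query |
| `escalate_k` | 15 | retry breadth when no candidate is significant |
| `dim` | 64 | embedding dimension of the synthetic provider |
| `max_len` | 1024 | longest embeddable sequence (longer ones are rejected) |

All tie-breaks (argmax, top-t, equal KNN cosines, equal soft scores) resolve
to the lower index or lexicographically smaller id, so every output is
deterministic for fixed inputs and seeds.

Ranking among significant candidates is by soft score, then pooled cosine,
then subject id. Sequences shorter than `min_mutual` cannot pass filtering;
`soft_align()` warns and `filter = FALSE` exposes the unfiltered alignment
for diagnostics.

## The embedding provider contract

Every downstream stage consumes only the embedding matrices, so providers
are pluggable. The shipped provider is synthetic and deterministic: each of
the 24 residue letters maps to a seeded pseudorandom unit vector, plus a
small position-keyed Gaussian jitter (`jitter = 0.05`, renormalised).
Consequences:

* identical sequences embed to identical matrices, so a self-comparison has
  an exactly-1 main diagonal;
* equal letters at different positions have cosine just below 1 (about
  $1/(1+\sigma^2 d)$ for jitter $\sigma$), which breaks argmax ties that
  would otherwise let repeated letters steal each other's best match;
* distinct letters are near-orthogonal, cosine $O(1/\sqrt{d})$.

With `jitter = 0` the provider becomes a pure "soft identity" embedder
(equal letters cosine exactly 1), useful for hand-checkable examples. A
trained transformer adapter can be plugged in as
`embedder_config(provider = "custom", fun = ...)`; the embedding dimension
is whatever the provider reports rather than a hard-coded model width.
`dim = 64` is the fixture default: small enough for fast tests, large
enough that background cosines concentrate well away from the planted
signal.

## What the synthetic fixtures emulate — and what they do not

`generate_unrelated_pair()` draws residues uniformly and embeddings i.i.d.
on the unit sphere: the background hypothesis of no correspondence
(expected cosine 0). `generate_homologous_pair()` plants one or more
co-linear blocks in which subject embeddings are spherical interpolations
of the query's at a controlled cosine (default 0.97) — if $u$ is the query
vector and $v$ a random unit vector orthogonal to it, the subject vector is
$\cos\theta\, u + \sin\theta\, v$ with $\cos\theta$ the target — and block
residues are copied so identity-based rescue is exercised.
`generate_annotation_db()` assembles a labelled subject set with planted
query homologies, optionally adding *pooled decoys*: subjects whose residue
vectors all hug the query's pooled direction, giving them a near-perfect
pooled cosine but no diagonal structure. Decoys reproduce the failure mode
of mean pooling — small homologous regions drowned by averaging — which is
exactly what the two-stage KNN escalation (k = 5, then 15) is for.

Passing tests on these fixtures show the *algorithmic* properties: exact
retrieval, correct classification and filtering, optimal chaining, planted
signal recovered, background rejected. They do not show that any particular
language model separates real homologs from non-homologs: real embeddings
are anisotropic, have position-dependent correlation structure along a
sequence, and produce many reciprocal-argmax matches between unrelated
proteins. On isotropic backgrounds the expected number of pre-filter mutual
matches between length-$n$ and length-$m$ sequences is about
$nm/(n+m-1)$ — order 200 for a 392-residue pair — of which essentially none
survive diagonal filtering; with real models the surviving count on
dissimilar pairs is small but nonzero. Claims about real-data sensitivity
require real embeddings and a curated database, which are out of scope here.

## The null model

The chance of a gap-free run of $k$ matches in an $n \times n$ similarity
matrix combines a window count with a per-cell match probability. The number
of length-$k$ diagonal windows is

$$S = (n - k + 1) + 2 \sum_{i=k}^{n-1} (i - k + 1),$$

verified in the tests against literal enumeration of every diagonal for all
$n \le 40$, and the run probability is

$$P(k \mid p, n) = \frac{S}{\binom{n^2}{k}}\, p^k,$$

computed in log space (`lchoose`) because $\binom{n^2}{k}$ overflows double
precision at realistic lengths. At $n = 400$, $k = 3$ the formula gives
$S = 158404$ and $\binom{160000}{3} \approx 6.83 \times 10^{14}$; published
values for this configuration differ ($S = 158968$,
$C \approx 5.37 \times 10^{18}$) and do not satisfy the formula as printed,
so this package evaluates the formula and documents the discrepancy rather
than adopting the constants. `estimate_p()` estimates $p$ as classified
(pre-filter) matches per matrix cell, the quantity that enters $p^k$; the
filtered survivor count is reported alongside as a companion statistic. The
square-matrix derivation is the reference; rectangular inputs are handled by
the alignment itself, not by the null model.

```{r nullmodel}
run_probability(400, 3, 1.1e-5)
```

## Numerical choices and degenerate inputs

* Cosines are clamped to $[-1, 1]$ after the matrix product to absorb
  floating-point excursions; chain scores are compared at $10^{-9}$.
* The optimal chain may not be unique under exact score ties; the DP's
  deterministic scan order fixes one representative, and only the score is
  contractual.
* If every candidate chain has negative total similarity the empty chain
  (score 0) is returned.
* Zero-norm vectors are rejected at index build, search and similarity
  time; empty indices are searchable and return no hits.
* Overlong sequences (`> max_len`) are rejected, mirroring the discard
  policy of fixed-context transformer embedding; `truncate = TRUE` is an
  explicit opt-in.
* Batch annotation never aborts: per-query errors land in an `error`
  column.

## Problem sizes used in the shipped checks

Verification runs at deliberately modest scale: null specificity over 200
seeded background pairs of length 100; planted-block recovery over 50
fixtures (blocks of 20–40 residues, $d = 64$); chain optimality against
exhaustive $2^M$ subset enumeration for $M \le 15$; KNN exactness against a
full cosine sort for databases up to $N = 1000$. These sizes give stable
pass/fail behaviour at sub-minute runtimes; all scale linearly upward.

## Worked example

```{r example}
fx <- generate_homologous_pair(
  100, 100, blocks = data.frame(q_start = 31, offset = 5, length = 30),
  seed = 42)
res <- soft_align(fx$q, fx$s, E_q = fx$E_q, E_s = fx$E_s)
res
cat(render_alignment(res, fx$q, fx$s))
```

## Known limitations

* No affine gap model: a long homology split across distant diagonals is
  chained only if each piece independently survives filtering.
* The significance threshold is a fixed score, not a length-corrected
  statistic; very long sequences accumulate more chance score than short
  ones (the null simulation makes this measurable via
  `simulate_null_scores()`).
* Secondary matches are not deduplicated across rows/columns; all pairs
  meeting the definition are kept.
* Multi-label truth (keyword sets) is not supported by `evaluate_calls()`;
  it scores single-category truth only.
* The pooled baseline's distance threshold is exposed as a plain cosine
  bound (`pooled_threshold`, default off).
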