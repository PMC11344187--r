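---
title: "Measuring vaccine-stance echo chambers in multilayer forum networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring vaccine-stance echo chambers in multilayer forum networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stancenet)
```

## The model

`stancenet` analyzes stance-segregated discussion on a PTT-style bulletin
board, where every post (board) carries a vaccine-stance label —
provaccination (P), vaccine hesitant (H) or antivaccination (A) — and every
comment carries one of three reaction marks: 推 (like), 噓 (boo) or →
(neutral). The analysis object is a directed, weighted multilayer network

$$M = \{G^P, G^H, G^A\}, \qquad G^l = (V^l, E^l),$$

over one shared user namespace: a node is a user, an edge is a comment
directed commenter → author (so an author's indegree counts attention
received), and the three layers partition the comments by the stance they
express. Each comment becomes one edge record via the flattening rule:

* a **like** or **neutral** comment joins the post's own layer, with weight
  2 (like) or 1 (neutral);
* a **boo** (weight 0.2) is reassigned to the opposing camp: a boo on a P
  post goes to layer A; a boo on an A post is ambiguous between P and H and
  is assigned uniformly at random; a boo on an H post is, by symmetry,
  assigned uniformly between P and A.

The boo-on-H case is a design choice: the deterministic opposing-camp rule
and the two-way random tie-break are both defined for the other post
stances, and mirroring the A-post rule is the least additional assumption.
Neutral comments joining the post's own layer generalizes the stated
treatment of neutral comments on provaccination posts to all three layers.
Self-comments (an author commenting on their own post) are excluded by
default (`include_self = FALSE`), since a self-loop would inflate both
degree directions of one node; the flag restores them.

The weights 2/1/0.2 express graded affinity and are stored on every
aggregated edge, but none of the degree metrics use them: all degrees are
counts of **distinct neighbors**, matching the $d^l(v) = |N^l(v)|$
definitions. Parallel comments between the same ordered pair collapse into
one edge carrying the summed weight and a comment count, so degree metrics
are automatically neighbor-set sizes. Weighted variants can be built from
the stored `weight`/`count` columns.

Time enters through cumulative snapshots: the network restricted to records
with time $\le t_n$, evaluated on a calendar-month grid
(`month_grid()`). Snapshots only accumulate, so every node and edge of an
earlier snapshot is present in every later one, and the final snapshot is
exactly the static network; `metric_series()` exploits this to trace any
metric over time.

## The chambering metrics

For a node $v$, direction $\mathrm{in}$ or $\mathrm{out}$, and layer $l$:

* `layer_degree()` — $d^l(v)$, distinct in-/out-neighbors within layer $l$;
* `cross_degree()` — $d^M(v)$, the size of the union of the per-layer
  neighbor sets across all three layers (a neighbor met in two layers
  counts once), always satisfying
  $\max_l d^l(v) \le d^M(v) \le \sum_l d^l(v)$;
* `layer_diversity()` — the mean of $d^M(v)$ over $v \in V^l$: how broadly
  a layer's members engage across the whole network;
* `spearman_pair()` — the Spearman rank correlation between the two
  within-layer degree vectors of the nodes common to a pair of layers
  (average ranks for ties). High values mean the same users dominate both
  layers; a low P–A value is the polarization signature;
* `layer_overlap()` — the percentage of shared nodes between two layers.
  The denominator is the union (Jaccard × 100) by default; the smaller
  layer or a single layer can be chosen instead, since no single convention
  is universal;
* `node_entropy()` — with $p(l)_v$ the share of $v$'s connections (in plus
  out) in layer $l$, $H_v = -\sum_l p(l)_v \ln p(l)_v$. Natural logarithm:
  only the ordering and the endpoints matter downstream, and those are
  base-invariant. $H_v = 0$ iff $v$ is single-layer; the maximum is
  $\ln 3$. Connections are counted as distinct neighbors by default;
  `basis = "comments"` switches to raw comment multiplicities;
* `select_hardliners()` — the $k = 30$ lowest-entropy nodes of a layer
  among those with at least `min_activity = 10` total connections. The
  floor matters: without it, every one-comment user ties at entropy 0 and
  the selection is meaningless. Ties break toward higher within-layer
  degree, then node id;
* `select_diverse()` — the top $k = 50$ nodes by $d^M_{in} + d^M_{out}$,
  ties toward higher entropy. The sum is used because both facets —
  receiving and giving across stances — define a spanner;
* `layer_proportions()` — for a node set, the per-layer share (in %) of its
  summed within-layer degrees; the three values sum to 100;
* `hardliner_degrees()` — the mean over a layer's hardliners of
  within-layer degree divided by the layer's mean degree in the same
  direction. "Standardized" is implemented as this ratio to the layer mean:
  a value above 1 reads directly as "more active inside the layer than the
  average member". (Division by the layer mean is one of several plausible
  standardizations; it is the one documented and tested here.)

Statistics that are undefined on a given input — an empty layer, fewer than
two common nodes, zero-variance degree vectors, an isolated node — return
`NA` with an audit message, never a silent 0.

## Degree distributions

`fit_power_law()` estimates the tail exponent of $p(d) \propto d^{-\delta}$
by discrete maximum likelihood with the lower cutoff $x_{\min}$ selected by
Kolmogorov–Smirnov distance minimization (the plfit procedure, via
`igraph::fit_power_law()`). The goodness-of-fit p-value comes from a
semi-parametric bootstrap: replicates draw tail values from the fitted
model and body values from the empirical below-cutoff data, are refitted
(including the cutoff search), and the p-value is the fraction with a KS
distance at least the observed one — so a small p-value signals deviation
from power-law behavior. Two numerical caveats are built into the tests:
the free cutoff search can evade rejection of a non-power-law sample by
retreating into the extreme tail (where almost anything fits), so the
exponential-tail rejection check pins $x_{\min} = 1$; and the discrete
sampler `rpower_discrete()` uses an exact probability-table inversion for
exponents $\ge 1.5$ but switches to the rounded continuous approximation
for heavier tails, where no practical truncation point exists.

## The synthetic forum generator

No public corpus of the studied forum exists, so validation runs on
generated corpora with known ground truth (`forum_config()`,
`generate_forum()`). The generator emulates the structural features the
analysis depends on:

* latent stances in the proportions 1283 : 1322 : 387 (P : H : A), the
  observed post split of the studied network, so synthetic ensembles are
  structurally comparable;
* per-user comment counts drawn from a discrete power law (default
  exponent 2.3, the value the layer degree distributions exhibit);
* a **chambering** probability: each background user's comment targets a
  post of their own stance with probability `chambering` (default 0.6, a
  moderate segregation level), otherwise one of the other two stances
  uniformly;
* **hardliner** users (default 5%) who only comment within their own
  stance, and **spanner** users (default 5%) who comment uniformly across
  stances;
* preferential attachment of comments to posts within the chosen stance
  (probability ∝ 1 + comments received so far), which reproduces the
  heavy-tailed indegrees;
* 24 monthly periods (January 2021 – December 2022) with burst months at
  periods 11 and 14 (November 2021 and February 2022, the observed surges)
  at doubled posting intensity; timestamps are uniform within a period and
  comments never precede their post.

The generator does **not** model comment text, reply trees, user churn, or
any feedback between network position and stance change. Passing tests on
synthetic corpora therefore certify the measurement pipeline — that the
metrics recover known segregation structure — not any claim about real
forum behavior.

Everything is reproducible: one root seed in the config is split into named
streams (users, corpus, boo reassignment, bootstrap), so the same config
yields a byte-identical corpus and report.

## Bootstrap design and its limits

Board classification is the dominant source of uncertainty, so
`bootstrap_metric()` resamples **boards** (posts with all their comments)
with replacement, holding the retained count fixed, rebuilds the network
per replicate and recomputes the metric; summaries report the full-data
estimate, the bootstrap mean and the percentile 2.5/97.5 interval,
formatted as `mean (low-high)`. The boo-reassignment layer of each comment
is flattened once and held fixed across replicates, so the bootstrap
isolates board-composition variability. Replicates in which the metric is
undefined in more than half the draws are flagged rather than averaged
away.

One statistical limitation is documented deliberately: for size-dependent
statistics such as the mean total degree ($2 e / v$), the board-cluster
bootstrap is biased whenever many users touch only a single board —
resampling then shrinks the distinct-node set while preserving the comment
mass, inflating the replicate values. The bias disappears for corpora of
recurrent commenters whose per-layer presence is stable under resampling.
The package's consistency and coverage studies therefore use
recurrent-commenter populations (`activity_min` raised so every user
comments across many boards, balanced layers), under which the percentile
interval attains its nominal coverage; on sparse, single-comment-heavy
corpora the percentile interval for mean degree should be interpreted
cautiously. `activity_min` defaults to 1 — realistic corpora are sparse —
and is raised only where the cluster bootstrap's own validity conditions
require it.

## Validation problem sizes

The shipped checks use these sizes, chosen as the smallest at which each
property is statistically sharp: brute-force oracle equivalence on 100
random multilayers of at most 12 nodes; power-law recovery within ±0.15 on
5000-draw samples across 10 seeds; chambering recovery (mean entropy
decreasing, hardliner within-layer share increasing, P–A outdegree
Spearman decreasing over chambering 0.34 → 0.6 → 0.9) on corpora of 2000
users and 600 posts, averaged over 2 seeds; bootstrap coverage on 200
corpora resampled from a 150-board recurrent-commenter population with 200
replicates each; and generator → thread-text → parser round-trip identity
on 50 random corpora.

## Thread-text dialect and anonymization

The forum's web layout is not a machine format, so the package defines a
plain-text dialect (documented at `emit_threads()`): a header block
(board id, author, time, title, label) and one tab-separated line per
comment, `MARK user time text`, with comment text wrapped at 39 characters
per line — the forum's own line limit — and continuation lines marked by a
leading tab. `parse_threads()` inverts it exactly; malformed lines are
skipped, counted and reported, not fatal, since scraped bulletin-board text
is noisy. `anonymize()` replaces each distinct username with a distinct
6-character alphanumeric token, injectively and seed-deterministically,
mirroring the de-identification step such scraped data requires. Keyword
filtering (`filter_vaccine_boards()`, default keyword 疫苗) searches titles
and comment text, since limiting it to titles alone would silently drop
boards whose stance lives in the discussion.

## Known limitations

* The entropy's connection counts, the diverse-node ranking key, the
  hardliner standardization and the overlap denominator each admit
  alternative conventions; the implemented choices are stated above and
  the alternatives are exposed as arguments where they change results.
* Percentile (not bias-corrected) bootstrap intervals; see the bias
  discussion above.
* The monthly grid assumes calendar-month boundaries in the corpus's local
  time; no time-zone arithmetic is applied.
* Degree-based influence only: no centrality beyond degrees, no community
  detection, no inter-layer coupling edges.
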