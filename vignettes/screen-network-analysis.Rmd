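---
title: "Methods: from batch-standardised screen scores to phenotype sub-networks"
author: "ovanet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from batch-standardised screen scores to phenotype sub-networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovanet)
```

# The analysis in one paragraph

A quantitative RNAi screen scores hundreds of gene knockdowns for two
reproductive phenotypes — egg laying (vial totals over five scored days,
three females per vial) and ovariole number (20 ovaries per gene, each ovary
an independent measurement) — against batch-matched controls. ovanet
standardises each gene against its own batch's controls, calls hits by
strict Z thresholds, and then treats the hit lists as *seed genes* on a
protein-protein interaction network (PIN): it asks whether seeds are more
interconnected than chance (modularity against resampled nulls), grows each
seed list into a sub-network with a greedy Seed Connector Algorithm that
recruits untested *connector* genes, and finally partitions the union of
sub-networks into the seven phenotype-signature groups of a three-screen
Venn diagram, testing inter-group connectivity by label permutation.

# Batch standardisation and hit calling

Batches have their own control distribution (batch drift is real in
multi-week screens), so raw means are not comparable across batches. For a
gene in batch $b$,

$$Z_\mathrm{gene} = \frac{x_\mathrm{gene} - \mu_b}{\sigma_b},$$

with $\mu_b, \sigma_b$ the mean and standard deviation of the pooled
control *measurement units* of that batch: vial five-day totals for egg
laying, single-ovary counts for ovarioles.

Choices a reader should know about:

* $\sigma_b$ uses the sample ($n-1$) denominator. Control groups are small
  (five vials), so the unbiased estimator is the defensible default.
* The egg-laying $x_\mathrm{gene}$ is the single candidate vial's five-day
  total (the screen runs one vial per gene); vials in which a fly died are
  excluded outright, never zero-filled, and a gene whose only vial is
  excluded drops out of that screen with a message.
* The ovariole $x_\mathrm{gene}$ is the **mean** of the gene's 20 ovary
  counts, standardised against the pooled per-ovary control counts (40 per
  batch). Treating each ovary as an observation but reporting one Z per
  gene admits two readings (mean of ovaries, or each ovary scored
  separately); the mean is the default here because downstream stages need
  exactly one score per gene. A consequence worth stating: because
  $\sigma_b$ is a per-ovary spread while $x$ is a mean of 20, null ovariole
  Z scores are tightly concentrated (spread $\approx \sqrt{1/20 + 1/40}$),
  which is why the ovariole screen tolerates the lower threshold of 2.
* Thresholds are strict inequalities on both sides; $|Z|$ exactly at the
  threshold is called `none`. Defaults: primary filter $|Z|>1$ (sensitised
  egg screen only), egg calls $|Z|>5$, ovariole calls $|Z|>2$.
* With five control vials, $\sigma_b$ carries only four degrees of freedom,
  so single-egg-screen Z values are noncentral-t distributed rather than
  normal. Detection of a "strong" effect of 8 control sd in *one* egg
  screen is therefore expected near, not at, ceiling; the package's
  recovery checks count a gene as detected when it passes threshold in at
  least one of the screens that measure the affected phenotype, which is
  also how positive candidates are counted across screens in practice.

# Network assembly and centralities

The PIN is the union of any number of two-column interaction tables:
self-pairs removed, direction collapsed, duplicates merged, per-edge source
provenance retained. Density is $2E/(N(N-1))$ (0 by convention for
$N \le 1$). Because density depends only on the counts,
`edgeDensityFromCounts()` reproduces a published density from published
$N$ and $E$ without the underlying tables.

The four centralities and their conventions on a possibly disconnected
graph:

* **degree**: $\deg(v)/(N-1)$.
* **betweenness**: endpoints excluded, normalised by $(N-1)(N-2)/2$
  (igraph's normalised undirected betweenness).
* **closeness**: reachable-set closeness with Wasserman–Faust scaling,
  $\frac{r}{N-1}\cdot\frac{r}{\sum d}$ for a node reaching $r$ others at
  total distance $\sum d$; isolated nodes score 0. This keeps the metric
  defined for every node of a disconnected PIN and comparable across
  components.
* **eigenvector**: leading adjacency eigenvector by power iteration on
  $A+I$ (the shift makes the dominant eigenvalue strictly positive, so the
  iteration cannot oscillate on bipartite graphs and converges on every
  graph with an edge), tolerance $10^{-10}$ on the max component change,
  at most 1000 iterations (exceeding them is an error naming the metric),
  result L2-normalised. Nodes outside the dominant component legitimately
  receive values near zero.

Centrality-versus-outcome prediction uses the rank (Mann–Whitney) form of
the ROC AUC with half credit for ties — ties are common in degree
centrality, so tie handling is part of the definition, not a corner case.

# Resampling machinery

**Pathway enrichment** reports both a Monte-Carlo Z (observed pathway
overlap vs. the null of drawing the same number of genes uniformly without
replacement from the reference pool, default 10,000 draws) and the
inclusive hypergeometric tail $P(X \ge M)$, plus fold enrichment
$(M/n)/(K/N)$. The pool is a parameter because two pools are legitimate:
all screened signalling genes, or the post-primary-filter subset. No
multiple-testing correction is applied to the primary p-values; a
Benjamini–Hochberg column is emitted alongside for transparency. A pathway
whose null has zero variance (e.g. the whole pool) gets an explicit
undefined Z, not a zero.

**Degree-controlled nulls** bin nodes by degree from lowest to highest,
closing a bin once it holds `minSize` nodes (default 100 at interactome
scale; tests use smaller bins on smaller graphs) and merging a trailing
under-full bin backwards so bins always partition the nodes. A
degree-matched draw samples, per bin, exactly as many genes as the target
set has there — the binned degree histogram is reproduced exactly on every
draw, which the tests assert as a hard property, not statistically.
Sampled genes may coincide with the target by default (an exclusion switch
exists) since excluding them would bias high-degree bins on small graphs.

**Metric nulls and modularity.** Sub-network metrics are evaluated on each
resampled gene set. Samples where the average shortest path is undefined
(LCC < 2) are excluded from that metric's null with the exclusion count
kept — zero-filling would bias the null downwards. The modularity verdict
is reported as four booleans (LCC, edges, density above the null mean;
average shortest path below), never collapsed into one scalar, because the
four metrics can genuinely disagree.

# The Seed Connector Algorithm

Greedy growth from the retained seeds (seeds absent from the PIN are
dropped with a warning and recorded): each iteration evaluates every gene
adjacent to the **current LCC** (not to all members), recomputing LCC and
seed coverage with that gene added; the accepted candidate must strictly
increase coverage, preferring maximal coverage, then minimal LCC node
count, then smallest gene identifier. The loop ends when no candidate
increases coverage. Coverage is integer, strictly increasing and bounded
by the seed count, so termination is guaranteed; the tie rules make reruns
bit-identical.

Deliberate consequences of this reading:

* A candidate that merges components without changing seed coverage is
  *not* added, even though it "tidies" the module.
* When two same-size components tie for LCC, the one whose
  lexicographically smallest member sorts first wins. Published connector
  counts from any specific study need not be reproduced exactly wherever
  the original tie-breaking differed.
* One connector per iteration; no batched additions.
* The greedy neighbourhood search can miss a single node that would join
  two *non-largest* seed components — by construction it only scans the
  LCC's neighbourhood. The test suite therefore asserts exhaustive-search
  optimality exactly on the instance class where it must hold (a single
  connector able to join all seed components is necessarily adjacent to
  the LCC), and upper-bounds greedy coverage by the best enumerated
  addition sequence elsewhere.

# Meta-network grouping

Every meta-network gene carries a three-flag phenotype signature. Seeds
take their screen positivity; connectors inherit the signature of the
sub-network(s) that predicted them (union if several; the core sub-network
carries all three flags); a gene that is both seed and connector combines
the two sources and keeps the seed role. The seven non-empty Venn regions
map to groups as: I = sensitised egg laying only, II = egg laying only,
III = sensitised ovariole only, IV = all three, V = sensitised egg +
ovariole, VI = egg laying + ovariole, VII = both egg-laying screens. The
anchors for this mapping are the fixed points any such table must satisfy
(core = IV; the ovariole/egg-laying dual region = VI; a gene that is an
egg-laying seed and a sensitised-egg connector = VII); the remaining
labels are then forced up to the obvious symmetry.

Edge densities use $E_{gh}/(n_g n_h)$ between groups and
$E_{gg}/\binom{n_g}{2}$ within (the between-group formula does not cover
the diagonal; the simple-graph denominator is the standard completion).
Empty-group pairs and size-1 diagonals are explicit `NA`s, never 0. The
permutation null reassigns the grouped genes to groups of the observed
sizes (default 1000 permutations); both seed-only and seed+connector
groupings are supported, and seeds keep identical groups in either mode.

# The synthetic-data generator

`synthConfig()` defaults encode the study design this package targets:
463 candidate genes in batches of ~50; five control vials (three females
each) per batch for egg laying; 20 control flies / 40 ovaries per batch and
20 ovaries per candidate for ovariole number; thresholds 1/5/2; a 2% vial
death rate to exercise the exclusion rule. Noise models: per-day egg counts
are negative-binomial (mean 60 eggs/vial/day, dispersion 10 — counts must
be integer and over-dispersed; dispersion `Inf` degrades to Poisson), with
a per-batch drift of the control mean (sd 10% of the daily mean) that the
standardisation must remove; ovariole counts are rounded Gaussians
truncated at 0 (mean 20, sd 2.5, batch drift 0.5 sd). True effects are
expressed in control-sd units of the phenotype's measurement unit, so
recovery targets are scale-free; the default plants a −8 sd effect on both
phenotypes for the module genes, matching the predominance of
loss-of-function hits in this kind of screen.

The planted interactome: hit genes form dense modules (sizes 15/12/10,
within-density 0.8, generated connected via a spanning path), consecutive
modules are chained by planted connector hubs (three attachments into each
of their two modules), and everything else is sparse background (density
0.004). Two suppressions keep the ground truth crisp, and both follow from
the definition of a planted connector as a node adjacent to two *otherwise
separate* clusters: background edges directly joining two modules are
dropped, and a background node may touch members of at most one module.
Without the second rule a lucky background gene adjacent to several
modules is a genuinely better connector than the planted hub — the
algorithm would be right to prefer it, and "recovery" would be testing the
background lottery rather than the method.

What the generator does **not** emulate: scale-free interactome topology
(only the degree heterogeneity needed to exercise degree bins),
correlation between a gene's centrality and its phenotype beyond what the
planted modules induce, hit effects that differ between the two egg-laying
screens (no sensitised-background biology), day-to-day egg-laying
dynamics, and per-fly correlation between the two ovaries. Passing
recovery tests therefore demonstrates correctness of the machinery under a
known generative model, not biological validity on real screens.

# Problem sizes and reproducibility

The test suite runs on deliberately small instances: 120-gene screens with
three planted modules for recovery properties, a 500-node PIN with a
20-gene planted module (within-density 0.5 over background 0.02) and
1000-draw nulls for the modularity check, exhaustive SCA oracles on 8–12
node graphs, 10,000-draw enrichment nulls against exact hypergeometric
moments, and 1000 degree-matched draws for the exact bin-histogram
property. The full suite and the acceptance script each complete in well
under the time a coffee takes. All stochastic stages consume explicit
seeds; the pipeline derives one substream per stage from the run seed, so
stages reproduce independently of execution order, and reruns with the
same configuration produce byte-identical outputs (asserted via manifest
digests).

# Known limitations

* Greedy SCA is a heuristic, not an exact Steiner solver; weighted or
  confidence-scored edges are out of scope.
* The closeness/eigenvector conventions on disconnected graphs are
  package choices (documented above); other implementations differ, and
  numeric centralities — though not usually their rank order — will differ
  with them.
* The ovariole aggregation (mean of 20) and the exact correlation
  statistic for egg-laying-versus-ovariole comparisons
  (`phenotypeCorrelation`, Pearson by default with Spearman and a
  permutation p as options) are configurable precisely because the
  "right" choice is under-determined.
* Group labels V–VII of the meta network rest on the anchored mapping
  described above; relabelling those three regions permutes rows of the
  outputs but changes no statistic.
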