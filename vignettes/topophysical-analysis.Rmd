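---
title: "Topophysical analysis of spatially embedded networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topophysical analysis of spatially embedded networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netrent)
```

## The model

Information-processing networks — neuronal connectomes, parcellated brain
networks, integrated circuits — live in two places at once: an abstract
interconnect *topology*, and a 2- or 3-dimensional *physical* embedding with
real wiring lengths. `netrent` quantifies both sides and their interplay
through Rent's rule, the empirical power law

$$ e = k\,n^{p}, $$

relating the number of nodes $n$ inside a block to the number of
connections $e$ crossing the block boundary. Everything in the package
derives from measuring this law in two ways:

* **Topological Rent exponent** $p_T$: blocks are graph partitions obtained
  by recursive balanced min-cut bisection. $p_T$ measures the intrinsic
  dimensionality of the interconnect through the fractal topological
  dimension $D_T = 1/(1-p_T)$; a $D$-dimensional lattice has
  $p_T = 1 - 1/D$ exactly, while long-range, hierarchically organised
  wiring pushes $D_T$ above the embedding dimension $D_E$.
* **Physical Rent exponent** $p$: blocks are axis-aligned boxes placed at
  random in the coordinate space. $p$ measures how the *placement* of nodes
  distributes wiring across scales. Its theoretical minimum over all
  placements of a fixed topology is
  $p_{\min} = \max(p_T,\, 1 - 1/D_E)$: no embedding can beat the intrinsic
  exponent, nor the $1 - 1/D_E$ floor set by the surface-to-volume ratio of
  regions of Euclidean space ($1/2$ in 2-D, $2/3$ in 3-D). An observed $p$
  close to $p_{\min}$ diagnoses a cost-efficient embedding.

Wiring economy is summarised by the node-to-node spacing $\delta$ (the mean
nearest-neighbour Euclidean distance, a degree-1 homogeneous length scale),
the dimensionless mean connection distance $\bar L$ (mean edge length over
$\delta$), and the cost-efficiency coefficient

$$ \kappa = \bar L \,/\, N^{1/D_E - 1/D_T}, \qquad D_T > D_E, $$

which inverts the expected-wiring relation for a cost-efficiently embedded
network of $N$ nodes; $\kappa$ near unity indicates the observed wiring
length is close to the efficient optimum for that topology. The
denominator is the standard VLSI-theoretic scaling of mean connection
distance (in spacing units) for a $D_T$-dimensional topology packed into
$D_E$ dimensions; it is only defined in the supra-Euclidean regime
$D_T > D_E$, and the package reports `NA` otherwise. Because real
anatomical distances are straight-line distances between region centroids,
$\bar L$ underestimates true tract lengths; all comparisons in the package
are therefore *relative* (observed vs rewired variants), and the raw mean
edge length is reported alongside the normalised $\bar L$ so that variant
comparisons never depend on the $\delta$ normalisation.

Finally, a sphere-approximation argument connects the physical Rent
exponent of a single species' cortical network to the cross-species
allometric scaling $V_w \propto V_g^{\,a}$ of white- to gray-matter volume:
the white-matter cross-section scales as $V_w^{2/3}$, and with constant
synaptic density ($e \propto$ area) and constant processing-element density
($n \propto V_g$), Rent's rule forces $a = \tfrac{3}{2}p$. The conversion
functions treat those two densities as exact constants; they cancel in the
exponent relation and never enter numerically. White-matter dilation is
ignored, a deliberate approximation whose contribution is small over the
mammalian range.

## Estimation choices

**Bisection.** Balanced min-cut bisection is NP-complete; the package uses
Fiduccia–Mattheyses refinement (gain-driven single-node moves with
rollback to the best prefix) from 10 random balanced starts, implemented in
C++ and deterministic under a seed. The balance window is
$||A|-|B|| \le \max(1, 0.1\,n)$; moves may overshoot the window by one node
during a pass, but only in-window states are accepted. On graphs small
enough for exhaustive search the refinement attains the exact optimum (the
test suite checks this), and on lattices it finds the straight cuts.

**Boundary counting and Region I.** For each partition the boundary count
`e` is, by default, the number of edges cut by the bisection that created
it — the partition's boundary *within its parent block*. The alternative
(`boundary = "network"`) counts all edges of the whole network leaving the
partition, i.e. the block's total terminal count. The parent-relative
default is a calibration choice: on a finite $L \times L$ lattice the
whole-network level means follow $e = 4\sqrt{n}\,(1 - \sqrt{n}/L)$, so the
largest blocks saturate (there is nothing beyond the network's own
boundary) and the fitted slope is biased below $1 - 1/D$ at any feasible
lattice size; parent-relative cuts reproduce the known lattice exponents at
every level. Correspondingly, the Region II exclusion (`exclude_top`)
defaults to 2 levels under whole-network counting — where the saturation
lives — and to 0 under parent-relative counting, where no saturation
occurs. The topological fit is a weighted regression of
$\log \bar e$ on $\log \bar n$ across levels, weighted by the number of
partitions per level.

**Box sampling.** 5000 boxes (square or cubic) are placed fully inside the
coordinate bounding volume; side lengths are uniform between the 5th
percentile of nearest-neighbour distances (below which boxes are mostly
empty) and the full extent, clipped per axis. Boxes are half-open — a node
exactly on a face belongs to the box only from the lower side — so node
counts are well defined on gridded coordinates; empty boxes are discarded
and resampled. Boxes containing $n \ge N/2$ nodes sit in the
boundary-affected Region II and are excluded (strictly $n < N/2$, plus
$n \ge 2$, $e \ge 1$ for the log fit). The fit is iteratively reweighted
least squares with a bisquare loss (`MASS::rlm`), robust to the
heavy-tailed scatter of random box placement; at least 50 surviving boxes
are required.

**Box-counting dimension.** The independent estimator covers the network
with topological boxes of shortest-path diameter $< l_B$, greedily, placing
hard-to-box nodes (many conflicts at that scale) first, with 10 randomised
orders per scale and the minimum box count kept. The regression of
$\log N_B$ on $\log l_B$ (weights $N_B$) spans $2 \le l_B \le
\max(4, \mathrm{diam}/4)$: $l_B = 1$ is the trivial singleton covering and
scales comparable to the network extent saturate toward one box — the
covering analogue of Region II. On a 64-node chain this returns
$D \approx 1$ and on a $16 \times 16$ grid $D \approx 1.8$, consistent with
the partition-based estimate at the same size.

**Model comparison.** Power, exponential, linear and quadratic fits are
ranked by AICc computed from residuals on the untransformed scale, so
log-space fits gain no artefactual advantage; exact ties resolve in favour
of the simpler model.

**Modularity significance.** Community structure is detected with the
Louvain algorithm (resolution 1, best of several vertex-permuted runs) and
Newman–Girvan modularity $Q$. Observed $Q$ is compared against 100
pure-random surrogates (same $N$, $m$) and 100 degree-preserving surrogates
(Maslov–Sneppen double-edge swaps, 15 *accepted* swaps per edge — swaps
creating self-loops or duplicate edges are rejected and retried; graphs
with no valid swap, such as stars and triangles, are returned unchanged
with a warning). The one-tailed p-value is the upper-tail probability of
the observed $Q$ under a $t$ reference scaled by the null standard
deviation, $p = P\!\left(T_{n-1} > (Q_{\mathrm{obs}} -
\bar Q_{\mathrm{null}})/s_{\mathrm{null}}\right)$. Scaling by the null SD
(not the standard error of the null mean) is what makes the test
calibrated: a network that *is* a draw from the null is flagged at rate
$\approx \alpha$, which the test suite verifies empirically. When the null
distribution degenerates to zero variance the exceedance count
$(1 + \#\{Q_{\mathrm{null}} \ge Q_{\mathrm{obs}}\})/(n+1)$ is used and
flagged. Crucially, the observed network and every surrogate are scored by
the *identical* Louvain procedure (same number of runs), since any
asymmetry would bias the comparison; one run per network is the default,
as calibration depends on symmetry rather than on per-network optimisation
effort. Hierarchical decomposition recurses into modules passing both
tests at $\alpha = 0.05$, with nulls rebuilt to match each submodule's own
size and degree sequence; modules under 8 nodes become untested leaves
(null $Q$ distributions are too coarse below that). The tree depth counts
significant hierarchical levels: 1 for a non-modular network, 2 for flat
modules, 3 for modules-within-modules. The co-classification matrix is a
Louvain consensus (co-assignment frequency across seeded runs, all
aggregation depths weighted equally, rows ordered by average-linkage
clustering); it is a visualisation device and no quantitative claim rests
on it.

**Rewired baselines.** The pure-random baseline resamples the edge set
uniformly among simple graphs with the same $N$ and $m$, keeping every
node's position. The minimally rewired baseline keeps positions and edge
count but rewires for minimum cost: the Euclidean minimum spanning tree
(connectivity) plus the shortest remaining candidate edges in ascending
order, with distance ties broken lexicographically so the result is
deterministic; on small instances this greedy construction matches the
exhaustive minimum-total-length connected subgraph, and for networks above
5000 nodes the candidate set narrows to 50 nearest neighbours per node.
The full pipeline (`run_full_analysis`) reports observed, minimal, and the
mean over 10 random instantiations, with per-stage seeds derived by
hashing stage names off one master seed so reports regenerate bit for bit.

## What the synthetic generators emulate

The package is validated entirely against generated networks with known
ground truth, standing in for connectome data:

* `make_lattice` — regular grids, the $p_T = 1 - 1/D$, $\kappa$-undefined,
  already-minimally-wired reference point.
* `make_hierarchical_modular` — a nested stochastic block model: $N =
  b\,2^{\ell-1}$ nodes in a balanced binary hierarchy, edge probability
  given by the deepest level two nodes share, strictly increasing from
  root to leaves. Coordinates are *spatially nested*: each binary split of
  the hierarchy also bisects the current cell of the unit square/cube, so
  modules are spatially localised the way cortical modules are. This is
  deliberate — with spatially uncorrelated coordinates the observed and
  randomly rewired variants would have exchangeable edge lengths and no
  wiring-cost trade-off could exist, which would make the generator useless
  as a stand-in for anatomically embedded networks. With probabilities
  decaying geometrically from the leaves by a ratio $r$, bisection cuts
  scale as $e \propto n^{2 - \log_2 r}$, so the generator produces genuine
  fractal Rentian topologies with a tunable exponent ($r \approx 2.4$
  gives $p_T \approx 0.75$ at the cut level).
* `make_powerlaw_scatter` — exact Rent's-rule points with log-normal
  multiplicative noise, for estimator parameter-recovery experiments.

What these fixtures do *not* emulate: degree heterogeneity beyond the
block structure, weighted or directed connectivity, distance-dependent
connection probabilities within a block, and measurement noise of real
tractography or covariance networks. Passing tests therefore demonstrate
estimator correctness and calibration on networks whose ground truth is
known, not the empirical values of any particular organism's connectome.

## Problem sizes and numerical conventions

The validation experiments run at desk scale, chosen once: lattices up to
$32 \times 32$ and $8^3$; hierarchical fixtures of $N = 256$ (three
levels, probability gaps 0.25, dense enough for stable Louvain recovery)
for the modularity calibration — 20 seeds each for the nested and the
rewired-random arm — and sparse $N = 128$ fractal hierarchies (five
levels, mean degree $\approx 8$, about 5% density, matching connectome
sparsity) for the wiring trade-off; 100 seeds for parameter-recovery
coverage. Degenerate inputs follow fixed conventions rather than silent
behaviour: self-loops, inconsistent coordinate arity and unknown ids are
rejected at read time; thresholding uses strict `>` so a threshold equal
to a weight excludes the pair, while the density rule includes all ties at
the cut and reports the achieved density; disconnected networks partition
component-wise first, with a warning; all-coincident coordinates are
errors for spacing and box sampling; `p_T \ge 1` (possible on dense
non-spatial graphs, where blocks' internal structure is volume- rather
than surface-dominated) maps to an error in the dimension conversion
rather than a negative dimension.

## Limitations

Euclidean centroid distances underestimate curved tract lengths, so
$\kappa$ comparisons across systems with very different anatomy should be
read qualitatively. The minimum-cut refinement is a heuristic; on
adversarial graphs the attained cuts, and hence $p_T$, can exceed the true
minima (mitigated by restarts, and immaterial on the fixture families used
here). The hierarchical significance cascade inherits the multiplicity of
recursive testing: with $\alpha = 0.05$ per module and two one-sided tests,
occasional spurious depth on random networks is expected at the few-percent
level, which is exactly what the calibration experiments measure. Weighted
and directed networks, overlapping communities, and hypergraph (multi-pin
net) treatments of circuit netlists are out of scope; circuits are analysed
as simple graphs for comparability with biological networks.
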