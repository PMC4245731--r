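---
title: "Detecting and characterizing enzyme access channels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing enzyme access channels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Many enzymes bury their active sites and connect them to the surrounding
solvent through one or more access channels. `chanatomy` detects such
channels in protein structures, measures their geometry (length, radius
profile, bottleneck, local narrowings), scores their walls
physico-chemically (hydropathy, polarity, charge), and aggregates cohorts of
structures into occurrence tables and amino-acid propensity tables. This
vignette explains the model, its parameters, the numerical choices, and what
the synthetic benchmark does and does not demonstrate.

## The void model

All computations happen on the *void graph* of a structure. The atoms
(heavy atoms of the biological assembly, with Bondi van der Waals radii
assigned per element) are the generators of a Delaunay tetrahedralization;
each tetrahedron contributes one vertex at its circumcenter — a Voronoi
vertex of the atomic centers — and face-adjacent tetrahedra are connected by
edges. Every vertex carries its *clearance*: the distance from the vertex to
the nearest atom's van der Waals surface,
`min_i(||p - x_i|| - r_i)`. Edge clearance is the minimum clearance sampled
every 0.5 Å along the connecting segment; exact 1-D minimization gains
nothing at the 3.5–4 Å atom spacing of real structures. Edges narrower than
the **interior threshold** (1.1 Å) are pruned: a void narrower than that is
not traversable by any ligand-sized probe.

Bulk solvent is removed by an iterative probe peel in the style of alpha
shapes: a tetrahedron lying on the current outer boundary (a convex-hull
face, or a face shared with an already peeled tetrahedron) is peeled when
its clearance is at least the **probe radius** (5 Å). The peel therefore
eats bulk solvent and wide invaginations but cannot descend into any opening
narrower than the probe. Peeled vertices are *exterior*; the remaining
vertices exposed to the hull or to a peeled tetrahedron are *boundary* (the
molecular surface, where channels end); the rest are *interior*. We peel by
clearance rather than by a literal vertex-wise clearance test because on a
dense, convex packing almost no near-surface vertex clears 5 Å — a vertex-wise
rule would leave the surface without boundary vertices and tunnels without
exits.

*Burial depth* is the unweighted hop distance from an interior vertex to the
nearest boundary vertex over traversable edges (infinite for sealed voids).
*Cavities* are connected components of interior, traversable vertices that
lie at least half a probe radius away from bulk solvent, where "bulk
solvent" is the union of empty balls around exterior vertices (each such
ball, with the vertex clearance as radius, contains no atom). The
solvent-depth condition matters: directly under the surface of any packed
structure there is a thin network of shallow traversable grooves, and
without the condition that network strings every cavity in the structure
into a single component. We verified the separation on two-cavity synthetic
structures: groove vertices lie within ~1.7 Å of a solvent ball, genuine
cavity vertices tens of Å away, so the threshold is uncritical anywhere in
between and we tie it to the probe (2.5 Å at the default probe).

## Channel extraction

For an annotated active site, the start vertex is chosen near the centroid
of the site residues' heavy atoms: among traversable non-exterior vertices
within the **origin radius** (5 Å, expanded once by 1.5× if empty), we take
the vertex with the largest clearance, breaking ties by burial depth and
then proximity to the centroid. Maximizing clearance — the roomiest point of
the active-site cavity — rather than raw burial depth is a deliberate
choice: hop depth is mesh-sensitive, and on test structures a depth-first
rule reproducibly picked narrow interstitial pockets *behind* the cavity
wall, inflating channel lengths by the pocket detour and reporting the
pocket neck as a spurious bottleneck. When a structure carries several
annotated sites, the site with the most channels wins (ties: larger total
channel length, then lexicographic site id), and each assembly copy of a
site is treated as a candidate site.

Channels are shortest paths in the traversable graph under the edge weight

    w = length / (clearance^2 + 0.01)

computed with Dijkstra's algorithm from the start vertex to every boundary
vertex. The weight prefers corridors that are both short and wide; the
0.01 Å² offset merely keeps the weight finite at zero clearance. Three
reductions turn the per-exit path set into a channel set:

1. **First surface contact.** A path that passes through a boundary vertex
   before its terminal one is discarded — it is a cheaper exit's channel
   plus a crawl through near-surface void.
2. **Surface cover.** Exits within the **surface cover radius** (10 Å) of a
   kept, cheaper exit are merged away, and — after the solvent trim below —
   a channel whose endpoint lands within that radius of a kept channel's
   endpoint is also dropped. The second form is needed because a wide mouth
   offers several vertex-disjoint corridors to boundary vertices more than
   10 Å apart that are nevertheless the same channel.
3. **Duplicate paths.** A channel sharing more than the **cutoff ratio**
   (0.7) of its vertices with a kept channel is dropped.

Each surviving path is measured (centerline = vertex positions, radius =
vertex clearance, length = polyline length) and trimmed at the solvent: the
trailing centerline points that lie inside an exterior vertex's empty ball
belong to bulk solvent, so the channel ends where it meets the solvent
rather than at the outermost unpeeled vertex of the mouth vestibule. Without
the trim, measured lengths overshoot planted ground truth by 5–9 Å on wide
mouths; with it they agree to a mean absolute error below 2 Å. Channels sustaining a radius below
the **bottleneck radius** (1.25 Å) over more than the **bottleneck length**
(3 Å) of arc are discarded as non-traversable. Channels shorter than the
**report length** (15 Å) are flagged sub-threshold and retained, so that
occurrence can be counted at 5/10/15/20 Å from one run. No centerline
smoothing is applied by default (a 3-point moving average exists but is
off), because reported lengths depend on it.

The four parameters that the detection setup leaves at customary defaults —
bottleneck radius 1.25 Å, bottleneck length 3 Å, cutoff ratio 0.7, surface
cover radius 10 Å — are config-overridable (`channel_params()`,
`read_run_config()`).

## Anatomy and physico-chemistry

The *bottleneck* is the global minimum of the radius profile (first index on
ties); *local minima* are interior profile points smaller than both
neighbours, with a plateau reporting its first index. A residue *lines* the
channel if one of its atoms comes within
`radius_i + vdw(atom) + contact_tolerance` of a centerline point `i`; the
default contact tolerance of 1 Å admits atoms just beyond the probe surface
that still shape the wall. A lining residue's weight is the fraction of the
channel's arc length whose centerline points it touches. Layers follow the
Euclidean rule: a residue whose closest touched centerline point lies within
the **layer distance** (5 Å) of the channel start is *internal*, within 5 Å
of the end *external*, otherwise *middle*; a residue in range of both zones
is internal (start precedence). Euclidean rather than along-path distance is
used deliberately — it matches the plain reading of "within 5 Å of the
start or end point" — and flagged as a sensitivity point.

Physico-chemical summaries are length-weighted means,
`sum(w_i v(aa_i)) / sum(w_i)`, of the Kyte–Doolittle hydropathy and
Zimmerman polarity scales; normalization (rather than a raw weighted sum) is
forced by the fact that published per-class values sit inside the
per-residue scale range. The scale tables ship as a CSV resource and are
anchor-checked at load time (Arg −4.5 to Ile +4.5; charged residues'
polarity in 49.5–52.0; all others below ~3.5 — the Zimmerman value for Gln
is 3.53, so the check allows 3.55). The charge census counts side-chain
instances unweighted (positive: Arg, Lys, His; negative: Asp, Glu); the
reported Δ is the per-channel net charge, and its cohort value the median
over channels.

## Cohort statistics

Per EC class and for the pooled cohort, `summarize_cohort()` reports the
mean atom count Na, the percentage P of enzymes with at least one qualifying
channel (all analyzed structures in the denominator, including failed
detections), the median channel count M and median channel length L over
enzymes that have channels, enzyme counts at the 5/10/15/20 Å thresholds,
pooled channel-level hydropathy/polarity with standard errors, the Spearman
rank correlation between Na and channel count, and a top-10 extremes report
in both hydropathy directions. Means are emitted alongside the medians.

Amino-acid frequencies pool residue *instances* across the cohort (a
per-structure-average mode exists behind a flag); a propensity is the ratio
of a region's frequency to the whole-structure background frequency, with
zero-background entries flagged undefined rather than dropped. Region tables
cover the channel wall, the bottleneck-touching residues, the three layers,
and generic (cavity-to-surface) versus active-site channels. The
surface/interior compartment split uses Shrake–Rupley accessible surface
area (probe 1.4 Å, 960 deterministic golden-spiral points per atom),
relative to Gly-X-Gly reference areas, surface at ≥ 25% relative
accessibility; this is the standard convention, chosen because the original
survey does not state its operational split, so compartment-level numbers
are indicative rather than reference-grade. A residue lining two channels
counts once per channel in channel-level statistics and once per structure
in compartment statistics.

## The synthetic benchmark

`make_tunnel_structure()` fills a ball with a jittered FCC packing of
single-heavy-atom pseudo-residues (spacing 3.6 Å ≈ protein heavy-atom
density; jitter ≤ 0.3 Å from a seeded generator breaks Delaunay
degeneracies deterministically), carves a spherical cavity and one or more
tunnels with a prescribed radius profile, renames the wall atoms according
to per-layer lining plans, and emits the structure as PDB together with
machine-readable ground truth (planted length, bottleneck, exit points,
per-layer composition). Planted channel length is counted from the cavity's
deepest apex (the cavity center) to the packing surface, matching what the
detector measures. Two generator details earn their keep:

* **Bottleneck gates.** A union-of-spheres carve through a lattice cannot
  realize a prescribed constriction radius — the nearest surviving atom sits
  wherever the lattice puts it, ~0.7 Å beyond the carve. Bottlenecks are
  therefore built the way real bottlenecks are: two rotated rings of six
  gate atoms at exactly `bottleneck_radius + vdW` from the axis, with a
  plateau radius profile wide enough that the neighbouring carve spheres do
  not swallow the constriction. Planted bottlenecks are then recovered to
  within the Voronoi discretization (±0.75 Å, usually exactly).
* **Tolerances.** Planted-versus-measured tolerances — length within
  max(4.5 Å, 15%), bottleneck within 0.75 Å — reflect the Voronoi-vertex
  discretization at this packing density, not detector slack: the centerline
  zigzags between lattice interstices, and endpoints are vertices, not
  surface points. For the same reason the cohort generator plants channel
  lengths in 20–34 Å, comfortably above the 15 Å report threshold, so that
  ground-truth occurrence is unambiguous under the length tolerance.

`make_cohort()` assigns EC labels round-robin and draws each class's lining
residues from a stated multinomial; the default compositions make EC1
strongly hydrophobic (Ile/Leu/Val/Phe-rich) and EC6 strongly hydrophilic
(Arg/Lys/Asp/Glu-rich) so that class-level orderings are recoverable.
Single-sphere pseudo-residues keep the lining bookkeeping exact; an optional
4-atom mode stresses lining detection with more realistic residue extents.

What passing the synthetic benchmark shows: the geometry engine is exact
against brute-force clearance; path extraction is optimal against exhaustive
enumeration; planted geometry, composition and class orderings survive the
full pipeline. What it does not show: performance on real protein shapes —
side-chain texture, water-mediated constrictions, crystallographic artifacts
and genuinely ambiguous start sites are absent from the packing model, so
agreement with published per-accession values carries re-implementation
tolerances rather than exactness.

## Numerical choices and degenerate inputs

* The Delaunay tetrahedralization is computed by Qhull (through
  `scipy.spatial.Delaunay` in a subprocess; `CHANATOMY_PYTHON` overrides the
  interpreter). Vertices are re-sorted by their sorted tetrahedron
  vertex-index quadruple, so runs are reproducible across executions.
* Near-flat sliver tetrahedra on the hull have circumcenters astronomically
  far away; positions beyond 1000 Å of the tetrahedron fall back to the
  centroid, and per-edge clearance sampling is capped at 80 points. These
  vertices lie in bulk solvent or junk space and never carry traversable
  edges; vertex clearance is always recomputed from the final position, so
  the clearance/position invariant is unaffected.
* Coplanar input (fewer than 4 affinely independent atoms) raises a
  triangulation error; structures with fewer than 4 atoms after
  sanitization raise a degenerate-structure error; a site whose
  neighbourhood contains no traversable vertex raises a site-unreachable
  error and the structure counts as channel-free in occurrence statistics.
* Single-vertex paths are flagged degenerate and excluded; channels whose
  solvent trim leaves fewer than 2 points likewise.
* Ties are broken deterministically everywhere: first index for bottleneck
  and plateau minima, vertex index in exit ordering, site id in site
  selection.
* Hydrogens and waters are always removed; HETATM groups are kept only if a
  non-metal atom sits within 1.05× the sum of covalent radii of a polymer
  heavy atom. Metal coordination deliberately does not count as covalent,
  so heme-like cofactors are removed — whether the original survey kept
  metal cofactors is unstated, and this is the conservative reading, flagged
  for sensitivity analysis.

## Problem sizes used in the shipped validation

The test suite and the acceptance script validate on: 20 random blobs of up
to 500 atoms (clearance oracle), 100 random graphs of up to 10 vertices
(path oracle), 20 single-tunnel structures with planted lengths 20–50 Å
(~2,000–15,000 atoms each), one 3-tunnel structure, and seeded cohorts of
30–50 structures with 1–2 tunnels each. These sizes exercise every code
path at full parameter defaults while keeping a complete validation run in
the tens of minutes on one CPU; the per-structure cost is dominated by the
triangulation and edge-clearance sampling and scales roughly linearly in
atom count for globular shapes.
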