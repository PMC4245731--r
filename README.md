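# chanatomy

Detection and anatomy of enzyme active-site access channels in protein
structures.

Many enzymes bury their catalytic sites and connect them to the solvent
through access channels — void pathways that co-determine which substrates
can reach the chemistry inside. `chanatomy` finds these channels and
characterizes them, for structural bioinformaticians who want
channel-level geometry and composition statistics over single structures or
whole cohorts of annotated enzymes.

## Method at its core

The atoms of a sanitized biological assembly (hydrogens, waters and
non-covalent ligands removed; Bondi vdW radii assigned) generate a Delaunay
tetrahedralization. Each tetrahedron's circumcenter is a Voronoi vertex of
the atomic centers and carries its *clearance*
c(p) = min_i (‖p − x_i‖ − r_i); face-adjacent tetrahedra are linked into a
void graph, edges below the interior threshold (1.1 Å) are pruned, and bulk
solvent is peeled away with a 5 Å probe. Starting from the roomiest
traversable vertex near an annotated active site, channels are extracted as
Dijkstra shortest paths to the molecular surface under the weight

    w(e) = length(e) / (clearance(e)² + 0.01 Ų),

deduplicated by surface patch and vertex overlap, and trimmed where they
meet the solvent. Each channel is a centerline with a radius profile, from
which the bottleneck (global radius minimum), local narrowings, and the
lining residues — weighted by touched arc length and layered into
internal/middle/external at 5 Å from the ends — are derived. Channel
physico-chemistry is the length-weighted mean of Kyte–Doolittle hydropathy
and Zimmerman polarity over the lining plus an unweighted charge census.
Cohorts aggregate into per-EC-class occurrence tables (Na, P, M, L, counts
at 5/10/15/20 Å), propensity tables (region frequency over whole-structure
frequency), and compartment compositions (active site / channel wall /
surface / interior, split by Shrake–Rupley relative accessibility).

A first-class synthetic generator plants tunnels of known length, radius
profile, bottleneck and lining composition in protein-like jittered FCC
packings, so every stage is testable against ground truth without any
downloads.

## Worked example

```r
library(chanatomy)

# a synthetic enzyme: one buried cavity, a 26 A channel with a 1.9 A
# bottleneck, annotated cavity-wall residues as the active site
syn <- make_tunnel_structure(
  tunnel_spec(direction = c(1, 0, 0), length = 26, radius = 2.6,
              bottleneck_radius = 1.9, cavity_radius = 5),
  seed = 3, id = "demo")

rec <- analyze_structure(syn$structure, syn$sites)
rec
#> <enzyme_record> demo: 2176 atoms, site SITE1, 1 channel(s) (1 above report length)

ch <- rec$channels[[1]]
ch
#> <channel> 31 points, length 23.8 A, bottleneck 1.90 A
ch$physchem
#> <physchem> hydropathy -0.69, polarity 20.1, charges +17/-10 (net +7)
table(ch$lining$layer)
#> external internal   middle
#>       13       27       39
```

The detected channel measures 23.8 Å against a planted 26 Å (within the
Voronoi discretization tolerance), the planted 1.9 Å bottleneck is
recovered exactly, and the lining splits into the three layers used by the
composition statistics. The slightly negative hydropathy and mid-range
polarity reflect the uniform filler composition of the packing. `run_detect()` / `run_cohort()` write the same
results as JSON/CSV reports, and `inst/cli/chanatomy` wraps them for shell
use:

```sh
Rscript inst/cli/chanatomy synthesize --n 10 --seed 7 --out demo/
Rscript inst/cli/chanatomy cohort --manifest demo/manifest.csv --out demo_report/
```

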