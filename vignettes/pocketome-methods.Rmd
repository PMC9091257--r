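---
title: "Methods: pocket maps, contact networks and site censuses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pocket maps, contact networks and site censuses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketome)
library(dplyr)
```

This vignette documents the models and procedures implemented in
`pocketome`, the parameters that matter, the choices made where the design
was genuinely open, and what the synthetic-data generators do and do not
emulate.

## Probe density grids

### The recording kernel

Docked molecular probes are converted to voxel density maps. Every
occurrence of a pharmacophore substructure is recorded not only in the
voxel containing it but also, with dampened fractional values, in its 26
lattice neighbours. The stencil has four shells:

* the **centre** voxel (containing the deposit point),
* 6 **face** neighbours at distance $d = s_v$,
* 12 **edge** neighbours at $d = \sqrt{2}\,s_v$,
* 8 **corner** neighbours at $d = \sqrt{3}\,s_v$,

where $s_v$ is the voxel spacing. A neighbour at distance $d$ receives
$v\,t/d$ with dampening factor $t$; the centre receives $v$ undampened
(a distance penalty is undefined at $d = 0$). The change $v$ is fixed by
requiring that one recording adds a total mass of exactly 1:

$$v = \frac{1}{1 + t\left(\frac{6}{s_v} + \frac{12}{\sqrt{2}\,s_v}
      + \frac{8}{\sqrt{3}\,s_v}\right)}.$$

The default spacing is $s_v = 0.5$ Å. The default dampening factor is
anchored so that the centre voxel retains 16.66% of each recording at that
spacing (hence 83.34% smears into the neighbours), which gives
$t \approx 0.13092$ Å; both parameters are user-settable
(`build_kernel()`, `default_dampening()`).

```{r kernel}
kernel_shells(build_kernel(s_v = 0.5))
```

Deposits are keyed to the half-open voxel $[o + i s_v, o + (i{+}1) s_v)$
containing the point: sub-voxel position inside the centre voxel does not
change the weights, because the kernel smears by lattice offset, not by
continuous distance. Grids are tight bounding boxes that grow
(re-originating on the same lattice) when a deposit falls outside the
current bounds, so streaming construction needs no pre-pass. Mass equals
the number of recordings at every stage, and the test suite checks this to
1e-9 relative.

### Deposit locations

Eight feature classes are recorded: hydrogen-bond donors and acceptors,
aromatic atoms, halogen atoms, basic and acidic substructures, aliphatic
ring atoms, and an `everything` class with one occurrence per atom. The
single-atom classes deposit at the atom position. Multi-atom groups
(acidic, basic) deposit at the unweighted centroid of the matched atoms by
default; `match_features(..., locations = "atom")` switches to one deposit
per matched atom for users who prefer strictly atomwise recording.

Feature perception runs directly on the pose bond graph: aromaticity from
SYBYL `ar` bonds, ring membership from the non-bridge edges of the graph,
implicit hydrogens from standard valences adjusted by formal charge. The
packaged pattern table (`default_feature_patterns()`) carries the
equivalent SMARTS string for each class as documentation of the intended
chemistry; a user pattern file selects which classes are matched.

### Master grids

Per-docking grids are combined by constructing a master grid that
encompasses all inputs and adding each source voxel's value into the (at
most) eight master voxels it overlaps, weighted by the product of per-axis
fractional overlaps. With aligned lattices this reduces to elementwise
addition; total mass is conserved exactly in either case. Class-level maps
are sums over member structures (`combine_grids()`). Resampling across
different spacings is deliberately unsupported — combining requires a
common $s_v$.

Exports: OpenDX scalar fields (`write_dx()`/`read_dx()`, last axis
fastest) and dummy-atom PDB files of the highest-density voxels covering a
user-given percentage of the grid mass (`top_fraction_points()`; residue
`DUM`, voxel value in the B-factor column). At the percentage cut, ties
break by ascending lattice index so output is deterministic.

## Residue contact networks

A contact exists between two residues when any atom pair is closer than
the sum of the atoms' van der Waals radii plus a 0.5 Å buffer. To avoid
noise from trivial local geometry, pairs fewer than four sequence
positions apart are ignored whenever one of the two atoms is a backbone
atom; side-chain/side-chain proximity still counts at any separation. Only
residues with generic numbers (helices 1–7, plus helix 8 by default since
contacts to the proximal helix-8 positions are informative) enter the map,
restricting it to the transmembrane bundle. Radii follow the Bondi
convention (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20, P 1.80 Å); unknown
elements fall back to 1.70 Å with a warning. All atoms present are used by
default (`heavy_only = TRUE` drops hydrogens). Insertion-coded residues
count as separation 0 from their base author number.

Contacts are compared across receptors through generic residue numbers
(Ballesteros–Weinstein labels `helix.position` and the analogous schemes
of the other classes), treated as opaque labels with string equality.
Residues without a generic number are excluded from contact maps — the
maps exist to be compared across receptors, and unnumbered residues have
no cross-receptor identity.

### Fingerprints and PCA

Per class, the union of contacts over all member structures — restricted
to contacts whose both positions are resolved in every member — defines a
bit vector; each structure's fingerprint sets a bit per contact it forms.
The binary matrix (structures × contacts) is mean-centred (no variance
scaling: the bits share a scale, and variance scaling would inflate rare
contacts) and decomposed by singular values. Components are ordered by
explained variance and signed deterministically: each component is flipped
so the mean score of inactive-labelled structures is at least that of
active-labelled ones, falling back to making the largest-magnitude loading
positive when a state group is absent. Under this convention, a positive
loading marks an inactive-state contact and a negative loading an
active-state contact.

### Clear states and contact importance

The full-class PCA mixes clear and intermediate structures. Clearly
assignable structures are selected by score thresholds — for class A,
inactive = PC1 > 7 and active = PC2 > 7.5; for class B1, structures with
PC1 > 3 are discarded (they separate for reasons unrelated to activation)
along with an explicit outlier id list — and the PCA is recalculated on
that subset (`select_clear_states()`, `recalculate_pca()`), after which
the first component separates the states. A structure exceeding both class
A thresholds goes with its larger score. The thresholds are data-scale
quantities: they suit fingerprint cohorts of a few hundred class A
structures and should be reviewed for other cohort sizes (the selection
errors out if either state set comes back empty).

Contact importance normalises the separating component's loadings by the
largest absolute value, so they range over $(0, 1]$ with the sign carrying
the state. Same-helix contacts are dropped (a ligand cannot usefully
bridge one helix to itself), and reporting cutoffs of 0.5 or 0.7 on the
normalised coefficient are typical. When site definitions are supplied,
contacts are restricted to those touching at least one site residue and
flagged `both`/`one` for full or partial membership. The packaged site
table lists the site-defining generic positions for OS5, OS6, OS9, KS2,
KS5 and KS8.

## Sequence analysis of sites

Site sequences are read off per receptor via the numbering tables (no
alignment is computed — generic numbers are the alignment), with gaps
where a receptor lacks a position. Pairwise **identity** is the percentage
of compared positions with the same residue; **similarity** the percentage
in the same physicochemical class, under a five-way classification:
apolar {A V L I M G P C}, aromatic {F W Y}, polar {S T N Q}, positive
{K R H}, negative {D E}. Histidine sits with the positives and cysteine
with the apolars; aromatic is its own class so F~Y counts similar but F~L
does not. The table is a packaged TSV, so alternatives are one edit away.
Positions gapped in either member of a pair are dropped from that pair's
denominator (pairwise-complete); a pair with nothing to compare is
reported missing rather than zero. **Polarity** is the per-receptor
fraction of non-gap site positions that are polar or charged (aromatic
counting as apolar), averaged across receptors.

## Occupancy census

Known sites are surveyed for crystallisation additives and co-purified
molecules. Components are grouped into five categories — surfactants,
steroids, fatty acids, polymers, anions (`other` as fallback) — by a
packaged het-code lookup. The original assignment of a component to a
pocket was visual; here it is a reproducible geometric rule: a component
occupies a site when at least one of its heavy atoms lies within 4.5 Å of
atoms of at least two distinct site residues. The two-residue requirement
rejects incidental grazing contact with a single residue; the cutoff is
configurable. Designed orthosteric/allosteric ligands are excluded by a
per-structure het-code exclusion list.

Aggregation counts structures (not component copies): a structure with two
fatty acids in a site contributes one to the fatty-acid count, matching
"n out of m structures" reporting. Because percentage denominators can
reasonably be either the occupied structures of a site or the whole
survey, both are emitted, clearly labelled (`pct_of_occupied`,
`pct_of_total`).

## Synthetic data: what it does and does not emulate

The generators (`make_bundle()`, `make_pose_cloud()`,
`make_fingerprint_cohort()`, `make_site_sequences()`,
`make_components()`) are pure functions of (spec, seed) and return
ground-truth manifests, so every pipeline stage is testable without
downloading structures.

* **Bundles** are idealised seven-helix bundles: ideal helices (3.6
  residues/turn, 1.5 Å rise) on a 9.2 Å circle with N/CA/C/O plus a CB
  pseudo-side-chain, a helix-8 stub, and generic numbers centred at
  `h.50` mid-helix. Activation is a 12° tilt of helix 6 about its
  extracellular end, swinging the intracellular half outward — enough to
  break a set of helix-6 contacts, which is the feature the contact
  pipeline needs. Real side-chain packing, loops, kinks and proline
  distortions are absent, so passing tests show the *rules* are
  implemented correctly, not that the geometry of any real receptor is
  reproduced.
* **Pose clouds** place rigid probe copies (default: a benzene ring, which
  exercises the aromatic and everything classes) with Gaussian-scattered
  centroids at planted cavity centres and uniform random orientations.
  There is no receptor, no scoring and no clash avoidance; the clouds
  emulate the *spatial statistics* of docking output, not its energetics.
* **Fingerprint cohorts** plant inter-helix contacts present in one state
  and absent in the other on top of a constant background, then flip every
  bit independently (default p = 0.05, n = 20 + 20 structures, 6 planted
  contacts among 60 background contacts). Real cohorts have correlated
  bit noise and unbalanced states; the generator's independence assumption
  is what makes the planted-recovery statements exact.
* **Site sequences** draw per-position letters from either a
  consensus-plus-uniform mixture (conservation c) or an explicit profile;
  the manifest records the closed-form expected class-match probability
  the similarity matrix should approach.
* **Component placements** drop a small component at the midpoint of the
  closest pair of site residues (`inside`, which satisfies the occupancy
  rule by construction) or 60 Å away (`far`, which cannot).

## Numerical choices and degenerate inputs

* Voxels are half-open intervals; voxel (1,1,1) starts at the grid origin
  and centres sit at `origin + (i - 1/2) s`.
* Kernel weights decrease strictly centre > face > edge > corner whenever
  $t < s_v$; the defaults satisfy this comfortably.
* Zero-variance fingerprint matrices yield all-zero components with a
  warning rather than an error; all-zero loadings on the separating
  component are an error in `contact_importance()`.
* Superposition (`superpose()`) is a Kabsch least-squares fit on CA atoms
  of shared generic positions, requiring at least three; it reports the
  rotation, translation and RMSD and is intended for already-similar or
  synthetic coordinates, not as a structure aligner.
* Alternate locations: the first listed conformation is kept. Only one
  chain per file is analysed, selected by the metadata table.
* Tie-breaks are deterministic everywhere (lattice order in grid exports,
  (helix, position) order for contacts), so repeated runs agree bit for
  bit.

## Problem sizes in the test suite

The suite exercises the pipeline at deliberately small scale: bundles of
176 residues, pose clouds of 300 poses per cavity at $\sigma = 1$ Å,
cohorts of 40 structures over 10 seeds, 25 receptors × 16 positions for
the sequence metrics, and a 5-structure occupancy census with planted
counts. These sizes make the planted ground truth recoverable with wide
margins while the whole suite stays fast; they are sanity scales, not
reproductions of any published corpus.

## Known limitations

* Arbitrary user SMARTS are not interpreted; the eight feature classes are
  fixed perception rules (their SMARTS equivalents are documentation).
* No protonation, minimisation or structure preparation: inputs are
  assumed prepared and aligned.
* Contact maps are binary and static; no MD-derived frequencies or
  weighted contacts.
* The three-way active/intermediate/inactive categorisation is taken from
  input labels; only the clear-state thresholds are implemented, not an
  independent state classifier.
* Free-text mining of crystallisation conditions is out of scope; the
  census background must come from a user-supplied table if needed.
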