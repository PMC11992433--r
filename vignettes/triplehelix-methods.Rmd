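---
title: "Models and methods: collagen duplication variants and triple-helix geometry"
author: "triplehelix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: collagen duplication variants and triple-helix geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triplehelix)
```

# Scope

`triplehelix` supports the structural assessment of in-frame duplications
in fibrillar collagen chains, the situation typified by vascular
Ehlers-Danlos syndrome (vEDS) variants in the collagen alpha-1(III) chain.
The package covers four stages:

1. **Variant arithmetic** -- parsing HGVS-style cDNA duplication
   descriptors, projecting them to protein coordinates, and checking them
   against the Gly-Xaa-Yaa triple-helix registry and the collagenase
   (MMP-1) cleavage-site context.
2. **Model building** -- idealized triple-helix coordinates for short
   chain windows and the enumeration of all eight wild-type/mutant trimer
   register combinations.
3. **Trajectory geometry** -- the statistics used to compare helix
   ensembles: end-to-end distance, curvature, flexibility, RMSD/RMSF,
   interchain hydrogen bonds and contacts, conformational clustering and
   block-shifted standard errors.
4. **Synthetic ensembles** -- generators with analytic ground truth, so
   that every statistic can be validated without molecular-dynamics runs.

Molecular-dynamics simulation itself (force fields, thermostats, binding
free energies) is out of scope: the package analyses coordinate
ensembles, it does not produce them physically.

# Variant arithmetic

Coordinates are 1-based and inclusive on both the cDNA and the protein,
following HGVS. A duplication `c.<start>_<end>dup` is in frame iff its
length is a multiple of 3. Protein projection builds the mutant coding
sequence, translates both alleles, finds the first differing residue and
shifts the insertion point to its 3'-most equivalent position (the HGVS
normalization under which the 18-nt COL3A1-type duplication is named
p.(Leu958_Gly963dup)). Duplications that are not codon-aligned can create
hybrid junction codons; when the inserted peptide is then not a clean
tandem repeat of the reference, the result is flagged (`is_tandem =
FALSE`) and anchored by the residue after which the run inserts.

The triple-helix registry is a frame: residue `domain_start` is the Gly
of the first triplet and every third residue from it must be Gly. An
insertion preserves the registry iff its length is a multiple of 3 and
every inserted residue landing on a Gly slot is Gly. Candidate collagenase
sites are Gly-Ile and Gly-Leu triplet starts; the canonical site is
distinguished by two imino-containing (Pro/Hyp) triplets upstream and two
imino-free triplets downstream. We read "two imino acid triplets
upstream" as *at least one imino residue per triplet*, which reproduces
the published context (Gly-Ala-Pro / Gly-Pro-Leu upstream of
Gly948|Ile949, Gly-Ile-Thr / Gly-Ala-Arg downstream). Distances to the
cleavage site are counted from the first residue after the scissile bond,
so a duplication starting at residue 958 lies 9 residues downstream of
the Gly948|Ile949 bond.

Because the full-length reference transcript is an optional input, the
package ships a deterministically constructed *synthetic* stand-in coding
sequence (`synthetic_col3a1_cds()`) that reproduces the local context of
the alpha-1(III) chain around the cleavage site and the Leu958-Gly963
duplication, embedded in a Gly-Pro-Pro background. Full-length statistics
(the 343-triplet domain, the Ile/Leu Xaa-position fractions) require the
real sequence, supplied by the user as FASTA.

# Idealized triple-helix models

Chain windows are 39 residues (13 triplets) with the window start on a
Gly position; the wild-type window is centered on the duplication locus
and the mutant window on the tandem repeat. Two mutant-window semantics
are provided: `trimmed` (default) keeps the 39-residue length by trimming
flanks symmetrically, `extended` keeps the full flanks (39 + 6 residues).
Every Pro at a Yaa position is marked hydroxyproline ("O"), standard
collagen chemistry; Pro at Xaa stays Pro.

Coordinates come from an analytic superhelix rather than a
crystallographic template: rise 0.286 nm/residue along the common axis,
chain radius 0.28 nm (which puts the minimal interchain C-alpha distance
near 0.49 nm, inside the physical 0.4-0.8 nm range), right-handed
supertwist of one turn per 30 residues, and a one-residue stagger between
successive register positions, so the three C-termini occupy the stagger
envelope (C-terminal alignment). The representation is minimal --
backbone N, CA, C, O plus C-beta and a schematic Hyp hydroxyl -- placed
at fixed offsets in the local helix frame. It supports geometric
statistics and file round-trips; it is not a chemically refined model,
and counts that depend on atomic detail (hydrogen bonds, contacts) are
calibrated by constructed fixtures, not by these schematic models.

For an untrimmed mutant chain inside a trimer of shorter chains, the six
inserted residues are interpolated along the axial gap left by the
wild-type frame with a radial out-bulge (default amplitude 0.15 nm): a
deliberately simple stand-in geometry for a bulged insertion, left for
downstream refinement tools.

`enumerate_trimers()` assigns wild type or mutant to each register
position (A leading, B middle, C trailing), producing the eight models
`WWW ... MMM`: one all-wild-type, three single-mutant, three
double-mutant, one all-mutant. All eight preserve the Gly-every-third
registry by construction of the windows.

# Trajectory geometry

All lengths are nm internally; PDB files carry Angstrom and are converted
at the boundary. A trajectory is an ordered set of frames with identical
atom ordering and a frame spacing `dt` in ps.

**End-to-end distance (L)** is measured between the C-alpha of the third
residue and the C-alpha of the third residue from the end of the middle
(B) chain, avoiding the partially unfolding termini. Its per-frame
standard deviation is the extension spread `s`.

**Curvature (1/r)** pools the C-alpha atoms of the three chains after
dropping terminal residues -- first/last 3 of chain A, 2 of chain B, 3 of
chain C by default. The phrase "first and last three" for the trailing
chain is grammatically ambiguous (1+3 or 3+3); we default to 3+3,
symmetric with the leading chain, and the scheme is configurable. The
pooled cloud is reduced to a plane and a circle is fitted; curvature is
the reciprocal radius, and **flexibility (f)** is the standard deviation
of the per-frame curvature series.

Two numerical points deserve care, because the bend being measured is
extremely shallow: at 1/r = 0.003 nm^-1 the sagitta over a 10-nm helix is
~0.04 nm, an order of magnitude smaller than the ~0.25 nm transverse
spread of the chain traces.

* *Plane choice.* The transverse second moments of a three-fold-symmetric
  trimer are nearly isotropic, so the smallest-singular-vector plane of
  the cloud is degenerate and would mix an arbitrary part of the bend out
  of the projection. The projection therefore keeps the leading principal
  axis as the longitudinal coordinate and chooses the second in-plane
  direction as the transverse direction carrying the quadratic (bowing)
  trend along the axis, estimated with per-chain intercepts. The
  intercepts matter twice: they stop a chain that protrudes past the
  others (chain B keeps one extra residue per end under the default
  omission) from faking a bowing signal, and subtracting them collapses
  the three strands onto the common axis so that noise in the
  bending-direction estimate cannot leak the strand-offset pattern into
  the fitted curvature. The general-purpose SVD plane fit
  (`fit_plane_svd()`) is still exported and is the right tool when the
  point set is not a symmetric multi-strand cloud.
* *Circle fit.* The algebraic (Kasa) least-squares circle is attenuated
  by orders of magnitude when the transverse point spread exceeds the
  sagitta, so it cannot measure shallow bends; it is retained
  (`method = "kasa"`) for interpolation problems, where it is exact. The
  default is the geometric (orthogonal-distance) fit in the algebraic
  parametrization A(x^2+y^2)+Bx+Cy+D = 0 with constraint B^2+C^2-4AD = 1,
  under which the exact point-to-circle distance is 2P/(1+sqrt(1+4AP)).
  This parametrization remains perfectly conditioned through the
  straight-line limit A -> 0, which the (center, radius) form does not.
  Levenberg-Marquardt refinement starts from the better of the Kasa
  circle, a parabolic-arc estimate and a total-least-squares line.
  Near-straight clouds report curvature 1/r with the radius capped at
  1e6 nm and a degenerate flag -- never an exception. The canonical
  projected coordinates are rounded at 1e-9 nm (far below atomic
  precision) so the whole computation is exactly invariant under global
  rotation and translation of a frame.

**RMSD/RMSF** superpose each frame on the reference over backbone atoms
(N, CA, C; Kabsch, via `bio3d::fit.xyz`) before measuring displacement;
RMSF is taken about the time-averaged structure and reported per residue
and chain. RMSD values are computed from the superposed coordinates
directly, keeping full precision on the nm scale.

**Hydrogen bonds and contacts** use geometric criteria, counted only
between different chains. The minimal representation carries no explicit
hydrogens, so the donor-acceptor rule is N...O (or Hyp hydroxyl) distance
<= 0.35 nm inclusive, with a donor-angle filter (>= 90 degrees at the
donor when its antecedent atom is present) and Pro/Hyp backbone nitrogens
excluded as donors. A hydroxyl-only donor mode is provided, since
published interchain bond counts in collagen often refer to Hyp
hydroxyls. Contacts are residue pairs on different chains with any
heavy-atom pair within 0.6 nm, counted once per frame. Both cutoffs are
configurable; they are common defaults, not fitted values.

**Block-shifted standard errors** follow the five-interleaved-grids
scheme: the frames are split into `n_sets = 5` grids offset by
`shift = 100` ps (so each grid samples every `n_sets * shift` ps); the
statistic is evaluated per grid and the standard error is the SD of the
grid values divided by sqrt(5).

**Daura clustering** is the greedy neighbor-count scheme at a pairwise
backbone-RMSD cutoff of 0.25 nm: the frame with the most neighbors within
the cutoff becomes a cluster representative, the cluster is removed, and
the procedure repeats. Ties go to the earliest frame.

# Synthetic ensembles and what they validate

The trimer generator emulates the *coarse* geometry of a collagen trimer
ensemble: three parallel strands 0.28 nm from a common axis, 120 degrees
apart, the axis laid along a circular arc of radius 1/kappa. Per frame,
the curvature is drawn from a Gamma law with the requested mean `kappa0`
and SD `curvature_sd` (strictly positive, exact moments), the axial
length is scaled to give the requested end-to-end spread, isotropic
Gaussian jitter of `noise_sigma` (default 0.01 nm) is added per atom, and
a random global rigid motion is applied -- to which all the statistics
are invariant. The strand phases (-30, 90, 210 degrees) place the middle
chain exactly in the bending plane, so the pooled C-alpha cloud stays
balanced about the central arc even under the asymmetric default end
omission. Draws use stratified inverse-CDF sampling with a random
permutation: the marginal law and frame exchangeability are unchanged,
but the realized ensemble mean and SD match the nominal ground truth to
O(1/n) rather than O(1/sqrt(n)), so even short ensembles carry their
nominal moments -- the point of a calibrated ground-truth generator.

Deliberate simplifications, and their consequences for interpretation:
bending happens in a fixed body plane by global arc-radius modulation
(no per-residue elastic modes, no sequence-dependent stiffness), strands
do not supertwist inside the generator, the noise is isotropic and
uncorrelated, and there is no solvent or thermodynamics. Passing the
recovery tests therefore demonstrates that the *statistics* are unbiased
and well-calibrated on ensembles with known geometry; it does not
demonstrate anything about force-field accuracy or about real collagen
dynamics beyond the geometric regime the generator spans (curvatures
0.002-0.01 nm^-1, flexibilities ~0.002 nm^-1, end-to-end ~10 nm, i.e.
the regime reported for 39-residue collagen model peptides).

Default problem sizes used by the test suite and the acceptance script --
1,000-frame ensembles for parameter recovery, 100-150 frames for
clustering and ordering replicates, 100 replicate pairs for the
flexibility-ordering check -- were chosen so the Monte-Carlo error of
each check sits well below its tolerance.

The hydrogen-bond fixture places donor/acceptor pairs at exactly known
geometry (0.29 nm ideal, 0.35 nm borderline -- counted, the criterion is
inclusive -- and 0.40 nm broken), spaced so no cross-pairing occurs; the
expected count is known by construction. The sequence generator emits
random Gly-Xaa-Yaa triplets with configurable imino density, an optional
embedded cleavage motif and an optional in-frame duplication, with
ground-truth annotations carried in metadata.

# Degenerate inputs and edge behavior

Straight (or noise-dominated) frames are reported with curvature 1e-6
nm^-1 and a degenerate flag rather than an error; collinear point sets
flag the plane fit; a single-frame ensemble has no flexibility (error
below two frames); block-shifted errors require the shift to be a
positive multiple of `dt` and at least one full sampling grid; clustering
of identical frames returns one cluster. Per-frame curvature estimates
carry a noise floor of roughly 2 sigma_fit / 70 nm^-1 (about 3e-4 nm^-1
at the default jitter), so curvatures well below that are reported as
near-zero values with large relative scatter -- visible in the recovery
tests at the smallest target curvature.

# Known limitations

* The built models are geometric idealizations; their absolute H-bond and
  contact counts reflect the schematic atom placement, not chemistry.
* The bulge geometry for untrimmed mutant chains is a placeholder for
  refinement, not a prediction.
* Full-length chain statistics require the user-supplied reference
  sequence; the shipped synthetic context covers only the neighborhood of
  the cleavage site and the duplication.
* The curvature statistic assumes a single dominant bend; strongly
  S-shaped conformations would be summarized by an effective (smaller)
  curvature.
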