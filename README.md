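# triplehelix

Structural-computational analysis of in-frame duplications in fibrillar
collagen chains — the class of variant typified by vascular
Ehlers–Danlos syndrome (vEDS) duplications in the collagen α1(III)
chain (*COL3A1*).

An in-frame duplication such as `c.2868_2885dup` inserts whole
Gly-Xaa-Yaa triplets into the triple-helical domain. Whether it is
tolerated depends on sequence arithmetic (is the Gly-every-third
registry preserved? how far is it from the unique collagenase
Gly948|Ile949 cleavage site?) and on helix mechanics (does the mutated
trimer bend and flex more than the wild type?). `triplehelix` implements
both halves for R users:

* **Variant registry** — HGVS duplication parsing, protein projection
  with 3'-most normalization, Gly-Xaa-Yaa registry checks, Xaa/Yaa
  occupancy statistics, collagenase-motif scanning (imino-rich upstream,
  imino-free downstream context) and signed distances to the scissile
  bond.
* **Helix builder** — idealized collagen superhelix coordinates for
  39-residue (13-triplet) chain windows, Yaa-proline hydroxylation, and
  enumeration of all 2³ = 8 wild-type/mutant trimer register
  combinations with C-terminal alignment.
* **Trajectory geometry** — the ensemble statistics used to compare
  helices: end-to-end distance *L* with spread *s* (third-to-third
  Cα of the middle chain), curvature 1/*r* by projection onto the
  bending plane followed by a geometric least-squares circle fit,
  flexibility *f* = SD of the time-dependent curvature, backbone
  RMSD/RMSF after Kabsch superposition, interchain hydrogen-bond and
  contact counts, Daura conformational clustering (cutoff 0.25 nm) and
  block-shifted standard errors (five interleaved grids, 100 ps shift).
* **Synthetic ensembles** — trimer generators with analytic ground truth
  (target curvature, flexibility, end-to-end spread, positional noise),
  hydrogen-bond fixtures with counts known by construction, and random
  collagen-like sequence generators, so the whole pipeline is testable
  offline.

The statistic at the core is the curvature of a gently bent trimer:
pooled Cα positions (terminal residues omitted: 3+3 for the leading
chain, 2+2 for the middle, 3+3 for the trailing) are projected onto the
plane containing the helix axis and the bowing direction, and a circle
is fitted by orthogonal-distance least squares in the parametrization
A(x²+y²)+Bx+Cy+D = 0, B²+C²−4AD = 1, which stays numerically stable
through the straight-helix limit. The flexibility *f* is the SD of the
per-frame curvature series. See the methods vignette
(`vignettes/triplehelix-methods.Rmd`) for the model, assumptions and
numerical choices.

## Worked example

Annotate the 18-nt duplication on the shipped synthetic α1(III)-context
coding sequence (a deterministic stand-in reproducing the cleavage-site
neighborhood; supply the real transcript FASTA for full-length work):

```r
library(triplehelix)

ref <- synthetic_col3a1_cds()
v <- parse_dup(ref$hgvs)
#> <coding_variant> SYNTH_COL3A1:c.2868_2885dup  (18 nt, in-frame)
p <- project_to_protein(v, ref$cds)
#> <protein_dup> p.958_963dup LAGPPG (6 aa)

prot <- strsplit(seqinr::c2s(seqinr::translate(seqinr::s2c(ref$cds))), "")[[1]]
sites <- scan_cleavage_sites(prot, ref$registry)
subset(sites, is_true_site)
#>   site_start partner upstream_ok downstream_ok is_true_site
#> 1        948       I        TRUE          TRUE         TRUE
distance_to_cleavage(p, subset(sites, is_true_site))
#> [1] 9
registry_check(ref$registry, p)
#> [1] TRUE
```

The duplication inserts Leu-Ala-Gly-Pro-Pro-Gly at residues 958–963,
nine residues downstream of the unique collagenase site at Gly948, and
keeps a Gly every third residue. Build the eight trimer models:

```r
wt  <- extract_window(prot, p, registry = ref$registry)
mut <- extract_window(prot, p, registry = ref$registry, mutant = TRUE)
mut
#> <chain_spec A mutant> GPLGIAGITGARGLAGPOGLAGPOGPOGPOGPOGPOGPO (13 triplets, 7 Hyp)
names(enumerate_trimers(wt, mut))
#> [1] "WWW" "WWM" "WMW" "WMM" "MWW" "MWM" "MMW" "MMM"
```

Analyze a synthetic ensemble generated at a wild-type-like helix regime
(mean curvature 0.00329 nm⁻¹, flexibility 0.00184 nm⁻¹, end-to-end
10.147 ± 0.102 nm):

```r
cfg <- generator_config(rise = 10.147 / 34, kappa0 = 0.00329,
                        curvature_sd = 0.00184, length_sd = 0.102,
                        n_frames = 400, seed = 42)
geometry_summary(make_bent_trimer(cfg))
#> <geometry_summary>
#>   L       = 10.1467 nm (s = 0.1024, SE = 0.004)
#>   1/r     = 0.00331 nm^-1 (SE = 9.52e-05)
#>   f       = 0.001843 nm^-1
#>   RMSD    = 0.0416 nm (max 0.1422)
#>   H-bonds = 227.84, contacts = 567.00, clusters = 1
```

The recovered *L*, *s*, 1/*r* and *f* match the generator's targets
within their block-shifted standard errors; an ensemble generated with a
larger curvature SD yields a larger *f*, reproducing the soft-vs-stiff
ordering the statistics are designed to detect. (Absolute H-bond and
contact counts on these schematic models reflect the minimal atom
representation; calibrated counting is exercised by the constructed
fixtures, e.g. `make_hbond_fixture(14, "ideal")` → 14.)

A one-call pipeline (`run_config()` + `run_pipeline()`) chains the
stages and writes TSV/JSON reports stamped with a configuration hash and
seed.

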