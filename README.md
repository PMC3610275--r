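# gpcrgeom

Structural-geometry toolkit for the TM6/TM7 micro-switch interface of
class A G-protein-coupled receptors (GPCRs).

## The problem

The CWxP motif of transmembrane helix 6 (positions 6.47–6.50 in
Ballesteros–Weinstein generic numbering) is among the most conserved
features of class A GPCRs. The tryptophan W6.48 has long dominated
activation models, but the preceding small residue — cysteine in ~70% of
receptors, threonine or serine in most of the rest — sits at the hinge of
the rigid-body TM6 motion that accompanies activation and participates in
a hydrogen-bond network running 6.47 → N7.45 → N7.49 → D2.50. Probing
that hypothesis requires a reproducible way to:

- assign generic positions to deposited structures by anchoring the
  conserved CWxP and NPxxY motifs (`find_motif_anchors()`,
  `build_bw_map()`);
- classify side-chain χ1 rotamers into the *gauche+* / *gauche−* /
  *trans* wells and tabulate their populations (`chi1()`,
  `classify_rotamer()`, `rotamer_population()`);
- measure donor–acceptor geometry at the interface — the D···A distance
  and Cβ–D···A angle of e.g. S(C6.47)···O(N7.45) — decide hydrogen-bond
  presence with element-aware cutoffs (thiol sulfur is a long-range,
  weakly directional donor), resolve the Asn amide-flip ambiguity, and
  scan whole residue sets for polar networks including water bridges
  (`measure_pair()`, `hbond_verdict()`, `assess_amide_flip()`,
  `network_scan()`);
- quantify whether the residue at 6.47 perturbs the TM6 proline kink,
  via backbone Φ/Ψ and HELANAL-style unit bend / unit twist profiles
  (window of four consecutive Cα; an ideal α-helix with 3.6
  residues/turn has unit twist 360/3.6 ≈ 100°) averaged over
  conformational ensembles and differenced against a reference peptide
  (`helix_profile()`, `ensemble_profile()`, `profile_delta()`,
  `flag_distortion()`).

A synthetic-structure module builds every needed fixture from internal
coordinates — ideal and Pro-kinked helical polyalanine peptides with
controlled Φ/Ψ, χ1 and kink angle, thermally perturbed multi-model
ensembles, engineered hydrogen-bond fixtures with exact geometry, and toy
alignments — so the full pipeline is testable with no downloads
(`build_peptide()`, `build_all_conformers()`, `perturb_ensemble()`,
`build_hbond_fixture()`, `toy_alignment()`).

## Worked example

```r
library(gpcrgeom)

## 25-residue polyalanine helix with a central CAAP motif, Cys chi1 = -60
panel <- build_all_conformers()          # AAAP reference + 9 conformers
names(panel)[1:4]
#> [1] "AAAP"    "CAAP g+" "CAAP g-" "CAAP t"

m <- panel[["CAAP g+"]]$model
chi1(m, "A", panel[["CAAP g+"]]$motif_i)$chi1
#> [1] -60
unit_twist_profile(m, "A")$twist[12]     # ideal alpha-helix: ~100 deg
#> [1] 99.36

## thermally perturbed ensembles, averaged profiles, test-minus-reference
## delta (both sides carry the same noise level: unit bend is a magnitude,
## so a noisy ensemble must be compared against an equally noisy reference)
ens  <- perturb_ensemble(ensemble_spec(panel[["CAAP g+"]]$spec,
                                       n_frames = 100, noise_sigma = 0.02,
                                       seed = 1))
ens0 <- perturb_ensemble(ensemble_spec(panel[["AAAP"]]$spec,
                                       n_frames = 100, noise_sigma = 0.02,
                                       seed = 2))
ref  <- ensemble_profile(ens0, "A", 12, peptide_label = "AAAP")
test <- ensemble_profile(ens, "A", 12, peptide_label = "CAAP g+")
flag_distortion(profile_delta(test, ref), threshold = 2)$verdict
#> [1] "unperturbed"

## engineered thiol-amide contact mirroring an inactive-state receptor
fx  <- build_hbond_fixture("CYS", "ASN", da_distance = 3.8,
                           approach_angle = 84.5)
map <- build_bw_map(fx, anchors = list("6.47" = "A:1", "7.45" = "A:10"))
measure_pair(fx, map, "6.47", "7.45")
#> <HBond 6.47 SG ... 7.45 OD1: 3.80 A, 84.5 deg, facing CO, H-bond>

## the same geometry at the agonist-state distance is no longer a bond
g <- measure_pair(build_hbond_fixture("CYS", "ASN", 4.4, 81.2),
                  map, "6.47", "7.45")
g$is_hbond
#> [1] FALSE
```

The twist value ~100° is the per-residue rotation of an ideal α-helix;
`"unperturbed"` means no |Δ| > 2° in any of the four channels (ΔΦ, ΔΨ,
Δbend, Δtwist) over positions i−7 … i+4 — the criterion for saying a
6.47 rotamer leaves the standard Pro-kink intact. The 3.8 Å / 4.4 Å pair
reproduces the inactive/active thiol–amide contact change: under the
default sulfur-donor cutoff (4.3 Å, distance-only) the first is a
hydrogen bond and the second is not.

## Reference tables

`reference_tm67_geometry()` and `reference_647_rotamers()` return the
published crystallographic panel (19 structure rows of 6.47→7.45/7.44
geometry; 15 receptor rows of 6.47 rotamer labels) used by the regression
fixtures. These are inputs, not package output; the test suite mirrors
each row as an engineered fixture with exactly the printed geometry.

## Command line

A thin CLI over the generators lives at `inst/cli/gpcrgeom.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/gpcrgeom.R", package="gpcrgeom"))')" \
  build-peptide --sequence AAAAAAAAAAACAAPAAAAAAAAAA --chi1 12:-60 --out cys_helix.pdb
```

Subcommands: `build-peptide`, `build-conformers`, `perturb`,
`hbond-fixture`, `toy-alignment`, `profile`.
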