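# putkit

Structural and biochemical analysis of putRNA elongation complexes.

The phage HK022 *put* RNA is a cis-acting nascent-RNA element that binds the
β′ zinc-binding domain (β′ZBD) of the bacterial RNA polymerase elongation
complex (EC) and suppresses transcriptional pausing. Pausing is associated
with *swiveling* — a rigid-body rotation of the clamp, dock, shelf, jaw, SI3
and β′ C-terminal domains about an axis roughly parallel to the bridge
helix — and putRNA works by holding the EC in the non-swiveled, active
conformation. `putkit` packages the quantitative analyses around that
mechanism for structural biologists and biochemists working with EC
coordinate models and in vitro transcription data:

- **Rigid geometry.** Kabsch least-squares superposition, rotation
  angle/axis extraction, and the two-stage swivel measurement: align target
  to reference on the core module, then report the residual rotation of the
  swivel module,

  θ = arccos((tr **R** − 1)/2),

  together with the angle between the residual axis and the bridge-helix
  axis and per-domain Cα RMSDs. Single-atom displacements (e.g. βE1006 Cα)
  and ion–ion distances (Mg²⁺–Zn²⁺) use the same machinery.
- **Interfaces and contacts.** Shrake–Rupley solvent-accessible surface
  area on a deterministic golden-spiral point set; buried surface area in
  the PISA convention, BSA = (SASA_A + SASA_B − SASA_AB)/2; typed polar
  contacts (hydrogen bonds, salt bridges, cation-π) with hydrogen-free
  heavy-atom criteria; and in-silico base substitution with H-bond
  recounting (the U28* pocket analysis).
- **Nucleic-acid annotation.** Base-pair detection with Saenger
  classification (XIX/XX canonical, XXVIII G·U wobble, VIII A·G imino, XI
  G·A sheared), triplex flagging (up to two partners per residue), RNA–DNA
  hybrid length and translocation register, and helix kink angles.
- **Assay statistics.** Cytosine-calibrated paused fractions
  P = (I_paused/n_C) / (I_paused/n_C + I_runoff/n_C′) and the relative
  anti-pausing activity 1 − (P_x − P_WT)/(P_put⁻ − P_WT), with SEM and
  inactivating (<0.2) / inert (>0.9) classification; per-column alignment
  conservation scores.
- **Native MS.** RNA transcript masses from elemental compositions and a
  charge-series consistency deconvolution recovering neutral masses.
- **Synthetic data.** Every stage has a ground-truth generator
  (`make_two_module_model`, `make_duplex`, `make_gel_dataset`,
  `simulate_charge_series`), so the whole pipeline is testable without any
  downloads.

## Worked example

```r
library(putkit)

# a two-module EC stand-in with a known 2.5 degree swivel + 0.1 A noise
fx <- make_two_module_model(angle = 2.5, noise_sigma = 0.1, seed = 7)
swivel_angle(fx$reference, fx$target, fx$domains)
#> Swivel synthetic_reference -> synthetic_target: 2.484 deg (axis 0.9 deg off the bridge helix)
#>   core fit: 330 atoms, rmsd 0.176 A; swivel module: 200 atoms
#>   per-domain CA rmsd after core alignment (A):
#>     core             0.176
#>     clamp            1.594
#>     ...
```

The recovered 2.484° is the residual swivel-module rotation after core
alignment; the per-domain RMSDs show the core is static (0.18 Å, pure
noise) while every swivel-module domain moved ~1.5 Å.

```r
bp <- detect_base_pairs(make_duplex(n_pairs = 10)$model)
bp[1:3, c("res_i", "base_i", "res_j", "base_j", "n_hbonds", "saenger_class")]
#>   res_i base_i res_j base_j n_hbonds saenger_class
#> 1     1      G    10      C        3           XIX
#> 2     2      A     9      U        2            XX
#> 3     3      C     8      G        3           XIX

gel <- make_gel_dataset(c(U28G = 0.6, G35A = 0.05), noise_cv = 0.05, seed = 7)
classify_mutants(gel$lanes)
#> Anti-pausing activities (4 constructs):
#>   WT           1.000 +/- 0.000 (n=3, inert)
#>   put-         0.000 +/- 0.000 (n=3, inactivating)
#>   U28G         0.572 +/- 0.036 (n=3, other)
#>   G35A         -0.028 +/- 0.024 (n=3, inactivating)
```

The calibrator constructs map to 1 and 0 by construction; the two simulated
mutants are recovered near their true activities (0.6, 0.05) and classified
by the 0.2/0.9 thresholds.

To run the same measurements on deposited elongation-complex models, read
them with `read_structure("7xue.cif")` and pass a domain config
(`load_domain_config()` ships curated E. coli RNAP residue ranges); see
`?swivel_angle`, `?buried_surface_area`, `?hybrid_length`.

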