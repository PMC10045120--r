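# redoxcell

Single-cell kinetic modeling of the redox response to an NQO1-bioactivatable
quinone drug (beta-lapachone), for systems biologists studying why
ROS-generating chemotherapeutics hit some tumors and spare others.

Tumor cells live with chronically elevated reactive oxygen species and
compensate with upregulated antioxidant systems. beta-Lapachone exploits
this: NQO1 reduces the quinone to an unstable hydroquinone that re-oxidizes
through a semiquinone, so each drug molecule cycles repeatedly, draining
NADPH and pouring out superoxide that SOD1 converts to H2O2. Whether a given
cell drowns in H2O2 depends not on NQO1 alone but on its whole clearance
network -- peroxiredoxin/thioredoxin/thioredoxin reductase, glutathione
peroxidase/glutathione reductase, catalase, protein thiols -- and on its
capacity to regenerate NADPH (G6PD, GLUD1).

`redoxcell` implements that argument quantitatively:

* a compartmental mass-action ODE model of H2O2 generation and clearance
  under quinone cycling (25 species, 23 reactions, stiff solver, 2 h
  horizon, conservation audited to ~1e-10 %), declared in a YAML config;
* per-cell parameterization from single-cell expression: seven rate
  constants scaled by expression ratios to the cohort average (`k_j * E /
  Ebar`), five enzyme pools set from equilibrium protein abundances
  (`P = k_sp R / k_dp`);
* one-at-a-time +-10% finite-difference sensitivity of four redox endpoints,
  `S_ij = (x_i(k_j(1 + d)) - x_i(k_j)) / (d k_j)`, raw and normalized;
* a cohort pipeline: one ODE model per cell, stability filtering, per-patient
  two-tailed Welch's t comparison of malignant vs non-malignant endpoint
  H2O2 (on log10 scale);
* PLSR (NIPALS, PLS1) of the endpoint NADPH:NADP+ ratio on 14 protein
  concentrations with cross-validated Q2 and VIP scores,
  `VIP_j = sqrt(p * sum_a SSY_a w_aj^2 / sum_a SSY_a)`;
* a patient-structured synthetic single-cell cohort generator with known
  ground truth (lognormal expression, patient offsets, implanted malignant
  NQO1 up-shift, expression-dependent dropout).

## Worked example

The `analysis/` directory is a numbered workflow over the package API.

```sh
Rscript analysis/01_simulate_cohort.R    # synthetic 10-patient cohort
Rscript analysis/02_baseline_dynamics.R  # average-cell kinetics + audit
Rscript analysis/03_sensitivity.R        # +-10% sensitivity spectrum
Rscript analysis/04_cohort_comparison.R  # 1000 per-cell models + Welch tests
Rscript analysis/05_plsr.R               # class-wise PLSR / VIP
```

Output of a run of this workflow:

```
cohort: 1000 cells, 35 genes, 10 patients
realized dropout rate: 0.304 (design 0.30)
realized malignant/non-malignant NQO1 mean ratio (pre-dropout): 4.04

drug-free cytosolic H2O2: 1.56e-10 M
2 h endpoint under 5 uM drug: H2O2 5.59e-09 M (36x baseline),
  NADPH:NADP+ 8.3, Trx-SH:Trx-SS 31.4, GSH:GSSG 3036
max moiety drift over 2 h: 1.01e-10%

top normalized H2O2 sensitivities (|(dx/x)/(dk/k)| at 2 h):
     k29 k_prx_ox    k_gpx    k_cat  k_nadph      k30   k_mito      k35
   0.808    0.494    0.392    0.154    0.108    0.058    0.027    0.023
share of normalized H2O2 sensitivities below 1: 1.00

retained 861 / 1000 cell simulations after the stability filter
endpoint H2O2 spans 2.6 orders of magnitude (1st-99th pct)
malignant mean log10 H2O2 exceeds non-malignant in 10 / 10 patients
Welch p < 0.05 in 10 / 10 patients

malignant model: A = 2, R2Y = 0.859, Q2 = 0.926 (n = 437)
  top VIP: NQO1 (3.10), G6PD (1.22), GSR (1.05), GLUD1 (0.88), PRX1 (0.57)
non_malignant model: A = 2, R2Y = 0.770, Q2 = 0.783 (n = 424)
  top VIP: NQO1 (3.21), G6PD (1.22), GLUD1 (0.91), TXNRD1 (0.67), PRX1 (0.48)
```

Reading the numbers: an average cell's cytosolic H2O2 rises ~36-fold under
a 5 uM dose while the five conserved moieties (drug, NADP(H), Trx, Prx,
glutathione) drift by ~1e-10 %, i.e. the integration is mass-consistent.
No single rate constant dominates H2O2 control (all normalized
sensitivities < 1; the largest, NQO1's k29, is below 10x the median of the
top ten) -- oxidative load is set by the network, not one enzyme. Across
the heterogeneous cohort, endpoint H2O2 spans orders of magnitude; because
the generator implants a 4-fold malignant NQO1 up-shift, malignant cells
run hotter in every patient, and the Welch tests detect it. The PLSR
deconstruction recovers the implant: NQO1 carries the top VIP score, with
the NADPH-producing enzymes (G6PD, GLUD1) next -- drug activation and
reductant supply, not the NQO1:catalase ratio, dominate the predicted redox
state.

Tables land in `results/` (`endpoints.csv`, `patient_comparisons.csv`,
`vip_scores.csv`, `plsr_loadings.csv`, ...). See the methods vignette
(`vignettes/redox-single-cell-modeling.Rmd`) for the model, its
assumptions, parameter choices, and what the synthetic cohorts do and do
not demonstrate.

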