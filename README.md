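# frailtymr

Drug-target Mendelian randomization (MR) of blood pressure on
deficit-accumulation frailty.

## The problem

Whether long-term pharmacological blood-pressure (BP) lowering affects
frailty risk is hard to answer observationally: medication use is
confounded by indication, and frailty itself alters both BP and
prescribing. Drug-target MR uses common variants in or near the genes
encoding antihypertensive drug targets (e.g. *ACE* for ACE inhibitors,
*ADRB1*/*KCNH2* for beta-blockers, *CACNA1C*/*CACNB2* for calcium-channel
blockers) as lifelong, randomly allocated proxies for target modulation.
`frailtymr` implements the full analysis for epidemiologists and
statistical geneticists:

* **Frailty index (FI)** — deficits present over items answered, with the
  clinical categories non-frail (FI < 0.12), pre-frail (0.12 ≤ FI ≤ 0.24)
  and frail (FI > 0.24), a modified FI excluding a cardiometabolic item
  subset, and the ≥10-missing-item exclusion rule.
* **Instrument selection** — gene-region windows (±100 kb), p < 5×10⁻⁸,
  MAF > 1%, greedy LD clumping (r² < 0.4 in drug-gene regions, 0.001
  genome-wide), and allele orientation to the BP-raising allele.
* **Genetic risk scores** — the weighted score
  `GRS = (β₁·SNP₁ + … + βₙ·SNPₙ) × n / Σβᵢ`, an unweighted allele count,
  and first-stage diagnostics (r², F).
* **One-sample MR by two-stage predictor substitution (2SPS)** — OLS of
  adjusted BP (mean of readings, +15/+10 mmHg for medicated individuals)
  on the score plus covariates, then a multinomial logit of frailty
  category on the fitted BP, reported as relative risk ratios (RRR) per
  10 mmHg systolic / 5 mmHg diastolic decrease, with the 0.025/0.05
  significance bands.
* **Summary-data MR (SMR) with HEIDI** — top cis-eQTL ratio estimate
  b_xy = b_zy/b_zx, T_SMR = z²_zx·z²_zy/(z²_zx + z²_zy) on χ²(1), the
  0.003 Bonferroni bound for 15 genes, and the HEIDI heterogeneity test
  (weak-instrument and r² > 0.9 exclusions, at most 20 SNPs) with a
  selection-replicating parametric-bootstrap null by default.
* **Synthetic data** — seeded generators for LD-blocked genotypes,
  BP phenotypes with medication masking, liability-model deficits, and
  summary-level eQTL/GWAS scenarios (causal / pleiotropy / linkage /
  null), so every stage is testable without restricted cohort data.

All functions take data frames first and return tibbles; fitted MR objects
support `tidy()`, `glance()` and `autoplot()`.

## Worked example

Simulate the reference cohort, select beta-blocker instruments from a
simulated external GWAS, and run the 2SPS analysis:

```r
library(frailtymr)

cfg <- sim_config(n_individuals = 20000, seed = 7)
genotypes <- simulate_genotypes(cfg)
cohort <- simulate_cohort(genotypes, cfg) |> adjust_bp() |> compute_fi()
descriptives(cohort)
#>   category      n   pct
#> 1 non_frail 13856  69.3
#> 2 pre_frail  4280  21.4
#> 3 frail      1864   9.3

gwas <- simulate_gwas_summary(genotypes, cfg, exposure = "sbp")
ld <- ld_from_panel(genotypes)
inst <- select_instruments(gwas, ld = ld, exposure = "sbp")

fit <- mr_2sps(cohort, build_grs(genotypes, inst$BB),
               exposure = "sbp", drug_class = "BB")
tidy(fit)
#>   drug_class contrast                 rrr ci_low ci_high          p flag
#> 1 BB         pre_frail_vs_non_frail 0.714  0.564   0.905 0.00525    significant
#> 2 BB         frail_vs_non_frail     0.448  0.322   0.623 0.00000185 significant
glance(fit)
#>   exposure drug_class     n r_squared f_stat converged
#> 1 SBP      BB         20000   0.00746   150. TRUE
```

The RRRs are per genetically predicted 10-mmHg decrease in systolic BP:
values below 1 mean genetically lowered BP through the beta-blocker
target genes reduces the risk of that frailty state (the default
synthetic cohort encodes a harmful effect of BP on frailty liability).
The first-stage F of 150 indicates a strong instrument.

The summary-level arm on a simulated cis window:

```r
sc <- simulate_summary_scenario("causal", gene = "KCNH2", seed = 7)
run_smr(sc, tissue = "artery")
#>   gene  tissue top_snp  b_xy    p_smr p_heidi n_heidi_snps passed_heidi
#> 1 KCNH2 artery esnp_15 0.209 1.09e-23   0.890           13 TRUE
```

`p_smr` tests the expression–outcome association; `passed_heidi` means the
heterogeneity test found no evidence that the signal is linkage of
distinct causal variants rather than a single shared one.

`run_pipeline(sim_config(seed = 7), out_dir = "report")` chains every
stage (both exposures, all drug classes including an ARB-like class with
no proxy, plus per-gene SMR) and writes TSV/JSON reports; a thin CLI
wrapper lives at `inst/cli/frailtymr-pipeline.R`.

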