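# ddrsim — Dental Diet Risk Score modeling and in-silico dietary simulation

Diet is a central determinant of oral health: free sugars drive caries,
acidic beverages erode enamel, and phytochemical-rich, fiber-dense foods are
protective. General-purpose dietary indices — the Mediterranean Diet
Adherence Screener (MEDAS, 0–14), the Dietary Phytochemical Index (DPI,
0–100) and the Healthy Eating Index (HEI, 0–100) — were not designed to
capture dental risk. `ddrsim` implements a theoretical **Dental Diet Risk
Score (DDRS)** that integrates the four oral-health-relevant dietary
pathways on a 0–100 scale,

```
DDRS = 0.40·S + 0.20·A + 0.25·(100 − K) + 0.15·(100 − Q)
```

where S = free-sugar exposure, A = acidic-beverage exposure,
K = protective-food intake and Q = overall diet quality (each 0–100,
weights configurable), and provides the full in-silico machinery to study
how DDRS aligns with MEDAS, DPI and HEI:

* a **seed-reproducible Monte Carlo generator** of dietary profiles: a
  latent diet-quality factor `H ~ Beta(a, b)` couples beta-distributed
  components (shapes within α 2–5, β 3–6, emulating NHANES-like skew) to the
  three indices via convex mixtures, so every value respects its scale by
  construction; the shipped parameters were calibrated once by grid search
  against the headline correlations and variance shares and frozen as a
  versioned fixture;
* **index normalization** onto a common 0–100 scale (MEDAS × 100/14; DPI and
  HEI pass through);
* **Pearson correlations** with Fisher-z confidence intervals,
  **covariance-based variance decomposition** of the composite
  (`share_i = 100·Cov(term_i, DDRS)/Var(DDRS)`, summing to 100 exactly even
  for correlated components), **scenario analysis** (healthy / unhealthy /
  mixed dietary patterns with medians, IQRs, Welch t and Cohen's d),
  **one-at-a-time ±20% weight-sensitivity (tornado) analysis** and the
  dedicated 0.30 → 0.50 sugar-weight experiment, and **convergence
  diagnostics** on nested subcohorts;
* a one-call pipeline `run_study()` writing deterministic CSV/JSON
  artifacts, plus a thin CLI (`inst/scripts/ddrs-cli.R`) with
  `simulate / score / analyze / scenarios / sensitivity / converge /
  run-all` subcommands.

Intended users: nutrition-epidemiology and dental-public-health researchers
exploring composite diet-risk constructs before clinical validation data
exist. The DDRS is a theoretical construct; nothing here validates it
against caries or periodontal outcomes.

## Worked example

```r
library(ddrsim)
report <- run_study(run_config(seed = 42))
print(report)
```

```
DDRS in-silico study report

DDRS-index correlations (Fisher-z 95% CI):
 index      r ci_low ci_high p_value     n
 medas -0.641 -0.652  -0.629       0 10000
   dpi -0.685 -0.695  -0.675       0 10000
   hei -0.556 -0.569  -0.542       0 10000

Variance shares (%):
 share_S share_A share_K share_Q
    41.7    18.2    27.8    12.3

Scenario DDRS summaries:
  scenario    n median_ddrs iqr_low iqr_high mean_medas mean_dpi mean_hei
   healthy 2000        27.0    22.5     31.4       92.8     90.7     82.8
 unhealthy 2000        76.3    71.3     81.0        9.0     11.7     27.1
     mixed 2000        50.1    44.9     55.2       54.5     24.9     64.7

Healthy vs unhealthy: t = -190.7, p < 0.001, Cohen's d = -6.03

Weight sensitivity (mean DDRS swing under +/- 20% ):
 component weight_low weight_high mean_ddrs_low mean_ddrs_high delta_range
         S       0.32        0.48        32.591         37.778       5.187
         K       0.20        0.30        36.147         34.223       1.924
         A       0.16        0.24        35.885         34.484       1.400
         Q       0.12        0.18        35.508         34.862       0.646

Sugar weight 0.30 -> 0.50: +20.3% change in mean DDRS
Convergence: stabilized at n = 3000
```

Reading the output: DDRS is inversely correlated with all three indices —
most strongly with DPI (phytochemical-rich diets align best with low
theoretical dental risk), then MEDAS, then HEI. Sugar exposure carries the
largest variance share (~42%) and the widest tornado bar, i.e. it is the
dominant determinant of the score; protective foods come second. The three
scenario cohorts separate cleanly (healthy median ≈ 27, mixed ≈ 50,
unhealthy ≈ 76), and all summary statistics stabilize well before the
10,000-profile production sample size.

Individual stages are available directly:

```r
cohort <- generate_profiles(calibrated_generator_config())
cohort$ddrs <- score_cohort(cohort, weight_config())
index_correlations(cohort, cohort$ddrs)
variance_decomposition(cohort)
tornado_analysis(cohort)
summarize_scenarios(cohort)      # threshold-based classification instead
```

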