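# relapsemarkers

Computational and fNIRS markers of relapse risk in alcohol use
disorder (AUD).

About half of hospitalized AUD patients relapse within six months of
discharge, and clinical scales alone predict this poorly. One line of
work asks whether *task-derived* markers measured during
hospitalization do better: risk preference estimated from gambling
choices by computational modeling, and prefrontal activation measured
with functional near-infrared spectroscopy (fNIRS) during an emotional
go/no-go task. `relapsemarkers` implements that analysis end to end as
a reusable, tested R package:

* **Risk-preference model** — prospect-theory subjective value
  `SV = w(p) · u(x)` with the one-parameter Prelec weighting
  `w(p) = exp(−(−ln p)^γ)` and power utility `u(x) = (x/x_max)^λ`
  (λ < 1 risk-averse, λ = 1 neutral, λ > 1 risk-seeking), a softmax
  choice rule with inverse temperature τ, and bounded multi-start
  maximum-likelihood fitting per subject, with catch-trial attention
  QC. Includes the task-schedule builder (120 main + 8 catch trials in
  3 sessions) and a generative agent.
* **fNIRS integral-mode pipeline** — 5-s moving-average smoothing,
  deterministic artifact-channel rejection (flatline / spikes /
  cardiac-band rhythmic power), linear inter-baseline correction
  anchored on the last 10 s of the pre- and post-task periods,
  integral oxy-Hb per region (frontopolar, left/right frontotemporal
  over channels #22–52), and the emotional-minus-neutral contrast.
* **Behavioral scoring** — emotional go/no-go (false alarms, omissions,
  hit RT), n-back (percent correct, RT per load), verbal fluency
  (unique-word count).
* **Group statistics & prognosis** — Mann-Whitney U (exact for small
  tie-free samples) / Student's t / chi-squared per variable, Spearman
  correlations, and a standardized binomial logistic regression with
  Box-Tidwell linearity check, Wald CIs on odds ratios, and in-sample
  sensitivity/specificity.
* **Synthetic cohort generator** — 24 abstainers / 17 relapsers with
  covariates, choices, behavioral logs and multichannel fNIRS
  recordings drawn from distributions calibrated to the published
  group statistics, with ground truth stored separately so recovery
  tests cannot leak.

## Worked example

```r
library(relapsemarkers)

cohort <- generateCohort(cohortConfig(), seed = 901)   # 41 subjects
fits  <- fitCohortRiskModels(choices(cohort))
acts  <- processCohortRecordings(cohort)$activations
sm    <- buildSubjectSummary(covariates(cohort), acts,
                             behaviorLogs(cohort), fits)
report <- runGroupAnalysis(sm)
report$risk
#>   variable           test statistic    p.value       abstainers        relapsers
#> 1   lambda mann_whitney_u     123.5 0.03424994 0.22 (0.15-0.39) 0.47 (0.29-0.66)
#> 2    gamma mann_whitney_u     150.0 0.15684575 1.10 (0.82-1.37) 0.96 (0.67-1.14)
```

Read: in this synthetic cohort the fitted utility sensitivity λ is
about twice as high in relapsers (median 0.47 vs 0.22, Mann-Whitney
p = 0.034) — both groups risk-averse, relapsers less so — while the
probability-weighting parameter γ shows no group difference, matching
the structure the generator injects. `report$fnirs` likewise shows the
relapse group's right-frontotemporal emotional-minus-neutral contrast
below the abstainers' (medians −51 vs +42 in the same run,
p = 0.0014), and `report$logistic$coefficients` gives the standardized
odds ratios of the six-predictor prognosis model. Any single cohort of
41 is noisy, of course: across seeds the λ comparison lands below
p = 0.05 in only about half of replicates (see the methods vignette).

The same run as a one-liner with a report bundle (CSV tables,
`summary.json`, log, manifest) on disk:

```r
runPipeline(pipelineConfig(seed = 901), outDir = "report")
```

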