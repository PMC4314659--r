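# sharktag

Longevity estimation for sharks from long-term tag-recapture data.

Published longevity estimates for many coastal sharks come from von
Bertalanffy growth-curve fits, which are easily biased by undersampling of old
individuals. A recaptured tagged shark gives a harder bound: its age at
recapture is at least its estimated age at tagging plus its time at liberty.
`sharktag` implements that analysis for fisheries biologists working with
tagging-program data:

* **Growth-curve backtransformation.** For a shark of fork length *L_t* at
  tagging, the von Bertalanffy growth function (VBGF)
  *L(t) = L&infin;(1 &minus; e^(&minus;k(t &minus; t&#8320;)))* is inverted to

  Age = ln(1 &minus; L_t / L&infin;) / (&minus;k) + t&#8320;

  using species- and sex-specific parameters (L&infin;, k, t&#8320;) supplied
  as a registry file. Age at recapture is the backtransformed age at tagging
  plus time at liberty (days / 365.25).
* **Vertebral band-pair ageing.** Unanimous reader band counts are converted
  to direct age estimates as *count &minus; 1.5* under the standard winter
  deposition schedule (birth band at parturition, second band at the first
  winter six months later, annual bands thereafter).
* **Paired comparison.** The two ageing routes are compared with a two-sided
  paired t-test, *t = mean(d) / (sd(d)/&radic;n)*, *df = n &minus; 1*, with
  the Student tail probability computed from the regularized incomplete beta
  function.
* **Mark-recapture simulator.** A generative model of a tagging study —
  individual lognormal heterogeneity in L&infin; and k, Gaussian length
  measurement error (precise vs angler-estimated), annual tag shedding and
  annual recapture — produces pipeline-ready CSVs with known truth, for
  recovery experiments and for asking how many long-liberty recaptures a
  study design can expect.

The package ships the eight long-term recaptures of a South Carolina longline
shark tagging program (five *Rhizoprionodon terraenovae*, three *Carcharhinus
acronotus*) as plain-CSV example data. The growth-curve parameters used to
backtransform those species in the source studies are external inputs; the
bundled registry `vbgf_params_synthetic.yaml` contains synthetic illustrative
values so the examples run end to end.

## Worked example

```r
library(sharktag)

out <- run_analysis(
  tags_path        = sharktag_example("tags.csv"),
  recaptures_path  = sharktag_example("recaptures.csv"),
  params_path      = sharktag_example("vbgf_params_synthetic.yaml"),
  band_counts_path = sharktag_example("band_counts.csv"),
  out_dir          = "reports")

summarize_liberty(out$records, "R. terraenovae")
```

The five *R. terraenovae* recaptures give `n = 5`, times at liberty from
7.68 to 13.96 years, mean 10.14 and SD 2.77 — reported (1-decimal, half away
from zero) as 7.7–14.0 years, mean 10.1. `reports/table1.csv` holds the
per-recapture table (growth, days and years at liberty, backtransformed and
direct ages; angler-estimated lengths starred, missing cells `-`),
`table2.csv` the per-species/sex longevity maxima, and `summary.txt` the
plain-text study summary.

Comparing the two ageing routes on the published per-recapture table (four
sharks have both estimates):

```r
pub   <- read.csv(sharktag_example("table1_published.csv"), na.strings = "")
pairs <- pub[!is.na(pub$age_direct), ]
paired_t_test(pairs$age_recap_bt, pairs$age_direct)
#> Paired t-test: backtransformed vs direct age
#>   n = 4 pairs, mean difference = 1.750 yr (sd 0.772)
#>   t = 4.531, df = 3, two-sided p = 0.0201 (significant at alpha = 0.05)
```

Backtransformed ages exceed direct vertebral ages by 1.8 years on average —
consistent with backtransformation returning the *average* age-at-length,
while an individual shark may be younger or older. The simulator demonstrates
exactly this mechanism:

```r
cfg <- simulation_config(5000, vbgf_params("R. terraenovae", "male", 900, 0.5, -1),
                         cv_Linf = 0.1, sd_measured = 0, sd_angler = 0,
                         annual_retention = 1, annual_recapture = 0.2,
                         study_years = 10, seed = 14)
recovery_experiment(cfg)   # nonzero backtransformed-age bias; direct ages exact
```

See the methods vignette (`vignettes/tag-recapture-longevity.Rmd`) for the
model, the band-deposition arithmetic, the simulator's event ordering and all
numerical conventions.

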