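# prodsuit

Bayesian production–environmental suitability modelling for coastal
seaweed harvests.

Edible seaweed production along a coastline declines under both
measurable environmental variation and diffuse anthropogenic pressure.
`prodsuit` is for quantitative ecologists and fishery analysts who want
to decompose a multi-decade annual production series into those two
parts: it fits a saturating response of production to an additive
environmental-suitability index while estimating, year by year, a latent
"human-induced disturbance" state.

## The model

Production $Y_t$ (thousand tonnes) follows a Michaelis–Menten-form curve
in the suitability index $ES_t$:

$$Y_t \sim N\!\left(\frac{V}{1+K/ES_t},\ \delta\right), \qquad
ES_t = \frac{1}{HD_t} + \frac{a}{R_t} + \frac{b}{C_t} + \frac{c}{T_t} +
\frac{d}{W_t} + e\,S_t + f\,N_t + g\,Q_t,$$

with $V$ the maximum production, $K$ the half-saturation suitability,
and seven mean-normalized covariates: rainfall $R$, seawater CO₂ $C$,
sea-surface temperature $T$, typhoon count $W$ (disturbances, entering
reciprocally), solar radiation $S$, water nutrients $N$ and water
quality $Q$ (benefits, entering linearly). The latent disturbance $HD_t$
starts at 1 and follows a Gaussian random walk,
$HD_t \sim N(HD_{t-1}, \tau)$, which acts as a smoothness prior.
Posterior sampling is by an adaptive Metropolis-within-Gibbs sampler
written in C++ (conjugate updates for $V$ and both precisions; adaptive
random-walk updates, plus two joint ridge moves, for the rest).

Around the fit the package provides factor-contribution percentages, a
decline decomposition (percentage production loss per percentage
suitability loss, period by period), two-period breakpoint trend
comparison of the disturbance trajectory, a seeded synthetic-study
generator, and a CSV pipeline runner
(`inst/scripts/run-pipeline.R` is a thin command-line wrapper).

## Worked example

```r
library(prodsuit)

sim <- psm_simulate(sim_config(seed = 1))      # 28-year synthetic study
fit <- psm(sim$production, sim$covariates,
           control = psm_control(iterations = 50000, thin = 10), seed = 1)
fit
#> Bayesian production-environmental suitability model fit
#>   years 1985..2012, 2500 retained draws (1 chain)
#>   posterior means: V = 385.425 kt, K = 2.107, delta = 31.141, tau = 0.8536
#>   effects: a=0.078, b=0.151, c=0.080, d=0.036, e=0.080, f=0.096, g=0.124
```

The generating values were $V = 304.5$, $K = 1.008$: the posterior means
sit high because $V$ and $K$ are only weakly identified from 28 years
that never push the curve deep into saturation (the credible intervals
cover the truth; see the vignette). The estimated disturbance trajectory,
by contrast, tracks the generating one at $r > 0.95$.

Evaluating the fitted curve of the published national analysis
($V = 304.508$ kt, $K = 1.008$) at its reported suitability anchors
decomposes the decline:

```r
decline_decomposition(
  data.frame(year = c(1990, 1997, 2004, 2011),
             es   = c(2.103, 0.875, 0.555, 0.459)),
  V = 304.508, K = 1.008)
#>  year_start year_end es_start es_end es_decrease es_decrease_pct y_start y_end
#>        1990     1997    2.103  0.875       1.228            58.4     206 141.5
#>        1997     2004    0.875  0.555       0.320            36.6     141 108.1
#>        2004     2011    0.555  0.459       0.096            17.3     108  95.3
#>  y_decrease y_decrease_pct sensitivity_ratio_pct
#>        64.3           31.3                  53.5
#>        33.4           23.6                  64.5
#>        12.9           11.9                  68.7
```

Read row 1: between 1990 and 1997 suitability fell 58.4% and predicted
production fell 31.3% (64,300 tonnes), so production lost 53.5% of a
percentage point per percentage point of suitability lost. The rising
ratio (53.5 → 68.7%) says production grows ever more sensitive to further
suitability loss as the curve leaves saturation. Factor contributions
from the fitted coefficients:

```r
round(contribution_percentages(reference_estimates()[letters[1:7]]), 1)
#>    a    b    c    d    e    f    g
#> 13.2 15.9 13.5  4.4 13.0 33.6  6.4
```

water nutrient level ($f$, 33.6%) dominates, typhoons ($d$, 4.4%) matter
least.

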