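# RDItools

Direct, quantitative comparison of lymphocyte receptor repertoires by their
V(D)J gene-segment usage.

High-throughput AIRR-seq experiments summarize a B- or T-cell repertoire as
counts per gene segment (V, D, J, or specific rearrangements). Comparing two
such profiles naively — say, Euclidean distance between frequency vectors —
confounds biology with sequencing depth: shallower repertoires look
artificially distant because their frequency estimates are noisier. RDItools
implements the **Repertoire Dissimilarity Index (RDI)**, a non-parametric
distance that removes this depth dependence, together with a simulation-based
calibration that converts raw RDI scores into interpretable units (average
fold change in gene usage). It is aimed at immunologists and computational
biologists who already have gene-annotated rearrangement tables (e.g. from
IMGT/HighV-QUEST, pRESTO, Change-O) and want to quantify how different two
repertoires are.

## The metric

For repertoires with feature-count vectors $x^{(1)},\dots,x^{(K)}$, each
RDI realization

1. subsamples every repertoire without replacement (multivariate
   hypergeometric) to the common depth $m$ (by default the smallest
   repertoire total),
2. tallies counts per feature,
3. normalizes each vector to a fixed total $n = 500$ and optionally applies
   the ArcSinh transform $\operatorname{asinh}(x) = \ln(x + \sqrt{x^2+1})$,
4. computes the Euclidean (root-mean-square) deviation between every pair,

and the final RDI is the mean over 100 such realizations. Untransformed, the
RDI grows with the average absolute *percent* change in gene frequencies;
with the ArcSinh transform it tracks the average absolute *log2 fold*
change, giving rare segments equal footing with prevalent ones.

Raw RDI values depend on $m$, so they are interpreted through simulation: a
baseline probability vector $P_\text{base}$ is perturbed on the log2 scale,

$$P_\text{fc} = 2^{\log_2 P_\text{base} + R}, \qquad
  R_i \sim \mathcal N(0, \sigma^2),$$

renormalized, and used to draw multinomial datasets matched to the real
data's size. A monotone smoothing spline of mean RDI against the realized
average deviation $\overline{|\log_2(P_\text{fc}/P_\text{base})|}$ converts
observed RDI values into average fold changes (`rdiToFold`), and the spline
residuals give local reference distributions — the **RDI ladder** — for
judging whether an observed distance exceeds sampling noise.

## Worked example

```r
library(RDItools)

## three perturbed + three baseline repertoires, 5000 sequences each,
## over a 50-segment V-gene pool; ground truth is recorded per repertoire
pBase <- defaultBaseline(50)
reps  <- simulatePerturbedSet(pBase, sigmas = c(0.3, 0.6, 1.2),
                              nSeq = 5000, nBaseline = 3, seed = 42)
repertoireTruth(reps)
#>   repertoire_id true_log2fc true_pct_change
#> 1  perturbed_01   0.2909559        18.44828
#> 2  perturbed_02   0.4692225        32.06500
#> 3  perturbed_03   0.9726174        67.48404
#> 4   baseline_01   0.0000000         0.00000
#> ...

## ArcSinh-transformed RDI, 100 subsampling iterations
rdi <- calcRDI(reps, RDIParams(), seed = 43)
round(rdiValues(rdi)[1:3, 4:6], 3)
#>              baseline_01 baseline_02 baseline_03
#> perturbed_01       2.041       1.806       2.203
#> perturbed_02       3.055       3.036       3.176
#> perturbed_03       5.296       5.346       5.455

## calibrate RDI -> average log2 fold change on simulations matched to
## this table, then convert the observed distances
cal <- buildCalibration(reps, RDIParams(), nPerturb = 300,
                        nBaseline = 20, seed = 44)
obs <- rowMeans(rdiValues(rdi)[1:3, 4:6])
data.frame(mean_rdi = round(obs, 3),
           estimated_log2fc = round(as.numeric(rdiToFold(cal, obs)), 3),
           true_log2fc = round(repertoireTruth(reps)$true_log2fc[1:3], 3))
#>              mean_rdi estimated_log2fc true_log2fc
#> perturbed_01    2.017            0.186       0.291
#> perturbed_02    3.089            0.496       0.469
#> perturbed_03    5.366            1.055       0.973
```

The estimated average log2 fold changes recover the recorded ground truth:
e.g. `perturbed_03` was built with an average absolute perturbation of 0.97
log2 units (~2-fold per gene on average) and converts back to 1.06. The
ladder gives reference levels — here, the RDI one should expect for
repertoire pairs differing on average by 1×, 1.2×, 1.5× and 2× per gene:

```r
makeLadder(cal, c(0, log2(1.2), log2(1.5), 1))
#> RDILadder (log2fc): 4 entries
#>  deviation mean_rdi    sd_rdi
#>  0.0000000 1.446803 0.2039589
#>  0.2630344 2.265166 0.2039589
#>  0.5849625 3.431428 0.2828418
#>  1.0000000 5.135078 0.3781891
```

An observed RDI of ~1.4 between two of these repertoires would be exactly
what resampling noise produces for identical repertoires at this depth
(`nullTailFraction(cal, 1.4)` returns 0.62: well inside the null), while
5.1 indicates an average 2-fold
difference per segment.

Real data enter through `readAIRR()` + `tabulateFeatures()`, which parse
AIRR-style rearrangement TSVs and collapse IMGT calls (`IGHV1-2*02` →
gene `IGHV1-2` or family `IGHV1`; ambiguous multi-assignments are dropped).
A command-line interface wrapping the same functions lives at
`inst/scripts/rdi_tool.R` (subcommands `tabulate`, `rdi`, `simulate`,
`calibrate`, `convert`, `ladder`; see the file header).

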