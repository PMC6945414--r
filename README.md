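# concordROC

Partial-curve evaluation of classifiers and diagnostic tests, built around
the **concordant partial AUC** and the **partial c statistic**.

## The problem

The ROC curve r(x) plots the true positive rate (sensitivity) against the
false positive rate as a decision threshold sweeps over classification
scores, and the area under it (AUC) equals the c statistic: the proportion
of positive–negative pairs the score ranks correctly, with ties counted as
one half,

    c = (1/PN) · Σ_j Σ_k H(g(p_j) − g(n_k)),   H(0) = 0.5.

With imbalanced, low-prevalence data only part of the curve matters — high
specificity on the left side — and the classical *partial* AUC over an FPR
range,

    pAUC = ∫_{x1}^{x2} r(x) dx,

keeps only the vertical (sensitivity) perspective: it ignores actual
negatives except as range bounds and loses the connection to concordance.
`concordROC` implements the symmetric repair. For a partial curve with FPR
range [x1, x2] and TPR range [y1, y2]:

- the **horizontal partial AUC** `pAUC_x = ∫_{y1}^{y2} (1 − r⁻¹(y)) dy`
  (average specificity over the range),
- the **concordant partial AUC** `pAUC_c = ½·pAUC + ½·pAUC_x`,
- the **partial c statistic** `c_Δ`, the pairwise-ranking statistic over the
  vertical and horizontal stripes of the P×N concordance matrix selected by
  the partial curve, with fractional instance weights where a boundary cuts
  through an instance's step.

These satisfy, to machine precision on empirical curves,

    pAUC_c = c_Δ   per partial curve, and
    Σ_i (pAUC_c)_i = AUC = c   over any spanning, non-overlapping partition,

so a partial region of an ROC plot can be summarized with the same
concordance interpretation as the whole AUC. The package also provides the
concordance matrix itself (whose concordant/discordant border *is* the
empirical ROC curve), the local c statistic, normalized partial measures,
McClish's standardized partial area (sPA), average precision in both class
orientations (AP+/AP−), a binormal score simulator with closed-form AUC for
calibration, staircase fixtures, score-table I/O and a command-line tool.

## Worked example

```r
library(concordROC)

d <- scored_dataset(scores = c(0.9, 0.7, 0.4, 0.2),
                    labels = c(1, 0, 1, 0))
compute_report(d, fpr_boundaries = c(0, 0.5, 1))
```

```
Partial-curve measure report
 i          FPR          TPR  pAUC pAUCc pAUCx c_delta    sPA
 1 [0.00, 0.50] [0.00, 1.00] 25.0% 50.0% 75.0%   50.0%  66.7%
 2 [0.50, 1.00] [1.00, 1.00] 50.0% 25.0%  0.0%   25.0% 100.0%
sums: pAUC = 75.0%, pAUCc = 75.0%, pAUCx = 75.0%, c_delta = 75.0%
whole: AUC = c = 75.0%; AP+,- = 83.3%, 83.3%
```

Reading the first row: over FPR ∈ [0, 0.5] the curve reaches TPR 1, the
average sensitivity on the range is 50% (pAUC 25% of a 0.5-wide strip) and
the average specificity over the matching TPR range is 75%; their
concordant combination, 50%, equals the partial c statistic and is exactly
the first part's contribution to the whole AUC = c = 75%. The two pAUC_c
rows sum to the AUC, which the plain pAUC column does not do on its own
interpretable scale.

The same pipeline runs from the shell:

```sh
Rscript inst/cli/concordroc simulate --p 50 --n 150 --seed 7 --out scores.tsv
Rscript inst/cli/concordroc evaluate --scores scores.tsv \
    --boundaries 0,0.33,0.66,1 --format tsv --out report.tsv
```

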