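# carniMark

Taxon-specific classification of carnivore tooth marks from RGB
microscope images, for taphonomists asking *who chewed this bone*:
crocodile, hyena, leopard or lion. Small, unbalanced reference
collections make ordinary deep learning fragile here, so the package
implements two few-shot regimes over one shared transfer-learning
architecture, plus the decision rule used to attribute marks on fossil
specimens.

* **FSSL** — supervised few-shot learning: class-balanced *n*-way
  *k*-shot mini-batches train a classification head by ordinary
  supervised descent over a frozen convolutional feature extractor.
* **MAML** — model-agnostic meta-learning: episodic training where the
  head adapts to each episode's support set by inner-loop gradient steps
  `θ' = θ − α∇L_support(θ)` and the outer loop descends the
  meta-gradient `∇_θ L_query(θ')`, differentiated through the inner
  steps (second order by default).
* **Dual ensemble + reliability rule** — per regime, an
  accuracy-weighted soft vote `p(x) = Σᵢ wᵢ pᵢ(x)` with
  `wᵢ = accᵢ / Σ acc`; a mark is attributed *reliably* only when both
  regime ensembles pick the same taxon with probability > 0.70,
  otherwise it is flagged "interpretation with caution".

Evaluation reports per-class precision/recall/F1/support with macro and
support-weighted averages (`F1 = 2PR/(P+R)`, accuracy =
support-weighted recall). A synthetic tooth-mark bank generator with a
single class-separability dial makes the whole pipeline testable
without the real image bank; a stand-in frozen backbone replaces the
large pre-trained networks, whose weights are not shipped.

## Worked example

```r
library(carniMark)

# a learnably separable synthetic bank: 120 marks per taxon at 64 px
cfg  <- bankConfig(perClassCounts = setNames(rep(120L, 4), taxonLevels()),
                   sizeRange = c(64, 64), separability = 1, seed = 42)
bank <- generateBank(cfg, "bank")
sp   <- stratifiedSplit(bank, splitSpec(seed = 42))   # 70/15/15
length(sp$train)
#> [1] 336

fit <- trainFSSL(buildClassifier("standin", "complex", inputSide = 64, seed = 7),
                 sp$train, sp$val, shotTask = shotTaskPreset("fssl-low"),
                 optimizer = optimizerSpec("adam", 1e-3), maxEpochs = 12, seed = 7)
ev  <- evaluateModel(fit$model, sp$test)
ev$accuracy
#> [1] 1
show(ev$report)
#>                   precision  recall  F1 score  support
#> crocodile              1.00    1.00      1.00       18
#> hyena                  1.00    1.00      1.00       18
#> leopard                1.00    1.00      1.00       18
#> lion                   1.00    1.00      1.00       18
#> accuracy                                 1.00       72
#> macro-average          1.00    1.00      1.00       72
#> weighted average       1.00    1.00      1.00       72
```

The printed table mirrors the standard classification-report layout:
one row per taxon, then accuracy, macro-average (unweighted class mean)
and weighted average (support-weighted mean). On this synthetic bank the
task is easy by construction — the generator's `separability = 1`
endpoint is meant to be learnable; at `separability = 0` the same
pipeline lands at chance (0.25).

The meta-learning regime and the fossil-mark verdict work the same way:

```r
cfgM  <- mamlConfig(innerLr = 0.01, innerSteps = 1,
                    metaOptimizer = optimizerSpec("adam", 1e-3))
fitM  <- trainMAML(buildClassifier("standin", "complex", inputSide = 64, seed = 7),
                   sp$train, sp$val, config = cfgM, maxEpochs = 10, seed = 7)
evM   <- evaluateModel(fitM$model, sp$test, adaptBank = sp$train,
                       shotTask = cfgM$shotTask, seed = 7)
evM$accuracy
#> [1] 0.9722222

fsslEns <- weightedEnsemble(asMemberModel(fit$model,  ev$accuracy))
mamlEns <- weightedEnsemble(asMemberModel(fitM$model, evM$accuracy))
dualVerdict(c(0, 0, 1, 0), c(0, 0, 0.99, 0.01))
#> leopard (reliable: FSSL 1.00, MAML 0.99)
dualVerdict(c(0.43, 0.12, 0.44, 0.011) / 1.001,
            c(0.23, 0.22, 0.53, 0.023) / 1.003)
#> leopard (caution: FSSL 0.44, MAML 0.53)
```

`classifyMarks()` runs a directory of mark images through both
ensembles and writes the per-mark probability/verdict table. A thin
command-line wrapper over these functions (commands `synth`, `split`,
`train-fssl`, `train-maml`, `evaluate`, `ensemble-classify`, `grid`)
is installed at `inst/cli/carnimark.R`.

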