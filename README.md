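# sparseviews

Minimal diagnostic view selection for multi-view specimen identification.

## The problem

Identifying fine-grained taxa — sibling fly or mosquito species in vector
surveillance, for instance — from pinned specimens uses several
standardized photographs per specimen, one per diagnostic anatomical view
(mesonotum, hypopleura, basicosta, wings, ...). Fusing views improves
accuracy, but every encoded view costs a full backbone forward pass, and
not every view carries diagnostic signal. `sparseviews` trains a gated
multi-view classifier that *learns which views to keep*:

* a shared-weight per-view encoder with learnable-query attention pooling
  produces one embedding per view;
* tokens `e_i = v_i + PE_i` (learnable view-specific positional
  encodings) are fused by 8-head self-attention and classified;
* each view passes through a stochastic **Hard-Concrete gate**
  `z_i = clip(σ((logit(u) + α_i)/β)·(ζ−γ) + γ, 0, 1)` with stretch
  ζ = 1.1, γ = −0.1 and temperature β annealed 0.67 → 0.1, which has
  exact point masses at 0 and 1 yet is differentiable in the logits α;
* the training objective is
  `L = L_CE + λ_contrast·L_contrast + λ_sparsity·L_L0`, where
  `L_L0 = Σ_i σ(α_i − β·log(−γ/ζ))` is the expected number of open
  gates and `L_contrast` is a supervised contrastive term (τ = 0.1,
  weight 0.2);
* sweeping `λ_sparsity` (default grid 0.1–0.5) traces the Pareto
  frontier between Top-1 accuracy and FLOPs, and a margin rule picks the
  **recommended configuration**: the fewest-view sweep point within 1
  percentage point of the all-view baseline.

Because no R autodiff stack is assumed, the package ships a
`reference-tiny` encoder and a fully analytic backpropagation engine
(finite-difference-verified in the tests) so the complete method runs on
one CPU in minutes. Production backbones plug in behind the same encoder
contract. A synthetic-data module generates multi-view datasets with a
*planted* informative subset so selection quality is measurable against
ground truth.

## Worked example

```r
library(sparseviews)

# a fly-collection-shaped synthetic dataset: 6 species x 8 views,
# signal planted in views 1-3, 240 train / 60 validation specimens
ds <- generate_dataset(synthetic_spec(seed = 1))

# stage 1: single-view pretraining; the best view is the single-view baseline
pre <- train_single_view(ds, config = desk_train_config(seed = 1))
pre$accuracy_table
#> # A tibble: 8 × 2
#>   view_name accuracy
#>   <chr>        <dbl>
#> 1 view01        66.7
#> 2 view02        55
#> 3 view03        51.7
#> 4 view04        18.3
#> 5 view05        16.7
#> 6 view06        15
#> 7 view07        21.7
#> 8 view08        20

# stage 2: sweep the sparsity weight, warm-starting from the encoder
cfg <- desk_train_config(seed = 1); cfg$eval_every <- 0
tab <- run_sweep(ds, config = cfg, model_factory = function(seed) pre$model)
select_recommended(tab)
#> # A tibble: 1 × 9
#>   lambda retained_views view_count accuracy accuracy_drop      flops flops_saved
#>    <dbl> <list>              <int>    <dbl>         <dbl>      <dbl>       <dbl>
#> 1    0.4 <chr [3]>               3      100           -10 0.00000634        62.5
```

The recommended record retains exactly the three planted views
(`view01 view02 view03`) at 100% validation accuracy — it even beats the
90% all-view baseline (drop −10 pp), the redundant-view dilution effect —
while cutting theoretical encoder cost by 5/8. (Single-view accuracies of
52–67% against a 16.7% chance rate reflect the generator's complementary
design: each informative view resolves only its own sibling-species
pair.) `autoplot(tab)` draws the accuracy–FLOPs
frontier; `autoplot(fit)` of a `train_fusion()` fit draws the per-view
retention-probability trajectories with the selection threshold.

On published sweep tables the same machinery reproduces the printed
arithmetic: an 8-view, 11.31 G baseline gives `flops_total(5, 11.31/8)`
= 7.07 G and `flops_saved_pct(11.31, 7.07)` = 37.49%, and the margin
rule applied to the printed rows returns the 5-part λ = 0.4 row
(see `read_sweep_csv()` + `select_recommended()`).

## Command line

A thin CLI over the same functions lives at `inst/cli/sparseviews`
(subcommands `simulate`, `train-single`, `train-fusion`, `sweep`,
`select`, `predict`, `report`); see `?sv_cli`.

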