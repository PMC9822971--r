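# rfdseg

Rough-fuzzy feature discretization and deep-supervised segmentation for
retinal OCT volumes.

## What it does

Voxel-wise segmentation of fluid lesions in optical coherence tomography
(OCT) — retinal edema area (REA), subretinal fluid (SRF), pigment epithelial
detachment (PED) — is limited by speckle noise and by grey-level redundancy:
an 8-bit slice carries 256 brightness levels, of which only a handful
distinguish tissue categories. `rfdseg` implements a supervised
discretization pre-module that compresses the brightness axis before the
image enters a 3D segmentation network:

1. **Fuzzification.** Fuzzy c-means (fuzzifier m = 2) assigns each pixel a
   membership `u_ij` to each of the M segmentation categories, making each
   category a fuzzy set `A_j` over the image's information decision table.
2. **Rough-fuzzy scoring.** A set of selected breakpoints partitions the
   brightness axis into intervals, inducing an equivalence relation R on
   pixels. The average approximate precision of the rough fuzzy sets,

   ```
   eta_bar = (1/M) * sum_j card(R_* A_j) / card(R^* A_j)
   ```

   (sigma-count cardinalities of the inf/sup approximations over
   equivalence classes), measures how well the intervals preserve the
   category structure; eta_bar = 1 iff every interval is pure.
3. **Genetic breakpoint search.** Binary chromosomes over the candidate
   breakpoints (the sorted unique observed values) are evolved to maximize

   ```
   Fitness = alpha * (N_CB - N_DS) / N_CB + beta * eta_bar,   alpha + beta = 1
   ```

   trading breakpoint parsimony against approximation precision.
4. **Segmentation.** The discretized volume feeds a compact 3D
   encoder-decoder (residual blocks, dual attention on skips, attention
   refinement with hybrid 3^3/5^3 kernels, deep supervision; channels
   16 -> 128) trained with the composite loss
   `L = kappa*L_DSC + gamma*L_CE + lambda*L_max` (defaults 1, 1, 0.5) by
   SGD with momentum. The network and its backpropagation are implemented
   in R (im2col convolutions over BLAS).

The package also ships a seeded layered-retina phantom generator (so every
stage runs without external data) and a full metric suite: Dice, HD95 (both
the scaled-max and percentile conventions), average symmetric surface
distance, sensitivity, specificity.

## Worked example

```r
library(rfdseg)

## a speckled 16x16x16 phantom with its gold mask
ph  <- generate_phantom(phantom_spec(shape = c(16, 16, 16), seed = 7))
tab <- build_decision_table(ph$volume, ph$mask, num_classes = 4,
                            mode = "whole_volume")
u   <- run_fcm(tab)
ga  <- ga_discretize(tab, u, config = ga_config(population_size = 30,
                                                generations = 30, seed = 11))
ga
#> ga_result: 61/202 breakpoints, fitness 0.801023 (eta_bar 0.904027) after 30 generations
```

Of the 202 observed grey levels, 61 cuts suffice to keep the average
approximate precision at 0.904; the fitness balances that precision against
the 70% reduction in breakpoints. Training the compact network on the
discretized phantom memorizes the mask completely:

```r
model <- build_network(network_config(num_classes = 4, depth = 2,
                                      patch_size = c(16, 16, 16)), seed = 3)
run  <- train_network(model, ph$volume, ph$mask, scheme = ga$best_scheme,
                      table = tab, tc = toy_train_config(iterations = 300))
pred <- predict_volume(run$model, ph$volume, scheme = ga$best_scheme, table = tab)
evaluate_segmentation(pred$label, ph$mask, num_classes = 4)
#> metrics_report (hd95 mode: paper )
#>   class present dsc hd95 asd sensitivity specificity
#>  class0    TRUE   1    0   0           1           1
#>  class1    TRUE   1    0   0           1           1
#>  class2    TRUE   1    0   0           1           1
#>  class3    TRUE   1    0   0           1           1
#> macro: dsc 1.0000  hd95 0.0000  asd 0.0000  sens 1.0000  spec 1.0000
```

A DSC of 1 per class means every voxel — including the single-voxel PED
lesion — is labeled correctly on the training phantom; HD95/ASD of 0 mean
the predicted and true surfaces coincide.

The same pipeline is scriptable from a shell:

```sh
inst/cli/rfdseg run --workdir out --seed 7 \
  --phantom.shape 16,16,16 --network.depth 2 --network.patch_size 16,16,16 \
  --train.lr 0.05 --train.grad_clip Inf --train.iterations 300
```

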