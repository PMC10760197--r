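# tnvae

Variational autoencoders (VAEs) are widely used to extract
low-dimensional latent factors from high-dimensional biological time
series — for example spectral features of chronic neural recordings,
where 30 LFP band powers plus total EMG power form a 31-dimensional
feature vector per time bin and the expected latent structure is the
wake / REM / SWS brain-state cycle. A standard VAE selected by
validation loss, however, routinely learns *spurious* features:
latent structure that reflects noise or optimization artifacts, looks
different on every retrain, and therefore cannot be interpreted
scientifically.

`tnvae` implements two countermeasures that both encode the prior
that latent factors evolve smoothly in time, plus the evaluation
machinery to show they work:

- **TN-VAE (Time-Neighbor VAE).** A VAE whose encoder of the
  observation $x_t$ parameterizes the posterior over the *next*
  latent state and whose decoder predicts the next observation. The
  objective is

$$
\mathcal{L} = -\mathbb{E}_{z \sim q_\phi(z_{t+1}\mid x_t)}
\big[\log p_\theta(x_{t+1}\mid z_{t+1})\big]
+ \beta\, \mathrm{KL}\big(q_\phi(z_{t+1}\mid x_t)\,\|\,p(z_{t+1})\big),
$$

  identical to a $\beta$-VAE except that the prediction target is
  $x_{t+1}$ rather than $x_t$ (`predictive = TRUE` vs `FALSE` in
  `vae_config()`).

- **Neighbor Loss (NL).** A model-selection metric on the
  posterior-mean latent trajectory $z_t$:

$$
\mathrm{NL} = \frac{\sum_t \lVert z_{t+1} - z_t \rVert}{\bar z},
\qquad \bar z = \frac{1}{N}\sum_t \lVert z_t \rVert ,
$$

  the summed latent step length normalized by the size of the latent
  manifold. It is scale- and rotation-invariant, needs no labels, and
  is cheap enough to track every epoch. Selecting models by low NL
  (instead of low validation loss) picks representations that match
  the generative structure and reproduce across model instances.

The package also provides ground-truth simulators (a sleep-like
3-state hidden Markov chain with 31-D Gaussian emissions; a noisy
2-D spiral nonlinearly embedded in 31 dimensions; an i.i.d.-shuffled
control), evaluation metrics (silhouette score against ground-truth
clusters, generalized Procrustes *encoding distance* between two
models' latents of the same test data, per-cluster skew/kurtosis
diagnostics), an ensemble training engine over hyperparameter grids
with checkpoint/resume, and three-arm selection comparisons.

The neural network core (MLP encoder/decoder, reparameterized
sampling, hand-derived backpropagation, Adam) is implemented directly
on BLAS matrix operations — no deep-learning framework is required.

## Worked example

```r
library(tnvae)

# simulate a sleep-like feature time series (31-D, 3 hidden states)
ts <- simulate_hmm(hmm_sleep_preset(), n_points = 4000, seed = 42)
print(ts)

# train a small TN-VAE
cfg <- vae_config(n_layers = 2, layer_dim = 50, beta = 1e-4,
                  batch_size = 256, learning_rate = 1e-3,
                  predictive = TRUE, seed = 1)
model <- train_vae(cfg, ts, split_spec(seed = 1), epochs = 60)
print(model)

# evaluate on the held-out terminal test block
test <- test_block(ts, model$split)
traj <- encode_trajectory(model, test)
sil  <- silhouette_score(traj$Z, test$labels[match(traj$t, test$t)])
cat(sprintf("test silhouette vs true states: %.3f\n", sil$score))
cat(sprintf("neighbor loss (per transition): %.4f\n",
            neighbor_loss_normalized(traj)))
```

Output:

```
<labeled_ts> 4000 time bins x 31 features
  labels: 1:1882 2:2034 3:84
<tnvae_config> TN-VAE | layers=2 dim=50 latent=2 beta=0.0001 batch=256 lr=0.001 seed=1
  input dim 31, trained 60 epoch(s)
  final: train 12.5784 | val 12.6842 | val NL 222.7548
test silhouette vs true states: 0.703
neighbor loss (per transition): 0.2939
```

A test silhouette of 0.70 means the 2-D latent encodings separate the
three true hidden states cleanly (1 = perfect separation, 0 = none);
a per-transition NL of 0.29 means consecutive time bins move on
average ~0.3 mean-radii through the latent space — a smooth
trajectory that mostly sits inside state clusters and jumps only at
state transitions.

For ensembles, `run_ensemble()` trains a grid
(`expand_config_grid()`) across seeds, `select_model()` applies a
selection criterion, `ensemble_analysis()` computes the
metric-vs-silhouette and metric-vs-encoding-distance correlations,
and `selection_comparison()` produces the three-arm
(VAE + val-loss, TN-VAE + val-loss, TN-VAE + NL) table.

A command-line front end lives at `inst/cli/tnvae.R`
(`simulate`, `train`, `ensemble`, `select`, `report` subcommands).

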