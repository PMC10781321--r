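# fogbci

Decode four-class motor-imagery EEG into machine commands with a
convolutional LSTM autoencoder and a random forest, and quantify how much
command latency a nearby fog node saves over cloud-only processing.

## Who this is for

Researchers and engineers prototyping brain-computer-interface (BCI)
control of machinery from a 4-electrode consumer headset (electrodes TP9,
AF7, AF8, TP10 of the 10-20 system). A trial is a 4 x S record in
microvolts, labeled with one of four imagined activities — left foot (LF),
left hand (LH), relaxation (RX), mental arithmetic (MA) — that modulate
alpha (8-13 Hz) and beta (>13 Hz) band power through event-related
desynchronization/synchronization. The package is self-contained: a seeded
synthetic generator reproduces that band-gain structure, so the entire
pipeline runs and is tested without any external data.

## The model

An autoencoder is trained to minimise the mean squared reconstruction
error

```
f_enc, f_dec = argmin || X - (f_dec ∘ f_enc) X ||²
```

and only the encoder survives into deployment. The encoder is a
convolutional LSTM along time with the four electrodes as its spatial axis
(20 filters, kernel 2, no padding), whose final 3 x 20 state passes
through a transposed convolution (one 14 x 2 filter, stride 1, no padding)
to give a 16 x 21 *latent image* `h = f_enc(x)`. A random forest (250
trees) classifies the 336 flattened pixels into a command:

```
h = f_enc(x);  C = RF(h)
```

Support vector machine (RBF, C = 1), decision tree (Gini) and gradient
boosting (159 rounds, depth 4) baselines, per-class
precision/recall/F1/accuracy reports, per-pixel Gini (mean decrease in
impurity) importance maps, and a FIFO discrete-event simulation of
sensor-fog-actuator versus sensor-cloud-actuator routing complete the
toolkit. Everything deep-learning is implemented in base R (forward pass,
full backpropagation through time, SGD-with-momentum and Adam optimisers)
and verified against finite
differences in the test suite; the methods vignette
(`vignettes/motor-imagery-decoding.Rmd`) documents every design choice.

## A worked example

```r
library(fogbci)

ds <- generate_dataset(synthetic_spec(n_records = 200, separation = 2, seed = 7))
ae <- train_autoencoder(ds, train_config(epochs = 30, seed = 8))
print(ae)
#> Convolutional LSTM EEG autoencoder
#>   records: 200  samples/record: 512  latent: 16 x 21
#>   epochs: 30  batch: 16  lr: 0.01  seed: 8
#>   training loss: 0.998034 (first) -> 0.997894 (final)

bench <- evaluate_suite(ds, ae$encoder, split_seed = 10)
round(bench$accuracy, 3)
#>    RF   SVM    DT    GB
#> 0.950 0.675 0.825 0.950
```

At this class separation the latent images isolate the four spectral
signatures almost perfectly: the tree ensembles classify nearly every
held-out record while the SVM trails the field — the same ordering the
benchmark is designed to probe. (The reconstruction loss barely moves because a 336-pixel latent
cannot encode 2048 samples of broadband noise; the classifier needs the
spectral envelope, which the encoder's long-memory state carries. See the
vignette.) Each report also carries per-class precision/recall/F1 and the
confusion matrix. Two more one-liners:

```r
double_miss_probability(0.96)   # chance of missing two commands in a row
#> [1] 0.0016
cmp <- compare_architectures(default_fog_topology(), fog_workload(seed = 11))
c(fog = cmp$fog_mean_ms, cloud = cmp$cloud_mean_ms)
#>      fog     cloud
#>  11.77999 107.77999
```

With identical 5 ms classification service at both nodes, proximity alone
(2 ms versus 50 ms links) cuts the mean command round trip by a factor of
about 9.

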