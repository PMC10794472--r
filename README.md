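# passid

Dynamic state-space modeling of photoacoustic (PA) sensor traces for blood
classification.

## The problem

A pulsed laser fired into a whole-blood sample launches an ultrasound wave
whose time profile carries information about the sample's composition (red
blood cell count, hemoglobin, cell size). `passid` treats one detected PA
trace as the impulse response of a linear dynamical system

```
x(k+1) = A x(k) + B u(k)
y(k)   = C x(k)
```

and estimates the triplet (A, B, C) directly from the samples by subspace
identification (block-Hankel past/future projection, SVD order selection,
shift-invariance least squares). Converted to continuous time and rotated to
modal form

```
A' -> [[-1/alpha,  omega_n],        C' -> [c1  c2]
       [-omega_n, -1/alpha]]
```

each trace collapses to four physical features P = {alpha, omega_n, c1, c2}:
the envelope decay constant (seconds), the natural frequency (rad/s), and two
mode-mixing coefficients — the cosine and sine amplitudes of the damped
sinusoid `exp(-t/alpha) (c1 cos(omega_n t) + c2 sin(omega_n t))`. A linear
discriminant classifier over those features separates five blood classes —
healthy female (HF), healthy male (HM), microcytic anemia (A1), macrocytic
anemia (A2), leukemia (L) — and is benchmarked against time-domain,
frequency-domain (1–20 MHz spectral line fit) and ARMA(2,2) feature families.
The fit quality of each model is scored by

```
NRMSE = (1 - ||y - yhat|| / ||y - mean(y)||) * 100%.
```

Because no measured blood traces are deposited, the package ships a synthetic
generator (`simulate_dataset()`) whose class-dependent damped-sinusoid
populations state the documented world (class sizes 10/10/4/4/7, arrivals
6.56/6.59 µs for HF/HM, natural frequencies inside 2.5–3.5e7 rad/s, additive
white Gaussian noise at a target SNR). See the methods vignette
(`vignettes/pa-state-space-modeling.Rmd`) for every modeling decision.

Intended users: biomedical signal-processing researchers evaluating
model-based PA feature extraction, and anyone needing a self-contained,
testable subspace-identification pipeline for decaying oscillatory traces.

## Worked example

```r
library(passid)
cfg <- pa_sim_config(snr_db = 30)          # five classes, 10 ns sampling, 1.2 us window
sig <- simulate_dataset(cfg)[[1]]          # one healthy-female trace
sig
#> <pa_signal> 120 samples, ts = 1e-08 s (fs = 1e+08 Hz), t0 = 6.5e-06 s, label = HF

fit <- identify_ss(sig)                    # subspace identification
fit
#> <pa_ident> order 2 model, NRMSE = 97.24%, 114 samples at ts = 1e-08 s

to_modal(to_continuous(fit$model))$params  # the four features
#> <pa_modal_params> alpha = 3.811e-07 s, omega_n = 2.856e+07 rad/s, c1 = 0.9308, c2 = 0.8975
unlist(sig$meta$true_params)               # generating values, for comparison
#>        alpha      omega_n           c1           c2
#> 3.812064e-07 2.857346e+07 9.331497e-01 8.957168e-01

b <- run_benchmark(cfg, seed = 7)          # 35 train + 20 held-out test
b
#> <pa_benchmark> split = holdout, seed = 7, 35 train / 20 test
#>   TD   accuracy =  85.0%
#>   FD   accuracy =  85.0%
#>   ARMA accuracy =  25.0%
#>   SS   accuracy = 100.0%
b$families$SS$report
#> <pa_class_report> accuracy = 100.0% on 20 samples
#>     predicted
#> true A1 A2 HF HM L
#>   A1  4  0  0  0 0
#>   A2  0  4  0  0 0
#>   HF  0  0  4  0 0
#>   HM  0  0  0  4 0
#>   L   0  0  0  0 4
```

Reading the numbers: the SVD gap selects a second-order model; its impulse
response reconstructs the noisy trace to 97.24% NRMSE (the 30 dB measurement
noise bounds this); the recovered decay constant, frequency and mode-mixing
coefficients match the generating values to well under 1%; and LDA on those
four features classifies all 20 held-out samples, beating every conventional
feature family on the same data.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "pa-ssid.R", package = "passid"))')
Rscript $CLI simulate  --out data/ --seed 42
Rscript $CLI identify  --in data/signal_001.txt --out model.json
Rscript $CLI features  --family ss --in data/ --out features.csv
Rscript $CLI benchmark --seed 7 --out report/
```

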