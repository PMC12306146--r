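---
title: "Methods: spiking networks for interaural phase difference coding"
author: "ipdnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spiking networks for interaural phase difference coding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`ipdnet` is a self-contained laboratory for asking how a small spiking
network can extract the interaural phase difference (IPD) of a pure tone —
the cue animals use, alongside level differences, to localize low-frequency
sounds in the frontal plane. No external data are involved: the stimulus
model *is* the data-generating process, and every experiment in the package
runs from a single integer seed.

## Stimulus and encoding

A tone of frequency $f$ reaches the left ear as $\sin(2\pi f t)$ and the
right ear as $\sin(2\pi f t + \alpha)$, with IPD $\alpha$ drawn uniformly
from $[-\pi/2, \pi/2]$. Each ear is represented by $N_\psi$ "auditory
nerve" channels with preassigned phase lags
$\psi_j = j\pi/(2(N_\psi - 1))$, $j = 0,\dots,N_\psi-1$, so that comparing a
left channel against a right channel can realize any phase difference in
the task range. Channel $(i, j)$ ($i = 0$ left, $i = 1$ right) fires
Poisson spikes with intensity

$$R_{ij}(t) = R_\mathrm{max}\left(\frac{1 + \sin(2\pi f t + i\alpha + \psi_j)}{2}\right)^2,$$

realized as independent per-bin Bernoulli draws with $p = R\,\mathrm{d}t$
(exact for a discrete-time simulation as long as
$R_\mathrm{max}\,\mathrm{d}t \le 1$; the default $600 \times 0.001 = 0.6$).
The endpoints of the $\psi$ grid are included: the uniform-spacing formula
pins $\psi_0 = 0$ and $\psi_{N_\psi - 1} = \pi/2$.

Defaults are $f = 50$ Hz, $N_\psi = 100$, $R_\mathrm{max} = 600$ sp/s,
100 ms stimuli at $\mathrm{d}t = 1$ ms. The stimulus onset phase is fixed
at 0; a per-trial random onset phase would be a one-line change in the
generator but is not part of the study conditions. Time stamps are bin
starts ($t = 0, \mathrm{d}t, \dots$).

## Network and decision rule

The $2N_\psi$ input channels feed all-to-all into $N_h$ leaky
integrate-and-fire (LIF) neurons ($\tau\,\mathrm{d}v/\mathrm{d}t = -v$, unit
threshold, reset to 0) through a dense weight matrix $W_{ih}$, and these
feed a layer of $N_c$ *non-spiking* leaky readout units through $W_{ho}$.
The membrane update is an exponential integrator
($v \leftarrow v e^{-\mathrm{d}t/\tau}$, then inputs, then threshold test),
which is exact for the linear ODE at bin edges and makes the free decay
independent of the step size. Spike-then-reset happens within the same bin
as the inputs that caused it.

The IPD range is divided into $N_c$ equal intervals; the class decision is
the readout unit with the largest time-averaged membrane potential
$\bar v_k$ (log-softmax for training; argmax with lowest-index tie-break
for inference; $+\pi/2$ belongs to the top class so the bins partition the
range), and the IPD estimate is the midpoint of the winning interval.
$\bar v$ averages over the entire stimulus, onset transient included — at
$\tau = 2$ ms the transient is two bins and immaterial.

## Training

Surrogate gradient descent: backpropagation through time where the
derivative of the spike step is replaced by the fast sigmoid
$\beta/(\beta|v - 1| + 1)^2$ with $\beta = 10$ (config-exposed), and the
reset factor is treated as constant in the backward pass. The loss is
cross-entropy plus a firing-rate regularizer: each hidden neuron's
batch-averaged rate $r_m$ contributes
$L_m = ((r_m - r_-)/(r_+ - r_-))^2$ above $r_- = 100$ sp/s (nothing below),
scaled by $c \sum_m L_m / N_h$ with $c = \ln N_c$, the initial
cross-entropy of a uniform predictor — so $r_m = r_+ = 200$ sp/s costs as
much as knowing nothing. Adam (lr $10^{-3}$), batches of 128, 16,384
fresh samples per epoch, 100 epochs. Fresh sampling per epoch is the
default (a fixed-dataset mode exists for ablations); weights initialize
uniformly in $\pm\sqrt{1/\mathrm{fan\,in}}$.

The backward pass is hand-written C++ (no autodiff dependency exists in
this stack, and the pass is 30 lines); it is validated two ways in the test
suite: the fused C++ forward is compared layer-by-layer against a plain-R
reference implementation, and the gradients are compared against central
finite differences on a *smooth* variant of the pass in which the step is
replaced by the sigmoid itself (with the reset product rule included), so
the comparison is against an exactly differentiable function rather than a
piecewise-constant one.

### Dale's law

Sign constraints are implemented by reparameterization: each presynaptic
unit gets a fixed sign and the effective weight is
$\mathrm{sign} \times |m|$ with $m$ the trained magnitude. The constraint
therefore holds *exactly* after every optimizer step — no projection, no
drift. Modes: `balanced` (half of each layer inhibitory, seeded
assignment), `excitatory_only`, `inhibitory_only`, or explicit per-layer
inhibitory fractions. An inhibitory-only input layer propagates no spikes
and classifies at chance, which the tests assert. Dale runs use the same
task, loss, and time constants as the base configuration.

## Decoding error and an honest floor

The evaluation reports accuracy, a confusion matrix, per-neuron hidden
rates, and the mean absolute IPD error in degrees, computed as
$|\hat\alpha - \alpha|$ with $\hat\alpha$ the winning class midpoint. Note
a structural floor: for uniformly drawn $\alpha$, even a perfect classifier
has MAE of a quarter bin width, $(180/N_c)/4 = 3.75°$ at $N_c = 12$.
Trained base models here reach $\approx 4.4°$ (83% accuracy), i.e., within
$0.7°$ of the floor; numbers below $3.75°$ are not reachable by any
midpoint decoder under these conditions.

# Learning delays

Two mechanisms replace the fixed $\psi$ bank with *learned* delays.

## Differentiable delay layer (DDL)

A spike train shifted by a delay $d$ (in bins) is computed by translation
plus two-point linear interpolation: integer $d$ reproduces exact index
shifting; fractional $d$ splits each spike's mass between adjacent bins,
which makes the output differentiable in $d$ (the derivative is the
difference of the two adjacent shifted trains). Inputs are zero-padded so
no mass is lost.

The 36-class task (class angles $-90°$ to $+85°$ in $5°$ steps) is solved
with *delays only*: one fixed delay on the left-ear train (a quarter
period, so every class's compensating delay is nonnegative) and one
learnable delay per class on the right-ear train. Each class filters both
delayed trains through a leaky dendrite ($\tau_m = 2$ ms, unit jumps) and
scores coincidence as $v_i = -\sum_t (u_{1i} - u_{2i})^2$ — a
multiplicative-synapse interaction once the square is expanded. Training is
cross-entropy on the softmax of the (per-bin-averaged, scaled) scores; the
softmax makes the 36-way problem well-posed, and only the delays receive
gradients (weights one, biases zero). Adam with lr 0.1 in bin units —
delay units are bins, so this is a small step; smaller rates converge to
the same delays, slower. At evaluation delays snap to integer bins
(multiples of the minimum delay). With 1 ms bins at 50 Hz one bin of delay
is 18° of phase, so the 5°-step task is *resolution-limited by design*:
trained accuracy lands near 11% (chance 2.8%) with MAE near 17–19°, and
the learned delays form the expected diagonal band
$d_i \approx d_\mathrm{fixed} + \alpha_i/(2\pi f\,\mathrm{d}t)$.

## Single-nonzero-kernel temporal convolution (DCLS-style)

Here delays are per-synapse: every input-to-hidden synapse is a 1D temporal
convolution whose kernel has one non-zero element at a continuous position.
During training the kernel is a *normalized* Gaussian bump of width
$\sigma$ centered on the position (taps always sum to the weight, so mass
is conserved at any position, including clamped boundary positions);
gradients flow into both the weight and the position. $\sigma$ anneals
linearly from 2 bins to 0.25 bins across epochs, and at evaluation the
kernel collapses to a single tap at the rounded position. The input bank
carries *no* preassigned phase delays (all $\psi = 0$; 50 interchangeable
channels per ear so spike counts stay informative); the hidden layer is the
same 8-unit LIF layer, the loss the same cross-entropy + rate regularizer,
12 classes. Kernel length is 25 bins — more than one stimulus period at
50 Hz. Positions initialize uniformly at random over the kernel; position
learning rate is 0.1 (bins), weight learning rate 0.002. Trained models
reach MAE $\approx$ 5–6° and export per-synapse (weight, delay) receptive
fields.

# Analysis of trained networks

**Tuning curves.** Mean responses on an IPD grid over repeated Poisson
draws: firing rate for hidden units, $\bar v$ for outputs; normalized per
neuron to max 1 (the raw curves are kept too — parameter fits use raw
rates so amplitudes stay commensurate with the weights). Silent units are
flagged and excluded from normalization. Trained hidden units consistently
show a high baseline with a localized *dip* at a least-preferred IPD;
output units peak at their own interval.

**Gaussian-dip fits.** $a + b\,e^{-(\alpha - \alpha_i)^2/2\sigma_\alpha^2}$
by trust-region least squares (`minpack.lm`), center initialized at the
curve's argmin, width at three grid spacings; flat curves are flagged
degenerate rather than fit. Hidden units are reordered by fitted dip
center ascending (ties by index) before any weight-structure analysis.

**Rate-based closed form.** A LIF neuron driven by constant suprathreshold
drive $r$ (threshold units) fires at
$1/(t_\mathrm{refrac} + \tau\ln(r/(r-1)))$, zero below threshold;
$t_\mathrm{refrac} = \mathrm{d}t$ in this discrete simulation. The drive
trace fed to this formula is the rate-weighted input current converted to
threshold units, $r_h(t) = c_h(t)/(1 - e^{-\mathrm{d}t/\tau})$ with
$c_h(t) = \sum_j W_{ih}[j,h] R_j(t)\,\mathrm{d}t$ the expected per-bin jump
— the constant-drive equivalent of the jump process. The test-suite oracle
integrates a LIF at $\tau/400$ with an explicit refractory hold of
$\tau/20$ and requires 5% agreement; a coarse simulation whose only
refractoriness is the bin itself shows ceil-quantized intervals and is not
a fair probe of the formula.

**Ricker fit and the six-parameter reduced model.** The reordered
$W_{ho}$ is summarized by
$a(1 - (\delta/\sigma_\delta)^2)e^{-\delta^2/2\sigma_\delta^2} + b$ with
$\delta = o - N_c h/N_h$. Combining one shared Gaussian dip
($a, b, \sigma_\alpha$; centers fixed at $\alpha_i = -\pi/2 + i\pi/N_h$)
with the Ricker ($a, b, \sigma_\delta$) yields a six-parameter model of the
whole network — against $N_\psi N_h + N_h N_c = 896$ for the full model at
(100, 8, 12) by the conventional count (note this counts $N_\psi$ rather
than $2N_\psi$ input rows). Two caveats we quantify in the tests: (i)
12-way argmax decisions sit close to noise — the full model agrees with
itself only ~79% across independent Poisson draws of the same stimuli, so
exact-argmax agreement between the reduced and full models is bounded by
trial noise; against the trial-averaged full decision the reduced model is
within one class of the full model >99% of the time but exactly equal only
~54%, partly because the $\alpha_i$ tiling formula is asymmetric while
trained dip centers tile symmetrically; (ii) trained $W_{ho}$ here keeps a
positive far-field that the Gaussian-enveloped Ricker cannot represent, so
its $R^2$ is moderate (~0.5). The reduced model is an excellent
*qualitative* account (flat-at-extremes output curves, diagonal structure)
and a near-miss exact classifier.

**Tensor component analysis.** Hidden spike trains are smoothed with a
normalized Gaussian kernel (default $\sigma = 3$ bins, truncated at
$4\sigma$) and arranged neurons × time × trials; nonnegative CP
decomposition is computed by hierarchical alternating least squares with
columnwise updates, best of 5 seeded restarts, stopping when the relative
reconstruction error changes by <1e-6 or after 500 sweeps. Neuron and time
columns are returned unit-norm with scale absorbed into trial factors. The
HALS updates never increase the reconstruction error, which the tests
assert, along with planted rank-1 recovery.

# Reproducibility and problem sizes

Every stochastic stage derives a child seed from one master seed and a
stage label, so adding stages never perturbs earlier draws, and
`train -> eval -> analyze` is bit-reproducible. Spike generation and the
training pass run in C++ (a counter-based xoshiro256++ stream, independent
of R's RNG); at the default conditions one training epoch costs about 2 s
on one CPU core, a full 100-epoch base run about 3–4 minutes.

The test suite trains one full base model (100 epochs, staged 30 + 70 from
one trace so the reduced-run and full-run claims share an optimization
history), one DDL model, one reduced-epoch DCLS model, and reduced-epoch
Dale pairs; the acceptance script re-trains everything from scratch at the
sizes stated in its header (three seeds for the base model; reduced epochs
for the Dale contrast and the delay learners, whose training lengths are
not part of the stated study conditions). What passing these simulations
shows is internal consistency of the implementation under the stimulus
model's idealizations — Poisson inputs, a single fixed frequency, no level
cue, no onset randomization; it does not certify behavior on natural
sounds, broadband stimuli, or multi-layer spiking architectures, where
spike timing could matter in ways this model provably cannot express
(Poisson inputs and one spiking layer leave no timing structure to
exploit).

# Known limitations

- The class-midpoint decoder imposes a 3.75° MAE floor at 12 classes;
  finer claims require a continuous readout, out of scope here.
- DDL delay resolution equals the simulation bin (1 ms = 18° at 50 Hz);
  sub-bin delays exist only transiently during training.
- The Ricker summary of $W_{ho}$ degrades when training leaves a positive
  far-field in the weights (see above).
- TCA restarts make the decomposition reproducible, not canonical; CP
  factors are identifiable only up to permutation and scale.
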