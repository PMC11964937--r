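---
title: "Models and metrics for orthogonalized state machines in a cue-delay-choice task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and metrics for orthogonalized state machines in a cue-delay-choice task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osmlab)
```

## The task and its symbolic encodings

The two-alternative cue-delay-choice (2ACDC) task takes place on a 230-cm
virtual linear track. A 40-cm indicator cue early in the track predicts
which of two visually identical reward zones - R1 at [130, 150) cm or R2 at
[180, 200) cm - will deliver water. Everything between the cues is visually
uniform grey, so four track segments (the initial stretch, the grey before
R1, the grey before R2, and the end of the track) are sensory-ambiguous
both within a trial and across the two trial types. Solving the task
requires carrying the indicator identity across the grey delay - a latent
task state, not a sensory one.

`osmlab` encodes each 10-cm segment as one symbol. Two dialects exist
because the models consume slightly different streams:

* `rnn` (7 symbols, 23 steps): grey = 1, indicators 2/3, reward-zone
  visuals 4/5, water 6, teleport 0.
* `cscg_visual_first` (8 symbols, 26 steps): as above plus a brick wall 7
  and the teleport symbol repeated three times. In the rewarded zone the
  visual symbol precedes the shared water symbol. `cscg_water_first`
  reverses that order and `cscg_conjunctive` fuses water and zone visuals
  into combined codes; these variants exist because the order of reward and
  visual events changes which grey region decorrelates first during
  learning.

Trial types are interleaved by limited Poisson sampling (run lengths
truncated Poisson with `lambda = 0.7`, at most 3 repeats), so the long-run
near fraction is 0.5 and no trial type ever repeats more than three times.
Stretched trials lengthen both grey gaps by 50 cm, moving R1 to the
standard location of R2; novel-indicator variants swap fresh symbol ids
into the indicator block only.

`context_ambiguity()` enumerates all within-trial n-gram contexts of the
two canonical sequences. A predictor limited to a 4-symbol context still
confuses the reward locations (the contexts `1,1,1,4` and `1,1,1,5` have
trial-type-dependent successors); 5 symbols always suffice. This threshold
is set by the 3-segment grey gap between the reward zones and is the
quantity the transformer's context-length experiments probe. Contexts never
cross trial boundaries, because the post-teleport trial type is sampled
randomly and is irreducibly unpredictable.

## Clone-structured causal graph

The CSCG is a hidden Markov model over `S = 8 x 100` states in which each
clone emits exactly one symbol, deterministically; learning only reshapes
the transition matrix. We train by Baum-Welch expectation maximization in
steps of 20 EM iterations on batches of 20 randomly drawn trials, the
structure under which representational change can be tracked over learning.

Numerical and design choices that matter:

* **Initialization.** Transition rows are drawn Dirichlet-style
  (normalized gamma draws) with concentration 0.3. This is not cosmetic:
  with near-uniform random rows, EM sits on a symmetric saddle in which the
  clones serving the two trial-type branches never separate - the grey
  regions split by position but near/far occupancies remain identical, and
  once a position's occupancy collapses onto a single shared clone the
  configuration is an exact local optimum with no remaining gradient
  toward branch separation. Sparse rows break the clone-permutation
  symmetry early enough for the branches to separate.
* **Restarts.** Even so, a minority of initializations freeze one
  pre-reward region in that shared-clone optimum. This is detectable
  without reference to any expected ordering - the region's correlation
  simply never crosses the threshold - and `run_cscg_experiment()` then
  retrains from a fresh initialization (up to 4 restarts), standard
  practice for EM local optima. The returned object records `converged`
  and `attempts`.
* **Smoothing.** A pseudocount of 1e-10 per transition keeps rows
  stochastic; larger values (1e-3 and up) visibly smear occupancies and
  distort correlations.
* **Occupancy PVs.** The population-vector analogue for the model is the
  *filtered* (forward) clone-occupancy distribution: the causal state
  estimate given current and past symbols. Smoothed posteriors leak future
  symbols - under smoothing the shared track start already "knows" the
  trial type - so filtering is the representation comparable to an
  animal's online state. Smoothed (`posterior`) and hard (`viterbi`) modes
  remain available.
* **Monotonicity.** Within each training step the batch log-likelihood is
  non-decreasing across EM iterations (asserted in the tests to 1e-8), and
  forward log-likelihoods agree with brute-force path enumeration to 1e-10
  on all small instances.

Viterbi refinement (hard-assignment re-estimation, ties to the lowest
state id) sharpens the solution before graph extraction;
`extract_graph()` keeps only clones on the Viterbi paths of the canonical
trials, which after training form two trial-type-specific chains merging
into the shared start/teleport segment.

## Representational comparison

All models and (synthetic) imaging data meet in the same container: a
positions x units population-vector matrix, compared across trial types by
Pearson correlation of every location pair. Region statistics average this
matrix over named track regions. Two averaging conventions are
implemented: the **block** average (the square region block of the matrix;
the default) and the **diagonal** average (corresponding positions only).
The source descriptions of the region statistic admit both readings; we
default to the block reading because under it the model-discriminating
phenomena - off-diagonal grey pairs decorrelating first, then pre-R2, then
pre-R1 for the visual-first stream, with the pre-R1/pre-R2 order flipping
for the water-first stream - reproduce robustly, whereas diagonal-only
averaging leaves the visual-first ordering marginal. For calcium-like data
with place-field-scale smoothness the two conventions barely differ; they
diverge only for near-one-hot model states.

Decorrelation trajectories track per-region means across training
checkpoints (per-EM-iteration snapshots, with the untrained model as
checkpoint zero, give the resolution needed: most separation happens within
the first training step). The time-to-threshold statistic is the first
downward crossing of 0.3, linearly interpolated between checkpoints, on a
normalized 0-1 training axis; regions that never cross are flagged rather
than assigned a time. Zero-variance population vectors correlate as 0 by
convention and are flagged; angles between nonnegative PVs complement
correlations (orthogonal PVs sit at 90 degrees).

## Spiking Hebbian network

The biologically grounded model is a 100-neuron spiking recurrent network
with 96 feedforward inputs (12 dedicated neurons per symbol, orthogonal
across the 8 symbols), global softmax inhibition (soft winner-take-all),
1-ms updates, 20-ms exponential traces, a 10-ms refractory period, and a
local rule applied only on postsynaptic spikes:
`dw = 0.1 * (exp(-w) * trace - 0.1)`, with all weights clipped at zero.
Feedforward and recurrent weights start half-normal with s.d. 3.5 and 2.5.

Two quantities the rule leaves open are the stimulus presentation time and
the input firing rate. We present each track segment for 20 ms at 50 Hz
per active input neuron. The presentation time is deliberately about one
trace constant: with long presentations (100 ms or more) the refractory
period forces the entire stimulus assembly to cycle through its members
every presentation, so the population vector becomes symbol-specific but
context-blind and near/far correlations plateau around 0.7 however long
the network trains. At 20 ms only the few winners selected jointly by the
input and the recurrent context fire, and after a few hundred trials the
network's pre-reward representations orthogonalize while the track start -
where no context information exists - stays correlated, the same pattern
the hippocampal data show.

## Gradient-trained predictors

Rate RNNs (activations: exponential softmax, 8th-power polynomial softmax,
ReLU, sigmoid), single-layer LSTMs (plain, L1-on-hidden, readout dropout,
or an explicit near/far correlation penalty), and a small causal
transformer (learned positional embeddings, GELU MLPs, pre-logit layer
read out for representation analysis) are all trained with Adam on
cross-entropy next-symbol prediction, half of the session's trials held
out. Input/recurrent weights start at N(0, 0.001^2), readouts at
N(0, 0.1^2); ReLU units additionally start with bias 0.1, because at this
weight scale a zero bias leaves the layer exactly dead and the recurrent
pathway cannot bootstrap (training the ReLU variant remains the most
seed-sensitive even so). The polynomial softmax uses `|u|^8` normalization computed
with max-rescaling for stability; its exact analytic gradient (the
rescaling cancels) is finite-difference tested, as are the LSTM, the
transformer and the correlation penalty. The penalty is the mean over
positions of the squared Pearson correlation between paired near/far
hidden vectors, with zero-variance positions contributing zero; it is
backpropagated through one canonical trial of each type per epoch with
weight `lambda`.

The transformer trains on randomly sampled block-size chunks of the
concatenated trial stream; for representation and accuracy analyses it
slides a block-size window along a trial and reads the last position, so
`context_length` directly limits the usable memory. Accuracy can be
restricted to the reward-determining positions (those whose next symbol is
both trial-type-dependent and in a reward zone - positions 14 and 19 of the
23-step trial), the positions that separate solving the task from
exploiting local statistics.

## Calcium-trace analysis

dF/F0 baselines use a 5-s Gaussian filter - interpreted as the full width,
so sigma is about 1.25 s - followed by a 30-s maximin (rolling maximum of
the rolling minimum). The noise scale sigma is the s.d. of dF/F0 over
frames in the lower 25th percentile of each 5-s bin; transients start at 5
sigma and end within 1 sigma. Tuning curves average dF/F0 in 5-cm bins over
frames faster than 5 cm/s in *active* trials (at least one lick in a reward
zone). Place fields are contiguous regions above 25% of the peak-to-25th-
percentile range, 15-120 cm wide, with in/out activity ratio at least 4 and
significant transients in at least 20% of occupied in-field frames;
significance requires fields in fewer than 5% of shuffles, where each
shuffle randomly permutes 10-s blocks of the trace relative to position (a
permutation, not a rotation, so the null has full support). Field detection
operates on trial-averaged curves. The splitter score combines the
near/far tuning correlation `r` with the fractional peak difference
`D = |A_near - A_far| / max(A_near, A_far)`; categories split at `r = 0.2`
and `D = 0.5` and partition all scoreable cells. The spatial dispersion
index is the Shannon entropy (bits) of the area-normalized tuning curve.

## Licking strategies

Lick densities per 5-cm bin, trial type and session half are regressed on
four unit-mass strategy bases: uniform random licking, licking at both
reward zones, lick-stop (both zones until the reward is collected - on
near trials nothing after R1), and expert (correct zone only). Supports
include a 20-cm anticipatory lead-in before each zone, consistent with
licking "at or just before" the rewarded location; the exact supports are
not printed anywhere and are configurable. The coefficient of partial
determination of regressor i is `(SSE_without_i - SSE_full) /
SSE_without_i` from nested ordinary least squares fits. The design has no
intercept: the uniform random-licking regressor spans the constant, and an
intercept would make it exactly collinear - its CPD identically zero - so
random licking could never be recovered as a dominant strategy. CPD is
invariant to regressor scaling, and the dominant strategy of a session
half is the argmax CPD. Per-trial accuracy is binary - licks in
the correct zone (with lead-in) and none in the incorrect one - and the
expert criterion is three consecutive sessions at 75%.

## Synthetic sessions and what they do and do not show

The generator plants known structure so every analysis has a recoverable
ground truth: behaviour (position at 25 cm/s with sub-threshold slow-downs
inside reward zones, 2-s teleport gaps, licks drawn from a stage's
strategy basis plus a 5% uniform floor) and calcium fluorescence (Gaussian
positional rate fields, Poisson events, a 50-ms rise / 700-ms decay
GCaMP6f-like kernel, Gaussian noise around a baseline of 100). Learning is
emulated as five tuning stages: broad sensory tuning; shared tuning across
all four grey regions ("hub"-like); single-region tuning shared across
trial types; trial-type splitting of pre-R2/R2; full splitting of all
mid-track regions. Splitter and remapping cells live between the indicator
and R2 while place cells tile the whole track, so the track start and end
stay correlated at every stage - and the planted decorrelation order
(off-diagonal grey, then pre-R2, then pre-R1) matches the observed CA1
progression by construction. Cell identities persist across the sessions
of a learning course.

Passing recovery tests on these sessions shows the analysis code inverts
the generative assumptions it was built against - stationary tuning within
a session, Poisson events, additive noise, no drift, no cross-session
misregistration, no licking-independent reward effects. Real imaging data
violate several of these, so recovered fractions and thresholds carry over
only qualitatively.

## Problem sizes

The test-suite and acceptance runs use desk-scale sizes chosen to exercise
every code path at full fidelity of the printed protocol parameters:
CSCG runs use the printed 100 clones, 20 EM iterations and 20-trial
batches over 8 training steps and 200-trial schedules; Hebbian runs 400
trials; gradient nets train 40-trial sessions at hidden sizes around
100-130 (the printed ranges reach 5,000, which changes capacity but not
the phenomena under study); place-field nulls use hundreds rather than
1,000 shuffles in property tests, with the count configurable up to the
full protocol.

## Known limitations

* EM convergence on this two-sequence task is harder than on rich
  environments: a minority of initializations require restarts, and the
  visual-first decorrelation ordering is a majority-of-seeds phenomenon,
  not a per-seed certainty - matching its statistical character in vivo.
* The Hebbian network's presentation-time sensitivity (above) means its
  orthogonalization is a dynamical-regime result, not parameter-free.
* The gradient nets are trained at small scale on a CPU; absolute
  correlation levels depend on hidden size, learning rate and training
  length within the printed ranges, and the package treats the
  between-family ordering, not absolute values, as the reproducible
  content. In particular, trained exponential-softmax RNNs here solve the
  task while keeping a shared softmax winner per position and carrying the
  trial type in the low-probability tail, so their pre-reward correlations
  plateau around 0.3-0.5 rather than reaching zero; full winner splitting
  was not observed at any size (64-1000 units), learning rate
  (0.002-0.2), epoch count (up to 4000) or batching tried. The polynomial
  softmax variant is implemented and gradient-checked but does not reach
  task-solving accuracy at these scales.
* No spike deconvolution, ROI segmentation or cross-session registration
  is implemented; sessions enter the pipeline as extracted fluorescence.
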