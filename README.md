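# osmlab

Models and metrics for studying how learning systems *orthogonalize* their
internal representations of a two-alternative cue–delay–choice (2ACDC)
task — the virtual-reality linear-track paradigm in which an indicator cue
early on a 230-cm corridor predicts which of two visually identical reward
zones (R1, near, at 130–150 cm; R2, far, at 180–200 cm) will deliver water.
Because four stretches of the track are visually identical grey, solving
the task requires inferring and carrying a *latent* task state across
ambiguous input — and learners that do so develop near-orthogonal
population representations of visually identical places, linked by learned
transitions: an orthogonalized state machine (OSM).

The package is aimed at computational neuroscientists who want to compare
sequence-learning models against (calcium-imaging-like) hippocampal data on
equal footing. It provides:

* **The symbolic task**: trial generators for every encoding dialect and
  variant (stretched tracks, novel indicator pairs), Poisson-limited trial
  schedules, and an exhaustive n-gram context-ambiguity analysis
  (`make_trial()`, `sample_session()`, `context_ambiguity()`).
* **A clone-structured causal graph (CSCG)** — a hidden Markov model whose
  "clones" each deterministically emit one symbol, trained by batched
  Baum–Welch EM with Viterbi refinement and transition-graph extraction
  (`init_cscg()`, `baum_welch_train()`, `state_occupancy_pv()`,
  `extract_graph()`).
* **A spiking Hebbian network** with soft winner-take-all inhibition
  (`f_k = e^{u_k} / Σ_l e^{u_l}`) and the local rule
  `Δw = α (e^{-w} x̄ − 0.1)` applied on postsynaptic spikes
  (`init_spiking_net()`, `run_session()`).
* **Gradient-trained predictors**: rate RNNs with exponential-softmax,
  polynomial-softmax (8th power), ReLU and sigmoid activations; LSTMs with
  optional L1, dropout, or an explicit near/far correlation penalty; and a
  small causal transformer — all with hand-verified backpropagation
  (`net_spec()`, `train_net()`, `hidden_pv()`).
* **The representational comparison layer**: position-binned population
  vectors, near×far Pearson cross-correlation matrices, region statistics
  and PV angles, decorrelation trajectories and the time-to-threshold(0.3)
  order statistic (`pv_cross_correlation()`, `region_correlations()`,
  `decorrelation_trajectory()`, `decorrelation_order()`).
* **Calcium-trace analysis**: maximin ΔF/F₀ baselines, 5σ/1σ transient
  detection, 5-cm tuning curves, place-field detection with a 10-s
  block-shuffle null, the spatial dispersion index
  (entropy = −Σ p log₂ p), splitter scores
  (`D = |A_near − A_far| / max(A_near, A_far)`, categories at r = 0.2,
  D = 0.5), and the stretched-trial tuning-shift analysis.
* **Licking-strategy regression**: coefficients of partial determination,
  `CPD_i = (SSE_{−i} − SSE_full) / SSE_{−i}`, over the four strategy bases
  (random, both-rewards, lick-stop, expert).
* **A ground-truthed synthetic generator** (`simulate_behavior()`,
  `simulate_neural()`, `simulate_learning_course()`) emulating the
  learning stages so the entire pipeline is testable without any
  recordings.

## A worked example

Train a CSCG on the task and ask in which order its representations of the
ambiguous track regions decorrelate:

```r
library(osmlab)

res <- run_cscg_experiment(seed = 2, n_steps = 8, refine = FALSE)
round(res$order$times, 3)
#> off_diagonal       pre_r2       pre_r1
#>        0.066        0.182        0.386
res$order$match
#> [1] TRUE

rs <- region_spec(attr(res$final_ccm, "positions_near"))
round(region_correlations(res$final_ccm, rs,
                          average = "diagonal")$region_means[
        c("initial", "pre_r1", "pre_r2")], 2)
#> initial  pre_r1  pre_r2
#>       1       0       0
```

The off-diagonal grey correlations (different grey regions compared across
trial types) fall below the 0.3 threshold first, at 6.6% of training, then
the grey region before the far reward (pre-R2, 18.2%), and last the grey
region before the near reward (pre-R1, 38.6%) — the same order as in the
hippocampal recordings the task models. In the trained model the track
start, where no trial-type information exists yet, stays perfectly
correlated across trial types (1.00), while both pre-reward regions end at
zero: visually identical places have been pulled apart into orthogonal
latent states. (The ordering is a majority-of-seeds phenomenon; the run
reports `converged` and `order$match` per seed.)

The context-ambiguity analysis shows why memory is needed at all:

```r
ca <- context_ambiguity(list(make_trial("near", "rnn"),
                             make_trial("far", "rnn")), L_max = 10)
ca$max_ambiguous_L
#> [1] 4
subset(ca$maps[[4]], ambiguous)$context
#> [1] "1,1,1,4" "1,1,1,5"
```

A 4-symbol memory still cannot tell the reward locations apart (the
contexts `1,1,1,4` and `1,1,1,5` continue differently on near and far
trials); five symbols always suffice, set by the 3-segment grey gap
between the reward zones.

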