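Package: osmlab
Title: Orthogonalized State Machine Models and Metrics for a Cue-Delay-Choice Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how sequence-learning systems orthogonalize
    representations of a two-alternative cue-delay-choice (2ACDC) virtual
    linear-track task. Provides the symbolic task generator (dialects,
    stretched and novel-indicator variants, Poisson-limited trial schedules,
    n-gram context-ambiguity analysis), a clone-structured causal graph
    (cloned hidden Markov model) trained by Baum-Welch expectation
    maximization with Viterbi refinement and transition-graph extraction, a
    spiking recurrent network with soft winner-take-all inhibition and a
    local Hebbian plasticity rule, gradient-trained next-symbol predictors
    (rate recurrent networks with several activation families, LSTMs with
    optional decorrelation penalty, and a small causal transformer), the
    representational comparison layer (position-binned population vectors,
    near-by-far Pearson cross-correlation matrices, region statistics,
    population-vector angles, decorrelation trajectories and
    time-to-threshold order statistics), calcium-trace analysis (dF/F0
    baselining, transient detection, tuning curves, place-field detection
    with a block-shuffle null, spatial dispersion entropy, splitter-cell
    scores, stretched-trial tuning shifts), licking-strategy regression via
    coefficients of partial determination, and a ground-truthed synthetic
    session generator so the full pipeline is testable without any external
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
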