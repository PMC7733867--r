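Package: occupop
Title: Past Population Size Conditioned on a Reconstructed Tree and
    Occurrence Data Under a Birth-Death Sampling Process
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a linear birth-death process with through-time
    tree sampling (psi), through-time occurrence sampling (omega),
    present-day sampling (rho) and a removal probability (r) applied at
    sampling.  Computes the joint probability density of a reconstructed
    phylogenetic tree with sampled ancestors plus a record of occurrences,
    by backward and forward breadth-first traversals of the pooled event
    schedule (truncated master equations solved by matrix-exponential
    action and by an analytic generating-function epoch formula).
    Combines the two traversals into the full posterior distribution of
    the past population size at any time, draws conditioned population
    size trajectories via the Doob h-transform of the hidden birth-death
    dynamics, and ships an exact Gillespie simulator of the full process
    together with a bootstrap particle-filter cross-validation oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    ape,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils-numeric.R'
    'AllClasses.R'
    'AllGenerics.R'
    'params.R'
    'core-probabilities.R'
    'newick.R'
    'occurrences.R'
    'schedule.R'
    'probvector.R'
    'backward-L.R'
    'forward-M.R'
    'posterior-K.R'
    'trajectories.R'
    'simulate.R'
    'reconstruct.R'
    'particle-filter.R'
    'occupop-package.R'
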