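#' @import methods
NULL

## Central S4 containers.  All times are measured before present: t = 0 is
## the present day and t increases into the past, up to the origin time tOr.

#' Birth-death sampling model parameters
#'
#' Holds the seven free parameters of the birth-death process with
#' through-time tree sampling (psi), occurrence sampling (omega),
#' present-day sampling (rho) and removal probability r, together with the
#' derived constants gamma = lambda + mu + psi + omega,
#' Delta = sqrt(gamma^2 - 4 lambda mu) and the two roots x1 <= x2 of the
#' quadratic lambda x^2 - gamma x + mu.
#'
#' @slot lambda per-capita birth rate (1/time), > 0.
#' @slot mu per-capita death rate, >= 0.
#' @slot psi tree-sampling rate, >= 0.
#' @slot omega occurrence-sampling rate, >= 0.
#' @slot rho present-day sampling probability in [0, 1].
#' @slot r removal probability at psi-/omega-sampling, in [0, 1].
#' @slot tOr origin time (time before present at which the process starts).
#' @slot gamma,Delta,x1,x2 derived constants (see description).
#'
#' @seealso [bdParams()]
#' @export
setClass("BDParams",
  representation(
    lambda = "numeric", mu = "numeric", psi = "numeric", omega = "numeric",
    rho = "numeric", r = "numeric", tOr = "numeric",
    gamma = "numeric", Delta = "numeric", x1 = "numeric", x2 = "numeric"
  )
)

setValidity("BDParams", function(object) {
  msg <- character()
  if (object@lambda <= 0) msg <- c(msg, "lambda must be > 0")
  if (object@mu < 0) msg <- c(msg, "mu must be >= 0")
  if (object@psi < 0 || object@omega < 0)
    msg <- c(msg, "psi and omega must be >= 0")
  if (object@rho < 0 || object@rho > 1) msg <- c(msg, "rho must be in [0, 1]")
  if (object@r < 0 || object@r > 1) msg <- c(msg, "r must be in [0, 1]")
  if (object@tOr <= 0) msg <- c(msg, "tOr must be > 0")
  if (object@Delta <= 0)
    msg <- c(msg, paste0(
      "critical case Delta = 0 (lambda = mu with psi = omega = 0) is not ",
      "supported; perturb the parameters"
    ))
  if (length(msg)) msg else TRUE
})

#' Reconstructed phylogenetic tree with sampled ancestors
#'
#' A rooted binary time-calibrated tree whose nodes carry an age (time
#' before present), a role, and for through-time samples a removal status.
#' Sampled ancestors are degree-2 nodes sitting on a branch.
#'
#' @slot nodes data.frame with one row per node: `id` (integer), `parent`
#'   (integer, NA for the root), `age` (numeric, >= 0), `role` (one of
#'   `"tip_present"`, `"leaf"` (ancient psi-leaf), `"sampled_ancestor"`,
#'   `"branching"`), `status` (`"removed"`, `"non_removed"`, `"unknown"`;
#'   NA for branchings and present-day tips), `label` (character).
#' @slot presentOffset age of the youngest tip (0 unless the tree has no
#'   present-day samples and an explicit anchor was supplied).
#' @export
setClass("ReconTree",
  representation(nodes = "data.frame", presentOffset = "numeric")
)

setValidity("ReconTree", function(object) {
  nd <- object@nodes
  need <- c("id", "parent", "age", "role", "status", "label")
  if (!all(need %in% names(nd))) return("missing node columns")
  if (any(nd$age < -1e-9)) return("node ages must be >= 0")
  root <- nd$id[is.na(nd$parent)]
  if (length(root) != 1L) return("tree must have exactly one root")
  pa <- nd$age[match(nd$parent, nd$id)]
  strict <- !is.na(nd$parent) & nd$role != "sampled_ancestor" &
    nd$role[match(nd$parent, nd$id)] != "sampled_ancestor"
  if (any(pa[strict] <= nd$age[strict] - 1e-9))
    return("parent age must exceed child age")
  sa <- nd$role == "sampled_ancestor"
  if (any(nd$status[sa] == "removed"))
    return("a sampled ancestor cannot be labeled as removed")
  kids <- table(factor(nd$parent, levels = nd$id))
  if (any(kids[nd$role == "branching"] != 2L))
    return("branching nodes must have exactly two children")
  if (any(kids[sa] != 1L))
    return("sampled ancestors must have exactly one child")
  if (any(kids[nd$role %in% c("tip_present", "leaf")] != 0L))
    return("tips and leaves must have no children")
  TRUE
})

#' Occurrence record
#'
#' The ordered list of omega-sampling times with their removal labels.
#'
#' @slot record data.frame with columns `time` (numeric, ascending, >= 0)
#'   and `status` (`"removed"`, `"non_removed"`, `"unknown"`).
#' @export
setClass("OccurrenceRecord", representation(record = "data.frame"))

setValidity("OccurrenceRecord", function(object) {
  rec <- object@record
  if (!all(c("time", "status") %in% names(rec))) return("missing columns")
  if (nrow(rec) && any(rec$time < 0)) return("occurrence times must be >= 0")
  if (is.unsorted(rec$time)) return("occurrence times must be sorted")
  if (nrow(rec) &&
      !all(rec$status %in% c("removed", "non_removed", "unknown")))
    return("invalid removal status")
  TRUE
})

#' Pooled, time-ordered event schedule
#'
#' The breadth-first schedule used by both traversals: every punctual event
#' of the tree and the occurrence record plus the requested evaluation grid
#' times, pooled, deduplicated and ordered from the present (t = 0) to the
#' origin (t = tOr), with the lineage-through-time count of the tree on
#' every epoch between consecutive times.
#'
#' @slot events data.frame with columns `time` (ascending; first row is the
#'   present at 0, last the origin at tOr), `kind` (one of
#'   `"present"`, `"removed_leaf"`, `"nonremoved_leaf"`, `"unknown_leaf"`,
#'   `"sampled_ancestor"`, `"removed_occurrence"`, `"nonremoved_occurrence"`,
#'   `"unknown_occurrence"`, `"branching"`, `"grid"`, `"origin"`) and
#'   `grid` (logical: record the traversals here).
#' @slot kEpoch integer vector, one entry per epoch `(t[h-1], t[h])`
#'   (length `nrow(events) - 1`): the number of tree lineages crossing it.
#' @slot k0 number of present-day tips.
#' @slot tOr origin time.
#' @export
setClass("EventSchedule",
  representation(events = "data.frame", kEpoch = "integer",
                 k0 = "integer", tOr = "numeric")
)

setValidity("EventSchedule", function(object) {
  ev <- object@events
  if (nrow(ev) < 2L) return("schedule needs at least present and origin")
  if (ev$kind[1L] != "present" || ev$kind[nrow(ev)] != "origin")
    return("schedule must start at the present and end at the origin")
  if (is.unsorted(ev$time, strictly = TRUE)) return("times must be strictly increasing")
  if (length(object@kEpoch) != nrow(ev) - 1L)
    return("one lineage count per epoch required")
  if (any(object@kEpoch < 0L)) return("negative lineage count")
  if (utils::tail(object@kEpoch, 1L) != 1L)
    return("the epoch adjoining the origin must carry exactly one lineage")
  TRUE
})

#' Truncated probability vector over hidden-individual counts
#'
#' Represents a backward (L) or forward (M) vector over the hidden count
#' i in 0..N at a given time, as `values * exp(logScale)`.
#'
#' @slot values non-negative numeric vector of length N + 1 (index i = 0..N).
#' @slot logScale accumulated log normalization factor.
#' @slot k lineage count of the epoch the vector currently sits in.
#' @slot t time stamp (before present).
#' @export
setClass("ProbVector",
  representation(values = "numeric", logScale = "numeric",
                 k = "integer", t = "numeric")
)

setValidity("ProbVector", function(object) {
  if (any(!is.finite(object@values)) || any(object@values < 0))
    return("values must be finite and >= 0")
  if (length(object@logScale) != 1L) return("logScale must be scalar")
  TRUE
})

#' Posterior distribution of the past population size on a time grid
#'
#' Row tau of `probs` is the posterior P(I_tau = k_tau + i | T, O) over
#' i = 0..N; the total population support therefore starts at n = k_tau.
#'
#' @slot times evaluation times (before present).
#' @slot k lineage count of the tree at each time.
#' @slot probs matrix, one row per time, columns i = 0..N, rows sum to 1.
#' @slot logDensity log joint density of the data, the normalization
#'   constant shared by all rows.
#' @slot logDensityDrift largest relative deviation of the per-row
#'   pre-normalization constant from `logDensity` (consistency diagnostic).
#' @export
setClass("PosteriorGrid",
  representation(times = "numeric", k = "integer", probs = "matrix",
                 logDensity = "numeric", logDensityDrift = "numeric")
)

setValidity("PosteriorGrid", function(object) {
  if (nrow(object@probs) != length(object@times)) return("row/time mismatch")
  if (length(object@k) != length(object@times)) return("k/time mismatch")
  if (any(object@probs < 0)) return("negative posterior mass")
  bad <- abs(rowSums(object@probs) - 1) > 1e-9
  if (any(bad)) return("posterior rows must sum to 1")
  TRUE
})

#' Outcome of a full forward simulation
#'
#' @slot events data.frame event log: `time`, `type` (`"birth"`, `"death"`,
#'   `"psi"`, `"omega"`), `id` (individual), `child` (new individual for
#'   births, NA otherwise), `removed` (logical, sampling events only).
#' @slot trajectory data.frame (`time`, `I`): the true population size,
#'   piecewise constant, from the origin (I = 1) to the present.
#' @slot rhoSampled integer vector of individuals rho-sampled at present.
#' @slot tree the reconstructed tree (`ReconTree`) or NULL if no tree sample.
#' @slot occurrences the derived `OccurrenceRecord`.
#' @slot params the generating `BDParams`.
#' @slot seed the seed used.
#' @export
setClass("SimOutcome",
  representation(events = "data.frame", trajectory = "data.frame",
                 rhoSampled = "integer", tree = "ANY",
                 occurrences = "OccurrenceRecord", params = "BDParams",
                 seed = "integer")
)

setMethod("show", "BDParams", function(object) {
  cat("Birth-death sampling model\n")
  cat(sprintf("  lambda=%.4g mu=%.4g psi=%.4g omega=%.4g rho=%.4g r=%.4g tOr=%.4g\n",
              object@lambda, object@mu, object@psi, object@omega,
              object@rho, object@r, object@tOr))
  cat(sprintf("  gamma=%.4g Delta=%.4g x1=%.6g x2=%.6g\n",
              object@gamma, object@Delta, object@x1, object@x2))
})

setMethod("show", "ReconTree", function(object) {
  nd <- object@nodes
  cat(sprintf(
    "Reconstructed tree: %d present tips, %d ancient leaves, %d sampled ancestors, %d branchings\n",
    sum(nd$role == "tip_present"), sum(nd$role == "leaf"),
    sum(nd$role == "sampled_ancestor"), sum(nd$role == "branching")))
  cat(sprintf("  root age %.4g, present offset %.4g\n",
              max(nd$age), object@presentOffset))
})

setMethod("show", "OccurrenceRecord", function(object) {
  rec <- object@record
  cat(sprintf("Occurrence record: %d occurrences", nrow(rec)))
  if (nrow(rec))
    cat(sprintf(" on [%.4g, %.4g] (%d removed, %d non-removed, %d unknown)",
                min(rec$time), max(rec$time), sum(rec$status == "removed"),
                sum(rec$status == "non_removed"), sum(rec$status == "unknown")))
  cat("\n")
})

setMethod("show", "EventSchedule", function(object) {
  ev <- object@events
  cat(sprintf("Event schedule: %d times on [0, %.4g], k0 = %d\n",
              nrow(ev), object@tOr, object@k0))
  print(table(ev$kind))
})

setMethod("show", "ProbVector", function(object) {
  cat(sprintf("ProbVector at t=%.4g (k=%d, N=%d, logScale=%.4g)\n",
              object@t, object@k, length(object@values) - 1L, object@logScale))
})

setMethod("show", "PosteriorGrid", function(object) {
  cat(sprintf(
    "Posterior population size on %d times in [%.4g, %.4g]; log P(T,O) = %.6g\n",
    length(object@times), min(object@times), max(object@times),
    object@logDensity))
})

setMethod("show", "SimOutcome", function(object) {
  cat(sprintf("Simulated process (seed %d): %d events, final I = %d\n",
              object@seed, nrow(object@events),
              utils::tail(object@trajectory$I, 1L)))
})
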