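## Pooling of all punctual events into the breadth-first schedule.

leafKind <- c(removed = "removed_leaf", non_removed = "nonremoved_leaf",
              unknown = "unknown_leaf")
occKind <- c(removed = "removed_occurrence",
             non_removed = "nonremoved_occurrence",
             unknown = "unknown_occurrence")

## backward (present -> origin) change of the lineage count when crossing
## an event: leaves appear (+1), branchings merge (-1)
kindKStep <- c(removed_leaf = 1L, nonremoved_leaf = 1L, unknown_leaf = 1L,
               sampled_ancestor = 0L, removed_occurrence = 0L,
               nonremoved_occurrence = 0L, unknown_occurrence = 0L,
               branching = -1L, grid = 0L, present = 0L, origin = 0L)

#' Build the pooled event schedule
#'
#' Pools the punctual events of the reconstructed tree (ancient leaves,
#' sampled ancestors, branchings), the occurrence record and the requested
#' evaluation grid into one strictly ordered schedule from the present
#' (t = 0) to the origin (t = tOr), and computes the lineage count of the
#' tree on every epoch by a single backward sweep.  A grid time may
#' coincide exactly with a data event (the traversals then record their
#' values on the present side of the event); two coincident data events are
#' rejected, since the model produces ties with probability zero.
#'
#' @param tree a [ReconTree-class] object; must contain at least one
#'   present-day tip or ancient leaf.
#' @param occ an [OccurrenceRecord-class] (default: empty).
#' @param params a [BDParams-class]; supplies the origin time.
#' @param gridTimes evaluation times in `[0, tOr]`.
#' @return an [EventSchedule-class] object.
#' @examples
#' p <- bdParams(1, 0.5, psi = 0.3, rho = 0.5, r = 0.2, tOr = 3)
#' tr <- readReconTree("((A:1,B:1):1);")
#' sched <- buildSchedule(tr, params = p, gridTimes = 0.5)
#' lineageCounts(sched)
#' @export
buildSchedule <- function(tree, occ = occurrenceRecord(), params,
                          gridTimes = numeric()) {
  stopifnot(is(tree, "ReconTree"), is(occ, "OccurrenceRecord"),
            is(params, "BDParams"))
  tOr <- params@tOr
  nd <- tree@nodes
  k0 <- sum(nd$role == "tip_present")
  if (k0 > 0L && params@rho == 0)
    stop("impossible data: present-day tips with rho = 0 (density is zero)")

  evTime <- numeric(); evKind <- character()
  anc <- nd$role == "leaf"
  evTime <- c(evTime, nd$age[anc])
  evKind <- c(evKind, leafKind[nd$status[anc]])
  sa <- nd$role == "sampled_ancestor"
  evTime <- c(evTime, nd$age[sa])
  evKind <- c(evKind, rep("sampled_ancestor", sum(sa)))
  br <- nd$role == "branching"
  evTime <- c(evTime, nd$age[br])
  evKind <- c(evKind, rep("branching", sum(br)))

  rec <- occ@record
  if (nrow(rec)) {
    if (any(rec$time <= 0) || any(rec$time >= tOr))
      stop("occurrence times must lie strictly inside (0, tOr)")
    evTime <- c(evTime, rec$time)
    evKind <- c(evKind, occKind[rec$status])
  }
  if (any(evTime >= tOr))
    stop("all tree events must predate the origin time tOr")
  if (anyDuplicated(evTime))
    stop("two data events share the same time; the model is tie-free, ",
         "so coincident times indicate malformed input")

  if (any(gridTimes < 0 | gridTimes > tOr))
    stop("grid times must lie in [0, tOr]")
  gridTimes <- sort(unique(gridTimes))

  time <- c(0, evTime, tOr)
  kind <- c("present", evKind, "origin")
  grid <- time %in% gridTimes
  extra <- setdiff(gridTimes, time)
  time <- c(time, extra); kind <- c(kind, rep("grid", length(extra)))
  grid <- c(grid, rep(TRUE, length(extra)))
  ord <- order(time)
  ev <- data.frame(time = time[ord], kind = kind[ord], grid = grid[ord],
                   stringsAsFactors = FALSE)

  m <- nrow(ev)
  kEpoch <- integer(m - 1L)
  k <- k0
  for (h in seq_len(m - 1L)) {
    kEpoch[h] <- k
    k <- k + kindKStep[[ev$kind[h + 1L]]]
    if (k < 0L) stop("malformed tree: lineage count dropped below zero")
  }
  if (kEpoch[m - 1L] != 1L)
    stop("malformed tree: ", kEpoch[m - 1L],
         " lineages reach the origin (exactly one must)")

  new("EventSchedule", events = ev, kEpoch = kEpoch,
      k0 = as.integer(k0), tOr = tOr)
}

## lineage count on the present side (t-) of each schedule row
kBelowRow <- function(schedule) {
  c(schedule@k0, schedule@kEpoch)
}
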