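## Reconstruction of the observed data (T, O) from a full event log:
## prune every lineage without a psi- or rho-sampled descendant-or-self,
## turn psi-samples with surviving sampled descent into sampled ancestors,
## and collect the omega-events into the occurrence record.

#' Reconstruct the observed data from a full event log
#'
#' @param events the event log of [simulateProcess()] (columns `time`,
#'   `type`, `id`, `child`, `removed`).
#' @param rhoSampled ids of the individuals rho-sampled at the present.
#' @param params the generating [BDParams-class] (for the origin time).
#' @return list with `tree` (a [ReconTree-class], or NULL when no psi- or
#'   rho-sample exists) and `occurrences` (an [OccurrenceRecord-class]).
#' @export
reconstructData <- function(events, rhoSampled, params) {
  occ <- events[events$type == "omega", , drop = FALSE]
  occRec <- occurrenceRecord(occ$time,
                             ifelse(occ$removed, "removed", "non_removed"))

  births <- events[events$type == "birth", , drop = FALSE]
  parentOf <- stats::setNames(births$id, births$child)
  birthOf <- stats::setNames(births$time, births$child)
  psis <- events[events$type == "psi", , drop = FALSE]

  ids <- unique(c(1L, births$child))
  hasOwn <- ids %in% c(psis$id, rhoSampled)
  names(hasOwn) <- ids
  ## kept = own sample or sampled descent; children are born after their
  ## parent, so one sweep from youngest birth upward settles descendants
  kept <- hasOwn
  for (j in order(births$time)) {           # youngest birth first
    ch <- as.character(births$child[j])
    pa <- as.character(births$id[j])
    if (kept[[ch]]) kept[[pa]] <- TRUE
  }
  if (!any(kept)) return(list(tree = NULL, occurrences = occRec))

  rows <- list()
  nid <- 0L
  addNode <- function(age, role, status, childIds) {
    nid <<- nid + 1L
    rows[[nid]] <<- list(id = nid, parent = NA_integer_, age = age,
                         role = role, status = status,
                         label = paste0("n", nid))
    for (c_ in childIds)
      rows[[c_]]$parent <<- nid
    nid
  }
  recurse <- function(ind) {
    ## events on this individual's lineage, oldest last in the stack below
    it <- data.frame(time = numeric(), what = character(),
                     child = integer(), removed = logical())
    kk <- births$child[births$id == ind]
    kk <- kk[kept[as.character(kk)]]
    if (length(kk))
      it <- rbind(it, data.frame(time = birthOf[as.character(kk)],
                                 what = "branch", child = kk,
                                 removed = NA))
    own <- psis[psis$id == ind, , drop = FALSE]
    if (nrow(own))
      it <- rbind(it, data.frame(time = own$time, what = "psi",
                                 child = NA_integer_,
                                 removed = own$removed))
    if (ind %in% rhoSampled)
      it <- rbind(it, data.frame(time = 0, what = "rho",
                                 child = NA_integer_, removed = NA))
    it <- it[order(it$time), , drop = FALSE]    # youngest first
    node <- NA_integer_
    for (j in seq_len(nrow(it))) {
      e <- it[j, ]
      if (e$what == "rho") {
        node <- addNode(0, "tip_present", NA_character_, integer())
      } else if (e$what == "psi" && isTRUE(e$removed)) {
        node <- addNode(e$time, "leaf", "removed", integer())
      } else if (e$what == "psi") {
        node <- if (is.na(node))
          addNode(e$time, "leaf", "non_removed", integer())
        else addNode(e$time, "sampled_ancestor", "non_removed", node)
      } else {                                  # branch to a kept child
        sub <- recurse(e$child)
        node <- if (is.na(node)) sub
        else addNode(e$time, "branching", NA_character_, c(node, sub))
      }
    }
    node
  }
  recurse(1L)
  nd <- do.call(rbind, lapply(rows, function(x)
    data.frame(x, stringsAsFactors = FALSE)))
  offset <- min(nd$age[nd$role %in% c("tip_present", "leaf")])
  tree <- new("ReconTree", nodes = nd, presentOffset = offset)
  list(tree = tree, occurrences = occRec)
}
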