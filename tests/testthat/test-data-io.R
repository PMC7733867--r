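test_that("Newick parsing classifies roles, ages and removal labels", {
  tr <- readReconTree("((A:1,B:1):1);")
  nd <- treeNodes(tr)
  expect_equal(sum(nd$role == "tip_present"), 2)
  expect_equal(sum(nd$role == "branching"), 1)
  expect_equal(nd$age[nd$role == "branching"], 1)

  tr2 <- readReconTree("((A:1,B:0.5[&rm=1]):1);")
  nd2 <- treeNodes(tr2)
  b <- nd2[nd2$label == "B", ]
  expect_equal(b$role, "leaf")
  expect_equal(b$status, "removed")
  expect_equal(b$age, 0.5)
  ## unannotated ancient leaf has unknown status
  tr3 <- readReconTree("((A:1,B:0.5):1);")
  expect_equal(treeNodes(tr3)$status[treeNodes(tr3)$label == "B"], "unknown")
})

test_that("both sampled-ancestor encodings normalize to degree-2 nodes", {
  zl <- readReconTree("((A:0.6,SA1[&rm=0]:0):0.4);")
  d2 <- readReconTree("((A:0.6)SA1[&rm=0]:0.4);")
  for (tr in list(zl, d2)) {
    nd <- treeNodes(tr)
    sa <- nd[nd$role == "sampled_ancestor", ]
    expect_equal(nrow(sa), 1)
    expect_equal(sa$status, "non_removed")
    expect_equal(sa$age, 0.6)
  }
  expect_error(readReconTree("((A:0.6,SA1[&rm=1]:0):0.4);"), "removed")
})

test_that("malformed Newick is rejected", {
  expect_error(readReconTree("((A:1,B:1,C:1):1);"), "binary")
  expect_error(readReconTree("((A:1,B:-1):1);"), "negative")
  expect_error(readReconTree("((A:1,B:1):1"), "Newick")
})

test_that("tree round-trips through Newick, including ancient-only trees", {
  set.seed(5)
  p <- refParams(1.4)
  for (seed in 1:6) {
    sim <- simulateProcess(p, seed = seed, requireTree = TRUE)
    txt <- writeReconTree(sim@tree)
    tr2 <- readReconTree(txt)
    s1 <- buildSchedule(sim@tree, sim@occurrences, p, numeric())
    s2 <- buildSchedule(tr2, sim@occurrences, p, numeric())
    expect_equal(scheduleEvents(s2)$time, scheduleEvents(s1)$time,
                 tolerance = 1e-9)
    expect_equal(scheduleEvents(s2)$kind, scheduleEvents(s1)$kind)
    expect_equal(lineageCounts(s2), lineageCounts(s1))
  }
})

test_that("topology agrees with an annotation-free reference parser", {
  tr <- readReconTree("((A:1,B:1):0.5,C:1.5);")
  ph <- ape::read.tree(text = "((A:1,B:1):0.5,C:1.5);")
  nd <- treeNodes(tr)
  expect_equal(sum(nd$role == "tip_present"), ape::Ntip(ph))
  expect_equal(sum(nd$role == "branching"), ph$Nnode)
  depths <- ape::node.depth.edgelength(ph)
  expect_equal(sort(nd$age[nd$role == "branching"]),
               sort(max(depths) - depths[-(1:ape::Ntip(ph))]))
})

test_that("occurrence TSV parses, sorts and handles unknown labels", {
  occ <- readOccurrences("time\tremoved\n0.4\t1\n1.2\t0\n")
  expect_equal(occurrences(occ)$time, c(0.4, 1.2))
  expect_equal(occurrences(occ)$status, c("removed", "non_removed"))
  expect_equal(nrow(occurrences(readOccurrences("time\tremoved\n"))), 0)
  unsorted <- readOccurrences("time\tremoved\n2\t0\n0.5\tNA\n1\t1\n")
  expect_equal(occurrences(unsorted)$time, c(0.5, 1, 2))
  expect_equal(occurrences(unsorted)$status[1], "unknown")
  rt <- readOccurrences(writeOccurrences(unsorted))
  expect_equal(occurrences(rt), occurrences(unsorted))
})

test_that("schedule pools events, inserts grid times and sweeps k", {
  p <- bdParams(1, 0.5, psi = 0.3, rho = 0.5, r = 0.2, tOr = 2)
  tr <- readReconTree("((A:1,B:1):1);")
  s <- buildSchedule(tr, params = p, gridTimes = 0.5)
  expect_equal(scheduleEvents(s)$time, c(0, 0.5, 1, 2))
  expect_equal(scheduleEvents(s)$kind,
               c("present", "grid", "branching", "origin"))
  expect_equal(lineageCounts(s), c(2L, 2L, 1L))
  ## occurrences split epochs but never change k
  occ <- occurrenceRecord(0.4, 1)
  s2 <- buildSchedule(tr, occ, p, gridTimes = 0.5)
  expect_equal(lineageCounts(s2), c(2L, 2L, 2L, 1L))
  ## a grid time may coincide with a data event; two data events may not
  s3 <- buildSchedule(tr, occ, p, gridTimes = 0.4)
  expect_true(scheduleEvents(s3)$grid[scheduleEvents(s3)$time == 0.4])
  expect_error(buildSchedule(tr, occurrenceRecord(c(0.4, 0.4), c(1, 0)), p,
                             numeric()), "tie-free")
  expect_error(buildSchedule(tr, occurrenceRecord(2.5, 1), p, numeric()),
               "inside")
})

test_that("lineage counts match an independent edge count on simulations", {
  set.seed(9)
  p <- refParams(1.5)
  for (seed in c(3, 8, 15)) {
    sim <- simulateProcess(p, seed = seed, requireTree = TRUE)
    sched <- buildSchedule(sim@tree, sim@occurrences, p, numeric())
    ev <- scheduleEvents(sched)
    kEp <- lineageCounts(sched)
    mids <- (ev$time[-1] + ev$time[-nrow(ev)]) / 2
    for (j in seq_along(mids))
      expect_equal(kEp[j], lttFromTree(sim@tree, p@tOr, mids[j]))
    ## branching-count identity of a rooted binary tree
    cts <- table(factor(ev$kind, levels = unique(ev$kind)))
    nLeaf <- sum(ev$kind %in% c("removed_leaf", "nonremoved_leaf",
                                "unknown_leaf"))
    expect_equal(sum(ev$kind == "branching"), nLeaf + sched@k0 - 1L)
  }
})
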