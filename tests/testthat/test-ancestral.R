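test_that("Newick trees read with polytomies preserved", {
  f <- withr::local_tempfile()
  writeLines("((A,B),C);", f)
  tr <- readSpeciesTree(f)
  expect_equal(length(tr$tip.label), 3L)
  expect_equal(tr$Nnode, 2L)

  writeLines("((A,B),(C,D),E);", f)
  tr2 <- readSpeciesTree(f)
  expect_equal(tr2$Nnode, 3L)  # root polytomy of degree 3 kept

  writeLines("((A,B),A);", f)
  expect_error(readSpeciesTree(f), "duplicate")

  # fixture-written random tree round-trips to an isomorphic topology
  set.seed(3)
  rt <- ape::rtree(12)
  ape::write.tree(rt, f)
  back <- readSpeciesTree(f)
  expect_true(ape::all.equal.phylo(rt, back, use.edge.length = FALSE))
})

test_that("worked reconstructions match enumeration", {
  tr <- ape::read.tree(text = "((A,B),C);")

  # constant leaves: zero-change solution
  fit0 <- wagnerReconstruct(tr, c(A = 4, B = 4, C = 4))
  expect_equal(totalCost(fit0), 0)
  expect_true(all(nodeStates(fit0) == 4L))

  # A=3,B=1,C=1: both ancestors at 1, one +2 expansion on the branch to A
  fit1 <- wagnerReconstruct(tr, c(A = 3, B = 1, C = 1))
  expect_equal(totalCost(fit1), 2)
  expect_equal(nodeStates(fit1)[4:5], c(1L, 1L))
  ev1 <- classifyBranchEvents(fit1)
  expect_equal(sum(ev1$event != "none"), 1L)
  expect_equal(ev1$event[ev1$child == "A"], "expansion")

  # A=2,B=0,C=0: ancestors at 0, a single gain into A
  fit2 <- wagnerReconstruct(tr, c(A = 2, B = 0, C = 0))
  expect_equal(totalCost(fit2), 2)
  expect_equal(nodeStates(fit2)[4:5], c(0L, 0L))
  ev2 <- classifyBranchEvents(fit2)
  expect_equal(sum(ev2$event != "none"), 1L)
  expect_equal(ev2$event[ev2$child == "A"], "gain")

  # enumeration gives the identical answers
  for (cts in list(c(A = 3, B = 1, C = 1), c(A = 2, B = 0, C = 0))) {
    bf <- bruteForceReconstruct(tr, cts)
    expect_equal(totalCost(bf), 2)
    expect_equal(nodeStates(bf),
                 nodeStates(wagnerReconstruct(tr, cts)))
  }
})

test_that("DP equals the brute-force oracle on random small instances", {
  set.seed(17)
  for (i in 1:60) {
    inst <- randomWagnerInstance()
    g <- sample(c(0.5, 1, 2), 1)
    w <- wagnerReconstruct(inst$tree, inst$counts, gain_penalty = g)
    b <- bruteForceReconstruct(inst$tree, inst$counts, gain_penalty = g)
    expect_equal(totalCost(w), totalCost(b))
    expect_identical(nodeStates(w), nodeStates(b))
  }
  expect_error(bruteForceReconstruct(ape::rtree(12),
                                     setNames(rep(1, 12),
                                              ape::rtree(12)$tip.label)),
               "bounds")
})

test_that("with gain penalty 1 the cost is complement-symmetric", {
  set.seed(23)
  for (i in 1:25) {
    inst <- randomWagnerInstance(max_count = 5)
    S <- 7L
    w1 <- wagnerReconstruct(inst$tree, inst$counts, 1, max_state = S)
    w2 <- wagnerReconstruct(inst$tree, S - inst$counts, 1, max_state = S)
    expect_equal(totalCost(w1), totalCost(w2))
  }
})

test_that("raising the gain penalty never removes loss branches", {
  set.seed(29)
  nLosses <- function(fit) sum(classifyBranchEvents(fit)$event == "loss")
  for (i in 1:20) {
    inst <- randomWagnerInstance()
    gs <- c(0.5, 1, 2, 4)
    losses <- vapply(gs, function(g)
      nLosses(wagnerReconstruct(inst$tree, inst$counts, g)), numeric(1))
    expect_true(!is.unsorted(losses))
  }
})

test_that("branch events are mutually exclusive and fixture-consistent", {
  tr <- ape::read.tree(text = "((A,B),C);")
  # 0 -> 2 on one branch is a gain, not an expansion
  fit <- wagnerReconstruct(tr, c(A = 2, B = 0, C = 0))
  ev <- classifyBranchEvents(fit)
  expect_equal(ev$event[ev$child == "A"], "gain")

  # hand-built histories: one event per branch type
  h <- generateHistory(6, 40, rates = c(gain = 0.15, loss = 0.1, shift = 0.15),
                       rng_seed = 8)
  fits <- reconstructFamilies(h$counts, h$tree)
  for (f in names(fits)) {
    ev <- classifyBranchEvents(fits[[f]])
    expect_equal(nrow(ev), nrow(h$tree$edge))
    expect_true(all(ev$event %in%
                    c("gain", "loss", "expansion", "contraction", "none")))
    # definitions: recompute labels directly from the states
    s <- ev$parent_state; t <- ev$child_state
    expect_equal(ev$event == "gain", s == 0 & t >= 1)
    expect_equal(ev$event == "loss", s >= 1 & t == 0)
    expect_equal(ev$event == "expansion", t > s & s >= 1)
    expect_equal(ev$event == "contraction", s > t & t >= 1)
  }
})

test_that("single planted events are recovered exactly", {
  # one +2 expansion planted on one branch, everything else constant
  tr <- ape::read.tree(text = "(((A,B),C),(D,E));")
  counts <- c(A = 3, B = 3, C = 1, D = 1, E = 1)  # +2 above MRCA(A,B)
  fit <- wagnerReconstruct(tr, counts, family = "fam1")
  ev <- classifyBranchEvents(fit)
  changed <- ev[ev$event != "none", ]
  expect_equal(nrow(changed), 1L)
  expect_equal(changed$event, "expansion")
  expect_equal(changed$parent_state, 1L)
  expect_equal(changed$child_state, 3L)
})

test_that("event totals aggregate overall and within node groups", {
  expect_equal(summarizeOverFamilies(list())$gain, 0L)

  tr <- ape::read.tree(text = "((A,B)AB,C)R;")
  fit <- wagnerReconstruct(tr, c(A = 2, B = 0, C = 0), family = "f")
  ev <- classifyBranchEvents(fit)
  out <- summarizeOverFamilies(list(ev), node_groups = list(G = c("A", "B", "AB")))
  expect_equal(out$gain[out$scope == "all"], 1L)
  expect_equal(out$gain[out$scope == "G"], 1L)
  out2 <- summarizeOverFamilies(list(ev), node_groups = list(G2 = "C"))
  expect_equal(out2$gain[out2$scope == "G2"], 0L)
  expect_error(summarizeOverFamilies(list(ev), list(G = "NOPE")), "unknown")

  # planted multi-family fixture: totals equal the planted bookkeeping
  h <- generateHistory(10, 60, rates = c(gain = 0.03, loss = 0.02, shift = 0.03),
                       rng_seed = 12)
  fits <- reconstructFamilies(h$counts, h$tree)
  evs <- lapply(fits, classifyBranchEvents)
  tot <- summarizeOverFamilies(evs)
  rec <- eventRecovery(h)
  # every recovered planted event appears in the totals
  expect_gte(sum(tot[tot$scope == "all", c("gain", "loss", "expansion",
                                           "contraction")]),
             rec$n_recovered)
})
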