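#' Read a rooted species tree in Newick format
#'
#' Thin wrapper over \code{\link[ape]{read.tree}} that additionally checks
#' the tree is usable for ancestral family-size reconstruction: rooted, with
#' unique leaf labels. Polytomies are preserved; branch lengths are carried
#' but ignored by the parsimony machinery.
#'
#' @param path Newick file path.
#' @return an \code{ape} \code{phylo} object.
#' @export
readSpeciesTree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels in species tree")
  # the basal node is taken as the root; a basal multifurcation is treated
  # as a hard polytomy of a rooted tree
  tr
}

# label every node: tips by tip.label, internal nodes by node.label when
# present, else "N<index>" (root is N<Ntip+1>)
.nodeLabels <- function(tree) {
  n <- length(tree$tip.label)
  inner <- if (!is.null(tree$node.label) && all(nzchar(tree$node.label)) &&
               !anyDuplicated(tree$node.label)) tree$node.label
           else paste0("N", n + seq_len(tree$Nnode))
  c(tree$tip.label, inner)
}

# per-unit asymmetric branch cost matrix over states 0..max_state
.transCost <- function(max_state, g) {
  s <- 0:max_state
  d <- outer(s, s, "-")          # s - t
  g * pmax(-d, 0) + pmax(d, 0)   # gain = increase (t > s), loss = decrease
}

#' Asymmetric Wagner parsimony reconstruction of family sizes
#'
#' Finds integer ancestral states minimising the total branch cost, where a
#' branch from parent state s to child state t costs
#' \code{gain_penalty * max(t - s, 0) + max(s - t, 0)}: each unit gained
#' costs \code{gain_penalty}, each unit lost costs 1. The root carries no
#' prior; its state is chosen to minimise the total cost. The exact optimum
#' is computed by bounded-state dynamic programming over \code{0..max_state}
#' (Sankoff-style), which is equivalent to the unbounded problem because
#' optimal internal states never exceed the largest observed count. Among
#' minimum-cost labelings, every node takes the smallest optimal state in a
#' top-down pass, a deterministic and conservative tie-break.
#'
#' @param tree rooted \code{phylo} tree.
#' @param leaf_counts named integer vector of observed family sizes, one per
#'   leaf label.
#' @param gain_penalty cost of a one-unit gain; a unit loss costs 1.
#' @param max_state upper bound of the state space; defaults to
#'   \code{max(leaf_counts) + 2} (the slack is never used by an optimal
#'   labeling, and serves as a guard that bounding is not binding).
#' @param family optional family label carried into the result.
#' @return a \linkS4class{WagnerFit}.
#' @examples
#' tr <- ape::read.tree(text = "((A,B),C);")
#' fit <- wagnerReconstruct(tr, c(A = 3, B = 1, C = 1))
#' totalCost(fit)  # 2: a two-copy expansion on the branch to A
#' @export
wagnerReconstruct <- function(tree, leaf_counts, gain_penalty = 1,
                              max_state = NULL, family = character(0)) {
  stopifnot(gain_penalty > 0)
  n_tip <- length(tree$tip.label)
  miss <- setdiff(tree$tip.label, names(leaf_counts))
  if (length(miss))
    stop("leaf without a count: ", paste(miss, collapse = ", "))
  counts <- as.integer(leaf_counts[tree$tip.label])
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(max_state)) max_state <- max(counts) + 2L
  max_state <- as.integer(max_state)
  if (max_state < max(counts)) stop("max_state below an observed count")

  S <- max_state + 1L
  trans <- .transCost(max_state, gain_penalty)
  n_nodes <- n_tip + tree$Nnode
  cost <- matrix(0, nrow = S, ncol = n_nodes)
  cost[, seq_len(n_tip)] <- Inf
  cost[cbind(counts + 1L, seq_len(n_tip))] <- 0

  po <- ape::reorder.phylo(tree, "postorder")
  # bottom-up: fold each child's cost vector into its parent
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1]; child <- po$edge[e, 2]
    # min over t of trans[s,t] + cost_child[t], for every s
    cost[, parent] <- cost[, parent] +
      apply(sweep(trans, 2, cost[, child], "+"), 1, min)
  }
  root <- n_tip + 1L
  total <- min(cost[, root])
  states <- integer(n_nodes)
  states[root] <- which(cost[, root] == total)[1] - 1L  # smallest optimal

  cw <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(cw$edge))) {
    parent <- cw$edge[e, 1]; child <- cw$edge[e, 2]
    v <- trans[states[parent] + 1L, ] + cost[, child]
    states[child] <- which(v == min(v))[1] - 1L
  }
  new("WagnerFit", tree = tree, states = states, cost = total,
      gainPenalty = gain_penalty, maxState = max_state,
      family = as.character(family))
}

#' Exhaustive-search reconstruction (testing oracle)
#'
#' Enumerates every labeling of the internal nodes over \code{0..max_state}
#' and returns the minimum-cost one, breaking ties by the lexicographically
#' smallest states in top-down (preorder) node order — the same cost model
#' and tie-break as \code{\link{wagnerReconstruct}}, computed by a route
#' that shares none of its machinery. Refuses instances beyond 8 internal
#' nodes or \code{max_state} 6.
#'
#' @inheritParams wagnerReconstruct
#' @param max_state state-space bound; defaults to \code{max(leaf_counts)}
#'   (optimal internal states never exceed the largest leaf count).
#' @return a \linkS4class{WagnerFit}.
#' @export
bruteForceReconstruct <- function(tree, leaf_counts, gain_penalty = 1,
                                  max_state = NULL, family = character(0)) {
  n_tip <- length(tree$tip.label)
  miss <- setdiff(tree$tip.label, names(leaf_counts))
  if (length(miss))
    stop("leaf without a count: ", paste(miss, collapse = ", "))
  counts <- as.integer(leaf_counts[tree$tip.label])
  if (is.null(max_state)) max_state <- max(counts)
  max_state <- as.integer(max_state)
  if (tree$Nnode > 8L || max_state > 6L)
    stop("instance exceeds brute-force enumeration bounds")
  if (max_state < max(counts)) stop("max_state below an observed count")

  g <- gain_penalty
  inner_ids <- n_tip + seq_len(tree$Nnode)
  grid <- as.matrix(expand.grid(rep(list(0:max_state), tree$Nnode),
                                KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- NULL
  stateOf <- function(node) {
    if (node <= n_tip) rep(counts[node], nrow(grid))
    else grid[, node - n_tip]
  }
  total <- numeric(nrow(grid))
  for (e in seq_len(nrow(tree$edge))) {
    s <- stateOf(tree$edge[e, 1]); t <- stateOf(tree$edge[e, 2])
    total <- total + g * pmax(t - s, 0) + pmax(s - t, 0)
  }
  best <- which(total == min(total))
  # lexicographic tie-break over internal nodes in preorder
  cw <- ape::reorder.phylo(tree, "cladewise")
  pre <- unique(as.vector(t(cw$edge)))
  pre_inner <- pre[pre > n_tip]
  if (!(n_tip + 1L) %in% pre_inner) pre_inner <- c(n_tip + 1L, pre_inner)
  ord <- do.call(order, lapply(pre_inner, function(nd) grid[best, nd - n_tip]))
  pick <- best[ord[1]]
  states <- integer(n_tip + tree$Nnode)
  states[seq_len(n_tip)] <- counts
  states[inner_ids] <- grid[pick, ]
  new("WagnerFit", tree = tree, states = states, cost = min(total),
      gainPenalty = gain_penalty, maxState = max_state,
      family = as.character(family))
}

#' Classify per-branch events of a reconstruction
#'
#' Each branch from parent state s to child state t is labelled with exactly
#' one event: \code{gain} (s = 0, t >= 1), \code{loss} (s >= 1, t = 0),
#' \code{expansion} (t > s >= 1), \code{contraction} (s > t >= 1) or
#' \code{none} (s = t). The categories are mutually exclusive; a branch on
#' which a family appears from zero counts once, as a gain, regardless of
#' the number of copies gained.
#'
#' @param fit a \linkS4class{WagnerFit}.
#' @return data.frame with one row per branch: \code{family}, \code{parent},
#'   \code{child} (node labels; the branch is identified by its child),
#'   \code{parent_state}, \code{child_state}, \code{event}.
#' @export
classifyBranchEvents <- function(fit) {
  stopifnot(is(fit, "WagnerFit"))
  tree <- fit@tree
  labs <- .nodeLabels(tree)
  s <- fit@states[tree$edge[, 1]]
  t <- fit@states[tree$edge[, 2]]
  event <- ifelse(s == t, "none",
           ifelse(s == 0 & t >= 1, "gain",
           ifelse(s >= 1 & t == 0, "loss",
           ifelse(t > s, "expansion", "contraction"))))
  data.frame(
    family = if (length(fit@family)) fit@family else NA_character_,
    parent = labs[tree$edge[, 1]], child = labs[tree$edge[, 2]],
    parent_state = s, child_state = t, event = event,
    stringsAsFactors = FALSE)
}

#' Reconstruct every family of a count matrix on a species tree
#'
#' @param x a \linkS4class{TAPCountMatrix} whose species all appear as tree
#'   leaves.
#' @param tree rooted \code{phylo} tree.
#' @param gain_penalty passed to \code{\link{wagnerReconstruct}}.
#' @return named list of \linkS4class{WagnerFit}, one per family.
#' @export
reconstructFamilies <- function(x, tree, gain_penalty = 1) {
  m <- tapCounts(x)
  miss <- setdiff(colnames(m), tree$tip.label)
  if (length(miss))
    stop("species not in tree: ", paste(miss, collapse = ", "))
  fits <- lapply(rownames(m), function(f)
    wagnerReconstruct(tree, m[f, ], gain_penalty = gain_penalty, family = f))
  names(fits) <- rownames(m)
  fits
}

#' Total events over families, overall and within node groups
#'
#' Sums gains, losses, expansions and contractions over a set of per-family
#' branch-event tables, overall and restricted to labelled groups of nodes.
#' A branch is attributed to its child node, so a node group captures the
#' events on the branches leading into its nodes.
#'
#' @param events list of data.frames from \code{\link{classifyBranchEvents}}
#'   (or one combined data.frame).
#' @param node_groups named list of character vectors of node labels.
#' @return data.frame with one row per scope ("all" plus each group) and
#'   columns \code{gain}, \code{loss}, \code{expansion}, \code{contraction}.
#' @export
summarizeOverFamilies <- function(events, node_groups = list()) {
  ev <- if (is.data.frame(events)) events else do.call(rbind, events)
  types <- c("gain", "loss", "expansion", "contraction")
  countEv <- function(d) setNames(
    vapply(types, function(tp) sum(d$event == tp), integer(1)), types)
  if (is.null(ev)) ev <- data.frame(child = character(0), event = character(0))
  all_nodes <- unique(ev$child)
  rows <- list(cbind(data.frame(scope = "all", stringsAsFactors = FALSE),
                     as.data.frame(as.list(countEv(ev)))))
  for (gname in names(node_groups)) {
    grp <- node_groups[[gname]]
    if (nrow(ev)) {
      known <- unique(c(ev$child, ev$parent))
      unknown <- setdiff(grp, known)
      if (length(unknown))
        stop("unknown node in group '", gname, "': ",
             paste(unknown, collapse = ", "))
    }
    sub <- ev[ev$child %in% grp, , drop = FALSE]
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(scope = gname, stringsAsFactors = FALSE),
      as.data.frame(as.list(countEv(sub))))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
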