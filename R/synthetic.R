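#' Write domain hits as a HMMER3 per-domain table
#'
#' Emits a syntactically valid \code{domtblout} file (comment header, 23
#' whitespace-delimited columns) that \code{\link{readDomtbl}} parses back
#' field-for-field. Model lengths are taken from \code{library}; fields the
#' hit table does not carry (bias, envelope coordinates, accuracy) are
#' written as neutral fillers.
#'
#' @param hits data.frame of domain hits (see \code{\link{readDomtbl}}).
#' @param library a \linkS4class{ProfileLibrary} covering every hit domain.
#' @param path output file path.
#' @export
writeDomtbl <- function(hits, library, path) {
  p <- profiles(library)
  m <- match(hits$domain, p$domain)
  if (anyNA(m))
    stop("hit domain absent from profile library: ",
         paste(unique(hits$domain[is.na(m)]), collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#                                                               --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------"),
    con)
  if (nrow(hits)) {
    tlen <- hits$ali_to + 10L
    lines <- sprintf(
      "%-20s -          %5d %-20s -          %5d %9.2g %6.1f   0.0   1   1 %9.2g %9.2g %6.1f   0.0 %5d %5d %5d %5d %5d %5d 0.90 -",
      hits$protein_id, tlen, hits$domain, p$model_length[m],
      hits$full_seq_evalue, hits$domain_score, hits$domain_ievalue,
      hits$domain_ievalue, hits$domain_score,
      hits$hmm_from, hits$hmm_to, hits$ali_from, hits$ali_to,
      pmax(hits$ali_from - 1L, 1L), hits$ali_to + 1L)
    writeLines(lines, con)
  }
  writeLines("#", con)
  invisible(path)
}

# one synthetic passing hit of `domain` for `protein`
.signalHit <- function(protein, domain, p_row, rng) {
  len <- p_row$model_length
  cov_thr <- if (is.na(p_row$coverage_threshold)) 0 else p_row$coverage_threshold
  span <- max(ceiling(cov_thr * len), ceiling(0.8 * len))
  from <- sample(seq_len(len - span + 1L), 1)
  # values at domtblout printed precision, so write/parse round-trips exactly
  ev <- signif(10^stats::runif(1, -30, -5), 2)
  data.frame(protein_id = protein, domain = p_row$domain,
             full_seq_evalue = ev, domain_ievalue = ev,
             domain_score = round(p_row$ga_threshold + stats::runif(1, 0.5, 30), 1),
             hmm_from = from, hmm_to = from + span - 1L,
             ali_from = 5L, ali_to = 4L + span, stringsAsFactors = FALSE)
}

# a decoy hit that must not survive filtering: sub-GA score
.decoyHit <- function(protein, p_row) {
  len <- p_row$model_length
  ev <- signif(10^stats::runif(1, -4, -1), 2)
  data.frame(protein_id = protein, domain = p_row$domain,
             full_seq_evalue = ev, domain_ievalue = ev,
             domain_score = round(max(p_row$ga_threshold - stats::runif(1, 0.6, 5), 0.1), 1),
             hmm_from = 1L, hmm_to = len, ali_from = 1L, ali_to = len,
             stringsAsFactors = FALSE)
}

#' Generate a proteome of planted domain hits with recorded ground truth
#'
#' Each protein is planted with either an unambiguous family signature (one
#' strong hit per should-domain of a family drawn uniformly from the rule
#' set) or, with probability \code{decoy_rate}, a decoy that must classify
#' to no family. Decoys come in two kinds, exercising the two rejection
#' paths: a sub-threshold hit of a should-domain (filter path), and a
#' passing should-domain hit paired with a passing forbidden-domain hit for
#' a family whose veto removes its only candidacy (veto path; only emitted
#' when the rule set offers such a pair). Signal proteins additionally carry
#' a sub-threshold decoy hit of some other domain.
#'
#' @param n_proteins number of proteins.
#' @param rules a \linkS4class{TAPRuleSet} (non-empty).
#' @param library a \linkS4class{ProfileLibrary} resolving every rule domain.
#' @param decoy_rate probability that a protein is a decoy.
#' @param rng_seed integer seed; generation is deterministic given it.
#' @param path optional file path; when given, the hit table is also written
#'   as \code{domtblout} via \code{\link{writeDomtbl}}.
#' @return list with \code{hits} (data.frame), \code{truth} (data.frame
#'   \code{protein_id}, \code{family} with \code{NA} for decoys), and
#'   \code{path} (the file written, or \code{NA}).
#' @export
generateHits <- function(n_proteins, rules, library, decoy_rate = 0.2,
                         rng_seed = 1L, path = NA_character_) {
  stopifnot(length(familyNames(rules)) > 0, decoy_rate >= 0, decoy_rate <= 1)
  set.seed(rng_seed)
  p <- profiles(library)
  fams <- familyNames(rules)
  # veto-path decoys need a family whose should-domain backs no other family
  veto_fams <- Filter(function(f) {
    length(shouldNotDomains(rules, f)) > 0 &&
      !any(vapply(setdiff(fams, f), function(o)
        all(shouldDomains(rules, o) %in% shouldDomains(rules, f)),
        logical(1)))
  }, fams)
  # the forbidden domain used must not itself complete another family's rule
  vetoPair <- function(f) {
    for (fd in shouldNotDomains(rules, f)) {
      completes <- vapply(fams, function(o)
        all(shouldDomains(rules, o) %in% c(shouldDomains(rules, f), fd)),
        logical(1))
      completes[f] <- FALSE
      if (!any(completes)) return(fd)
    }
    NA_character_
  }
  rows <- list(); truth_fam <- character(n_proteins)
  for (i in seq_len(n_proteins)) {
    prot <- sprintf("p%04d", i)
    if (stats::runif(1) < decoy_rate) {
      truth_fam[i] <- NA_character_
      kind <- sample(c("filter", "veto"), 1)
      fd <- NA_character_
      if (kind == "veto" && length(veto_fams)) {
        f <- sample(veto_fams, 1)
        fd <- vetoPair(f)
      }
      if (!is.na(fd)) {
        for (d in shouldDomains(rules, f))
          rows[[length(rows) + 1L]] <-
            .signalHit(prot, d, p[p$domain == d, ], NULL)
        rows[[length(rows) + 1L]] <-
          .signalHit(prot, fd, p[p$domain == fd, ], NULL)
      } else {
        f <- sample(fams, 1)
        d <- sample(shouldDomains(rules, f), 1)
        rows[[length(rows) + 1L]] <- .decoyHit(prot, p[p$domain == d, ])
      }
    } else {
      f <- sample(fams, 1)
      truth_fam[i] <- f
      for (d in shouldDomains(rules, f))
        rows[[length(rows) + 1L]] <-
          .signalHit(prot, d, p[p$domain == d, ], NULL)
      # plus a harmless sub-threshold decoy on another domain
      other <- setdiff(p$domain, c(shouldDomains(rules, f),
                                   shouldNotDomains(rules, f)))
      if (length(other))
        rows[[length(rows) + 1L]] <-
          .decoyHit(prot, p[p$domain == sample(other, 1), ])
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else .emptyHits()
  rownames(hits) <- NULL
  if (!is.na(path)) writeDomtbl(hits, library, path)
  list(hits = hits,
       truth = data.frame(protein_id = sprintf("p%04d", seq_len(n_proteins)),
                          family = truth_fam, stringsAsFactors = FALSE),
       path = path)
}

#' Simulate family-size histories on a random species tree
#'
#' Draws a random bifurcating rooted tree and, per family, a root count in
#' \code{0..3}, then walks root-to-tip planting at most one change per
#' branch: on a branch entering with count 0, a gain (to 1 or 2 copies) with
#' probability \code{rates["gain"]}; on a branch entering with a positive
#' count, a loss to 0 with probability \code{rates["loss"]}, otherwise a
#' one-copy shift (expansion, or contraction keeping the count positive)
#' with probability \code{rates["shift"]}. Tip counts stay small (bounded at
#' 10 copies), the regime of TAP family sizes. The true event list is
#' retained for recovery scoring.
#'
#' @param n_leaves number of species (>= 3).
#' @param n_families number of families to simulate.
#' @param rates named numeric vector with entries \code{gain}, \code{loss},
#'   \code{shift}, each in \code{[0, 1]}.
#' @param rng_seed integer seed.
#' @param max_events_per_family cap on the number of change events planted
#'   per family; \code{1} gives the rare-event regime in which every planted
#'   event is isolated on its branch, \code{Inf} (default) leaves planting
#'   entirely to the rates.
#' @param tree_path,matrix_path optional file paths; when given, the tree is
#'   written as Newick and the tip counts as a count-matrix TSV.
#' @return list with \code{tree} (phylo), \code{counts} (a
#'   \linkS4class{TAPCountMatrix} of tip counts), \code{events} (data.frame
#'   \code{family}, \code{child}, \code{event}, \code{from}, \code{to}) and
#'   \code{root_counts}.
#' @export
generateHistory <- function(n_leaves, n_families,
                            rates = c(gain = 0.006, loss = 0.003, shift = 0.005),
                            rng_seed = 1L,
                            max_events_per_family = Inf,
                            tree_path = NA_character_,
                            matrix_path = NA_character_) {
  stopifnot(n_leaves >= 3, all(rates >= 0), all(rates <= 1),
            all(c("gain", "loss", "shift") %in% names(rates)))
  set.seed(rng_seed)
  tree <- ape::rtree(n_leaves, rooted = TRUE,
                     tip.label = sprintf("SP%03d", seq_len(n_leaves)))
  labs <- .nodeLabels(tree)
  cw <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- n_leaves
  root <- n_tip + 1L

  fam_names <- sprintf("fam%03d", seq_len(n_families))
  counts <- matrix(0L, nrow = n_families, ncol = n_tip,
                   dimnames = list(fam_names, tree$tip.label))
  root_counts <- integer(n_families)
  ev_rows <- list()
  for (k in seq_len(n_families)) {
    states <- integer(n_tip + tree$Nnode)
    states[root] <- sample(0:3, 1)
    root_counts[k] <- states[root]
    n_ev <- 0L
    for (e in seq_len(nrow(cw$edge))) {
      par <- cw$edge[e, 1]; ch <- cw$edge[e, 2]
      s <- states[par]; t <- s; ev <- NA_character_
      u <- if (n_ev >= max_events_per_family) 1 else stats::runif(1)
      if (s == 0L) {
        if (u < rates["gain"]) { t <- sample(1:2, 1); ev <- "gain" }
      } else if (u < rates["loss"]) {
        t <- 0L; ev <- "loss"
      } else if (u < rates["loss"] + rates["shift"]) {
        dir <- if (s == 1L) 1L else sample(c(-1L, 1L), 1)
        t <- min(s + dir, 10L)
        ev <- if (t > s) "expansion" else if (t < s) "contraction" else NA
      }
      states[ch] <- t
      if (!is.na(ev)) n_ev <- n_ev + 1L
      if (!is.na(ev))
        ev_rows[[length(ev_rows) + 1L]] <- data.frame(
          family = fam_names[k], child = labs[ch], event = ev,
          from = s, to = t, stringsAsFactors = FALSE)
    }
    counts[k, ] <- states[seq_len(n_tip)]
  }
  events <- if (length(ev_rows)) do.call(rbind, ev_rows) else
    data.frame(family = character(0), child = character(0),
               event = character(0), from = integer(0), to = integer(0))
  cm <- new("TAPCountMatrix", SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts)))
  if (!is.na(tree_path)) ape::write.tree(tree, tree_path)
  if (!is.na(matrix_path)) writeCountMatrix(cm, matrix_path)
  list(tree = tree, counts = cm, events = events, root_counts = root_counts)
}

#' Fraction of planted events recovered by parsimony reconstruction
#'
#' Reconstructs every simulated family with \code{\link{wagnerReconstruct}}
#' and scores the fraction of planted events that reappear with the same
#' branch (child node) and event type.
#'
#' @param history result of \code{\link{generateHistory}}.
#' @param gain_penalty passed to the reconstruction.
#' @return list with \code{recovery} (fraction in \code{[0, 1]}; \code{NaN}
#'   when no event was planted), \code{n_planted}, \code{n_recovered}.
#' @export
eventRecovery <- function(history, gain_penalty = 1) {
  fits <- reconstructFamilies(history$counts, history$tree,
                              gain_penalty = gain_penalty)
  rec <- do.call(rbind, lapply(fits, classifyBranchEvents))
  planted <- history$events
  key <- function(d) paste(d$family, d$child, d$event)
  hit <- key(planted) %in% key(rec[rec$event != "none", , drop = FALSE])
  list(recovery = mean(hit), n_planted = nrow(planted),
       n_recovered = sum(hit))
}
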