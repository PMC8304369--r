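# shared fixture builders and independent oracles

# one-row domain hit with sensible defaults
hit <- function(protein = "p1", domain = "zf-C2H2", score = 25,
                ievalue = 1e-10, hmm_from = 1L, hmm_to = 23L,
                ali_from = 1L, ali_to = hmm_to - hmm_from + 1L) {
  data.frame(protein_id = protein, domain = domain,
             full_seq_evalue = ievalue, domain_ievalue = ievalue,
             domain_score = score,
             hmm_from = as.integer(hmm_from), hmm_to = as.integer(hmm_to),
             ali_from = as.integer(ali_from), ali_to = as.integer(ali_to),
             stringsAsFactors = FALSE)
}

hits <- function(...) do.call(rbind, list(...))

tinyLibrary <- function() {
  profileLibrary(
    domain = c("zf-C2H2", "HLH", "bZIP_AUREO", "bZIP_CDD", "HMG_box", "PHD"),
    model_length = c(23L, 54L, 100L, 100L, 70L, 52L),
    ga_threshold = c(9.45, 14.00, 22.00, 20.00, 21.20, 16.00),
    coverage_threshold = c(NA, NA, 0.75, 0.50, NA, NA))
}

# exact two-sided Wilcoxon rank-sum p-value by full enumeration of rank
# assignments — independent of stats::wilcox.test
enumWilcoxP <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(a)])
  combos <- utils::combn(length(pooled), length(a))
  ws <- apply(combos, 2, function(ix) sum(r[ix]))
  p <- 2 * min(mean(ws <= w_obs), mean(ws >= w_obs))
  min(p, 1)
}

# random small Wagner instance for oracle comparisons
randomWagnerInstance <- function(max_leaves = 8L, max_count = 5L) {
  n <- sample(3:max_leaves, 1)
  tr <- ape::rtree(n)
  counts <- stats::setNames(sample(0:max_count, n, replace = TRUE),
                            tr$tip.label)
  list(tree = tr, counts = counts)
}
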