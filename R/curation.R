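#' Read a seed alignment from aligned FASTA
#'
#' @param path FASTA file of aligned (equal-length, gapped) protein
#'   sequences.
#' @param domain domain name to attach.
#' @return list with \code{domain}, \code{sequences} (an
#'   \code{AAStringSet}), \code{seed_size}.
#' @export
readSeedAlignment <- function(path, domain = NA_character_) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) && length(unique(Biostrings::width(seqs))) != 1L)
    stop("seed alignment rows differ in length")
  list(domain = domain, sequences = seqs, seed_size = length(seqs))
}

#' Cap on the number of sequences that may augment a seed alignment
#'
#' New sequences must not exceed a quarter of the original seed alignment,
#' so the cap is \code{floor(0.25 * seed_size)}.
#'
#' @param seed_size number of sequences in the original seed alignment.
#' @return integer cap.
#' @examples
#' computeCap(40)  # 10
#' @export
computeCap <- function(seed_size) {
  stopifnot(seed_size >= 1)
  as.integer(floor(0.25 * seed_size))
}

#' Select candidate sequences to rebalance a biased seed alignment
#'
#' Implements the selection policy for augmenting a taxonomically biased
#' seed alignment: incomplete candidates are screened out first; the
#' survivors are ranked into tiers by species pass, so that tier 1 holds one
#' sequence per distinct (group, species) pair, tier 2 the second sequence
#' of any species, and so on — as many groups and species as possible are
#' represented before any is repeated. Tiers are taken in full while they
#' fit under the cap; the first tier that does not fit is thinned by
#' allocating the remaining slots round-robin over taxon groups and breaking
#' the leftover ties uniformly at random under \code{rng_seed}. The result
#' is deterministic given the pool order, cap and seed.
#'
#' @param pool data.frame with columns \code{id}, \code{species},
#'   \code{group}, \code{complete} (logical).
#' @param cap maximum number of sequences to select (see
#'   \code{\link{computeCap}}).
#' @param rng_seed integer seed driving the random-elimination tier only.
#' @return data.frame of the selected pool rows with an extra column
#'   \code{tier}: the round-robin pass on which each sequence was picked.
#' @export
selectAugmentation <- function(pool, cap, rng_seed = 1L) {
  stopifnot(cap >= 0)
  req <- c("id", "species", "group", "complete")
  if (!all(req %in% names(pool)))
    stop("pool must have columns: ", paste(req, collapse = ", "))
  pool <- pool[pool$complete, , drop = FALSE]
  if (cap == 0L || !nrow(pool)) {
    out <- pool[integer(0), , drop = FALSE]
    out$tier <- integer(0)
    return(out)
  }

  # tier = species pass: tier 1 holds one sequence per distinct
  # (group, species) pair, tier 2 the second sequence of a species, ...
  pool$tier <- stats::ave(seq_len(nrow(pool)),
                          paste(pool$group, pool$species, sep = "\r"),
                          FUN = seq_along)

  local_seed <- function(expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(rng_seed)
    expr
  }

  picked <- integer(0)
  remaining <- cap
  for (t in sort(unique(pool$tier))) {
    members <- which(pool$tier == t)
    if (length(members) <= remaining) {
      picked <- c(picked, members)
      remaining <- remaining - length(members)
      if (remaining == 0L) break
      next
    }
    # final tier: members are identical in priority; allocate slots as
    # evenly as possible over groups (round-robin) and break the remaining
    # ties uniformly at random under the seed
    grp <- pool$group[members]
    within_rank <- local_seed({
      r <- integer(length(members))
      for (g in unique(grp)) {
        gi <- which(grp == g)
        r[sample(gi)] <- seq_along(gi)
      }
      r
    })
    ord <- order(within_rank, match(grp, unique(grp)))
    picked <- c(picked, members[ord][seq_len(remaining)])
    break
  }
  out <- pool[sort(picked), , drop = FALSE]
  rownames(out) <- NULL
  out
}
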