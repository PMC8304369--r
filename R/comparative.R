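#' Build a families-by-species TAP count matrix
#'
#' @param profiles named list: per species (five-letter code), a named
#'   integer vector of family counts as returned by
#'   \code{\link{genomeTapProfile}}.
#' @param family_universe optional character vector fixing the row set and
#'   order; defaults to the union of families in first-appearance order.
#'   Missing (family, species) pairs are filled with 0.
#' @return a \linkS4class{TAPCountMatrix}.
#' @export
buildCountMatrix <- function(profiles, family_universe = NULL) {
  sp <- names(profiles)
  if (anyDuplicated(sp)) stop("duplicate species names")
  if (is.null(family_universe))
    family_universe <- unique(unlist(lapply(profiles, names), use.names = FALSE))
  m <- matrix(0L, nrow = length(family_universe), ncol = length(sp),
              dimnames = list(family_universe, sp))
  for (s in sp) {
    v <- profiles[[s]]
    if (!length(v)) next
    if (any(v < 0)) stop("negative count for species ", s)
    unknown <- setdiff(names(v), family_universe)
    if (length(unknown))
      stop("family outside family_universe: ", paste(unknown, collapse = ", "))
    m[names(v), s] <- as.integer(v)
  }
  new("TAPCountMatrix", SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m)))
}

#' TAP counts as an integer matrix
#'
#' @param x a \linkS4class{TAPCountMatrix}.
#' @return the families-by-species integer matrix.
#' @export
tapCounts <- function(x) {
  stopifnot(is(x, "TAPCountMatrix"))
  SummarizedExperiment::assay(x, "counts")
}

#' Read / write a count matrix as TSV (families in rows, species in columns)
#'
#' @param path file path.
#' @return \code{readCountMatrix}: a \linkS4class{TAPCountMatrix}.
#' @export
readCountMatrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  new("TAPCountMatrix", SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m)))
}

#' @rdname readCountMatrix
#' @param x a \linkS4class{TAPCountMatrix}.
#' @export
writeCountMatrix <- function(x, path) {
  m <- tapCounts(x)
  df <- data.frame(family = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Keep families present in at least one focal species
#'
#' Retains exactly the families with a count of one or more in at least one
#' of the focal species; the species columns are unchanged. This is the
#' filter used to restrict a broad family catalogue to the families observed
#' in a clade of interest before ordination.
#'
#' @param x a \linkS4class{TAPCountMatrix}.
#' @param focal_species character vector of species codes, a subset of the
#'   matrix columns.
#' @return the filtered \linkS4class{TAPCountMatrix}.
#' @export
selectFamiliesWithPresence <- function(x, focal_species) {
  m <- tapCounts(x)
  unknown <- setdiff(focal_species, colnames(m))
  if (length(unknown))
    stop("unknown focal species: ", paste(unknown, collapse = ", "))
  keep <- rowSums(m[, focal_species, drop = FALSE] >= 1L) >= 1L
  x[keep, ]
}

#' Normality-gated two-group comparison of family sizes
#'
#' Compares the counts of one family (or the per-species totals over all
#' families, \code{family_or_total = "total"}) between two disjoint species
#' groups. Each group is screened with a Shapiro\enc{–}{-}Wilk test; if both
#' groups are consistent with normality at \code{alpha_normality}, a
#' two-sided two-sample t-test is used, otherwise a two-sided Wilcoxon
#' rank-sum test (exact for small untied samples, normal approximation with
#' tie correction otherwise). Groups with constant values cannot be screened
#' and fall through to the Wilcoxon route, flagged in the result.
#'
#' @param x a \linkS4class{TAPCountMatrix}.
#' @param family_or_total a family name, or \code{"total"}.
#' @param group_a,group_b disjoint character vectors of species codes,
#'   each of size >= 3.
#' @param alpha_normality significance level of the normality gate.
#' @param pool_groups if \code{TRUE}, the Shapiro\enc{–}{-}Wilk screen is run
#'   once on the mean-centred values pooled over both groups instead of per
#'   group.
#' @return data.frame (one row): \code{family_or_total}, \code{n_a},
#'   \code{n_b}, \code{mean_a}, \code{mean_b}, \code{normality_p} (minimum
#'   over groups, or the pooled p), \code{test_used} ("t-test" or
#'   "Wilcoxon"), \code{p_value}, \code{degenerate} (TRUE when the normality
#'   gate could not run).
#' @export
compareGroups <- function(x, family_or_total, group_a, group_b,
                          alpha_normality = 0.05, pool_groups = FALSE) {
  m <- tapCounts(x)
  groups <- c(group_a, group_b)
  unknown <- setdiff(groups, colnames(m))
  if (length(unknown)) stop("unknown species: ", paste(unknown, collapse = ", "))
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  if (length(group_a) < 3L || length(group_b) < 3L)
    stop("each group needs >= 3 species for the normality gate")
  vals <- if (identical(family_or_total, "total")) colSums(m) else {
    if (!family_or_total %in% rownames(m))
      stop("unknown family: ", family_or_total)
    m[family_or_total, ]
  }
  a <- as.numeric(vals[group_a]); b <- as.numeric(vals[group_b])

  if (length(unique(c(a, b))) == 1L) {
    # perfectly constant data: no evidence of any difference
    return(data.frame(family_or_total = family_or_total,
                      n_a = length(a), n_b = length(b),
                      mean_a = mean(a), mean_b = mean(b),
                      normality_p = NA_real_, test_used = "Wilcoxon",
                      p_value = 1, degenerate = TRUE,
                      stringsAsFactors = FALSE))
  }
  degenerate <- FALSE
  norm_p <- NA_real_
  if (pool_groups) {
    pooled <- c(a - mean(a), b - mean(b))
    if (length(unique(pooled)) < 3L) degenerate <- TRUE
    else norm_p <- stats::shapiro.test(pooled)$p.value
  } else {
    pa <- if (length(unique(a)) >= 3L) stats::shapiro.test(a)$p.value else NA_real_
    pb <- if (length(unique(b)) >= 3L) stats::shapiro.test(b)$p.value else NA_real_
    if (is.na(pa) || is.na(pb)) degenerate <- TRUE
    else norm_p <- min(pa, pb)
  }
  normal <- !degenerate && norm_p > alpha_normality

  if (normal) {
    test_used <- "t-test"
    p <- stats::t.test(a, b, alternative = "two.sided")$p.value
  } else {
    test_used <- "Wilcoxon"
    has_ties <- anyDuplicated(c(a, b)) > 0
    exact <- !has_ties && length(a) <= 10L && length(b) <= 10L
    p <- suppressWarnings(stats::wilcox.test(
      a, b, alternative = "two.sided", exact = exact,
      correct = !exact)$p.value)
  }
  data.frame(family_or_total = family_or_total,
             n_a = length(a), n_b = length(b),
             mean_a = mean(a), mean_b = mean(b),
             normality_p = norm_p, test_used = test_used, p_value = p,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Principal component analysis of a TAP count matrix
#'
#' Species are the observations and families the variables. The matrix is
#' column-centred (variance scaling off by default) and decomposed by SVD.
#' Component signs are fixed deterministically by making the
#' largest-magnitude loading of each component positive. Variance fractions
#' are the squared singular values normalised to sum to one.
#'
#' @param x a \linkS4class{TAPCountMatrix} with >= 2 species.
#' @param scale. if \code{TRUE}, variables are additionally scaled to unit
#'   variance (constant families are dropped first in that case).
#' @return list with \code{scores} (species x components), \code{loadings}
#'   (families x components), \code{variance_fraction} (per component, sums
#'   to 1 over all components).
#' @export
runPCA <- function(x, scale. = FALSE) {
  m <- t(tapCounts(x))  # species x families
  if (nrow(m) < 2L) stop("PCA needs at least 2 species")
  if (scale.) m <- m[, apply(m, 2, stats::sd) > 0, drop = FALSE]
  pc <- stats::prcomp(m, center = TRUE, scale. = scale.)
  # deterministic sign: largest-|loading| entry of each component positive
  for (k in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[i, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation, variance_fraction = vf)
}
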