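#' @import methods
#' @importFrom stats setNames
NULL

setOldClass("phylo")

#' Profile metadata library
#'
#' Holds per-profile metadata needed to filter domain hits: the profile
#' (domain) name, the model length in match states, the gathering (GA)
#' bit-score threshold, and an optional model-coverage threshold.
#'
#' @slot profiles data.frame with columns \code{domain}, \code{model_length},
#'   \code{ga_threshold}, \code{coverage_threshold} (NA when no coverage
#'   filter applies to the profile).
#' @export
setClass("ProfileLibrary", representation(profiles = "data.frame"))

setValidity("ProfileLibrary", function(object) {
  p <- object@profiles
  req <- c("domain", "model_length", "ga_threshold", "coverage_threshold")
  if (!all(req %in% names(p)))
    return(paste("profiles must have columns:", paste(req, collapse = ", ")))
  if (anyDuplicated(p$domain))
    return("duplicate domain names in profile library")
  if (nrow(p) && any(p$model_length < 1 | p$model_length != floor(p$model_length)))
    return("model_length must be a positive integer")
  cov <- p$coverage_threshold
  if (any(!is.na(cov) & (cov < 0 | cov > 1)))
    return("coverage_threshold must lie in [0, 1]")
  TRUE
})

#' TAP family rule set
#'
#' A family is defined by the domains its members must carry (\code{should})
#' and the domains that veto membership (\code{should not}). Families may
#' additionally be labelled with a TAP class: TF (transcription factor),
#' TR (transcriptional regulator) or PT (putative TAP).
#'
#' @slot should named list; per family, the character vector of required
#'   domains (non-empty).
#' @slot shouldNot named list; per family, the character vector of forbidden
#'   domains (possibly empty).
#' @slot classification named character; per family, one of
#'   \code{"TF"}, \code{"TR"}, \code{"PT"}.
#' @export
setClass("TAPRuleSet", representation(
  should = "list", shouldNot = "list", classification = "character"))

setValidity("TAPRuleSet", function(object) {
  fams <- names(object@should)
  if (anyDuplicated(fams)) return("duplicate family names")
  if (!identical(sort(fams), sort(names(object@shouldNot))))
    return("should and shouldNot must cover the same families")
  for (f in fams) {
    if (length(object@should[[f]]) == 0)
      return(sprintf("family '%s' has no required (should) domain", f))
    if (length(intersect(object@should[[f]], object@shouldNot[[f]])))
      return(sprintf("family '%s' lists a domain as both should and should not", f))
  }
  cls <- object@classification
  if (length(cls) && !all(cls %in% c("TF", "TR", "PT")))
    return("classification values must be TF, TR or PT")
  if (length(cls) && !all(names(cls) %in% fams))
    return("classification refers to unknown families")
  TRUE
})

#' Families-by-species TAP count matrix
#'
#' A \linkS4class{SummarizedExperiment} whose single assay \code{"counts"}
#' holds non-negative integer TAP family sizes; rows are families, columns
#' are species (conventionally five-letter codes).
#'
#' @export
setClass("TAPCountMatrix", contains = "SummarizedExperiment")

setValidity("TAPCountMatrix", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  m <- SummarizedExperiment::assay(object, "counts")
  if (anyDuplicated(rownames(m))) return("duplicate family names")
  if (anyDuplicated(colnames(m))) return("duplicate species codes")
  if (length(m) && (any(m < 0) || any(m != floor(m))))
    return("counts must be non-negative integers")
  TRUE
})

#' Ancestral family-size reconstruction on a species tree
#'
#' Result of asymmetric Wagner parsimony for one family: an integer state for
#' every node of the tree (leaf states equal the observed counts) and the
#' minimal total branch cost, where a per-unit increase costs
#' \code{gainPenalty} and a per-unit decrease costs 1.
#'
#' @slot tree the rooted \code{phylo} tree the states live on.
#' @slot states integer vector over nodes, indexed in ape node order
#'   (1..Ntip are leaves, then internal nodes).
#' @slot cost minimal total cost of the reconstruction.
#' @slot gainPenalty cost of a one-unit increase along a branch.
#' @slot maxState upper bound of the integer state space used by the DP.
#' @slot family family label (informational).
#' @export
setClass("WagnerFit", representation(
  tree = "phylo", states = "integer", cost = "numeric",
  gainPenalty = "numeric", maxState = "integer", family = "character"))

setValidity("WagnerFit", function(object) {
  n_nodes <- length(object@tree$tip.label) + object@tree$Nnode
  if (length(object@states) != n_nodes)
    return("states must have one entry per tree node")
  if (any(object@states < 0)) return("states must be non-negative")
  if (object@gainPenalty <= 0) return("gainPenalty must be > 0")
  TRUE
})

setMethod("show", "ProfileLibrary", function(object) {
  cat(sprintf("ProfileLibrary with %d profiles\n", nrow(object@profiles)))
  if (nrow(object@profiles)) {
    n_cov <- sum(!is.na(object@profiles$coverage_threshold))
    cat(sprintf("  GA thresholds set: %d; coverage filters: %d\n",
                sum(!is.na(object@profiles$ga_threshold)), n_cov))
  }
})

setMethod("show", "TAPRuleSet", function(object) {
  cat(sprintf("TAPRuleSet with %d families\n", length(object@should)))
  n_veto <- sum(lengths(object@shouldNot) > 0)
  cat(sprintf("  families with should-not vetoes: %d\n", n_veto))
})

setMethod("show", "TAPCountMatrix", function(object) {
  cat(sprintf("TAPCountMatrix: %d families x %d species\n",
              nrow(object), ncol(object)))
  callNextMethod()
})

setMethod("show", "WagnerFit", function(object) {
  cat(sprintf("WagnerFit%s: cost %.3f (gain penalty %g, states 0..%d)\n",
              if (length(object@family)) paste0(" [", object@family, "]") else "",
              object@cost, object@gainPenalty, object@maxState))
})

#' @describeIn ProfileLibrary-class profile metadata as a data.frame
#' @param x a \code{ProfileLibrary}
#' @export
profiles <- function(x) {
  stopifnot(is(x, "ProfileLibrary"))
  x@profiles
}

#' @describeIn TAPRuleSet-class family names covered by the rules
#' @param x a \code{TAPRuleSet}
#' @export
familyNames <- function(x) {
  stopifnot(is(x, "TAPRuleSet"))
  names(x@should)
}

#' @describeIn TAPRuleSet-class required (should) domains of one family
#' @param family family name
#' @export
shouldDomains <- function(x, family) {
  stopifnot(is(x, "TAPRuleSet"))
  x@should[[family]]
}

#' @describeIn TAPRuleSet-class forbidden (should-not) domains of one family
#' @export
shouldNotDomains <- function(x, family) {
  stopifnot(is(x, "TAPRuleSet"))
  x@shouldNot[[family]]
}

#' @describeIn TAPRuleSet-class TF/TR/PT class labels, named by family
#' @export
familyClass <- function(x) {
  stopifnot(is(x, "TAPRuleSet"))
  x@classification
}

#' @describeIn WagnerFit-class reconstructed state of every node, in ape
#'   node order
#' @param x a \code{WagnerFit}
#' @export
nodeStates <- function(x) {
  stopifnot(is(x, "WagnerFit"))
  x@states
}

#' @describeIn WagnerFit-class minimal total reconstruction cost
#' @export
totalCost <- function(x) {
  stopifnot(is(x, "WagnerFit"))
  x@cost
}
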