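#' Construct a TAP family rule set
#'
#' @param should named list: per family, character vector of required domains.
#' @param shouldNot named list: per family, character vector of forbidden
#'   domains; families omitted here get an empty veto list.
#' @param classification named character: optional TF/TR/PT label per family.
#' @return a \linkS4class{TAPRuleSet}.
#' @export
ruleSet <- function(should, shouldNot = list(), classification = character(0)) {
  fams <- names(should)
  sn <- setNames(vector("list", length(fams)), fams)
  for (f in fams) sn[[f]] <- as.character(shouldNot[[f]] %||% character(0))
  new("TAPRuleSet", should = lapply(should, as.character), shouldNot = sn,
      classification = classification)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a family rule table
#'
#' Each non-comment line is a semicolon-separated triplet
#' \code{family; domain; should} or \code{family; domain; should not}
#' (whitespace around fields is ignored; \code{#} starts a comment line).
#' An optional \code{family; CLASS; class} line records the family's TAP
#' class, where CLASS is TF, TR or PT. Any other third field is an error:
#' unknown rule kinds are rejected rather than guessed at.
#'
#' @param path file path.
#' @return a \linkS4class{TAPRuleSet}.
#' @export
readRules <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  should <- list(); shouldNot <- list(); cls <- character(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    f <- trimws(strsplit(ln, ";")[[1]])
    if (length(f) != 3L)
      stop(sprintf("rule parse error at line %d: expected 'family; domain; kind'", i))
    fam <- f[1]; dom <- f[2]; kind <- f[3]
    if (kind == "should") {
      should[[fam]] <- c(should[[fam]], dom)
      shouldNot[[fam]] <- shouldNot[[fam]] %||% character(0)
    } else if (kind == "should not") {
      shouldNot[[fam]] <- c(shouldNot[[fam]], dom)
    } else if (kind == "class") {
      if (!dom %in% c("TF", "TR", "PT"))
        stop(sprintf("rule parse error at line %d: class must be TF, TR or PT", i))
      cls[fam] <- dom
    } else {
      stop(sprintf("rule parse error at line %d: unknown rule kind '%s'", i, kind))
    }
  }
  # a should-not line may precede/outlive its should lines only if the family
  # gains at least one should domain overall
  orphan <- setdiff(names(shouldNot), names(should))
  if (length(orphan))
    stop("family with should-not rules but no should domain: ",
         paste(orphan, collapse = ", "))
  ruleSet(should, shouldNot, cls)
}

#' Write a rule set in the semicolon-triplet dialect
#'
#' @param rules a \linkS4class{TAPRuleSet}.
#' @param path output file path.
#' @export
writeRules <- function(rules, path) {
  stopifnot(is(rules, "TAPRuleSet"))
  lines <- character(0)
  for (f in names(rules@should)) {
    lines <- c(lines,
               sprintf("%s; %s; should", f, rules@should[[f]]),
               sprintf("%s; %s; should not", f, rules@shouldNot[[f]]))
    if (f %in% names(rules@classification))
      lines <- c(lines, sprintf("%s; %s; class", f, rules@classification[[f]]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Candidate families for one protein's filtered hits
#'
#' A family is a candidate iff every one of its should-domains has at least
#' one hit and none of its should-not-domains has any. The candidate's
#' representative E-value is the minimum independent domain E-value over its
#' should-domain hits. Families knocked out by a forbidden domain are
#' reported with the offending domain. Hits are expected to be GA/coverage
#' filtered already: a sub-threshold forbidden domain does not veto.
#'
#' @param hits data.frame of filtered hits, all of one protein.
#' @param rules a \linkS4class{TAPRuleSet}.
#' @return list with elements \code{candidates} (data.frame \code{family},
#'   \code{evalue}) and \code{vetoed} (data.frame \code{family},
#'   \code{forbidden_domain}).
#' @export
candidateFamilies <- function(hits, rules) {
  stopifnot(is(rules, "TAPRuleSet"))
  doms <- unique(hits$domain)
  cand <- list(); veto <- list()
  for (f in names(rules@should)) {
    if (!all(rules@should[[f]] %in% doms)) next
    bad <- intersect(rules@shouldNot[[f]], doms)
    if (length(bad)) {
      veto[[length(veto) + 1L]] <- data.frame(
        family = f, forbidden_domain = bad[1], stringsAsFactors = FALSE)
      next
    }
    ev <- min(hits$domain_ievalue[hits$domain %in% rules@should[[f]]])
    cand[[length(cand) + 1L]] <- data.frame(
      family = f, evalue = ev, stringsAsFactors = FALSE)
  }
  list(candidates = if (length(cand)) do.call(rbind, cand) else
         data.frame(family = character(0), evalue = numeric(0)),
       vetoed = if (length(veto)) do.call(rbind, veto) else
         data.frame(family = character(0), forbidden_domain = character(0)))
}

#' Resolve competing candidate families
#'
#' The family with the smallest (strongest) representative E-value wins;
#' exact ties are broken lexicographically by family name. No candidates
#' resolves to \code{NA}.
#'
#' @param candidates data.frame with columns \code{family}, \code{evalue}.
#' @return the winning family name, or \code{NA_character_}.
#' @export
resolveAssignment <- function(candidates) {
  if (!nrow(candidates)) return(NA_character_)
  stopifnot(all(candidates$evalue > 0))
  best <- candidates$evalue == min(candidates$evalue)
  sort(candidates$family[best])[1]
}

#' Classify a proteome's domain hits into TAP families
#'
#' Per protein: hits are GA/coverage filtered, candidate families evaluated
#' under the should/should-not rules, and competitors resolved by E-value.
#' Each protein receives at most one family; proteins with no surviving
#' candidate get \code{NA}. The result is a pure function of its inputs.
#'
#' @param hits data.frame of raw domain hits (whole proteome).
#' @param library a \linkS4class{ProfileLibrary}.
#' @param rules a \linkS4class{TAPRuleSet}.
#' @return data.frame with one row per protein seen in \code{hits}, in first
#'   appearance order: \code{protein_id}, \code{family} (NA if none),
#'   \code{class} (TF/TR/PT or NA), \code{evalue} (representative E-value of
#'   the winning family), \code{n_support} (number of filtered hits of the
#'   winning family's should-domains). The attribute \code{"vetoed"} holds a
#'   data.frame (\code{protein_id}, \code{family}, \code{forbidden_domain})
#'   of candidacies knocked out by a forbidden domain.
#' @export
classifyProteome <- function(hits, library, rules) {
  kept <- filterHits(hits, library)
  prot_ids <- unique(hits$protein_id)
  n <- length(prot_ids)
  fam <- rep(NA_character_, n); ev <- rep(NA_real_, n)
  nsupp <- integer(n); vetoes <- list()
  by_prot <- split(seq_len(nrow(kept)), factor(kept$protein_id, levels = prot_ids))
  for (i in seq_len(n)) {
    ph <- kept[by_prot[[i]], , drop = FALSE]
    if (!nrow(ph)) next
    cf <- candidateFamilies(ph, rules)
    if (nrow(cf$vetoed))
      vetoes[[length(vetoes) + 1L]] <- cbind(protein_id = prot_ids[i], cf$vetoed)
    win <- resolveAssignment(cf$candidates)
    if (is.na(win)) next
    fam[i] <- win
    ev[i] <- cf$candidates$evalue[cf$candidates$family == win]
    nsupp[i] <- sum(ph$domain %in% rules@should[[win]])
  }
  cls <- rules@classification[fam]
  out <- data.frame(protein_id = prot_ids, family = fam,
                    class = ifelse(is.na(fam), NA_character_, unname(cls)),
                    evalue = ev, n_support = nsupp, stringsAsFactors = FALSE)
  attr(out, "vetoed") <- if (length(vetoes)) do.call(rbind, vetoes) else
    data.frame(protein_id = character(0), family = character(0),
               forbidden_domain = character(0))
  out
}

#' Per-family TAP counts of one genome
#'
#' @param assignments data.frame from \code{\link{classifyProteome}}.
#' @return named integer vector of protein counts per assigned family;
#'   unassigned proteins are excluded.
#' @export
genomeTapProfile <- function(assignments) {
  fam <- assignments$family[!is.na(assignments$family)]
  if (!length(fam)) return(setNames(integer(0), character(0)))
  tab <- table(fam)
  setNames(as.integer(tab), names(tab))
}

#' Demonstration profile library
#'
#' Covers the domains used by \code{\link{demoRuleSet}}. The zf-C2H2 and HLH
#' gathering thresholds (9.45 and 14.00 bits) and the bZIP_AUREO/bZIP_CDD
#' coverage cutoffs (0.75 and 0.50) are the tuned production values; the
#' remaining thresholds are demonstration values.
#'
#' @return a \linkS4class{ProfileLibrary}.
#' @export
demoProfileLibrary <- function() {
  profileLibrary(
    domain = c("zf-C2H2", "HLH", "bZIP_1", "bZIP_2", "bZIP_AUREO", "bZIP_CDD",
               "AP2", "HMG_box", "Homeobox", "PHD", "CBFD_NFYB_HMF",
               "SNF2_N", "HSF_DNA-bind"),
    model_length = c(23L, 54L, 65L, 50L, 60L, 55L, 57L, 70L, 57L, 52L,
                     92L, 390L, 99L),
    ga_threshold = c(9.45, 14.00, 20.10, 17.40, 22.00, 20.00, 16.50, 21.20,
                     17.90, 16.00, 24.00, 26.10, 22.30),
    coverage_threshold = c(NA, NA, NA, NA, 0.75, 0.50, NA, NA, NA, NA,
                           NA, NA, NA))
}

#' Demonstration TAP family rule set
#'
#' A compact rule catalogue covering the families whose rules changed between
#' rule-set versions 2 and 3: the bZIP umbrella with its bZIPAUREO/bZIPCDD
#' refinements (vetoed by HLH and Homeobox), and the HMG multi-domain fix, in
#' which PHD, CCAAT_HAP5 and SWI/SNF_SNF2 acquire an HMG_box veto so that
#' HMG-box multi-domain proteins resolve to HMG. \code{version = 2} returns
#' the rule set without the HMG_box vetoes and without the bZIP refinement
#' families.
#'
#' @param version 2 or 3.
#' @return a \linkS4class{TAPRuleSet}.
#' @export
demoRuleSet <- function(version = 3) {
  stopifnot(version %in% c(2, 3))
  should <- list(
    C2H2 = "zf-C2H2",
    bHLH = "HLH",
    bZIP = "bZIP_1",
    `AP2/EREBP` = "AP2",
    HMG = "HMG_box",
    PHD = "PHD",
    CCAAT_HAP5 = "CBFD_NFYB_HMF",
    `SWI/SNF_SNF2` = "SNF2_N",
    HSF = "HSF_DNA-bind")
  shouldNot <- list(bZIP = c("HLH", "Homeobox"))
  cls <- c(C2H2 = "TF", bHLH = "TF", bZIP = "TF", `AP2/EREBP` = "TF",
           HMG = "TR", PHD = "TR", CCAAT_HAP5 = "TF", `SWI/SNF_SNF2` = "TR",
           HSF = "TF", bZIPAUREO = "TF", bZIPCDD = "TF")
  if (version == 3) {
    should$bZIPAUREO <- "bZIP_AUREO"
    should$bZIPCDD <- "bZIP_CDD"
    shouldNot$bZIPAUREO <- c("HLH", "Homeobox")
    shouldNot$bZIPCDD <- c("HLH", "Homeobox")
    shouldNot$PHD <- "HMG_box"
    shouldNot$CCAAT_HAP5 <- "HMG_box"
    shouldNot$`SWI/SNF_SNF2` <- "HMG_box"
  } else {
    cls <- cls[!names(cls) %in% c("bZIPAUREO", "bZIPCDD")]
  }
  ruleSet(should, shouldNot, cls)
}
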