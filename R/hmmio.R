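#' Construct a profile library from metadata
#'
#' @param domain character vector of profile (domain) names.
#' @param model_length integer vector, number of match states per model.
#' @param ga_threshold numeric vector of gathering (GA) bit-score cutoffs;
#'   \code{NA} marks a profile whose GA must be supplied before filtering.
#' @param coverage_threshold numeric vector in \code{[0, 1]} or \code{NA};
#'   minimum fraction of the model a hit must span. \code{NA} disables the
#'   coverage filter for that profile.
#' @return a \linkS4class{ProfileLibrary}.
#' @examples
#' profileLibrary(c("zf-C2H2", "HLH"), c(23L, 54L), c(9.45, 14.00))
#' @export
profileLibrary <- function(domain, model_length, ga_threshold = NA_real_,
                           coverage_threshold = NA_real_) {
  df <- data.frame(domain = as.character(domain),
                   model_length = as.integer(model_length),
                   ga_threshold = as.numeric(rep_len(ga_threshold, length(domain))),
                   coverage_threshold = as.numeric(rep_len(coverage_threshold,
                                                           length(domain))),
                   stringsAsFactors = FALSE)
  new("ProfileLibrary", profiles = df)
}

#' Read profile metadata from a TSV sheet or HMMER3 profile file
#'
#' Two formats are accepted and auto-detected. A tab-separated sheet with a
#' header line and columns \code{domain}, \code{model_length},
#' \code{ga_threshold} and optionally \code{coverage_threshold}; or a HMMER3
#' ASCII profile flatfile, from which the \code{NAME}, \code{LENG} and
#' (when present) \code{GA} header lines of every model are taken. Profiles
#' without a GA line are recorded with \code{NA} and must be given a
#' threshold before \code{\link{filterHits}} will accept their hits.
#'
#' @param path file path.
#' @return a \linkS4class{ProfileLibrary}.
#' @export
readProfileMeta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("^HMMER3", lines))) {
    return(.parseHmmHeaders(lines))
  }
  .parseMetaSheet(lines, path)
}

.parseMetaSheet <- function(lines, path) {
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) return(profileLibrary(character(0), integer(0)))
  df <- utils::read.delim(text = lines, header = TRUE,
                          stringsAsFactors = FALSE)
  req <- c("domain", "model_length", "ga_threshold")
  if (!all(req %in% names(df)))
    stop("metadata sheet must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(df$domain))
    stop("duplicate domain name in metadata sheet: ",
         df$domain[duplicated(df$domain)][1])
  if (any(is.na(df$model_length)))
    stop("missing model_length in metadata sheet")
  cov <- if ("coverage_threshold" %in% names(df))
    as.numeric(df$coverage_threshold) else NA_real_
  profileLibrary(df$domain, df$model_length, as.numeric(df$ga_threshold), cov)
}

# NAME/LENG/GA lines of a (possibly multi-model) HMMER3 ASCII flatfile.
# GA lines look like "GA    25.00 25.00;" — the first number is the sequence
# threshold, used here as the per-domain cutoff as well.
.parseHmmHeaders <- function(lines) {
  name <- NA_character_; leng <- NA_integer_; ga <- NA_real_
  out <- list()
  flush <- function() {
    if (!is.na(name)) {
      if (is.na(leng)) stop("profile '", name, "' has no LENG line")
      out[[length(out) + 1L]] <<- data.frame(
        domain = name, model_length = leng, ga_threshold = ga,
        coverage_threshold = NA_real_, stringsAsFactors = FALSE)
    }
    name <<- NA_character_; leng <<- NA_integer_; ga <<- NA_real_
  }
  for (ln in lines) {
    if (grepl("^NAME\\s", ln)) {
      name <- sub("^NAME\\s+", "", ln)
    } else if (grepl("^LENG\\s", ln)) {
      leng <- as.integer(sub("^LENG\\s+", "", ln))
    } else if (grepl("^GA\\s", ln)) {
      ga <- as.numeric(strsplit(trimws(sub("^GA\\s+", "", ln)), "\\s+")[[1]][1])
    } else if (grepl("^//", ln)) {
      flush()
    }
  }
  flush()
  df <- do.call(rbind, out)
  if (is.null(df)) return(profileLibrary(character(0), integer(0)))
  if (anyDuplicated(df$domain))
    stop("duplicate domain name in profile file: ",
         df$domain[duplicated(df$domain)][1])
  new("ProfileLibrary", profiles = df)
}

# domtblout column layout (hmmsearch: target = protein, query = profile)
.DOMTBL_COLS <- c(protein_id = 1L, domain = 4L, model_length = 6L,
                  full_seq_evalue = 7L, domain_ievalue = 13L,
                  domain_score = 14L, hmm_from = 16L, hmm_to = 17L,
                  ali_from = 18L, ali_to = 19L)

#' Read a HMMER3 per-domain table (domtblout)
#'
#' Parses the whitespace-delimited per-domain tabular output of
#' \code{hmmsearch --domtblout}. One row is returned per domain record, in
#' file order; \code{#} comment lines are skipped. Column 1 is taken as the
#' protein (target) id and column 4 as the profile (query) name, the
#' \code{hmmsearch} orientation.
#'
#' @param path file path.
#' @return data.frame with columns \code{protein_id}, \code{domain},
#'   \code{full_seq_evalue}, \code{domain_ievalue}, \code{domain_score},
#'   \code{hmm_from}, \code{hmm_to}, \code{ali_from}, \code{ali_to}.
#' @export
readDomtbl <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  rows <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 22L)
      stop(sprintf("domtblout parse error at line %d: expected >= 22 columns, got %d",
                   i, length(f)))
    num <- suppressWarnings(as.numeric(
      f[.DOMTBL_COLS[c("full_seq_evalue", "domain_ievalue", "domain_score",
                       "hmm_from", "hmm_to", "ali_from", "ali_to")]]))
    if (anyNA(num))
      stop(sprintf("domtblout parse error at line %d: non-numeric score/coordinate field", i))
    rows[[k]] <- data.frame(
      protein_id = f[.DOMTBL_COLS["protein_id"]],
      domain = f[.DOMTBL_COLS["domain"]],
      full_seq_evalue = num[1], domain_ievalue = num[2], domain_score = num[3],
      hmm_from = as.integer(num[4]), hmm_to = as.integer(num[5]),
      ali_from = as.integer(num[6]), ali_to = as.integer(num[7]),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else .emptyHits()
  rownames(out) <- NULL
  .checkHits(out)
  out
}

.emptyHits <- function() {
  data.frame(protein_id = character(0), domain = character(0),
             full_seq_evalue = numeric(0), domain_ievalue = numeric(0),
             domain_score = numeric(0), hmm_from = integer(0),
             hmm_to = integer(0), ali_from = integer(0), ali_to = integer(0),
             stringsAsFactors = FALSE)
}

.checkHits <- function(hits) {
  if (!nrow(hits)) return(invisible(hits))
  if (any(hits$hmm_from > hits$hmm_to) || any(hits$ali_from > hits$ali_to))
    stop("invalid domain hit: coordinate start exceeds end")
  if (any(hits$hmm_from < 1L) || any(hits$ali_from < 1L))
    stop("invalid domain hit: coordinates must be >= 1")
  if (any(hits$full_seq_evalue <= 0) || any(hits$domain_ievalue <= 0))
    stop("invalid domain hit: E-values must be strictly positive")
  invisible(hits)
}

#' Fraction of the profile model spanned by a hit
#'
#' Coverage is measured on the model side: the number of match states the
#' hit aligns to, \code{hmm_to - hmm_from + 1}, divided by the model length.
#'
#' @param hmm_from,hmm_to 1-based inclusive model coordinates of the hit.
#' @param model_length model length of the profile.
#' @return coverage in \code{[0, 1]}; vectorised.
#' @examples
#' computeCoverage(26, 75, 100)  # 0.5
#' @export
computeCoverage <- function(hmm_from, hmm_to, model_length) {
  if (any(hmm_from < 1L) || any(hmm_to < hmm_from))
    stop("invalid model coordinates")
  if (any(hmm_to > model_length))
    stop("hmm_to exceeds model_length")
  (hmm_to - hmm_from + 1) / model_length
}

#' Filter domain hits by gathering threshold and model coverage
#'
#' Keeps exactly the hits whose per-domain bit score is at or above the
#' profile's GA threshold and, where the profile defines a coverage
#' threshold, whose model coverage is at or above it. Comparisons are
#' inclusive: a score or coverage exactly at the cutoff passes. Input order
#' is preserved and the operation is idempotent. Multiple surviving hits of
#' one domain on one protein are all retained.
#'
#' @param hits data.frame of domain hits as returned by
#'   \code{\link{readDomtbl}}.
#' @param library a \linkS4class{ProfileLibrary} covering every hit domain,
#'   each with a GA threshold.
#' @return the surviving subset of \code{hits}.
#' @export
filterHits <- function(hits, library) {
  stopifnot(is(library, "ProfileLibrary"))
  .checkHits(hits)
  if (!nrow(hits)) return(hits)
  p <- library@profiles
  m <- match(hits$domain, p$domain)
  if (anyNA(m))
    stop("hit domain absent from profile library: ",
         paste(unique(hits$domain[is.na(m)]), collapse = ", "))
  ga <- p$ga_threshold[m]
  if (anyNA(ga))
    stop("no GA threshold configured for domain: ",
         paste(unique(hits$domain[is.na(ga)]), collapse = ", "))
  cov <- computeCoverage(hits$hmm_from, hits$hmm_to, p$model_length[m])
  cov_thr <- p$coverage_threshold[m]
  keep <- hits$domain_score >= ga & (is.na(cov_thr) | cov >= cov_thr)
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
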