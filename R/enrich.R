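#' Upper-tail hypergeometric p-value for over-representation
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(population
#' \code{bgSize}, successes \code{bgHits}, draws \code{fgSize}) — the
#' probability of observing at least the seen overlap by random sampling from
#' the background (one-sided Fisher's exact test for over-representation).
#'
#' @param fgHits observed foreground members of the term.
#' @param fgSize foreground set size.
#' @param bgHits term members in the background.
#' @param bgSize background (whole network) size.
#' @return the upper-tail probability.
#' @export
hypergeomPValue <- function(fgHits, fgSize, bgHits, bgSize) {
  if (fgSize > bgSize || bgHits > bgSize || fgHits > fgSize ||
      fgHits > bgHits) {
    stop("inconsistent hypergeometric counts")
  }
  stats::phyper(fgHits - 1, bgHits, bgSize - bgHits, fgSize,
                lower.tail = FALSE)
}

#' Fold enrichment of a term in a foreground set
#'
#' Ratio of the term's foreground frequency to its background frequency:
#' \eqn{(k/n) / (K/N)}.
#'
#' @inheritParams hypergeomPValue
#' @return the fold-enrichment ratio.
#' @export
foldEnrichment <- function(fgHits, fgSize, bgHits, bgSize) {
  if (bgHits <= 0 || fgSize <= 0) stop("zero denominator in fold enrichment")
  (fgHits / fgSize) / (bgHits / bgSize)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Standard step-up FDR control, returned in input order. Applied within each
#' annotation category separately by \code{\link{enrichCategory}}.
#'
#' @param pValues numeric vector of p-values in (0, 1].
#' @return q-values in input order.
#' @export
bhAdjust <- function(pValues) {
  stats::p.adjust(pValues, method = "BH")
}

#' Over-representation analysis of one annotation category
#'
#' For every term: counts against the supplied background (term members are
#' intersected with the background first), upper-tail hypergeometric p-value,
#' fold enrichment, BH correction within the category, and a retention flag
#' combining the four high-confidence thresholds: FDR <= \code{maxFdr}
#' (default 0.001), fold enrichment strictly > \code{minFold} (default 1),
#' foreground count >= \code{minFgCount} (default 5) and background count <=
#' \code{maxBgCount} (default 500).
#'
#' @param proteinSet character IDs of the foreground (candidate) proteins;
#'   must be a subset of the background.
#' @param sets named list of term member-ID vectors (one annotation category).
#' @param background character IDs of the background universe (the full
#'   network).
#' @param category label recorded in the output rows.
#' @param maxFdr,minFold,minFgCount,maxBgCount retention thresholds.
#' @return data.frame with one row per term: category, term, fgCount, fgSize,
#'   bgCount, bgSize, foldEnrichment, pValue, fdr, retained.
#' @export
enrichCategory <- function(proteinSet, sets, background,
                           category = "category", maxFdr = 0.001,
                           minFold = 1, minFgCount = 5L, maxBgCount = 500L) {
  if (!length(proteinSet)) stop("empty protein set")
  if (!all(proteinSet %in% background)) {
    stop("protein set must be a subset of the background")
  }
  bgSize <- length(background)
  fgSize <- length(proteinSet)
  rows <- lapply(names(sets), function(term) {
    members <- intersect(sets[[term]], background)
    bgCount <- length(members)
    if (!bgCount) return(NULL)
    fgCount <- length(intersect(members, proteinSet))
    data.frame(category = category, term = term, fgCount = fgCount,
               fgSize = fgSize, bgCount = bgCount, bgSize = bgSize,
               foldEnrichment = foldEnrichment(fgCount, fgSize, bgCount,
                                               bgSize),
               pValue = hypergeomPValue(fgCount, fgSize, bgCount, bgSize),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(tab)) {
    return(data.frame(category = character(), term = character(),
                      fgCount = integer(), fgSize = integer(),
                      bgCount = integer(), bgSize = integer(),
                      foldEnrichment = numeric(), pValue = numeric(),
                      fdr = numeric(), retained = logical()))
  }
  tab$fdr <- bhAdjust(tab$pValue)
  tab$retained <- tab$fdr <= maxFdr & tab$foldEnrichment > minFold &
    tab$fgCount >= minFgCount & tab$bgCount <= maxBgCount
  tab
}

#' Run enrichment across all annotation categories
#'
#' @param proteinSet foreground candidate IDs.
#' @param annotations an \linkS4class{AnnotationSets}.
#' @param background background universe IDs (full network).
#' @param allowTerms optional character vector of term IDs; when given, only
#'   these terms can be retained (a pass-through relevance allowlist).
#' @param ... thresholds passed to \code{\link{enrichCategory}}.
#' @return data.frame of all category tables stacked.
#' @export
enrichAll <- function(proteinSet, annotations, background,
                      allowTerms = NULL, ...) {
  tabs <- lapply(names(categories(annotations)), function(cat) {
    enrichCategory(proteinSet, categories(annotations)[[cat]], background,
                   category = cat, ...)
  })
  tab <- do.call(rbind, tabs)
  if (!is.null(allowTerms)) {
    tab$retained <- tab$retained & tab$term %in% allowTerms
  }
  tab
}

#' Intersection-based candidate refinement
#'
#' A candidate survives refinement iff, for every category that has at least
#' one retained term, it belongs to at least one retained term of that
#' category (categories with no retained terms are vacuous and skipped). This
#' is the per-candidate reading of "intersection across all enrichment
#' categories"; the coverage report makes the evidence auditable.
#'
#' @param candidates character IDs of the candidate pool.
#' @param enrichmentTable output of \code{\link{enrichAll}} (or a stack of
#'   \code{\link{enrichCategory}} tables).
#' @param annotations the \linkS4class{AnnotationSets} used for enrichment.
#' @return list with \code{refined} (surviving IDs, sorted), \code{coverage}
#'   (data.frame: node, category, coveringTerms) and
#'   \code{activeCategories}.
#' @export
refineCandidates <- function(candidates, enrichmentTable, annotations) {
  retained <- enrichmentTable[enrichmentTable$retained, , drop = FALSE]
  if (!nrow(retained)) {
    warning("no retained terms in any category; refined set is empty")
    return(list(refined = character(), coverage = data.frame(),
                activeCategories = character()))
  }
  active <- unique(retained$category)
  keep <- rep(TRUE, length(candidates))
  coverage <- list()
  for (cat in active) {
    terms <- retained$term[retained$category == cat]
    sets <- categories(annotations)[[cat]][terms]
    covered <- lapply(candidates, function(cand) {
      terms[vapply(sets, function(m) cand %in% m, TRUE)]
    })
    keep <- keep & vapply(covered, length, 1L) > 0L
    coverage[[cat]] <- data.frame(
      node = candidates, category = cat,
      coveringTerms = vapply(covered, paste, character(1), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  list(refined = sort(candidates[keep]),
       coverage = do.call(rbind, coverage),
       activeCategories = active)
}
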