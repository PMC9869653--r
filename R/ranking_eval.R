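# Tie-aware top-n selection, clinical tier annotation from a local table,
# and tier-proportion summaries.

# 10-level clinical-support taxonomy, best (most clinically advanced) first:
# 1A approved for the cancer type under study ... 6 no support.
TIER_LEVELS <- c("1A", "1B", "2A", "2B", "3A", "3B", "4A", "4B", "5", "6")
SUPPORTED_TIERS <- setdiff(TIER_LEVELS, "6")            # any oncotherapy link
APPROVED_TRIAL_TIERS <- c("1A", "1B", "2A", "2B")       # approved / in trials
INDICATED_TIERS <- c("1A", "2A", "3A", "4A")            # for this cancer type

#' Tie-inclusive top-n drug selection
#'
#' Returns the top `n` drugs by descending score, plus every drug tying
#' the n-th score: if the sixth and seventh drugs score the same as the
#' fifth, a top-5 selection contains seven drugs. Within the returned
#' list, order is descending score with a lexicographic drug-name
#' tie-break. Excluded drugs all score strictly below every included one.
#'
#' @param scores a [drug_scores()] object or named numeric vector.
#' @param n number of top drugs requested (`>= 1`); if fewer drugs exist,
#'   all are returned.
#' @return Character vector of selected drug identifiers, ordered.
#' @export
top_n_with_ties <- function(scores, n) {
  if (length(n) != 1L || !is.numeric(n) || n < 1)
    stop("n must be a single number >= 1")
  s <- unclass(scores)
  attributes(s) <- list(names = names(s))
  stopifnot(!is.null(names(s)))
  ord <- order(-s, names(s))
  s <- s[ord]
  if (length(s) <= n) return(names(s))
  cutoff <- s[[n]]
  names(s)[s >= cutoff]
}

#' Load a drug-tier annotation table
#'
#' TSV with columns `drug` and `tier`; tiers must come from the 10-level
#' taxonomy (`1A`, `1B`, `2A`, `2B`, `3A`, `3B`, `4A`, `4B`, `5`, `6`).
#'
#' @param path path to a TSV file.
#' @return Named character vector, drug identifier -> tier label.
#' @export
load_tier_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", comment.char = "",
                           stringsAsFactors = FALSE)
  stopifnot(ncol(tab) >= 2L)
  tier_table(stats::setNames(trimws(tab[[2L]]), trimws(tab[[1L]])))
}

#' Validate a drug-tier mapping
#'
#' @param tiers named character vector, drug -> tier label drawn from the
#'   10-level taxonomy.
#' @return The validated named character vector.
#' @export
tier_table <- function(tiers) {
  stopifnot(is.character(tiers))
  if (length(tiers) && is.null(names(tiers)))
    stop("tier table must be named by drug identifier")
  bad <- setdiff(unique(tiers), TIER_LEVELS)
  if (length(bad))
    stop("unknown tier label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(TIER_LEVELS, collapse = ", "), ")")
  tiers
}

# Best (lowest-index) tier among a set of labels; tier 6 if none given.
best_tier <- function(labels) {
  labels <- labels[labels %in% TIER_LEVELS]
  if (!length(labels)) return("6")
  TIER_LEVELS[min(match(labels, TIER_LEVELS))]
}

#' Annotate selected drugs with clinical tiers
#'
#' Every selected drug receives a tier; drugs absent from the table
#' default to tier 6 (no support). A merged drug (identifier
#' `"D1/D2"`, or any entry of `merge_ledger`) takes the best — most
#' clinically advanced — tier among its member drugs, since a merged node
#' represents any member being prescribable.
#'
#' @param selected character vector of drug identifiers (e.g. from
#'   [top_n_with_ties()]).
#' @param tiers a [tier_table()] mapping.
#' @param merge_ledger optional named list (merged identifier -> original
#'   names) as produced by [merge_equivalent_drugs()]; identifiers
#'   containing `"/"` are also split directly.
#' @return Data frame with columns `drug` and `tier` (factor with the 10
#'   taxonomy levels), one row per selected drug.
#' @export
annotate_tiers <- function(selected, tiers, merge_ledger = NULL) {
  tiers <- tier_table(tiers)
  resolve <- function(drug) {
    members <- if (!is.null(merge_ledger) && drug %in% names(merge_ledger))
      merge_ledger[[drug]]
    else strsplit(drug, "/", fixed = TRUE)[[1L]]
    best_tier(tiers[members[members %in% names(tiers)]])
  }
  data.frame(
    drug = as.character(selected),
    tier = factor(vapply(as.character(selected), resolve, character(1L)),
                  levels = TIER_LEVELS),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Tier proportions of a selected drug set
#'
#' @param annotated data frame from [annotate_tiers()] (non-empty).
#' @return An object of class `tier_summary`: list with `proportions`
#'   (named over the 10 tiers, summing to 1), `supported` (tiers 1A-5,
#'   i.e. 1 minus the tier-6 proportion), `approved_trial` (tiers 1-2)
#'   and `indicated_for_type` (tiers 1A, 2A, 3A, 4A), plus the selection
#'   size `n`.
#' @export
tier_proportions <- function(annotated) {
  stopifnot(is.data.frame(annotated), "tier" %in% names(annotated))
  if (nrow(annotated) == 0L)
    stop("tier_proportions: empty annotated drug list")
  tier <- factor(as.character(annotated$tier), levels = TIER_LEVELS)
  if (anyNA(tier)) stop("tier_proportions: invalid tier label")
  prop <- as.numeric(table(tier)) / length(tier)
  names(prop) <- TIER_LEVELS
  structure(
    list(proportions = prop,
         supported = sum(prop[SUPPORTED_TIERS]),
         approved_trial = sum(prop[APPROVED_TRIAL_TIERS]),
         indicated_for_type = sum(prop[INDICATED_TIERS]),
         n = length(tier)),
    class = "tier_summary"
  )
}

#' @export
print.tier_summary <- function(x, ...) {
  cat(sprintf("tier_summary over %d drug(s):\n", x$n))
  print(round(x$proportions, 3))
  cat(sprintf("supported (tiers 1-5): %.3f | approved/trial (tiers 1-2): %.3f | indicated for type: %.3f\n",
              x$supported, x$approved_trial, x$indicated_for_type))
  invisible(x)
}
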