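# Container for per-drug scores produced by either scoring method.

#' Construct a drug-score vector
#'
#' @param scores named nonnegative numeric vector, one entry per drug.
#' @param method `"distance"` or `"propagation"`.
#' @param parameters list of parameters used by the scorer.
#' @param empty_driver_set flag set when no altered gene passed the
#'   driverness filter (all scores are 0 in that case).
#' @return A `drug_scores` object (a named numeric vector with attributes).
#' @export
drug_scores <- function(scores, method = c("distance", "propagation"),
                        parameters = list(), empty_driver_set = FALSE) {
  method <- match.arg(method)
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  if (any(scores < -1e-12)) stop("drug scores must be nonnegative")
  scores[scores < 0] <- 0
  structure(scores, class = "drug_scores", method = method,
            parameters = parameters, empty_driver_set = empty_driver_set)
}

#' @export
print.drug_scores <- function(x, n = 10L, ...) {
  cat(sprintf("drug_scores (%s method): %d drugs%s\n", attr(x, "method"),
              length(x),
              if (isTRUE(attr(x, "empty_driver_set"))) " [empty driver set]" else ""))
  print(utils::head(sort(unclass(x), decreasing = TRUE), n))
  invisible(x)
}

#' Tabulate drug scores with min-rank ties
#'
#' @param x a `drug_scores` object.
#' @param ... unused.
#' @return Data frame with columns `drug`, `score`, `rank`, sorted by
#'   descending score (lexicographic drug-name tie-break); tying scores
#'   share the same (minimum) rank.
#' @export
as.data.frame.drug_scores <- function(x, ...) {
  s <- unclass(x)
  attributes(s) <- list(names = names(s))
  ord <- order(-s, names(s))
  s <- s[ord]
  data.frame(drug = names(s), score = unname(s),
             rank = rank(-s, ties.method = "min"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a ranked drug-score table to TSV
#'
#' @param x a `drug_scores` object.
#' @param path output path.
#' @export
write_drug_scores <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
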