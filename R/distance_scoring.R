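# Distance-based drug scoring: per-pair score driver_g / (dist(d,g) + 1)^2,
# averaged over the altered genes passing the driverness filter.

#' Hop distances from one drug to every gene
#'
#' Computes `dist(d, g) = 1 + min_t hop(t, g)` over the drug's in-network
#' targets `t`, where hop distances are unweighted shortest paths on the
#' gene-only graph. Drug nodes are never used as intermediary nodes:
#' paths run entirely through gene-gene edges, with the final drug-target
#' edge contributing the leading 1. Genes in no target's connected
#' component (and all genes, for an isolated drug) are unreachable
#' (`Inf`).
#'
#' @param xnet an [extend_network()] result.
#' @param drug a drug identifier present in `xnet$drug_nodes`.
#' @return Named numeric vector over all gene nodes: hop counts (`>= 1`),
#'   `Inf` for unreachable genes.
#' @export
drug_gene_distances <- function(xnet, drug) {
  stopifnot(inherits(xnet, "extended_network"))
  if (!drug %in% xnet$drug_nodes) stop("unknown drug: '", drug, "'")
  genes <- xnet$gene_network$nodes
  targets <- xnet$drug_edges$gene[xnet$drug_edges$drug == drug]
  if (!length(targets))
    return(stats::setNames(rep(Inf, length(genes)), genes))
  g <- gene_graph(xnet$gene_network)
  d <- igraph::distances(g, v = targets, to = genes, weights = NA)
  hops <- if (length(targets) == 1L) as.numeric(d) else apply(d, 2L, min)
  stats::setNames(1 + hops, genes)
}

#' Score one drug-gene pair
#'
#' `driver / (dist + 1)^2`: the +1 guards against division by zero and the
#' square makes the contribution decay quickly with distance, emphasizing
#' genes close to the drug. An unreachable gene scores 0 (the limit as
#' `dist` grows).
#'
#' @param dist hop count (`>= 1` in practice) or `Inf` for unreachable;
#'   vectorized.
#' @param driver driverness score in `[0, 1]`; vectorized.
#' @return Numeric score(s) `>= 0`.
#' @export
pair_score <- function(dist, driver) {
  out <- driver / (dist + 1)^2
  out[is.infinite(dist)] <- 0
  out
}

#' Distance-based drug scores for one sample
#'
#' For the altered-gene set `G* = {g : driver_g > driver_threshold, g` in
#' the network`}`, each drug scores the mean over `G*` of
#' [pair_score()] applied to its hop distances. Unreachable genes
#' contribute 0 but remain in the denominator. Altered genes above the
#' threshold but absent from the network are excluded with a warning
#' (they have no node, hence no distance). If `G*` is empty every drug
#' scores 0 and the result carries an `empty_driver_set` flag.
#'
#' @param xnet an [extend_network()] result.
#' @param drivers named numeric vector, gene symbol -> driverness
#'   probability in `[0, 1]`. Genes absent from the vector are treated as
#'   driverness 0.
#' @param driver_threshold strict lower driverness cutoff in `[0, 1)`
#'   (default 0.05); only genes with driverness strictly above it enter
#'   `G*`. Set to a negative value to disable filtering.
#' @return A `drug_scores` object: named numeric vector over every drug in
#'   `xnet` (nonnegative; isolated drugs score exactly 0), with
#'   attributes `method = "distance"`, `parameters`, and
#'   `empty_driver_set`.
#' @export
score_distance_based <- function(xnet, drivers, driver_threshold = 0.05) {
  stopifnot(inherits(xnet, "extended_network"))
  drivers <- validate_drivers(drivers)
  if (length(driver_threshold) != 1L || !is.numeric(driver_threshold) ||
      driver_threshold >= 1)
    stop("driver_threshold must be a single number < 1")

  genes <- xnet$gene_network$nodes
  altered <- names(drivers)[drivers > driver_threshold]
  off_net <- setdiff(altered, genes)
  if (length(off_net))
    warning("score_distance_based: ", length(off_net),
            " altered gene(s) above threshold absent from the network: ",
            paste(utils::head(off_net, 5L), collapse = ", "),
            if (length(off_net) > 5L) ", ..." else "")
  gstar <- intersect(altered, genes)

  empty <- length(gstar) == 0L
  scores <- stats::setNames(rep(0, length(xnet$drug_nodes)), xnet$drug_nodes)
  if (!empty) {
    g <- gene_graph(xnet$gene_network)
    # hop distances from every altered gene to every gene node, computed once
    hop <- igraph::distances(g, v = gstar, to = genes, weights = NA)
    dimnames(hop) <- list(gstar, genes)
    w <- drivers[gstar]
    for (d in xnet$drug_nodes) {
      targets <- xnet$drug_edges$gene[xnet$drug_edges$drug == d]
      if (!length(targets)) next
      sub <- hop[, targets, drop = FALSE]
      dmin <- 1 + do.call(pmin, c(as.data.frame(sub), list(na.rm = FALSE)))
      scores[d] <- sum(pair_score(dmin, w)) / length(gstar)
    }
  }
  drug_scores(scores, method = "distance",
              parameters = list(driver_threshold = driver_threshold),
              empty_driver_set = empty)
}

validate_drivers <- function(drivers) {
  if (is.data.frame(drivers)) {
    stopifnot(ncol(drivers) >= 2L)
    drivers <- stats::setNames(as.numeric(drivers[[2L]]),
                               trimws(as.character(drivers[[1L]])))
  }
  stopifnot(is.numeric(drivers))
  if (length(drivers) && is.null(names(drivers)))
    stop("driverness scores must be named by gene symbol")
  if (anyNA(drivers) || any(drivers < 0) || any(drivers > 1))
    stop("driverness scores must lie in [0, 1]")
  if (anyDuplicated(names(drivers))) {
    # keep the maximum score per gene
    drivers <- vapply(split(drivers, names(drivers)), max, numeric(1L))
  }
  drivers
}

#' Read a per-sample driverness table
#'
#' TSV with a gene-symbol column and a driverness-probability column
#' (driveR-style output).
#'
#' @param path path to a TSV file.
#' @param gene_col,score_col column names or 1-based indices.
#' @return Named numeric vector of driverness scores in `[0, 1]`.
#' @export
load_driver_scores <- function(path, gene_col = 1L, score_col = 2L) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  g <- if (is.numeric(gene_col)) tab[[gene_col]] else tab[[match.arg(gene_col, names(tab))]]
  s <- if (is.numeric(score_col)) tab[[score_col]] else tab[[match.arg(score_col, names(tab))]]
  validate_drivers(stats::setNames(as.numeric(s), trimws(as.character(g))))
}
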