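# Propagation scoring: Laplacian-normalized random walk with restart over
# the drug-extended network.

#' Laplacian-normalized adjacency of the extended network
#'
#' Builds the symmetric 0/1 adjacency W of the extended network (gene-gene
#' plus drug-target edges, both conducting in either direction) over a
#' fixed, deterministic node ordering — sorted gene nodes followed by
#' sorted drug nodes — and normalizes it as `W' = D^(-1/2) W D^(-1/2)`
#' with `D` the diagonal degree matrix. Isolated nodes (degree 0) get
#' all-zero rows and columns: they neither send nor receive signal, so
#' isolated drugs score exactly 0.
#'
#' @param xnet an [extend_network()] result with at least one edge.
#' @return An object of class `normalized_adjacency`: list with `W`
#'   (symmetric sparse [Matrix::Matrix] with entries
#'   `1/sqrt(deg_i * deg_j)` per edge), `nodes` (ordered node names, drug
#'   nodes internally prefixed), `is_drug` (logical mask) and `drug_ids`
#'   (original drug identifiers in node order).
#' @export
laplacian_normalize <- function(xnet) {
  stopifnot(inherits(xnet, "extended_network"))
  genes <- sort(xnet$gene_network$nodes)
  drugs <- sort(xnet$drug_nodes)
  nodes <- c(genes, drug_node_name(drugs))
  n <- length(nodes)
  ge <- xnet$gene_network$edges
  de <- xnet$drug_edges
  if (nrow(ge) + nrow(de) == 0L)
    stop("no interactions to propagate over (edgeless network)")
  ii <- c(match(ge$from, nodes), match(drug_node_name(de$drug), nodes))
  jj <- c(match(ge$to, nodes), match(de$gene, nodes))
  W <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = 1,
                            dims = c(n, n), dimnames = list(nodes, nodes))
  deg <- Matrix::rowSums(W)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  Wn <- Matrix::Diagonal(n, dinv) %*% W %*% Matrix::Diagonal(n, dinv)
  dimnames(Wn) <- list(nodes, nodes)
  structure(
    list(W = Wn, nodes = nodes,
         is_drug = c(rep(FALSE, length(genes)), rep(TRUE, length(drugs))),
         drug_ids = drugs),
    class = "normalized_adjacency"
  )
}

#' Build the prior vector for propagation
#'
#' Maps driverness scores of altered genes onto the extended network: the
#' prior Y carries each in-network altered gene's driverness and 0 for
#' unaltered genes and for all drug nodes. No driverness threshold is
#' applied by default (the >0.05 filter belongs to the distance method
#' only), but one can be supplied. Altered genes absent from the network
#' are dropped with a warning.
#'
#' @param Wn a [laplacian_normalize()] result (fixes the node ordering).
#' @param drivers named numeric vector of driverness scores in `[0, 1]`.
#' @param driver_threshold optional strict cutoff; `NULL` (default) keeps
#'   all altered genes.
#' @return Numeric prior vector Y over `Wn$nodes`.
#' @export
build_prior <- function(Wn, drivers, driver_threshold = NULL) {
  stopifnot(inherits(Wn, "normalized_adjacency"))
  drivers <- validate_drivers(drivers)
  if (!is.null(driver_threshold))
    drivers <- drivers[drivers > driver_threshold]
  Y <- stats::setNames(rep(0, length(Wn$nodes)), Wn$nodes)
  hit <- names(drivers) %in% Wn$nodes[!Wn$is_drug]
  if (any(!hit) && length(drivers))
    warning("build_prior: ", sum(!hit),
            " altered gene(s) absent from the network dropped")
  drivers <- drivers[hit]
  Y[names(drivers)] <- drivers
  if (all(Y == 0))
    stop("no prior signal: no altered gene with positive driverness is in the network")
  Y
}

#' Random walk with restart
#'
#' Iterates `F(t) = (1 - alpha) W' F(t-1) + alpha Y` from `F(0) = Y` until
#' the L2 change drops below `tol` or the iteration cap is reached. Since
#' W' is a symmetric normalized adjacency its spectral radius is at most
#' 1, so for `alpha > 0` the update is a contraction with factor at most
#' `1 - alpha` and convergence is geometric. Hitting the cap is reported
#' with a warning, not an error: it signals pathological input worth
#' inspecting.
#'
#' @param Wn a [laplacian_normalize()] result.
#' @param Y prior vector from [build_prior()] (nonnegative, not all zero).
#' @param alpha restart parameter in `(0, 1]` (default 0.05).
#' @param tol L2 convergence threshold (default 1e-4).
#' @param max_iter iteration cap (default 1000).
#' @return An object of class `propagation_result`: list with `F` (named
#'   propagation scores over all nodes), `iterations`, `converged`,
#'   `alpha`, `tol`.
#' @export
propagate <- function(Wn, Y, alpha = 0.05, tol = 1e-4, max_iter = 1000L) {
  stopifnot(inherits(Wn, "normalized_adjacency"))
  if (length(alpha) != 1L || !is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must be a single number in (0, 1]")
  stopifnot(is.numeric(Y), length(Y) == length(Wn$nodes))
  if (any(Y < 0)) stop("prior Y must be nonnegative")
  if (all(Y == 0)) stop("no prior signal: Y is identically zero")

  W <- Wn$W
  f <- Y
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    f_new <- as.numeric((1 - alpha) * (W %*% f)) + alpha * Y
    if (sqrt(sum((f_new - f)^2)) < tol) {
      f <- f_new
      converged <- TRUE
      break
    }
    f <- f_new
  }
  if (!converged)
    warning("propagate: not converged after ", max_iter, " iterations")
  structure(
    list(F = stats::setNames(f, Wn$nodes), iterations = iter,
         converged = converged, alpha = alpha, tol = tol),
    class = "propagation_result"
  )
}

#' @export
print.propagation_result <- function(x, ...) {
  cat(sprintf("propagation_result: %d nodes, alpha = %g, %d iteration(s), %s\n",
              length(x$F), x$alpha, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Propagation-based drug scores for one sample
#'
#' Runs [laplacian_normalize()], [build_prior()] and [propagate()], then
#' restricts the final propagation vector to the drug nodes: the score of
#' a drug is its final propagation score. Drugs isolated in the extended
#' network score exactly 0.
#'
#' @inheritParams propagate
#' @inheritParams build_prior
#' @param xnet an [extend_network()] result.
#' @return A [drug_scores()] object with `method = "propagation"`; its
#'   `propagation` attribute holds the full [propagate()] result.
#' @export
score_propagation <- function(xnet, drivers, alpha = 0.05, tol = 1e-4,
                              max_iter = 1000L, driver_threshold = NULL) {
  Wn <- laplacian_normalize(xnet)
  Y <- build_prior(Wn, drivers, driver_threshold = driver_threshold)
  res <- propagate(Wn, Y, alpha = alpha, tol = tol, max_iter = max_iter)
  scores <- res$F[Wn$is_drug]
  names(scores) <- Wn$drug_ids
  out <- drug_scores(scores[xnet$drug_nodes], method = "propagation",
                     parameters = list(alpha = alpha, tol = tol,
                                       max_iter = max_iter,
                                       driver_threshold = driver_threshold))
  attr(out, "propagation") <- res[c("iterations", "converged", "alpha", "tol")]
  out
}

#' Score drugs across a grid of restart parameters
#'
#' Convenience helper for exploring the sensitivity of propagation
#' rankings to the restart parameter: one ranked score table per alpha.
#' Judging which alpha yields the most relevant rankings is left to the
#' analyst.
#'
#' @inheritParams score_propagation
#' @param alphas numeric vector of restart parameters in `(0, 1]`.
#' @return Named list (one element per alpha, names `format(alpha)`) of
#'   [drug_scores()] objects.
#' @export
alpha_sweep <- function(xnet, drivers, alphas = c(0.05, 0.1, 0.25, 0.5, 0.75, 0.9),
                        tol = 1e-4, max_iter = 1000L) {
  stats::setNames(
    lapply(alphas, function(a)
      score_propagation(xnet, drivers, alpha = a, tol = tol, max_iter = max_iter)),
    format(alphas)
  )
}
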