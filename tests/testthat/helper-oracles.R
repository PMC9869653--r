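# Independent oracles used to cross-check the implementation. These are
# deliberately naive: dense matrices, literal formulas, cubic all-pairs
# shortest paths. They share no code with the package's scoring paths.

# Floyd-Warshall all-pairs hop distances over the gene nodes of a
# gene_network. Returns a dense matrix (Inf = unreachable).
oracle_fw_distances <- function(net) {
  nodes <- net$nodes
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  for (r in seq_len(nrow(net$edges))) {
    i <- match(net$edges$from[r], nodes)
    j <- match(net$edges$to[r], nodes)
    D[i, j] <- 1
    D[j, i] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n))
    D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
  D
}

# Literal per-drug score: mean over altered genes (driverness strictly
# above threshold, in-network) of driver / (1 + 1 + min_t hop(t, g))^2,
# with unreachable genes contributing zero.
oracle_distance_scores <- function(net, dmap, drivers, threshold = 0.05) {
  D <- oracle_fw_distances(net)
  gstar <- intersect(names(drivers)[drivers > threshold], net$nodes)
  out <- stats::setNames(rep(0, length(dmap)), names(dmap))
  if (!length(gstar)) return(out)
  for (d in names(dmap)) {
    targets <- intersect(dmap[[d]], net$nodes)
    if (!length(targets)) next
    total <- 0
    for (g in gstar) {
      hops <- min(D[targets, g])
      dist <- 1 + hops
      if (is.finite(dist)) total <- total + drivers[[g]] / (dist + 1)^2
    }
    out[d] <- total / length(gstar)
  }
  out
}

# Dense closed-form RWR fixed point F* = alpha (I - (1-alpha) W')^{-1} Y,
# with W' built by an explicit dense D^{-1/2} W D^{-1/2} product over
# sorted genes followed by sorted (prefixed) drug nodes.
oracle_dense_normalized <- function(net, dmap) {
  genes <- sort(net$nodes)
  drugs <- sort(names(dmap))
  nodes <- c(genes, paste0("drug::", drugs))
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(net$edges))) {
    W[net$edges$from[r], net$edges$to[r]] <- 1
    W[net$edges$to[r], net$edges$from[r]] <- 1
  }
  for (d in drugs) for (g in intersect(dmap[[d]], genes)) {
    W[paste0("drug::", d), g] <- 1
    W[g, paste0("drug::", d)] <- 1
  }
  deg <- rowSums(W)
  dhalf <- diag(ifelse(deg > 0, 1 / sqrt(deg), 0), n)
  Wp <- dhalf %*% W %*% dhalf
  dimnames(Wp) <- list(nodes, nodes)
  Wp
}

oracle_rwr_fixed_point <- function(net, dmap, drivers, alpha = 0.05) {
  Wp <- oracle_dense_normalized(net, dmap)
  nodes <- rownames(Wp)
  Y <- stats::setNames(rep(0, length(nodes)), nodes)
  hit <- intersect(names(drivers), nodes)
  Y[hit] <- drivers[hit]
  Fstar <- alpha * solve(diag(length(nodes)) - (1 - alpha) * Wp, Y)
  stats::setNames(as.numeric(Fstar), nodes)
}
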