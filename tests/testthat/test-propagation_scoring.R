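test_that("Laplacian normalization reproduces closed forms on small graphs", {
  # single edge: degrees (1, 1)
  net <- gene_network(data.frame(from = "A", to = "B"))
  xnet <- extend_network(net, drug_target_map(list(D = "A")), verbose = FALSE)
  Wn <- laplacian_normalize(xnet)
  W <- as.matrix(Wn$W)
  expect_equal(W["A", "B"], W["B", "A"])
  expect_true(isSymmetric(W))
  expect_true(all(diag(W) == 0))

  # path A-B-C without drugs: degrees (1, 2, 1) -> off-diagonals 1/sqrt(2)
  path <- toy_path_network(c("A", "B", "C"))
  xp <- extend_network(path, drug_target_map(list(D = "Z")), verbose = FALSE)
  Wp <- as.matrix(laplacian_normalize(xp)$W)
  expect_equal(Wp["A", "B"], 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(Wp["B", "C"], 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(Wp["A", "C"], 0)

  # star with k leaves: every normalized entry is 1/sqrt(k)
  for (k in 1:5) {
    leaves <- sprintf("L%d", seq_len(k))
    star <- gene_network(data.frame(from = rep("X", k), to = leaves))
    xs <- extend_network(star, drug_target_map(list(D = "X")), verbose = FALSE)
    Ws <- as.matrix(laplacian_normalize(xs)$W)
    # the drug edge raises the center's degree to k + 1
    for (l in leaves)
      expect_equal(Ws["X", l], 1 / sqrt(k + 1), tolerance = 1e-12)
  }
})

test_that("normalized adjacency matches the dense oracle and zeroes isolated nodes", {
  for (seed in 1:5) {
    fix <- small_random_fixture(seed = 600L + seed)
    merged <- merge_equivalent_drugs(fix$drug_targets)
    xnet <- extend_network(fix$network, merged, verbose = FALSE)
    Wn <- laplacian_normalize(xnet)
    dense <- oracle_dense_normalized(fix$network, merged)
    expect_equal(as.matrix(Wn$W), dense, tolerance = 1e-12)
    iso <- paste0("drug::", xnet$isolated_drugs)
    if (length(xnet$isolated_drugs)) {
      expect_true(all(as.matrix(Wn$W)[iso, ] == 0))
      expect_true(all(as.matrix(Wn$W)[, iso] == 0))
    }
    expect_true(all(Wn$W@x >= 0 & Wn$W@x <= 1))
  }
})

test_that("an edgeless extended network cannot be normalized", {
  net <- structure(list(nodes = c("A", "B"),
                        edges = data.frame(from = character(0),
                                           to = character(0)),
                        confidence = NULL, min_confidence = NA_real_),
                   class = "gene_network")
  xnet <- extend_network(net, drug_target_map(list(D = "Z")), verbose = FALSE)
  expect_error(laplacian_normalize(xnet), "no interactions")
})

test_that("the prior carries in-network driverness and zero elsewhere", {
  net <- gene_network(data.frame(from = "A", to = "B"))
  xnet <- extend_network(net, drug_target_map(list(D = "B")), verbose = FALSE)
  Wn <- laplacian_normalize(xnet)
  Y <- build_prior(Wn, c(A = 0.9))
  expect_equal(Y[["A"]], 0.9)
  expect_equal(Y[["B"]], 0)
  expect_equal(Y[["drug::D"]], 0)

  expect_warning(Y2 <- build_prior(Wn, c(A = 0.9, ZZ = 0.7)), "dropped")
  expect_equal(unname(Y2["A"]), 0.9)
  expect_error(suppressWarnings(build_prior(Wn, c(ZZ = 0.9))), "no prior signal")
  # no driverness filter by default; an explicit threshold removes low genes
  Y3 <- build_prior(Wn, c(A = 0.9, B = 0.03))
  expect_equal(unname(Y3["B"]), 0.03)
  Y4 <- build_prior(Wn, c(A = 0.9, B = 0.03), driver_threshold = 0.05)
  expect_equal(unname(Y4["B"]), 0)
})

test_that("alpha = 1 returns the prior after a single iteration", {
  net <- toy_path_network(c("A", "B", "C"))
  xnet <- extend_network(net, drug_target_map(list(D = "A")), verbose = FALSE)
  Wn <- laplacian_normalize(xnet)
  Y <- build_prior(Wn, c(A = 0.7, C = 0.2))
  res <- propagate(Wn, Y, alpha = 1)
  expect_true(res$converged)
  expect_equal(res$iterations, 1L)
  expect_equal(unname(res$F), unname(Y))
})

test_that("the two-node fixed point matches the analytic solution", {
  net <- gene_network(data.frame(from = "A", to = "B"))
  xnet <- extend_network(net, drug_target_map(list(D = "Z")), verbose = FALSE)
  Wn <- laplacian_normalize(xnet)
  Y <- build_prior(Wn, c(A = 1))
  res <- propagate(Wn, Y, alpha = 0.05, tol = 1e-10)
  # alpha (I - (1-alpha) W')^{-1} Y = (0.05/0.0975) * (1, 0.95)
  expect_equal(unname(res$F["A"]), 0.05 / 0.0975, tolerance = 1e-6)
  expect_equal(unname(res$F["B"]), 0.0475 / 0.0975, tolerance = 1e-6)
  expect_true(res$converged)
})

test_that("propagation is linear in the prior", {
  fix <- small_random_fixture(seed = 17L)
  merged <- merge_equivalent_drugs(fix$drug_targets)
  f1 <- oracle_rwr_fixed_point(fix$network, merged, c(g0001 = 0.5))
  f2 <- oracle_rwr_fixed_point(fix$network, merged, c(g0002 = 0.3))
  f12 <- oracle_rwr_fixed_point(fix$network, merged, c(g0001 = 0.5, g0002 = 0.3))
  expect_equal(f12, f1 + f2, tolerance = 1e-10)

  # scaling the prior scales the iterative result exactly
  xnet <- extend_network(fix$network, merged, verbose = FALSE)
  Wn <- laplacian_normalize(xnet)
  Y <- suppressWarnings(build_prior(Wn, fix$driver_scores))
  r1 <- propagate(Wn, Y, tol = 1e-9)
  r3 <- propagate(Wn, 3 * Y, tol = 3e-9)
  expect_equal(unname(r3$F), unname(3 * r1$F), tolerance = 1e-9)
})

test_that("iterative propagation converges geometrically to the direct solve", {
  for (seed in 1:5) {
    fix <- small_random_fixture(seed = 700L + seed)
    merged <- merge_equivalent_drugs(fix$drug_targets)
    xnet <- extend_network(fix$network, merged, verbose = FALSE)
    Wn <- laplacian_normalize(xnet)
    Y <- suppressWarnings(build_prior(Wn, fix$driver_scores))
    alpha <- 0.05
    tol <- 1e-4
    res <- propagate(Wn, Y, alpha = alpha, tol = tol)
    expect_true(res$converged)
    expect_lt(res$iterations, 1000L)
    want <- oracle_rwr_fixed_point(fix$network, merged, fix$driver_scores,
                                   alpha = alpha)
    # contraction bound: ||F(t) - F*|| <= (1 - alpha)/alpha * ||F(t) - F(t-1)||
    expect_lt(max(abs(res$F[names(want)] - want)), (1 - alpha) / alpha * tol)

    # and the geometric error decay is visible with a tighter stopping rule
    res2 <- propagate(Wn, Y, alpha = alpha, tol = 1e-10)
    expect_lt(max(abs(res2$F[names(want)] - want)), 1e-8)
  }
})

test_that("increasing the prior never decreases any fixed-point entry", {
  for (seed in 1:5) {
    fix <- small_random_fixture(seed = 800L + seed, n_altered = 6L)
    merged <- merge_equivalent_drugs(fix$drug_targets)
    drivers <- fix$driver_scores
    base <- oracle_rwr_fixed_point(fix$network, merged, drivers)
    pick <- names(drivers)[1 + (seed %% length(drivers))]
    drivers[pick] <- min(1, drivers[pick] + 0.4)
    up <- oracle_rwr_fixed_point(fix$network, merged, drivers)
    expect_true(all(up - base >= -1e-12))
  }
})

test_that("relabeling genes permutes propagation scores identically", {
  fix <- small_random_fixture(seed = 19L, n_genes = 20L)
  merged <- merge_equivalent_drugs(fix$drug_targets)
  xnet <- extend_network(fix$network, merged, verbose = FALSE)
  s1 <- suppressWarnings(score_propagation(xnet, fix$driver_scores, tol = 1e-8))

  relabel <- stats::setNames(sprintf("h%04d", rev(seq_along(fix$network$nodes))),
                             fix$network$nodes)
  net2 <- gene_network(data.frame(from = unname(relabel[fix$network$edges$from]),
                                  to = unname(relabel[fix$network$edges$to])))
  map2 <- drug_target_map(lapply(merged, function(g) {
    out <- ifelse(g %in% names(relabel), relabel[g], g)
    unname(out)
  }))
  xnet2 <- extend_network(net2, map2, verbose = FALSE)
  drivers2 <- stats::setNames(fix$driver_scores,
                              ifelse(names(fix$driver_scores) %in% names(relabel),
                                     relabel[names(fix$driver_scores)],
                                     names(fix$driver_scores)))
  s2 <- suppressWarnings(score_propagation(xnet2, drivers2, tol = 1e-8))
  expect_equal(unclass(s2)[names(s1)], unclass(s1)[names(s1)],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("signal reaches drugs through the network; disconnected drugs get zero", {
  # A-B with D targeting B: signal flows A -> B -> D
  net <- gene_network(data.frame(from = "A", to = "B"))
  xnet <- extend_network(net, drug_target_map(list(D = "B")), verbose = FALSE)
  s <- score_propagation(xnet, c(A = 0.9))
  expect_gt(s["D"], 0)

  # drug attached only to a component with no altered gene scores zero
  net2 <- gene_network(data.frame(from = c("A", "X"), to = c("B", "Y")))
  xnet2 <- extend_network(net2, drug_target_map(list(D1 = "B", D2 = "X")),
                          verbose = FALSE)
  s2 <- score_propagation(xnet2, c(A = 0.9))
  expect_gt(s2["D1"], 0)
  expect_equal(unname(s2["D2"]), 0)
})

test_that("invalid restart parameters and priors are rejected", {
  net <- gene_network(data.frame(from = "A", to = "B"))
  xnet <- extend_network(net, drug_target_map(list(D = "A")), verbose = FALSE)
  Wn <- laplacian_normalize(xnet)
  Y <- build_prior(Wn, c(A = 1))
  expect_error(propagate(Wn, Y, alpha = 0), "alpha")
  expect_error(propagate(Wn, Y, alpha = 1.5), "alpha")
  expect_error(propagate(Wn, rep(0, length(Y))), "no prior signal")
})

test_that("alpha_sweep returns one ranked score set per alpha", {
  fix <- small_random_fixture(seed = 23L)
  xnet <- extend_fixture(fix)
  sweep <- suppressWarnings(alpha_sweep(xnet, fix$driver_scores,
                                        alphas = c(0.05, 0.5, 1)))
  expect_named(sweep, format(c(0.05, 0.5, 1)))
  for (s in sweep) expect_s3_class(s, "drug_scores")
  expect_equal(attr(sweep[["0.50"]], "parameters")$alpha, 0.5)
})
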