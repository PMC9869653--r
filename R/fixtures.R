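# Seeded synthetic fixture generator: random gene networks, drug-target
# maps and sparse driverness vectors with the structural features the
# scorers must handle (duplicate target sets, out-of-network targets,
# mostly-low driverness with a few high scores).

#' Specification for a synthetic fixture
#'
#' Defaults emulate the shape of the real inputs: a heavy-tailed
#' (scale-free) interaction network, drugs with small target sets, and a
#' driverness profile where most altered genes fall below the 0.05 filter
#' and a few score high.
#'
#' @param n_genes number of genes in the network.
#' @param edge_model `"scale_free"` (Barabasi-Albert, see `attachment`) or
#'   `"erdos_renyi"` (see `edge_prob`).
#' @param edge_prob edge probability for the Erdos-Renyi model.
#' @param attachment edges added per new node for the scale-free model.
#' @param n_drugs number of drugs.
#' @param targets_per_drug integer range `c(min, max)` of targets per drug.
#' @param n_altered number of altered genes (may be 0).
#' @param frac_high fraction of altered genes drawn from `high_range`;
#'   the rest come from `low_range`.
#' @param high_range,low_range driverness ranges within `[0, 1]`.
#' @param duplicate_target_fraction fraction of drugs given a target set
#'   identical to another drug's (rounded to an even count of drugs).
#' @param orphan_target_fraction fraction of all drug-target slots replaced
#'   by gene symbols absent from the network.
#' @param with_confidence attach uniform confidence scores in `[0.4, 1]`
#'   to edges (`FALSE` yields a plain two-column edge list).
#' @param seed integer seed; identical seed and spec give byte-identical
#'   outputs.
#' @return A `fixture_spec` object (validated list of the above).
#' @export
fixture_spec <- function(n_genes = 100L, edge_model = c("scale_free", "erdos_renyi"),
                         edge_prob = 0.05, attachment = 2L, n_drugs = 20L,
                         targets_per_drug = c(1L, 3L), n_altered = 15L,
                         frac_high = 0.2, high_range = c(0.5, 1),
                         low_range = c(0, 0.05),
                         duplicate_target_fraction = 0.1,
                         orphan_target_fraction = 0.1,
                         with_confidence = TRUE, seed = 1L) {
  edge_model <- match.arg(edge_model)
  spec <- list(n_genes = as.integer(n_genes), edge_model = edge_model,
               edge_prob = edge_prob, attachment = as.integer(attachment),
               n_drugs = as.integer(n_drugs),
               targets_per_drug = as.integer(range(targets_per_drug)),
               n_altered = as.integer(n_altered), frac_high = frac_high,
               high_range = high_range, low_range = low_range,
               duplicate_target_fraction = duplicate_target_fraction,
               orphan_target_fraction = orphan_target_fraction,
               with_confidence = isTRUE(with_confidence),
               seed = as.integer(seed))
  stopifnot(spec$n_genes >= 1L, spec$n_drugs >= 1L, spec$n_altered >= 0L,
            spec$targets_per_drug[1L] >= 1L,
            spec$duplicate_target_fraction >= 0, spec$duplicate_target_fraction <= 1,
            spec$orphan_target_fraction >= 0, spec$orphan_target_fraction <= 1,
            spec$frac_high >= 0, spec$frac_high <= 1,
            all(spec$high_range >= 0), all(spec$high_range <= 1),
            all(spec$low_range >= 0), all(spec$low_range <= 1))
  if (spec$targets_per_drug[2L] > spec$n_genes)
    stop("targets_per_drug exceeds n_genes")
  if (spec$n_altered > spec$n_genes)
    stop("n_altered exceeds n_genes")
  structure(spec, class = "fixture_spec")
}

with_fixture_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Generate a synthetic fixture
#'
#' @param spec a [fixture_spec()].
#' @return A `fixture` object: list with `network` ([gene_network()]),
#'   `drug_targets` ([drug_target_map()], pre-merge), `driver_scores`
#'   (named numeric vector) and the `spec`.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_fixture_seed(spec$seed, {
    genes <- sprintf("g%04d", seq_len(spec$n_genes))
    g <- switch(spec$edge_model,
      erdos_renyi = igraph::sample_gnp(spec$n_genes, spec$edge_prob),
      scale_free = igraph::sample_pa(spec$n_genes, power = 1,
                                     m = spec$attachment, directed = FALSE))
    el <- igraph::as_edgelist(g, names = FALSE)
    edf <- data.frame(from = genes[el[, 1L]], to = genes[el[, 2L]],
                      stringsAsFactors = FALSE)
    # drop self loops / multi-edges the generators may emit
    edf <- edf[edf$from != edf$to, , drop = FALSE]
    if (spec$with_confidence)
      edf$confidence <- round(stats::runif(nrow(edf), 0.4, 1), 3L)
    net <- gene_network(edf, min_confidence = if (spec$with_confidence) 0.4 else NA_real_)

    # drug target sets, with exact counts of orphan slots and duplicate pairs
    sizes <- sample(seq(spec$targets_per_drug[1L], spec$targets_per_drug[2L]),
                    spec$n_drugs, replace = TRUE)
    targets <- lapply(sizes, function(k) sample(genes, k))
    n_orphan <- round(spec$orphan_target_fraction * sum(sizes))
    if (n_orphan > 0L) {
      slots <- sample(sum(sizes), n_orphan)
      flat <- unlist(targets, use.names = FALSE)
      flat[slots] <- sprintf("zz_orphan%03d", seq_len(n_orphan))
      targets <- split(flat, rep(seq_along(sizes), sizes))
    }
    n_dup <- 2L * floor(spec$duplicate_target_fraction * spec$n_drugs / 2)
    if (n_dup > 0L)
      for (k in seq_len(n_dup / 2L))
        targets[[2L * k]] <- targets[[2L * k - 1L]]
    names(targets) <- sprintf("drug%03d", seq_len(spec$n_drugs))
    dmap <- drug_target_map(targets)

    drivers <- numeric(0)
    if (spec$n_altered > 0L) {
      altered <- sample(genes, spec$n_altered)
      n_high <- round(spec$frac_high * spec$n_altered)
      vals <- c(stats::runif(n_high, spec$high_range[1L], spec$high_range[2L]),
                stats::runif(spec$n_altered - n_high,
                             spec$low_range[1L], spec$low_range[2L]))
      drivers <- stats::setNames(round(vals, 6L), altered)
    }
    structure(list(network = net, drug_targets = dmap,
                   driver_scores = drivers, spec = spec),
              class = "fixture")
  })
}

#' Write a fixture to disk as plain TSV files
#'
#' Writes `pin.tsv`, `drug_targets.tsv`, `driver_scores.tsv` and
#' `manifest.json` (spec, seed and MD5 checksums) into `dir`. The TSVs
#' round-trip losslessly through the package loaders.
#'
#' @param fixture a [generate_fixture()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pin <- file.path(dir, "pin.tsv")
  dt <- file.path(dir, "drug_targets.tsv")
  ds <- file.path(dir, "driver_scores.tsv")
  write_gene_network(fixture$network, pin)
  pairs <- data.frame(
    drug_claim_name = rep(names(fixture$drug_targets),
                          lengths(fixture$drug_targets)),
    gene_name = unlist(fixture$drug_targets, use.names = FALSE))
  utils::write.table(pairs, dt, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_symbol = names(fixture$driver_scores),
               driverness_prob = unname(fixture$driver_scores)),
    ds, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(spec = unclass(fixture$spec),
                   checksums = as.list(tools::md5sum(c(pin, dt, ds))))
  names(manifest$checksums) <- basename(names(manifest$checksums))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Fixture with a planted top drug
#'
#' Builds a network where one planted drug directly targets the unique
#' high-driverness gene (driverness 0.95) while every other drug's targets
#' sit at least 3 hops from every altered gene, so both scoring methods
#' must rank the planted drug first. Gene labels and the path layout are
#' shuffled by the seed; the construction (a labeled path with one
#' high-driverness endpoint, one low-driverness neighbor and far-away
#' decoy targets) is fixed.
#'
#' @param seed integer seed.
#' @param n_genes path length (default 25).
#' @param n_decoys number of decoy drugs (default 5).
#' @return List with `network` (confidence-free [gene_network()]),
#'   `drug_targets`, `driver_scores` and `expected_top_drug`.
#' @export
planted_signal_fixture <- function(seed, n_genes = 25L, n_decoys = 5L) {
  stopifnot(n_genes >= 8L, n_decoys >= 1L)
  with_fixture_seed(seed, {
    labels <- sample(sprintf("g%04d", sample(1000L, n_genes))) # shuffled names
    ord <- sample(labels)                                      # path layout
    net <- gene_network(data.frame(from = ord[-n_genes], to = ord[-1L],
                                   stringsAsFactors = FALSE))
    drivers <- stats::setNames(c(0.95, round(stats::runif(1, 0, 0.05), 6L)),
                               ord[1:2])
    targets <- c(
      list(PLANTED = ord[1L]),
      stats::setNames(lapply(seq_len(n_decoys), function(i)
        sample(ord[5:n_genes], 1L)), sprintf("decoy%02d", seq_len(n_decoys)))
    )
    list(network = net, drug_targets = drug_target_map(targets),
         driver_scores = drivers, expected_top_drug = "PLANTED")
  })
}
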