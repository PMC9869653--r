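# Small builders shared across tests.

toy_path_network <- function(genes = c("A", "B", "C")) {
  gene_network(data.frame(from = genes[-length(genes)], to = genes[-1L],
                          stringsAsFactors = FALSE))
}

# Random small fixture for oracle comparisons: Erdos-Renyi gene graph,
# a handful of drugs, mixed driverness.
small_random_fixture <- function(seed, n_genes = 30L, n_drugs = 6L,
                                 edge_prob = 0.12, n_altered = 8L) {
  generate_fixture(fixture_spec(
    n_genes = n_genes, edge_model = "erdos_renyi", edge_prob = edge_prob,
    n_drugs = n_drugs, targets_per_drug = c(1L, 3L), n_altered = n_altered,
    frac_high = 0.4, duplicate_target_fraction = 0.2,
    orphan_target_fraction = 0.1, seed = seed))
}

extend_fixture <- function(fix) {
  extend_network(fix$network, merge_equivalent_drugs(fix$drug_targets),
                 verbose = FALSE)
}

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
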