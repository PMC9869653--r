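# Loading, validation and assembly of the gene network, the drug-target map
# and the drug-extended network.

#' Construct a gene network object
#'
#' Builds a validated undirected gene-gene interaction network from an edge
#' table. Self-loops and duplicate edges (in either orientation) are removed;
#' edges are stored with endpoints in lexicographic order.
#'
#' @param edges data frame with at least two character columns giving the
#'   edge endpoints; an optional third numeric column is interpreted as a
#'   per-edge confidence score in (0, 1].
#' @param min_confidence confidence threshold already applied (recorded as
#'   metadata; use [load_gene_network()] to filter on load).
#' @return An object of class `gene_network`: a list with `nodes` (sorted
#'   character vector), `edges` (two-column data frame, `from < to`),
#'   `confidence` (numeric vector parallel to `edges`, or `NULL`) and
#'   `min_confidence`.
#' @seealso [load_gene_network()], [extend_network()]
#' @export
gene_network <- function(edges, min_confidence = NA_real_) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2)
  from <- trimws(as.character(edges[[1L]]))
  to <- trimws(as.character(edges[[2L]]))
  conf <- if (ncol(edges) >= 3L) as.numeric(edges[[3L]]) else NULL

  keep <- from != to & nzchar(from) & nzchar(to)
  from <- from[keep]
  to <- to[keep]
  if (!is.null(conf)) conf <- conf[keep]

  # canonical orientation, then deduplicate (keep first occurrence)
  swap <- from > to
  tmp <- from[swap]
  from[swap] <- to[swap]
  to[swap] <- tmp
  key <- paste(from, to, sep = "\r")
  dup <- duplicated(key)
  from <- from[!dup]
  to <- to[!dup]
  if (!is.null(conf)) conf <- conf[!dup]

  ord <- order(from, to)
  net <- structure(
    list(
      nodes = sort(unique(c(from, to))),
      edges = data.frame(from = from[ord], to = to[ord],
                         stringsAsFactors = FALSE),
      confidence = if (is.null(conf)) NULL else conf[ord],
      min_confidence = min_confidence
    ),
    class = "gene_network"
  )
  validate_gene_network(net)
  net
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d edges%s\n",
              length(x$nodes), nrow(x$edges),
              if (is.null(x$confidence)) "" else
                sprintf(" (confidence >= %s)", format(x$min_confidence))))
  invisible(x)
}

validate_gene_network <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  e <- net$edges
  if (any(e$from == e$to)) stop("gene_network invariant violated: self-loop present")
  if (anyDuplicated(paste(e$from, e$to, sep = "\r")))
    stop("gene_network invariant violated: duplicate edge")
  if (!all(c(e$from, e$to) %in% net$nodes))
    stop("gene_network invariant violated: edge endpoint missing from nodes")
  if (!is.null(net$confidence)) {
    if (length(net$confidence) != nrow(e))
      stop("gene_network invariant violated: confidence length mismatch")
    if (!is.na(net$min_confidence) && any(net$confidence < net$min_confidence))
      stop("gene_network invariant violated: confidence below threshold retained")
  }
  invisible(TRUE)
}

# Heuristic header detection: the first row is a header if any field matches a
# well-known column name, or if the confidence field is non-numeric.
.looks_like_header <- function(fields) {
  known <- c("node1", "node2", "protein1", "protein2", "gene1", "gene2",
             "combined_score", "score", "confidence", "from", "to",
             "interactor_a", "interactor_b")
  if (any(tolower(fields) %in% known)) return(TRUE)
  if (length(fields) >= 3L &&
      is.na(suppressWarnings(as.numeric(fields[3L])))) return(TRUE)
  FALSE
}

#' Load a gene interaction network from a TSV edge list
#'
#' Reads an undirected edge list in the STRING-links dialect (two node
#' columns plus an optional `combined_score`) or a plain two-column
#' (BioGRID-style) list. Edges below `min_confidence` are discarded,
#' self-loops and duplicate rows are dropped. Reading is
#' gzip-transparent.
#'
#' @param path path to a TSV file (optionally gzip-compressed).
#' @param min_confidence minimum confidence score for an edge to be kept
#'   (default 0.4, the moderate-confidence STRING cutoff). Ignored when the
#'   file has no confidence column.
#' @param dialect `"unit"` if scores are already in (0, 1]; `"string1000"`
#'   if scores are STRING-style integers 0-1000, which are divided by 1000
#'   before thresholding.
#' @param header `NA` to auto-detect a header row, or `TRUE`/`FALSE`.
#' @param verbose log row counts and filter thresholds via [message()].
#' @return A [gene_network()] object.
#' @export
load_gene_network <- function(path, min_confidence = 0.4,
                              dialect = c("unit", "string1000"),
                              header = NA, verbose = TRUE) {
  dialect <- match.arg(dialect)
  stopifnot(is.numeric(min_confidence), length(min_confidence) == 1L)

  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) == 0L) stop("empty network: file '", path, "' has no rows")
  ncols <- nf[1L]
  if (ncols < 2L) stop("parse error at line 1: expected >= 2 tab-separated columns")
  bad <- which(nf != ncols)
  if (length(bad))
    stop("parse error at line ", bad[1L], ": expected ", ncols,
         " columns, found ", nf[bad[1L]])

  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character", quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  if (is.na(header)) header <- .looks_like_header(as.character(raw[1L, ]))
  if (isTRUE(header)) raw <- raw[-1L, , drop = FALSE]
  if (nrow(raw) == 0L) stop("empty network: no data rows in '", path, "'")

  n_in <- nrow(raw)
  conf <- NULL
  if (ncols >= 3L) {
    conf <- suppressWarnings(as.numeric(raw[[3L]]))
    if (anyNA(conf)) {
      line <- which(is.na(conf))[1L] + as.integer(header)
      stop("parse error at line ", line, ": non-numeric confidence value '",
           raw[[3L]][which(is.na(conf))[1L]], "'")
    }
    if (dialect == "string1000") conf <- conf / 1000
    keep <- conf >= min_confidence
    raw <- raw[keep, , drop = FALSE]
    conf <- conf[keep]
  }
  if (nrow(raw) == 0L)
    stop("empty network: no edges with confidence >= ", min_confidence)

  df <- data.frame(from = raw[[1L]], to = raw[[2L]], stringsAsFactors = FALSE)
  if (!is.null(conf)) df$confidence <- conf
  net <- gene_network(df, min_confidence = if (is.null(conf)) NA_real_ else min_confidence)
  if (nrow(net$edges) == 0L)
    stop("empty network: all rows were self-loops or blank")
  if (verbose)
    message(sprintf(
      "load_gene_network: %d rows read, %d edges retained (%d dropped; threshold %s)",
      n_in, nrow(net$edges), n_in - nrow(net$edges),
      if (is.null(conf)) "none" else format(min_confidence)))
  net
}

#' Write a gene network to a TSV edge list
#'
#' Inverse of [load_gene_network()]: reloading the written file with the same
#' threshold reproduces the node set, edge set and confidences.
#'
#' @param net a [gene_network()] object.
#' @param path output path.
#' @export
write_gene_network <- function(net, path) {
  validate_gene_network(net)
  df <- net$edges
  names(df) <- c("node1", "node2")
  if (!is.null(net$confidence)) df$combined_score <- net$confidence
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a drug-target map
#'
#' @param targets named list; names are drug identifiers, elements are
#'   character vectors of target gene symbols. Targets are trimmed,
#'   deduplicated and sorted; every target set must be non-empty.
#' @return An object of class `drug_target_map` (a named list of sorted
#'   character vectors), optionally carrying a `merge_ledger` attribute
#'   after [merge_equivalent_drugs()].
#' @export
drug_target_map <- function(targets) {
  stopifnot(is.list(targets))
  if (length(targets) && is.null(names(targets)))
    stop("drug_target_map: 'targets' must be a named list")
  out <- lapply(targets, function(g) sort(unique(trimws(as.character(g)))))
  if (any(vapply(out, function(g) length(g) == 0L || any(!nzchar(g)), logical(1L))))
    stop("drug_target_map: every drug must have a non-empty set of non-blank targets")
  structure(out, class = "drug_target_map")
}

#' @export
print.drug_target_map <- function(x, ...) {
  cat(sprintf("drug_target_map: %d drugs, %d drug-target pairs\n",
              length(x), sum(lengths(x))))
  invisible(x)
}

#' Load a drug-to-target-gene table from TSV
#'
#' Reads a DGIdb-export-style table with a drug-name column and a gene-symbol
#' column. Rows are grouped by drug, duplicate (drug, gene) rows are
#' collapsed, and names are whitespace-trimmed. Rows with an empty drug or
#' gene field are skipped with a warning giving the count.
#'
#' @param path path to a TSV file (optionally gzip-compressed).
#' @param drug_col,gene_col column names (or 1-based indices) holding the
#'   drug identifier and the target gene symbol.
#' @param verbose log row counts.
#' @return A [drug_target_map()] (pre-merge; see [merge_equivalent_drugs()]).
#' @export
load_drug_targets <- function(path, drug_col = "drug_claim_name",
                              gene_col = "gene_name", verbose = TRUE) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  pick <- function(col, default_idx) {
    if (is.numeric(col)) return(tab[[col]])
    if (col %in% names(tab)) return(tab[[col]])
    # tolerate plain "drug"/"gene" headers
    alias <- c(drug_claim_name = "drug", gene_name = "gene")
    if (!is.na(alias[col]) && alias[col] %in% names(tab))
      return(tab[[alias[col]]])
    if (ncol(tab) >= default_idx) return(tab[[default_idx]])
    stop("load_drug_targets: column '", col, "' not found in '", path, "'")
  }
  drug <- trimws(pick(drug_col, 1L))
  gene <- trimws(pick(gene_col, 2L))

  ok <- nzchar(drug) & nzchar(gene)
  n_bad <- sum(!ok)
  if (n_bad) warning("load_drug_targets: skipped ", n_bad,
                     " row(s) with empty drug or gene field")
  drug <- drug[ok]
  gene <- gene[ok]
  if (!length(drug)) stop("load_drug_targets: no valid rows in '", path, "'")
  out <- drug_target_map(split(gene, drug))
  if (verbose)
    message(sprintf("load_drug_targets: %d rows -> %d drugs, %d pairs (%d skipped)",
                    length(ok), length(out), sum(lengths(out)), n_bad))
  out
}

#' Merge drugs with identical target sets
#'
#' Drugs targeting completely overlapping (identical) sets of genes are
#' merged and treated as a single drug. The merged identifier is the
#' lexicographically sorted member names joined by `"/"`; a merge ledger
#' mapping each merged identifier to its original names is attached so that
#' per-drug annotations (e.g. clinical tiers) remain usable downstream.
#' The operation is idempotent.
#'
#' @param map a [drug_target_map()].
#' @return A `drug_target_map` with unique target sets and a `merge_ledger`
#'   attribute: a named list, merged identifier -> character vector of
#'   original drug names (singleton for unmerged drugs).
#' @export
merge_equivalent_drugs <- function(map) {
  stopifnot(inherits(map, "drug_target_map"))
  if (!length(map)) {
    attr(map, "merge_ledger") <- list()
    return(map)
  }
  key <- vapply(map, function(g) paste(g, collapse = "\r"), character(1L))
  groups <- split(names(map), key)
  merged <- lapply(groups, function(members) sort(members))
  new_names <- vapply(merged, paste, character(1L), collapse = "/")
  out <- stats::setNames(map[vapply(merged, `[[`, character(1L), 1L)], new_names)
  out <- out[order(names(out))]
  ledger <- stats::setNames(merged, new_names)[names(out)]
  out <- drug_target_map(out)
  attr(out, "merge_ledger") <- lapply(ledger, identity)
  out
}

# Internal node-name prefix keeping drug identifiers disjoint from gene
# symbols inside any joint graph or matrix.
.drug_prefix <- "drug::"
drug_node_name <- function(drug) {
  if (!length(drug)) return(character(0))  # paste0() would recycle to length 1
  paste0(.drug_prefix, drug)
}

#' Extend a gene network with drug nodes
#'
#' Adds one node per drug, wired to its in-network target genes ("extended
#' PIN"). Targets absent from the network are dropped edge-wise (counted);
#' a drug with no in-network target is retained as an isolated, flagged
#' node so that every drug still receives a (zero) score downstream. Drug
#' identifiers live in a separate namespace, so collisions with gene
#' symbols are impossible.
#'
#' @param net a [gene_network()].
#' @param drugs a [drug_target_map()] (typically after
#'   [merge_equivalent_drugs()]).
#' @param verbose log dropped-target counts.
#' @return An object of class `extended_network`: a list with
#'   `gene_network`, `drug_nodes` (character), `drug_edges` (data frame
#'   `drug`, `gene`), `isolated_drugs` (drugs with zero in-network targets),
#'   `dropped_targets` (named integer, per-drug count of out-of-network
#'   targets) and the `merge_ledger` carried over from `drugs`.
#' @export
extend_network <- function(net, drugs, verbose = TRUE) {
  validate_gene_network(net)
  stopifnot(inherits(drugs, "drug_target_map"))
  in_net <- lapply(drugs, function(g) g[g %in% net$nodes])
  dropped <- lengths(drugs) - lengths(in_net)
  isolated <- names(drugs)[lengths(in_net) == 0L]
  edges <- data.frame(
    drug = rep(names(drugs), lengths(in_net)),
    gene = unlist(in_net, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  if (verbose && sum(dropped))
    message(sprintf("extend_network: dropped %d out-of-network target edge(s); %d isolated drug(s)",
                    sum(dropped), length(isolated)))
  structure(
    list(
      gene_network = net,
      drug_nodes = names(drugs),
      drug_edges = edges,
      isolated_drugs = isolated,
      dropped_targets = dropped,
      merge_ledger = attr(drugs, "merge_ledger")
    ),
    class = "extended_network"
  )
}

#' @export
print.extended_network <- function(x, ...) {
  cat(sprintf("extended_network: %d genes, %d gene-gene edges, %d drugs, %d drug-target edges (%d isolated drugs)\n",
              length(x$gene_network$nodes), nrow(x$gene_network$edges),
              length(x$drug_nodes), nrow(x$drug_edges),
              length(x$isolated_drugs)))
  invisible(x)
}

# igraph view of the gene-only graph (drug nodes excluded by construction,
# which also enforces the drugs-are-never-intermediaries path rule).
gene_graph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}
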