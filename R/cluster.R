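#' All-vs-all read similarity search
#'
#' k-mer seeded (default k = 12, >= 2 shared seeds), banded Smith-Waterman
#' local alignment of every candidate read pair on both strands, scoring
#' match +1 / mismatch -3 with affine gaps (open 5, extend 2 per gap base).
#' For every unordered read pair at most one hit is emitted: the best-scoring
#' alignment satisfying all three thresholds. Deterministic given inputs.
#'
#' @param reads A [read_set()] or a named character vector of sequences.
#' @param min_len Minimum alignment length in bp.
#' @param min_identity Minimum percent identity
#'   (100 * matches / alignment columns).
#' @param min_coverage Minimum fraction of the shorter read covered by the
#'   alignment (alignment columns / shorter read length).
#' @param k Seed k-mer length.
#' @param band Banded-DP halfwidth around the modal seed diagonal.
#' @param min_seeds Minimum shared k-mers for a pair to be aligned.
#' @param match,mismatch,gap_open,gap_ext Alignment scoring parameters.
#' @return A data.frame of hits: `query`, `subject` (read identifiers),
#'   `score`, `length`, `identity`, `strand` (+1/-1).
#' @export
pairwise_hits <- function(reads, min_len = 55, min_identity = 90,
                          min_coverage = 0.55, k = 12L, band = 10L,
                          min_seeds = 2L, match = 1L, mismatch = -3L,
                          gap_open = 5L, gap_ext = 2L) {
  seqs <- read_sequences(reads)
  if (length(seqs) == 0L) stop("no reads supplied")
  hits <- .cpp_all_vs_all_hits(unname(seqs), as.integer(k), as.integer(band),
                               as.integer(min_seeds), min_len, min_identity,
                               min_coverage, as.integer(match),
                               as.integer(mismatch), as.integer(gap_open),
                               as.integer(gap_ext))
  hits$query <- names(seqs)[hits$query]
  hits$subject <- names(seqs)[hits$subject]
  attr(hits, "read_ids") <- names(seqs)
  hits
}

#' Align query sequences to a reference set
#'
#' Same seeded banded Smith-Waterman engine as [pairwise_hits()], querying
#' each sequence (both strands) against a forward-indexed reference set.
#' Emits the best qualifying hit per (query, reference) pair. Used for
#' cluster annotation, contaminant screening and transcript mapping.
#'
#' @param queries Character vector of query sequences.
#' @param refs Character vector of reference sequences.
#' @inheritParams pairwise_hits
#' @return A data.frame of hits with integer `query`/`subject` indices.
#' @export
align_to_reference <- function(queries, refs, min_len = 55, min_identity = 90,
                               k = 12L, band = 10L, min_seeds = 2L,
                               match = 1L, mismatch = -3L,
                               gap_open = 5L, gap_ext = 2L) {
  stopifnot(length(refs) >= 1L)
  .cpp_reads_vs_refs_hits(unname(queries), unname(refs), as.integer(k),
                          as.integer(band), as.integer(min_seeds),
                          min_len, min_identity, as.integer(match),
                          as.integer(mismatch), as.integer(gap_open),
                          as.integer(gap_ext))
}

# Flatten a read_set to an id-named vector of mate sequences.
read_sequences <- function(reads) {
  if (inherits(reads, "read_set")) {
    stats::setNames(c(reads$seq1, reads$seq2), c(reads$id1, reads$id2))
  } else if (is.character(reads)) {
    if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
    reads
  } else stop("reads must be a read_set or a named character vector")
}

#' Build a weighted similarity graph from alignment hits
#'
#' One undirected edge per read pair, weight = alignment score; when the same
#' pair appears more than once the maximum-score edge is kept. Reads without
#' any hit are excluded from the graph and tallied as unclustered.
#'
#' @param hits A hit data.frame from [pairwise_hits()].
#' @param all_reads Optional character vector of every read identifier, used
#'   to tally isolated (unclustered) reads; defaults to the ids seen in
#'   `hits` (or the `read_ids` attribute if present).
#' @return An object of class `similarity_graph` with elements `edges`
#'   (data.frame `from`, `to`, `weight`), `nodes`, and `unclustered`.
#' @export
build_graph <- function(hits, all_reads = NULL) {
  if (is.null(all_reads)) all_reads <- attr(hits, "read_ids")
  if (nrow(hits) > 0) {
    a <- pmin(hits$query, hits$subject)
    b <- pmax(hits$query, hits$subject)
    keyed <- data.frame(from = a, to = b, weight = hits$score,
                        stringsAsFactors = FALSE)
    keyed <- keyed[keyed$from != keyed$to, , drop = FALSE]
    o <- order(keyed$from, keyed$to, -keyed$weight)
    keyed <- keyed[o, , drop = FALSE]
    dup <- duplicated(paste(keyed$from, keyed$to, sep = "\r"))
    edges <- keyed[!dup, , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  nodes <- unique(c(edges$from, edges$to))
  if (is.null(all_reads)) all_reads <- nodes
  structure(list(edges = edges, nodes = nodes,
                 unclustered = setdiff(all_reads, nodes)),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat("similarity_graph:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges,", length(x$unclustered), "unclustered reads\n")
  invisible(x)
}

#' Louvain community detection
#'
#' Two-phase Louvain maximization of weighted modularity
#' `Q = sum_c [Sin_c/(2m) - (Stot_c/(2m))^2]` at resolution 1. The node visit
#' order is shuffled from the seed; a deterministic multistart (`n_restarts`
#' seeded restarts, best Q kept) guards against local optima of the greedy
#' moves. Q never decreases across passes and the reported Q is recomputed
#' from the returned partition.
#'
#' @param graph A [build_graph()] result.
#' @param seed Integer seed for the visit-order shuffles.
#' @param n_restarts Number of seeded restarts.
#' @return An object of class `cluster_set`: `clusters` (named list of read id
#'   vectors), `membership` (named integer), `modularity`, `unclustered`,
#'   and an empty `merge_log`.
#' @export
louvain_cluster <- function(graph, seed = 1L, n_restarts = 10L) {
  stopifnot(inherits(graph, "similarity_graph"))
  if (nrow(graph$edges) == 0L) stop("cannot cluster an empty graph")
  nodes <- graph$nodes
  fr <- match(graph$edges$from, nodes)
  to <- match(graph$edges$to, nodes)
  res <- .cpp_louvain(fr, to, as.numeric(graph$edges$weight),
                      length(nodes), as.integer(seed),
                      as.integer(n_restarts))
  membership <- stats::setNames(res$membership, nodes)
  clusters <- split(nodes, membership)
  names(clusters) <- paste0("CL", names(clusters))
  structure(list(clusters = clusters, membership = membership,
                 modularity = res$modularity,
                 unclustered = graph$unclustered,
                 merge_log = data.frame(cluster_a = character(),
                                        cluster_b = character(),
                                        links = integer(),
                                        stringsAsFactors = FALSE)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set:", length(x$clusters), "clusters, Q =",
      format(x$modularity, digits = 4), ",", length(x$unclustered),
      "unclustered\n")
  invisible(x)
}

#' Recompute modularity of a partition
#'
#' Independent evaluation of `Q = sum_c [Sin_c/(2m) - (Stot_c/(2m))^2]` for
#' any assignment of graph nodes to communities.
#'
#' @param graph A [build_graph()] result.
#' @param membership Named integer vector (community per node).
#' @return Modularity Q.
#' @export
modularity_q <- function(graph, membership) {
  e <- graph$edges
  m <- sum(e$weight)
  cf <- unname(membership[e$from])
  ct <- unname(membership[e$to])
  comms <- sort(unique(unname(membership)))
  f <- factor(c(cf, ct), levels = comms)
  deg <- as.numeric(tapply(c(e$weight, e$weight), f, sum, default = 0))
  intra_f <- factor(cf[cf == ct], levels = comms)
  intra <- as.numeric(tapply(e$weight[cf == ct], intra_f, sum, default = 0))
  sum(intra / m - (deg / (2 * m))^2)
}

#' Merge clusters through mate-pair links
#'
#' Two clusters merge when at least `min_links` mate pairs span them; merging
#' is applied iteratively (links between the current, already-merged clusters
#' are recounted each round) until a fixpoint, which subsumes transitive
#' chains. Each union is recorded in `merge_log` with its link count.
#'
#' @param clusters A [louvain_cluster()] result.
#' @param reads The [read_set()] the clusters were built from (defines the
#'   mate relation).
#' @param min_links Minimum number of spanning mate pairs for a merge.
#' @return A `cluster_set` with merged clusters.
#' @export
merge_by_mates <- function(clusters, reads, min_links = 2L) {
  stopifnot(inherits(clusters, "cluster_set"), inherits(reads, "read_set"))
  log <- clusters$merge_log
  # current cluster label per read (integer)
  cur <- clusters$membership
  repeat {
    p1 <- unname(cur[reads$id1])
    p2 <- unname(cur[reads$id2])
    ok <- !is.na(p1) & !is.na(p2) & p1 != p2
    a <- pmin(p1[ok], p2[ok])
    b <- pmax(p1[ok], p2[ok])
    if (length(a) == 0L) break
    tab <- table(paste(a, b, sep = "-"))
    tab <- tab[tab >= min_links]
    if (length(tab) == 0L) break
    # union-find over cluster labels for this round
    maxlab <- max(cur, na.rm = TRUE)
    parent <- seq_len(maxlab)
    find_root <- function(x) {
      while (parent[x] != x) x <- parent[x]
      x
    }
    for (key in names(tab)) {
      ab <- as.integer(strsplit(key, "-", fixed = TRUE)[[1]])
      ra <- find_root(ab[1]); rb <- find_root(ab[2])
      if (ra == rb) next
      log <- rbind(log, data.frame(cluster_a = paste0("CL", min(ra, rb)),
                                   cluster_b = paste0("CL", max(ra, rb)),
                                   links = as.integer(tab[[key]]),
                                   stringsAsFactors = FALSE))
      parent[max(ra, rb)] <- min(ra, rb)
    }
    roots <- vapply(seq_len(maxlab), find_root, 0L)
    cur[] <- roots[cur]
  }
  clusters$membership <- cur
  cl <- split(names(cur), cur)
  names(cl) <- paste0("CL", names(cl))
  clusters$clusters <- cl
  clusters$merge_log <- log
  clusters
}
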