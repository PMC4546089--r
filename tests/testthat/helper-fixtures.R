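# Shared fixtures and independent oracles, all generated in code.

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Biostrings full O(nm) Smith-Waterman: the independent alignment oracle.
sw_oracle_score <- function(a, b, match = 1, mismatch = -3,
                            gap_open = 5, gap_ext = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  fwd <- Biostrings::score(Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_ext))
  rcb <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(b)))
  rev <- Biostrings::score(Biostrings::pairwiseAlignment(
    a, rcb, type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_ext))
  max(fwd, rev)
}

# A small read_set built directly from sequences (constant high quality).
make_read_set <- function(seq1, seq2 = NULL, qual = NULL) {
  n <- length(seq1)
  if (is.null(seq2)) seq2 <- vapply(nchar(seq1), function(k) rand_seq(k), "")
  q1 <- if (is.null(qual)) vapply(nchar(seq1), function(k) strrep("I", k), "")
        else qual
  q2 <- vapply(nchar(seq2), function(k) strrep("I", k), "")
  read_set(id1 = sprintf("p%03d/1", seq_len(n)), seq1 = seq1, qual1 = q1,
           id2 = sprintf("p%03d/2", seq_len(n)), seq2 = seq2, qual2 = q2)
}

# Exhaustive maximum-modularity partition of a small graph (Bell-number
# enumeration); the oracle for the Louvain tests.
best_partition_q <- function(edges, n_nodes) {
  all_parts <- matrix(1L, 1, 1)
  for (k in seq_len(n_nodes)[-1]) {
    grown <- lapply(seq_len(nrow(all_parts)), function(r) {
      mx <- max(all_parts[r, ])
      cbind(matrix(all_parts[r, ], mx + 1L, k - 1L, byrow = TRUE),
            seq_len(mx + 1L))
    })
    all_parts <- do.call(rbind, grown)
  }
  g <- structure(list(edges = edges,
                      nodes = as.character(seq_len(n_nodes)),
                      unclustered = character()),
                 class = "similarity_graph")
  best <- -Inf
  for (r in seq_len(nrow(all_parts))) {
    memb <- stats::setNames(all_parts[r, ], as.character(seq_len(n_nodes)))
    q <- modularity_q(g, memb)
    if (q > best) best <- q
  }
  best
}

# Random connected-ish weighted graph on <= 8 nodes for the Louvain oracle.
random_small_graph <- function(n_nodes, p = 0.5) {
  pairs <- t(utils::combn(n_nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p
  if (!any(keep)) keep[sample.int(nrow(pairs), 1)] <- TRUE
  data.frame(from = as.character(pairs[keep, 1]),
             to = as.character(pairs[keep, 2]),
             weight = sample(1:5, sum(keep), replace = TRUE),
             stringsAsFactors = FALSE)
}

# Standard synthetic genome used by the recovery tests: three superfamilies
# planted at 30 / 15 / 5 percent of a 1 Mb genome.
recovery_genome <- function(seed = 42, genome_length = 1e6) {
  fam <- data.frame(
    name = c("RLG-1", "RLG-2", "RLC-1", "RLC-2", "RIL-1"),
    superfamily = c("Gypsy", "Gypsy", "Copia", "Copia", "L1"),
    family = c("RLG_alpha", "RLG_beta", "RLC_gamma", "RLC_delta", "RIL_eps"),
    consensus_length = c(2500, 3000, 2500, 2500, 2500),
    copy_number = round(c(60, 50, 30, 30, 20) * genome_length / 1e6),
    divergence = 0.02, indel_rate = 0.002,
    stringsAsFactors = FALSE)
  make_genome(genome_spec(genome_length, fam, background_gc = 0.4,
                          seed = seed))
}
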