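test_that("identical and reverse-complement reads give the same full hit", {
  withr::local_seed(14)
  r <- rand_seq(100)
  h <- pairwise_hits(c(a = r, b = r))
  expect_equal(h$score, 100)
  expect_equal(h$length, 100)
  expect_equal(h$identity, 100)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r)))
  h2 <- pairwise_hits(c(a = r, b = rc))
  expect_equal(h2[c("score", "length", "identity")],
               h[c("score", "length", "identity")])
  expect_equal(h2$strand, -1)
})

test_that("a shared 60 bp block inside random flanks is found at the oracle score", {
  withr::local_seed(8)
  for (i in 1:10) {
    core <- rand_seq(60)
    s1 <- paste0(rand_seq(20), core, rand_seq(20))
    s2 <- paste0(rand_seq(25), core, rand_seq(15))
    h <- pairwise_hits(c(x = s1, y = s2), min_len = 55, min_identity = 90,
                       min_coverage = 0.55)
    expect_equal(nrow(h), 1L)
    expect_gte(h$length, 60)
    expect_equal(h$score, sw_oracle_score(s1, s2))
  }
})

test_that("hits are symmetric under read-order reversal", {
  withr::local_seed(81)
  core <- rand_seq(70)
  mut <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    p <- sample(length(v), k)
    v[p] <- vapply(v[p], function(b) sample(setdiff(c("A","C","G","T"), b), 1), "")
    paste(v, collapse = "")
  }
  s1 <- paste0(rand_seq(15), core, rand_seq(15))
  s2 <- paste0(rand_seq(10), mut(core, 3), rand_seq(20))
  h_ab <- pairwise_hits(c(a = s1, b = s2), min_len = 50, min_coverage = 0.4)
  h_ba <- pairwise_hits(c(b = s2, a = s1), min_len = 50, min_coverage = 0.4)
  expect_equal(sort(c(h_ab$query, h_ab$subject)),
               sort(c(h_ba$query, h_ba$subject)))
  expect_equal(h_ab$score, h_ba$score)
})

test_that("graph construction keeps one max-weight edge per pair", {
  hits <- data.frame(query = c("a", "b", "a"), subject = c("b", "a", "c"),
                     score = c(10, 25, 7), length = 60, identity = 95,
                     strand = 1)
  g <- build_graph(hits, all_reads = c("a", "b", "c", "d"))
  expect_equal(nrow(g$edges), 2L)
  expect_equal(g$edges$weight[g$edges$from == "a" & g$edges$to == "b"], 25)
  expect_equal(g$unclustered, "d")

  empty <- build_graph(hits[0, ], all_reads = c("a", "b"))
  expect_equal(nrow(empty$edges), 0L)
  expect_equal(sort(empty$unclustered), c("a", "b"))
})

test_that("Louvain recovers planted cliques and reports consistent Q", {
  cl4 <- t(utils::combn(1:4, 2)); cl8 <- t(utils::combn(5:8, 2))
  hits <- data.frame(query = as.character(c(cl4[, 1], cl8[, 1])),
                     subject = as.character(c(cl4[, 2], cl8[, 2])),
                     score = 1, length = 60, identity = 100, strand = 1)
  g <- build_graph(hits)
  cl <- louvain_cluster(g, seed = 4)
  expect_equal(cl$modularity, 0.5, tolerance = 1e-12)
  expect_equal(length(cl$clusters), 2L)
  expect_equal(modularity_q(g, cl$membership), cl$modularity,
               tolerance = 1e-12)
  # single-edge graph: both nodes in one community, Q = 0
  g1 <- build_graph(data.frame(query = "a", subject = "b", score = 3,
                               length = 60, identity = 100, strand = 1))
  cl1 <- louvain_cluster(g1, seed = 1)
  expect_equal(length(cl1$clusters), 1L)
  expect_equal(cl1$modularity, 0, tolerance = 1e-12)
  expect_error(louvain_cluster(build_graph(hits[0, ]), seed = 1), "empty")
})

test_that("Louvain attains the exhaustive optimum on random small graphs", {
  withr::local_seed(19)
  for (i in 1:15) {
    n <- sample(4:7, 1)
    edges <- random_small_graph(n)
    g <- structure(list(edges = edges, nodes = as.character(seq_len(n)),
                        unclustered = character()),
                   class = "similarity_graph")
    cl <- louvain_cluster(g, seed = i)
    expect_equal(cl$modularity, best_partition_q(edges, n),
                 tolerance = 1e-10)
  }
})

test_that("Louvain matches igraph's modularity on a larger random graph", {
  skip_if_not_installed("igraph")
  withr::local_seed(27)
  n <- 60
  edges <- random_small_graph(n, p = 0.08)
  g <- structure(list(edges = edges, nodes = as.character(seq_len(n)),
                      unclustered = character()),
                 class = "similarity_graph")
  cl <- louvain_cluster(g, seed = 5)
  ig <- igraph::graph_from_data_frame(edges, directed = FALSE)
  iq <- max(vapply(1:10, function(i)
    igraph::modularity(igraph::cluster_louvain(ig,
                                               weights = edges$weight)), 0))
  expect_gte(cl$modularity + 1e-9, iq - 0.02)
})

test_that("mate-link merging honors the threshold and closes chains", {
  rs <- read_set(id1 = c("r1a", "r2a", "r3a", "r4a"),
                 seq1 = rep("ACGT", 4),
                 id2 = c("r1b", "r2b", "r3b", "r4b"),
                 seq2 = rep("ACGT", 4))
  base <- list(clusters = list(CL1 = c("r1a", "r2a"), CL2 = c("r1b", "r2b")),
               membership = stats::setNames(c(1L, 1L, 2L, 2L),
                                            c("r1a", "r2a", "r1b", "r2b")),
               modularity = 0.4, unclustered = character(),
               merge_log = data.frame(cluster_a = character(),
                                      cluster_b = character(),
                                      links = integer()))
  class(base) <- "cluster_set"
  merged <- merge_by_mates(base, rs[1:2, ], min_links = 2)
  expect_equal(length(merged$clusters), 1L)
  expect_equal(nrow(merged$merge_log), 1L)
  unmerged <- merge_by_mates(base, rs[1:2, ], min_links = 3)
  expect_equal(length(unmerged$clusters), 2L)

  # chain A-B (2 links), B-C (2 links) collapses at min_links = 2
  chain <- list(clusters = list(A = c("r1a", "r2a"), B = c("r1b", "r2b",
                                                           "r3a", "r4a"),
                                C = c("r3b", "r4b")),
                membership = stats::setNames(c(1L, 1L, 2L, 2L, 2L, 2L, 3L, 3L),
                                             c("r1a", "r2a", "r1b", "r2b",
                                               "r3a", "r4a", "r3b", "r4b")),
                modularity = 0.4, unclustered = character(),
                merge_log = data.frame(cluster_a = character(),
                                       cluster_b = character(),
                                       links = integer()))
  class(chain) <- "cluster_set"
  out <- merge_by_mates(chain, rs, min_links = 2)
  expect_equal(length(out$clusters), 1L)
})

test_that("reads from one easy planted family form a single cluster", {
  fam <- data.frame(name = "RLG-1", superfamily = "Gypsy", family = "RLG_x",
                    consensus_length = 1000, copy_number = 10,
                    divergence = 0.01, indel_rate = 0,
                    stringsAsFactors = FALSE)
  gen <- make_genome(genome_spec(60000, fam, seed = 5))
  reads <- simulate_reads(gen, coverage = 3, read_len = 100,
                          insert_mean = 300, insert_sd = 20,
                          error_rate = 0, seed = 6)
  hits <- pairwise_hits(reads)
  g <- build_graph(hits)
  cl <- merge_by_mates(louvain_cluster(g, seed = 2), reads, min_links = 2)
  # which reads truly originate inside a planted copy?
  orig <- attr(reads, "origin")
  pl <- gen$ledger$placements
  inside <- function(lo, hi) any(lo >= pl$start & hi <= pl$end)
  fam_pairs <- orig$pair[mapply(inside, orig$fragment_start,
                                orig$fragment_end)]
  fam_ids <- c(paste0(fam_pairs, "/1"), paste0(fam_pairs, "/2"))
  homes <- unique(cl$membership[fam_ids])
  expect_equal(length(homes), 1L)
  # conservation: every read is clustered or unclustered
  expect_equal(length(cl$membership) + length(cl$unclustered),
               2L * nrow(reads))
})
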