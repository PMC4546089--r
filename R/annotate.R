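#' Annotate a read cluster against a repeat library
#'
#' Each cluster read votes for the family of its single best-scoring library
#' hit passing the thresholds (score ties broken by library order); the
#' cluster label is the plurality family, with its superfamily and class
#' inherited from the library entry. `hit_fraction` is the fraction of
#' cluster reads voting for the winning family. A cluster with no qualifying
#' hit is "unannotated" with hit fraction 0.
#'
#' @param cluster_reads Character vector of cluster read sequences.
#' @param library Repeat library data.frame from [read_repeat_library()].
#' @param min_len Minimum alignment length in bp.
#' @param min_identity Minimum percent identity.
#' @param ... Passed to [align_to_reference()].
#' @return A list of class `cluster_annotation`: `family`, `superfamily`,
#'   `te_class`, `hit_fraction`, `vote_breakdown` (named counts),
#'   `cluster_size`.
#' @export
annotate_cluster <- function(cluster_reads, library, min_len = 55,
                             min_identity = 90, ...) {
  stopifnot(length(cluster_reads) >= 1L, nrow(library) >= 1L)
  hits <- align_to_reference(cluster_reads, library$sequence,
                             min_len = min_len, min_identity = min_identity,
                             ...)
  annotate_from_hits(hits, length(cluster_reads), library)
}

# Shared vote aggregation given precomputed read-vs-library hits with integer
# query (read index) and subject (library row) columns.
annotate_from_hits <- function(hits, n_reads, library) {
  if (nrow(hits) == 0L) {
    ann <- list(family = "unannotated", superfamily = "unannotated",
                te_class = "unannotated", hit_fraction = 0,
                vote_breakdown = integer(), cluster_size = n_reads)
    class(ann) <- "cluster_annotation"
    return(ann)
  }
  # best hit per read: max score, ties by library order (lower subject index)
  o <- order(hits$query, -hits$score, hits$subject)
  h <- hits[o, , drop = FALSE]
  best <- h[!duplicated(h$query), , drop = FALSE]
  fam <- library$family[best$subject]
  votes <- sort(table(fam), decreasing = TRUE)
  # plurality; ties broken by library order of the family
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1L) {
    top <- top[order(match(top, library$family))][1L]
  } else top <- top[1L]
  lib_row <- library[match(top, library$family), ]
  ann <- list(family = top,
              superfamily = lib_row$superfamily,
              te_class = lib_row$te_class,
              hit_fraction = sum(fam == top) / n_reads,
              vote_breakdown = c(table(fam)),
              cluster_size = n_reads)
  class(ann) <- "cluster_annotation"
  ann
}

#' Annotate every cluster of a cluster set
#'
#' Aligns all clustered reads to the library once, then aggregates votes per
#' cluster with the [annotate_cluster()] rules.
#'
#' @param clusters A [louvain_cluster()]/[merge_by_mates()] result.
#' @param reads The [read_set()] behind the clusters.
#' @param library Repeat library data.frame.
#' @inheritParams annotate_cluster
#' @return Named list of `cluster_annotation`s, one per cluster.
#' @export
annotate_clusters <- function(clusters, reads, library, min_len = 55,
                              min_identity = 90, ...) {
  seqs <- read_sequences(reads)
  clustered_ids <- unlist(clusters$clusters, use.names = FALSE)
  hits <- align_to_reference(unname(seqs[clustered_ids]), library$sequence,
                             min_len = min_len, min_identity = min_identity,
                             ...)
  id_of_query <- clustered_ids[hits$query]
  out <- lapply(clusters$clusters, function(members) {
    sub <- hits[id_of_query %in% members, , drop = FALSE]
    sub$query <- match(id_of_query[id_of_query %in% members], members)
    annotate_from_hits(sub, length(members), library)
  })
  out
}

#' Single-replicate genomic composition
#'
#' Converts cluster sizes and annotations into genome-referenced fractions:
#' the fraction credited to a family is
#' `(cluster_size / total_sampled_reads) * hit_fraction` summed over clusters
#' sharing the family; the `(1 - hit_fraction)` remainder of each annotated
#' cluster accrues to "unannotated", and reads outside any cluster accrue to
#' "unclustered", so all fractions sum to 1 exactly.
#'
#' @param clusters A cluster set.
#' @param annotations Result of [annotate_clusters()].
#' @param total_reads Total number of sampled reads (mates, not pairs).
#' @return A data.frame with columns `family`, `superfamily`, `te_class`,
#'   `fraction`; includes "unannotated" and "unclustered" rows.
#' @export
composition <- function(clusters, annotations, total_reads) {
  sizes <- lengths(clusters$clusters)
  if (sum(sizes) + length(clusters$unclustered) > total_reads) {
    stop("cluster sizes exceed total sampled reads: ",
         sum(sizes) + length(clusters$unclustered), " > ", total_reads)
  }
  rows <- list()
  unannotated <- 0
  for (i in seq_along(annotations)) {
    ann <- annotations[[i]]
    share <- sizes[i] / total_reads
    if (ann$family == "unannotated") {
      unannotated <- unannotated + share
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        family = ann$family, superfamily = ann$superfamily,
        te_class = ann$te_class, fraction = share * ann$hit_fraction,
        stringsAsFactors = FALSE)
      unannotated <- unannotated + share * (1 - ann$hit_fraction)
    }
  }
  fam <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family = character(), superfamily = character(),
               te_class = character(), fraction = numeric(),
               stringsAsFactors = FALSE)
  if (nrow(fam)) {
    fam <- stats::aggregate(fraction ~ family + superfamily + te_class, fam,
                            sum)[, c("family", "superfamily", "te_class",
                                     "fraction")]
  }
  # every read outside a cluster is unclustered, so fractions sum to 1 exactly
  unclustered <- (total_reads - sum(sizes)) / total_reads
  extras <- data.frame(
    family = c("unannotated", "unclustered"),
    superfamily = c("unannotated", "unclustered"),
    te_class = c("unannotated", "unclustered"),
    fraction = c(unannotated, unclustered),
    stringsAsFactors = FALSE)
  out <- rbind(fam[order(-fam$fraction), ], extras)
  rownames(out) <- NULL
  out
}

# Run sample -> all-vs-all -> Louvain -> mate merge -> annotate -> composition
# for one replicate.
run_replicate <- function(reads, library, k, seed,
                          cluster_args = list(), annotate_args = list()) {
  samp <- sample_pairs(reads, k, seed)
  ca <- utils::modifyList(list(min_len = 55, min_identity = 90,
                               min_coverage = 0.55, merge_links = 2L,
                               n_restarts = 10L), cluster_args)
  hits <- pairwise_hits(samp, min_len = ca$min_len,
                        min_identity = ca$min_identity,
                        min_coverage = ca$min_coverage)
  graph <- build_graph(hits)
  total <- 2L * nrow(samp)
  if (nrow(graph$edges) == 0L) {
    clusters <- structure(list(clusters = list(),
                               membership = integer(),
                               modularity = NA_real_,
                               unclustered = c(samp$id1, samp$id2),
                               merge_log = NULL), class = "cluster_set")
    anns <- list()
  } else {
    clusters <- louvain_cluster(graph, seed = seed, n_restarts = ca$n_restarts)
    clusters <- merge_by_mates(clusters, samp, min_links = ca$merge_links)
    aa <- utils::modifyList(list(min_len = 55, min_identity = 90),
                            annotate_args)
    anns <- annotate_clusters(clusters, samp, library,
                              min_len = aa$min_len,
                              min_identity = aa$min_identity)
  }
  comp <- composition(clusters, anns, total)
  list(composition = comp, clusters = clusters, modularity =
         clusters$modularity)
}

#' Replicated composition estimate
#'
#' Runs the sample -> cluster -> annotate -> composition pipeline once per
#' replicate seed and tabulates the per-family genomic fraction with mean and
#' sample SD across replicates (SD is `NA` with a single replicate).
#'
#' @param reads The filtered/screened [read_set()] pool.
#' @param library Repeat library data.frame.
#' @param k Pairs sampled per replicate.
#' @param seeds Integer vector, one seed per replicate.
#' @param cluster_args,annotate_args Optional threshold overrides (lists).
#' @return A `composition_table` data.frame: `family`, `superfamily`,
#'   `te_class`, one `repN` column per replicate, `mean`, `sd` (fractions).
#' @export
replicate_composition <- function(reads, library, k, seeds = c(101, 202, 303),
                                  cluster_args = list(),
                                  annotate_args = list()) {
  stopifnot(length(seeds) >= 1L)
  reps <- lapply(seeds, function(s)
    run_replicate(reads, library, k, s, cluster_args, annotate_args))
  comps <- lapply(reps, `[[`, "composition")
  keys <- unique(do.call(rbind, lapply(comps, function(x)
    x[c("family", "superfamily", "te_class")])))
  mat <- sapply(comps, function(x)
    x$fraction[match(keys$family, x$family)])
  mat <- matrix(mat, nrow = nrow(keys))
  mat[is.na(mat)] <- 0
  colnames(mat) <- paste0("rep", seq_along(seeds))
  out <- cbind(keys, as.data.frame(mat),
               mean = rowMeans(mat),
               sd = if (length(seeds) >= 2L) apply(mat, 1L, stats::sd)
                    else NA_real_)
  out <- out[order(-out$mean), ]
  rownames(out) <- NULL
  structure(out, class = c("composition_table", "data.frame"),
            seeds = seeds)
}

#' Superfamily and class totals of a composition table
#' @param comp A [replicate_composition()] result.
#' @param by `"superfamily"` or `"te_class"`.
#' @return Data.frame of summed mean fractions.
#' @export
composition_totals <- function(comp, by = c("superfamily", "te_class")) {
  by <- match.arg(by)
  agg <- stats::aggregate(comp$mean, list(group = comp[[by]]), sum)
  names(agg)[2] <- "mean_fraction"
  agg[order(-agg$mean_fraction), ]
}

#' Coverage-titration coefficient of variation
#'
#' For each genome-coverage level, runs `length(seeds)` replicates of the
#' pipeline at the implied sample size
#' `k = round(level * genome_length / (2 * read_len))` and computes the
#' coefficient of variation (sample SD / mean) of every family's fraction
#' across replicates. The per-level summary is the mean CV over families with
#' nonzero mean; zero-mean families are excluded and counted.
#'
#' @param reads Read pool ([read_set()]).
#' @param library Repeat library.
#' @param levels Numeric vector of genome-coverage fractions (e.g. 0.051 for
#'   5.1 % coverage).
#' @param genome_length Genome size in bp the coverage refers to.
#' @param read_len Read length in bp.
#' @param seeds Base seeds, one per replicate; level index is folded in.
#' @param ... Passed to [replicate_composition()].
#' @return A data.frame per level: `level`, `pairs`, `mean_cv`,
#'   `n_families`, `n_excluded`.
#' @export
coverage_titration <- function(reads, library, levels, genome_length,
                               read_len = 100L, seeds = c(11, 22, 33), ...) {
  res <- lapply(seq_along(levels), function(li) {
    k <- max(1L, as.integer(round(levels[li] * genome_length /
                                    (2 * read_len))))
    if (k > nrow(reads)) {
      stop("coverage level ", levels[li], " implies ", k,
           " pairs but only ", nrow(reads), " are available")
    }
    comp <- replicate_composition(reads, library, k,
                                  seeds = seeds + 1000L * li, ...)
    fam <- comp[!comp$family %in% c("unannotated", "unclustered"), ]
    cv <- fam$sd / fam$mean
    usable <- is.finite(cv) & fam$mean > 0
    data.frame(level = levels[li], pairs = k,
               mean_cv = if (any(usable)) mean(cv[usable]) else NA_real_,
               n_families = sum(usable), n_excluded = sum(!usable))
  })
  do.call(rbind, res)
}
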