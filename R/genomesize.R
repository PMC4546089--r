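#' Map reads to a transcript reference for coverage estimation
#'
#' Each read contributes its best qualifying alignment's length to exactly
#' one transcript (best-hit rule; score ties go to the lowest transcript
#' index, logged in the result attributes). Per-transcript coverage is
#' `cov = N / L`, with `N` the total aligned bases accumulated on the
#' transcript and `L` the transcript length. Only alignments of at least
#' `min_aln_len` bp and `min_identity` percent identity contribute.
#'
#' @param reads A [read_set()] or character vector of read sequences.
#' @param transcripts Named character vector of transcript sequences.
#' @param min_aln_len Minimum alignment length in bp (default 60).
#' @param min_identity Minimum percent identity (default 70).
#' @param hits Optional precomputed hit table (from [align_to_reference()]
#'   at looser thresholds) to re-filter instead of realigning.
#' @return A data.frame of class `transcript_coverage`: `transcript_id`,
#'   `L`, `N`, `cov`; attribute `n_reads` carries the total read count.
#' @export
map_to_transcripts <- function(reads, transcripts, min_aln_len = 60,
                               min_identity = 70, hits = NULL) {
  stopifnot(length(transcripts) >= 1L)
  seqs <- read_sequences(reads)
  if (is.null(names(transcripts)))
    names(transcripts) <- paste0("tx", seq_along(transcripts))
  if (is.null(hits)) {
    hits <- align_to_reference(unname(seqs), unname(transcripts),
                               min_len = min_aln_len,
                               min_identity = min_identity)
  } else {
    hits <- hits[hits$length >= min_aln_len &
                   hits$identity >= min_identity, , drop = FALSE]
  }
  n_ties <- 0L
  if (nrow(hits)) {
    o <- order(hits$query, -hits$score, hits$subject)
    h <- hits[o, , drop = FALSE]
    first <- !duplicated(h$query)
    # reads whose best score is shared by >1 transcript (tie-broken by index)
    top_score <- stats::ave(h$score, h$query, FUN = max)
    n_ties <- sum(tapply(h$score == top_score, h$query, sum) > 1L)
    best <- h[first, , drop = FALSE]
    N <- vapply(seq_along(transcripts), function(j)
      sum(best$length[best$subject == j]), 0)
  } else {
    N <- numeric(length(transcripts))
  }
  L <- nchar(transcripts)
  out <- data.frame(transcript_id = names(transcripts), L = unname(L),
                    N = N, cov = N / unname(L), stringsAsFactors = FALSE)
  structure(out, class = c("transcript_coverage", "data.frame"),
            n_reads = length(seqs), tie_breaks = n_ties)
}

#' Top-trimmed mean transcript coverage
#'
#' Zero-coverage transcripts are excluded first; the remaining coverages are
#' sorted descending and the top `ceil(trim_top * count)` are dropped before
#' taking the arithmetic mean. When trimming would empty the set, nothing is
#' trimmed and a warning is issued.
#'
#' @param coverages A [map_to_transcripts()] result or numeric vector.
#' @param trim_top Fraction of highest-coverage transcripts to drop
#'   (default 0.10).
#' @return The trimmed mean coverage.
#' @export
trimmed_mean_cov <- function(coverages, trim_top = 0.10) {
  cov <- if (is.data.frame(coverages)) coverages$cov else coverages
  cov <- cov[cov > 0]
  if (length(cov) == 0L) {
    stop("all transcript coverages are zero; cannot estimate genome size")
  }
  drop <- ceiling(trim_top * length(cov))
  if (drop >= length(cov)) {
    warning("trimming ", drop, " of ", length(cov),
            " transcripts would empty the set; trimming 0 instead")
    drop <- 0L
  }
  cov <- sort(cov, decreasing = TRUE)
  mean(cov[(drop + 1L):length(cov)])
}

#' Genome-size estimate from read depth
#'
#' `Cval = P * (n * l / mean_cov)`: ploidy times total read bases divided by
#' the trimmed-mean per-transcript coverage.
#'
#' @param P Ploidy level (positive integer).
#' @param n Total number of reads.
#' @param l Read length in bp.
#' @param mean_cov Trimmed mean transcript coverage, see
#'   [trimmed_mean_cov()].
#' @return An object of class `genome_size_estimate` with fields `P`, `n`,
#'   `l`, `mean_cov`, `Cval` (bp).
#' @export
estimate_cval <- function(P, n, l, mean_cov) {
  stopifnot(P > 0, n > 0, l > 0)
  if (mean_cov <= 0) stop("mean coverage must be positive")
  structure(list(P = P, n = n, l = l, mean_cov = mean_cov,
                 Cval = P * (n * l / mean_cov)),
            class = "genome_size_estimate")
}

#' @export
print.genome_size_estimate <- function(x, ...) {
  cat(sprintf("Cval = %.0f bp (P = %d, n = %d reads, l = %d bp, mean cov = %.4g)\n",
              x$Cval, as.integer(x$P), as.integer(x$n), as.integer(x$l),
              x$mean_cov))
  invisible(x)
}

#' One-call genome-size estimation
#' @inheritParams map_to_transcripts
#' @param P Ploidy.
#' @param trim_top Trim fraction for [trimmed_mean_cov()].
#' @return A `genome_size_estimate`.
#' @export
genome_size <- function(reads, transcripts, P = 1L, min_aln_len = 60,
                        min_identity = 70, trim_top = 0.10) {
  seqs <- read_sequences(reads)
  covs <- map_to_transcripts(seqs, transcripts, min_aln_len, min_identity)
  estimate_cval(P, length(seqs), round(mean(nchar(seqs))),
                trimmed_mean_cov(covs, trim_top))
}

#' Threshold sensitivity grid for the genome-size estimator
#'
#' Recomputes the estimate at every (alignment length, identity) threshold
#' pair over the supplied grids, re-filtering a single base alignment run,
#' and returns the absolute relative error against a known truth together
#' with the argmin. Deterministic.
#'
#' @inheritParams genome_size
#' @param lens Alignment-length thresholds to scan (bp).
#' @param ids Percent-identity thresholds to scan.
#' @param truth Known genome size in bp (synthetic ledger or flow cytometry).
#' @return A data.frame grid (`min_len`, `min_identity`, `Cval`,
#'   `rel_error`) with attribute `argmin` (row index of smallest error).
#' @export
threshold_grid <- function(reads, transcripts, truth,
                           lens = seq(50, 100, by = 10),
                           ids = seq(50, 100, by = 10),
                           P = 1L, trim_top = 0.10) {
  stopifnot(truth > 0)
  seqs <- read_sequences(reads)
  base <- align_to_reference(unname(seqs), unname(transcripts),
                             min_len = min(lens), min_identity = min(ids))
  grid <- expand.grid(min_len = lens, min_identity = ids)
  grid$Cval <- NA_real_
  l <- round(mean(nchar(seqs)))
  for (g in seq_len(nrow(grid))) {
    covs <- map_to_transcripts(seqs, transcripts,
                               min_aln_len = grid$min_len[g],
                               min_identity = grid$min_identity[g],
                               hits = base)
    grid$Cval[g] <- tryCatch(
      estimate_cval(P, length(seqs), l, trimmed_mean_cov(covs, trim_top))$Cval,
      error = function(e) NA_real_)
  }
  grid$rel_error <- abs(grid$Cval - truth) / truth
  structure(grid, argmin = which.min(grid$rel_error))
}
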