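#' Read filtering policy
#'
#' Defaults reproduce the standard short-read screen applied before repeat
#' clustering: minimum length 40 bp, minimum mean Phred quality 15, trinucleotide
#' entropy score >= 60, poly-N right-trimming at 10, at most 20 % N, and
#' rejection of non-IUPAC characters.
#'
#' @param min_len Minimum mate length in bp after trimming.
#' @param min_mean_qual Minimum mean Phred quality.
#' @param entropy_threshold Minimum complexity score in \[0, 100\],
#'   see [entropy_score()].
#' @param trim_ns_right Minimum length of a trailing poly-N run for it to be
#'   trimmed off the 3' end before testing.
#' @param max_n_percent Maximum percentage of N bases tolerated per mate.
#' @param drop_non_iupac Reject mates containing characters outside
#'   `{A,C,G,T,N}`.
#' @return An object of class `filter_policy`.
#' @export
filter_policy <- function(min_len = 40L, min_mean_qual = 15,
                          entropy_threshold = 60, trim_ns_right = 10L,
                          max_n_percent = 20, drop_non_iupac = TRUE) {
  stopifnot(min_len >= 1, min_mean_qual >= 0,
            entropy_threshold >= 0, entropy_threshold <= 100,
            trim_ns_right >= 0, max_n_percent >= 0, max_n_percent <= 100)
  structure(list(min_len = as.integer(min_len),
                 min_mean_qual = min_mean_qual,
                 entropy_threshold = entropy_threshold,
                 trim_ns_right = as.integer(trim_ns_right),
                 max_n_percent = max_n_percent,
                 drop_non_iupac = isTRUE(drop_non_iupac)),
            class = "filter_policy")
}

#' Trinucleotide entropy complexity score
#'
#' `100 * H3 / Hmax`, where `H3` is the Shannon entropy (natural log) of the
#' overlapping 3-mer counts of the sequence and `Hmax = ln(min(64, L - 2))`.
#' A homopolymer scores 0; a sequence whose 3-mers are all distinct scores 100.
#'
#' @param seq Character vector of sequences, each of length >= 3.
#' @return Numeric scores in \[0, 100\].
#' @export
entropy_score <- function(seq) {
  vapply(seq, function(s) {
    L <- nchar(s)
    if (L < 3L) stop("entropy score undefined for sequences shorter than 3 bp")
    tri <- substring(s, 1:(L - 2L), 3:L)
    p <- table(tri) / (L - 2L)
    h <- -sum(p * log(p))
    hmax <- log(min(64L, L - 2L))
    if (hmax == 0) return(if (h == 0) 100 else 0) # L = 3: single 3-mer
    100 * h / hmax
  }, 0, USE.NAMES = FALSE)
}

# Remove a trailing poly-N run when it is at least `min_run` long.
# Idempotent: after trimming no qualifying run remains.
trim_ns_right <- function(seq, qual, min_run) {
  if (min_run <= 0L) return(list(seq = seq, qual = qual))
  tail_n <- nchar(seq) - nchar(sub("N+$", "", seq))
  cut <- tail_n >= min_run
  newlen <- ifelse(cut, nchar(seq) - tail_n, nchar(seq))
  list(seq = substr(seq, 1L, newlen),
       qual = ifelse(is.na(qual), qual, substr(qual, 1L, newlen)))
}

mate_failure_cause <- function(seq, qual, policy) {
  n <- length(seq)
  cause <- rep(NA_character_, n)
  if (policy$drop_non_iupac) {
    bad <- grepl("[^ACGTN]", seq)
    cause[is.na(cause) & bad] <- "non_iupac"
  }
  short <- nchar(seq) < policy$min_len
  cause[is.na(cause) & short] <- "min_len"
  meanq <- vapply(phred_scores(qual), function(q)
    if (length(q)) mean(q) else Inf, 0)
  cause[is.na(cause) & meanq < policy$min_mean_qual] <- "min_qual"
  npct <- 100 * (nchar(seq) - nchar(gsub("N", "", seq, fixed = TRUE))) /
    pmax(nchar(seq), 1L)
  cause[is.na(cause) & npct > policy$max_n_percent] <- "max_n"
  ok <- is.na(cause) & nchar(seq) >= 3L
  if (any(ok)) {
    ent <- entropy_score(seq[ok])
    idx <- which(ok)[ent < policy$entropy_threshold]
    cause[idx] <- "low_complexity"
  }
  cause
}

#' Quality/complexity filter of paired reads
#'
#' Each mate is right-trimmed of poly-N tails, then tested against every
#' enabled policy test; a pair is kept only when BOTH mates pass. Thresholds
#' are inclusive: a mate exactly at `min_len`, `min_mean_qual` or
#' `entropy_threshold` passes. Order of survivors is preserved.
#'
#' @param reads A [read_set()].
#' @param policy A [filter_policy()].
#' @return A list with `kept` (a `read_set` of trimmed survivors) and
#'   `rejections`, a named integer vector counting removed pairs by the first
#'   failing cause (mate 1 tested before mate 2).
#' @export
filter_reads <- function(reads, policy = filter_policy()) {
  stopifnot(inherits(reads, "read_set"), inherits(policy, "filter_policy"))
  causes <- c("non_iupac", "min_len", "min_qual", "max_n", "low_complexity")
  if (nrow(reads) == 0L) {
    return(list(kept = reads,
                rejections = stats::setNames(integer(length(causes)), causes)))
  }
  t1 <- trim_ns_right(reads$seq1, reads$qual1, policy$trim_ns_right)
  t2 <- trim_ns_right(reads$seq2, reads$qual2, policy$trim_ns_right)
  c1 <- mate_failure_cause(t1$seq, t1$qual, policy)
  c2 <- mate_failure_cause(t2$seq, t2$qual, policy)
  pair_cause <- ifelse(!is.na(c1), c1, c2)
  keep <- is.na(pair_cause)
  prov <- attr(reads, "provenance")
  prov <- prov[setdiff(names(prov), "filter_policy")]
  kept <- read_set(id1 = reads$id1[keep], seq1 = t1$seq[keep],
                   qual1 = t1$qual[keep],
                   id2 = reads$id2[keep], seq2 = t2$seq[keep],
                   qual2 = t2$qual[keep],
                   provenance = c(prov, list(filter_policy = policy)))
  rej <- table(factor(pair_cause[!keep], levels = causes))
  list(kept = kept, rejections = stats::setNames(as.integer(rej), causes))
}

#' Screen read pairs against a contaminant reference
#'
#' A pair is dropped when either mate has a local alignment to any contaminant
#' sequence meeting both the identity and length thresholds (organelle screen
#' defaults: 90 % identity over >= 50 bp).
#'
#' @param reads A [read_set()].
#' @param contaminants Named character vector of contaminant sequences, or a
#'   FASTA path.
#' @param min_identity Minimum percent identity of a disqualifying hit.
#' @param min_len Minimum alignment length in bp of a disqualifying hit.
#' @return A `read_set` of clean pairs, with attribute `n_removed`.
#' @export
screen_contaminants <- function(reads, contaminants,
                                min_identity = 90, min_len = 50) {
  stopifnot(inherits(reads, "read_set"))
  if (is.character(contaminants) && length(contaminants) == 1L &&
      file.exists(contaminants)) {
    contaminants <- read_fasta(contaminants)
  }
  if (length(contaminants) == 0L) {
    stop("empty contaminant set; omit the screen instead of passing nothing")
  }
  if (nrow(reads) == 0L) {
    return(structure(reads, n_removed = 0L))
  }
  mates <- c(reads$seq1, reads$seq2)
  hits <- align_to_reference(mates, unname(contaminants),
                             min_len = min_len, min_identity = min_identity)
  dirty_mate <- unique(hits$query)
  dirty_pair <- unique(((dirty_mate - 1L) %% nrow(reads)) + 1L)
  keep <- setdiff(seq_len(nrow(reads)), dirty_pair)
  out <- read_set(id1 = reads$id1[keep], seq1 = reads$seq1[keep],
                  qual1 = reads$qual1[keep],
                  id2 = reads$id2[keep], seq2 = reads$seq2[keep],
                  qual2 = reads$qual2[keep],
                  provenance = attr(reads, "provenance"))
  structure(out, n_removed = length(dirty_pair))
}

#' Random paired-aware subsampling
#'
#' Uniform sampling of `k` pairs without replacement; mates are never split.
#' The sampled pairs are returned in their original input order (canonical
#' order), so `k = nrow(reads)` is the identity. Deterministic for a given
#' seed and input.
#'
#' @param reads A [read_set()].
#' @param k Number of pairs to draw.
#' @param seed Integer seed.
#' @return A `read_set` of `k` pairs.
#' @export
sample_pairs <- function(reads, k, seed) {
  stopifnot(inherits(reads, "read_set"))
  n <- nrow(reads)
  if (k > n) stop("cannot sample ", k, " pairs from a population of ", n)
  idx <- sort(with_local_seed(seed, sample.int(n, k)))
  prov <- c(attr(reads, "provenance"), list(sample_seed = seed, sample_k = k))
  read_set(id1 = reads$id1[idx], seq1 = reads$seq1[idx],
           qual1 = reads$qual1[idx],
           id2 = reads$id2[idx], seq2 = reads$seq2[idx],
           qual2 = reads$qual2[idx], provenance = prov)
}

# Evaluate `expr` under a private RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
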