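#' Specification of a synthetic repeat-bearing genome
#'
#' @param genome_length Genome size in bp.
#' @param families Data.frame with columns `name`, `superfamily`, `family`,
#'   `consensus_length` (bp), `copy_number`, `divergence` (per-base
#'   substitution rate per copy, in \[0, 0.5)), `indel_rate` (per-base).
#' @param background_gc GC fraction of the single-copy background.
#' @param seed Integer seed.
#' @return A validated list of class `genome_spec`.
#' @export
genome_spec <- function(genome_length, families = NULL, background_gc = 0.4,
                        seed = 1L) {
  if (is.null(families)) {
    families <- data.frame(name = character(), superfamily = character(),
                           family = character(), consensus_length = integer(),
                           copy_number = integer(), divergence = numeric(),
                           indel_rate = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(genome_length >= 1,
            all(families$divergence >= 0), all(families$divergence < 0.5),
            background_gc > 0, background_gc < 1)
  planted <- sum(families$consensus_length * families$copy_number)
  if (planted > genome_length) {
    stop("planted repeat content (", planted, " bp) exceeds genome length (",
         genome_length, " bp)")
  }
  structure(list(genome_length = as.integer(genome_length),
                 families = families, background_gc = background_gc,
                 seed = as.integer(seed)),
            class = "genome_spec")
}

random_sequence <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Substitutions then indels at the stated per-base rates.
mutate_sequence <- function(seq, divergence, indel_rate) {
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  nsub <- stats::rbinom(1, n, divergence)
  if (nsub > 0) {
    pos <- sample.int(n, nsub)
    bases <- c("A", "C", "G", "T")
    v[pos] <- vapply(v[pos], function(b)
      sample(setdiff(bases, b), 1), "")
  }
  nind <- stats::rbinom(1, n, indel_rate)
  if (nind > 0) {
    for (i in seq_len(nind)) {
      pos <- sample.int(length(v), 1)
      if (stats::runif(1) < 0.5) {
        v <- v[-pos]                                   # deletion
      } else {
        v <- append(v, sample(c("A", "C", "G", "T"), 1), after = pos)
      }
    }
  }
  paste(v, collapse = "")
}

#' Generate a synthetic genome with planted TE families
#'
#' An i.i.d. background sequence receives, per family, a random consensus and
#' `copy_number` mutated copies (substitutions and indels at the stated
#' rates, random strand) placed uniformly at non-overlapping positions by
#' rejection sampling. Optional `single_copy` sequences (e.g. transcripts)
#' are each embedded once. The returned truth ledger records every placement
#' (0-based half-open coordinates, "+" strand = consensus orientation) and
#' the per-family true genomic fraction; the library holds the clean
#' consensus per family under the 3-field tab header dialect.
#'
#' @param spec A [genome_spec()].
#' @param single_copy Optional named character vector of sequences embedded
#'   once each.
#' @param max_tries Placement retries before giving up.
#' @return A list of class `synthetic_genome`: `sequence`, `ledger` (list
#'   with `genome_length`, `placements` data.frame, `fractions`),
#'   `library` (data.frame as from [read_repeat_library()]).
#' @export
make_genome <- function(spec, single_copy = NULL, max_tries = 2000L) {
  stopifnot(inherits(spec, "genome_spec"))
  with_local_seed(spec$seed, {
    G <- spec$genome_length
    genome <- random_sequence(G, spec$background_gc)
    fam <- spec$families
    consensus <- stats::setNames(
      vapply(seq_len(nrow(fam)), function(i)
        random_sequence(fam$consensus_length[i], 0.5), ""),
      fam$name)
    inserts <- list()
    for (i in seq_len(nrow(fam))) {
      for (cp in seq_len(fam$copy_number[i])) {
        s <- mutate_sequence(consensus[[i]], fam$divergence[i],
                             fam$indel_rate[i])
        strand <- if (stats::runif(1) < 0.5) "+" else "-"
        inserts[[length(inserts) + 1L]] <- list(
          what = fam$name[i], family = fam$family[i],
          superfamily = fam$superfamily[i], kind = "repeat",
          seq = if (strand == "+") s else revcomp_chr(s), strand = strand)
      }
    }
    for (nm in names(single_copy)) {
      inserts[[length(inserts) + 1L]] <- list(
        what = nm, family = NA_character_, superfamily = NA_character_,
        kind = "single_copy", seq = single_copy[[nm]], strand = "+")
    }
    # non-overlapping placement by rejection sampling
    placed <- data.frame(name = character(), family = character(),
                         superfamily = character(), kind = character(),
                         start = integer(), end = integer(),
                         strand = character(), stringsAsFactors = FALSE)
    occupied_start <- integer(); occupied_end <- integer()
    for (ins in inserts) {
      len <- nchar(ins$seq)
      if (len > G) stop("insert longer than genome")
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        st <- sample.int(G - len + 1L, 1L) - 1L  # 0-based
        en <- st + len
        if (!any(st < occupied_end & en > occupied_start)) { ok <- TRUE; break }
      }
      if (!ok) {
        stop("could not place all copies without overlap after ", max_tries,
             " tries; lower the repeat density")
      }
      occupied_start <- c(occupied_start, st)
      occupied_end <- c(occupied_end, en)
      substr(genome, st + 1L, en) <- ins$seq
      placed <- rbind(placed, data.frame(
        name = ins$what, family = ins$family, superfamily = ins$superfamily,
        kind = ins$kind, start = st, end = en, strand = ins$strand,
        stringsAsFactors = FALSE))
    }
    rep_rows <- placed[placed$kind == "repeat", , drop = FALSE]
    fractions <- if (nrow(rep_rows)) {
      agg <- stats::aggregate((rep_rows$end - rep_rows$start),
                              list(family = rep_rows$family,
                                   superfamily = rep_rows$superfamily), sum)
      names(agg)[3] <- "bp"
      agg$fraction <- agg$bp / G
      agg
    } else {
      data.frame(family = character(), superfamily = character(),
                 bp = integer(), fraction = numeric())
    }
    library <- data.frame(
      name = fam$name, superfamily = fam$superfamily, family = fam$family,
      te_class = classify_superfamily(fam$superfamily),
      sequence = unname(consensus), stringsAsFactors = FALSE)
    structure(list(sequence = genome,
                   ledger = list(genome_length = G, placements = placed,
                                 fractions = fractions,
                                 background_fraction = 1 - sum(
                                   (placed$end - placed$start)) / G),
                   library = library),
              class = "synthetic_genome")
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("synthetic_genome:", x$ledger$genome_length, "bp,",
      nrow(x$ledger$placements), "planted inserts\n")
  invisible(x)
}

#' Simulate paired-end reads from a genome
#'
#' `round(coverage * genome_length / (2 * read_len))` fragments are drawn
#' uniformly; insert sizes are Normal(insert_mean, insert_sd) truncated to
#' \[read_len, genome\]. R1 is the forward fragment start, R2 the
#' reverse-complemented fragment end. Substitution errors are uniform at
#' `error_rate`; qualities are constant Q35. The origin ledger records the
#' true source interval of every read.
#'
#' @param genome A `synthetic_genome` or a genome string.
#' @param coverage Target fold-coverage.
#' @param read_len Read length in bp.
#' @param insert_mean,insert_sd Fragment insert size distribution (bp);
#'   `insert_mean` must exceed `read_len`.
#' @param error_rate Per-base substitution error rate.
#' @param seed Integer seed.
#' @return A [read_set()] with attribute `origin` (data.frame of 0-based
#'   half-open source intervals per pair).
#' @export
simulate_reads <- function(genome, coverage, read_len = 100L,
                           insert_mean = 400L, insert_sd = 40L,
                           error_rate = 0.005, seed = 1L) {
  gseq <- if (inherits(genome, "synthetic_genome")) genome$sequence else genome
  G <- nchar(gseq)
  stopifnot(insert_mean > read_len)
  if (insert_mean > G) stop("insert size exceeds genome length")
  n_pairs <- round(coverage * G / (2 * read_len))
  if (n_pairs < 1L) stop("coverage too low for a single pair")
  with_local_seed(seed, {
    ins <- pmax(read_len, pmin(G, round(stats::rnorm(n_pairs, insert_mean,
                                                     insert_sd))))
    start <- vapply(ins, function(i) sample.int(G - i + 1L, 1L) - 1L, 0L)
    r1 <- substring(gseq, start + 1L, start + read_len)
    r2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(
      substring(gseq, start + ins - read_len + 1L, start + ins))))
    if (error_rate > 0) {
      r1 <- add_errors(r1, error_rate)
      r2 <- add_errors(r2, error_rate)
    }
    q <- strrep(rawToChar(as.raw(33L + 35L)), read_len)
    ids <- sprintf("sim%06d", seq_len(n_pairs))
    origin <- data.frame(pair = ids, fragment_start = start,
                         fragment_end = start + ins,
                         stringsAsFactors = FALSE)
    rs <- read_set(id1 = paste0(ids, "/1"), seq1 = r1, qual1 = q,
                   id2 = paste0(ids, "/2"), seq2 = r2, qual2 = q,
                   provenance = list(seed = seed, coverage = coverage,
                                     read_len = read_len))
    structure(rs, origin = origin)
  })
}

add_errors <- function(reads, rate) {
  vapply(reads, function(s) {
    n <- nchar(s)
    k <- stats::rbinom(1, n, rate)
    if (k == 0) return(s)
    pos <- sample.int(n, k)
    v <- strsplit(s, "")[[1]]
    v[pos] <- vapply(v[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    paste(v, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Generate a random transcript set
#'
#' Independent random sequences standing in for a reference transcriptome;
#' embed them in a genome with `make_genome(spec, single_copy = ...)` so
#' that their true coverage is known.
#'
#' @param count Number of transcripts (>= 1).
#' @param len_range Length bounds in bp (uniform).
#' @param seed Integer seed.
#' @return Named character vector of transcript sequences.
#' @export
make_transcripts <- function(count, len_range = c(500L, 1500L), seed = 1L) {
  stopifnot(count >= 1)
  with_local_seed(seed, {
    lens <- sample(len_range[1]:len_range[2], count, replace = TRUE)
    stats::setNames(vapply(lens, random_sequence, "", gc = 0.5),
                    sprintf("tx%04d", seq_len(count)))
  })
}

#' Simulate a pure-birth tree with a Brownian trait
#'
#' A Yule tree on `n_tips` and a trait evolved by recursive Brownian motion:
#' child value = parent value + Normal(0, sigma2 * branch length).
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate of the pure-birth process.
#' @param bm_sigma2 Brownian rate parameter.
#' @param seed Integer seed.
#' @param root_value Trait value at the root.
#' @return A list: `tree` (ape `phylo`), `trait` (named tip vector),
#'   `sigma2`.
#' @export
simulate_tree_and_traits <- function(n_tips, birth_rate = 1, bm_sigma2 = 1,
                                     seed = 1L, root_value = 0) {
  stopifnot(n_tips >= 2)
  with_local_seed(seed, {
    tree <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
    trait <- bm_on_tree(tree, bm_sigma2, root_value)
    list(tree = tree, trait = trait, sigma2 = bm_sigma2)
  })
}

# Recursive BM along edges; uses the current RNG state.
bm_on_tree <- function(tree, sigma2, root_value = 0) {
  n <- length(tree$tip.label)
  val <- rep(NA_real_, n + tree$Nnode)
  val[n + 1L] <- root_value
  pre <- stats::reorder(tree, "cladewise")
  for (e in seq_len(nrow(pre$edge))) {
    par <- pre$edge[e, 1]; ch <- pre$edge[e, 2]
    val[ch] <- val[par] + stats::rnorm(1, 0, sqrt(sigma2 * pre$edge.length[e]))
  }
  stats::setNames(val[seq_len(n)], tree$tip.label)
}
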