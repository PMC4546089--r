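#' Read a FASTQ file (optionally paired)
#'
#' Reads Phred+33 FASTQ, gzip-transparent. With `paired_with`, the two files
#' are read in parallel and returned as synchronized mate pairs; a length
#' mismatch between the files is a pairing error.
#'
#' @param path Path to the (R1) FASTQ file, plain or gzipped.
#' @param paired_with Optional path to the R2 FASTQ file.
#' @return With one file, a data.frame with columns `id`, `seq`, `qual`
#'   (quality as a Phred+33 character string). With two files, a
#'   [read_set()] of mate pairs.
#' @export
read_fastq <- function(path, paired_with = NULL) {
  r1 <- read_fastq_one(path)
  if (is.null(paired_with)) return(r1)
  r2 <- read_fastq_one(paired_with)
  if (nrow(r1) != nrow(r2)) {
    stop("mate pairing error: ", basename(path), " has ", nrow(r1),
         " records but ", basename(paired_with), " has ", nrow(r2),
         " (desynchronized after pair ", min(nrow(r1), nrow(r2)), ")")
  }
  read_set(id1 = r1$id, seq1 = r1$seq, qual1 = r1$qual,
           id2 = r2$id, seq2 = r2$seq, qual2 = r2$qual,
           provenance = list(files = c(path, paired_with)))
}

read_fastq_one <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) {
    return(data.frame(id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  }
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) stop("malformed FASTQ in ", basename(path), ": ",
                             conditionMessage(e)))
  qual <- as.character(S4Vectors::mcols(x)$qualities)
  seqs <- toupper(as.character(x))
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad)) {
    stop("malformed FASTQ record ", bad[1], " in ", basename(path),
         ": sequence and quality lengths differ")
  }
  ids <- sub("\\s.*$", "", names(x))
  if (any(!nzchar(ids))) stop("empty read identifier in ", basename(path))
  data.frame(id = ids, seq = seqs, qual = qual, stringsAsFactors = FALSE)
}

#' Construct a paired-read set
#'
#' The unit of sampling and clustering: both mates of a pair are present or
#' the pair is absent. Stored as a data.frame with one row per pair.
#'
#' @param id1,seq1,qual1 Identifier, sequence and Phred+33 quality string of
#'   the first mate (`qual` may be `NA` for FASTA-derived reads).
#' @param id2,seq2,qual2 Same for the second mate.
#' @param provenance Optional list recording source files, seed and policy.
#' @return An object of class `read_set`.
#' @export
read_set <- function(id1, seq1, qual1 = NA_character_,
                     id2, seq2, qual2 = NA_character_,
                     provenance = list()) {
  df <- data.frame(id1 = id1, seq1 = seq1, qual1 = qual1,
                   id2 = id2, seq2 = seq2, qual2 = qual2,
                   stringsAsFactors = FALSE)
  ids <- c(df$id1, df$id2)
  if (anyDuplicated(ids)) {
    stop("duplicate read identifiers in read set: ",
         paste(utils::head(ids[duplicated(ids)], 3), collapse = ", "))
  }
  structure(df, provenance = provenance,
            class = c("read_set", "data.frame"))
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set with", nrow(x), "pairs\n")
  invisible(x)
}

#' Decode a Phred+33 quality string to integer scores
#' @param qual Character vector of quality strings.
#' @return A list of integer vectors.
#' @export
phred_scores <- function(qual) {
  lapply(qual, function(q) {
    if (is.na(q)) return(integer())
    utf8ToInt(q) - 33L
  })
}

#' Write reads to FASTQ (or interleaved FASTQ)
#'
#' @param x A data.frame from [read_fastq()] or a [read_set()].
#' @param path Output path; a `read_set` is written interleaved.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path) {
  if (inherits(x, "read_set")) {
    n <- nrow(x)
    idx <- rep(seq_len(n), each = 2L)
    ids <- as.vector(rbind(x$id1, x$id2))
    seqs <- as.vector(rbind(x$seq1, x$seq2))
    quals <- as.vector(rbind(x$qual1, x$qual2))
  } else {
    ids <- x$id; seqs <- x$seq; quals <- x$qual
  }
  quals[is.na(quals)] <- vapply(nchar(seqs[is.na(quals)]),
                                function(n) strrep("I", n), "")
  s <- Biostrings::DNAStringSet(seqs)
  names(s) <- ids
  Biostrings::writeXStringSet(s, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals))
  invisible(path)
}

#' Read / write FASTA
#' @param path File path (gzip-transparent on read).
#' @return Named character vector of sequences (upper-case).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- names(x)
  out
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  s <- Biostrings::DNAStringSet(seqs)
  names(s) <- names(seqs)
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' Superfamily-to-class classification table
#'
#' The shipped table maps repeat superfamily names to coarse classes
#' ("Class I LTR", "Class I non-LTR", "Class II"); superfamilies absent from
#' the table map to "unknown". The table is a plain TSV under `extdata` and
#' can be replaced by the user.
#'
#' @param path Optional path to an alternative two-column TSV
#'   (superfamily, te_class) with a header line.
#' @return A data.frame with columns `superfamily`, `te_class`.
#' @export
te_classification <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "te_superfamily_classes.tsv",
                        package = "repeatscape")
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

classify_superfamily <- function(superfamily, table = te_classification()) {
  cls <- table$te_class[match(superfamily, table$superfamily)]
  cls[is.na(cls)] <- "unknown"
  cls
}

#' Read a repeat consensus library
#'
#' FASTA with tab-separated 3-field headers `>name<TAB>superfamily<TAB>family`
#' (RepBase-like dialect). A bare `>name` header is accepted permissively and
#' assigns superfamily and family "unknown". Each entry receives a `te_class`
#' from the classification table.
#'
#' @param path FASTA file path.
#' @param class_table Classification table, see [te_classification()].
#' @return A data.frame with columns `name`, `superfamily`, `family`,
#'   `te_class`, `sequence`.
#' @export
read_repeat_library <- function(path, class_table = te_classification()) {
  seqs <- read_fasta(path)
  fields <- strsplit(names(seqs), "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(!nf %in% c(1L, 3L))) {
    bad <- which(!nf %in% c(1L, 3L))[1]
    stop("repeat library header must have 1 or 3 tab-separated fields; ",
         "entry ", bad, " has ", nf[bad])
  }
  name <- vapply(fields, `[`, "", 1L)
  superfamily <- ifelse(nf == 3L, vapply(fields, `[`, "", 2L), "unknown")
  family <- ifelse(nf == 3L, vapply(fields, `[`, "", 3L), "unknown")
  if (anyDuplicated(name)) {
    stop("duplicate repeat library entry name: ",
         name[duplicated(name)][1])
  }
  data.frame(name = name, superfamily = superfamily, family = family,
             te_class = classify_superfamily(superfamily, class_table),
             sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Read / write Newick trees
#'
#' Thin wrappers over ape's Newick parser adding the validation the pipeline
#' relies on: unique tip labels and non-negative branch lengths. Round-trip
#' preserves topology, labels and branch lengths to 10 significant digits.
#'
#' @param x A file path or a Newick string (detected by the presence of
#'   parentheses and a terminal semicolon).
#' @return An ape `phylo` object.
#' @export
read_newick <- function(x) {
  tr <- if (length(x) == 1L && grepl("\\(", x) && grepl(";", x)) {
    ape::read.tree(text = x)
  } else {
    ape::read.tree(x)
  }
  if (is.null(tr)) stop("could not parse Newick input")
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate tip label: ", tr$tip.label[duplicated(tr$tip.label)][1])
  }
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0)) {
    stop("negative branch length in tree")
  }
  tr
}

#' @rdname read_newick
#' @param tree An ape `phylo` object.
#' @param path Optional output file; when `NULL` the Newick text is returned.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree, digits = 10)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Read a tip-mapped trait table
#'
#' TSV with a header line; first column is the tip label, remaining columns
#' are numeric traits.
#'
#' @param path TSV file path.
#' @return A data.frame with rownames set to tip labels.
#' @export
read_trait_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("trait table needs a tip column plus >= 1 trait")
  rownames(df) <- df[[1L]]
  df[-1L]
}

#' Extract one trait aligned to a tree's tips
#' @param traits A trait data.frame from [read_trait_table()] or a named
#'   numeric vector.
#' @param tree An ape `phylo` object.
#' @param name Trait column name (ignored for vectors).
#' @return Named numeric vector ordered as `tree$tip.label`.
#' @export
trait_for_tree <- function(traits, tree, name = NULL) {
  v <- if (is.data.frame(traits)) {
    stats::setNames(traits[[name]], rownames(traits))
  } else traits
  miss <- setdiff(tree$tip.label, names(v))
  if (length(miss)) {
    stop("missing trait values for tips: ", paste(miss, collapse = ", "),
         " (prune the tree first)")
  }
  v[tree$tip.label]
}
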