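#' End-to-end repeat discovery pipeline
#'
#' Wires the stages together: quality filter -> optional contaminant screen
#' -> replicated sample/cluster/annotate -> composition table, with RAD model
#' selection and diversity statistics on the resulting family abundances.
#' All randomness derives from one root seed via fixed per-replicate
#' offsets, so a run is reproducible end to end; the returned manifest
#' records every seed and threshold used.
#'
#' @param reads A [read_set()] (e.g. from [read_fastq()] with two files).
#' @param library Repeat library ([read_repeat_library()] result).
#' @param sample_k Pairs sampled per replicate.
#' @param replicates Number of replicates.
#' @param seed Root seed.
#' @param policy A [filter_policy()].
#' @param contaminants Optional contaminant sequences (or FASTA path).
#' @param cluster_args,annotate_args Threshold overrides, see
#'   [replicate_composition()].
#' @param rad_scale Scale from genome fraction to pseudo-counts for the RAD
#'   fits.
#' @param out_dir Optional directory; when given, the composition table
#'   (TSV), RAD table (TSV) and manifest (JSON) are written there.
#' @return A list of class `repeatscape_run`: `composition`,
#'   `superfamily_totals`, `rad`, `diversity`, `rejections`, `manifest`.
#' @export
run_pipeline <- function(reads, library, sample_k, replicates = 3L,
                         seed = 1L, policy = filter_policy(),
                         contaminants = NULL,
                         cluster_args = list(), annotate_args = list(),
                         rad_scale = 1e6, out_dir = NULL) {
  stopifnot(inherits(reads, "read_set"), nrow(library) >= 1L,
            replicates >= 1L)
  filtered <- filter_reads(reads, policy)
  pool <- filtered$kept
  if (!is.null(contaminants)) {
    pool <- screen_contaminants(pool, contaminants)
  }
  if (sample_k > nrow(pool)) {
    stop("sample_k (", sample_k, ") exceeds the filtered pool (",
         nrow(pool), " pairs)")
  }
  seeds <- seed + 1000L * seq_len(replicates)
  comp <- replicate_composition(pool, library, sample_k, seeds = seeds,
                                cluster_args = cluster_args,
                                annotate_args = annotate_args)
  fam <- comp[!comp$family %in% c("unannotated", "unclustered") &
                comp$mean > 0, ]
  rad <- if (nrow(fam) >= 4L) {
    select_model(abundance_vector(fam$mean, fam$family, scale = rad_scale))
  } else NULL
  div <- if (nrow(fam) >= 1L)
    diversity_stats(abundance_vector(fam$mean, fam$family)) else NULL
  manifest <- list(
    seed = seed, replicate_seeds = seeds, sample_k = sample_k,
    filter_policy = unclass(policy),
    cluster_args = utils::modifyList(
      list(min_len = 55, min_identity = 90, min_coverage = 0.55,
           merge_links = 2L, n_restarts = 10L), cluster_args),
    annotate_args = utils::modifyList(
      list(min_len = 55, min_identity = 90), annotate_args),
    rad_scale = rad_scale,
    n_input_pairs = nrow(reads), n_filtered_pairs = nrow(pool),
    rejections = as.list(filtered$rejections))
  out <- structure(list(composition = comp,
                        superfamily_totals = composition_totals(comp),
                        rad = rad, diversity = div,
                        rejections = filtered$rejections,
                        manifest = manifest),
                   class = "repeatscape_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(comp, file.path(out_dir, "composition.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(rad)) {
      utils::write.table(rad$table, file.path(out_dir, "radfit.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.repeatscape_run <- function(x, ...) {
  cat("repeatscape run:", x$manifest$n_filtered_pairs, "filtered pairs,",
      length(x$manifest$replicate_seeds), "replicates\n")
  cat("superfamily totals (mean fraction):\n")
  print(utils::head(x$superfamily_totals, 10), row.names = FALSE)
  if (!is.null(x$rad)) cat("best RAD model:", x$rad$best, "\n")
  if (!is.null(x$diversity))
    cat(sprintf("Shannon H = %.3f, E = %.3f\n", x$diversity$H,
                x$diversity$E))
  invisible(x)
}
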