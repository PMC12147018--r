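# Two-step classification: pool first-pass results across grouped samples,
# select species by a read-count cutoff (or a gold-standard set), rebuild a
# dynamic library from only those species' genomes, and classify all reads
# again against it.

#' Pooled species-level read totals from first-pass results
#'
#' For each species-rank taxon T, the total is the number of reads whose
#' label is T or any descendant of T (a read pair counts once). Reads
#' labelled above species level contribute to no total; so do reads whose
#' label has no species ancestor (unranked clades below species).
#'
#' @param results A result data.frame (or list of them, pooled) from
#'   [classify_reads()].
#' @param tree A [taxonomy_tree()].
#' @param genome_taxa Optional vector of genome-bearing taxids; when given,
#'   only species with at least one genome-bearing clade member are kept.
#' @return Named integer vector: species taxid -> pooled read count.
#' @export
species_read_totals <- function(results, tree, genome_taxa = NULL) {
  if (is.list(results) && !is.data.frame(results))
    results <- do.call(rbind, results)
  labels <- results$label[results$classified]
  totals <- setNames(integer(0), character(0))
  if (length(labels)) {
    lab_tb <- table(labels)
    sp <- vapply(as.integer(names(lab_tb)), function(t) {
      if (canonical_rank_position(tree, t) > 1L) NA_integer_
      else species_ancestor(tree, t)
    }, integer(1))
    keep <- !is.na(sp)
    if (any(keep)) {
      agg <- tapply(as.integer(lab_tb)[keep], sp[keep], sum)
      totals <- setNames(as.integer(agg), names(agg))
    }
  }
  if (!is.null(genome_taxa) && length(totals)) {
    genome_taxa <- as.integer(genome_taxa)
    has_genome <- vapply(as.integer(names(totals)), function(t) {
      any(clade_descendants(tree, t) %in% genome_taxa)
    }, logical(1))
    totals <- totals[has_genome]
  }
  totals
}

#' Select species for the dynamic library by read cutoff
#'
#' Keeps every species whose pooled first-pass read total is at least
#' `cutoff_R`, and expands the selection to all genome-bearing taxa in
#' those species' clades (the species and its taxonomic children).
#'
#' @param totals Named integer vector from [species_read_totals()].
#' @param cutoff_R Positive integer read cutoff.
#' @param tree A [taxonomy_tree()].
#' @param lib A [genome_library()].
#' @return An object of class `taxon_selection` with `cutoff_R`,
#'   `selected_species`, `library_taxa` and `totals`.
#' @export
select_taxa <- function(totals, cutoff_R, tree, lib) {
  stopifnot(cutoff_R >= 1)
  selected <- as.integer(names(totals))[totals >= cutoff_R]
  if (length(selected) == 0L)
    stop("no species passed the read cutoff R=", cutoff_R,
         "; consider a lower cutoff")
  .taxon_selection(cutoff_R, selected, tree, lib)
}

.taxon_selection <- function(cutoff_R, selected, tree, lib) {
  gt <- library_taxa(lib)
  keep <- sort(unique(unlist(lapply(selected, function(t) {
    intersect(clade_descendants(tree, t), gt)
  }))))
  structure(list(cutoff_R = cutoff_R,
                 selected_species = sort(selected),
                 library_taxa = keep),
            class = "taxon_selection")
}

#' @export
print.taxon_selection <- function(x, ...) {
  cat(sprintf("taxon_selection (%s): %d species, %d genome taxa\n",
              if (identical(x$cutoff_R, "gold")) "gold set"
              else paste0("R=", x$cutoff_R),
              length(x$selected_species), length(x$library_taxa)))
  invisible(x)
}

#' Gold-standard taxon selection
#'
#' The selection a perfect heuristic would make: the species ancestors of
#' all ground-truth taxa across the sample family, intersected with the
#' species actually represented in the reference library. Independent of
#' read counts.
#'
#' @param truth Vector of true taxids over all reads of the family.
#' @param tree A [taxonomy_tree()].
#' @param lib A [genome_library()].
#' @return A `taxon_selection` with `cutoff_R = "gold"`.
#' @export
gold_set_selection <- function(truth, tree, lib) {
  truth <- unique(as.integer(truth))
  if (length(truth) == 0L) stop("empty ground truth")
  sp <- unique(vapply(truth, function(t) species_ancestor(tree, t),
                      integer(1)))
  sp <- sp[!is.na(sp)]
  gt <- library_taxa(lib)
  in_lib <- vapply(sp, function(t) {
    any(clade_descendants(tree, t) %in% gt)
  }, logical(1))
  sp <- sp[in_lib]
  if (length(sp) == 0L)
    stop("no ground-truth species is represented in the library")
  .taxon_selection("gold", sp, tree, lib)
}

#' Run two-step classification
#'
#' Per sample group: (1) classify every sample against the static database;
#' (2) pool the group's results and select species by the read cutoff (or
#' the gold set); (3) rebuild a dynamic database restricted to the selected
#' taxa; (4) classify all of the group's reads again against it. Step-1
#' labels are unaffected by grouping; only the selection (and hence step 2)
#' pools information across samples.
#'
#' @param samples Named list: sample_id -> reads data.frame.
#' @param static_db The step-1 `lca_db`.
#' @param lib The [genome_library()] the static database was built from.
#' @param tree A [taxonomy_tree()].
#' @param cfg A [classify_config()] applied in both steps.
#' @param cutoff_R Read cutoff (ignored when `gold_truth` is given).
#' @param gold_truth Optional vector of true taxids; switches selection to
#'   gold-set mode.
#' @param groups Optional named character vector sample_id -> group label;
#'   default puts all samples in one group.
#' @return A list with `final` (per-sample step-2 results), `step1`
#'   (per-sample step-1 results), `selections` (per group) and `stats`
#'   (per-group selected species and dynamic record counts).
#' @export
run_two_step <- function(samples, static_db, lib, tree,
                         cfg = classify_config(), cutoff_R = 100L,
                         gold_truth = NULL, groups = NULL) {
  ids <- names(samples)
  if (is.null(groups)) groups <- setNames(rep("all", length(ids)), ids)
  if (!all(ids %in% names(groups)))
    stop("groups must cover every sample")

  step1 <- classify_samples(samples, static_db, tree, cfg)
  final <- vector("list", length(ids)); names(final) <- ids
  selections <- list(); stats <- list()

  for (g in unique(groups[ids])) {
    members <- ids[groups[ids] == g]
    pooled <- do.call(rbind, step1[members])
    sel <- if (!is.null(gold_truth)) {
      gold_set_selection(gold_truth, tree, lib)
    } else {
      totals <- species_read_totals(pooled, tree,
                                    genome_taxa = library_taxa(lib))
      select_taxa(totals, cutoff_R, tree, lib)
    }
    dyn_db <- rebuild_subset(lib, tree, static_db$params, sel$library_taxa)
    for (s in members)
      final[[s]] <- classify_reads(samples[[s]], dyn_db, tree, cfg,
                                   sample_id = s)
    selections[[g]] <- sel
    stats[[g]] <- list(n_selected_species = length(sel$selected_species),
                       n_library_taxa = length(sel$library_taxa),
                       dynamic_records = length(dyn_db$key),
                       static_records = length(static_db$key))
  }
  list(final = final, step1 = step1, selections = selections, stats = stats)
}
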