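# Evaluation against per-read ground truth: TP/VP/FP/FN categories, read
# index and soft index, rank breakdowns, taxon-set precision/recall and
# read-profile distances.

#' Assess one read against its ground truth
#'
#' Categories, with truth at species level:
#' * TP — the true label equals, or is an ancestor of, the classified
#'   label, or the two share the same species-level ancestor (a strain hit
#'   counts for its species).
#' * VP — the true label is a descendant of the classified label and the
#'   classified label is above species level; the rank gap records how many
#'   canonical ranks separate them.
#' * FP — the true label is neither a descendant nor an ancestor of the
#'   classified label.
#' * FN — the read was left unclassified.
#'
#' @param true_label Species-level true taxid.
#' @param classified Classified taxid, or `NA` for unclassified.
#' @param tree A [taxonomy_tree()].
#' @return A list of class `assessment` with `category` and `vp_rank_gap`
#'   (integer 1..8 for VP, otherwise `NA`).
#' @export
assess_read <- function(true_label, classified, tree) {
  .check_node(tree, true_label)
  true_label <- as.integer(true_label)
  if (canonical_rank_position(tree, true_label) > 1L)
    stop("true_label must be at species level (or below)")

  if (is.na(classified))
    return(structure(list(category = "FN", vp_rank_gap = NA_integer_),
                     class = "assessment"))
  .check_node(tree, classified)
  classified <- as.integer(classified)

  true_sp <- species_ancestor(tree, true_label)
  cls_sp <- species_ancestor(tree, classified)
  tp <- identical(true_label, classified) ||
    is_ancestor(tree, true_label, classified) ||
    (!is.na(cls_sp) && !is.na(true_sp) && cls_sp == true_sp)
  if (tp)
    return(structure(list(category = "TP", vp_rank_gap = NA_integer_),
                     class = "assessment"))

  above_species <- canonical_rank_position(tree, classified) > 1L
  if (above_species && is_ancestor(tree, classified, true_label)) {
    gap <- rank_distance(tree, classified, true_label)
    return(structure(list(category = "VP", vp_rank_gap = as.integer(gap)),
                     class = "assessment"))
  }
  structure(list(category = "FP", vp_rank_gap = NA_integer_),
            class = "assessment")
}

#' Read index of an assessment
#'
#' TP reads weigh 0, VP reads their rank gap (1..8), FP reads 9, and
#' unclassified (FN) reads 9. The number of ranks in the taxonomic tree is
#' 8, which is why FPs weigh 9.
#'
#' @param a An `assessment` from [assess_read()].
#' @return Integer in 0..9.
#' @export
read_index <- function(a) {
  switch(a$category,
         TP = 0L,
         VP = a$vp_rank_gap,
         FP = 9L,
         FN = 9L)
}

#' Soft read index (s-index) of an assessment
#'
#' Identical to [read_index()] except that unclassified (FN) reads weigh 0,
#' so the soft index measures the quality of the labels that were assigned
#' without penalizing abstention.
#'
#' @param a An `assessment` from [assess_read()].
#' @return Integer in 0..9.
#' @export
soft_read_index <- function(a) {
  if (a$category == "FN") 0L else read_index(a)
}

#' Sample index: mean read index over all reads of a sample
#'
#' @param assessments Nonempty list of `assessment` objects.
#' @param soft Use the soft index (FN -> 0) instead of the hard index.
#' @return Mean index, a value in \[0, 9\].
#' @export
sample_index <- function(assessments, soft = FALSE) {
  if (length(assessments) == 0L) stop("no assessments to average")
  f <- if (soft) soft_read_index else read_index
  mean(vapply(assessments, f, integer(1)))
}

#' Assess a result table against a truth map
#'
#' @param results A result data.frame from [classify_reads()].
#' @param truth Named vector: read_id -> true species taxid.
#' @param tree A [taxonomy_tree()].
#' @return A list of `assessment` objects, one per result row.
#' @export
assess_results <- function(results, truth, tree) {
  tl <- truth[results$read_id]
  if (anyNA(tl)) stop("truth is missing for some read ids")
  lapply(seq_len(nrow(results)), function(i) {
    assess_read(as.integer(tl[i]),
                if (results$classified[i]) results$label[i] else NA_integer_,
                tree)
  })
}

#' Rank breakdown of classifications
#'
#' Fractions of total reads whose label sits at species level (or below),
#' genus, family, above family (up to and including the root), or that are
#' unclassified.
#'
#' @param results A result data.frame from [classify_reads()].
#' @param tree A [taxonomy_tree()].
#' @return Named numeric vector over
#'   `c("species", "genus", "family", "above_family", "unclassified")`,
#'   summing to 1.
#' @export
rank_breakdown <- function(results, tree) {
  n <- nrow(results)
  buckets <- c(species = 0L, genus = 0L, family = 0L,
               above_family = 0L, unclassified = 0L)
  for (i in seq_len(n)) {
    if (!results$classified[i]) {
      buckets["unclassified"] <- buckets["unclassified"] + 1L
    } else {
      pos <- canonical_rank_position(tree, results$label[i])
      b <- if (pos <= 1L) "species"
           else if (pos == 2L) "genus"
           else if (pos == 3L) "family"
           else "above_family"
      buckets[b] <- buckets[b] + 1L
    }
  }
  if (n == 0L) return(buckets + 0)
  buckets / n
}

#' Species-level read counts from a result table
#'
#' Clade-summed to species: a read labelled at a strain (or any node below
#' species) counts towards its species.
#'
#' @param results A result data.frame from [classify_reads()].
#' @param tree A [taxonomy_tree()].
#' @return Named integer vector: species taxid -> read count.
#' @export
species_read_counts <- function(results, tree) {
  species_read_totals(results, tree)
}

#' Taxon-set precision and recall at a detection threshold
#'
#' A species is "detected" when at least `detection_threshold` reads are
#' assigned to it (clade-summed) in the final result. Precision is the
#' fraction of detected species that are truly present; recall the fraction
#' of truly present species detected. Precision is 1 when nothing is
#' detected; an empty truth set is an error.
#'
#' @param counts Named integer vector: species taxid -> reads (see
#'   [species_read_counts()]).
#' @param truth_species Vector of truly present species taxids.
#' @param detection_threshold Minimum reads for detection (default 10).
#' @return A list with `precision`, `recall`, and the `detected` set.
#' @export
taxon_set_metrics <- function(counts, truth_species,
                              detection_threshold = 10L) {
  truth_species <- unique(as.integer(truth_species))
  if (length(truth_species) == 0L) stop("empty truth species set")
  detected <- as.integer(names(counts))[counts >= detection_threshold]
  tp <- length(intersect(detected, truth_species))
  precision <- if (length(detected) == 0L) 1 else tp / length(detected)
  recall <- tp / length(truth_species)
  list(precision = precision, recall = recall, detected = sort(detected))
}

#' Read-profile vector from a result table
#'
#' @param results A result data.frame from [classify_reads()].
#' @param tree A [taxonomy_tree()].
#' @return Named numeric vector: species taxid -> fraction of total reads.
#' @export
profile_vector <- function(results, tree) {
  counts <- species_read_counts(results, tree)
  n <- nrow(results)
  if (n == 0L) return(setNames(numeric(0), character(0)))
  counts / n
}

#' Distance between two read-count profiles
#'
#' Profiles are fraction-of-reads vectors keyed by taxid; the union of keys
#' is used with missing entries as 0. `L1` is the Manhattan distance, `LSE`
#' the Euclidean distance; the `log10` variants apply `log10` after
#' flooring zeros at `zero_floor`.
#'
#' @param x,t Named numeric profile vectors.
#' @param metric One of `"L1"`, `"LSE"`, `"L1log10"`, `"LSElog10"`.
#' @param zero_floor Floor applied to zero entries before `log10`.
#' @return A nonnegative distance.
#' @export
profile_distance <- function(x, t, metric = c("L1", "LSE", "L1log10",
                                              "LSElog10"),
                             zero_floor = 1e-10) {
  metric <- match.arg(metric)
  keys <- union(names(x), names(t))
  xv <- ifelse(keys %in% names(x), x[keys], 0)
  tv <- ifelse(keys %in% names(t), t[keys], 0)
  if (metric %in% c("L1log10", "LSElog10")) {
    xv <- log10(pmax(xv, zero_floor))
    tv <- log10(pmax(tv, zero_floor))
  }
  d <- xv - tv
  if (metric %in% c("L1", "L1log10")) sum(abs(d)) else sqrt(sum(d^2))
}

#' Per-sample evaluation summary
#'
#' @param results A result data.frame from [classify_reads()].
#' @param truth Named vector: read_id -> true species taxid.
#' @param tree A [taxonomy_tree()].
#' @param detection_threshold Reads required for species detection.
#' @return A list with `sample_index`, `sample_s_index`, category counts,
#'   `rank_breakdown`, `taxon_precision` and `taxon_recall`.
#' @export
evaluate_sample <- function(results, truth, tree, detection_threshold = 10L) {
  a <- assess_results(results, truth, tree)
  cats <- vapply(a, function(x) x$category, character(1))
  ts <- taxon_set_metrics(species_read_counts(results, tree),
                          unique(as.integer(truth[results$read_id])),
                          detection_threshold)
  list(sample_index = sample_index(a, soft = FALSE),
       sample_s_index = sample_index(a, soft = TRUE),
       categories = table(factor(cats, levels = c("TP", "VP", "FP", "FN"))),
       rank_breakdown = rank_breakdown(results, tree),
       taxon_precision = ts$precision,
       taxon_recall = ts$recall)
}
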