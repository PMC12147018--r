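# Read classification: per-window minimizer lookups aggregated into taxon
# hit counts, majority-vote path scoring, and confidence-threshold
# promotion towards the root.

#' Classification configuration
#'
#' @param confidence_threshold Fraction in \[0,1\]: the minimum fraction of
#'   a read's queried windows that must fall inside the clade of the
#'   assigned label. A candidate below the threshold is promoted towards
#'   the root until it passes, or the read is left unclassified. 0.15 is a
#'   commonly used operating point.
#' @return An object of class `classify_config`.
#' @export
classify_config <- function(confidence_threshold = 0.15) {
  stopifnot(is.numeric(confidence_threshold),
            length(confidence_threshold) == 1L,
            confidence_threshold >= 0, confidence_threshold <= 1)
  structure(list(confidence_threshold = confidence_threshold),
            class = "classify_config")
}

# hit-run token conventions: taxid > 0 hit, 0 no-hit, -1 mate separator
.MATE_SEP <- -1L

#' Collect per-window database hits for a read
#'
#' Every k-window of every unambiguous segment of each mate is looked up by
#' its masked minimizer key. Hits contribute the record's LCA taxon, misses
#' a no-hit marker; mates are separated by a divider run. Windows skipped
#' for ambiguity are not queried and not counted.
#'
#' @param read A list with `read_id`, `mate1` and optionally `mate2`.
#' @param db An `lca_db`.
#' @return A list with `hit_runs` (data.frame `token`,`count`; the mate
#'   separator has count `NA`), `counts` (named integer, window hits per
#'   taxid), `total_queried` and `lengths` (bp per mate).
#' @export
collect_hits <- function(read, db) {
  mates <- list(read$mate1)
  if (!is.null(read$mate2) && !is.na(read$mate2)) mates <- c(mates, read$mate2)

  tokens <- integer(0)
  total <- 0L
  for (i in seq_along(mates)) {
    if (i > 1L) tokens <- c(tokens, .MATE_SEP)
    mk <- minimizers_of(mates[[i]], db$params)
    tok <- db_lookup(db, mk$key)
    tok[is.na(tok)] <- 0L
    tokens <- c(tokens, tok)
    total <- total + nrow(mk)
  }

  runs <- if (length(tokens)) {
    r <- rle(tokens)
    data.frame(token = r$values, count = r$lengths)
  } else data.frame(token = integer(0), count = integer(0))
  if (nrow(runs)) runs$count[runs$token == .MATE_SEP] <- NA_integer_

  hit <- tokens[tokens > 0L]
  counts <- if (length(hit)) {
    tb <- table(hit)
    setNames(as.integer(tb), names(tb))
  } else setNames(integer(0), character(0))

  list(hit_runs = runs, counts = counts, total_queried = total,
       lengths = vapply(mates, nchar, integer(1)))
}

#' Resolve a read's label from taxon hit counts
#'
#' Majority vote over root-to-leaf paths: each hit taxon scores the sum of
#' hit counts along its root path, and the top-scoring hit taxon becomes
#' the candidate label (ties resolve to the LCA of the tied taxa). The
#' candidate's confidence is the fraction of queried windows whose hit
#' falls inside its clade; while it is below the threshold the candidate is
#' promoted to its parent, and a read still below threshold at the root is
#' left unclassified.
#'
#' @param counts Named integer vector: window hit count per taxid.
#' @param total_queried Total windows looked up for the read.
#' @param tree A [taxonomy_tree()].
#' @param cfg A [classify_config()].
#' @return A list with `label` (taxid or `NA`) and `confidence`.
#' @export
resolve_label <- function(counts, total_queried, tree, cfg) {
  if (length(counts) == 0L)
    return(list(label = NA_integer_, confidence = 0))
  if (total_queried <= 0L)
    stop("internal error: nonempty hit counts with no queried windows")

  taxa <- as.integer(names(counts))
  cnt <- as.numeric(counts)
  path_weight <- vapply(taxa, function(t) {
    sum(cnt[taxa %in% root_path(tree, t)])
  }, numeric(1))
  best <- which(path_weight == max(path_weight))
  cand <- if (length(best) == 1L) taxa[best] else lca_set(tree, taxa[best])

  thr <- cfg$confidence_threshold
  repeat {
    in_clade <- vapply(taxa, function(t) is_ancestor(tree, cand, t),
                       logical(1))
    conf <- sum(cnt[in_clade]) / total_queried
    if (conf >= thr) return(list(label = cand, confidence = conf))
    if (cand == tree$root_id)
      return(list(label = NA_integer_, confidence = 0))
    cand <- .parent_of(tree, cand)
  }
}

#' Classify a single read
#'
#' Composition of [collect_hits()] and [resolve_label()].
#'
#' @param read A list with `read_id`, `mate1`, optionally `mate2` and
#'   `sample_id`.
#' @inheritParams resolve_label
#' @param db An `lca_db`.
#' @return A list of class `read_classification` with fields `sample_id`,
#'   `read_id`, `classified`, `label`, `lengths`, `hit_runs`,
#'   `confidence`, `counts` and `total_queried`.
#' @export
classify_read <- function(read, db, tree, cfg = classify_config()) {
  h <- collect_hits(read, db)
  r <- resolve_label(h$counts, h$total_queried, tree, cfg)
  structure(list(sample_id = read$sample_id %||% NA_character_,
                 read_id = read$read_id,
                 classified = !is.na(r$label),
                 label = r$label,
                 lengths = h$lengths,
                 hit_runs = h$hit_runs,
                 confidence = if (is.na(r$label)) 0 else r$confidence,
                 counts = h$counts,
                 total_queried = h$total_queried),
            class = "read_classification")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify a table of reads
#'
#' @param reads data.frame with columns `read_id`, `mate1` and optionally
#'   `mate2` (`NA` for single-end).
#' @param db An `lca_db`.
#' @param tree A [taxonomy_tree()].
#' @param cfg A [classify_config()].
#' @param sample_id Sample identifier attached to every result row.
#' @return A data.frame with one row per read, in input order: `sample_id`,
#'   `read_id`, `classified`, `label`, `length1`, `length2`, `confidence`
#'   and `hits` (the rendered hit-run string).
#' @export
classify_reads <- function(reads, db, tree, cfg = classify_config(),
                           sample_id = NA_character_) {
  n <- nrow(reads)
  if (n == 0L)
    return(data.frame(sample_id = character(0), read_id = character(0),
                      classified = logical(0), label = integer(0),
                      length1 = integer(0), length2 = integer(0),
                      confidence = numeric(0), hits = character(0),
                      stringsAsFactors = FALSE))
  has_m2 <- "mate2" %in% names(reads)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rd <- list(read_id = reads$read_id[i], mate1 = reads$mate1[i],
               mate2 = if (has_m2) reads$mate2[i] else NULL,
               sample_id = sample_id)
    rc <- classify_read(rd, db, tree, cfg)
    out[[i]] <- data.frame(
      sample_id = sample_id,
      read_id = rc$read_id,
      classified = rc$classified,
      label = if (rc$classified) rc$label else NA_integer_,
      length1 = rc$lengths[1],
      length2 = if (length(rc$lengths) > 1L) rc$lengths[2] else NA_integer_,
      confidence = rc$confidence,
      hits = render_hit_runs(rc$hit_runs),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Classify several samples against one database
#'
#' Per-read results are identical to classifying each sample alone: the
#' pooled/grouped execution of the two-step workflow affects only the
#' dynamic library selection, never individual first-pass labels.
#'
#' @param samples Named list: sample_id -> reads data.frame (see
#'   [classify_reads()]).
#' @inheritParams classify_reads
#' @return Named list of per-sample result data.frames, in input order.
#' @export
classify_samples <- function(samples, db, tree, cfg = classify_config()) {
  ids <- names(samples)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("samples must be a named list of read tables")
  if (anyDuplicated(ids)) stop("duplicate sample_id: ",
                               ids[duplicated(ids)][1])
  out <- lapply(ids, function(s) {
    classify_reads(samples[[s]], db, tree, cfg, sample_id = s)
  })
  names(out) <- ids
  out
}
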