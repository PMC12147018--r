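# Genome libraries and the unhashed minimizer -> LCA database.
#
# Records are held as a sorted hex key vector plus a parallel integer taxid
# vector: binary search / hashing on sorted full keys, never a compact hash
# table, so unrelated minimizers can never collide.

#' Construct a genome library
#'
#' @param sequences data.frame with columns `seqid` and `seq`.
#' @param seq_taxid Named integer vector mapping seqid to taxid.
#' @return An object of class `genome_library`.
#' @export
genome_library <- function(sequences, seq_taxid) {
  stopifnot(is.data.frame(sequences),
            all(c("seqid", "seq") %in% names(sequences)))
  if (anyDuplicated(sequences$seqid))
    stop("duplicate seqid in genome library: ",
         sequences$seqid[duplicated(sequences$seqid)][1])
  missing <- setdiff(sequences$seqid, names(seq_taxid))
  if (length(missing))
    stop("sequence(s) without a taxid assignment: ",
         paste(missing, collapse = ", "))
  seq_taxid <- setNames(as.integer(seq_taxid[sequences$seqid]),
                        sequences$seqid)
  structure(list(sequences = sequences, seq_taxid = seq_taxid),
            class = "genome_library")
}

#' @export
print.genome_library <- function(x, ...) {
  cat(sprintf("genome_library: %d sequences, %d distinct taxa\n",
              nrow(x$sequences), length(unique(x$seq_taxid))))
  invisible(x)
}

#' Taxa with at least one genome in a library
#' @param lib A `genome_library`.
#' @return Sorted integer vector of taxids.
#' @export
library_taxa <- function(lib) sort(unique(unname(lib$seq_taxid)))

#' Load a genome library from FASTA
#'
#' Taxon assignments come from a 2-column TSV (`seqid <tab> taxid`) and/or a
#' Kraken-style `kraken:taxid|NNN` directive embedded in the FASTA header;
#' the header directive takes precedence. A sequence without a resolvable
#' taxid is an error.
#'
#' @param fasta_paths Character vector of FASTA file paths.
#' @param taxid_map_path Optional path to the seqid->taxid TSV.
#' @return A [genome_library()].
#' @export
load_genome_library <- function(fasta_paths, taxid_map_path = NULL) {
  seqs <- character(0); ids <- character(0); directive <- integer(0)
  for (p in fasta_paths) {
    ss <- Biostrings::readDNAStringSet(p)
    hdr <- names(ss)
    tok <- vapply(strsplit(hdr, "[ \t]"), `[`, character(1), 1L)
    m <- regmatches(tok, regexpr("kraken:taxid\\|[0-9]+", tok))
    has_dir <- grepl("kraken:taxid\\|[0-9]+", tok)
    tid <- rep(NA_integer_, length(tok))
    tid[has_dir] <- as.integer(sub("kraken:taxid\\|", "", m))
    sid <- sub("\\|kraken:taxid\\|[0-9]+.*$", "", tok)
    seqs <- c(seqs, as.character(ss))
    ids <- c(ids, sid)
    directive <- c(directive, tid)
  }
  if (anyDuplicated(ids))
    stop("duplicate seqid across FASTA inputs: ", ids[duplicated(ids)][1])

  taxid <- directive
  if (!is.null(taxid_map_path)) {
    map <- read.delim(taxid_map_path, header = FALSE,
                      colClasses = c("character", "integer"))
    idx <- match(ids, map[[1]])
    taxid[is.na(taxid)] <- map[[2]][idx][is.na(taxid)]
  }
  if (anyNA(taxid))
    stop("no taxid for sequence(s): ",
         paste(ids[is.na(taxid)], collapse = ", "))
  genome_library(data.frame(seqid = ids, seq = unname(seqs),
                            stringsAsFactors = FALSE),
                 setNames(taxid, ids))
}

#' Build an unhashed minimizer-LCA database
#'
#' For every distinct masked minimizer key found across the library's
#' genomes, the record value is the lowest common ancestor over the exact
#' set of taxa whose genomes contain that key. A key occurring many times
#' within one genome contributes that genome's taxon once.
#'
#' @param lib A [genome_library()].
#' @param tree A [taxonomy_tree()]; every library taxid must be a node.
#' @param params A [minimizer_params()].
#' @return An object of class `lca_db` with sorted fields `key` (hex) and
#'   `taxid` (LCA per key), plus `taxa_with_genomes`, the `params` used and
#'   the taxonomy fingerprint.
#' @export
build_database <- function(lib, tree, params) {
  stopifnot(inherits(lib, "genome_library"),
            inherits(tree, "taxonomy_tree"),
            inherits(params, "minimizer_params"))
  if (nrow(lib$sequences) == 0L) stop("empty genome library")
  for (t in unique(lib$seq_taxid)) .check_node(tree, t)

  parts <- vector("list", nrow(lib$sequences))
  for (i in seq_len(nrow(lib$sequences))) {
    mk <- minimizers_of(lib$sequences$seq[i], params)
    parts[[i]] <- as.data.table(list(
      key = unique(mk$key),
      taxid = lib$seq_taxid[[lib$sequences$seqid[i]]]))
  }
  dt <- unique(rbindlist(parts))
  setkey(dt, key)

  # fast path: keys confined to a single taxon keep it; shared keys get the
  # LCA over their taxon set
  ntax <- dt[, .(n = length(unique(taxid))), by = key]
  single <- dt[key %in% ntax[ntax$n == 1L]$key]
  shared <- dt[key %in% ntax[ntax$n > 1L]$key]
  rec <- unique(single)
  if (nrow(shared)) {
    merged <- shared[, .(taxid = lca_set(tree, taxid)), by = key]
    rec <- rbindlist(list(rec, merged))
  }
  setkey(rec, key)

  structure(list(params = params,
                 key = rec$key,
                 taxid = as.integer(rec$taxid),
                 taxa_with_genomes = library_taxa(lib),
                 taxonomy_fingerprint = taxonomy_fingerprint(tree)),
            class = "lca_db")
}

#' @export
print.lca_db <- function(x, ...) {
  cat(sprintf("lca_db: %d minimizer records over %d genome taxa (k=%d, ell=%d)\n",
              length(x$key), length(x$taxa_with_genomes),
              x$params$k, x$params$ell))
  invisible(x)
}

#' Rebuild a database restricted to a taxon subset
#'
#' Equivalent to [build_database()] on the sub-library of genomes whose
#' taxid is in `keep_taxa`: LCAs are recomputed from genome content, never
#' copied from the full database, so removing a genome can push a shared
#' minimizer's LCA down the tree.
#'
#' @param lib A [genome_library()] (the full library).
#' @param tree A [taxonomy_tree()].
#' @param params A [minimizer_params()].
#' @param keep_taxa Nonempty vector of taxids to retain.
#' @return An `lca_db`.
#' @export
rebuild_subset <- function(lib, tree, params, keep_taxa) {
  keep_taxa <- unique(as.integer(keep_taxa))
  if (length(keep_taxa) == 0L) stop("keep_taxa must be nonempty")
  sel <- lib$seq_taxid %in% keep_taxa
  if (!any(sel))
    stop("keep_taxa has no overlap with the library's taxa")
  sub <- genome_library(lib$sequences[sel, , drop = FALSE],
                        lib$seq_taxid[sel])
  build_database(sub, tree, params)
}

#' Look up minimizer keys in a database
#'
#' @param db An `lca_db`.
#' @param keys Character vector of hex keys.
#' @return Integer vector of LCA taxids; `NA` where the key is absent.
#' @export
db_lookup <- function(db, keys) {
  db$taxid[match(keys, db$key)]
}

#' Write an LCA database to disk
#'
#' A flat sorted table (`<path>`: `key <tab> taxid`, one record per line,
#' keys in lexicographic = numeric order) plus a JSON sidecar
#' (`<path>.json`) carrying the parameters, genome taxa and taxonomy
#' fingerprint.
#'
#' @param db An `lca_db`.
#' @param path Output path for the record table.
#' @return `path`, invisibly.
#' @export
write_lca_db <- function(db, path) {
  writeLines(paste(db$key, db$taxid, sep = "\t"), path)
  sidecar <- list(format = "dynlca-s2ldb/1",
                  k = db$params$k, ell = db$params$ell,
                  spaces = db$params$spaces,
                  seed_pattern = db$params$seed_pattern,
                  toggle_mask = db$params$toggle_mask,
                  n_records = length(db$key),
                  taxa_with_genomes = db$taxa_with_genomes,
                  taxonomy_fingerprint = db$taxonomy_fingerprint)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an LCA database from disk
#'
#' Refuses to load a database whose recorded taxonomy fingerprint does not
#' match the supplied taxonomy: LCA values are taxonomy-relative.
#'
#' @param path Path written by [write_lca_db()].
#' @param tree The `taxonomy_tree` the database will be used with.
#' @return An `lca_db`.
#' @export
read_lca_db <- function(path, tree) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  fp <- taxonomy_fingerprint(tree)
  if (!identical(sidecar$taxonomy_fingerprint, fp))
    stop("database taxonomy fingerprint mismatch: database was built ",
         "against a different taxonomy")
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  params <- minimizer_params(sidecar$k, sidecar$ell, sidecar$spaces,
                             sidecar$seed_pattern, sidecar$toggle_mask)
  structure(list(params = params,
                 key = vapply(parts, `[`, character(1), 1L),
                 taxid = as.integer(vapply(parts, `[`, character(1), 2L)),
                 taxa_with_genomes = as.integer(sidecar$taxa_with_genomes),
                 taxonomy_fingerprint = sidecar$taxonomy_fingerprint),
            class = "lca_db")
}
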