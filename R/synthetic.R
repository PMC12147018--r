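# Synthetic taxonomies, genome libraries with controlled conserved-region
# sharing, and labelled reads: every pipeline stage is testable without
# downloads. All generation is pure given the spec's seed.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# One uniform draw per base, whatever the rate: the same draw decides both
# whether a base mutates and which substitute it becomes, so communities
# generated at different error rates share read positions and strands.
.mutate_dna <- function(seq, rate) {
  u <- runif(nchar(seq))
  if (rate <= 0) return(seq)
  hit <- which(u < rate)
  if (length(hit) == 0L) return(seq)
  chars <- strsplit(seq, "")[[1]]
  for (i in hit) {
    alt <- setdiff(c("A", "C", "G", "T"), chars[i])
    chars[i] <- alt[1L + floor(3 * u[i] / rate) %% 3L]
  }
  paste(chars, collapse = "")
}

#' Specification of a synthetic community
#'
#' Defines the taxonomy shape, genome structure (private sequence plus
#' conserved blocks shared genus-wide and between sibling pairs), read
#' simulation parameters and the seed making everything reproducible.
#'
#' @param n_genera,species_per_genus,strains_per_species Taxonomy shape;
#'   with `strains_per_species > 0`, genomes attach to strain nodes below
#'   species.
#' @param genome_length Genome length in bp per species.
#' @param conserved_fraction Fraction of each genome shared with siblings
#'   (genus-wide and pairwise blocks); in \[0, 1).
#' @param abundances Optional named vector, species taxid -> fraction
#'   (summing to 1); default uniform over all species with genomes.
#' @param read_length,n_reads,error_rate,paired,insert_size Read simulation:
#'   read length in bp, total reads (pairs when paired), per-base
#'   substitution probability (in \[0, 0.1\]), paired-end mode and insert
#'   size in bp.
#' @param seed Integer seed.
#' @return An object of class `community_spec`.
#' @export
community_spec <- function(n_genera = 3L, species_per_genus = 3L,
                           strains_per_species = 0L, genome_length = 4000L,
                           conserved_fraction = 0.3, abundances = NULL,
                           read_length = 150L, n_reads = 500L,
                           error_rate = 0.005, paired = FALSE,
                           insert_size = 400L, seed = 1L) {
  stopifnot(n_genera >= 1L, species_per_genus >= 1L,
            strains_per_species >= 0L,
            conserved_fraction >= 0, conserved_fraction < 1,
            error_rate >= 0, error_rate <= 0.1,
            read_length >= 1L, n_reads >= 0L)
  if (n_genera > 50L || n_genera * species_per_genus > 500L)
    stop("community too large for the fixed taxid layout")
  if (!is.null(abundances)) {
    if (abs(sum(abundances) - 1) > 1e-9)
      stop("abundances must sum to 1")
  }
  structure(list(n_genera = as.integer(n_genera),
                 species_per_genus = as.integer(species_per_genus),
                 strains_per_species = as.integer(strains_per_species),
                 genome_length = as.integer(genome_length),
                 conserved_fraction = conserved_fraction,
                 abundances = abundances,
                 read_length = as.integer(read_length),
                 n_reads = as.integer(n_reads),
                 error_rate = error_rate,
                 paired = isTRUE(paired),
                 insert_size = as.integer(insert_size),
                 seed = as.integer(seed)),
            class = "community_spec")
}

#' Build the taxonomy of a synthetic community
#'
#' A full 8-rank ladder from the root down to species (root, domain,
#' kingdom, phylum, class, order, family shared by all genera; then
#' genera, species, and optionally strains as below-species "no rank"
#' nodes). Taxid assignment is a fixed function of the shape: genera start
#' at 10, species at 100, strains at 1000.
#'
#' @param spec A [community_spec()].
#' @return A [taxonomy_tree()].
#' @export
make_taxonomy <- function(spec) {
  parent <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 3L, `5` = 4L,
              `6` = 5L, `7` = 6L)
  rank <- c(`1` = "no rank", `2` = "superkingdom", `3` = "kingdom",
            `4` = "phylum", `5` = "class", `6` = "order", `7` = "family")
  name <- c(`1` = "root", `2` = "Domain_1", `3` = "Kingdom_1",
            `4` = "Phylum_1", `5` = "Class_1", `6` = "Order_1",
            `7` = "Family_1")
  for (g in seq_len(spec$n_genera)) {
    gid <- 9L + g
    parent[as.character(gid)] <- 7L
    rank[as.character(gid)] <- "genus"
    name[as.character(gid)] <- sprintf("Genus_%d", g)
    for (s in seq_len(spec$species_per_genus)) {
      sid <- 99L + (g - 1L) * spec$species_per_genus + s
      parent[as.character(sid)] <- gid
      rank[as.character(sid)] <- "species"
      name[as.character(sid)] <- sprintf("Species_%d_%d", g, s)
      for (st in seq_len(spec$strains_per_species)) {
        tid <- 999L + ((sid - 100L) * max(1L, spec$strains_per_species)) + st
        parent[as.character(tid)] <- sid
        rank[as.character(tid)] <- "no rank"
        name[as.character(tid)] <- sprintf("Strain_%d_%d_%d", g, s, st)
      }
    }
  }
  taxonomy_tree(parent, rank, name, root_id = 1L)
}

#' Species taxids of a synthetic taxonomy
#' @param tree A `taxonomy_tree`.
#' @return Integer vector of species-rank taxids.
#' @export
species_nodes <- function(tree) {
  ids <- tax_nodes(tree)
  ids[.norm_rank(tree$rank[as.character(ids)]) == "species"]
}

#' Generate genomes with controlled conserved-region sharing
#'
#' Each species genome concatenates private random sequence with conserved
#' blocks: one block shared genus-wide and pairwise blocks shared with the
#' neighbouring sibling (cyclically when the genus has 3+ species), so
#' shared blocks produce genus-level LCA records and private blocks
#' species-level records. With `strains_per_species > 0` each strain gets a
#' lightly mutated copy of the species genome. The planted block layout is
#' attached as attribute `"layout"` for assertions.
#'
#' @param tree The taxonomy from [make_taxonomy()].
#' @param spec A [community_spec()].
#' @return A [genome_library()] with a `"layout"` attribute.
#' @export
make_genomes <- function(tree, spec) {
  .with_seed(spec$seed * 7L + 1L, {
    min_block <- 66L  # >= k + ell so each block holds at least one window
    L <- spec$genome_length
    C <- round(spec$conserved_fraction * L)
    S <- spec$species_per_genus
    use_pairs <- S >= 2L && C > 0L
    if (C > 0L) {
      pb <- if (use_pairs) max(min_block, C %/% 4L) else 0L
      gb <- C - (if (use_pairs) 2L * pb else 0L)
      if (gb < min_block || (use_pairs && pb < min_block))
        stop("conserved_fraction too small to allocate blocks of >= ",
             min_block, " bp; increase it or the genome length")
    } else { gb <- 0L; pb <- 0L }
    priv_total <- L - gb - (if (use_pairs) 2L * pb else 0L)
    if (priv_total < min_block)
      stop("conserved_fraction too large: no room for private sequence")

    seqs <- character(0); ids <- character(0); taxid <- integer(0)
    layout <- list()
    for (g in seq_len(spec$n_genera)) {
      g_block <- if (gb > 0L) .random_dna(gb) else ""
      pair_blocks <- if (use_pairs)
        vapply(seq_len(S), function(i) .random_dna(pb), character(1))
      else character(0)
      for (s in seq_len(S)) {
        sid <- 99L + (g - 1L) * S + s
        p_prev <- if (use_pairs && (S >= 3L || s == 2L))
          pair_blocks[if (s == 1L) S else s - 1L] else ""
        p_next <- if (use_pairs && (S >= 3L || s == 1L))
          pair_blocks[s] else ""
        used <- gb + nchar(p_prev) + nchar(p_next)
        npriv <- L - used
        a <- npriv %/% 3L; b <- npriv %/% 3L; cpriv <- npriv - a - b
        genome <- paste0(.random_dna(a), g_block, .random_dna(b),
                         p_prev, p_next, .random_dna(cpriv))
        blocks <- data.frame(
          scope = c("private", "genus", "private", "pair_prev",
                    "pair_next", "private"),
          start = cumsum(c(0L, a, gb, b, nchar(p_prev), nchar(p_next))),
          length = c(a, gb, b, nchar(p_prev), nchar(p_next), cpriv))
        if (spec$strains_per_species > 0L) {
          for (st in seq_len(spec$strains_per_species)) {
            tid <- 999L + ((sid - 100L) * spec$strains_per_species) + st
            sqid <- sprintf("g%d", tid)
            seqs <- c(seqs, .mutate_dna(genome, 0.002))
            ids <- c(ids, sqid); taxid <- c(taxid, tid)
            layout[[sqid]] <- blocks
          }
        } else {
          sqid <- sprintf("g%d", sid)
          seqs <- c(seqs, genome); ids <- c(ids, sqid)
          taxid <- c(taxid, sid)
          layout[[sqid]] <- blocks
        }
      }
    }
    lib <- genome_library(data.frame(seqid = ids, seq = seqs,
                                     stringsAsFactors = FALSE),
                          setNames(taxid, ids))
    attr(lib, "layout") <- layout
    lib
  })
}

#' Simulate labelled reads from a community
#'
#' Species read counts are multinomial in the abundances; start positions
#' and strands are uniform; substitutions i.i.d. at `error_rate`. In paired
#' mode the second mate comes from the opposite strand at `insert_size`.
#' The truth map records the species of origin of each read.
#'
#' @param lib A [genome_library()] from [make_genomes()].
#' @param tree The matching taxonomy.
#' @param spec A [community_spec()].
#' @return A list with `reads` (data.frame `read_id`, `mate1`, `mate2`) and
#'   `truth` (named integer vector read_id -> species taxid).
#' @export
simulate_reads <- function(lib, tree, spec) {
  .with_seed(spec$seed * 7L + 2L, {
    gt <- library_taxa(lib)
    species <- Filter(function(s) any(clade_descendants(tree, s) %in% gt),
                      species_nodes(tree))
    ab <- spec$abundances
    if (is.null(ab)) {
      ab <- setNames(rep(1 / length(species), length(species)),
                     as.character(species))
    }
    species <- as.integer(names(ab))
    span <- if (spec$paired) spec$insert_size else spec$read_length
    if (span > spec$genome_length)
      stop("read span exceeds genome length")

    n_per <- as.integer(stats::rmultinom(1, spec$n_reads, prob = ab))
    read_id <- character(spec$n_reads)
    mate1 <- character(spec$n_reads); mate2 <- rep(NA_character_,
                                                   spec$n_reads)
    truth <- integer(spec$n_reads)
    i <- 0L
    for (si in seq_along(species)) {
      sp <- species[si]
      genome_ids <- lib$sequences$seqid[
        lib$seq_taxid %in% intersect(clade_descendants(tree, sp), gt)]
      for (r in seq_len(n_per[si])) {
        i <- i + 1L
        gidx <- if (length(genome_ids) == 1L) genome_ids else
          sample(genome_ids, 1L)
        genome <- lib$sequences$seq[lib$sequences$seqid == gidx]
        glen <- nchar(genome)
        start <- sample.int(glen - span + 1L, 1L)
        frag <- substr(genome, start, start + span - 1L)
        if (runif(1) < 0.5) frag <- reverse_complement(frag)
        m1 <- substr(frag, 1L, spec$read_length)
        m1 <- .mutate_dna(m1, spec$error_rate)
        read_id[i] <- sprintf("r%06d", i)
        mate1[i] <- m1
        if (spec$paired) {
          m2 <- reverse_complement(
            substr(frag, span - spec$read_length + 1L, span))
          mate2[i] <- .mutate_dna(m2, spec$error_rate)
        }
        truth[i] <- sp
      }
    }
    perm <- sample.int(i)
    list(reads = data.frame(read_id = read_id[perm], mate1 = mate1[perm],
                            mate2 = mate2[perm], stringsAsFactors = FALSE),
         truth = setNames(truth[perm], read_id[perm]))
  })
}

#' Deterministic three-genome toy fixture
#'
#' One genus G1 with species S1, S2, S3 whose genomes carry six
#' minimizer-bearing regions A..F (membership: a in S1; b in S1,S2; c,d in
#' S2; e in S1,S3; f in S3), each region exactly one k-window wide and
#' separated by ambiguous spacers so that the full database has exactly six
#' records, two at genus and four at species level. Three reads (all drawn
#' from S1) cover E, B+E, and A respectively; removing S2 pushes minimizer
#' b, and with it read 2, down to species level.
#'
#' @return A list with `tree`, `lib`, `reads`, `truth`, `params`,
#'   `regions`, and `expected` (record counts and per-database labels).
#' @export
fig1_fixture <- function() {
  params <- minimizer_params()
  parent <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 3L, `5` = 4L, `6` = 5L,
              `7` = 6L, `10` = 7L, `101` = 10L, `102` = 10L, `103` = 10L)
  rank <- c(`1` = "no rank", `2` = "superkingdom", `3` = "kingdom",
            `4` = "phylum", `5` = "class", `6` = "order", `7` = "family",
            `10` = "genus", `101` = "species", `102` = "species",
            `103` = "species")
  name <- c(`1` = "root", `2` = "Domain_1", `3` = "Kingdom_1",
            `4` = "Phylum_1", `5` = "Class_1", `6` = "Order_1",
            `7` = "Family_1", `10` = "G1", `101` = "S1", `102` = "S2",
            `103` = "S3")
  tree <- taxonomy_tree(parent, rank, name)

  regions <- .with_seed(1014L, {
    repeat {
      rg <- setNames(lapply(1:6, function(i) .random_dna(params$k)),
                     c("A", "B", "C", "D", "E", "F"))
      keys <- vapply(rg, function(s) minimizers_of(s, params)$key,
                     character(1))
      if (!anyDuplicated(keys)) break
    }
    rg
  })

  glue <- function(...) paste(..., sep = "NN")
  lib <- genome_library(
    data.frame(seqid = c("S1", "S2", "S3"),
               seq = c(glue(regions$A, regions$B, regions$E),
                       glue(regions$B, regions$C, regions$D),
                       glue(regions$E, regions$F)),
               stringsAsFactors = FALSE),
    c(S1 = 101L, S2 = 102L, S3 = 103L))

  reads <- data.frame(
    read_id = c("read1", "read2", "read3"),
    mate1 = c(regions$E, glue(regions$B, regions$E), regions$A),
    mate2 = NA_character_, stringsAsFactors = FALSE)
  truth <- c(read1 = 101L, read2 = 101L, read3 = 101L)

  expected <- list(
    db1_records = 6L, db1_genus_records = 2L, db1_species_records = 4L,
    db1_labels = c(read1 = 10L, read2 = 10L, read3 = 101L),
    db2_records = 4L,
    db2_labels = c(read1 = 10L, read2 = 101L, read3 = 101L),
    genus = 10L, species = c(101L, 102L, 103L))

  list(tree = tree, lib = lib, reads = reads, truth = truth,
       params = params, regions = regions, expected = expected)
}

#' Write a community to disk in standard formats
#'
#' Genomes as FASTA plus a seqid->taxid TSV, the taxonomy as
#' nodes.dmp/names.dmp, reads as FASTQ (two files when paired) and the
#' truth as a read_id->taxid TSV.
#'
#' @param lib A [genome_library()].
#' @param tree A [taxonomy_tree()].
#' @param readset A list as returned by [simulate_reads()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_community <- function(lib, tree, readset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genomes <- Biostrings::DNAStringSet(setNames(lib$sequences$seq,
                                               lib$sequences$seqid))
  Biostrings::writeXStringSet(genomes, file.path(dir, "genomes.fasta"))
  utils::write.table(data.frame(names(lib$seq_taxid), unname(lib$seq_taxid)),
              file.path(dir, "taxid_map.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  write_taxonomy(tree, file.path(dir, "nodes.dmp"),
                 file.path(dir, "names.dmp"))

  .write_fastq <- function(seqs, ids, path) {
    x <- Biostrings::DNAStringSet(setNames(seqs, ids))
    q <- Biostrings::BStringSet(vapply(nchar(seqs), strrep,
                                       character(1), x = "I"))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  }
  reads <- readset$reads
  paired <- "mate2" %in% names(reads) && !all(is.na(reads$mate2))
  if (paired) {
    .write_fastq(reads$mate1, reads$read_id, file.path(dir, "reads_1.fastq"))
    .write_fastq(reads$mate2, reads$read_id, file.path(dir, "reads_2.fastq"))
  } else {
    .write_fastq(reads$mate1, reads$read_id, file.path(dir, "reads.fastq"))
  }
  utils::write.table(data.frame(names(readset$truth), unname(readset$truth)),
              file.path(dir, "truth.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(dir)
}
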