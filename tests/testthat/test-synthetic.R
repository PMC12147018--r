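test_that("synthetic taxonomies have the full ladder and closed-form size", {
  spec <- community_spec(n_genera = 1L, species_per_genus = 3L)
  tree <- make_taxonomy(spec)
  # one genus with three species children, like the toy figure
  expect_setequal(tree$children[["10"]], c(100L, 101L, 102L))
  expect_equal(unname(tree$rank["10"]), "genus")
  # ladder: species is 8 canonical steps below the root
  expect_equal(rank_distance(tree, 1L, 100L), 8L)
  # node count: 7 ladder nodes + genera + species (+ strains)
  count_nodes <- function(s) length(tax_nodes(make_taxonomy(s)))
  expect_equal(count_nodes(spec), 7L + 1L + 3L)
  spec2 <- community_spec(n_genera = 2L, species_per_genus = 2L,
                          strains_per_species = 2L)
  expect_equal(count_nodes(spec2), 7L + 2L + 4L + 8L)
  # determinism
  expect_identical(make_taxonomy(spec), make_taxonomy(spec))
})

test_that("conserved fraction zero yields species-level records only", {
  spec <- community_spec(n_genera = 1L, species_per_genus = 3L,
                         genome_length = 600L, conserved_fraction = 0,
                         seed = 7L)
  tree <- make_taxonomy(spec)
  lib <- make_genomes(tree, spec)
  db <- build_database(lib, tree, minimizer_params())
  pos <- vapply(db$taxid, canonical_rank_position, integer(1), tree = tree)
  expect_true(all(pos == 1L))
})

test_that("planted blocks create the record ranks they promise", {
  for (seed in c(11L, 13L, 17L)) {
    spec <- community_spec(n_genera = 2L, species_per_genus = 3L,
                           genome_length = 1200L, conserved_fraction = 0.35,
                           seed = seed)
    tree <- make_taxonomy(spec)
    lib <- make_genomes(tree, spec)
    layout <- attr(lib, "layout")
    p <- minimizer_params()
    db <- build_database(lib, tree, p)
    for (sqid in lib$sequences$seqid[c(1, 4)]) {
      genome <- lib$sequences$seq[lib$sequences$seqid == sqid]
      blocks <- layout[[sqid]]
      gb <- blocks[blocks$scope == "genus", ]
      gseq <- substr(genome, gb$start + 1L, gb$start + gb$length)
      # the genus-wide block appears verbatim in every sibling genome
      sid <- lib$seq_taxid[[sqid]]
      genus <- unname(tree$parent[as.character(sid)])
      sibs <- lib$sequences$seq[lib$seq_taxid %in%
                                  clade_descendants(tree, genus)]
      expect_true(all(vapply(sibs, grepl, logical(1), pattern = gseq,
                             fixed = TRUE)))
      # and yields at least one genus-level record
      gkeys <- minimizers_of(gseq, p)$key
      granks <- vapply(db_lookup(db, gkeys), canonical_rank_position,
                       integer(1), tree = tree)
      expect_true(any(granks == 2L))
      # interior windows of private blocks yield species-level records;
      # skip the k-1 windows at each end that reach into neighbours
      pr <- blocks[blocks$scope == "private" & blocks$length >= 3L * p$k, ][1, ]
      pseq <- substr(genome, pr$start + p$k, pr$start + pr$length - p$k)
      pkeys <- minimizers_of(pseq, p)$key
      pl <- db_lookup(db, pkeys)
      expect_true(all(pl == sid))
    }
  }
})

test_that("error-free reads are exact genome substrings; generation is pure", {
  spec <- community_spec(n_genera = 1L, species_per_genus = 2L,
                         genome_length = 800L, n_reads = 40L,
                         error_rate = 0, seed = 19L)
  tree <- make_taxonomy(spec)
  lib <- make_genomes(tree, spec)
  rs <- simulate_reads(lib, tree, spec)
  expect_equal(nrow(rs$reads), 40L)
  expect_setequal(names(rs$truth), rs$reads$read_id)
  for (i in seq_len(nrow(rs$reads))) {
    genome <- lib$sequences$seq[lib$seq_taxid ==
                                  rs$truth[[rs$reads$read_id[i]]]]
    m <- rs$reads$mate1[i]
    expect_true(grepl(m, genome, fixed = TRUE) ||
                  grepl(oracle_revcomp(m), genome, fixed = TRUE))
  }
  # identical seeds give identical communities end to end
  lib2 <- make_genomes(tree, spec)
  expect_identical(lib$sequences, lib2$sequences)
  expect_identical(simulate_reads(lib, tree, spec)$reads, rs$reads)
})

test_that("paired reads come from opposite strands at the insert size", {
  spec <- community_spec(n_genera = 1L, species_per_genus = 1L,
                         genome_length = 900L, n_reads = 20L,
                         error_rate = 0, paired = TRUE, insert_size = 300L,
                         read_length = 100L, seed = 23L)
  tree <- make_taxonomy(spec)
  lib <- make_genomes(tree, spec)
  rs <- simulate_reads(lib, tree, spec)
  genome <- lib$sequences$seq[1]
  for (i in seq_len(nrow(rs$reads))) {
    m1 <- rs$reads$mate1[i]; m2 <- rs$reads$mate2[i]
    expect_equal(nchar(m1), 100L)
    expect_equal(nchar(m2), 100L)
    fwd1 <- grepl(m1, genome, fixed = TRUE)
    hit2 <- if (fwd1) oracle_revcomp(m2) else m2
    expect_true(grepl(hit2, genome, fixed = TRUE))
  }
})

test_that("species read proportions follow the multinomial abundances", {
  ab <- c(`100` = 0.6, `101` = 0.3, `102` = 0.1)
  spec <- community_spec(n_genera = 1L, species_per_genus = 3L,
                         genome_length = 500L, n_reads = 20000L,
                         read_length = 60L, error_rate = 0,
                         conserved_fraction = 0,
                         abundances = ab, seed = 41L)
  tree <- make_taxonomy(spec)
  lib <- make_genomes(tree, spec)
  rs <- simulate_reads(lib, tree, spec)
  n <- length(rs$truth)
  for (sp in names(ab)) {
    phat <- mean(rs$truth == as.integer(sp))
    sigma <- sqrt(ab[[sp]] * (1 - ab[[sp]]) / n)
    expect_lt(abs(phat - ab[[sp]]), 3 * sigma + 1e-9)
  }
})

test_that("substitution errors perturb reads at roughly the set rate", {
  spec0 <- community_spec(n_genera = 1L, species_per_genus = 1L,
                          genome_length = 2000L, n_reads = 200L,
                          error_rate = 0, seed = 43L)
  spec1 <- community_spec(n_genera = 1L, species_per_genus = 1L,
                          genome_length = 2000L, n_reads = 200L,
                          error_rate = 0.02, seed = 43L)
  tree <- make_taxonomy(spec0)
  lib <- make_genomes(tree, spec0)
  clean <- simulate_reads(lib, tree, spec0)
  noisy <- simulate_reads(lib, tree, spec1)
  # same seed, same sampled positions: pairwise hamming ~ Binom(n, rate)
  stopifnot(identical(clean$reads$read_id, noisy$reads$read_id))
  mm <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, clean$reads$mate1, noisy$reads$mate1)
  total_bases <- sum(nchar(clean$reads$mate1))
  rate <- sum(mm) / total_bases
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.03)
})

test_that("community export writes readable standard formats", {
  spec <- community_spec(n_genera = 1L, species_per_genus = 2L,
                         genome_length = 1200L, n_reads = 10L,
                         error_rate = 0, seed = 47L)
  tree <- make_taxonomy(spec)
  lib <- make_genomes(tree, spec)
  rs <- simulate_reads(lib, tree, spec)
  dir <- tempfile()
  write_community(lib, tree, rs, dir)
  lib2 <- load_genome_library(file.path(dir, "genomes.fasta"),
                              file.path(dir, "taxid_map.tsv"))
  expect_identical(lib2$sequences$seq, lib$sequences$seq)
  expect_identical(lib2$seq_taxid, lib$seq_taxid)
  tree2 <- load_taxonomy(file.path(dir, "nodes.dmp"),
                         file.path(dir, "names.dmp"))
  expect_identical(tree2$parent[names(tree$parent)], tree$parent)
  fq <- Biostrings::readDNAStringSet(file.path(dir, "reads.fastq"),
                                     format = "fastq")
  expect_identical(unname(as.character(fq)), rs$reads$mate1)
  truth <- read.delim(file.path(dir, "truth.tsv"), header = FALSE)
  expect_identical(setNames(as.integer(truth[[2]]), truth[[1]]), rs$truth)
})
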