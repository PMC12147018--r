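# The S1/G1/S3 topology used in the hand-worked examples comes from the
# toy fixture: counts on S1 and its genus G1 versus sibling S3.

test_that("resolve_label applies majority-vote path scoring and promotion", {
  fx <- fig1_fixture()
  tree <- fx$tree
  # S1's path weight (1+1=2) beats S3's (1): label S1, confidence 1/2
  r <- resolve_label(c(`101` = 1L, `10` = 1L), 2L, tree, classify_config(0))
  expect_equal(r$label, 101L)
  expect_equal(r$confidence, 0.5)
  # a 0.6 threshold promotes to the genus, whose clade holds all hits
  r2 <- resolve_label(c(`101` = 1L, `10` = 1L), 2L, tree,
                      classify_config(0.6))
  expect_equal(r2$label, 10L)
  expect_equal(r2$confidence, 1.0)
  # no hits -> unclassified
  r3 <- resolve_label(setNames(integer(0), character(0)), 10L, tree,
                      classify_config(0))
  expect_true(is.na(r3$label))
  expect_equal(r3$confidence, 0)
  # hits with zero queried windows violate an internal invariant
  expect_error(resolve_label(c(`101` = 1L), 0L, tree, classify_config(0)),
               "internal")
})

test_that("collect_hits aggregates window lookups and round-trips runs", {
  fx <- fig1_fixture()
  db <- build_database(fx$lib, fx$tree, fx$params)
  # read 2 covers regions B and E, both at genus level in database 1
  h <- collect_hits(list(read_id = "read2", mate1 = fx$reads$mate1[2]), db)
  expect_equal(h$counts, c(`10` = 2L))
  expect_equal(h$total_queried, 2L)  # one window per region, N-split
  # a foreign read yields only no-hit runs over every window
  set.seed(107)
  alien <- random_dna_str(100L)
  ha <- collect_hits(list(read_id = "x", mate1 = alien), db)
  expect_length(ha$counts, 0L)
  expect_equal(ha$total_queried, 100L - 35L + 1L)
  expect_true(all(ha$hit_runs$token == 0L))
  expect_equal(sum(ha$hit_runs$count), 66L)
})

test_that("hit runs expand to the per-window token sequence of a naive oracle", {
  set.seed(23)
  fx <- fig1_fixture()
  spec <- community_spec(n_genera = 2L, species_per_genus = 2L,
                         genome_length = 900L, conserved_fraction = 0.3,
                         seed = 23L)
  tree <- make_taxonomy(spec)
  lib <- make_genomes(tree, spec)
  p <- minimizer_params()
  db <- build_database(lib, tree, p)
  for (i in seq_len(30L)) {
    g <- sample(nrow(lib$sequences), 1)
    start <- sample(700L, 1)
    rd <- substr(lib$sequences$seq[g], start, start + 149L)
    h <- collect_hits(list(read_id = "r", mate1 = rd), db)
    # naive: re-derive each window's token independently
    mk <- minimizers_of(rd, p)
    tok <- db_lookup(db, mk$key)
    tok[is.na(tok)] <- 0L
    expanded <- rep(h$hit_runs$token, ifelse(is.na(h$hit_runs$count), 1L,
                                             h$hit_runs$count))
    expanded <- expanded[expanded != -1L]
    expect_identical(expanded, as.integer(tok))
    expect_equal(h$total_queried, nrow(mk))
  }
})

test_that("paired mates share one counts map and are separated in runs", {
  fx <- fig1_fixture()
  db <- build_database(fx$lib, fx$tree, fx$params)
  h <- collect_hits(list(read_id = "p", mate1 = fx$regions$B,
                         mate2 = fx$regions$E), db)
  expect_equal(h$counts, c(`10` = 2L))
  expect_equal(h$total_queried, 2L)
  expect_true(-1L %in% h$hit_runs$token)
  expect_equal(h$lengths, c(35L, 35L))
})

test_that("the toy fixture reads get their expected labels in both databases", {
  fx <- fig1_fixture()
  cfg <- classify_config(0)
  db1 <- build_database(fx$lib, fx$tree, fx$params)
  res1 <- classify_reads(fx$reads, db1, fx$tree, cfg)
  expect_equal(res1$label, unname(fx$expected$db1_labels))
  db2 <- rebuild_subset(fx$lib, fx$tree, fx$params, c(101L, 103L))
  res2 <- classify_reads(fx$reads, db2, fx$tree, cfg)
  expect_equal(res2$label, unname(fx$expected$db2_labels))
  # a read with no library overlap stays unclassified
  set.seed(109)
  alien <- data.frame(read_id = "a", mate1 = random_dna_str(120L),
                      mate2 = NA_character_)
  ra <- classify_reads(alien, db1, fx$tree, cfg)
  expect_false(ra$classified)
  expect_true(is.na(ra$label))
})

test_that("pooled multi-sample classification equals per-sample runs", {
  set.seed(29)
  cc <- confounder_community(29L, n_reads = 60L)
  db <- build_database(cc$lib, cc$tree, minimizer_params())
  cfg <- classify_config(0.15)
  half <- nrow(cc$reads) %/% 2L
  s1 <- cc$reads[seq_len(half), ]
  s2 <- cc$reads[(half + 1L):nrow(cc$reads), ]
  pooled <- classify_samples(list(a = s1, b = s2), db, cc$tree, cfg)
  alone1 <- classify_samples(list(a = s1), db, cc$tree, cfg)
  alone2 <- classify_samples(list(b = s2), db, cc$tree, cfg)
  expect_identical(pooled$a$label, alone1$a$label)
  expect_identical(pooled$b$label, alone2$b$label)
  # empty sample gives a valid empty result
  empty <- classify_samples(list(e = cc$reads[0, ]), db, cc$tree, cfg)
  expect_equal(nrow(empty$e), 0L)
  expect_error(classify_samples(setNames(list(s1, s2), c("a", "a")),
                                db, cc$tree, cfg), "duplicate")
})

test_that("every read is classified or unclassified, and thresholds only promote", {
  cc <- confounder_community(31L, n_reads = 80L)
  db <- build_database(cc$lib, cc$tree, minimizer_params())
  thresholds <- c(0, 0.05, 0.1, 0.15)
  res <- lapply(thresholds, function(th)
    classify_reads(cc$reads, db, cc$tree, classify_config(th)))
  for (r in res)
    expect_equal(sum(r$classified) + sum(!r$classified), nrow(cc$reads))
  # rising threshold: label is promoted (ancestor-or-equal) or dropped
  for (j in seq_len(length(thresholds) - 1L)) {
    lo <- res[[j]]; hi <- res[[j + 1L]]
    for (i in seq_len(nrow(lo))) {
      if (hi$classified[i]) {
        expect_true(lo$classified[i])
        expect_true(is_ancestor(cc$tree, hi$label[i], lo$label[i]))
      }
    }
  }
  # classified reads always meet the applied threshold
  for (j in seq_along(thresholds)) {
    r <- res[[j]]
    expect_true(all(r$confidence[r$classified] >= thresholds[j]))
  }
})

test_that("labels match the exhaustive path-enumeration oracle", {
  set.seed(33)
  spec <- community_spec(n_genera = 2L, species_per_genus = 2L,
                         strains_per_species = 1L)
  tree <- make_taxonomy(spec)  # small tree, all paths enumerable
  ids <- tax_nodes(tree)
  for (i in seq_len(200L)) {
    n_hit <- sample(0:4, 1)
    taxa <- if (n_hit) sample(ids, n_hit) else integer(0)
    counts <- setNames(sample(1:10, n_hit, replace = TRUE),
                       as.character(taxa))
    total <- sum(counts) + sample(0:20, 1)
    if (length(counts) && total == 0L) total <- sum(counts)
    thr <- sample(c(0, 0.05, 0.15, 0.4, 0.9), 1)
    got <- resolve_label(counts, total, tree, classify_config(thr))
    want <- oracle_classify(counts, total, tree, thr)
    expect_identical(got$label, want)
  }
  # threshold 0 reproduces pure path-vote scoring (never unclassified when
  # any hit exists, and equal to the oracle's pre-promotion candidate)
  for (i in seq_len(50L)) {
    taxa <- sample(ids, 3)
    counts <- setNames(sample(1:5, 3, replace = TRUE), as.character(taxa))
    got <- resolve_label(counts, sum(counts) + 5L, tree, classify_config(0))
    expect_false(is.na(got$label))
    expect_identical(got$label,
                     oracle_classify(counts, sum(counts) + 5L, tree, 0))
  }
})

test_that("reads shorter than k in all segments are unclassified with no windows", {
  fx <- fig1_fixture()
  db <- build_database(fx$lib, fx$tree, fx$params)
  short <- data.frame(read_id = "tiny", mate1 = "ACGTACGT",
                      mate2 = NA_character_)
  r <- classify_reads(short, db, fx$tree, classify_config(0))
  expect_false(r$classified)
  expect_equal(r$hits, "0:0")
})
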