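# Independent oracles, kept deliberately naive: string/bit-vector
# arithmetic instead of the package's 64-bit compiled path, and literal
# path enumeration instead of the classifier's scoring loop.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
        collapse = "")
}

# bits of the 2-bit encoding, most significant first; NULL if ambiguous
oracle_bits <- function(s) {
  map <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  codes <- map[strsplit(toupper(s), "")[[1]]]
  if (anyNA(codes)) return(NULL)
  as.integer(rbind(codes %/% 2L, codes %% 2L))
}

oracle_bitstr <- function(bits) paste(bits, collapse = "")

# canonical = numerically smaller of the two strand encodings
oracle_canonical_bits <- function(s) {
  b1 <- oracle_bits(s)
  if (is.null(b1)) return(NULL)
  b2 <- oracle_bits(oracle_revcomp(s))
  if (oracle_bitstr(b1) <= oracle_bitstr(b2)) b1 else b2
}

# hex string -> MSB-first bit vector of length n
oracle_hex_bits <- function(hex, n) {
  per <- lapply(strsplit(hex, "")[[1]], function(d) {
    v <- strtoi(d, 16L)
    c(v %/% 8L %% 2L, v %/% 4L %% 2L, v %/% 2L %% 2L, v %% 2L)
  })
  bits <- unlist(per)
  bits[(length(bits) - n + 1):length(bits)]
}

oracle_bits_hex <- function(bits) {
  bits <- c(rep(0L, 64L - length(bits)), bits)
  paste(vapply(seq(1L, 64L, by = 4L), function(i) {
    sprintf("%x", sum(bits[i + 0:3] * c(8L, 4L, 2L, 1L)))
  }, character(1)), collapse = "")
}

# window-by-window re-derivation of minimizers: for each k-window of each
# unambiguous segment, pick the candidate ell-mer with the smallest
# (masked XOR toggled) bit string, leftmost on ties; emit the masked key.
oracle_minimizers <- function(seq, params) {
  k <- params$k; ell <- params$ell
  seed <- oracle_hex_bits(params$seed_pattern, 2L * ell)
  toggle <- oracle_hex_bits(params$toggle_mask, 2L * ell)
  offs <- integer(0); keys <- character(0)

  m <- gregexpr("[ACGTacgt]+", seq)[[1]]
  if (m[1] == -1L) return(data.frame(offset = offs, key = keys))
  for (si in seq_along(m)) {
    start <- as.integer(m[si]); len <- attr(m, "match.length")[si]
    if (len < k) next
    seg <- substr(seq, start, start + len - 1L)
    cand_masked <- character(len - ell + 1L)
    cand_ord <- character(len - ell + 1L)
    for (p in seq_len(len - ell + 1L)) {
      b <- oracle_canonical_bits(substr(seg, p, p + ell - 1L))
      masked <- b * (1L - seed)
      cand_masked[p] <- oracle_bits_hex(masked)
      cand_ord[p] <- oracle_bitstr(xor(masked == 1L, toggle == 1L) * 1L)
    }
    for (w in seq_len(len - k + 1L)) {
      cands <- w:(w + k - ell)
      best <- cands[order(cand_ord[cands])[1]]  # stable: leftmost tie
      offs <- c(offs, start - 1L + w - 1L)
      keys <- c(keys, cand_masked[best])
    }
  }
  data.frame(offset = offs, key = keys, stringsAsFactors = FALSE)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a random taxonomy: node i's parent drawn uniformly among earlier nodes
random_tree <- function(n, with_ranks = TRUE) {
  parent <- c(`1` = 1L)
  rank <- c(`1` = "no rank")
  pool <- c("no rank", "species", "genus", "family", "order", "class",
            "phylum", "kingdom", "superkingdom")
  for (i in 2:n) {
    parent[as.character(i)] <- sample(seq_len(i - 1L), 1L)
    rank[as.character(i)] <- if (with_ranks) sample(pool, 1L) else "no rank"
  }
  taxonomy_tree(parent, rank)
}

oracle_root_path <- function(tree, t) {
  path <- integer(0)
  cur <- as.integer(t)
  repeat {
    path <- c(path, cur)
    p <- tree$parent[[as.character(cur)]]
    if (p == cur) break
    cur <- p
  }
  path
}

oracle_lca <- function(tree, a, b) {
  pa <- oracle_root_path(tree, a)
  pb <- oracle_root_path(tree, b)
  common <- pa[pa %in% pb]
  common[1]
}

# literal evaluation of the classification rule: every root-to-leaf path
# is scored by the summed hit counts of taxa on it; the deepest hit taxon
# of a maximal path is the candidate (ties -> LCA of tied candidates);
# then the confidence/promotion rule is applied verbatim.
oracle_classify <- function(counts, total, tree, threshold) {
  if (length(counts) == 0L) return(NA_integer_)
  taxa <- as.integer(names(counts))
  cnt <- as.numeric(counts)
  ids <- tax_nodes(tree)
  leaves <- ids[vapply(ids, function(t) {
    kids <- tree$children[[as.character(t)]]
    is.null(kids) || length(kids) == 0L
  }, logical(1))]
  best_w <- -Inf; cands <- integer(0)
  for (L in leaves) {
    path <- oracle_root_path(tree, L)
    on_path <- taxa[taxa %in% path]
    if (length(on_path) == 0L) next
    w <- sum(cnt[taxa %in% path])
    deepest <- on_path[which.min(match(on_path, path))]
    if (w > best_w) { best_w <- w; cands <- deepest }
    else if (w == best_w) cands <- union(cands, deepest)
  }
  cand <- if (length(cands) == 1L) cands else lca_set(tree, cands)
  repeat {
    clade <- clade_descendants(tree, cand)
    conf <- sum(cnt[taxa %in% clade]) / total
    if (conf >= threshold) return(cand)
    if (cand == tree$root_id) return(NA_integer_)
    cand <- tree$parent[[as.character(cand)]]
  }
}

# a random but internally consistent classification result table, for
# format round-trip tests
random_results <- function(tree, n, sample_id = "s") {
  ids <- tax_nodes(tree)
  rows <- lapply(seq_len(n), function(i) {
    classified <- runif(1) < 0.8
    paired <- runif(1) < 0.5
    n_runs <- sample(1:5, 1)
    runs <- data.frame(token = sample(c(0L, ids), n_runs, replace = TRUE),
                       count = sample(1:20, n_runs, replace = TRUE))
    if (paired) {
      sep <- sample(seq_len(n_runs + 1L), 1L)
      runs <- rbind(head(runs, sep - 1L),
                    data.frame(token = -1L, count = NA_integer_),
                    tail(runs, n_runs - sep + 1L))
    }
    data.frame(sample_id = sample_id,
               read_id = sprintf("r%04d", i),
               classified = classified,
               label = if (classified) sample(ids, 1) else NA_integer_,
               length1 = sample(50:250, 1),
               length2 = if (paired) sample(50:250, 1) else NA_integer_,
               confidence = round(runif(1), 3),
               hits = render_hit_runs(runs),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# small community with sibling confounder genomes: reads are drawn only
# from `sampled` species while the library keeps every genome
confounder_community <- function(seed, n_reads = 150L) {
  spec <- community_spec(n_genera = 2L, species_per_genus = 3L,
                         genome_length = 2500L, conserved_fraction = 0.3,
                         n_reads = n_reads, error_rate = 0,
                         read_length = 150L, seed = seed)
  tree <- make_taxonomy(spec)
  lib <- make_genomes(tree, spec)
  sampled <- sort(sample(species_nodes(tree), 3L))
  ab <- setNames(rep(1 / 3, 3L), as.character(sampled))
  spec_r <- community_spec(n_genera = 2L, species_per_genus = 3L,
                           genome_length = 2500L, conserved_fraction = 0.3,
                           n_reads = n_reads, error_rate = 0,
                           read_length = 150L, seed = seed,
                           abundances = ab)
  rs <- simulate_reads(lib, tree, spec_r)
  list(tree = tree, lib = lib, reads = rs$reads, truth = rs$truth,
       sampled = sampled)
}

count_species_tp <- function(results, truth, tree) {
  a <- assess_results(results, truth, tree)
  sum(vapply(a, function(x) x$category == "TP", logical(1)))
}
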