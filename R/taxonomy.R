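# NCBI-dialect taxonomy: parsing, LCA and rank arithmetic.
#
# A taxonomy_tree holds parent/rank/name maps keyed by taxid. The canonical
# rank ladder has 8 ranks (species..domain); NCBI "superkingdom" is treated
# as domain. Non-canonical nodes (strain, subspecies, "no rank") take the
# rank position of their nearest canonical ancestor, so a strain sits at the
# species position and counts as distance 0 from its species.

.CANONICAL_RANKS <- c(species = 1L, genus = 2L, family = 3L, order = 4L,
                      class = 5L, phylum = 6L, kingdom = 7L, domain = 8L)
.ABOVE_DOMAIN_POS <- 9L

#' The canonical rank ladder
#'
#' The 8 canonical rank names from lowest to highest. "superkingdom" in
#' input files is mapped onto "domain".
#'
#' @return Character vector of length 8.
#' @export
rank_ladder <- function() names(.CANONICAL_RANKS)

.norm_rank <- function(rank) ifelse(rank == "superkingdom", "domain", rank)

#' Construct a taxonomy tree
#'
#' @param parent Named integer vector: names are taxids (as strings), values
#'   the parent taxid. The root is its own parent.
#' @param rank Named character vector of rank names per taxid.
#' @param name Named character vector of scientific names per taxid;
#'   missing entries default to the taxid as a string.
#' @param root_id Root taxid (NCBI convention 1).
#' @return An object of class `taxonomy_tree`.
#' @export
taxonomy_tree <- function(parent, rank, name = NULL, root_id = 1L) {
  ids <- as.integer(names(parent))
  parent <- as.integer(parent)
  root_id <- as.integer(root_id)
  if (anyNA(ids) || anyNA(parent)) stop("taxids must be integers")
  if (anyDuplicated(ids)) stop("duplicate taxid in nodes")
  if (!root_id %in% ids) stop("root_id is not a node")
  key <- as.character(ids)
  names(parent) <- key

  missing_parent <- setdiff(parent, ids)
  if (length(missing_parent))
    stop("node(s) reference unknown parent taxid: ",
         paste(missing_parent, collapse = ", "))
  if (parent[as.character(root_id)] != root_id)
    stop("root must be its own parent")

  # acyclicity: every node must reach the root in <= n steps
  n <- length(ids)
  for (t in ids) {
    cur <- t; steps <- 0L
    while (cur != root_id) {
      cur <- parent[[as.character(cur)]]
      steps <- steps + 1L
      if (steps > n) stop("cycle detected in taxonomy at taxid ", t)
    }
  }

  rank <- as.character(rank)[match(key, names(rank))]
  rank[is.na(rank)] <- "no rank"
  names(rank) <- key
  nm <- character(n)
  names(nm) <- key
  if (!is.null(name)) {
    idx <- match(key, names(name))
    nm <- ifelse(is.na(idx), key, as.character(name)[idx])
    names(nm) <- key
  } else nm[] <- key

  children <- split(ids, as.character(parent))
  # drop the root's self-edge from its child list
  rc <- as.character(root_id)
  children[[rc]] <- setdiff(children[[rc]], root_id)

  structure(list(parent = parent, rank = rank, name = nm,
                 root_id = root_id, children = children),
            class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("taxonomy_tree: %d nodes, root %d\n", length(x$parent), x$root_id))
  invisible(x)
}

#' Taxids of all nodes in a taxonomy
#' @param tree A `taxonomy_tree`.
#' @return Integer vector of taxids.
#' @export
tax_nodes <- function(tree) as.integer(names(tree$parent))

.check_node <- function(tree, t) {
  if (!as.character(t) %in% names(tree$parent))
    stop("unknown taxid: ", t)
}

.parent_of <- function(tree, t) tree$parent[[as.character(t)]]

#' Parse NCBI-dialect nodes.dmp / names.dmp
#'
#' Fields are split on `\t|\t` with a trailing `\t|` stripped; only
#' "scientific name" class rows are read from names.dmp. Merged/deleted
#' taxid remapping is not supported: unknown taxids are hard errors.
#'
#' @param nodes Path to a nodes.dmp file, or a character vector of its lines.
#' @param names Optional path to names.dmp (or its lines). When absent,
#'   names default to the taxid as a string.
#' @return A [taxonomy_tree()].
#' @examples
#' tree <- load_taxonomy(c("1\t|\t1\t|\tno rank\t|",
#'                         "2\t|\t1\t|\tsuperkingdom\t|"))
#' @export
load_taxonomy <- function(nodes, names = NULL) {
  node_lines <- .read_lines_arg(nodes)
  node_lines <- node_lines[nzchar(node_lines)]
  parent <- integer(length(node_lines))
  rank <- character(length(node_lines))
  ids <- integer(length(node_lines))
  for (i in seq_along(node_lines)) {
    f <- .split_dmp(node_lines[i])
    if (length(f) < 3L)
      stop(sprintf("malformed nodes.dmp line %d: expected >= 3 fields", i))
    ids[i] <- suppressWarnings(as.integer(f[1]))
    parent[i] <- suppressWarnings(as.integer(f[2]))
    rank[i] <- f[3]
    if (is.na(ids[i]) || is.na(parent[i]))
      stop(sprintf("malformed nodes.dmp line %d: non-integer taxid", i))
  }
  names(parent) <- ids
  names(rank) <- ids

  nm <- NULL
  if (!is.null(names)) {
    name_lines <- .read_lines_arg(names)
    name_lines <- name_lines[nzchar(name_lines)]
    nm <- character(0)
    for (i in seq_along(name_lines)) {
      f <- .split_dmp(name_lines[i])
      if (length(f) < 4L)
        stop(sprintf("malformed names.dmp line %d: expected >= 4 fields", i))
      if (f[4] == "scientific name") nm[f[1]] <- f[2]
    }
  }
  taxonomy_tree(parent, rank, nm, root_id = ids[parent == ids][1])
}

#' Serialize a taxonomy back to dmp text
#'
#' @param tree A `taxonomy_tree`.
#' @param nodes_path,names_path Output file paths; when `NULL`, the lines
#'   are returned instead of written.
#' @return Invisibly, a list with `nodes` and `names` line vectors.
#' @export
write_taxonomy <- function(tree, nodes_path = NULL, names_path = NULL) {
  ids <- tax_nodes(tree)
  nodes <- sprintf("%d\t|\t%d\t|\t%s\t|", ids, tree$parent, tree$rank)
  nms <- sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|", ids, tree$name)
  if (!is.null(nodes_path)) writeLines(nodes, nodes_path)
  if (!is.null(names_path)) writeLines(nms, names_path)
  invisible(list(nodes = nodes, names = nms))
}

.read_lines_arg <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) readLines(x)
  else unlist(strsplit(x, "\n", fixed = TRUE))
}

.split_dmp <- function(line) {
  line <- sub("\t\\|$", "", line)
  strsplit(line, "\t|\t", fixed = TRUE)[[1]]
}

#' Root path of a taxon
#'
#' @param tree A `taxonomy_tree`.
#' @param t Taxid.
#' @return Integer vector from `t` up to the root, inclusive.
#' @export
root_path <- function(tree, t) {
  .check_node(tree, t)
  path <- integer(0)
  cur <- as.integer(t)
  repeat {
    path <- c(path, cur)
    if (cur == tree$root_id) break
    cur <- .parent_of(tree, cur)
  }
  path
}

#' Lowest common ancestor of two taxa
#'
#' @param tree A `taxonomy_tree`.
#' @param a,b Taxids.
#' @return The deepest node ancestral (inclusive) to both.
#' @export
lca <- function(tree, a, b) {
  .check_node(tree, a); .check_node(tree, b)
  pa <- root_path(tree, a)
  cur <- as.integer(b)
  repeat {
    if (cur %in% pa) return(cur)
    if (cur == tree$root_id) return(tree$root_id)
    cur <- .parent_of(tree, cur)
  }
}

#' Lowest common ancestor of a set of taxa
#'
#' Fold of [lca()] over the set; order-independent.
#'
#' @param tree A `taxonomy_tree`.
#' @param taxa Nonempty vector of taxids.
#' @return A taxid.
#' @export
lca_set <- function(tree, taxa) {
  taxa <- unique(as.integer(taxa))
  if (length(taxa) == 0L) stop("lca_set requires a nonempty set of taxa")
  acc <- taxa[1]
  .check_node(tree, acc)
  for (t in taxa[-1]) acc <- lca(tree, acc, t)
  acc
}

#' Is one taxon an ancestor of another?
#'
#' @param tree A `taxonomy_tree`.
#' @param anc,desc Taxids.
#' @return `TRUE` iff `anc` lies on `desc`'s root path (inclusive).
#' @export
is_ancestor <- function(tree, anc, desc) {
  .check_node(tree, anc); .check_node(tree, desc)
  anc <- as.integer(anc)
  cur <- as.integer(desc)
  repeat {
    if (cur == anc) return(TRUE)
    if (cur == tree$root_id) return(FALSE)
    cur <- .parent_of(tree, cur)
  }
}

#' Species-level ancestor of a taxon
#'
#' @param tree A `taxonomy_tree`.
#' @param t Taxid.
#' @return The unique ancestor (inclusive) whose rank is "species", or `NA`
#'   if `t` lies above species level.
#' @export
species_ancestor <- function(tree, t) {
  .check_node(tree, t)
  cur <- as.integer(t)
  repeat {
    if (.norm_rank(tree$rank[[as.character(cur)]]) == "species") return(cur)
    if (cur == tree$root_id) return(NA_integer_)
    cur <- .parent_of(tree, cur)
  }
}

#' Canonical rank position of a taxon
#'
#' Position on the 8-rank ladder: species = 1 ... domain = 8. Nodes with a
#' non-canonical rank take the position of their nearest canonical-ranked
#' ancestor; nodes with no canonical ancestor (e.g. the root) sit at 9.
#'
#' @param tree A `taxonomy_tree`.
#' @param t Taxid.
#' @return Integer in 1..9.
#' @export
canonical_rank_position <- function(tree, t) {
  .check_node(tree, t)
  cur <- as.integer(t)
  repeat {
    r <- .norm_rank(tree$rank[[as.character(cur)]])
    if (r %in% names(.CANONICAL_RANKS)) return(.CANONICAL_RANKS[[r]])
    if (cur == tree$root_id) return(.ABOVE_DOMAIN_POS)
    cur <- .parent_of(tree, cur)
  }
}

#' Rank distance between an ancestor and a descendant
#'
#' Number of canonical ladder steps from `lower`'s canonical rank position
#' up to `upper`'s. A label below species counts at the species position, so
#' a strain is at distance 0 from its species; the root is 8 ranks above a
#' species.
#'
#' @param tree A `taxonomy_tree`.
#' @param upper Ancestor taxid (must be an ancestor of `lower`).
#' @param lower Descendant taxid.
#' @return Integer in 0..8.
#' @export
rank_distance <- function(tree, upper, lower) {
  if (!is_ancestor(tree, upper, lower))
    stop("rank_distance: ", upper, " is not an ancestor of ", lower)
  canonical_rank_position(tree, upper) - canonical_rank_position(tree, lower)
}

#' All descendants of a taxon (inclusive)
#'
#' @param tree A `taxonomy_tree`.
#' @param t Taxid.
#' @return Integer vector: `t` plus all transitive descendants.
#' @export
clade_descendants <- function(tree, t) {
  .check_node(tree, t)
  out <- integer(0)
  queue <- as.integer(t)
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    out <- c(out, cur)
    kids <- tree$children[[as.character(cur)]]
    if (!is.null(kids)) queue <- c(queue, kids)
  }
  out
}

#' Fingerprint of a taxonomy
#'
#' An md5 checksum over the canonical serialization; LCA databases record it
#' so that a database is never used with a different taxonomy.
#'
#' @param tree A `taxonomy_tree`.
#' @return A hex string.
#' @export
taxonomy_fingerprint <- function(tree) {
  ids <- sort(tax_nodes(tree))
  txt <- paste(ids, tree$parent[as.character(ids)],
               tree$rank[as.character(ids)], sep = ":", collapse = "\n")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}
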