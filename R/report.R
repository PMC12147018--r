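# Kraken-compatible per-read output and per-sample report, with parsers
# for round-tripping.

#' Render a hit-run table as the Kraken hits field
#'
#' Runs are rendered `taxid:count`, no-hit runs `0:count`, and the paired
#' mate separator `|:|`. A read with no queried windows renders `0:0`.
#'
#' @param hit_runs data.frame with columns `token` and `count`.
#' @return A single string.
#' @export
render_hit_runs <- function(hit_runs) {
  if (nrow(hit_runs) == 0L) return("0:0")
  parts <- ifelse(hit_runs$token == .MATE_SEP, "|:|",
                  paste0(hit_runs$token, ":", hit_runs$count))
  paste(parts, collapse = " ")
}

#' Parse a Kraken hits field back into a hit-run table
#'
#' @param hits A hits string as produced by [render_hit_runs()].
#' @return data.frame with columns `token` and `count`.
#' @export
parse_hit_runs <- function(hits) {
  parts <- strsplit(hits, " ", fixed = TRUE)[[1]]
  token <- integer(length(parts)); count <- integer(length(parts))
  for (i in seq_along(parts)) {
    if (parts[i] == "|:|") { token[i] <- .MATE_SEP; count[i] <- NA_integer_ }
    else {
      kv <- strsplit(parts[i], ":", fixed = TRUE)[[1]]
      token[i] <- as.integer(kv[1]); count[i] <- as.integer(kv[2])
    }
  }
  data.frame(token = token, count = count)
}

#' Write Kraken-style per-read output
#'
#' One line per read: `C|U <tab> read_id <tab> taxid (0 if unclassified)
#' <tab> length or len1|len2 <tab> hit runs`.
#'
#' @param results A per-sample result data.frame from [classify_reads()].
#' @param path Optional output file; when `NULL` the lines are returned.
#' @return Character vector of lines, invisibly when written to `path`.
#' @export
write_kraken_output <- function(results, path = NULL) {
  lens <- ifelse(is.na(results$length2),
                 as.character(results$length1),
                 paste0(results$length1, "|", results$length2))
  lines <- paste(ifelse(results$classified, "C", "U"),
                 results$read_id,
                 ifelse(results$classified, results$label, 0L),
                 lens,
                 results$hits,
                 sep = "\t")
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}

#' Parse Kraken-style per-read output
#'
#' @param x A path or a character vector of output lines.
#' @return A data.frame with columns `read_id`, `classified`, `label`,
#'   `length1`, `length2` and `hits`.
#' @export
parse_kraken_output <- function(x) {
  lines <- .read_lines_arg(x)
  f <- strsplit(lines, "\t", fixed = TRUE)
  lens <- vapply(f, `[`, character(1), 4L)
  two <- grepl("|", lens, fixed = TRUE)
  l1 <- as.integer(ifelse(two, sub("\\|.*$", "", lens), lens))
  l2 <- rep(NA_integer_, length(lens))
  l2[two] <- as.integer(sub("^.*\\|", "", lens[two]))
  cls <- vapply(f, `[`, character(1), 1L) == "C"
  lab <- as.integer(vapply(f, `[`, character(1), 3L))
  lab[!cls] <- NA_integer_
  data.frame(read_id = vapply(f, `[`, character(1), 2L),
             classified = cls, label = lab,
             length1 = l1, length2 = l2,
             hits = vapply(f, `[`, character(1), 5L),
             stringsAsFactors = FALSE)
}

.RANK_CODES <- c(domain = "D", kingdom = "K", phylum = "P", class = "C",
                 order = "O", family = "F", genus = "G", species = "S")

# Kraken report rank code: canonical ranks get their letter, the root "R",
# and non-canonical nodes the nearest canonical ancestor's code with the
# number of steps below it (e.g. a strain directly under a species -> "S1").
.rank_code <- function(tree, t) {
  r <- .norm_rank(tree$rank[[as.character(t)]])
  if (r %in% names(.RANK_CODES)) return(.RANK_CODES[[r]])
  if (t == tree$root_id) return("R")
  steps <- 0L
  cur <- as.integer(t)
  repeat {
    cur <- .parent_of(tree, cur)
    steps <- steps + 1L
    r <- .norm_rank(tree$rank[[as.character(cur)]])
    if (r %in% names(.RANK_CODES))
      return(paste0(.RANK_CODES[[r]], steps))
    if (cur == tree$root_id) return(paste0("R", steps))
  }
}

#' Write a Kraken-style classification report
#'
#' Six tab-separated columns per line: percent of the sample's reads in the
#' clade (2 decimals), clade read count (cumulative over descendants),
#' direct read count, rank code, taxid, and the taxon name indented two
#' spaces per tree depth. The unclassified line comes first; clades are
#' listed depth-first with children ordered by clade count (descending,
#' then taxid).
#'
#' @param results A per-sample result data.frame from [classify_reads()].
#' @param tree A [taxonomy_tree()].
#' @param path Optional output file.
#' @return Character vector of report lines (invisibly when written).
#' @export
write_report <- function(results, tree, path = NULL) {
  total <- nrow(results)
  n_uncl <- sum(!results$classified)
  labels <- results$label[results$classified]

  direct <- integer(0)
  clade <- integer(0)
  if (length(labels)) {
    tb <- table(labels)
    direct <- setNames(as.integer(tb), names(tb))
    for (t in names(direct)) {
      for (anc in root_path(tree, as.integer(t))) {
        a <- as.character(anc)
        clade[a] <- (if (is.na(clade[a])) 0L else clade[a]) + direct[[t]]
      }
    }
  }

  pct <- function(n) sprintf("%.2f", if (total > 0) 100 * n / total else 0)
  lines <- sprintf("%s\t%d\t%d\tU\t0\tunclassified",
                   pct(n_uncl), n_uncl, n_uncl)

  if (length(clade)) {
    emit <- function(t, depth) {
      tc <- as.character(t)
      d <- if (tc %in% names(direct)) direct[[tc]] else 0L
      lines <<- c(lines, sprintf("%s\t%d\t%d\t%s\t%d\t%s%s",
                                 pct(clade[[tc]]), clade[[tc]], d,
                                 .rank_code(tree, t), t,
                                 strrep("  ", depth),
                                 tree$name[[tc]]))
      kids <- tree$children[[tc]]
      kids <- kids[as.character(kids) %in% names(clade)]
      if (length(kids)) {
        ord <- order(-clade[as.character(kids)], kids)
        for (kid in kids[ord]) emit(kid, depth + 1L)
      }
    }
    emit(tree$root_id, 0L)
  }
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}

#' Parse a Kraken-style report
#'
#' @param x A path or character vector of report lines.
#' @return A data.frame with columns `percent`, `clade_reads`,
#'   `direct_reads`, `rank_code`, `taxid`, `name` (whitespace-trimmed) and
#'   `depth` (indentation level).
#' @export
parse_report <- function(x) {
  lines <- .read_lines_arg(x)
  f <- strsplit(lines, "\t", fixed = TRUE)
  raw_name <- vapply(f, `[`, character(1), 6L)
  indent <- nchar(raw_name) - nchar(sub("^ +", "", raw_name))
  data.frame(percent = as.numeric(vapply(f, `[`, character(1), 1L)),
             clade_reads = as.integer(vapply(f, `[`, character(1), 2L)),
             direct_reads = as.integer(vapply(f, `[`, character(1), 3L)),
             rank_code = vapply(f, `[`, character(1), 4L),
             taxid = as.integer(vapply(f, `[`, character(1), 5L)),
             name = sub("^ +", "", raw_name),
             depth = indent %/% 2L,
             stringsAsFactors = FALSE)
}
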