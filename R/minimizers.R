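# User-facing minimizer operations. The heavy lifting (2-bit encoding,
# canonicalization, windowed selection) is compiled code; see
# src/minimizers.cpp. Keys are 16-digit hex strings; lexicographic order on
# them equals numeric order on the underlying 64-bit value.

#' Reverse complement of a nucleotide string
#'
#' @param seq A nucleotide string (IUPAC characters pass through
#'   complementation of A/C/G/T only; case preserved for those four).
#' @return The reverse complement string.
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  comp <- chartr("ACGTacgt", "TGCAtgca", seq)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

#' Canonical 2-bit encoding of an ell-mer
#'
#' Encodes the sequence and its reverse complement at two bits per
#' nucleotide (A=00, C=01, G=10, T=11) and returns the smaller of the two
#' values as a raw (unmasked) key. Any character outside A/C/G/T
#' (case-insensitive) makes the ell-mer ambiguous.
#'
#' @param seq A nucleotide string of length 1..32, or a vector of them.
#' @return A 16-digit hex key per input, `NA` for ambiguous ell-mers.
#' @examples
#' encode_canonical(strrep("A", 31))  # all-zero key
#' @export
encode_canonical <- function(seq) {
  .encode_canonical_cpp(as.character(seq))
}

#' Ordering value of a key
#'
#' The value used to compare candidate minimizers within a window:
#' `(key AND NOT seed_pattern) XOR toggle_mask`. It determines which
#' ell-mer is selected but is never stored.
#'
#' @param key Hex key(s) as returned by [encode_canonical()].
#' @param params A [minimizer_params()] object.
#' @return Hex string(s); compare lexicographically.
#' @export
ordering_value <- function(key, params) {
  stopifnot(inherits(params, "minimizer_params"))
  .ordering_value_cpp(as.character(key), params$seed_pattern,
                      params$toggle_mask, params$ell)
}

#' Split a sequence on ambiguous characters
#'
#' Maximal runs of unambiguous A/C/G/T characters of length >= k, with
#' their 0-based offsets in the original sequence. No classification window
#' ever spans or abuts an ambiguous character, so segments shorter than k
#' are dropped.
#'
#' @param seq A nucleotide string.
#' @param k Minimum segment (window) length in bp.
#' @return A data.frame with columns `offset` (0-based) and `seq`.
#' @export
split_on_ambiguity <- function(seq, k) {
  stopifnot(is.character(seq), length(seq) == 1L)
  m <- gregexpr("[ACGTacgt]+", seq)[[1]]
  if (m[1] == -1L)
    return(data.frame(offset = integer(0), seq = character(0)))
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  keep <- lens >= k
  data.frame(offset = starts[keep] - 1L,
             seq = substring(seq, starts[keep], starts[keep] + lens[keep] - 1L),
             stringsAsFactors = FALSE)
}

#' Minimizers of every k-window of a sequence
#'
#' For every k-length window in every unambiguous segment, selects the
#' ell-mer minimizing [ordering_value()] (leftmost wins ties) and emits its
#' *masked* canonical key (seed positions cleared; the toggle is applied
#' only for ordering). Consecutive windows sharing a minimizer each emit it:
#' deduplication is the caller's choice.
#'
#' @param seq A nucleotide string.
#' @param params A [minimizer_params()] object.
#' @return A data.frame with columns `offset` (0-based window start) and
#'   `key` (16-digit hex).
#' @export
minimizers_of <- function(seq, params) {
  stopifnot(is.character(seq), length(seq) == 1L,
            inherits(params, "minimizer_params"))
  res <- .minimizers_cpp(seq, params$k, params$ell,
                         params$seed_pattern, params$toggle_mask)
  data.frame(offset = res$offset, key = res$key, stringsAsFactors = FALSE)
}
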