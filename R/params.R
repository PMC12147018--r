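# Minimizer extraction parameters.
#
# Keys are 2-bit encoded nucleotide strings (A=00, C=01, G=10, T=11), held
# as fixed-width 16-digit lowercase hex so that lexicographic string order
# equals numeric order. ell is therefore capped at 32 (64-bit keys).

#' Default spaced-seed mask
#'
#' A 2·ell-bit mask whose set bit pairs mark the nucleotide positions that
#' are *cleared* from the stored minimizer key, so that single-nucleotide
#' variants at those positions still match at lookup time. The default
#' clears 7 alternating positions at the low-order (3') end of the encoded
#' minimizer: nucleotide positions 1, 3, 5, 7, 9, 11, 13 (0-based from the
#' low end), i.e. hex `000000000ccccccc`.
#'
#' @return A 16-digit hex string.
#' @export
default_seed_pattern <- function() "000000000ccccccc"

#' Default XOR toggle mask
#'
#' A fixed arbitrary 62-bit constant XORed onto masked keys when comparing
#' candidate minimizers within a window. It scrambles the ordering so that
#' minimizers are not biased towards low-complexity (poly-A) sequence; it is
#' never part of the stored key.
#'
#' @return A 16-digit hex string.
#' @export
default_toggle_mask <- function() "237e28c4271b5a2d"

#' Minimizer parameters
#'
#' Bundles the window length `k`, minimizer length `ell`, spaced-seed mask
#' and XOR toggle used identically during library building and read
#' classification. Defaults follow the conventional Kraken-style values
#' k = 35, ell = 31 with 7 spaced-seed positions.
#'
#' @param k Window / k-mer length in bp.
#' @param ell Minimizer length in bp; `ell <= k` and `ell <= 32`.
#' @param spaces Number of cleared nucleotide positions in `seed_pattern`.
#' @param seed_pattern 16-digit hex string; bit pairs mark cleared positions.
#' @param toggle_mask 16-digit hex string XORed for candidate ordering only.
#' @return An object of class `minimizer_params`.
#' @examples
#' minimizer_params()
#' minimizer_params(k = 21, ell = 15, spaces = 0, seed_pattern = "0")
#' @export
minimizer_params <- function(k = 35L, ell = 31L, spaces = 7L,
                             seed_pattern = default_seed_pattern(),
                             toggle_mask = default_toggle_mask()) {
  k <- as.integer(k); ell <- as.integer(ell); spaces <- as.integer(spaces)
  stopifnot(length(k) == 1L, length(ell) == 1L, k >= 1L, ell >= 1L)
  if (ell > k) stop("ell must not exceed k")
  if (ell > 32L) stop("ell must be <= 32 (keys are held in 64 bits)")
  seed_pattern <- .norm_hex(seed_pattern)
  toggle_mask <- .norm_hex(toggle_mask)

  bits <- .hex_to_bits(seed_pattern)
  if (any(bits[seq(2L * ell + 1L, 64L)] != 0L))
    stop("seed_pattern has bits set above position 2*ell")
  lo <- bits[seq(1L, 2L * ell, by = 2L)]
  hi <- bits[seq(2L, 2L * ell, by = 2L)]
  if (any(lo != hi))
    stop("seed_pattern must clear whole nucleotides (aligned bit pairs)")
  n_cleared <- sum(lo)
  if (n_cleared != spaces)
    stop(sprintf("seed_pattern clears %d nucleotide positions but spaces = %d",
                 n_cleared, spaces))

  structure(list(k = k, ell = ell, spaces = spaces,
                 seed_pattern = seed_pattern, toggle_mask = toggle_mask),
            class = "minimizer_params")
}

#' @export
print.minimizer_params <- function(x, ...) {
  cat(sprintf("minimizer_params: k=%d ell=%d spaces=%d\n  seed_pattern=%s\n  toggle_mask=%s\n",
              x$k, x$ell, x$spaces, x$seed_pattern, x$toggle_mask))
  invisible(x)
}

# normalize a hex string to 16 lowercase digits
.norm_hex <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- tolower(sub("^0x", "", x))
  if (!grepl("^[0-9a-f]{1,16}$", x)) stop("not a valid 64-bit hex string: ", x)
  paste0(strrep("0", 16L - nchar(x)), x)
}

# hex string -> 64 bits, position 1 = least significant bit
.hex_to_bits <- function(hex) {
  digits <- rev(strsplit(hex, "")[[1]])
  vals <- strtoi(digits, base = 16L)
  bits <- integer(64L)
  for (i in seq_along(vals)) {
    v <- vals[i]
    bits[(i - 1L) * 4L + 1:4] <- c(v %% 2L, (v %/% 2L) %% 2L,
                                   (v %/% 4L) %% 2L, (v %/% 8L) %% 2L)
  }
  bits
}

# 64 bits (LSB first) -> 16-digit hex
.bits_to_hex <- function(bits) {
  stopifnot(length(bits) == 64L)
  vals <- vapply(seq(1L, 64L, by = 4L), function(i) {
    sum(bits[i + 0:3] * c(1L, 2L, 4L, 8L))
  }, integer(1))
  paste(rev(sprintf("%x", vals)), collapse = "")
}
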