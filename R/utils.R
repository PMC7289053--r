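# Shared helpers: amino-acid alphabet, deterministic RNG substreams,
# locale-independent ordering.

#' The 20-letter amino-acid alphabet used throughout the package
#'
#' Order defines the integer encoding passed to the alignment kernels.
#' @return Character vector of 20 single-letter residue codes.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# integer-encode a protein string; errors name the first bad position
encode_protein <- function(x, what = "sequence") {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  codes <- match(chars, aa_alphabet())
  if (anyNA(codes)) {
    pos <- which(is.na(codes))[1]
    stop(sprintf("non-amino-acid character '%s' at position %d of %s",
                 chars[pos], pos, what))
  }
  codes
}

decode_protein <- function(codes) {
  paste(aa_alphabet()[codes], collapse = "")
}

#' Derive a deterministic RNG substream seed
#'
#' Hashes an arbitrary label string together with a top-level integer seed
#' into a seed below 2^31, so that independent parts of a simulation (one
#' per tree branch, one per purpose) draw from reproducible, decoupled
#' streams.
#'
#' @param seed Integer top-level seed.
#' @param ... Character or numeric labels identifying the substream.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, ...) {
  label <- paste(vapply(list(...), as.character, ""), collapse = "\r")
  mod <- 2147483647
  h <- 5381
  for (v in utf8ToInt(label)) h <- (h * 33 + v) %% mod
  h <- (h + (as.numeric(seed) %% mod) * 2654435) %% mod
  # two Lehmer mixing rounds
  h <- (h * 48271) %% mod
  h <- (h * 48271) %% mod
  as.integer(h %% (mod - 2) + 1)
}

# evaluate expr with a temporary RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# locale-independent string ordering (C collation via radix sort)
radix_order <- function(...) order(..., method = "radix")
radix_sort <- function(x) x[order(x, method = "radix")]

# stable numeric formatting for on-disk artifacts (byte-identical reruns)
num_chr <- function(x, digits = 6) {
  formatC(x, format = "g", digits = digits)
}
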