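# All-vs-all protein similarity search: exact Smith-Waterman with affine
# gaps (Gotoh), Karlin-Altschul-style e-values, blast-tabular output.
# Stands in for a heuristic search engine at desk scale, where exact DP is
# affordable and heuristics would only add nondeterminism.

#' Substitution matrices restricted to the package alphabet
#'
#' Returns the named scoring matrix from \pkg{Biostrings}, subset and
#' reordered to [aa_alphabet()].
#'
#' @param name `"BLOSUM62"` or `"BLOSUM50"`.
#' @return A 20x20 numeric matrix.
#' @export
scoring_matrix <- function(name = c("BLOSUM62", "BLOSUM50")) {
  name <- match.arg(name)
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  m <- get(name, envir = env)
  ab <- aa_alphabet()
  m <- m[ab, ab]
  storage.mode(m) <- "double"
  m
}

#' Search parameter defaults
#'
#' Conventional comparative-genomics settings: BLOSUM62, affine gap 11/1,
#' e-value cutoff 1e-5, five subjects kept per query.  `K` and `lambda`
#' are Karlin-Altschul constants fitted by shuffle calibration
#' ([calibrate_evalue()]) for this package's gap convention (the first
#' gap residue costs `gap_open`); the literature gapped-BLOSUM62 values
#' assume a different first-residue charge and overstate significance
#' here.
#'
#' @param matrix Substitution matrix name.
#' @param gap_open,gap_extend Affine gap penalties (first / each further
#'   gap residue).
#' @param evalue_max Expectation-value cutoff for reported hits.
#' @param top_n Non-self subjects kept per query.
#' @param K,lambda Karlin-Altschul calibration constants.
#' @return A named list of parameters.
#' @export
search_params <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                          evalue_max = 1e-5, top_n = 5,
                          K = 0.025, lambda = 0.22) {
  list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
       evalue_max = evalue_max, top_n = top_n, K = K, lambda = lambda)
}

#' Optimal local alignment of two proteins
#'
#' Smith-Waterman with affine gaps (Gotoh).  The traceback is
#' deterministic: ties prefer the diagonal, then the vertical (gap in
#' `b`), then the horizontal move.
#'
#' @param a,b Protein strings.
#' @param matrix 20x20 substitution matrix (see [scoring_matrix()]) or a
#'   matrix name.
#' @param gap_open Penalty for the first residue of a gap.
#' @param gap_extend Penalty for each further gap residue.
#' @return List with `score`, `a_start`, `a_end`, `b_start`, `b_end`
#'   (1-based, inclusive, 0 when the best score is 0), `n_ident`,
#'   `aln_len` and `pct_identity` over the aligned region.
#' @export
local_align <- function(a, b, matrix = "BLOSUM62", gap_open = 11,
                        gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  S <- if (is.character(matrix)) scoring_matrix(matrix) else matrix
  res <- sw_affine_cpp(encode_protein(a, "a"), encode_protein(b, "b"),
                       S, gap_open, gap_extend)
  res$pct_identity <- if (res$aln_len > 0) 100 * res$n_ident / res$aln_len else 0
  res
}

#' Karlin-Altschul expectation value
#'
#' `E = K * m * n * exp(-lambda * score)` for a search space of an
#' `m`-residue query against `n` residues of subject.
#'
#' @param score Alignment score.
#' @param m,n Query and subject lengths (residues).
#' @param K,lambda Calibration constants; `lambda` must be positive.
#' @return Expectation value (vectorised over `score`).
#' @export
estimate_evalue <- function(score, m, n, K = 0.025, lambda = 0.22) {
  if (lambda <= 0) stop("lambda must be > 0")
  K * m * n * exp(-lambda * score)
}

#' Empirical e-value calibration by sequence shuffling
#'
#' Fits `lambda` and `K` from maximum local-alignment scores of shuffled
#' sequence pairs (method of moments on the Gumbel distribution).  Only
#' needed when non-default scoring is used; the shipped defaults are the
#' literature constants.
#'
#' @param lengths Integer vector of two sequence lengths per pair.
#' @param n_pairs Number of shuffled pairs to score.
#' @param params [search_params()] list.
#' @param seed Integer seed.
#' @return A [search_params()] list with refitted `K` and `lambda`.
#' @export
calibrate_evalue <- function(lengths = c(200, 200), n_pairs = 200,
                             params = search_params(), seed = 1) {
  S <- scoring_matrix(params$matrix)
  scores <- with_seed(substream_seed(seed, "calibrate"), {
    vapply(seq_len(n_pairs), function(i) {
      a <- sample.int(20, lengths[1], replace = TRUE)
      b <- sample.int(20, lengths[2], replace = TRUE)
      sw_scores_block_cpp(list(a, b), S, params$gap_open,
                          params$gap_extend)[1, 2]
    }, 0)
  })
  # Gumbel: mean = u + gamma/lambda, var = pi^2 / (6 lambda^2)
  lam <- pi / sqrt(6 * stats::var(scores))
  u <- mean(scores) - 0.5772156649 / lam
  K <- exp(lam * u) / (lengths[1] * lengths[2])
  params$lambda <- lam
  params$K <- K
  params
}

# flatten a list of AnnotatedGenomes into one gene table with uids
gene_table <- function(genomes) {
  if (!length(genomes)) stop("empty gene set")
  tabs <- lapply(genomes, function(g) {
    df <- g$genes
    df$genome_id <- g$genome_id
    df$uid <- paste(g$genome_id, df$gene_id, sep = ":")
    df
  })
  do.call(rbind, c(tabs, list(make.row.names = FALSE)))
}

#' Reciprocal all-vs-all protein search
#'
#' Scores every unordered gene pair (within and between genomes) by exact
#' Smith-Waterman, converts scores to e-values, keeps for each query its
#' `top_n` best non-self subjects with `evalue <= evalue_max`, and closes
#' the hit set under reciprocity so the resulting hit graph is symmetric.
#'
#' @param genomes List of `AnnotatedGenome` objects.
#' @param params [search_params()] list.
#' @return A data.frame of hits in blast-tabular column order: `query`,
#'   `subject` (genome-qualified uids), `pct_identity`, `aln_len`,
#'   `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`, `send`, `evalue`,
#'   `score`.
#' @export
all_vs_all <- function(genomes, params = search_params()) {
  genes <- gene_table(genomes)
  if (!nrow(genes)) stop("empty gene set")
  S <- scoring_matrix(params$matrix)
  n <- nrow(genes)
  enc <- lapply(seq_len(n),
                function(i) encode_protein(genes$protein[i], genes$uid[i]))
  ai <- rep(seq_len(n - 1), times = (n - 1):1)
  bi <- unlist(lapply(seq_len(n - 1), function(i) seq(i + 1, n)))
  if (!length(ai)) return(empty_hits())
  sc <- sw_scores_pairs_cpp(enc, ai, bi, S, params$gap_open,
                            params$gap_extend)
  len <- nchar(genes$protein)
  ev <- params$K * len[ai] * len[bi] * exp(-params$lambda * sc)
  keep <- ev <= params$evalue_max
  ai <- ai[keep]; bi <- bi[keep]; sc <- sc[keep]; ev <- ev[keep]
  if (!length(ai)) return(empty_hits())
  # top_n per query by score (ties by subject uid for determinism)
  qi <- c(ai, bi); si <- c(bi, ai)
  qsc <- c(sc, sc); qev <- c(ev, ev)
  o <- radix_order(genes$uid[qi], -qsc, genes$uid[si])
  qi <- qi[o]; si <- si[o]
  rank_in_query <- stats::ave(seq_along(qi), qi, FUN = seq_along)
  capped <- rank_in_query <= params$top_n
  # reciprocal closure: symmetrise the kept set
  key <- paste(pmin(qi, si)[capped], pmax(qi, si)[capped])
  ukey <- unique(key)
  parts <- strsplit(ukey, " ", fixed = TRUE)
  ua <- as.integer(vapply(parts, `[`, "", 1))
  ub <- as.integer(vapply(parts, `[`, "", 2))
  qs <- c(ua, ub); ss <- c(ub, ua)
  # alignment details per unordered pair (computed once)
  det <- lapply(seq_along(ua), function(k) {
    sw_affine_cpp(enc[[ua[k]]], enc[[ub[k]]], S, params$gap_open,
                  params$gap_extend)
  })
  mk <- function(f) vapply(det, function(d) as.numeric(d[[f]]), 0)
  n_ident <- mk("n_ident"); aln_len <- mk("aln_len")
  score2 <- mk("score")
  ev2 <- params$K * len[qs] * len[ss] * exp(-params$lambda *
                                            rep(score2, 2))
  hits <- data.frame(
    query = genes$uid[qs],
    subject = genes$uid[ss],
    pct_identity = round(100 * rep(n_ident, 2) / pmax(rep(aln_len, 2), 1), 2),
    aln_len = as.integer(rep(aln_len, 2)),
    mismatch = as.integer(rep(aln_len - n_ident, 2)),
    gapopen = 0L,
    qstart = as.integer(c(mk("a_start"), mk("b_start"))),
    qend = as.integer(c(mk("a_end"), mk("b_end"))),
    sstart = as.integer(c(mk("b_start"), mk("a_start"))),
    send = as.integer(c(mk("b_end"), mk("a_end"))),
    evalue = ev2,
    score = rep(score2, 2),
    stringsAsFactors = FALSE)
  hits <- hits[radix_order(hits$query, hits$evalue, hits$subject), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  data.frame(query = character(), subject = character(),
             pct_identity = numeric(), aln_len = integer(),
             mismatch = integer(), gapopen = integer(),
             qstart = integer(), qend = integer(), sstart = integer(),
             send = integer(), evalue = numeric(), score = numeric(),
             stringsAsFactors = FALSE)
}
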