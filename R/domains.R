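# Profile-based domain detection: position-specific scoring matrices built
# from seed alignments, ungapped best-window scanning with an empirical
# shuffle null for e-values, architecture classification, and a
# divergence pre-filter for candidate family genes.

#' Build a PSSM profile from a seed alignment
#'
#' Columns with less than 50% occupancy are dropped before counting.
#' Log-odds use pseudocounts proportional to the background:
#' `log((count + pc * bg_r) / (n_eff + pc) / bg_r)` (natural log).
#'
#' @param seed_alignment Character vector of equal-length aligned rows
#'   (gaps as `-`).
#' @param pseudocount Total pseudocount mass.
#' @param background Residue background frequencies (default uniform).
#' @param name Profile name.
#' @return A `ProfileModel`: list with `length`, `log_odds`
#'   (length x 20 matrix), `background`, `name`.
#' @export
build_profile <- function(seed_alignment, pseudocount = 1,
                          background = NULL, name = "profile") {
  if (length(seed_alignment) < 2) stop("need >= 2 aligned sequences")
  lens <- nchar(seed_alignment)
  if (length(unique(lens)) != 1) stop("alignment rows of unequal length")
  ab <- aa_alphabet()
  if (is.null(background)) background <- setNames(rep(1 / 20, 20), ab)
  if (abs(sum(background) - 1) > 1e-8) stop("background must sum to 1")
  M <- do.call(rbind, strsplit(seed_alignment, ""))
  occ <- colMeans(M != "-")
  M <- M[, occ >= 0.5, drop = FALSE]
  if (!ncol(M)) stop("no columns left after occupancy filter")
  W <- ncol(M)
  lo <- matrix(0, W, 20, dimnames = list(NULL, ab))
  for (j in seq_len(W)) {
    col <- M[, j]
    col <- col[col != "-"]
    n_eff <- length(col)
    cnt <- table(factor(col, levels = ab))
    lo[j, ] <- log((as.numeric(cnt) + pseudocount * background) /
                   (n_eff + pseudocount) / background)
  }
  structure(list(length = W, log_odds = lo, background = background,
                 name = name),
            class = "ProfileModel")
}

#' @export
print.ProfileModel <- function(x, ...) {
  cat(sprintf("ProfileModel '%s': %d columns\n", x$name, x$length))
  invisible(x)
}

#' Scan parameters
#'
#' @param evalue_max Inclusion threshold on the empirical e-value
#'   (inclusive boundary; a hit at exactly the threshold is kept).
#' @param n_shuffles Shuffled copies of the protein used for the null.
#' @param db_factor Database-size multiplier applied to the empirical
#'   P-value.
#' @param seed Seed for the shuffle null.
#' @return Named list.
#' @export
scan_params <- function(evalue_max = 0.007, n_shuffles = 200, db_factor = 1,
                        seed = 1) {
  list(evalue_max = evalue_max, n_shuffles = n_shuffles,
       db_factor = db_factor, seed = seed)
}

#' Scan a protein with a PSSM profile
#'
#' The score of an offset is the ungapped sum of the profile's per-column
#' log-odds over a window of `profile$length` residues.  The e-value of a
#' hit is the fraction of `n_shuffles` shuffled versions of the protein
#' whose best window scores at least as high, times `db_factor`.  Hits
#' with e-value less than or equal to the threshold are returned
#' best-first; overlapping hits are suppressed greedily.  A protein
#' shorter than the profile has no window and yields no hit (not an
#' error).
#'
#' @param protein Protein string.
#' @param profile `ProfileModel`.
#' @param params [scan_params()] list.
#' @param gene_id Identifier copied into the hits (also salts the
#'   shuffle-null substream).
#' @return data.frame of `DomainHit` rows: `gene_id`, `domain`, `start`,
#'   `end` (0-based half-open residue coordinates), `score`, `evalue`.
#' @export
scan_domains <- function(protein, profile, params = scan_params(),
                         gene_id = "gene") {
  W <- profile$length
  L <- nchar(protein)
  empty <- data.frame(gene_id = character(), domain = character(),
                      start = integer(), end = integer(),
                      score = numeric(), evalue = numeric(),
                      stringsAsFactors = FALSE)
  if (L < W) return(empty)
  codes <- encode_protein(protein, gene_id)
  P <- profile$log_odds
  # per-offset window scores
  n_off <- L - W + 1
  scores <- vapply(seq_len(n_off), function(o)
    sum(P[cbind(seq_len(W), codes[o + seq_len(W) - 1L])]), 0)
  best <- max(scores)
  if (best <= 0) return(empty) # conservative prefilter: null P would be ~0.5
  null <- with_seed(substream_seed(params$seed, "scan", profile$name,
                                   gene_id), {
    shuf <- lapply(seq_len(params$n_shuffles), function(i) sample(codes))
    pssm_null_scores_cpp(shuf, P)
  })
  # greedy non-overlapping hit selection
  hits <- empty
  taken <- rep(FALSE, L)
  ord <- order(-scores, seq_along(scores))
  for (o in ord) {
    if (scores[o] <= 0) break
    span <- o:(o + W - 1)
    if (any(taken[span])) next
    ev <- mean(null >= scores[o] - 1e-12) * params$db_factor
    if (ev <= params$evalue_max + 1e-15) {
      hits <- rbind(hits, data.frame(
        gene_id = gene_id, domain = profile$name,
        start = o - 1L, end = o + W - 1L, score = scores[o], evalue = ev,
        stringsAsFactors = FALSE))
      taken[span] <- TRUE
    } else if (o == ord[1]) {
      break # best window already fails; weaker ones cannot pass
    }
  }
  hits
}

#' Scan all genes of several genomes with several profiles
#'
#' @param genomes List of `AnnotatedGenome`.
#' @param profiles List of `ProfileModel`.
#' @param params [scan_params()]; `db_factor` defaults to the number of
#'   scanned proteins when left at 1 and `auto_db` is TRUE.
#' @param auto_db Scale the e-value by the number of proteins scanned.
#' @return data.frame of domain hits with genome-qualified `uid` column.
#' @export
scan_genomes <- function(genomes, profiles, params = scan_params(),
                         auto_db = FALSE) {
  genes <- gene_table(genomes)
  if (auto_db) params$db_factor <- params$db_factor * nrow(genes)
  out <- list()
  for (pr in profiles) {
    for (i in seq_len(nrow(genes))) {
      L <- nchar(genes$protein[i])
      if (L < pr$length) next # no window can exist
      h <- scan_domains(genes$protein[i], pr, params,
                        gene_id = genes$gene_id[i])
      if (nrow(h)) {
        h$uid <- genes$uid[i]
        h$genome_id <- genes$genome_id[i]
        out[[length(out) + 1L]] <- h
      }
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(), domain = character(),
                      start = integer(), end = integer(), score = numeric(),
                      evalue = numeric(), uid = character(),
                      genome_id = character(), stringsAsFactors = FALSE))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Classify domain architecture from scan hits
#'
#' HMGL-like plus LeuA hits give `IPMS-like`; HMGL-like alone gives
#' `MAM-like` (highly diverged HMGL-only outliers are separated later by
#' the divergence filter); no HMGL-like hit gives `none`.
#'
#' @param hits Domain-hit data.frame for one gene ([scan_domains()]).
#' @param hmgl_name,leua_name Profile names.
#' @return One of `"IPMS-like"`, `"MAM-like"`, `"none"`.
#' @export
classify_architecture <- function(hits, hmgl_name = "HMGL-like",
                                  leua_name = "LeuA") {
  has_h <- any(hits$domain == hmgl_name)
  has_l <- any(hits$domain == leua_name)
  if (has_h && has_l) "IPMS-like" else if (has_h) "MAM-like" else "none"
}

#' Architecture calls for all scanned genes
#'
#' @param genomes List of `AnnotatedGenome`.
#' @param hits Output of [scan_genomes()].
#' @inheritParams classify_architecture
#' @return Named character vector keyed by uid.
#' @export
architectures_from_hits <- function(genomes, hits, hmgl_name = "HMGL-like",
                                    leua_name = "LeuA") {
  genes <- gene_table(genomes)
  vapply(genes$uid, function(u)
    classify_architecture(hits[hits$uid == u, , drop = FALSE],
                          hmgl_name, leua_name), "",
    USE.NAMES = TRUE)
}

#' Divergence pre-filter against reference family members
#'
#' A candidate is kept iff its minimum corrected distance to any labelled
#' reference sequence is at most `max_ratio` times the median pairwise
#' distance among the references.  Mirrors the exclusion of clades far
#' more diverged than any known family member.
#'
#' @param candidates Named character vector of candidate proteins.
#' @param references Named character vector of reference proteins
#'   (>= 2 required).
#' @param max_ratio Relative distance threshold.
#' @return List with `kept`, `removed` (names) and the `threshold` used.
#' @export
filter_by_divergence <- function(candidates, references, max_ratio = 2) {
  if (length(references) < 2) stop("need >= 2 reference sequences")
  ref_d <- utils::combn(length(references), 2, function(ix)
    pair_distance(references[[ix[1]]], references[[ix[2]]]))
  thr <- max_ratio * stats::median(ref_d)
  dmin <- vapply(candidates, function(cand)
    min(vapply(references, function(r) pair_distance(cand, r), 0)), 0)
  list(kept = names(candidates)[dmin <= thr],
       removed = names(candidates)[dmin > thr],
       min_distance = dmin, threshold = thr)
}

# corrected distance between two unaligned proteins: global-align, then
# Kimura-corrected p-distance over aligned columns (gaps excluded)
pair_distance <- function(a, b, matrix = NULL) {
  if (is.null(matrix)) matrix <- scoring_matrix("BLOSUM62")
  al <- nw_affine_cpp(encode_protein(a), encode_protein(b), matrix, 10, 1)
  shared <- al$aln_a > 0 & al$aln_b > 0
  n <- sum(shared)
  if (!n) return(Inf)
  p <- sum(al$aln_a[shared] != al$aln_b[shared]) / n
  kimura_correct(p)
}

kimura_correct <- function(p, cap_p = 0.85, cap_d = 5) {
  ifelse(p >= cap_p, cap_d, -log(1 - p - 0.2 * p^2))
}
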