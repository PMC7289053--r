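# Collinear-block detection from homology anchors by dynamic-programming
# chaining over gene-rank (ordinal) coordinates, in the MCScanX style:
# blocks are chains of anchors monotone in both genomes, extracted
# best-score-first per chromosome pair with used anchors removed.

#' Chaining parameter defaults (MCScanX-like)
#'
#' @param min_block_size Minimum anchors per reported block.
#' @param max_gap Maximum intervening genes between consecutive anchors,
#'   on either side.
#' @param gap_penalty Score added per skipped gene (negative).
#' @param max_anchor_score Cap on the per-anchor bit-like score.
#' @return Named list.
#' @export
chain_params <- function(min_block_size = 5, max_gap = 25, gap_penalty = -1,
                         max_anchor_score = 50) {
  list(min_block_size = min_block_size, max_gap = max_gap,
       gap_penalty = gap_penalty, max_anchor_score = max_anchor_score)
}

# raw alignment score -> capped bit-like anchor score
anchor_bit_score <- function(score, params = search_params(),
                             cap = 50) {
  pmin((params$lambda * score - log(params$K)) / log(2), cap)
}

#' Chain anchors on one chromosome pair into collinear blocks
#'
#' Dynamic program over anchors sorted by `pos_a`:
#' `chain(i) = score_i + max_j chain(j) + gap_penalty * (gap_a + gap_b)`
#' over predecessors `j` whose ordinal gaps on both sides are at most
#' `max_gap` and that are strictly monotone in both coordinates
#' (increasing `pos_b` for the same orientation, decreasing for the
#' inverted one).  Chains are extracted best-first, removing used anchors,
#' until no anchors remain; chains shorter than `min_block_size` are
#' dropped.  Ties break by higher anchor count, then lexicographic anchor
#' order, which makes the output independent of input anchor order.
#'
#' @param anchors data.frame with columns `gene_a`, `gene_b`, `pos_a`,
#'   `pos_b`, `score` (deduplicated per gene pair, best score kept).
#' @param params [chain_params()] list.
#' @return List of blocks; each a list with `anchors` (data.frame in chain
#'   order), `orientation` (`"same"`/`"inverted"`) and `block_score`.
#' @export
chain_anchors <- function(anchors, params = chain_params()) {
  if (params$max_gap < 1) stop("max_gap must be >= 1")
  if (!nrow(anchors)) return(list())
  anchors <- anchors[radix_order(anchors$pos_a, anchors$pos_b), ,
                     drop = FALSE]
  rownames(anchors) <- NULL
  alive <- rep(TRUE, nrow(anchors))
  blocks <- list()
  repeat {
    idx <- which(alive)
    if (!length(idx)) break
    best <- NULL
    for (orient in c("same", "inverted")) {
      ch <- best_chain_dp(anchors[idx, , drop = FALSE], orient, params)
      if (is.null(ch)) next
      ch$members <- idx[ch$members]
      if (is.null(best) || chain_better(ch, best)) best <- ch
    }
    if (is.null(best)) break
    alive[best$members] <- FALSE
    if (length(best$members) >= params$min_block_size) {
      blocks[[length(blocks) + 1L]] <- list(
        anchors = anchors[best$members, , drop = FALSE],
        orientation = best$orientation,
        block_score = best$score)
    }
  }
  blocks
}

chain_better <- function(a, b) {
  if (abs(a$score - b$score) > 1e-9) return(a$score > b$score)
  if (length(a$members) != length(b$members))
    return(length(a$members) > length(b$members))
  # lexicographically smallest member index sequence wins
  for (k in seq_along(a$members)) {
    if (a$members[k] != b$members[k]) return(a$members[k] < b$members[k])
  }
  FALSE
}

# best single chain by DP; anchors must be sorted by (pos_a, pos_b)
best_chain_dp <- function(anchors, orientation, params) {
  n <- nrow(anchors)
  score <- anchors$score
  pa <- anchors$pos_a
  pb <- anchors$pos_b
  chain <- score
  prev <- rep(0L, n)
  for (i in seq_len(n)) {
    best_j <- 0L
    best_val <- -Inf
    for (j in seq_len(i - 1L)) {
      if (pa[j] >= pa[i]) next
      gap_a <- pa[i] - pa[j] - 1L
      if (gap_a > params$max_gap) next
      if (orientation == "same") {
        if (pb[j] >= pb[i]) next
        gap_b <- pb[i] - pb[j] - 1L
      } else {
        if (pb[j] <= pb[i]) next
        gap_b <- pb[j] - pb[i] - 1L
      }
      if (gap_b > params$max_gap) next
      val <- chain[j] + params$gap_penalty * (gap_a + gap_b)
      if (val > best_val + 1e-12) { # ties: lowest predecessor index wins
        best_val <- val
        best_j <- j
      }
    }
    if (best_j > 0L && best_val > 0) {
      chain[i] <- score[i] + best_val
      prev[i] <- best_j
    }
  }
  if (!n) return(NULL)
  end <- which.max(chain) # first maximum: deterministic
  members <- integer()
  k <- end
  while (k > 0L) {
    members <- c(k, members)
    k <- prev[k]
  }
  list(members = members, score = chain[end], orientation = orientation)
}

#' Scan all genome pairs for collinear blocks
#'
#' Every unordered genome pair, including each genome against itself
#' (trivial self-diagonal anchors `gene_a == gene_b` excluded), per
#' chromosome pair and in deterministic order.  Intra-genome blocks are
#' the polyploidy signal.
#'
#' @param genomes Named list of `AnnotatedGenome`.
#' @param hits Hit table from [all_vs_all()].
#' @param params [chain_params()] list.
#' @param search [search_params()] used for the bit-score conversion.
#' @return data.frame of blocks (schema `blocks`): one row per block with
#'   the anchor gene pairs packed as `a1|b1 a2|b2 ...`.
#' @export
collinearity_scan <- function(genomes, hits, params = chain_params(),
                              search = search_params()) {
  genes <- gene_table(genomes)
  gidx <- setNames(seq_len(nrow(genes)), genes$uid)
  h <- hits[hits$query %in% names(gidx) & hits$subject %in% names(gidx), ,
            drop = FALSE]
  # keep one record per unordered pair
  a <- pmin(h$query, h$subject)
  b <- pmax(h$query, h$subject)
  key <- paste(a, b)
  o <- radix_order(key, -h$score)
  keep <- !duplicated(key[o])
  h <- h[o, ][keep, , drop = FALSE]
  a <- pmin(h$query, h$subject); b <- pmax(h$query, h$subject)
  self <- a == b
  h <- h[!self, , drop = FALSE]; a <- a[!self]; b <- b[!self]
  ga <- genes$genome_id[gidx[a]]; gb <- genes$genome_id[gidx[b]]
  ca <- genes$chrom[gidx[a]]; cb <- genes$chrom[gidx[b]]
  oa <- genes$ordinal[gidx[a]]; ob <- genes$ordinal[gidx[b]]
  # canonical side assignment per anchor: (genome, chrom) of side A <= side B
  ka <- paste(ga, ca); kb <- paste(gb, cb)
  flip <- ka > kb | (ka == kb & oa > ob)
  A <- ifelse(flip, b, a); B <- ifelse(flip, a, b)
  posA <- ifelse(flip, ob, oa); posB <- ifelse(flip, oa, ob)
  keyA <- ifelse(flip, kb, ka); keyB <- ifelse(flip, ka, kb)
  bit <- anchor_bit_score(h$score, search, params$max_anchor_score)
  pair_key <- paste(keyA, keyB, sep = "\t")
  out <- list()
  for (pk in radix_sort(unique(pair_key))) {
    w <- which(pair_key == pk)
    anc <- data.frame(gene_a = A[w], gene_b = B[w], pos_a = posA[w],
                      pos_b = posB[w], score = bit[w],
                      stringsAsFactors = FALSE)
    bl <- chain_anchors(anc, params)
    if (!length(bl)) next
    parts <- strsplit(pk, "\t", fixed = TRUE)[[1]]
    sidea <- strsplit(parts[1], " ", fixed = TRUE)[[1]]
    sideb <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
    for (k in seq_along(bl)) {
      blk <- bl[[k]]
      out[[length(out) + 1L]] <- data.frame(
        block_id = sprintf("B%04d", length(out) + 1L),
        genome_a = sidea[1], chrom_a = sidea[2],
        genome_b = sideb[1], chrom_b = sideb[2],
        orientation = blk$orientation,
        n_anchors = nrow(blk$anchors),
        block_score = blk$block_score,
        anchors = paste(paste(blk$anchors$gene_a, blk$anchors$gene_b,
                              sep = "|"), collapse = " "),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(block_id = character(), genome_a = character(),
                      chrom_a = character(), genome_b = character(),
                      chrom_b = character(), orientation = character(),
                      n_anchors = integer(), block_score = numeric(),
                      anchors = character(), stringsAsFactors = FALSE))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# unpack the anchors column of a block row into a two-column matrix of uids
block_anchor_pairs <- function(block_row) {
  pairs <- strsplit(block_row$anchors, " ", fixed = TRUE)[[1]]
  do.call(rbind, strsplit(pairs, "|", fixed = TRUE))
}

#' Write blocks in an MCScanX-like `.collinearity` text format
#'
#' @param blocks Block table from [collinearity_scan()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_collinearity <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("############### collinear blocks ###############", con)
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    writeLines(sprintf("## Alignment %s: score=%s %s:%s&%s:%s %s",
                       b$block_id, num_chr(b$block_score), b$genome_a,
                       b$chrom_a, b$genome_b, b$chrom_b, b$orientation),
               con)
    prs <- block_anchor_pairs(b)
    writeLines(sprintf("%s-%d:\t%s\t%s", b$block_id, seq_len(nrow(prs)),
                       prs[, 1], prs[, 2]), con)
  }
  invisible(path)
}
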