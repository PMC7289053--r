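# Independent oracles: deliberately naive reimplementations used to check
# the package's optimised code paths.  These share no code with R/.

# -- naive affine-gap local alignment score (full matrices, no rolling) ----
oracle_sw_score <- function(a, b, S, go, ge) {
  ai <- match(strsplit(a, "")[[1]], rownames(S))
  bi <- match(strsplit(b, "")[[1]], rownames(S))
  n <- length(ai); m <- length(bi)
  NEG <- -1e30
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      diag <- max(M[i, j], X[i, j], Y[i, j], 0)
      M[i + 1, j + 1] <- diag + S[ai[i], bi[j]]
      X[i + 1, j + 1] <- max(M[i, j + 1] - go, X[i, j + 1] - ge)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - go, Y[i + 1, j] - ge)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# -- exhaustive monotone-chain enumeration oracle (n <= 10 anchors) --------
# replicates the published extraction semantics: best chain first (score,
# then anchor count, then lexicographic member order), remove used
# anchors, report chains >= min_block_size.
oracle_chain_blocks <- function(anchors, params) {
  anchors <- anchors[order(anchors$pos_a, anchors$pos_b), , drop = FALSE]
  rownames(anchors) <- NULL
  n <- nrow(anchors)
  chain_score <- function(members, orient) {
    sc <- anchors$score[members[1]]
    if (length(members) > 1) {
      for (k in 2:length(members)) {
        i <- members[k - 1]; j <- members[k]
        ga <- anchors$pos_a[j] - anchors$pos_a[i] - 1
        gb <- if (orient == "same") anchors$pos_b[j] - anchors$pos_b[i] - 1
              else anchors$pos_b[i] - anchors$pos_b[j] - 1
        sc <- sc + anchors$score[j] + params$gap_penalty * (ga + gb)
      }
    }
    sc
  }
  valid_chain <- function(members, orient) {
    if (length(members) < 2) return(TRUE)
    for (k in 2:length(members)) {
      i <- members[k - 1]; j <- members[k]
      if (anchors$pos_a[j] <= anchors$pos_a[i]) return(FALSE)
      ga <- anchors$pos_a[j] - anchors$pos_a[i] - 1
      if (ga > params$max_gap) return(FALSE)
      gb <- if (orient == "same") anchors$pos_b[j] - anchors$pos_b[i] - 1
            else anchors$pos_b[i] - anchors$pos_b[j] - 1
      if ((orient == "same" && anchors$pos_b[j] <= anchors$pos_b[i]) ||
          (orient == "inverted" && anchors$pos_b[j] >= anchors$pos_b[i]))
        return(FALSE)
      if (gb > params$max_gap) return(FALSE)
    }
    TRUE
  }
  all_subsets <- function(idx) {
    out <- list()
    for (mask in 1:(2^length(idx) - 1)) {
      out[[mask]] <- idx[bitwAnd(mask, 2^(seq_along(idx) - 1)) > 0]
    }
    out
  }
  better <- function(a, b) {
    if (is.null(b)) return(TRUE)
    if (abs(a$score - b$score) > 1e-9) return(a$score > b$score)
    if (length(a$members) != length(b$members))
      return(length(a$members) > length(b$members))
    for (k in seq_along(a$members))
      if (a$members[k] != b$members[k]) return(a$members[k] < b$members[k])
    FALSE
  }
  alive <- rep(TRUE, n)
  blocks <- list()
  repeat {
    idx <- which(alive)
    if (!length(idx)) break
    best <- NULL
    for (sub in all_subsets(idx)) {
      for (orient in c("same", "inverted")) {
        if (!valid_chain(sub, orient)) next
        cand <- list(members = sub, orientation = orient,
                     score = chain_score(sub, orient))
        if (better(cand, best)) best <- cand
      }
    }
    if (is.null(best)) break
    alive[best$members] <- FALSE
    if (length(best$members) >= params$min_block_size)
      blocks[[length(blocks) + 1L]] <- list(
        anchors = anchors[best$members, , drop = FALSE],
        orientation = best$orientation, block_score = best$score)
  }
  blocks
}

# canonical fingerprint of a block list for oracle comparison
block_fingerprint <- function(blocks) {
  if (!length(blocks)) return(character())
  sort(vapply(blocks, function(b)
    paste(b$orientation, paste(b$anchors$gene_a, b$anchors$gene_b,
                               sep = "|", collapse = " "),
          sprintf("%.6f", b$block_score)), ""))
}

# -- brute-force k-clique percolation (k-subset enumeration) ---------------
oracle_cpm <- function(edges, k) {
  verts <- sort(unique(c(edges$from, edges$to)))
  if (length(verts) < k) return(list())
  amat <- matrix(FALSE, length(verts), length(verts),
                 dimnames = list(verts, verts))
  for (r in seq_len(nrow(edges))) {
    amat[edges$from[r], edges$to[r]] <- TRUE
    amat[edges$to[r], edges$from[r]] <- TRUE
  }
  subs <- utils::combn(verts, k, simplify = FALSE)
  is_clique <- function(s) all(amat[s, s] | diag(k))
  kc <- Filter(is_clique, subs)
  if (!length(kc)) return(list())
  m <- length(kc)
  comp <- seq_len(m)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  if (m > 1) {
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      if (length(intersect(kc[[i]], kc[[j]])) >= k - 1) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(m), find, 0L)
  comms <- lapply(split(seq_len(m), roots), function(ix)
    sort(unique(unlist(kc[ix]))))
  unname(comms[order(vapply(comms, `[`, "", 1))])
}

community_fingerprint <- function(comms) {
  if (!length(comms)) return(character())
  members <- lapply(comms, function(cm)
    if (is.list(cm)) cm$members else cm)
  sort(vapply(members, paste, "", collapse = ","))
}

# -- random Erdos-Renyi edge list ------------------------------------------
random_graph_edges <- function(n, p) {
  verts <- sprintf("v%02d", seq_len(n))
  pairs <- utils::combn(verts, 2)
  keep <- runif(ncol(pairs)) < p
  data.frame(from = pairs[1, keep], to = pairs[2, keep],
             stringsAsFactors = FALSE)
}

# -- additive distances from a random topology -----------------------------
random_additive_case <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(k) runif(k, 0.05, 1))
  tr$tip.label <- sprintf("x%02d", seq_len(n_taxa))
  D <- ape::cophenetic.phylo(tr)
  D <- D[sort(rownames(D)), sort(colnames(D))]
  list(tree = tr, D = D)
}

same_topology <- function(t1, t2) {
  isTRUE(all.equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))[1], 0))
}

# -- brute-force best-window PSSM score ------------------------------------
scan_score <- function(protein, profile) {
  codes <- match(strsplit(protein, "")[[1]], aa_alphabet())
  W <- profile$length
  max(vapply(seq_len(length(codes) - W + 1), function(o)
    sum(profile$log_odds[cbind(seq_len(W), codes[o + seq_len(W) - 1])]),
    0))
}
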