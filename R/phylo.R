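# Alignment and distance-based tree inference: center-star progressive
# MSA, occupancy-based column cleaning, Kimura-corrected protein
# distances, canonical neighbor-joining with deterministic tie-breaks,
# nonparametric bootstrap, and exemplar-anchored clade assignment.

#' Progressive multiple sequence alignment (center star)
#'
#' The center is the sequence minimising the summed pairwise edit
#' distance; every other sequence is aligned to it by global affine-gap
#' alignment (BLOSUM62, 10/1) and the pairwise alignments are merged
#' under "once a gap, always a gap".
#'
#' @param sequences Named character vector (>= 2 proteins).
#' @return A `MultipleAlignment`: named character vector of equal-length
#'   gapped rows, with attribute `"center"`.
#' @export
progressive_msa <- function(sequences) {
  if (length(sequences) < 2) stop("need >= 2 sequences")
  if (any(!nzchar(sequences))) stop("empty sequence")
  nm <- names(sequences)
  if (is.null(nm) || anyDuplicated(nm)) stop("sequences must be uniquely named")
  dm <- utils::adist(sequences)
  center <- which.min(rowSums(dm)) # first minimum: deterministic
  S <- scoring_matrix("BLOSUM62")
  enc <- lapply(sequences, encode_protein)
  cen <- enc[[center]]
  # master gap pattern for the center; each row stored relative to it
  aligned <- list()
  master_len <- length(cen)
  # master columns: each is either a center position (>0) or an inserted
  # gap column (0).  Start with the plain center.
  master <- seq_along(cen)
  rows <- list()
  rows[[nm[center]]] <- cen
  for (i in seq_along(sequences)) {
    if (i == center) next
    al <- nw_affine_cpp(cen, enc[[i]], S, 10, 1)
    # positions of center residues within this pairwise alignment
    ca <- al$aln_a
    cb <- al$aln_b
    # merge: walk master and pairwise alignment in parallel
    new_master <- integer()
    new_row <- integer()
    upd <- vector("list", length(rows))
    names(upd) <- names(rows)
    for (r in names(rows)) upd[[r]] <- integer()
    mi <- 1L; pi <- 1L
    nM <- length(master); nP <- length(ca)
    while (mi <= nM || pi <= nP) {
      m_is_res <- mi <= nM && master[mi] > 0L
      p_is_res <- pi <= nP && ca[pi] > 0L
      if (mi <= nM && !m_is_res) {
        # master-only gap column: gap in the new row
        new_master <- c(new_master, 0L)
        for (r in names(rows)) upd[[r]] <- c(upd[[r]], col_of(rows[[r]], mi))
        new_row <- c(new_row, 0L)
        mi <- mi + 1L
      } else if (pi <= nP && !p_is_res) {
        # insertion in the new sequence: gap column for everyone else
        new_master <- c(new_master, 0L)
        for (r in names(rows)) upd[[r]] <- c(upd[[r]], 0L)
        new_row <- c(new_row, cb[pi])
        pi <- pi + 1L
      } else {
        # both reference the same center residue
        new_master <- c(new_master, master[mi])
        for (r in names(rows)) upd[[r]] <- c(upd[[r]], col_of(rows[[r]], mi))
        new_row <- c(new_row, cb[pi])
        mi <- mi + 1L
        pi <- pi + 1L
      }
    }
    for (r in names(rows)) rows[[r]] <- upd[[r]]
    rows[[nm[i]]] <- new_row
    master <- new_master
  }
  ab <- aa_alphabet()
  out <- vapply(rows, function(codes)
    paste(ifelse(codes > 0L, ab[pmax(codes, 1L)], "-"), collapse = ""), "")
  out <- out[nm] # input order
  structure(out, center = nm[center], class = "MultipleAlignment")
}

# helper: rows are stored as per-column code vectors aligned to master
col_of <- function(row_codes, idx) row_codes[idx]

#' @export
print.MultipleAlignment <- function(x, ...) {
  cat(sprintf("MultipleAlignment: %d rows x %d columns\n", length(x),
              nchar(x[[1]])))
  invisible(x)
}

alignment_matrix <- function(aln) {
  do.call(rbind, strsplit(unclass(aln), ""))
}

matrix_alignment <- function(M, names_) {
  structure(setNames(apply(M, 1, paste, collapse = ""), names_),
            class = "MultipleAlignment")
}

#' Drop low-occupancy alignment columns
#'
#' Keeps every column whose fraction of non-gap characters is at least
#' `occupancy` (boundary inclusive: exactly 50% survives the default).
#'
#' @param aln `MultipleAlignment` or named character vector of gapped
#'   rows.
#' @param occupancy Minimum column occupancy in (0, 1].
#' @return Cleaned `MultipleAlignment`.
#' @export
clean_alignment <- function(aln, occupancy = 0.5) {
  if (occupancy <= 0 || occupancy > 1) stop("occupancy must be in (0, 1]")
  M <- alignment_matrix(aln)
  occ <- colMeans(M != "-")
  keep <- occ >= occupancy
  if (!any(keep))
    stop("no columns left at occupancy ", occupancy,
         "; lower the threshold")
  matrix_alignment(M[, keep, drop = FALSE], names(aln))
}

#' Kimura-corrected protein distance matrix
#'
#' p = mismatches / shared non-gap columns;
#' d = -ln(1 - p - 0.2 p^2), with saturated pairs (p >= 0.85) capped at
#' d = 5.
#'
#' @param aln `MultipleAlignment`.
#' @return Symmetric matrix with zero diagonal; attribute `"saturated"`
#'   flags capped pairs.
#' @export
distance_matrix <- function(aln) {
  M <- alignment_matrix(aln)
  n <- nrow(M)
  if (n < 2) stop("need >= 2 rows")
  D <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  sat <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      sh <- M[i, ] != "-" & M[j, ] != "-"
      if (!any(sh))
        stop(sprintf("no shared columns between %s and %s",
                     names(aln)[i], names(aln)[j]))
      p <- sum(M[i, sh] != M[j, sh]) / sum(sh)
      D[i, j] <- D[j, i] <- kimura_correct(p)
      sat[i, j] <- sat[j, i] <- p >= 0.85
    }
  }
  attr(D, "saturated") <- sat
  D
}

#' Neighbor-joining tree
#'
#' Canonical Saitou-Nei neighbor joining with Studier-Keppler updates.
#' Negative branch lengths are clamped to zero; the joined pair at each
#' step is the Q-minimal pair, ties broken by the lexicographically
#' smallest (label, label) pair, so permuting the input order cannot
#' change the topology.
#'
#' @param D Symmetric distance matrix with unique dimnames.
#' @return An unrooted `phylo` object ([ape::read.tree()] class).
#' @export
nj_tree <- function(D) {
  if (anyNA(D)) stop("distances contain NA")
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  labels <- rownames(D)
  n <- nrow(D)
  if (n < 3) stop("need >= 3 taxa")
  # newick fragments use placeholder tip names (labels may contain newick
  # metacharacters such as ':'); mapped back after parsing
  ph <- sprintf("t%06d", seq_len(n))
  # tie-breaking uses cluster representatives: the smallest real label
  rep_lab <- labels
  frag <- ph
  act <- seq_len(n)
  Dm <- D
  fmt <- function(x) formatC(max(x, 0), format = "g", digits = 10)
  while (length(act) > 3) {
    m <- length(act)
    sub <- Dm[act, act, drop = FALSE]
    r <- rowSums(sub)
    Q <- (m - 2) * sub - outer(r, r, "+")
    diag(Q) <- Inf
    # minimal Q with deterministic tie-break on the sorted label pair
    Q[lower.tri(Q, diag = TRUE)] <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    if (nrow(cand) > 1) {
      keys <- vapply(seq_len(nrow(cand)), function(k)
        paste(radix_sort(c(rep_lab[act[cand[k, 1]]],
                           rep_lab[act[cand[k, 2]]])), collapse = "\r"), "")
      cand <- cand[radix_order(keys)[1], , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    di <- 0.5 * sub[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    dj <- sub[i, j] - di
    ai <- act[i]; aj <- act[j]
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[ai], fmt(di), frag[aj],
                        fmt(dj))
    # Studier-Keppler distance of new node u to remaining k
    rest <- act[-c(i, j)]
    du <- 0.5 * (Dm[ai, rest] + Dm[aj, rest] - Dm[ai, aj])
    # grow matrix
    Dm <- rbind(cbind(Dm, 0), 0)
    frag <- c(frag, new_frag)
    rep_lab <- c(rep_lab, min(rep_lab[ai], rep_lab[aj]))
    u <- nrow(Dm)
    Dm[u, rest] <- du
    Dm[rest, u] <- du
    act <- c(rest, u)
  }
  # final 3-taxon star via the three-point equations
  a <- act[1]; b <- act[2]; c3 <- act[3]
  la <- (Dm[a, b] + Dm[a, c3] - Dm[b, c3]) / 2
  lb <- (Dm[a, b] + Dm[b, c3] - Dm[a, c3]) / 2
  lc <- (Dm[a, c3] + Dm[b, c3] - Dm[a, b]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[a], fmt(la), frag[b],
                 fmt(lb), frag[c3], fmt(lc))
  tr <- ape::read.tree(text = txt)
  tr$tip.label <- labels[match(tr$tip.label, ph)]
  tr
}

# -------------------------------------------------------------- bootstrap ----

# canonical bipartition keys of all internal edges of an unrooted tree
tree_splits <- function(tree) {
  tips <- tree$tip.label
  n_tip <- length(tips)
  splits <- character()
  desc <- descendants_by_node(tree)
  for (node in (n_tip + 1):(n_tip + tree$Nnode)) {
    side <- radix_sort(tips[desc[[node - n_tip]]])
    if (length(side) <= 1 || length(side) >= n_tip - 1) next
    other <- radix_sort(setdiff(tips, side))
    key <- if (side[1] < other[1]) paste(side, collapse = ",") else
      paste(other, collapse = ",")
    splits <- c(splits, key)
  }
  unique(splits)
}

# tip index sets below each internal node
descendants_by_node <- function(tree) {
  n_tip <- length(tree$tip.label)
  res <- vector("list", tree$Nnode)
  edge <- tree$edge
  # postorder accumulation
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(po))) {
    par <- po[k, 1]; ch <- po[k, 2]
    cur <- if (ch <= n_tip) ch else res[[ch - n_tip]]
    res[[par - n_tip]] <- c(res[[par - n_tip]], cur)
  }
  res
}

#' Bootstrap support for an alignment's NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds distance + NJ
#' trees, and labels each internal edge of the full-data tree with the
#' percentage of replicates containing the same leaf bipartition.
#'
#' @param aln `MultipleAlignment`.
#' @param n_reps Bootstrap replicates (the reference analysis used 1000;
#'   desk-scale tests use 100).
#' @param seed Integer seed.
#' @return List with `tree` (phylo, `node.label` holding supports) and
#'   `supports`, a named numeric vector keyed by bipartition.
#' @export
bootstrap_support <- function(aln, n_reps = 100, seed = 1) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  main <- nj_tree(distance_matrix(aln))
  keys <- tree_splits(main)
  counts <- setNames(numeric(length(keys)), keys)
  M <- alignment_matrix(aln)
  L <- ncol(M)
  with_seed(substream_seed(seed, "bootstrap"), {
    for (b in seq_len(n_reps)) {
      cols <- sample.int(L, L, replace = TRUE)
      rep_aln <- matrix_alignment(M[, cols, drop = FALSE], names(aln))
      rep_tree <- try(nj_tree(distance_matrix(rep_aln)), silent = TRUE)
      if (inherits(rep_tree, "try-error")) next
      rs <- tree_splits(rep_tree)
      hit <- keys %in% rs
      counts[hit] <- counts[hit] + 1
    }
  })
  supports <- 100 * counts / n_reps
  # attach to node labels of the main tree
  n_tip <- length(main$tip.label)
  desc <- descendants_by_node(main)
  labs <- character(main$Nnode)
  tips <- main$tip.label
  for (node in seq_len(main$Nnode)) {
    side <- radix_sort(tips[desc[[node]]])
    if (length(side) <= 1 || length(side) >= n_tip - 1) { labs[node] <- ""; next }
    other <- radix_sort(setdiff(tips, side))
    key <- if (side[1] < other[1]) paste(side, collapse = ",") else
      paste(other, collapse = ",")
    labs[node] <- num_chr(supports[[key]], 4)
  }
  main$node.label <- labs
  list(tree = main, supports = supports)
}

# ----------------------------------------------------------- clade calls ----

#' Exemplar-anchored clade assignment
#'
#' Each clade label is seeded by one or more exemplar leaves.  A label's
#' clade is the smallest tree bipartition side that contains all of its
#' exemplars, none of any other label's, and has bootstrap support at
#' least `min_support` (single-leaf sides count as trivially supported).
#' Leaves falling in no such side are `"unresolved"`; a label with no
#' qualifying side is reported non-monophyletic.
#'
#' @param boot Result of [bootstrap_support()] (or a list with `tree` and
#'   `supports`).
#' @param exemplars Named character vector: leaf label -> clade label.
#' @param min_support Minimum support percentage.
#' @return List with `assignment` (named vector leaf -> clade or
#'   `"unresolved"`) and `non_monophyletic` (labels without a qualifying
#'   clade).
#' @export
assign_clades <- function(boot, exemplars, min_support = 70) {
  tree <- boot$tree
  supports <- boot$supports
  tips <- tree$tip.label
  missing <- setdiff(names(exemplars), tips)
  if (length(missing)) stop("exemplar not in tree: ", missing[1])
  # candidate sides: every bipartition side + every single leaf
  sides <- list()
  for (key in names(supports)) {
    side <- strsplit(key, ",", fixed = TRUE)[[1]]
    sides[[length(sides) + 1L]] <- list(set = side, support = supports[[key]])
    sides[[length(sides) + 1L]] <- list(set = setdiff(tips, side),
                                        support = supports[[key]])
  }
  for (tp in tips)
    sides[[length(sides) + 1L]] <- list(set = tp, support = 100)
  labels <- radix_sort(unique(exemplars))
  assignment <- setNames(rep("unresolved", length(tips)), tips)
  non_mono <- character()
  for (lb in labels) {
    ex <- names(exemplars)[exemplars == lb]
    other <- setdiff(names(exemplars), ex)
    ok <- Filter(function(s)
      all(ex %in% s$set) && !any(other %in% s$set) &&
        s$support >= min_support && length(s$set) < length(tips),
      sides)
    if (!length(ok)) { non_mono <- c(non_mono, lb); next }
    # maximal qualifying group; deterministic tie-break on member list
    sizes <- vapply(ok, function(s) length(s$set), 0L)
    keys <- vapply(ok, function(s) paste(radix_sort(s$set),
                                         collapse = ","), "")
    pick <- ok[[radix_order(-sizes, keys)[1]]]
    memb <- pick$set
    clash <- memb[assignment[memb] != "unresolved"]
    assignment[setdiff(memb, clash)] <- lb
    assignment[clash] <- "unresolved"
  }
  list(assignment = assignment, non_monophyletic = non_mono)
}

#' Slice domain regions out of proteins
#'
#' Builds the domain-only sequence set from domain hits, so the domain
#' tree pipeline is a pure input change relative to the full-sequence
#' pipeline.
#'
#' @param sequences Named character vector of proteins (by uid).
#' @param hits Domain-hit table with `uid`, `start`, `end` (0-based
#'   half-open), filtered to one domain.
#' @return Named character vector of domain subsequences (genes without a
#'   hit are dropped).
#' @export
domain_sequences <- function(sequences, hits) {
  hits <- hits[hits$uid %in% names(sequences), , drop = FALSE]
  hits <- hits[!duplicated(hits$uid), , drop = FALSE]
  setNames(substr(sequences[hits$uid], hits$start + 1L, hits$end),
           hits$uid)
}
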