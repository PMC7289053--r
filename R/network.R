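# Synteny-network assembly, the windowed family-subnetwork query, k-clique
# percolation communities (CFinder semantics), and membership statistics.

#' Build the full synteny network from collinear blocks
#'
#' One node per gene appearing in an anchor, one edge per anchored gene
#' pair; a pair anchored in several blocks carries all block ids on a
#' single edge.
#'
#' @param blocks Block table from [collinearity_scan()].
#' @param genomes Named list of `AnnotatedGenome` (validates that anchors
#'   reference known genes and supplies node attributes).
#' @param architectures Optional named vector (by uid) of architecture
#'   calls joined onto nodes.
#' @return A `SyntenyNetwork`: list with `nodes` (data.frame: `uid`,
#'   `genome_id`, `chrom`, `ordinal`, `architecture`), `edges`
#'   (data.frame: `from`, `to`, `blocks`), `blocks` and the gene index.
#' @export
build_network <- function(blocks, genomes, architectures = NULL) {
  genes <- gene_table(genomes)
  rows <- list()
  for (i in seq_len(nrow(blocks))) {
    prs <- block_anchor_pairs(blocks[i, ])
    rows[[i]] <- data.frame(from = pmin(prs[, 1], prs[, 2]),
                            to = pmax(prs[, 1], prs[, 2]),
                            block = blocks$block_id[i],
                            stringsAsFactors = FALSE)
  }
  e <- if (length(rows)) do.call(rbind, rows) else
    data.frame(from = character(), to = character(), block = character())
  unknown <- setdiff(unique(c(e$from, e$to)), genes$uid)
  if (length(unknown))
    stop("anchor references unknown gene: ", unknown[1])
  key <- paste(e$from, e$to)
  agg <- tapply(e$block, key, function(b) paste(radix_sort(unique(b)),
                                                collapse = ","))
  ukey <- radix_sort(unique(key))
  parts <- strsplit(ukey, " ", fixed = TRUE)
  edges <- data.frame(from = vapply(parts, `[`, "", 1),
                      to = vapply(parts, `[`, "", 2),
                      blocks = unname(agg[ukey]),
                      stringsAsFactors = FALSE)
  node_ids <- radix_sort(unique(c(edges$from, edges$to)))
  gi <- genes[match(node_ids, genes$uid), , drop = FALSE]
  nodes <- data.frame(uid = node_ids, genome_id = gi$genome_id,
                      chrom = gi$chrom, ordinal = gi$ordinal,
                      architecture = if (is.null(architectures))
                        NA_character_ else
                        unname(architectures[node_ids]),
                      stringsAsFactors = FALSE)
  net <- list(nodes = nodes, edges = edges, blocks = blocks,
              gene_index = genes)
  class(net) <- "SyntenyNetwork"
  net
}

#' @export
print.SyntenyNetwork <- function(x, ...) {
  cat(sprintf("SyntenyNetwork: %d nodes, %d edges, %d blocks\n",
              nrow(x$nodes), nrow(x$edges), nrow(x$blocks)))
  invisible(x)
}

#' Extract the gene-family subnetwork with an ordinal context window
#'
#' Two candidate genes are connected iff some collinear block between
#' their chromosomes contains an anchor lying within `window` ordinal
#' positions of both candidates on their respective chromosomes.  The
#' candidates need not be anchors themselves -- this is what recovers
#' tandem-array members whose own anchor signal is masked by the local
#' duplicates.  All non-candidate genes are pruned.
#'
#' @param network `SyntenyNetwork` from [build_network()].
#' @param candidates Character vector of candidate uids (genes passing the
#'   domain and divergence filters).
#' @param window Context radius in gene ranks (default 25).
#' @return A `SyntenyNetwork` over the candidates only; edge `blocks`
#'   lists the supporting block ids.
#' @export
extract_family_subnetwork <- function(network, candidates, window = 25) {
  if (!length(candidates)) stop("empty candidate set")
  if (window < 1) stop("window must be >= 1")
  genes <- network$gene_index
  cand <- genes[genes$uid %in% candidates, , drop = FALSE]
  cand <- cand[radix_order(cand$uid), , drop = FALSE]
  blocks <- network$blocks
  # precompute anchor positions per block
  blk_anch <- lapply(seq_len(nrow(blocks)), function(i) {
    prs <- block_anchor_pairs(blocks[i, ])
    list(pa = genes$ordinal[match(prs[, 1], genes$uid)],
         pb = genes$ordinal[match(prs[, 2], genes$uid)])
  })
  ckey <- paste(cand$genome_id, cand$chrom)
  bkey_a <- paste(blocks$genome_a, blocks$chrom_a)
  bkey_b <- paste(blocks$genome_b, blocks$chrom_b)
  # chromosome-pair index over blocks
  bmap <- split(seq_len(nrow(blocks)), paste(bkey_a, bkey_b, sep = "\t"))
  n <- nrow(cand)
  ef <- character(); et <- character(); eb <- character()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      support <- character()
      cand_blocks <- unique(c(
        bmap[[paste(ckey[i], ckey[j], sep = "\t")]],
        bmap[[paste(ckey[j], ckey[i], sep = "\t")]]))
      for (bi in cand_blocks) {
        # candidate i on side A and j on side B, or the reverse
        ia <- ckey[i] == bkey_a[bi] && ckey[j] == bkey_b[bi]
        ib <- ckey[j] == bkey_a[bi] && ckey[i] == bkey_b[bi]
        if (!ia && !ib) next
        pa <- blk_anch[[bi]]$pa; pb <- blk_anch[[bi]]$pb
        hit <- if (ia)
          any(abs(pa - cand$ordinal[i]) <= window &
              abs(pb - cand$ordinal[j]) <= window) else FALSE
        if (!hit && ib)
          hit <- any(abs(pa - cand$ordinal[j]) <= window &
                     abs(pb - cand$ordinal[i]) <= window)
        # same (genome, chrom) on both sides: both role assignments
        if (!hit && ia && ib)
          hit <- any(abs(pa - cand$ordinal[j]) <= window &
                     abs(pb - cand$ordinal[i]) <= window)
        if (hit) support <- c(support, blocks$block_id[bi])
      }
      if (length(support)) {
        ef <- c(ef, cand$uid[i]); et <- c(et, cand$uid[j])
        eb <- c(eb, paste(support, collapse = ","))
      }
    }
  }
  nodes <- data.frame(uid = cand$uid, genome_id = cand$genome_id,
                      chrom = cand$chrom, ordinal = cand$ordinal,
                      architecture = network$nodes$architecture[
                        match(cand$uid, network$nodes$uid)],
                      stringsAsFactors = FALSE)
  net <- list(nodes = nodes,
              edges = data.frame(from = ef, to = et, blocks = eb,
                                 stringsAsFactors = FALSE),
              blocks = blocks, gene_index = genes)
  class(net) <- "SyntenyNetwork"
  net
}

# ------------------------------------------------------ clique percolation ----

#' All maximal cliques (Bron-Kerbosch with pivoting)
#'
#' @param adj Named list: vertex -> character vector of neighbours.
#' @return List of character vectors (each sorted), in deterministic
#'   order.
#' @export
max_cliques_bk <- function(adj) {
  out <- list()
  verts <- radix_sort(names(adj))
  bk <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      out[[length(out) + 1L]] <<- radix_sort(R)
      return(invisible(NULL))
    }
    # pivot: vertex of P u X with most neighbours in P
    px <- c(P, X)
    deg <- vapply(px, function(u) length(intersect(adj[[u]], P)), 0L)
    pivot <- px[which.max(deg)]
    for (v in setdiff(P, adj[[pivot]])) {
      bk(c(R, v), intersect(P, adj[[v]]), intersect(X, adj[[v]]))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  bk(character(), verts, character())
  out
}

#' k-clique percolation communities (CFinder semantics)
#'
#' Communities are unions of k-cliques reachable through (k-1)-node
#' overlaps, computed from the maximal cliques: all maximal cliques of
#' size >= k are adjacent when they share >= k-1 nodes, and a community is
#' the node union of a connected component of that clique graph.  Nodes in
#' no k-clique are unassigned; communities may overlap.
#'
#' @param network `SyntenyNetwork` or data.frame of edges (`from`, `to`).
#' @param k Clique size (>= 2).
#' @return List of `CliqueCommunity`: each a list with `community_id`,
#'   `members` (sorted uids) and `k`.  Empty when the graph has no
#'   k-clique.
#' @export
clique_communities <- function(network, k = 3) {
  if (k < 2) stop("k must be >= 2")
  edges <- if (inherits(network, "SyntenyNetwork")) network$edges
           else network
  if (!nrow(edges)) return(list())
  verts <- radix_sort(unique(c(edges$from, edges$to)))
  adj <- setNames(lapply(verts, function(v)
    radix_sort(unique(c(edges$to[edges$from == v],
                        edges$from[edges$to == v])))), verts)
  cl <- Filter(function(x) length(x) >= k, max_cliques_bk(adj))
  if (!length(cl)) return(list())
  m <- length(cl)
  # connected components of the clique-overlap graph
  comp <- seq_len(m)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (i in seq_len(m - 1)) {
    for (j in seq(i + 1, m)) {
      if (length(intersect(cl[[i]], cl[[j]])) >= k - 1) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(m), find, 0L)
  groups <- split(seq_len(m), roots)
  comms <- lapply(groups, function(ix)
    radix_sort(unique(unlist(cl[ix]))))
  # deterministic order: by first member
  comms <- comms[radix_order(vapply(comms, `[`, "", 1))]
  lapply(seq_along(comms), function(i)
    structure(list(community_id = sprintf("C%02d", i),
                   members = comms[[i]], k = k),
              class = "CliqueCommunity"))
}

#' Clade-by-community membership percentages
#'
#' One row per (clade, community) pair with
#' `percent = 100 * |clade intersect community| / |clade|`; genes in no
#' community are counted in a `"none"` pseudo-community, unlabelled genes
#' in an `"unlabeled"` clade.
#'
#' @param communities List from [clique_communities()].
#' @param clade_labels Named character vector: uid -> clade label.
#' @return data.frame with `clade`, `community`, `n`, `percent`.
#' @export
membership_stats <- function(communities, clade_labels) {
  genes <- names(clade_labels)
  lab <- ifelse(is.na(clade_labels) | !nzchar(clade_labels), "unlabeled",
                clade_labels)
  in_any <- rep(FALSE, length(genes))
  rows <- list()
  for (cm in communities) {
    hit <- genes %in% cm$members
    in_any <- in_any | hit
    for (cl in radix_sort(unique(lab))) {
      sel <- lab == cl
      n <- sum(sel & hit)
      if (n > 0)
        rows[[length(rows) + 1L]] <- data.frame(
          clade = cl, community = cm$community_id, n = n,
          percent = 100 * n / sum(sel), stringsAsFactors = FALSE)
    }
  }
  for (cl in radix_sort(unique(lab))) {
    sel <- lab == cl
    n <- sum(sel & !in_any)
    if (n > 0)
      rows[[length(rows) + 1L]] <- data.frame(
        clade = cl, community = "none", n = n,
        percent = 100 * n / sum(sel), stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(clade = character(), community = character(),
                      n = integer(), percent = numeric()))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Export a network as GraphML
#'
#' @param network `SyntenyNetwork`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_graphml <- function(network, path) {
  g <- igraph::graph_from_data_frame(
    network$edges, directed = FALSE,
    vertices = network$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
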