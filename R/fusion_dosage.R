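# The bespoke family analyses: segment-wise fusion test (before / domain /
# after donor attribution), conservation summary at a modal-residue
# threshold, duplication-type classification, and locus dosage profiling.

#' Split a protein into before / domain / after segments
#'
#' Exact partition of the protein at the boundaries of its single
#' HMGL-like domain hit.
#'
#' @param protein Protein string.
#' @param domain_hit One domain-hit row (`start`, `end`, 0-based
#'   half-open).
#' @param gene_id Identifier for the triplet.
#' @return A `SegmentTriplet` data.frame row: `gene_id`, `before`,
#'   `domain`, `after`.
#' @export
split_segments <- function(protein, domain_hit, gene_id = "gene") {
  if (is.null(domain_hit) || !nrow(domain_hit)) stop("no domain hit")
  if (nrow(domain_hit) > 1) {
    warning("multiple domain hits for ", gene_id, "; gene excluded")
    return(NULL)
  }
  s <- domain_hit$start[1]
  e <- domain_hit$end[1]
  L <- nchar(protein)
  if (s < 0 || e > L || s >= e) stop("domain hit outside protein")
  data.frame(gene_id = gene_id,
             before = substr(protein, 1, s),
             domain = substr(protein, s + 1, e),
             after = if (e < L) substr(protein, e + 1, L) else "",
             stringsAsFactors = FALSE)
}

# global percent identity of two segments; gaps count as mismatches
segment_identity <- function(a, b, S) {
  if (!nzchar(a) && !nzchar(b)) return(100)
  if (!nzchar(a) || !nzchar(b)) return(0)
  al <- nw_affine_cpp(encode_protein(a), encode_protein(b), S, 10, 1)
  100 * al$n_ident / al$aln_len
}

#' Segment-wise fusion test
#'
#' For each segment type (before, domain, after) computes all pairwise
#' global percent identities of the focal group against each donor group
#' and compares the two identity samples with a two-sided Mann-Whitney
#' rank-sum test.  A segment's verdict is the higher-mean donor when
#' p < alpha, else `"indistinguishable"`.  A fusion is flagged when
#' different segments have different winning donors.
#'
#' @param focal,donorA,donorB Segment-triplet data.frames
#'   ([split_segments()] rows).
#' @param alpha Significance level.
#' @return A `FusionVerdict` list: `table` (per-segment means, statistic,
#'   p-value, verdict), `fusion_flagged`, `alpha`.
#' @export
fusion_test <- function(focal, donorA, donorB, alpha = 0.05) {
  for (g in list(focal, donorA, donorB))
    if (is.null(g) || nrow(g) < 1) stop("each group needs >= 1 gene")
  S <- scoring_matrix("BLOSUM62")
  segs <- c("before", "domain", "after")
  rows <- list()
  for (sg in segs) {
    idA <- as.vector(outer(seq_len(nrow(focal)), seq_len(nrow(donorA)),
                           Vectorize(function(i, j)
                             segment_identity(focal[[sg]][i],
                                              donorA[[sg]][j], S))))
    idB <- as.vector(outer(seq_len(nrow(focal)), seq_len(nrow(donorB)),
                           Vectorize(function(i, j)
                             segment_identity(focal[[sg]][i],
                                              donorB[[sg]][j], S))))
    if (length(idA) < 4 || length(idB) < 4)
      warning("fewer than 4 pairwise comparisons for segment '", sg,
              "'; test underpowered")
    wt <- suppressWarnings(wilcox.test(idA, idB, exact = FALSE))
    verdict <- if (is.na(wt$p.value) || wt$p.value >= alpha)
      "indistinguishable"
    else if (mean(idA) > mean(idB)) "donorA" else "donorB"
    rows[[sg]] <- data.frame(segment = sg, mean_donorA = mean(idA),
                             mean_donorB = mean(idB),
                             statistic = unname(wt$statistic),
                             p_value = if (is.na(wt$p.value)) 1 else wt$p.value,
                             verdict = verdict, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  wins <- unique(tab$verdict[tab$verdict != "indistinguishable"])
  structure(list(table = tab, fusion_flagged = length(wins) > 1,
                 alpha = alpha),
            class = "FusionVerdict")
}

#' @export
print.FusionVerdict <- function(x, ...) {
  print(x$table)
  cat(if (x$fusion_flagged) "fusion flagged\n" else "no fusion signal\n")
  invisible(x)
}

#' Per-clade domain conservation summary
#'
#' A column is conserved iff its modal residue frequency among non-gap
#' rows is at least `threshold` (boundary inclusive); the clade score is
#' the fraction of conserved columns.
#'
#' @param domain_alignment Gapped rows (one clade's domain sequences).
#' @param threshold Modal-frequency threshold in (0, 1].
#' @return List with `score`, `conserved` (logical per column),
#'   `degenerate` (TRUE when the clade has a single row).
#' @export
conservation_summary <- function(domain_alignment, threshold = 0.8) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (length(domain_alignment) == 1)
    return(list(score = 1, conserved = rep(TRUE, nchar(domain_alignment)),
                degenerate = TRUE))
  M <- alignment_matrix(domain_alignment)
  conserved <- vapply(seq_len(ncol(M)), function(j) {
    col <- M[, j]
    col <- col[col != "-"]
    if (!length(col)) return(FALSE)
    max(table(col)) / length(col) >= threshold
  }, TRUE)
  list(score = mean(conserved), conserved = conserved, degenerate = FALSE)
}

#' Rank clades by domain conservation
#'
#' @param alignments Named list of per-clade domain alignments.
#' @param threshold Passed to [conservation_summary()].
#' @return data.frame sorted most-conserved first.
#' @export
conservation_ranking <- function(alignments, threshold = 0.8) {
  sc <- vapply(alignments, function(a)
    conservation_summary(a, threshold)$score, 0)
  out <- data.frame(clade = names(sc), score = unname(sc),
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$clade, method = "radix"), , drop = FALSE]
}

# ------------------------------------------------------- duplication type ----

#' Classify family genes by duplication type
#'
#' Decision cascade per gene: (1) tandem -- another family gene within
#' `tandem_gap` ordinals on the same chromosome; (2) syntenic_wgd -- an
#' intra-genome family-subnetwork edge to a non-tandem paralog, or
#' membership of a community while a same-genome paralog sits in a
#' different community; (3) transposed -- has family homologs but no
#' community membership; (4) dispersed; (5) singleton (no family
#' homolog).
#'
#' @param family_uids Character vector of family gene uids.
#' @param subnet Family `SyntenyNetwork` ([extract_family_subnetwork()]).
#' @param communities [clique_communities()] result on `subnet`.
#' @param genomes Named list of `AnnotatedGenome`.
#' @param hits Hit table ([all_vs_all()]), used for homolog existence.
#' @param tandem_gap Ordinal radius for tandem calls.
#' @return data.frame of `DuplicationCall`s: `uid`, `type`, `evidence`.
#' @export
classify_duplications <- function(family_uids, subnet, communities, genomes,
                                  hits, tandem_gap = 5) {
  genes <- gene_table(genomes)
  fam <- genes[genes$uid %in% family_uids, , drop = FALSE]
  fam <- fam[radix_order(fam$uid), , drop = FALSE]
  comm_of <- lapply(communities, `[[`, "members")
  names(comm_of) <- vapply(communities, `[[`, "", "community_id")
  in_comm <- function(u) names(comm_of)[vapply(comm_of, function(m)
    u %in% m, TRUE)]
  has_homolog <- function(u) {
    hs <- c(hits$subject[hits$query == u], hits$query[hits$subject == u])
    any(hs %in% setdiff(fam$uid, u))
  }
  edges <- subnet$edges
  out <- lapply(seq_len(nrow(fam)), function(i) {
    u <- fam$uid[i]
    gme <- fam$genome_id[i]
    sibs <- fam[fam$genome_id == gme & fam$uid != u, , drop = FALSE]
    near <- sibs[sibs$chrom == fam$chrom[i] &
                 abs(sibs$ordinal - fam$ordinal[i]) <= tandem_gap, ,
                 drop = FALSE]
    if (nrow(near))
      return(data.frame(uid = u, type = "tandem",
                        evidence = paste(near$uid, collapse = ","),
                        stringsAsFactors = FALSE))
    # (a) intra-genome subnetwork edge to a distal paralog
    nb <- c(edges$to[edges$from == u], edges$from[edges$to == u])
    distal <- intersect(nb, sibs$uid)
    if (length(distal))
      return(data.frame(uid = u, type = "syntenic_wgd",
                        evidence = paste(radix_sort(distal), collapse = ","),
                        stringsAsFactors = FALSE))
    # (b) a same-genome paralog at a distinct position shares a community
    mine <- in_comm(u)
    if (length(mine)) {
      for (cm in mine) {
        co_sibs <- intersect(comm_of[[cm]], sibs$uid)
        if (length(co_sibs))
          return(data.frame(uid = u, type = "syntenic_wgd",
                            evidence = paste0("shares ", cm, " with ",
                                              paste(radix_sort(co_sibs),
                                                    collapse = ",")),
                            stringsAsFactors = FALSE))
      }
    }
    if (!has_homolog(u))
      return(data.frame(uid = u, type = "singleton", evidence = "",
                        stringsAsFactors = FALSE))
    if (!length(mine))
      return(data.frame(uid = u, type = "transposed",
                        evidence = "no community membership",
                        stringsAsFactors = FALSE))
    data.frame(uid = u, type = "dispersed",
               evidence = paste(mine, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# ---------------------------------------------------------------- dosage ----

#' Locus dosage profile across genomes
#'
#' Counts family genes per genome and community (locus), split by
#' architecture, and reports per-genome deltas against a baseline (the
#' ancestral per-locus counts when known, else the first genome).  Flags
#' (a) loci whose counts are not a power-of-two (or stated multiplier)
#' multiple of the baseline and (b) anti-correlated count changes between
#' locus pairs -- reported, never asserted as biology.
#'
#' @param genomes Named list of `AnnotatedGenome`.
#' @param communities Either [clique_communities()] output or a named
#'   list of uid vectors (e.g. truth loci).
#' @param architectures Named vector (uid -> architecture call).
#' @param baseline Optional named numeric: locus -> ancestral family
#'   count.
#' @return List with `profiles` (data.frame, schema `profiles`),
#'   `deltas` (genome x locus matrix), `anticorrelated` (data.frame of
#'   locus pairs with opposite-sign deltas in some genome).
#' @export
dosage_profile <- function(genomes, communities, architectures,
                           baseline = NULL) {
  memb <- if (is.list(communities) && !is.null(names(communities)) &&
              !inherits(communities[[1]], "CliqueCommunity")) communities
  else setNames(lapply(communities, `[[`, "members"),
                vapply(communities, `[[`, "", "community_id"))
  genes <- gene_table(genomes)
  fam_uids <- names(architectures)[architectures %in% c("IPMS-like",
                                                        "MAM-like")]
  rows <- list()
  counts <- matrix(0, length(genomes), length(memb),
                   dimnames = list(radix_sort(names(genomes)),
                                   radix_sort(names(memb))))
  for (gid in rownames(counts)) {
    mine <- genes$uid[genes$genome_id == gid & genes$uid %in% fam_uids]
    assigned <- character()
    for (cm in colnames(counts)) {
      members <- intersect(memb[[cm]], mine)
      assigned <- union(assigned, members)
      counts[gid, cm] <- length(members)
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = gid, community = cm, n_genes = length(members),
        n_ipms_like = sum(architectures[members] == "IPMS-like"),
        n_mam_like = sum(architectures[members] == "MAM-like"),
        stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      genome_id = gid, community = "unassigned",
      n_genes = length(setdiff(mine, assigned)),
      n_ipms_like = sum(architectures[setdiff(mine, assigned)] ==
                        "IPMS-like"),
      n_mam_like = sum(architectures[setdiff(mine, assigned)] ==
                       "MAM-like"),
      stringsAsFactors = FALSE)
  }
  profiles <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(baseline))
    baseline <- counts[1, , drop = TRUE]
  base <- baseline[colnames(counts)]
  base[is.na(base)] <- 0
  deltas <- sweep(counts, 2, base)
  non_pow2 <- which(counts > 0 & base > 0 &
                    abs(log2(pmax(counts, 1) /
                             matrix(pmax(base, 1), nrow(counts),
                                    ncol(counts), byrow = TRUE)) %% 1) >
                    1e-9, arr.ind = TRUE)
  anti <- list()
  cn <- colnames(counts)
  for (i in seq_along(cn)) for (j in seq_along(cn)) {
    if (j <= i) next
    opp <- deltas[, i] * deltas[, j] < 0
    if (any(opp))
      anti[[length(anti) + 1L]] <- data.frame(
        locus_a = cn[i], locus_b = cn[j],
        genomes = paste(rownames(counts)[opp], collapse = ","),
        stringsAsFactors = FALSE)
  }
  list(profiles = profiles, counts = counts, deltas = deltas,
       non_power_multiple = non_pow2,
       anticorrelated = if (length(anti))
         do.call(rbind, c(anti, list(make.row.names = FALSE))) else
           data.frame(locus_a = character(), locus_b = character(),
                      genomes = character()))
}
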