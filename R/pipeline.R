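# End-to-end driver: search -> collinearity -> domain scan -> family
# subnetwork -> communities -> tree -> classification -> dosage, with all
# artifacts written as deterministic text files.

#' Run the full micro-synteny family pipeline
#'
#' @param genomes Named list of `AnnotatedGenome`.
#' @param profiles List of `ProfileModel` (typically the HMGL-like and
#'   LeuA profiles).
#' @param outdir Output directory, or `NULL` to skip writing.
#' @param seed Integer seed (shuffle nulls, bootstrap).
#' @param window Ordinal context window for the family subnetwork.
#' @param k Clique size for community detection.
#' @param n_boot Bootstrap replicates for the family tree.
#' @param references Optional named protein vector for the divergence
#'   pre-filter; `NULL` skips the filter.
#' @param search,chain,scan Parameter lists ([search_params()],
#'   [chain_params()], [scan_params()]).
#' @param tandem_gap Ordinal radius for tandem duplication calls.
#' @return List with every intermediate: `hits`, `blocks`, `domain_hits`,
#'   `architectures`, `candidates`, `network`, `subnet`, `communities`,
#'   `calls`, `membership`, `dosage`, `tree`, and `files` when `outdir`
#'   is given.
#' @export
run_pipeline <- function(genomes, profiles, outdir = NULL, seed = 1,
                         window = 25, k = 3, n_boot = 100,
                         references = NULL,
                         search = search_params(), chain = chain_params(),
                         scan = NULL, tandem_gap = 5) {
  if (is.null(scan)) scan <- scan_params(seed = seed)
  genes <- gene_table(genomes)
  hits <- all_vs_all(genomes, search)
  blocks <- collinearity_scan(genomes, hits, chain, search)
  domain_hits <- scan_genomes(genomes, profiles, scan)
  arch <- architectures_from_hits(genomes, domain_hits)
  candidates <- names(arch)[arch != "none"]
  removed <- character()
  if (!is.null(references) && length(candidates)) {
    seqs <- setNames(genes$protein[match(candidates, genes$uid)],
                     candidates)
    flt <- filter_by_divergence(seqs, references)
    candidates <- flt$kept
    removed <- flt$removed
  }
  network <- build_network(blocks, genomes, arch)
  subnet <- if (length(candidates))
    extract_family_subnetwork(network, candidates, window) else NULL
  communities <- if (!is.null(subnet)) clique_communities(subnet, k) else
    list()
  calls <- if (length(candidates))
    classify_duplications(candidates, subnet, communities, genomes, hits,
                          tandem_gap) else NULL
  membership <- membership_stats(communities, arch[candidates])
  dosage <- dosage_profile(genomes, communities, arch)
  tree <- NULL
  if (length(candidates) >= 3) {
    seqs <- setNames(genes$protein[match(candidates, genes$uid)],
                     candidates)
    aln <- clean_alignment(progressive_msa(seqs), 0.5)
    tree <- bootstrap_support(aln, n_reps = n_boot, seed = seed)
  }
  out <- list(hits = hits, blocks = blocks, domain_hits = domain_hits,
              architectures = arch, candidates = candidates,
              removed = removed, network = network, subnet = subnet,
              communities = communities, calls = calls,
              membership = membership, dosage = dosage, tree = tree)
  if (!is.null(outdir)) out$files <- write_pipeline(out, outdir)
  out
}

write_pipeline <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_table(res$hits, "hits", p("hits.tsv"))
  write_table(res$blocks, "blocks", p("blocks.tsv"))
  write_collinearity(res$blocks, p("blocks.collinearity"))
  dh <- res$domain_hits
  dh$gene_id <- dh$uid
  write_table(dh[, c("gene_id", "domain", "start", "end", "score",
                     "evalue")],
              "domains", p("domains.tsv"))
  if (!is.null(res$subnet))
    write_table(res$subnet$edges, "edges", p("family_edges.tsv"))
  comm <- do.call(rbind, c(lapply(res$communities, function(cm)
    data.frame(community_id = cm$community_id, gene = cm$members,
               stringsAsFactors = FALSE)),
    list(make.row.names = FALSE)))
  if (is.null(comm))
    comm <- data.frame(community_id = character(), gene = character())
  write_table(comm, "communities", p("communities.tsv"))
  if (!is.null(res$calls))
    write_table(res$calls, "calls", p("duplication_calls.tsv"))
  write_table(res$dosage$profiles, "profiles", p("locus_profiles.tsv"))
  if (!is.null(res$tree)) write_newick(res$tree$tree, p("family_tree.nwk"))
  list.files(outdir, full.names = TRUE)
}
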