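# Shared fixtures, built in code.  Small configurations keep unit tests
# fast; the acceptance suite runs the full defaults.

small_cfg <- function(seed = 1, ...) {
  sim_config(n_chromosomes = 2, n_background_genes = 20,
             bg_len_range = c(40, 70),
             len_flank1 = 15, len_hmgl = 60, len_linker = 8,
             len_leua = 50, len_flank2 = 10,
             seed = seed, ...)
}

# memoised small simulation shared across tests in one file run
.sim_cache <- new.env()
cached_small_sim <- function(seed = 1) {
  key <- paste0("s", seed)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- evolve(default_tree(), small_cfg(seed))
  .sim_cache[[key]]
}

# toy AnnotatedGenome from a bare table (uids "<genome>:<gene>")
toy_genome <- function(genome_id, chrom, gene_id, protein = NULL) {
  n <- length(gene_id)
  if (is.null(protein)) protein <- rep(strrep("ACDEFGHIK", 5), n)
  ord <- stats::ave(seq_len(n), chrom, FUN = seq_along) - 1L
  g <- list(genome_id = genome_id,
            genes = data.frame(gene_id = gene_id, protein = protein,
                               strand = "+", chrom = chrom,
                               ordinal = as.integer(ord),
                               start = as.integer(ord * 1000L),
                               end = as.integer(ord * 1000L + 300L),
                               is_family = TRUE,
                               stringsAsFactors = FALSE))
  class(g) <- "AnnotatedGenome"
  g
}

random_protein_str <- function(len) {
  paste(sample(aa_alphabet(), len, replace = TRUE), collapse = "")
}
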