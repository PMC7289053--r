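# Forward simulator of genome and protein evolution for a two-domain gene
# family (IPMS-like: HMGL-like + LeuA domains; MAM-like: HMGL-like only).
# Produces per-leaf annotated genomes plus a complete, replayable event log
# so that downstream network / phylogenetic / classification stages can be
# scored against ground truth.
#
# Event model per branch of the species tree:
#   1. scheduled whole-genome duplication/triplication (x2 / x3) with
#      per-duplicate Bernoulli retention,
#   2. planted deterministic events (scenario plants, e.g. compensatory
#      losses),
#   3. Poisson-count tandem duplications, transposed duplications, losses
#      (mean = rate * branch_length * n_family_genes at branch start) and
#      fusions (mean = rate_fusion * branch_length),
#   4. i.i.d. per-site substitutions with probability 1 - exp(-t), drawn
#      from a dedicated RNG substream so the event log plus the top-level
#      seed determine every leaf genome byte-for-byte.

#' Simulation configuration
#'
#' Defaults describe a small crucifer-like clade: three chromosomes of 40
#' background genes each, an IPMS-like gene (both domains) on chr1 and a
#' MAM-like gene (HMGL-like only) on chr2 -- the post-polyploidy state in
#' which the family is born -- a whole-genome duplication on the stem
#' branch, and a duplication-hot family (the MAM locus is famously tandem-
#' duplication prone).
#'
#' @param n_chromosomes Chromosomes in the ancestral genome.
#' @param n_background_genes Background (non-family) genes per chromosome.
#' @param bg_len_range Min/max background protein length (aa).
#' @param len_flank1,len_hmgl,len_linker,len_leua,len_flank2 Segment
#'   lengths (aa) of the family architecture
#'   flank + HMGL-like + linker + LeuA + flank.
#' @param family_loci Data frame with columns `chrom`, `architecture`
#'   (`"IPMS-like"` or `"MAM-like"`) and `locus`; one row per ancestral
#'   family gene.
#' @param rate_tandem,rate_transposed,rate_loss Expected events per family
#'   gene per unit branch length.
#' @param rate_fusion Expected chimera formations per genome per unit
#'   branch length.
#' @param p_domain_loss Probability that a newly created family duplicate
#'   loses its LeuA domain (when it has one).
#' @param wgd_events List of `list(branch =, multiplier =)` entries;
#'   multiplier 2 or 3.
#' @param wgd_retention Bernoulli keep probability per duplicate gene copy.
#' @param planted_events List of `list(kind = "loss", branch =, locus =)`
#'   deterministic events applied after any WGD on the branch.
#' @param seed Integer top-level seed; fixing it makes all outputs
#'   byte-identical.
#' @return An `EvolutionConfig` list.
#' @export
sim_config <- function(n_chromosomes = 3,
                       n_background_genes = 40,
                       bg_len_range = c(50, 85),
                       len_flank1 = 25, len_hmgl = 110, len_linker = 10,
                       len_leua = 90, len_flank2 = 15,
                       family_loci = NULL,
                       rate_tandem = 4, rate_transposed = 2.5,
                       rate_loss = 0.5, rate_fusion = 0,
                       p_domain_loss = 0.5,
                       wgd_events = list(list(branch = "stem", multiplier = 2)),
                       wgd_retention = 0.6,
                       planted_events = list(),
                       seed = 1) {
  if (is.null(family_loci)) {
    family_loci <- data.frame(
      chrom = c("chr1", "chr2")[seq_len(min(2, n_chromosomes))],
      architecture = c("IPMS-like", "MAM-like")[seq_len(min(2, n_chromosomes))],
      locus = c("L1", "L2")[seq_len(min(2, n_chromosomes))],
      stringsAsFactors = FALSE)
  }
  cfg <- list(n_chromosomes = n_chromosomes,
              n_background_genes = n_background_genes,
              bg_len_range = bg_len_range,
              len_flank1 = len_flank1, len_hmgl = len_hmgl,
              len_linker = len_linker, len_leua = len_leua,
              len_flank2 = len_flank2,
              family_loci = family_loci,
              rate_tandem = rate_tandem, rate_transposed = rate_transposed,
              rate_loss = rate_loss, rate_fusion = rate_fusion,
              p_domain_loss = p_domain_loss,
              wgd_events = wgd_events, wgd_retention = wgd_retention,
              planted_events = planted_events,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "EvolutionConfig"
  cfg
}

validate_sim_config <- function(cfg) {
  rates <- c(cfg$rate_tandem, cfg$rate_transposed, cfg$rate_loss,
             cfg$rate_fusion)
  if (any(rates < 0)) stop("invalid config: rates must be >= 0")
  if (cfg$n_background_genes < 1)
    stop("invalid config: n_background_genes must be >= 1")
  if (cfg$p_domain_loss < 0 || cfg$p_domain_loss > 1)
    stop("invalid config: p_domain_loss must be in [0, 1]")
  for (w in cfg$wgd_events) {
    if (!w$multiplier %in% c(2, 3))
      stop("invalid config: wgd multiplier must be 2 or 3")
  }
  invisible(cfg)
}

#' Default 4-genome species tree
#'
#' Balanced 4-leaf tree with a stem branch (the root edge) carrying the
#' shared whole-genome duplication.
#' @return Newick string.
#' @export
default_tree <- function() {
  "((A:0.1,B:0.1)n1:0.05,(C:0.1,D:0.1)n2:0.05)root:0.02;"
}

#' Parse and validate a species tree
#'
#' Branch ids are the labels of the child node of each edge (internal
#' nodes are auto-labelled `n1`, `n2`, ... when unlabelled); the root
#' edge, when present, has branch id `"stem"`.
#'
#' @param newick Newick string or path understood by [ape::read.tree()].
#' @return List with `phylo` (an [ape::read.tree()] tree), a `branches`
#'   data.frame (`id`, `parent`, `child`, `length`) and `stem_length`.
#' @export
parse_species_tree <- function(newick) {
  tr <- if (file.exists(newick)) ape::read.tree(newick)
        else ape::read.tree(text = newick)
  if (is.null(tr)) stop("could not parse species tree")
  if (anyDuplicated(tr$tip.label)) stop("leaf labels must be unique")
  if (is.null(tr$edge.length) || any(tr$edge.length <= 0))
    stop("all branch lengths must be > 0")
  n_tip <- length(tr$tip.label)
  n_node <- tr$Nnode
  if (is.null(tr$node.label) || !all(nzchar(tr$node.label)))
    tr$node.label <- paste0("n", seq_len(n_node))
  lab <- c(tr$tip.label, tr$node.label)
  br <- data.frame(id = lab[tr$edge[, 2]],
                   parent = lab[tr$edge[, 1]],
                   child = lab[tr$edge[, 2]],
                   length = tr$edge.length,
                   stringsAsFactors = FALSE)
  list(phylo = tr, branches = br,
       stem_length = if (is.null(tr$root.edge)) 0 else tr$root.edge,
       root_label = lab[n_tip + 1])
}

# ---------------------------------------------------------------- blocks ----

#' Ancestral domain blocks of the family architecture
#'
#' The HMGL-like and LeuA consensus blocks are drawn once from the config
#' seed; all family genes descend from them.
#' @param cfg [sim_config()] list.
#' @return List with `hmgl` and `leua` protein strings.
#' @export
family_blocks <- function(cfg) {
  with_seed(substream_seed(cfg$seed, "blocks"), {
    list(hmgl = random_protein(cfg$len_hmgl),
         leua = random_protein(cfg$len_leua))
  })
}

random_protein <- function(len) {
  paste(sample(aa_alphabet(), len, replace = TRUE), collapse = "")
}

#' Mutate a protein by i.i.d. site replacement
#'
#' Each site is replaced with probability `p` by a residue drawn uniformly
#' from the 19 alternatives.  Uses the current RNG state.
#'
#' @param protein Protein string.
#' @param p Per-site replacement probability.
#' @return Mutated protein string.
#' @export
mutate_protein <- function(protein, p) {
  codes <- encode_protein(protein)
  hit <- which(runif(length(codes)) < p)
  if (length(hit)) {
    repl <- sample.int(19L, length(hit), replace = TRUE)
    codes[hit] <- ifelse(repl >= codes[hit], repl + 1L, repl)
  }
  decode_protein(codes)
}

#' Apply one branch's substitutions to an ordered set of proteins
#'
#' Substitutions are drawn from the substream keyed by
#' `(seed, "subst", branch_id)`, independent of the event stream, so an
#' event-log replay can reproduce leaf sequences exactly.  Proteins must
#' be supplied in canonical genome order (chromosomes in C-locale order,
#' genes in position order).
#'
#' @param proteins Character vector of proteins in canonical order.
#' @param branch_id Branch identifier.
#' @param t Branch length (expected substitutions per site).
#' @param seed Top-level simulation seed.
#' @return Character vector of mutated proteins.
#' @export
apply_branch_substitutions <- function(proteins, branch_id, t, seed) {
  p <- 1 - exp(-t)
  with_seed(substream_seed(seed, "subst", branch_id), {
    vapply(proteins, mutate_protein, "", p = p, USE.NAMES = FALSE)
  })
}

# -------------------------------------------------------------- ancestor ----

family_gene_row <- function(cfg, blocks, architecture, locus, gene_id) {
  f1 <- random_protein(cfg$len_flank1)
  f2 <- random_protein(cfg$len_flank2)
  if (architecture == "IPMS-like") {
    lk <- random_protein(cfg$len_linker)
    protein <- paste0(f1, blocks$hmgl, lk, blocks$leua, f2)
    leua_start <- cfg$len_flank1 + cfg$len_hmgl + cfg$len_linker
    row <- list(has_leua = TRUE, leua_start = leua_start,
                leua_end = leua_start + cfg$len_leua)
  } else {
    protein <- paste0(f1, blocks$hmgl, f2)
    row <- list(has_leua = FALSE, leua_start = NA_integer_,
                leua_end = NA_integer_)
  }
  data.frame(gene_id = gene_id, protein = protein, strand = "+",
             is_family = TRUE, has_hmgl = TRUE,
             hmgl_start = cfg$len_flank1,
             hmgl_end = cfg$len_flank1 + cfg$len_hmgl,
             has_leua = row$has_leua, leua_start = row$leua_start,
             leua_end = row$leua_end,
             origin = "ancestral", locus = locus,
             stringsAsFactors = FALSE)
}

bg_gene_row <- function(cfg, gene_id) {
  len <- sample(seq(cfg$bg_len_range[1], cfg$bg_len_range[2]), 1)
  data.frame(gene_id = gene_id, protein = random_protein(len),
             strand = sample(c("+", "-"), 1),
             is_family = FALSE, has_hmgl = FALSE,
             hmgl_start = NA_integer_, hmgl_end = NA_integer_,
             has_leua = FALSE, leua_start = NA_integer_,
             leua_end = NA_integer_,
             origin = "background", locus = NA_character_,
             stringsAsFactors = FALSE)
}

#' Build the ancestral genome
#'
#' Chromosomes of random background genes with family genes (one per row
#' of `cfg$family_loci`) planted at the middle position of their
#' chromosome.  The family protein is
#' flank + HMGL-like + linker + LeuA + flank for the IPMS-like
#' architecture and flank + HMGL-like + flank for the MAM-like one.
#'
#' @param cfg [sim_config()] list.
#' @return An `AnnotatedGenome` (genome_id `"ancestor"`) whose gene table
#'   carries the truth columns (`is_family`, domain presence and
#'   coordinates, `origin`, `locus`).
#' @export
build_ancestral_genome <- function(cfg) {
  validate_sim_config(cfg)
  blocks <- family_blocks(cfg)
  counter <- new.env()
  counter$n <- 0L
  next_id <- function() {
    counter$n <- counter$n + 1L
    sprintf("g%05d", counter$n)
  }
  state <- with_seed(substream_seed(cfg$seed, "ancestor"), {
    chroms <- list()
    for (ci in seq_len(cfg$n_chromosomes)) {
      chrom <- sprintf("chr%d", ci)
      rows <- do.call(rbind, lapply(seq_len(cfg$n_background_genes),
                                    function(i) bg_gene_row(cfg, next_id())))
      fam_here <- cfg$family_loci[cfg$family_loci$chrom == chrom, ,
                                  drop = FALSE]
      if (nrow(fam_here)) {
        mid <- floor(nrow(rows) / 2)
        fam_rows <- do.call(rbind, lapply(seq_len(nrow(fam_here)), function(i)
          family_gene_row(cfg, blocks, fam_here$architecture[i],
                          fam_here$locus[i], next_id())))
        rows <- rbind(rows[seq_len(mid), , drop = FALSE], fam_rows,
                      rows[seq(mid + 1, nrow(rows)), , drop = FALSE])
      }
      chroms[[chrom]] <- rows
    }
    chroms
  })
  g <- state_to_genome(state, "ancestor")
  attr(g, "id_counter") <- counter$n
  g
}

# convert internal chromosome-list state into an AnnotatedGenome
state_to_genome <- function(state, genome_id) {
  chroms <- radix_sort(names(state))
  tabs <- lapply(chroms, function(ch) {
    df <- state[[ch]]
    if (!nrow(df)) return(NULL)
    df$chrom <- ch
    df$ordinal <- seq_len(nrow(df)) - 1L
    df$start <- df$ordinal * 5000L
    df$end <- df$start + 3L * nchar(df$protein)
    df
  })
  genes <- do.call(rbind, c(tabs[!vapply(tabs, is.null, TRUE)],
                            list(make.row.names = FALSE)))
  g <- list(genome_id = genome_id, genes = genes)
  class(g) <- "AnnotatedGenome"
  g
}

# back-convert (used when evolving from a built ancestor)
genome_to_state <- function(genome) {
  split(genome$genes[, setdiff(names(genome$genes),
                               c("chrom", "ordinal", "start", "end"))],
        genome$genes$chrom)
}

#' @export
print.AnnotatedGenome <- function(x, ...) {
  cat(sprintf("AnnotatedGenome '%s': %d genes on %d chromosome(s), %d family\n",
              x$genome_id, nrow(x$genes), length(unique(x$genes$chrom)),
              sum(x$genes$is_family)))
  invisible(x)
}

# --------------------------------------------------------------- chimera ----

#' Splice a chimeric protein from two parents
#'
#' The output alternates segments of `a` and `b`, switching source at each
#' breakpoint, starting with `a`.  Breakpoints are 0-based residue indices
#' and must be strictly increasing and within both sequences.
#'
#' @param a,b Protein strings.
#' @param breakpoints Integer vector of switch positions (0-based).
#' @return Chimeric protein string.
#' @export
make_chimera <- function(a, b, breakpoints) {
  if (!length(breakpoints)) return(a)
  bp <- as.integer(breakpoints)
  if (any(diff(bp) <= 0)) stop("breakpoints must be strictly increasing")
  if (any(bp < 0) || any(bp > min(nchar(a), nchar(b))))
    stop("breakpoint beyond sequence range")
  seqs <- c(a, b)
  bounds <- c(0L, bp)
  out <- character(length(bounds))
  for (k in seq_along(bounds)) {
    src <- seqs[[(k - 1) %% 2 + 1]]
    from <- bounds[k] + 1L
    to <- if (k < length(bounds)) bounds[k + 1] else nchar(src)
    out[k] <- if (from <= to) substr(src, from, to) else ""
  }
  paste(out, collapse = "")
}

# ---------------------------------------------------------------- evolve ----

new_event <- function(kind, branch, parents = character(), children = character(),
                      breakpoints = integer(), chrom = NA_character_,
                      position = NA_integer_) {
  data.frame(kind = kind, branch = branch,
             parent_ids = paste(parents, collapse = ","),
             child_ids = paste(children, collapse = ","),
             breakpoints = paste(breakpoints, collapse = ";"),
             chrom = chrom, position = position,
             stringsAsFactors = FALSE)
}

# environment-based simulation context (gene id counter + event log)
sim_ctx <- function(start_counter = 0L) {
  e <- new.env()
  e$counter <- as.integer(start_counter)
  e$log <- list()
  e
}
ctx_next_id <- function(ctx) {
  ctx$counter <- ctx$counter + 1L
  sprintf("g%05d", ctx$counter)
}
ctx_log <- function(ctx, ev) ctx$log[[length(ctx$log) + 1L]] <- ev

# duplicate a family gene row under a new id, with possible LeuA loss.
# Returns the child row with attribute "lost_leua"; the caller logs the
# domain_loss event after its own creation event so the log replays in
# order.
duplicate_family_row <- function(row, new_id, cfg, new_locus = NULL) {
  child <- row
  child$gene_id <- new_id # origin is overwritten by the caller
  if (!is.null(new_locus)) child$locus <- new_locus
  lost <- FALSE
  if (isTRUE(row$is_family) && isTRUE(row$has_leua) &&
      runif(1) < cfg$p_domain_loss) {
    child <- drop_leua(child)
    lost <- TRUE
  }
  attr(child, "lost_leua") <- lost
  child
}

log_domain_loss <- function(ctx, child, branch) {
  if (isTRUE(attr(child, "lost_leua")))
    ctx_log(ctx, new_event("domain_loss", branch, child$gene_id,
                           child$gene_id))
}

drop_leua <- function(row) {
  p <- row$protein
  row$protein <- paste0(substr(p, 1, row$leua_start),
                        substr(p, row$leua_end + 1, nchar(p)))
  row$has_leua <- FALSE
  row$leua_start <- NA_integer_
  row$leua_end <- NA_integer_
  row
}

# family gene index across the chromosome-list state, canonical order
family_index <- function(state) {
  chroms <- radix_sort(names(state))
  out <- NULL
  for (ch in chroms) {
    df <- state[[ch]]
    w <- which(df$is_family)
    if (length(w))
      out <- rbind(out, data.frame(chrom = ch, row = w,
                                   gene_id = df$gene_id[w],
                                   stringsAsFactors = FALSE))
  }
  out
}

insert_row <- function(df, row, at) {
  # insert so that `row` ends up at 1-based index `at`
  n <- nrow(df)
  row <- row[, names(df), drop = FALSE]
  if (at <= 1) rbind(row, df)
  else if (at > n) rbind(df, row)
  else rbind(df[seq_len(at - 1), , drop = FALSE], row,
             df[seq(at, n), , drop = FALSE])
}

apply_wgd <- function(state, multiplier, retention, cfg, ctx, branch) {
  chroms <- radix_sort(names(state))
  for (ch in chroms) {
    df <- state[[ch]]
    for (copy in 2:multiplier) {
      new_ch <- sprintf("%s_d%d", ch, copy)
      kept <- list()
      for (i in seq_len(nrow(df))) {
        if (runif(1) < retention) {
          row <- df[i, , drop = FALSE]
          nid <- ctx_next_id(ctx)
          child <- if (row$is_family) {
            duplicate_family_row(row, nid, cfg,
                                 new_locus = sprintf("%s/d%d", row$locus,
                                                     copy))
          } else {
            row2 <- row; row2$gene_id <- nid; row2
          }
          child$origin <- if (row$is_family) "wgd" else row$origin
          kept[[length(kept) + 1L]] <- child
          ctx_log(ctx, new_event("wgd", branch, row$gene_id, nid,
                                 chrom = new_ch,
                                 position = length(kept)))
          log_domain_loss(ctx, child, branch)
        }
      }
      if (length(kept))
        state[[new_ch]] <- do.call(rbind, c(kept, list(make.row.names = FALSE)))
    }
  }
  state
}

apply_planted <- function(state, cfg, ctx, branch) {
  for (pe in cfg$planted_events) {
    if (!identical(pe$branch, branch)) next
    if (identical(pe$kind, "loss")) {
      fam <- family_index(state)
      fam <- fam[vapply(seq_len(nrow(fam)), function(i)
        identical(state[[fam$chrom[i]]]$locus[fam$row[i]], pe$locus), TRUE), ,
        drop = FALSE]
      if (!nrow(fam)) next
      ch <- fam$chrom[1]; ri <- fam$row[1]
      ctx_log(ctx, new_event("loss", branch, state[[ch]]$gene_id[ri],
                             chrom = ch, position = ri))
      state[[ch]] <- state[[ch]][-ri, , drop = FALSE]
    } else stop("unsupported planted event kind: ", pe$kind)
  }
  state
}

process_branch <- function(state, branch, t, cfg, ctx) {
  with_seed(substream_seed(cfg$seed, "events", branch), {
    for (w in cfg$wgd_events) {
      if (identical(w$branch, branch))
        state <- apply_wgd(state, w$multiplier, cfg$wgd_retention, cfg, ctx,
                           branch)
    }
    state <- apply_planted(state, cfg, ctx, branch)
    fam0 <- family_index(state)
    n_fam <- if (is.null(fam0)) 0L else nrow(fam0)
    n_tan <- rpois(1, cfg$rate_tandem * t * n_fam)
    n_trn <- rpois(1, cfg$rate_transposed * t * n_fam)
    n_los <- rpois(1, cfg$rate_loss * t * n_fam)
    n_fus <- rpois(1, cfg$rate_fusion * t)
    for (i in seq_len(n_tan)) {
      fam <- family_index(state)
      if (is.null(fam)) break
      pick <- fam[sample.int(nrow(fam), 1), ]
      parent <- state[[pick$chrom]][pick$row, , drop = FALSE]
      nid <- ctx_next_id(ctx)
      child <- duplicate_family_row(parent, nid, cfg)
      child$origin <- "tandem"
      state[[pick$chrom]] <- insert_row(state[[pick$chrom]], child,
                                        pick$row + 1L)
      ctx_log(ctx, new_event("tandem_dup", branch, parent$gene_id, nid,
                             chrom = pick$chrom, position = pick$row + 1L))
      log_domain_loss(ctx, child, branch)
    }
    for (i in seq_len(n_trn)) {
      fam <- family_index(state)
      if (is.null(fam)) break
      pick <- fam[sample.int(nrow(fam), 1), ]
      parent <- state[[pick$chrom]][pick$row, , drop = FALSE]
      nid <- ctx_next_id(ctx)
      child <- duplicate_family_row(parent, nid, cfg,
                                    new_locus = paste0("T:", nid))
      child$origin <- "transposed"
      chroms <- radix_sort(names(state))
      dest <- chroms[sample.int(length(chroms), 1)]
      at <- sample.int(nrow(state[[dest]]) + 1L, 1)
      state[[dest]] <- insert_row(state[[dest]], child, at)
      ctx_log(ctx, new_event("transposed_dup", branch, parent$gene_id, nid,
                             chrom = dest, position = at))
      log_domain_loss(ctx, child, branch)
    }
    for (i in seq_len(n_los)) {
      fam <- family_index(state)
      if (is.null(fam) || nrow(fam) < 2) break # keep the family alive
      pick <- fam[sample.int(nrow(fam), 1), ]
      ctx_log(ctx, new_event("loss", branch,
                             state[[pick$chrom]]$gene_id[pick$row],
                             chrom = pick$chrom, position = pick$row))
      state[[pick$chrom]] <- state[[pick$chrom]][-pick$row, , drop = FALSE]
    }
    for (i in seq_len(n_fus)) {
      fam <- family_index(state)
      if (is.null(fam) || nrow(fam) < 2) break
      ab <- sample.int(nrow(fam), 2)
      pa <- fam[ab[1], ]; pb <- fam[ab[2], ]
      ra <- state[[pa$chrom]][pa$row, , drop = FALSE]
      rb <- state[[pb$chrom]][pb$row, , drop = FALSE]
      # switch at the HMGL-like boundaries: before from a, domain from b,
      # after from a; requires matching domain coordinates
      if (!isTRUE(ra$hmgl_start == rb$hmgl_start) ||
          !isTRUE(ra$hmgl_end == rb$hmgl_end)) next
      bp <- c(ra$hmgl_start, ra$hmgl_end)
      nid <- ctx_next_id(ctx)
      child <- ra
      child$gene_id <- nid
      child$protein <- make_chimera(ra$protein, rb$protein, bp)
      # origin/locus inherited from the replaced acceptor
      state[[pa$chrom]][pa$row, ] <- child[, names(state[[pa$chrom]])]
      ctx_log(ctx, new_event("fusion", branch,
                             c(ra$gene_id, rb$gene_id), nid,
                             breakpoints = bp, chrom = pa$chrom,
                             position = pa$row))
    }
    state
  })
}

apply_substitutions_state <- function(state, branch, t, cfg) {
  chroms <- radix_sort(names(state))
  prots <- unlist(lapply(chroms, function(ch) state[[ch]]$protein),
                  use.names = FALSE)
  mut <- apply_branch_substitutions(prots, branch, t, cfg$seed)
  k <- 0L
  for (ch in chroms) {
    n <- nrow(state[[ch]])
    if (n) state[[ch]]$protein <- mut[k + seq_len(n)]
    k <- k + n
  }
  state
}

#' Evolve an ancestral genome along a species tree
#'
#' @param tree Newick string/path or the result of [parse_species_tree()].
#' @param cfg [sim_config()] list.
#' @return List with `genomes` (named list of `AnnotatedGenome`, one per
#'   leaf), `log` (an `EventLog`: ordered event data.frame + tree + cfg)
#'   and `ancestor`.
#' @export
evolve <- function(tree = default_tree(), cfg = sim_config()) {
  validate_sim_config(cfg)
  st <- if (is.list(tree) && !inherits(tree, "phylo")) tree
        else parse_species_tree(tree)
  anc <- build_ancestral_genome(cfg)
  ctx <- sim_ctx(attr_or(anc, "id_counter", max_gene_number(anc)))
  state0 <- genome_to_state(anc)
  genomes <- list()

  walk <- function(state, node_label) {
    kids <- st$branches[st$branches$parent == node_label, , drop = FALSE]
    if (!nrow(kids)) { # leaf
      genomes[[node_label]] <<- state_to_genome(state, node_label)
      return(invisible(NULL))
    }
    for (i in seq_len(nrow(kids))) {
      b <- kids[i, ]
      ctx_log(ctx, new_event("speciation", b$id))
      child_state <- process_branch(state, b$id, b$length, cfg, ctx)
      child_state <- apply_substitutions_state(child_state, b$id, b$length,
                                               cfg)
      walk(child_state, b$child)
    }
  }

  state <- state0
  if (st$stem_length > 0) {
    state <- process_branch(state, "stem", st$stem_length, cfg, ctx)
    state <- apply_substitutions_state(state, "stem", st$stem_length, cfg)
  }
  walk(state, st$root_label)

  log <- do.call(rbind, c(ctx$log, list(make.row.names = FALSE)))
  if (is.null(log)) log <- new_event("speciation", "none")[0, ]
  out <- list(events = log, tree = st, cfg = cfg)
  class(out) <- "EventLog"
  list(genomes = genomes[radix_sort(names(genomes))], log = out,
       ancestor = anc)
}

attr_or <- function(x, name, default) {
  v <- attr(x, name)
  if (is.null(v)) default else v
}

max_gene_number <- function(genome) {
  max(as.integer(sub("^g", "", genome$genes$gene_id)))
}

#' @export
print.EventLog <- function(x, ...) {
  cat(sprintf("EventLog: %d events (%s)\n", nrow(x$events),
              paste(sprintf("%s=%d", names(table(x$events$kind)),
                            as.integer(table(x$events$kind))),
                    collapse = ", ")))
  invisible(x)
}

# ------------------------------------------------------------ truth maps ----

#' Ground-truth domain architecture per gene
#'
#' @param genome An `AnnotatedGenome` from the simulator.
#' @return Named character vector (`IPMS-like`, `MAM-like`, `none`) keyed
#'   by gene id.
#' @export
truth_architectures <- function(genome) {
  g <- genome$genes
  arch <- ifelse(g$is_family & g$has_hmgl & g$has_leua, "IPMS-like",
          ifelse(g$is_family & g$has_hmgl, "MAM-like", "none"))
  setNames(arch, g$gene_id)
}

#' Ground-truth duplication type per family gene
#'
#' Mirrors the observable semantics of the duplicate classifier, computed
#' from the simulator's hidden state (locus identity and birth mode):
#' tandem (a family gene within `tandem_gap` positions on the same
#' chromosome), else syntenic_wgd (the genome holds a family gene at a
#' polyploidy-sister locus), else transposed (locus created by a
#' transposition), else dispersed / singleton.
#'
#' @param genomes Named list of `AnnotatedGenome` objects.
#' @param tandem_gap Maximum ordinal distance for a tandem call.
#' @return data.frame with `genome_id`, `gene_id`, `uid`, `truth_type`.
#' @export
truth_duplication_types <- function(genomes, tandem_gap = 5) {
  out <- lapply(genomes, function(g) {
    fam <- g$genes[g$genes$is_family, , drop = FALSE]
    if (!nrow(fam)) return(NULL)
    base_locus <- sub("/d[0-9]+$", "", fam$locus)
    type <- character(nrow(fam))
    for (i in seq_len(nrow(fam))) {
      same_chr <- fam$chrom == fam$chrom[i]
      tandem <- any(same_chr & fam$gene_id != fam$gene_id[i] &
                    abs(fam$ordinal - fam$ordinal[i]) <= tandem_gap)
      wgd_sister <- any(base_locus == base_locus[i] &
                        fam$locus != fam$locus[i] &
                        !startsWith(base_locus, "T:"))
      if (tandem) type[i] <- "tandem"
      else if (wgd_sister) type[i] <- "syntenic_wgd"
      else if (startsWith(fam$locus[i], "T:")) type[i] <- "transposed"
      else if (nrow(fam) > 1) type[i] <- "dispersed"
      else type[i] <- "singleton"
    }
    data.frame(genome_id = g$genome_id, gene_id = fam$gene_id,
               uid = paste(g$genome_id, fam$gene_id, sep = ":"),
               truth_type = type, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out[!vapply(out, is.null, TRUE)],
                   list(make.row.names = FALSE)))
}

# ------------------------------------------------------------- scenarios ----

#' Default simulation with guaranteed event content
#'
#' Draws simulations from [sim_config()] defaults under sub-seeds derived
#' from `seed` until the realised history contains at least 5 tandem
#' duplications, 3 transposed duplications and one retained polyploidy
#' duplicate, and every leaf keeps at least 2 family genes.  This
#' conditions the Poisson draw on the scenario the acceptance tests
#' describe without changing any rate.
#'
#' @param seed Integer seed.
#' @param max_tries Attempts before giving up.
#' @return As [evolve()], plus `attempt`.
#' @export
simulate_default <- function(seed = 1, max_tries = 50) {
  for (k in seq_len(max_tries)) {
    cfg <- sim_config(seed = substream_seed(seed, "default-sim", k))
    sim <- evolve(default_tree(), cfg)
    ev <- sim$log$events
    n_tan <- sum(ev$kind == "tandem_dup")
    n_trn <- sum(ev$kind == "transposed_dup")
    n_wgd <- sum(vapply(sim$genomes, function(g)
      any(g$genes$origin == "wgd" & g$genes$is_family), TRUE))
    fam_ok <- all(vapply(sim$genomes,
                         function(g) sum(g$genes$is_family) >= 2, TRUE))
    if (n_tan >= 5 && n_trn >= 3 && n_wgd >= 1 && fam_ok) {
      sim$attempt <- k
      # desk-scale analysis settings: the reference 25-gene window assumes
      # chromosomes of thousands of genes; on ~80-gene chromosomes the
      # proportional context radius is a few genes
      sim$analysis <- list(window = 3, k = 3, tandem_gap = 5)
      return(sim)
    }
  }
  stop("no qualifying simulation in ", max_tries, " attempts")
}

#' Planted gene-fusion scenario
#'
#' Two donor lineages (A and B) at the given inter-lineage divergence and
#' a focal group of chimeras whose before/after segments descend from
#' lineage A and whose domain segment descends from lineage B.
#'
#' @param seed Integer seed.
#' @param divergence Expected fraction of differing sites between the two
#'   lineage ancestors.
#' @param n_per_group Genes per group.
#' @param within_p Within-lineage per-site divergence.
#' @param cfg [sim_config()] supplying segment lengths.
#' @return List of `focal`, `donorA`, `donorB` segment-triplet data.frames
#'   (columns `gene_id`, `before`, `domain`, `after`) and `truth`, the
#'   per-segment donor (`before = "donorA"`, `domain = "donorB"`,
#'   `after = "donorA"`).
#' @export
simulate_fusion_scenario <- function(seed = 1, divergence = 0.2,
                                     n_per_group = 5, within_p = 0.03,
                                     cfg = sim_config()) {
  blocks <- family_blocks(cfg)
  with_seed(substream_seed(seed, "fusion-scenario"), {
    f1 <- random_protein(cfg$len_flank1)
    f2 <- random_protein(cfg$len_flank2)
    anc <- paste0(f1, blocks$hmgl, f2)
    s <- cfg$len_flank1
    e <- cfg$len_flank1 + cfg$len_hmgl
    ancA <- mutate_protein(anc, divergence / 2)
    ancB <- mutate_protein(anc, divergence / 2)
    draw_group <- function(ancestor, prefix) {
      data.frame(gene_id = sprintf("%s%d", prefix, seq_len(n_per_group)),
                 protein = vapply(seq_len(n_per_group), function(i)
                   mutate_protein(ancestor, within_p), ""),
                 stringsAsFactors = FALSE)
    }
    ga <- draw_group(ancA, "A")
    gb <- draw_group(ancB, "B")
    gf <- data.frame(gene_id = sprintf("F%d", seq_len(n_per_group)),
                     protein = vapply(seq_len(n_per_group), function(i)
                       make_chimera(mutate_protein(ancA, within_p),
                                    mutate_protein(ancB, within_p),
                                    c(s, e)), ""),
                     stringsAsFactors = FALSE)
    triplets <- function(df) {
      data.frame(gene_id = df$gene_id,
                 before = substr(df$protein, 1, s),
                 domain = substr(df$protein, s + 1, e),
                 after = substr(df$protein, e + 1, nchar(df$protein)),
                 stringsAsFactors = FALSE)
    }
    list(focal = triplets(gf), donorA = triplets(ga), donorB = triplets(gb),
         truth = c(before = "donorA", domain = "donorB", after = "donorA"))
  })
}

#' Planted dosage scenario: polyploidy with compensatory loss
#'
#' A two-genome clade in which one genome undergoes a whole-genome
#' triplication after which the IPMS-architecture locus is retained in
#' duplicate while the MAM locus suffers compensatory losses, ending one
#' gene below its ancestral count.
#'
#' @param seed Integer seed.
#' @return As [evolve()], plus `baseline`, the ancestral per-locus family
#'   counts.
#' @export
simulate_dosage_scenario <- function(seed = 1) {
  fam <- data.frame(chrom = c("chr1", "chr2", "chr2"),
                    architecture = c("IPMS-like", "MAM-like", "MAM-like"),
                    locus = c("L1", "L2", "L2"),
                    stringsAsFactors = FALSE)
  planted <- list(
    list(kind = "loss", branch = "GG", locus = "L1/d3"),
    list(kind = "loss", branch = "GG", locus = "L2/d2"),
    list(kind = "loss", branch = "GG", locus = "L2/d2"),
    list(kind = "loss", branch = "GG", locus = "L2/d3"),
    list(kind = "loss", branch = "GG", locus = "L2/d3"),
    list(kind = "loss", branch = "GG", locus = "L2"))
  cfg <- sim_config(family_loci = fam,
                    rate_tandem = 0, rate_transposed = 0, rate_loss = 0,
                    rate_fusion = 0, p_domain_loss = 0,
                    wgd_events = list(list(branch = "GG", multiplier = 3)),
                    wgd_retention = 1,
                    planted_events = planted,
                    seed = substream_seed(seed, "dosage-scenario"))
  sim <- evolve("(CV:0.08,GG:0.08)root:0.01;", cfg)
  sim$baseline <- c(L1 = 1, L2 = 2)
  sim
}

# ------------------------------------------------------------ seed aligns ----

#' Simulate a seed alignment for a domain profile
#'
#' Independent diverged copies of an ancestral domain block; rows are
#' ungapped and equal length, ready for [build_profile()].
#'
#' @param cfg [sim_config()] list (provides the blocks and seed).
#' @param domain `"hmgl"` or `"leua"`.
#' @param n Number of rows.
#' @param divergence Per-site divergence of each row from the block.
#' @return Named character vector of aligned rows.
#' @export
simulate_seed_alignment <- function(cfg, domain = c("hmgl", "leua"), n = 10,
                                    divergence = 0.1) {
  domain <- match.arg(domain)
  block <- family_blocks(cfg)[[domain]]
  with_seed(substream_seed(cfg$seed, "seed-aln", domain), {
    setNames(vapply(seq_len(n), function(i)
      mutate_protein(block, divergence), ""),
      sprintf("%s_seed%d", domain, seq_len(n)))
  })
}
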