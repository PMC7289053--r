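# Independent event-log replay: rebuilds every leaf genome from the
# ancestor plus the EventLog (events give chromosome and position; the
# substitution substream is regenerated from the top-level seed).  This is
# written against the documented event semantics, not the simulator code.

oracle_replay <- function(sim) {
  log <- sim$log
  cfg <- log$cfg
  st <- log$tree
  ev <- log$events
  anc <- sim$ancestor$genes
  # state: chrom -> data.frame(gene_id, protein, leua_start, leua_end,
  #                            hmgl_start, hmgl_end)
  cols <- c("gene_id", "protein", "hmgl_start", "hmgl_end", "leua_start",
            "leua_end")
  state0 <- split(anc[, cols], anc$chrom)
  leaves <- list()

  canon_chroms <- function(state) sort(names(state), method = "radix")

  apply_subst <- function(state, branch, t) {
    chroms <- canon_chroms(state)
    prots <- unlist(lapply(chroms, function(ch) state[[ch]]$protein),
                    use.names = FALSE)
    mut <- apply_branch_substitutions(prots, branch, t, cfg$seed)
    k <- 0
    for (ch in chroms) {
      nn <- nrow(state[[ch]])
      if (nn) state[[ch]]$protein <- mut[k + seq_len(nn)]
      k <- k + nn
    }
    state
  }

  find_gene <- function(state, gid) {
    for (ch in names(state)) {
      w <- which(state[[ch]]$gene_id == gid)
      if (length(w)) return(list(chrom = ch, row = w[1]))
    }
    stop("replay: gene not found: ", gid)
  }

  apply_events <- function(state, branch) {
    rows <- ev[ev$branch == branch & ev$kind != "speciation", ,
               drop = FALSE]
    for (r in seq_len(nrow(rows))) {
      e <- rows[r, ]
      if (e$kind == "wgd") {
        loc <- find_gene(state, e$parent_ids)
        src <- state[[loc$chrom]][loc$row, , drop = FALSE]
        src$gene_id <- e$child_ids
        if (is.null(state[[e$chrom]]))
          state[[e$chrom]] <- src[0, , drop = FALSE]
        df <- state[[e$chrom]]
        stopifnot(e$position == nrow(df) + 1) # children logged in order
        state[[e$chrom]] <- rbind(df, src)
      } else if (e$kind %in% c("tandem_dup", "transposed_dup")) {
        loc <- find_gene(state, e$parent_ids)
        src <- state[[loc$chrom]][loc$row, , drop = FALSE]
        src$gene_id <- e$child_ids
        df <- state[[e$chrom]]
        at <- e$position
        if (e$kind == "tandem_dup") {
          # tandem children sit immediately after their parent at birth
          stopifnot(e$chrom == loc$chrom, at == loc$row + 1)
        }
        state[[e$chrom]] <-
          if (at <= 1) rbind(src, df)
          else if (at > nrow(df)) rbind(df, src)
          else rbind(df[1:(at - 1), , drop = FALSE], src,
                     df[at:nrow(df), , drop = FALSE])
      } else if (e$kind == "loss") {
        loc <- find_gene(state, e$parent_ids)
        state[[loc$chrom]] <- state[[loc$chrom]][-loc$row, , drop = FALSE]
      } else if (e$kind == "domain_loss") {
        loc <- find_gene(state, e$parent_ids)
        g <- state[[loc$chrom]][loc$row, , drop = FALSE]
        p <- g$protein
        g$protein <- paste0(substr(p, 1, g$leua_start),
                            substr(p, g$leua_end + 1, nchar(p)))
        g$leua_start <- NA_integer_
        g$leua_end <- NA_integer_
        state[[loc$chrom]][loc$row, ] <- g
      } else if (e$kind == "fusion") {
        par <- strsplit(e$parent_ids, ",", fixed = TRUE)[[1]]
        bp <- as.integer(strsplit(e$breakpoints, ";", fixed = TRUE)[[1]])
        la <- find_gene(state, par[1])
        lb <- find_gene(state, par[2])
        a <- state[[la$chrom]]$protein[la$row]
        b <- state[[lb$chrom]]$protein[lb$row]
        # hand splice: a[1..bp1] + b[bp1+1..bp2] + a[bp2+1..]
        chim <- paste0(substr(a, 1, bp[1]), substr(b, bp[1] + 1, bp[2]),
                       substr(a, bp[2] + 1, nchar(a)))
        state[[la$chrom]]$gene_id[la$row] <- e$child_ids
        state[[la$chrom]]$protein[la$row] <- chim
      } else stop("replay: unknown event kind ", e$kind)
    }
    state
  }

  walk <- function(state, node_label) {
    kids <- st$branches[st$branches$parent == node_label, , drop = FALSE]
    if (!nrow(kids)) {
      leaves[[node_label]] <<- state
      return(invisible(NULL))
    }
    for (i in seq_len(nrow(kids))) {
      b <- kids[i, ]
      s2 <- apply_events(state, b$id)
      s2 <- apply_subst(s2, b$id, b$length)
      walk(s2, b$child)
    }
  }

  state <- state0
  if (st$stem_length > 0) {
    state <- apply_events(state, "stem")
    state <- apply_subst(state, "stem", st$stem_length)
  }
  walk(state, st$root_label)
  leaves
}

# compare a replayed state against a simulated leaf genome: identical
# chromosome sets, gene orders, and protein sequences
expect_replay_equal <- function(replayed, genome) {
  g <- genome$genes
  chroms <- sort(unique(g$chrom), method = "radix")
  got <- sort(names(replayed)[vapply(replayed, nrow, 0L) > 0],
              method = "radix")
  expect_identical(got, chroms)
  for (ch in chroms) {
    sim_df <- g[g$chrom == ch, , drop = FALSE]
    rep_df <- replayed[[ch]]
    expect_identical(rep_df$gene_id, sim_df$gene_id)
    expect_identical(rep_df$protein, sim_df$protein)
  }
}
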