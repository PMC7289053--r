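test_that("ancestral genome construction honours the config", {
  cfg <- sim_config(n_chromosomes = 1, n_background_genes = 50,
                    family_loci = data.frame(chrom = "chr1",
                                             architecture = "IPMS-like",
                                             locus = "L1"),
                    seed = 3)
  g <- build_ancestral_genome(cfg)
  expect_equal(nrow(g$genes), 51)
  fam <- g$genes[g$genes$is_family, ]
  expect_equal(nrow(fam), 1)
  expect_true(fam$has_hmgl && fam$has_leua)
  # protein length is the sum of the declared segment lengths
  expect_equal(nchar(fam$protein),
               cfg$len_flank1 + cfg$len_hmgl + cfg$len_linker +
                 cfg$len_leua + cfg$len_flank2)
  # domain blocks sit at their declared coordinates
  blocks <- family_blocks(cfg)
  expect_equal(substr(fam$protein, fam$hmgl_start + 1, fam$hmgl_end),
               blocks$hmgl)
  expect_equal(substr(fam$protein, fam$leua_start + 1, fam$leua_end),
               blocks$leua)
  # gene order strictly increasing coordinates
  expect_true(all(diff(g$genes$start) > 0))
  # determinism: same seed, same genome
  expect_identical(build_ancestral_genome(cfg), g)
  expect_error(sim_config(n_background_genes = 0), "n_background_genes")
  expect_error(sim_config(rate_loss = -1), "rates")
  expect_error(sim_config(wgd_events = list(list(branch = "stem",
                                                 multiplier = 4))),
               "multiplier")
})

test_that("make_chimera splices segments as specified", {
  expect_equal(make_chimera("AAAA", "CCCC", 2), "AACC")
  expect_equal(make_chimera("AAAA", "CCCC", integer()), "AAAA")
  # alternation with two breakpoints: a, then b, then a again
  expect_equal(make_chimera("AAAAAA", "CCCCCC", c(2, 4)), "AACCAA")
  # unequal lengths: final segment comes from the active source's own end
  expect_equal(make_chimera("AA", "CCCCC", 2), "AACCC")
  expect_error(make_chimera("AAAA", "CC", 3), "beyond")
  expect_error(make_chimera("AAAA", "CCCC", c(3, 2)), "increasing")
})

test_that("pure vertical descent and clean WGD conserve gene content", {
  quiet_cfg <- small_cfg(5, rate_tandem = 0, rate_transposed = 0,
                         rate_loss = 0, wgd_events = list())
  sim <- evolve("(A:0.05,B:0.05);", quiet_cfg)
  anc <- sim$ancestor$genes
  for (g in sim$genomes) {
    expect_identical(g$genes$gene_id, anc$gene_id)
    expect_identical(g$genes$chrom, anc$chrom)
    expect_equal(nchar(g$genes$protein), nchar(anc$protein))
  }
  # only speciation markers in the log
  expect_true(all(sim$log$events$kind == "speciation"))

  wgd_cfg <- small_cfg(5, rate_tandem = 0, rate_transposed = 0,
                       rate_loss = 0, wgd_retention = 1,
                       p_domain_loss = 0,
                       wgd_events = list(list(branch = "stem",
                                              multiplier = 2)))
  sim2 <- evolve(default_tree(), wgd_cfg)
  for (g in sim2$genomes)
    expect_equal(nrow(g$genes), 2 * nrow(anc))
  # triplication gives 3x
  wgt_cfg <- small_cfg(5, rate_tandem = 0, rate_transposed = 0,
                       rate_loss = 0, wgd_retention = 1,
                       p_domain_loss = 0,
                       wgd_events = list(list(branch = "stem",
                                              multiplier = 3)))
  sim3 <- evolve("(A:0.02,B:0.02)root:0.01;", wgt_cfg)
  expect_equal(nrow(sim3$genomes$A$genes), 3 * nrow(anc))
})

test_that("event-log replay reconstructs every leaf genome exactly", {
  for (seed in c(1, 11)) {
    sim <- evolve(default_tree(),
                  small_cfg(seed, rate_fusion = 2, p_domain_loss = 0.5))
    expect_gt(nrow(sim$log$events), 6) # events beyond speciation markers
    replayed <- oracle_replay(sim)
    for (leaf in names(sim$genomes))
      expect_replay_equal(replayed[[leaf]], sim$genomes[[leaf]])
  }
})

test_that("count conservation holds per leaf against the log", {
  sim <- cached_small_sim(2)
  ev <- sim$log$events
  st <- sim$log$tree
  path_to <- function(leaf) {
    out <- leaf
    cur <- leaf
    repeat {
      up <- st$branches$parent[st$branches$id == cur]
      if (!length(up)) break
      cur <- up
      if (cur == st$root_label) break
      out <- c(out, cur)
    }
    c(out, "stem")
  }
  anc_n <- nrow(sim$ancestor$genes)
  for (leaf in names(sim$genomes)) {
    br <- path_to(leaf)
    on_path <- ev[ev$branch %in% br, , drop = FALSE]
    gains <- sum(on_path$kind %in% c("wgd", "tandem_dup", "transposed_dup"))
    losses <- sum(on_path$kind == "loss")
    expect_equal(nrow(sim$genomes[[leaf]]$genes), anc_n + gains - losses)
  }
})

test_that("branch event counts are Poisson with mean rate x length", {
  # one family gene, one branch of length 0.5, rate 2 => mean 1 per branch
  cfg <- sim_config(n_chromosomes = 1, n_background_genes = 2,
                    bg_len_range = c(30, 40),
                    len_flank1 = 5, len_hmgl = 20, len_linker = 4,
                    len_leua = 15, len_flank2 = 5,
                    family_loci = data.frame(chrom = "chr1",
                                             architecture = "IPMS-like",
                                             locus = "L1"),
                    rate_tandem = 2, rate_transposed = 0, rate_loss = 0,
                    wgd_events = list(), seed = 1)
  r <- 2; t <- 0.5
  counts <- vapply(1:200, function(i) {
    cfg$seed <- i
    sim <- evolve("(A:0.5,B:0.001);", cfg)
    sum(sim$log$events$kind == "tandem_dup" & sim$log$events$branch == "A")
  }, 0)
  mu <- r * t
  se <- sqrt(mu / 200) # Poisson variance = mean
  expect_lt(abs(mean(counts) - mu), 3 * se)
})

test_that("the default simulation carries the stated event content", {
  sim <- simulate_default(4)
  ev <- sim$log$events
  expect_gte(sum(ev$kind == "tandem_dup"), 5)
  expect_gte(sum(ev$kind == "transposed_dup"), 3)
  expect_length(sim$genomes, 4)
  expect_true(all(vapply(sim$genomes,
                         function(g) sum(g$genes$is_family) >= 2, TRUE)))
  # byte-identical under a fixed seed
  sim2 <- simulate_default(4)
  expect_identical(sim$genomes, sim2$genomes)
  expect_identical(sim$log$events, sim2$log$events)
})

test_that("truth maps follow the hidden state", {
  sim <- cached_small_sim(2)
  g <- sim$genomes[[1]]
  arch <- truth_architectures(g)
  expect_setequal(unique(unname(arch)), intersect(
    c("IPMS-like", "MAM-like", "none"), unique(unname(arch))))
  expect_true(all(arch[!g$genes$is_family] == "none"))
  td <- truth_duplication_types(sim$genomes)
  expect_true(all(td$truth_type %in%
                  c("tandem", "syntenic_wgd", "transposed", "dispersed",
                    "singleton")))
})
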