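test_that("segment splitting is an exact partition", {
  prot <- strrep("ACDEFGHIKL", 30) # 300 aa
  hit <- data.frame(start = 100L, end = 220L)
  tri <- split_segments(prot, hit, "g1")
  expect_equal(nchar(tri$before), 100)
  expect_equal(nchar(tri$domain), 120)
  expect_equal(nchar(tri$after), 80)
  expect_equal(paste0(tri$before, tri$domain, tri$after), prot)
  # domain spanning the whole protein: empty flanks are legal
  tri2 <- split_segments("ACDEF", data.frame(start = 0L, end = 5L), "g2")
  expect_equal(tri2$before, "")
  expect_equal(tri2$after, "")
  expect_error(split_segments(prot, hit[0, ], "g"), "no domain hit")
  expect_warning(out <- split_segments(prot, rbind(hit, hit), "g"),
                 "excluded")
  expect_null(out)
  # concatenation identity on simulated family genes
  sim <- cached_small_sim(1)
  g <- sim$genomes$A$genes
  fam <- g[g$is_family, ][1, ]
  tri3 <- split_segments(fam$protein,
                         data.frame(start = fam$hmgl_start,
                                    end = fam$hmgl_end), fam$gene_id)
  expect_equal(paste0(tri3$before, tri3$domain, tri3$after), fam$protein)
})

test_that("fusion test attributes segments and flags chimerism", {
  sc <- simulate_fusion_scenario(seed = 3)
  v <- fusion_test(sc$focal, sc$donorA, sc$donorB)
  expect_true(v$fusion_flagged)
  verd <- setNames(v$table$verdict, v$table$segment)
  expect_equal(unname(verd["domain"]), "donorB")
  expect_equal(unname(verd["before"]), "donorA")
  expect_equal(unname(verd["after"]), "donorA")
  # label symmetry: swapping the donors swaps verdicts, p unchanged
  vs <- fusion_test(sc$focal, sc$donorB, sc$donorA)
  expect_equal(vs$table$p_value, v$table$p_value, tolerance = 1e-12)
  flip <- c(donorA = "donorB", donorB = "donorA",
            indistinguishable = "indistinguishable")
  expect_equal(unname(flip[v$table$verdict]), vs$table$verdict)
})

test_that("identical and label-shuffled donors give the stated verdicts", {
  sc <- simulate_fusion_scenario(seed = 4)
  # focal identical to donorA throughout: all segments donorA, no flag
  v <- fusion_test(sc$donorA, sc$donorA, sc$donorB)
  expect_false(v$fusion_flagged)
  expect_true(all(v$table$verdict %in% c("donorA", "indistinguishable")))
  expect_true(any(v$table$verdict == "donorA"))
  # donors drawn from one pool: indistinguishable
  pool <- rbind(sc$donorA, sc$donorA)
  v2 <- fusion_test(sc$focal, pool[1:5, ], pool[6:10, ])
  expect_true(all(v2$table$verdict == "indistinguishable"))
  expect_error(fusion_test(sc$focal[0, ], sc$donorA, sc$donorB),
               ">= 1 gene")
})

test_that("conservation summary applies the modal-frequency rule", {
  expect_equal(conservation_summary(c("ACDE", "ACDE", "ACDE"))$score, 1)
  # column with 4/5 identical at threshold 0.8: conserved (boundary >=)
  rows <- c("A", "A", "A", "A", "C")
  expect_true(conservation_summary(rows, 0.8)$conserved[1])
  # 3/5 is not
  rows2 <- c("A", "A", "A", "C", "C")
  expect_false(conservation_summary(rows2, 0.8)$conserved[1])
  # single row: degenerate score 1
  d <- conservation_summary("ACDE")
  expect_true(d$degenerate)
  expect_equal(d$score, 1)
  # row-order invariance and threshold monotonicity
  set.seed(61)
  aln <- vapply(1:6, function(i)
    paste(sample(c("A", "C", "G"), 40, replace = TRUE,
                 prob = c(0.7, 0.2, 0.1)), collapse = ""), "")
  s1 <- conservation_summary(aln, 0.8)$score
  expect_equal(conservation_summary(sample(aln), 0.8)$score, s1)
  scores <- vapply(c(0.5, 0.6, 0.8, 0.9, 1),
                   function(th) conservation_summary(aln, th)$score, 0)
  expect_true(all(diff(scores) <= 0))
})

test_that("slow clades score as more conserved than fast clades", {
  wins <- vapply(1:10, function(s) {
    set.seed(700 + s)
    anc <- random_protein_str(80)
    slow <- vapply(1:5, function(i) mutate_protein(anc, 0.03), "")
    fast <- vapply(1:5, function(i) mutate_protein(anc, 0.3), "")
    conservation_summary(slow, 0.8)$score >
      conservation_summary(fast, 0.8)$score
  }, TRUE)
  expect_true(all(wins))
})

test_that("duplication cascade resolves rule order deterministically", {
  # toy genome: tandem pair (g1,g2 adjacent), WGD pair (g3 on chr1,
  # g4 on chr2 linked intra-genome), transposed singleton-context g5
  gA <- toy_genome("A", c("chr1", "chr1", "chr2", "chr3", "chr4"),
                   paste0("g", 1:5))
  subnet <- list(nodes = NULL,
                 edges = data.frame(from = "A:g3", to = "A:g4",
                                    blocks = "B0001"),
                 blocks = NULL, gene_index = NULL)
  comms <- list(structure(list(community_id = "C01",
                               members = c("A:g3", "A:g4", "B:x"), k = 3),
                          class = "CliqueCommunity"))
  hits <- data.frame(query = paste0("A:g", c(1, 2, 3, 4, 5)),
                     subject = paste0("A:g", c(2, 1, 4, 3, 1)))
  calls <- classify_duplications(paste0("A:g", 1:5), subnet, comms,
                                 list(gA), hits, tandem_gap = 5)
  got <- setNames(calls$type, calls$uid)
  expect_equal(unname(got["A:g1"]), "tandem")
  expect_equal(unname(got["A:g2"]), "tandem")
  expect_equal(unname(got["A:g3"]), "syntenic_wgd")
  expect_equal(unname(got["A:g4"]), "syntenic_wgd")
  expect_equal(unname(got["A:g5"]), "transposed")
  # tandem outranks wgd evidence: g1 adjacent to g2 AND in a community
  comms2 <- c(comms, list(structure(list(community_id = "C02",
                                         members = c("A:g1", "A:g2",
                                                     "B:y"), k = 3),
                                    class = "CliqueCommunity")))
  calls2 <- classify_duplications(paste0("A:g", 1:5), subnet, comms2,
                                  list(gA), hits, 5)
  expect_equal(calls2$type[calls2$uid == "A:g1"], "tandem")
  # no homolog at all: singleton
  calls3 <- classify_duplications("A:g5", subnet, list(), list(gA),
                                  hits[0, ], 5)
  expect_equal(calls3$type, "singleton")
})

test_that("dosage profile counts loci and flags compensatory change", {
  sim <- simulate_dosage_scenario(1)
  genes <- syntegraph:::gene_table(sim$genomes)
  arch <- setNames(ifelse(genes$is_family & genes$has_leua, "IPMS-like",
                   ifelse(genes$is_family, "MAM-like", "none")),
                   genes$uid)
  # truth loci as community stand-ins
  loci <- split(genes$uid[genes$is_family],
                sub("/d[0-9]+$", "", genes$locus[genes$is_family]))
  prof <- dosage_profile(sim$genomes, loci, arch, baseline = sim$baseline)
  # CV keeps the ancestral counts; GG gained one IPMS and lost one MAM
  expect_equal(unname(prof$deltas["CV", c("L1", "L2")]), c(0, 0))
  expect_equal(unname(prof$deltas["GG", c("L1", "L2")]), c(1, -1))
  expect_equal(nrow(prof$anticorrelated), 1)
  # counts + unassigned add up to the family size in every genome
  for (gid in names(sim$genomes)) {
    fam_n <- sum(sim$genomes[[gid]]$genes$is_family)
    pp <- prof$profiles[prof$profiles$genome_id == gid, ]
    expect_equal(sum(pp$n_genes), fam_n)
  }
  # no events: all deltas zero
  quiet <- evolve("(A:0.02,B:0.02);",
                  small_cfg(2, rate_tandem = 0, rate_transposed = 0,
                            rate_loss = 0, wgd_events = list()))
  g2 <- syntegraph:::gene_table(quiet$genomes)
  arch2 <- setNames(ifelse(g2$is_family & g2$has_leua, "IPMS-like",
                    ifelse(g2$is_family, "MAM-like", "none")), g2$uid)
  loci2 <- split(g2$uid[g2$is_family], g2$locus[g2$is_family])
  prof2 <- dosage_profile(quiet$genomes, loci2, arch2,
                          baseline = c(L1 = 1, L2 = 1))
  expect_true(all(prof2$deltas == 0))
})
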