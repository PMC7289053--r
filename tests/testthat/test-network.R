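mk_block_row <- function(id, ga, ca, gb, cb, pairs) {
  data.frame(block_id = id, genome_a = ga, chrom_a = ca, genome_b = gb,
             chrom_b = cb, orientation = "same",
             n_anchors = length(pairs),
             block_score = 10 * length(pairs),
             anchors = paste(pairs, collapse = " "),
             stringsAsFactors = FALSE)
}

test_that("network assembly creates one edge per anchored pair", {
  gA <- toy_genome("A", rep("chr1", 5), paste0("g", 1:5))
  gB <- toy_genome("B", rep("chr1", 5), paste0("g", 1:5))
  pairs <- paste0("A:g", 1:5, "|B:g", 1:5)
  blocks <- mk_block_row("B0001", "A", "chr1", "B", "chr1", pairs)
  net <- build_network(blocks, list(gA, gB))
  expect_equal(nrow(net$nodes), 10)
  expect_equal(nrow(net$edges), 5)
  # duplicate anchor pair in two blocks: one edge carrying both block ids
  blocks2 <- rbind(blocks,
                   mk_block_row("B0002", "A", "chr1", "B", "chr1",
                                pairs[1]))
  net2 <- build_network(blocks2, list(gA, gB))
  expect_equal(nrow(net2$edges), 5)
  e1 <- net2$edges[net2$edges$from == "A:g1", ]
  expect_equal(e1$blocks, "B0001,B0002")
  # unknown gene in an anchor is fatal
  bad <- mk_block_row("B0003", "A", "chr1", "B", "chr1", "A:zz|B:g1")
  expect_error(build_network(bad, list(gA, gB)), "unknown gene")
})

test_that("edge count equals deduplicated anchor count on simulation", {
  sim <- cached_small_sim(1)
  hits <- all_vs_all(sim$genomes)
  blocks <- collinearity_scan(sim$genomes, hits)
  net <- build_network(blocks, sim$genomes)
  all_pairs <- unlist(lapply(seq_len(nrow(blocks)), function(i) {
    m <- syntegraph:::block_anchor_pairs(blocks[i, ])
    paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  }))
  expect_equal(nrow(net$edges), length(unique(all_pairs)))
})

test_that("window rule keeps and drops subnetwork edges as specified", {
  # two genomes, 60 genes each; candidates at ordinals 30 (X) and 30 (Y)
  # with a supporting block; candidates far from any anchor lose edges
  gX <- toy_genome("X", rep("chr1", 60), sprintf("x%02d", 1:60),
                   vapply(1:60, function(i) strrep("ACDEFGHIKL", 6), ""))
  gY <- toy_genome("Y", rep("chr1", 60), sprintf("y%02d", 1:60),
                   vapply(1:60, function(i) strrep("ACDEFGHIKL", 6), ""))
  # block anchors at ordinals 0..9 on both sides
  pairs <- paste0("X:x", sprintf("%02d", 1:10), "|Y:y",
                  sprintf("%02d", 1:10))
  blocks <- mk_block_row("B0001", "X", "chr1", "Y", "chr1", pairs)
  net <- build_network(blocks, list(gX, gY))
  # candidates that are themselves anchors: edge kept
  sub1 <- extract_family_subnetwork(net, c("X:x01", "Y:y01"), 25)
  expect_equal(nrow(sub1$edges), 1)
  # candidate 40+ genes away from every anchor with window 25: dropped
  sub2 <- extract_family_subnetwork(net, c("X:x50", "Y:y50"), 25)
  expect_equal(nrow(sub2$edges), 0)
  # but kept with a window large enough to reach the block
  sub3 <- extract_family_subnetwork(net, c("X:x50", "Y:y50"), 45)
  expect_equal(nrow(sub3$edges), 1)
  # masked tandem neighbour: X:x11 is no anchor but lies within the
  # window of the block next to Y:y05
  sub4 <- extract_family_subnetwork(net, c("X:x11", "Y:y05"), 25)
  expect_equal(nrow(sub4$edges), 1)
  expect_error(extract_family_subnetwork(net, character(), 25), "empty")
})

test_that("subnetwork extraction is monotone in the window", {
  sim <- cached_small_sim(2)
  hits <- all_vs_all(sim$genomes)
  blocks <- collinearity_scan(sim$genomes, hits)
  net <- build_network(blocks, sim$genomes)
  genes <- syntegraph:::gene_table(sim$genomes)
  cand <- genes$uid[genes$is_family]
  key <- function(sub) paste(sub$edges$from, sub$edges$to)
  prev <- character()
  for (w in c(1, 3, 8, 20)) {
    cur <- key(extract_family_subnetwork(net, cand, w))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("clique percolation reproduces the CPM definition", {
  # complete graph K4 at k=3: one community with all four nodes
  k4 <- data.frame(from = c("a", "a", "a", "b", "b", "c"),
                   to = c("b", "c", "d", "c", "d", "d"))
  comms <- clique_communities(k4, 3)
  expect_length(comms, 1)
  expect_equal(comms[[1]]$members, c("a", "b", "c", "d"))
  # two triangles sharing one node: two overlapping communities
  tri2 <- data.frame(from = c("a", "a", "b", "c", "c", "d"),
                     to = c("b", "c", "c", "d", "e", "e"))
  comms2 <- clique_communities(tri2, 3)
  expect_length(comms2, 2)
  expect_true("c" %in% comms2[[1]]$members &&
              "c" %in% comms2[[2]]$members)
  # k larger than the largest clique: empty, not an error
  expect_length(clique_communities(k4, 5), 0)
  expect_error(clique_communities(k4, 1), "k must be")
})

test_that("clique percolation equals the brute-force oracle", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(6:11, 1)
    e <- random_graph_edges(n, runif(1, 0.25, 0.6))
    if (!nrow(e)) next
    for (k in c(3, 4)) {
      expect_identical(community_fingerprint(clique_communities(e, k)),
                       community_fingerprint(oracle_cpm(e, k)))
    }
  }
})

test_that("membership statistics do the arithmetic", {
  comms <- list(structure(list(community_id = "C01",
                               members = c("g1", "g2", "g3"), k = 3),
                          class = "CliqueCommunity"),
                structure(list(community_id = "C02",
                               members = c("g4", "g5", "g6", "g7",
                                           "g8", "g9", "g10"), k = 3),
                          class = "CliqueCommunity"))
  labels <- setNames(c(rep("cladeA", 3), rep("cladeB", 10)),
                     paste0("g", 1:13))
  ms <- membership_stats(comms, labels)
  expect_equal(ms$percent[ms$clade == "cladeA" & ms$community == "C01"],
               100)
  # clade B: 7 of 10 in C02, 3 of 10 (g11-13) in none
  expect_equal(ms$percent[ms$clade == "cladeB" & ms$community == "C02"],
               70)
  expect_equal(ms$percent[ms$clade == "cladeB" & ms$community == "none"],
               30)
  # a 3/7 split across two communities gives 30% and 70%
  comms2 <- list(structure(list(community_id = "C01",
                                members = paste0("g", 1:3), k = 3),
                           class = "CliqueCommunity"),
                 structure(list(community_id = "C02",
                                members = paste0("g", 4:10), k = 3),
                           class = "CliqueCommunity"))
  labels2 <- setNames(rep("clade", 10), paste0("g", 1:10))
  ms2 <- membership_stats(comms2, labels2)
  expect_setequal(round(ms2$percent), c(30, 70))
})

test_that("a conserved locus across four genomes forms one k=3 community", {
  ok <- vapply(1:8, function(s) {
    sim <- cached_small_sim(s)
    hits <- all_vs_all(sim$genomes)
    blocks <- collinearity_scan(sim$genomes, hits)
    net <- build_network(blocks, sim$genomes)
    genes <- syntegraph:::gene_table(sim$genomes)
    # the ancestral IPMS locus gene, vertically inherited in all genomes
    anc_id <- sim$ancestor$genes$gene_id[sim$ancestor$genes$is_family &
                                         sim$ancestor$genes$has_leua][1]
    locus <- genes$uid[genes$gene_id == anc_id]
    if (length(locus) < 4) return(NA)
    cand <- genes$uid[genes$is_family]
    sub <- extract_family_subnetwork(net, cand, 3)
    comms <- clique_communities(sub, 3)
    any(vapply(comms, function(cm) all(locus %in% cm$members), TRUE))
  }, TRUE)
  ok <- ok[!is.na(ok)]
  expect_gte(mean(ok), 0.9)
})
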