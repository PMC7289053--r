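test_that("center-star MSA behaves on base cases", {
  same <- setNames(rep("ACDEFGHIK", 3), paste0("s", 1:3))
  aln <- progressive_msa(same)
  expect_true(all(!grepl("-", aln, fixed = TRUE)))
  # a deletion yields exactly one gap column in the shorter sequence
  two <- c(a = "ACDE", b = "ACE")
  aln2 <- progressive_msa(two)
  expect_equal(nchar(aln2[["a"]]), 4)
  expect_equal(aln2[["a"]], "ACDE")
  expect_equal(aln2[["b"]], "AC-E")
  # ungapping recovers every input exactly
  set.seed(51)
  for (rep in 1:5) {
    fam <- setNames(vapply(1:6, function(i)
      random_protein_str(sample(30:50, 1)), ""), paste0("q", 1:6))
    a <- progressive_msa(fam)
    expect_identical(gsub("-", "", a, fixed = TRUE)[names(fam)], fam)
    expect_equal(length(unique(nchar(a))), 1)
  }
  expect_error(progressive_msa(c(a = "AC")), ">= 2")
  expect_error(progressive_msa(c(a = "AC", b = "")), "empty")
})

test_that("occupancy cleaning drops exactly the under-filled columns", {
  rows <- c(r1 = "A-CDE", r2 = "A-CD-", r3 = "A--D-", r4 = "AAC-E",
            r5 = "A-CDE")
  # column occupancies: 1.0, 0.2, 0.8, 0.8, 0.6
  cl <- clean_alignment(rows, 0.5)
  expect_equal(unname(nchar(cl[1])), 4)
  expect_equal(cl[["r1"]], "ACDE")
  # exactly 50% occupancy is kept (boundary >=)
  rows2 <- c(r1 = "AC", r2 = "A-", r3 = "AC", r4 = "A-")
  cl2 <- clean_alignment(rows2, 0.5)
  expect_equal(unname(nchar(cl2[1])), 2)
  # gap-free alignment is unchanged at any threshold
  gapfree <- c(x = "ACDE", y = "ACDF")
  expect_equal(unclass(clean_alignment(gapfree, 1))[seq_along(gapfree)],
               unclass(gapfree))
  # column count is monotone non-increasing in occupancy
  widths <- vapply(c(0.2, 0.4, 0.6, 0.8, 1),
                   function(o) nchar(clean_alignment(rows, o)[[1]]), 0)
  expect_true(all(diff(widths) <= 0))
  expect_error(clean_alignment(c(a = "--", b = "--"), 0.5), "no columns")
  expect_error(clean_alignment(rows, 0), "occupancy")
})

test_that("distance matrix applies the stated correction", {
  rows <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAC")
  D <- distance_matrix(rows)
  # p = 0.1: d = -ln(1 - 0.1 - 0.2 * 0.01) = -ln(0.898)
  expect_equal(D["a", "b"], -log(0.898), tolerance = 1e-12)
  expect_equal(D["a", "b"], 0.1076, tolerance = 1e-3)
  expect_equal(D["a", "a"], 0)
  expect_true(isSymmetric(unname(D)))
  # identical rows: zero
  expect_equal(distance_matrix(c(x = "ACD", y = "ACD"))["x", "y"], 0)
  # saturation cap
  r2 <- c(a = strrep("A", 20), b = strrep("C", 20))
  expect_equal(distance_matrix(r2)["a", "b"], 5)
  # no shared columns names the pair
  expect_error(distance_matrix(c(p = "A-", q = "-C")), "p and q")
})

test_that("neighbor joining solves small cases exactly", {
  # 3 taxa: the unique star with three-point branch lengths
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  el <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(el[["A"]], 1) # (3+4-5)/2
  expect_equal(el[["B"]], 2)
  expect_equal(el[["C"]], 3)
  # additive 4-taxon case AB|CD with internal branch 1
  tr4 <- ape::read.tree(text = "((A:1,B:2):0.5,(C:1.5,D:2.5):0.5);")
  D4 <- ape::cophenetic.phylo(tr4)
  got <- nj_tree(D4)
  expect_true(same_topology(got, tr4))
  # exact branch lengths: total tree length is preserved
  expect_equal(sum(got$edge.length), sum(tr4$edge.length))
  # permuting taxa does not change the topology
  perm <- sample(4)
  got2 <- nj_tree(D4[perm, perm])
  expect_true(same_topology(got2, got))
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2,
                              dimnames = list(c("a", "b"), c("a", "b")))),
               "symmetric|taxa")
})

test_that("NJ is consistent on additive matrices", {
  set.seed(52)
  for (rep in 1:10) {
    case <- random_additive_case(sample(5:12, 1))
    expect_true(same_topology(nj_tree(case$D), case$tree))
  }
})

test_that("bootstrap supports are percentages with exact determinism", {
  set.seed(53)
  base <- random_protein_str(120)
  grp <- function(p, pre) setNames(vapply(1:3, function(i)
    mutate_protein(base, p), ""), paste0(pre, 1:3))
  seqs <- c(with_seed(1, grp(0.03, "a")), with_seed(2, grp(0.25, "b")))
  aln <- progressive_msa(seqs)
  b1 <- bootstrap_support(aln, n_reps = 20, seed = 5)
  b2 <- bootstrap_support(aln, n_reps = 20, seed = 5)
  expect_identical(b1$supports, b2$supports)
  expect_true(all(b1$supports >= 0 & b1$supports <= 100))
  # a single replicate can only give 0 or 100
  b3 <- bootstrap_support(aln, n_reps = 1, seed = 6)
  expect_true(all(b3$supports %in% c(0, 100)))
})

test_that("a clean split gets high support", {
  ok <- vapply(1:5, function(s) {
    set.seed(600 + s)
    anc <- random_protein_str(150)
    left <- mutate_protein(anc, 0.35)
    seqs <- c(setNames(vapply(1:3, function(i) mutate_protein(anc, 0.02),
                              ""), paste0("L", 1:3)),
              setNames(vapply(1:3, function(i) mutate_protein(left, 0.02),
                              ""), paste0("R", 1:3)))
    b <- bootstrap_support(progressive_msa(seqs), n_reps = 50,
                           seed = 600 + s)
    focal <- b$supports[paste(sort(c("L1", "L2", "L3")), collapse = ",")]
    if (is.na(focal)) focal <- b$supports[
      paste(sort(c("R1", "R2", "R3")), collapse = ",")]
    !is.na(focal) && focal >= 95
  }, TRUE)
  expect_gte(mean(ok), 0.8)
})

test_that("clade assignment anchors on exemplars", {
  tr <- ape::read.tree(text = "(((a1:1,a2:1):2,(b1:1,b2:1):2):1,out:3);")
  boot <- list(tree = tr,
               supports = setNames(rep(100, length(tree_splits(tr))),
                                   tree_splits(tr)))
  res <- assign_clades(boot, c(a1 = "A", b1 = "B"), min_support = 70)
  expect_equal(unname(res$assignment[c("a1", "a2")]), c("A", "A"))
  expect_equal(unname(res$assignment[c("b1", "b2")]), c("B", "B"))
  expect_equal(unname(res$assignment["out"]), "unresolved")
  # impossible support threshold: everything unresolved or trivial
  res2 <- assign_clades(boot, c(a1 = "A", b1 = "B"), min_support = 101)
  expect_true(all(res2$assignment[c("a2", "b2", "out")] == "unresolved"))
})

test_that("domain slicing makes the domain tree a pure input change", {
  seqs <- c("A:g1" = paste0("AAAA", "CDEFGHIK", "YYYY"))
  hits <- data.frame(uid = "A:g1", start = 4L, end = 12L)
  expect_equal(unname(domain_sequences(seqs, hits)), "CDEFGHIK")
})

test_that("a six-subfamily radiation is mostly recovered from exemplars", {
  recovered <- vapply(1:5, function(s) {
    set.seed(800 + s)
    anc <- random_protein_str(140)
    founders <- setNames(lapply(1:6, function(i) mutate_protein(anc, 0.22)),
                         letters[1:6])
    seqs <- unlist(lapply(letters[1:6], function(lb)
      setNames(vapply(1:3, function(i)
        mutate_protein(founders[[lb]], 0.02), ""),
        paste0(lb, 1:3))))
    aln <- clean_alignment(progressive_msa(seqs), 0.5)
    boot <- bootstrap_support(aln, n_reps = 50, seed = 800 + s)
    exemplars <- setNames(letters[1:6], paste0(letters[1:6], 1))
    res <- assign_clades(boot, exemplars, min_support = 70)
    sum(vapply(letters[1:6], function(lb)
      all(res$assignment[paste0(lb, 1:3)] == lb), TRUE))
  }, 0)
  expect_gte(mean(recovered >= 5), 0.8)
})
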