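test_that("gap trimming removes heavy-gap columns and maps indices back", {
  aln <- aln_from(a = "A--A", b = "C--C", c = "D-DD", d = "E--E",
                  e = "FF-F")
  tr <- trim_alignment(aln, gap_fraction_max = 0.5)
  expect_identical(tr$index_map, c(1L, 4L))
  expect_identical(tr$alignment$seqs[["a"]], "AA")
  gapless <- random_aln(4, 10, gap_rate = 0, seed = 2)
  expect_identical(trim_alignment(gapless)$alignment$seqs, gapless$seqs)
  allgap <- aln_from(a = "--", b = "--")
  expect_error(trim_alignment(allgap, 0.5), "nothing left")
})

test_that("JTT distances are zero for identical pairs and grow with divergence", {
  s <- paste(rep("ACDEFGHIKL", 20), collapse = "")
  expect_equal(jtt_distance(s, s), 0, tolerance = 1e-9)
  # progressively mutate a fraction of sites
  base <- strsplit(s, "")[[1]]
  d_at <- function(k) {
    mut <- base
    mut[seq_len(k)] <- rep(c("W", "Y", "M", "R"), length.out = k)
    jtt_distance(s, paste(mut, collapse = ""))
  }
  dists <- vapply(c(5, 20, 50, 100), d_at, 0)
  expect_true(all(diff(dists) > 0))
  expect_error(jtt_distance("A--", "-A-"), "no co-non-gap")
})

test_that("neighbor joining reproduces the additive 4-taxon tree exactly", {
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 5
  d["A", "D"] <- d["D", "A"] <- 6
  d["B", "C"] <- d["C", "B"] <- 6
  d["B", "D"] <- d["D", "B"] <- 7
  d["C", "D"] <- d["D", "C"] <- 7
  tr <- neighbor_joining(d)
  co <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(co, d, tolerance = 1e-9)
  ref <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:4);")
  expect_equal(as.numeric(ape::dist.topo(tr, ref)), 0)
  # three taxa: closed-form star resolution
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr3 <- neighbor_joining(d3)
  co3 <- ape::cophenetic.phylo(tr3)[rownames(d3), colnames(d3)]
  expect_equal(co3, d3, tolerance = 1e-9)
  expect_error(neighbor_joining(d3[1:2, 1:2]), "3 taxa")
})

test_that("NJ recovers topology and path lengths from random additive matrices", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(5:8, 1)
    tr <- ape::unroot(ape::rtree(n, br = function(k) runif(k, 0.1, 1)))
    d <- ape::cophenetic.phylo(tr)
    est <- neighbor_joining(d)
    expect_equal(as.numeric(ape::dist.topo(tr, est)), 0)
    expect_equal(ape::cophenetic.phylo(est)[rownames(d), colnames(d)], d,
                 tolerance = 1e-9)
  }
})

test_that("NJ is invariant to taxon input order up to relabeling", {
  set.seed(23)
  tr <- ape::unroot(ape::rtree(6, br = function(k) runif(k, 0.1, 1)))
  d <- ape::cophenetic.phylo(tr)
  perm <- sample(rownames(d))
  t1 <- neighbor_joining(d)
  t2 <- neighbor_joining(d[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(t1, t2)), 0)
})

test_that("column bootstrap is seed-deterministic", {
  # random sequences are saturated, so the d_max cap fires by design
  aln <- random_aln(6, 60, gap_rate = 0, seed = 31)
  b1 <- suppressWarnings(bootstrap_trees(aln, n = 4, seed = 42))
  b2 <- suppressWarnings(bootstrap_trees(aln, n = 4, seed = 42))
  expect_identical(lapply(b1, ape::write.tree), lapply(b2, ape::write.tree))
  expect_identical(bootstrap_trees(aln, n = 0, seed = 1), list())
})

test_that("majority consensus keeps only splits above 50% with correct supports", {
  t1 <- ape::read.tree(text = "((A,B),(C,D),E);")
  t2 <- ape::read.tree(text = "((A,C),(B,D),E);")
  t3 <- ape::read.tree(text = "((A,D),(B,C),E);")
  # identical inputs: same topology, every split at 100
  same <- majority_consensus(list(t1, t1, t1))
  expect_equal(as.numeric(ape::dist.topo(same, t1)), 0)
  expect_true(all(same$node.label[nzchar(same$node.label)] == "100"))
  # two trees disagreeing on a split: the split is dropped (strict rule)
  half <- majority_consensus(list(t1, t2))
  expect_identical(half$Nnode, 1L)
  # 60/20/20 multiset: majority splits retained at 60
  mix <- majority_consensus(c(rep(list(t1), 6), rep(list(t2), 2),
                              rep(list(t3), 2)))
  expect_equal(as.numeric(ape::dist.topo(mix, t1)), 0)
  expect_setequal(mix$node.label[nzchar(mix$node.label)], "60")
  t_bad <- ape::read.tree(text = "((A,B),(C,F),E);")
  expect_error(majority_consensus(list(t1, t_bad)), "mismatched")
})

test_that("Newick I/O round-trips lengths and parses supports; malformed input errors", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:2):1,C:3,D:4);", path)
  tr <- read_newick(path)
  write_newick(tr, path)
  back <- read_newick(path)
  expect_equal(sort(back$edge.length), sort(tr$edge.length),
               tolerance = 1e-9)
  supp <- parse_newick("((A:1,B:2)85:0.1,C:3,D:4);")
  expect_true("85" %in% supp$node.label)
  expect_error(parse_newick("((A,B),C;"), "unbalanced")
})
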