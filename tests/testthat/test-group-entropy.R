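aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# direct arithmetic oracle for the pseudocounted frequencies
pseudo_freq <- function(counts, beta = 1, q = rep(1 / 20, 20)) {
  (counts + beta * q) / (sum(counts) + beta)
}

test_that("group frequencies follow the pseudocount formula", {
  aln <- prot_aln(setNames(c(rep("A", 10), rep("C", 10)),
                           sprintf("s%02d", 1:20)))
  part <- group_partition(setNames(rep(c("g1", "g2"), each = 10), aln$ids))
  f <- group_frequencies(aln, part, "g1", 1, beta = 1)
  expect_equal(unname(f["A"]), 10.05 / 11, tolerance = 1e-12)
  expect_equal(sum(f), 1, tolerance = 1e-12)
  f0 <- group_frequencies(aln, part, "g1", 1, beta = 0)
  expect_equal(unname(f0["A"]), 1, tolerance = 1e-12)
  expect_error(group_frequencies(aln, part, "nope", 1), "empty group")
})

test_that("group entropy is zero for matched distributions and large for disjoint ones", {
  # group and complement share the same composition -> GE = 0
  aln <- prot_aln(setNames(rep(c("A", "C"), 10), sprintf("s%02d", 1:20)))
  part <- group_partition(setNames(rep(c("g1", "g2"), each = 10), aln$ids))
  expect_equal(group_entropy(aln, part, "g1", 1), 0, tolerance = 1e-12)

  # 10 vs 10, all A against all C: brute-force the 20-term sum
  aln2 <- prot_aln(setNames(c(rep("A", 10), rep("C", 10)),
                            sprintf("s%02d", 1:20)))
  f <- pseudo_freq(setNames(replace(rep(0, 20), match("A", aa20), 10), aa20))
  r <- pseudo_freq(setNames(replace(rep(0, 20), match("C", aa20), 10), aa20))
  expected <- sum(f * log2(f / r))
  expect_equal(group_entropy(aln2, part, "g1", 1), expected,
               tolerance = 1e-12)
  expect_gt(expected, 6)   # strongly diverged composition
  expect_error(gent_scan(aln2, group_partition(
    setNames(rep("g1", 20), aln2$ids))), "2 groups")
})

test_that("group entropy grows as within-group conservation sharpens", {
  ge_at <- function(cc) {
    sim <- generate_alignment(synthetic_config(
      n_groups = 2, group_size = 25, L = 2, n_family = 0,
      n_group_specific = 1, n_class = 0, conservation = cc,
      gap_rate = 0, seed = 5))
    site <- sim$truth[sim$truth$type == "GROUP_SPECIFIC", ][1, ]
    group_entropy(sim$alignment, sim$partition, site$owner, site$index)
  }
  vals <- vapply(c(0.4, 0.6, 0.8, 0.95, 1), ge_at, 0)
  expect_true(all(diff(vals) > 0))
})

test_that("family entropy separates invariant, bimodal and uniform columns", {
  params <- gent_params()
  # one of each residue: family frequencies equal uniform background -> 0
  aln_u <- prot_aln(setNames(aa20, sprintf("s%02d", 1:20)))
  expect_equal(family_entropy(aln_u, 1, params), 0, tolerance = 1e-12)
  # invariant column with vanishing pseudocount -> log2(20)
  aln_i <- prot_aln(setNames(rep("W", 20), sprintf("s%02d", 1:20)))
  expect_equal(family_entropy(aln_i, 1, gent_params(beta = 1e-9)),
               log2(20), tolerance = 1e-6)
  # 50/50 two-residue column sits strictly below the invariant one
  aln_b <- prot_aln(setNames(rep(c("W", "F"), 10), sprintf("s%02d", 1:20)))
  expect_lt(family_entropy(aln_b, 1, params), family_entropy(aln_i, 1, params))
})

test_that("gapped columns are excluded with an explicit marker, never a silent zero", {
  # g1 is 60% gapped at the column; g2 and g3 are clean, so g1 fails its
  # own gap rule while g2/g3 see a complement at 30% gaps and stay scored
  aln <- prot_aln(setNames(c(rep("-", 6), rep("A", 4),
                             rep("C", 10), rep("D", 10)),
                           sprintf("s%02d", 1:30)))
  part <- group_partition(setNames(rep(c("g1", "g2", "g3"), each = 10),
                                   aln$ids))
  ge <- group_entropy(aln, part, "g1", 1)
  expect_true(is.na(ge))
  expect_true(attr(ge, "excluded"))
  tab <- gent_scan(aln, part)
  expect_true(tab$excluded[tab$group == "g1"])
  expect_false(tab$excluded[tab$group == "g2"])
  expect_false(tab$excluded[tab$group == "g3"])
  # strict mode: any gap anywhere excludes the column
  tab0 <- gent_scan(aln, part, gent_params(gap_max = 0))
  expect_true(all(tab0$excluded))
})

test_that("the scan is invariant to sequence order and reports other groups' residues", {
  sim <- generate_alignment(synthetic_config(
    n_groups = 3, group_size = 10, L = 40, n_family = 2,
    n_group_specific = 2, n_class = 1, seed = 7))
  tab <- gent_scan(sim$alignment, sim$partition)
  set.seed(1)
  perm <- sample(length(sim$alignment$ids))
  aln_p <- prot_aln(sim$alignment$seqs[perm])
  tab_p <- gent_scan(aln_p, sim$partition)
  ord <- function(x) x[order(x$group, x$index), ]
  expect_equal(ord(tab)$group_entropy, ord(tab_p)$group_entropy,
               tolerance = 1e-12)
  expect_identical(ord(tab)$highest_group_residue,
                   ord(tab_p)$highest_group_residue)

  # common-residue fields match a direct per-group tally
  m <- as.matrix(sim$alignment)
  for (row in sample(nrow(tab), 10)) {
    rec <- tab[row, ]
    if (rec$excluded) next
    for (o in setdiff(sim$partition$groups, rec$group)) {
      ids <- names(sim$partition$assignment)[
        sim$partition$assignment == o]
      col <- m[match(ids, sim$alignment$ids), rec$index]
      col <- col[col %in% aa20]
      if (!length(col)) next
      modal <- names(sort(table(col), decreasing = TRUE))[1]
      expect_true(startsWith(rec[[paste0("common_", o)]], modal) ||
                    grepl(modal, rec[[paste0("common_", o)]], fixed = TRUE))
    }
  }
})

test_that("shuffling group labels destroys the planted selection", {
  sim <- generate_alignment(synthetic_config(
    n_groups = 4, group_size = 25, L = 120, n_family = 4,
    n_group_specific = 5, n_class = 2, seed = 3))
  params <- gent_params(mode = "threshold", theta_g = 6, theta_f = 3)
  tab <- gent_scan(sim$alignment, sim$partition, params)
  n_real <- sum(tab$selected)
  expect_gte(n_real, 4 * 5 * 0.8)   # most planted sites selected
  set.seed(99)
  n_perm <- replicate(20, {
    shuffled <- sim$partition$assignment
    names(shuffled) <- sample(names(shuffled))
    sum(gent_scan(sim$alignment,
                  group_partition(shuffled, sim$partition$groups),
                  params)$selected)
  })
  expect_lte(mean(n_perm), 4 * 5)
  expect_lt(mean(n_perm), n_real)
})
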