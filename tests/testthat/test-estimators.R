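uniform_p <- function() setNames(rep(0.05, 20), strsplit(
  "ACDEFGHIKLMNPQRSTVWY", "")[[1]])

point_mass <- function(aa) {
  p <- setNames(rep(0, 20), names(uniform_p()))
  p[aa] <- 1
  p
}

two_mass <- function(a1, a2, w = 0.5) {
  p <- setNames(rep(0, 20), names(uniform_p()))
  p[a1] <- w; p[a2] <- 1 - w
  p
}

random_p <- function() {
  x <- rgamma(20, 0.7)
  setNames(x / sum(x), names(uniform_p()))
}

test_that("Shannon and relative entropy hit their analytic values", {
  expect_equal(shannon_entropy(point_mass("A")), 0, tolerance = 1e-12)
  expect_equal(shannon_entropy(uniform_p()), log2(20), tolerance = 1e-12)
  expect_equal(shannon_entropy(two_mass("A", "C")), 1, tolerance = 1e-12)

  expect_equal(relative_entropy(uniform_p(), uniform_p()), 0,
               tolerance = 1e-12)
  expect_equal(relative_entropy(point_mass("A"), uniform_p()), log2(20),
               tolerance = 1e-12)
  # hand-summed two-term value for p = {A: 3/4, C: 1/4} against uniform
  expect_equal(relative_entropy(two_mass("A", "C", 0.75), uniform_p()),
               0.75 * log2(0.75 / 0.05) + 0.25 * log2(0.25 / 0.05),
               tolerance = 1e-12)
  set.seed(1)
  for (i in 1:50) expect_gte(relative_entropy(random_p(), uniform_p()), 0)
  expect_error(shannon_entropy(rep(0.1, 20)), "summing to 1")
})

test_that("Jensen-Shannon divergence is symmetric, bounded and zero at p = q", {
  expect_equal(js_divergence(uniform_p(), uniform_p()), 0, tolerance = 1e-12)
  expect_equal(js_divergence(point_mass("A"), point_mass("C")), 1,
               tolerance = 1e-12)
  set.seed(2)
  for (i in 1:25) {
    p <- random_p(); q <- random_p()
    expect_equal(js_divergence(p, q), js_divergence(q, p),
                 tolerance = 1e-12)
    expect_gte(js_divergence(p, q), 0)
    expect_lte(js_divergence(p, q), 1 + 1e-12)
  }
  expect_error(js_divergence(uniform_p(), uniform_p(), lambda = 1), "lambda")
})

test_that("property entropy aggregates classes and never exceeds residue entropy", {
  # all K and R fall in one class
  expect_equal(property_entropy(two_mass("K", "R")), 0, tolerance = 1e-12)
  # uniform over {K,R,D,E}: two classes at 0.5 each
  p <- setNames(rep(0, 20), names(uniform_p()))
  p[c("K", "R", "D", "E")] <- 0.25
  expect_equal(property_entropy(p), 1, tolerance = 1e-12)
  set.seed(3)
  for (i in 1:25) {
    pr <- random_p()
    expect_lte(property_entropy(pr), shannon_entropy(pr) + 1e-12)
  }
  expect_error(property_entropy(uniform_p(), partition = list(a = "A")),
               "cover")
})

test_that("sum of pairs averages the pair similarities and ignores order", {
  S <- diag(20)
  dimnames(S) <- list(names(uniform_p()), names(uniform_p()))
  expect_equal(sum_of_pairs(c("A", "A", "C", "C"), S), 2 / 6,
               tolerance = 1e-12)
  expect_equal(sum_of_pairs(c("C", "A", "C", "A"), S), 2 / 6,
               tolerance = 1e-12)
  Sb <- similarity_transform(substitution_matrix("blosum62"))
  expect_equal(sum_of_pairs(rep("W", 5), Sb), 1, tolerance = 1e-12)
  expect_true(is.na(sum_of_pairs(c("A", "-", "-"), Sb)))
})

test_that("von Neumann entropy reduces to Shannon under identity similarity", {
  expect_equal(vn_entropy(two_mass("A", "C")), 1, tolerance = 1e-9)
  Sb <- similarity_transform(substitution_matrix("blosum62"))
  expect_equal(vn_entropy(point_mass("H"), Sb), 0, tolerance = 1e-9)
  set.seed(4)
  for (i in 1:200) {
    p <- random_p()
    expect_equal(vn_entropy(p), shannon_entropy(p), tolerance = 1e-9)
    v <- vn_entropy(p, Sb)
    expect_gte(v, -1e-9)
    expect_lte(v, log2(20) + 1e-9)
  }
})

test_that("similarity transforms have unit diagonal and [0,1] range for all seven matrices", {
  for (nm in c("blosum35", "blosum40", "blosum45", "blosum50",
               "blosum62", "blosum80", "blosum100")) {
    M <- substitution_matrix(nm)
    expect_true(isSymmetric(unname(M)))
    S <- similarity_transform(M)
    expect_equal(unname(diag(S)), rep(1, 20), tolerance = 1e-12)
    expect_true(all(S >= 0 & S <= 1))
  }
  for (bg in c("blosum62", "swissprot", "pf", "uniform")) {
    q <- background_distribution(bg)
    expect_equal(sum(q), 1, tolerance = 1e-12)
    expect_true(all(q > 0))
  }
})

test_that("gap adjustment is monotone: extra gaps never raise the adjusted score", {
  base <- c(rep("L", 8), rep("I", 2))
  for (me in c("js_divergence", "shannon_entropy", "sum_of_pairs",
               "vn_entropy")) {
    prev <- Inf
    for (n_gap in c(0, 2, 4, 6)) {
      col <- base
      if (n_gap > 0) col[seq_len(n_gap)] <- "-"
      aln <- prot_aln(setNames(col, sprintf("s%02d", 1:10)))
      sc <- score_alignment(aln, me)
      expect_lte(sc$adjusted[1], prev + 1e-9)
      prev <- sc$adjusted[1]
    }
  }
})

test_that("every estimator ranks an invariant column above a spread column", {
  set.seed(5)
  m <- cbind(rep("H", 30),
             sample(names(uniform_p()), 30, replace = TRUE))
  aln <- prot_aln(setNames(apply(m, 1, paste, collapse = ""),
                           sprintf("s%02d", 1:30)))
  for (me in c("js_divergence", "property_entropy", "vn_entropy",
               "relative_entropy", "shannon_entropy", "sum_of_pairs")) {
    sc <- score_alignment(aln, me)
    expect_gt(sc$adjusted[1], sc$adjusted[2])
  }
})

test_that("identified columns take the top floor-fraction with deterministic tie-break", {
  sc <- data.frame(index = 1:40, adjusted = c(rep(5, 3), rep(1, 37)))
  expect_identical(identified_columns(sc, 0.05), 1L:2L)  # floor(2.0) = 2
  expect_identical(identified_columns(sc, 0.10), 1L:4L)  # tie at 1 -> index 4
  expect_identical(identified_columns(sc, 0.001), 1L)    # never empty
})

test_that("the 21-way consensus is contained in every single run", {
  sim <- generate_alignment(synthetic_config(
    n_groups = 2, group_size = 15, L = 60, n_family = 3,
    n_group_specific = 2, n_class = 1, conservation = 1, seed = 9))
  aln <- sim$alignment
  for (me in c("relative_entropy", "sum_of_pairs")) {
    cons <- consensus_identified(aln, me)
    for (bg in c("blosum62", "pf")) for (mat in c("blosum35", "blosum100")) {
      ids <- identified_columns(score_alignment(aln, me, bg, mat))
      expect_true(all(cons %in% ids))
    }
  }
})
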