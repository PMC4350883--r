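test_that("p-distances match hand counts under both deletion modes", {
  D0 <- p_distance(c(a = "AAAA", b = "AAAA"))
  expect_equal(D0$d["a", "b"], 0)
  D1 <- p_distance(c(a = "AAAA", b = "AAAT"))
  expect_equal(D1$d["a", "b"], 0.25)
  D2 <- p_distance(c(a = "A-AA", b = "AGAT"), deletion = "pairwise")
  expect_equal(D2$d["a", "b"], 1 / 3)
  expect_equal(D2$comparable_sites["a", "b"], 3)
  # X counts as ambiguous
  D3 <- p_distance(c(a = "AXAA", b = "AGAT"), deletion = "pairwise")
  expect_equal(D3$comparable_sites["a", "b"], 3)
  # complete deletion removes the gap column for every pair
  D4 <- p_distance(c(a = "A-AA", b = "AGAT", c = "AGAA"),
                   deletion = "complete")
  expect_true(all(D4$comparable_sites[upper.tri(D4$d)] == 3))
  # pairwise never uses fewer sites than complete
  D5 <- p_distance(c(a = "A-AA", b = "AGAT", c = "AGAA"),
                   deletion = "pairwise")
  expect_true(all(D5$comparable_sites >= D4$comparable_sites))
  # symmetry, zero diagonal
  expect_equal(D5$d, t(D5$d))
  expect_true(all(diag(D5$d) == 0))
  # a pair with no comparable sites is an error naming the pair
  err <- tryCatch(p_distance(c(a = "A---", b = "-GGG", c = "AGGG")),
                  error = function(e) e)
  expect_s3_class(err, "wrky_degenerate_distance")
  expect_match(conditionMessage(err), "a and b")
})

test_that("Poisson correction is -ln(1-p), increasing and above p", {
  expect_equal(poisson_correct(0), 0)
  expect_equal(poisson_correct(0.25), 0.2876821, tolerance = 1e-6)
  grid <- seq(0, 0.95, by = 0.05)
  d <- poisson_correct(grid)
  expect_equal(d, -log(1 - grid))
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= grid))
  expect_error(poisson_correct(1), class = "wrky_domain_error")
})

test_that("site coverage filtering eliminates only sub-threshold columns", {
  # gapless alignment is unchanged
  aln <- setNames(c("WRKY", "WRKY", "WRKY"), paste0("s", 1:3))
  expect_equal(site_coverage_filter(aln), aln)
  # 1 gap in 20 rows: coverage exactly 0.95, retained under "< 95%" rule
  rows <- c("A-BBB", rep("AABBB", 19))
  names(rows) <- paste0("s", 1:20)
  kept <- site_coverage_filter(rows, 0.95)
  expect_equal(nchar(kept[[1]]), 5)
  # 2 gaps in 10 rows: coverage 0.8, removed
  rows2 <- setNames(c("A-AAA", "A-AAA", rep("AAAAA", 8)), paste0("t", 1:10))
  expect_equal(nchar(site_coverage_filter(rows2, 0.95)[[1]]), 4)
  # all columns removed warns but does not error
  expect_warning(site_coverage_filter(setNames(c("--", "--", "AA"),
                                               c("a", "b", "c")), 0.95),
                 class = "wrky_empty_alignment")
})

test_that("three-taxon NJ solves the closed-form branch lengths", {
  d <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.6,
                0.5, 0.6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  # x = (dab + dac - dbc)/2 etc.
  want <- c(a = (0.3 + 0.5 - 0.6) / 2, b = (0.3 + 0.6 - 0.5) / 2,
            c = (0.5 + 0.6 - 0.3) / 2)
  got <- setNames(tr$edge.length[match(seq_along(tr$tip.label),
                                       tr$edge[, 2])], tr$tip.label)
  expect_equal(got[c("a", "b", "c")], want, tolerance = 1e-12)
  expect_error(nj_tree(d[1:2, 1:2]), class = "wrky_precondition_error")
})

test_that("NJ recovers the generating topology from additive distances", {
  set.seed(99)
  for (rep in 1:100) {
    n <- sample(5:8, 1)
    tr <- ape::rtree(n)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
    D <- stats::cophenetic(tr)
    nj <- nj_tree(D)
    expect_equal(phangorn::RF.dist(ape::unroot(tr), nj), 0)
  }
})

test_that("tied distance matrices resolve deterministically", {
  d <- matrix(0.5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  t1 <- nj_tree(d)
  t2 <- nj_tree(d)
  expect_identical(write_newick(t1), write_newick(t2))
})

test_that("bootstrap separates planted clades and is reproducible", {
  aln <- two_clade_alignment(seed = 3)
  bt <- bootstrap_support(aln, n_replicates = 200, seed = 3)
  expect_equal(clade_support(bt, paste0("A", 1:4)), 1.0)
  bt2 <- bootstrap_support(aln, n_replicates = 200, seed = 3)
  expect_identical(bt$support, bt2$support)
  # single replicate: supports are 0 or 1
  bt1 <- bootstrap_support(aln, n_replicates = 1, seed = 8)
  expect_true(all(bt1$support$support %in% c(0, 1)))
  expect_error(bootstrap_support(aln, n_replicates = 0),
               class = "wrky_precondition_error")
})

test_that("bootstrap supports are invariant to taxon order", {
  aln <- two_clade_alignment(seed = 12)
  perm <- aln[c(5, 1, 7, 3, 2, 8, 4, 6)]
  b1 <- bootstrap_support(aln, n_replicates = 50, seed = 4)
  b2 <- bootstrap_support(perm, n_replicates = 50, seed = 4)
  s1 <- setNames(b1$support$support, b1$support$key)
  s2 <- setNames(b2$support$support, b2$support$key)
  expect_setequal(names(s1), names(s2))
  expect_equal(s1[sort(names(s1))], s2[sort(names(s1))])
})

test_that("monophyly queries follow the bipartition semantics", {
  tr <- read_newick(text = "((a:1,b:1):1,(c:1,d:1):1,e:1);")
  expect_true(is_monophyletic(tr, "a"))
  expect_true(is_monophyletic(tr, c("a", "b", "c", "d", "e")))
  expect_true(is_monophyletic(tr, c("a", "b")))
  expect_true(is_monophyletic(tr, c("c", "d")))
  expect_false(is_monophyletic(tr, c("a", "c")))
  expect_error(is_monophyletic(tr, "zz"), class = "wrky_precondition_error")
})
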