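# independent brute-force matcher used as an oracle for best_match_accuracy
brute_match <- function(pred, truth) {
  pf <- as.integer(factor(pred)); tf <- as.integer(factor(truth))
  labs <- seq_len(max(max(pf), max(tf)))
  perm_list <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perm_list(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- 0
  for (p in perm_list(labs))
    best <- max(best, mean(p[pf] == tf))
  best
}

test_that("best_match_accuracy maximizes over bijective label matchings", {
  expect_equal(best_match_accuracy(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(best_match_accuracy(c(1, 1, 2, 2), c("b", "b", "a", "a")), 1)
  expect_equal(best_match_accuracy(c(0, 0, 1, 1, 2, 2),
                                   c("a", "a", "a", "b", "b", "c")), 4 / 6)
  set.seed(61)
  for (i in 1:10) {
    pred <- sample(3, 12, replace = TRUE)
    truth <- sample(4, 12, replace = TRUE)
    expect_equal(best_match_accuracy(pred, truth), brute_match(pred, truth))
  }
  expect_error(best_match_accuracy(1:3, 1:4), "length")
})

test_that("best_match_accuracy is invariant to relabeling either side", {
  set.seed(62)
  for (i in 1:5) {
    truth <- sample(letters[1:3], 30, replace = TRUE)
    pred <- sample(3, 30, replace = TRUE)
    relab <- c(10, 20, 30)[pred]
    expect_equal(best_match_accuracy(relab, truth),
                 best_match_accuracy(pred, truth))
    expect_equal(best_match_accuracy(pred, c(a = "q", b = "r",
                                             c = "s")[truth]),
                 best_match_accuracy(pred, truth))
    # a constant predictor scores exactly the majority-class frequency
    expect_equal(best_match_accuracy(rep(1, 30), truth),
                 max(table(truth)) / 30)
  }
})

test_that("gmm_stage_assign separates well-separated clusters perfectly", {
  set.seed(63)
  x <- c(rnorm(40, 1, 0.05), rnorm(40, 3, 0.05), rnorm(40, 5, 0.05))
  truth <- rep(1:3, each = 40)
  sa <- gmm_stage_assign(x, n_components = 3, seed = 0, truth = truth)
  expect_equal(sa$accuracy, 1)
  expect_identical(gmm_stage_assign(x, seed = 4)$labels,
                   gmm_stage_assign(x, seed = 4)$labels)
  one <- gmm_stage_assign(x, n_components = 1, seed = 0)
  expect_true(all(one$labels == 1))
  expect_error(gmm_stage_assign(rep(2, 50)), "degenerate")
})

test_that("circular alignment recovers constructed transforms", {
  set.seed(64)
  t_true <- runif(300, 0, 2 * pi)
  id <- circular_alignment_score(t_true, t_true)
  expect_equal(id$score, 1, tolerance = 1e-12)
  expect_false(id$reflected)
  expect_lt(min(id$offset, 2 * pi - id$offset), 1e-8)
  # reflected + rotated copy
  inf <- (2 * pi - t_true + 1.3) %% (2 * pi)
  al <- circular_alignment_score(inf, t_true)
  expect_equal(al$score, 1, tolerance = 1e-12)
  expect_true(al$reflected)
  realigned <- apply_alignment(inf, al)
  expect_lt(max(pmin(abs(realigned - t_true),
                     2 * pi - abs(realigned - t_true))), 1e-8)
  # independent angles score near zero
  set.seed(65)
  expect_lte(circular_alignment_score(runif(1000, 0, 2 * pi),
                                      runif(1000, 0, 2 * pi))$score, 0.1)
  expect_error(circular_alignment_score(rep(1, 10), runif(10)), "constant")
})

test_that("alignment score is invariant to a common offset", {
  set.seed(66)
  a <- runif(100, 0, 2 * pi)
  b <- (a + rnorm(100, sd = 0.2)) %% (2 * pi)
  s0 <- circular_alignment_score(a, b)$score
  s1 <- circular_alignment_score((a + 0.9) %% (2 * pi),
                                 (b + 0.9) %% (2 * pi))$score
  expect_equal(s0, s1, tolerance = 1e-10)
})

test_that("subclone separability detects disjoint gene programs", {
  set.seed(67)
  n <- 60
  block <- function(active) {
    cbind(matrix(rnorm(n * 20, mean = if (active) 3 else 0), n, 20),
          matrix(rnorm(n * 20, mean = if (active) 0 else 3), n, 20))
  }
  m <- expression_matrix(rbind(block(TRUE), block(FALSE)), scale = "log")
  labels <- rep(c("c1", "c2"), each = n)
  sep <- subclone_separability(m, labels, seed = 1)
  expect_gte(as.numeric(sep), 0.95)
  expect_identical(as.numeric(subclone_separability(m, labels, seed = 1)),
                   as.numeric(sep))
  expect_error(subclone_separability(m, rep("c1", 2 * n)), "two distinct")
  expect_error(subclone_separability(m$values[1:5, ], rep(c("a", "b"), 3)[1:5]),
               "10 cells")
})

test_that("shuffled clone labels give chance-level separability", {
  set.seed(68)
  m <- expression_matrix(matrix(rnorm(576 * 40), 576, 40), scale = "log")
  labels <- sample(rep(c("c1", "c2"), each = 288))
  sep <- as.numeric(subclone_separability(m, labels, seed = 2))
  expect_lt(abs(sep - 0.5), 0.07)
})

test_that("cycling_fraction partitions the pseudo-time density sensibly", {
  set.seed(69)
  # uniform occupancy: everything cycles
  expect_equal(as.numeric(cycling_fraction(runif(500, 0, 2 * pi))), 1)
  # 90% resting in a narrow arc, 10% spread over the opposite half
  pt <- c(rnorm(900, pi / 2, 0.05) %% (2 * pi), runif(100, 3.5, 5.5))
  cf <- cycling_fraction(pt)
  expect_lt(abs(as.numeric(cf) - 0.10), 0.03)
  expect_gt(nrow(attr(cf, "gaps")), 0)
  # a single point mass: nothing cycles
  expect_lt(as.numeric(cycling_fraction(rnorm(200, 1, 0.01) %% (2 * pi))),
            0.02)
  expect_error(cycling_fraction(runif(10)), "20 cells")
})

test_that("gene_set_score averages over the named columns", {
  vals <- cbind(a = c(1, 1), b = c(3, 5), c = c(10, 20))
  m <- expression_matrix(vals, c("x", "y"), c("a", "b", "c"), scale = "log")
  expect_equal(as.numeric(gene_set_score(m, "b")), c(3, 5))
  expect_equal(as.numeric(gene_set_score(m, c("a", "b"))), c(2, 3))
  set.seed(70)
  m2 <- expression_matrix(matrix(rnorm(50), 5, 10), scale = "log")
  pick <- sample(m2$gene_ids, 4)
  expect_equal(as.numeric(gene_set_score(m2, pick)),
               unname(apply(m2$values[, pick], 1, mean)))
  expect_message(gene_set_score(m, c("a", "zzz")), "not present")
  expect_error(gene_set_score(m, "zzz"), "no genes")
})
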