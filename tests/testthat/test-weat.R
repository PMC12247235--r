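# the hand-derivable 2-D toy: s-values {1, 0.2, -1, -0.2}
toy <- list(X = list(c(1, 0), c(0.8, 0.6)),
            Y = list(c(0, 1), c(0.6, 0.8)),
            A = list(c(1, 0)),
            B = list(c(0, 1)))
toy_inputs <- weat_inputs(toy$X, toy$Y, toy$A, toy$B)

test_that("cosine similarity matches closed forms", {
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 0), c(1, 0)), 1)
  expect_equal(cosine_similarity(c(1, 1), c(1, 0)), sqrt(2) / 2)
  expect_error(cosine_similarity(c(0, 0), c(1, 0)), "degenerate-embedding")
  expect_error(cosine_similarity(c(1, 0), c(1, 0, 0)), "dimension")
})

test_that("association score matches hand arithmetic and the oracle", {
  w <- c(0.8, 0.6)
  expect_equal(weat_association(w, toy$A, toy$B), 0.2)
  expect_equal(weat_association(c(1, 0), toy$A, toy$B), 1)
  # A = B: zero for any w
  expect_equal(weat_association(w, toy$A, toy$A), 0)
  set.seed(1)
  for (i in 1:20) {
    inst <- random_instance(3, dim = 6)
    expect_equal(weat_association(inst$X[[1]], inst$A, inst$B),
                 oracle_association(inst$X[[1]], inst$A, inst$B),
                 tolerance = 1e-12)
  }
})

test_that("toy statistic, effect size and p match the hand derivation", {
  expect_equal(weat_statistic(toy_inputs), 2.4)
  expect_equal(weat_statistic(weat_inputs(toy$X, toy$Y, toy$B, toy$A)), -2.4)
  expect_equal(weat_statistic(weat_inputs(toy$X, toy$X, toy$A, toy$B)), 0)
  # d = 1.2 / sqrt(0.52)
  expect_equal(weat_effect_size(toy_inputs), 1.2 / sqrt(0.52))
  expect_equal(weat_effect_size(weat_inputs(toy$Y, toy$X, toy$A, toy$B)),
               -1.2 / sqrt(0.52))
  p <- weat_permutation_p(toy_inputs, "exhaustive")
  expect_equal(p$p, 0)
  expect_equal(p$n_used, 6)
  # the partition scoring S = 0 sits above exactly 2 of the 6 partitions
  mixed <- weat_inputs(list(toy$X[[1]], toy$Y[[1]]),
                       list(toy$X[[2]], toy$Y[[2]]), toy$A, toy$B)
  expect_equal(weat_permutation_p(mixed, "exhaustive")$p, 2 / 6)
})

test_that("degenerate geometries raise rather than return NaN", {
  # A = B: all associations zero, sigma = 0
  same <- weat_inputs(toy$X, toy$Y, toy$A, toy$A)
  expect_error(weat_effect_size(same), "zero-variance-association")
  # but the permutation p is well-defined: all partitions tie at 0
  expect_equal(weat_permutation_p(same, "exhaustive")$p, 0)
  expect_equal(weat_permutation_p(same, "exhaustive")$tie_mass, 1)
})

test_that("antisymmetry, bound, and invariances hold on random inputs", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(2:5, 1)
    inst <- random_instance(n, dim = 12, n_attr = sample(2:4, 1))
    inp <- weat_inputs(inst$X, inst$Y, inst$A, inst$B)
    d <- weat_effect_size(inp)
    # |d| <= 2 for equal-size targets
    expect_lte(abs(d), 2)
    # exact antisymmetry under X <-> Y and A <-> B
    expect_equal(weat_effect_size(weat_inputs(inst$Y, inst$X, inst$A, inst$B)),
                 -d)
    expect_equal(weat_effect_size(weat_inputs(inst$X, inst$Y, inst$B, inst$A)),
                 -d)
    # invariance under positive scaling and common rotation
    R <- random_rotation(12)
    rot <- lapply(inst, function(vs) lapply(vs, function(v) drop(R %*% (2.5 * v))))
    inp_rot <- weat_inputs(rot$X, rot$Y, rot$A, rot$B)
    expect_equal(weat_effect_size(inp_rot), d, tolerance = 1e-9)
    expect_equal(weat_statistic(inp_rot), weat_statistic(inp),
                 tolerance = 1e-9)
    expect_equal(weat_permutation_p(inp_rot, "exhaustive")$p,
                 weat_permutation_p(inp, "exhaustive")$p)
  }
})

test_that("exhaustive p equals the enumeration oracle; complements sum right", {
  set.seed(11)
  for (i in 1:15) {
    n <- sample(2:4, 1)
    inst <- random_instance(n, dim = 8)
    inp <- weat_inputs(inst$X, inst$Y, inst$A, inst$B)
    res <- weat_permutation_p(inp, "exhaustive")
    expect_identical(res$p, oracle_perm_p(inst$X, inst$Y, inst$A, inst$B))
    # complementarity: p(A,B) + p(B,A) = 1 - tie mass at S_obs
    res_ba <- weat_permutation_p(weat_inputs(inst$X, inst$Y, inst$B, inst$A),
                                 "exhaustive")
    expect_equal(res$p + res_ba$p, 1 - res$tie_mass, tolerance = 1e-12)
  }
})

test_that("monte-carlo p is seeded, validated, and near the exhaustive value", {
  inst <- random_instance(4, dim = 10)
  inp <- weat_inputs(inst$X, inst$Y, inst$A, inst$B)
  expect_error(weat_permutation_p(inp, "monte-carlo", n_draws = 50),
               "n_draws")
  m1 <- weat_permutation_p(inp, "monte-carlo", n_draws = 2000, seed = 3)
  m2 <- weat_permutation_p(inp, "monte-carlo", n_draws = 2000, seed = 3)
  expect_identical(m1$p, m2$p)
  expect_equal(m1$mode, "monte-carlo")
  ex <- weat_permutation_p(inp, "exhaustive")
  expect_lt(abs(m1$p - ex$p), 0.05)
  # unequal target sizes are rejected upstream
  expect_error(weat_inputs(inst$X[1:3], inst$Y, inst$A, inst$B), "equal size")
})

test_that("run_weat wires benchmark, table and permutation test together", {
  syn <- synthetic_benchmark(n_targets = 4, n_attributes = 4)
  tab <- synth_table_for_benchmark(syn, mode = "exact-geometry", dim = 10,
                                   seed = 1)
  res <- run_weat(syn, tab)
  expect_s3_class(res, "weat_result")
  expect_equal(res$effect_size, 2)
  expect_equal(res$p_value, 0)
  expect_equal(res$mode, "exhaustive")
  # ordered pair reversal negates d
  rev <- run_weat(syn, tab, group_pair = c("A2", "A1"))
  expect_equal(rev$effect_size, -res$effect_size)
  expect_error(run_weat(syn, tab, group_pair = c("A1", "nope")),
               "unknown attribute group")
})

test_that("pairwise_weat reports every ordered pair with negation symmetry", {
  h1 <- load_bundled_benchmark("H-1")
  tab <- synth_table_for_benchmark(h1, beta = 0.6, dim = 20, seed = 4)
  pw <- pairwise_weat(h1, tab)
  expect_length(pw, 6)  # 3 groups -> 6 ordered pairs
  expect_setequal(names(pw),
                  c("Black-Hispanic", "Black-White", "Hispanic-Black",
                    "Hispanic-White", "White-Black", "White-Hispanic"))
  expect_equal(pw[["Black-Hispanic"]]$effect_size,
               -pw[["Hispanic-Black"]]$effect_size)
  # 2-group benchmark -> 2 results
  g1 <- load_bundled_benchmark("G-1")
  tabg <- synth_table_for_benchmark(g1, beta = 0, dim = 10, seed = 5)
  expect_length(pairwise_weat(g1, tabg), 2)
})
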