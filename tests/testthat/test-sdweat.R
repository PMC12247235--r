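test_that("pool_attributes concatenates groups in declaration order", {
  g1 <- load_bundled_benchmark("G-1")
  pool <- pool_attributes(g1)
  expect_length(pool, 16)
  expect_equal(pool[1:8], g1$attribute_groups[[1]]$terms)
  expect_equal(pool[9:16], g1$attribute_groups[[2]]$terms)
  # single-group dataset: the group's list unchanged
  e2 <- load_bundled_benchmark("E-2")
  expect_equal(pool_attributes(e2),
               unlist(lapply(e2$attribute_groups, `[[`, "terms"),
                      use.names = FALSE))
})

test_that("sample_attribute_pairs draws 4 distinct words, seeded", {
  pool4 <- c("w1", "w2", "w3", "w4")
  draws <- sample_attribute_pairs(pool4, K = 20, seed = 1)
  expect_length(draws, 20)
  for (d in draws) {
    expect_length(intersect(d$A, d$B), 0)
    expect_setequal(c(d$A, d$B), pool4)  # forced: pool of exactly 4
  }
  expect_identical(sample_attribute_pairs(pool4, K = 20, seed = 1), draws)
  expect_error(sample_attribute_pairs(c("a", "b", "c"), K = 5),
               "pool-too-small")
})

test_that("each pool word is drawn with frequency about 4/|pool|", {
  pool <- sprintf("w%02d", 1:16)
  draws <- sample_attribute_pairs(pool, K = 10000, seed = 42)
  freq <- table(factor(unlist(lapply(draws, unlist)), levels = pool)) / 10000
  # binomial sampling theory: p = 4/16, sd = sqrt(p(1-p)/K) ~ 0.0043
  expect_true(all(abs(freq - 0.25) < 4.5 * sqrt(0.25 * 0.75 / 10000)))
})

test_that("sd_of_effect_sizes is the population SD", {
  expect_equal(sd_of_effect_sizes(c(0.5, 0.5, 0.5)), 0)
  expect_equal(sd_of_effect_sizes(c(1, -1)), 1)
  expect_equal(sd_of_effect_sizes(c(1, 0.2, -1, -0.2)), sqrt(0.52))
  expect_error(sd_of_effect_sizes(1), "at least 2")
})

test_that("run_sdweat is reproducible and internally consistent", {
  g1 <- load_bundled_benchmark("G-1")
  tab <- synth_table_for_benchmark(g1, beta = 0.8, dim = 20, seed = 9)
  r1 <- run_sdweat(g1, tab, K = 50, seed = 9, pvalue_reps = 99)
  r2 <- run_sdweat(g1, tab, K = 50, seed = 9, pvalue_reps = 99)
  expect_identical(r1, r2)
  expect_length(r1$effect_sizes, 50)
  expect_gte(r1$score, 0)
  expect_equal(r1$score, sd_of_effect_sizes(r1$effect_sizes))
  expect_true(r1$p_value >= 1 / 100 && r1$p_value <= 1)
  # draws are 2+2 splits of pooled attribute words
  for (d in r1$draws[1:5]) {
    expect_length(d$A, 2); expect_length(d$B, 2)
    expect_true(all(c(d$A, d$B) %in% pool_attributes(g1)))
    expect_length(unique(c(d$A, d$B)), 4)
  }
})

test_that("planted bias raises the score relative to a paired-seed null", {
  g1 <- load_bundled_benchmark("G-1")
  tab_b <- synth_table_for_benchmark(g1, beta = 1.6, dim = 50, seed = 21)
  tab_0 <- synth_table_for_benchmark(g1, beta = 0, dim = 50, seed = 21)
  s_b <- run_sdweat(g1, tab_b, K = 100, seed = 21, pvalue_method = "none")
  s_0 <- run_sdweat(g1, tab_0, K = 100, seed = 21, pvalue_method = "none")
  expect_gt(s_b$score, s_0$score)
})

test_that("score is invariant under scaling and rotation of the table", {
  syn <- synthetic_benchmark()
  tab <- synth_table_for_benchmark(syn, beta = 0.5, dim = 12, seed = 2)
  set.seed(33)
  R <- random_rotation(12)
  tab_rot <- embedding_table(3 * tab$vectors %*% t(R))
  r <- run_sdweat(syn, tab, K = 40, seed = 5, pvalue_method = "none")
  r_rot <- run_sdweat(syn, tab_rot, K = 40, seed = 5, pvalue_method = "none")
  expect_equal(r_rot$score, r$score, tolerance = 1e-9)
  expect_equal(r_rot$effect_sizes, r$effect_sizes, tolerance = 1e-9)
})

test_that("identical target geometries give score 0 and p-value 1", {
  # T1 and T2 have distinct names but the very same vectors, so every draw
  # has d = 0 exactly: degenerate world, score 0, and the shuffle p is 1
  m <- rbind(t1a = c(1, 0, 0), t1b = c(0, 1, 0),
             t2a = c(1, 0, 0), t2b = c(0, 1, 0),
             a1 = c(0.6, 0.8, 0), a2 = c(0, 0.6, 0.8),
             b1 = c(0.8, 0, 0.6), b2 = c(0.5, 0.5, 0.1))
  tab <- embedding_table(m)
  ds <- bias_benchmark("SYN-DEG",
    targets = list(list(label = "T1", terms = c("t1a", "t1b")),
                   list(label = "T2", terms = c("t2a", "t2b"))),
    attribute_groups = list(list(label = "A1", terms = c("a1", "a2")),
                            list(label = "A2", terms = c("b1", "b2"))))
  r <- run_sdweat(ds, tab, K = 25, seed = 1, pvalue_reps = 99)
  expect_equal(r$score, 0)
  expect_equal(unique(r$effect_sizes), 0)
  expect_equal(r$p_value, 1)
})

test_that("constant attribute geometry exhausts the degenerate-draw cap", {
  # all attribute vectors identical: every draw has zero association
  # variance, resampling cannot fix it
  m <- rbind(t1 = c(1, 0), t2 = c(0.9, 0.1), u1 = c(0, 1), u2 = c(0.1, 0.9),
             a1 = c(1, 1), a2 = c(1, 1), a3 = c(1, 1), a4 = c(1, 1))
  ds <- bias_benchmark("SYN-CONST",
    targets = list(list(label = "T1", terms = c("t1", "t2")),
                   list(label = "T2", terms = c("u1", "u2"))),
    attribute_groups = list(list(label = "A1", terms = c("a1", "a2")),
                            list(label = "A2", terms = c("a3", "a4"))))
  expect_error(run_sdweat(ds, embedding_table(m), K = 5, seed = 1),
               "degenerate-draws")
})

test_that("attribute groups without contrast behave like the null", {
  # both attribute groups planted on the same direction: attribute identity
  # carries no recoverable contrast, so the mean score tracks the null's
  syn <- synthetic_benchmark(n_targets = 4, n_attributes = 6)
  score_of <- function(directions, seed) {
    cfg <- synth_config(
      groups = list(T1 = syn$targets[[1]]$terms,
                    T2 = syn$targets[[2]]$terms,
                    A1 = syn$attribute_groups[[1]]$terms,
                    A2 = syn$attribute_groups[[2]]$terms),
      directions = directions, dim = 30, beta = 1.2, seed = seed)
    run_sdweat(syn, generate_table(cfg), K = 100, seed = seed,
               pvalue_method = "none")$score
  }
  seeds <- 1:12
  contrast <- mean(vapply(seeds, function(s)
    score_of(c(T1 = 1, T2 = 2, A1 = 1, A2 = 2), s), numeric(1)))
  no_contrast <- mean(vapply(seeds, function(s)
    score_of(c(T1 = 1, T2 = 2, A1 = 1, A2 = 1), s), numeric(1)))
  null_like <- mean(vapply(seeds, function(s)
    score_of(c(T1 = 0, T2 = 0, A1 = 0, A2 = 0), s), numeric(1)))
  expect_gt(contrast, no_contrast)
  expect_lt(abs(no_contrast - null_like), 0.15)
})

test_that("sdweat_pvalue flags strong planted structure", {
  syn <- synthetic_benchmark()
  tab <- synth_table_for_benchmark(syn, mode = "exact-geometry", dim = 20,
                                   seed = 13)
  p <- sdweat_pvalue(syn, tab, K = 50, seed = 13, pvalue_reps = 199)
  expect_lte(p, 0.01)
  expect_error(sdweat_pvalue(syn, tab, K = 50, seed = 1, pvalue_reps = 50),
               "at least 99")
})
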