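#' Pool the attribute groups of a benchmark into one list
#'
#' Concatenates all attribute groups in declaration order. No deduplication
#' is needed: groups are pairwise disjoint by invariant. This pooled list is
#' what SD-WEAT draws its random attribute pairs from, which is how the
#' statistic handles multi-class (non-binary) attribute structure.
#'
#' @param ds a [bias_benchmark()].
#' @return character vector of pooled attribute terms.
#' @export
pool_attributes <- function(ds) {
  stopifnot(inherits(ds, "bias_benchmark"))
  unlist(lapply(ds$attribute_groups, `[[`, "terms"), use.names = FALSE)
}

#' Draw random attribute pairs from a pooled list
#'
#' Each of the `K` draws samples four distinct words without replacement
#' from the pool; the first two form attribute set A, the next two set B.
#' Draws are independent across tests (repeats across tests permitted) and
#' fully determined by the seed.
#'
#' @param pool character vector of pooled attribute terms (length >= 4).
#' @param K number of draws.
#' @param seed RNG seed, or `NULL` to use the current RNG state.
#' @return list of `K` elements `list(A = <2 terms>, B = <2 terms>)`.
#' @export
sample_attribute_pairs <- function(pool, K = 100L, seed = NULL) {
  if (length(pool) < 4L)
    stop("pool-too-small: need at least 4 pooled attribute words, have ",
         length(pool))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  idx <- draw_pair_indices(length(pool), K)
  lapply(seq_len(K), function(i)
    list(A = pool[idx[i, 1:2]], B = pool[idx[i, 3:4]]))
}

# K x 4 matrix of pool indices, 4 distinct per row (uses current RNG state)
draw_pair_indices <- function(p, K) {
  t(vapply(seq_len(K), function(i) sample.int(p, 4L), integer(4L)))
}

#' Population standard deviation of effect sizes
#'
#' The SD-WEAT score summarizer: population (divide-by-N) SD, consistent
#' with the effect-size standardization.
#'
#' @param effect_sizes numeric vector, length >= 2.
#' @return nonnegative real.
#' @export
sd_of_effect_sizes <- function(effect_sizes) {
  if (length(effect_sizes) < 2L) stop("need at least 2 effect sizes")
  sd_pop(effect_sizes)
}

# Vectorized WEAT effect sizes for many 2+2 attribute draws sharing one
# target x pool cosine matrix C (rows = targets, X rows first).
# idx: K x 4 matrix of pool column indices. Returns length-K vector with NA
# where the draw has zero association variance.
effect_sizes_from_cosine <- function(C, n_x, idx) {
  S <- (C[, idx[, 1L], drop = FALSE] + C[, idx[, 2L], drop = FALSE] -
        C[, idx[, 3L], drop = FALSE] - C[, idx[, 4L], drop = FALSE]) / 2
  n <- nrow(C)
  xs <- colMeans(S[seq_len(n_x), , drop = FALSE])
  ys <- colMeans(S[n_x + seq_len(n - n_x), , drop = FALSE])
  mu <- colMeans(S)
  sigma <- sqrt(pmax(colMeans(S * S) - mu * mu, 0))
  d <- unname((xs - ys) / sigma)
  d[sigma < 1e-14] <- NA_real_
  d
}

# K effect sizes with degenerate draws resampled (cap = 10*K retries).
# Returns list(d = effect sizes, idx = final K x 4 index matrix).
sample_effect_sizes <- function(C, n_x, K, retry_cap = 10L * K) {
  idx <- draw_pair_indices(ncol(C), K)
  d <- effect_sizes_from_cosine(C, n_x, idx)
  retries <- 0L
  while (anyNA(d)) {
    bad <- which(is.na(d))
    retries <- retries + length(bad)
    if (retries > retry_cap)
      stop("degenerate-draws: exceeded ", retry_cap,
           " resamples of zero-variance attribute draws", call. = FALSE)
    idx[bad, ] <- draw_pair_indices(ncol(C), length(bad))
    d[bad] <- effect_sizes_from_cosine(C, n_x,
                                       idx[bad, , drop = FALSE])
  }
  list(d = d, idx = idx)
}

# Embed a benchmark and precompute the target x pooled-attribute cosine
# matrix that every SD-WEAT draw reuses.
sdweat_workspace <- function(ds, table, policy = embed_policy()) {
  emb <- embed_benchmark(ds, table, policy)
  pool_terms <- unlist(lapply(emb$attribute_groups, names), use.names = FALSE)
  P <- do.call(rbind, unlist(unname(emb$attribute_groups), recursive = FALSE))
  X <- do.call(rbind, emb$targets[[1L]])
  Y <- do.call(rbind, emb$targets[[2L]])
  Tm <- rbind(X, Y)
  list(C = unit_rows(Tm) %*% t(unit_rows(P)),
       n_x = nrow(X), n_y = nrow(Y),
       pool_terms = pool_terms,
       target_terms = rownames(Tm))
}

#' Run SD-WEAT on a benchmark
#'
#' Pools all attribute words, draws `K` random 2+2 attribute pairs, computes
#' the WEAT effect size of each draw against the fixed target sets, and
#' reports the population standard deviation of those effect sizes as the
#' bias score. Draws whose association scores are constant (zero variance,
#' so the effect size is undefined) are resampled, up to a cap of `10 * K`
#' retries.
#'
#' The p-value (when `pvalue_method = "target-shuffle"`) is a Monte-Carlo
#' resampling test: `R` null replicates shuffle target-set membership (an
#' equal-size re-partition of X union Y) and recompute the K-draw score with
#' fresh attribute draws; `p = (#{SD_null >= SD_obs} + 1) / (R + 1)`.
#'
#' @param ds a [bias_benchmark()].
#' @param table an [embedding_table()].
#' @param policy an [embed_policy()].
#' @param K number of WEAT draws (canonical default 100).
#' @param seed RNG seed governing all draws and shuffles.
#' @param pvalue_method `"target-shuffle"` or `"none"`.
#' @param pvalue_reps number of null replicates `R` (>= 99).
#' @return an `sdweat_result`: list with `score`, `effect_sizes` (length K),
#'   `p_value` (or `NA` under `"none"`), `draws` (list of K A/B term pairs),
#'   `K`, `seed`, `pvalue_reps`, `benchmark`.
#' @export
run_sdweat <- function(ds, table, policy = embed_policy(), K = 100L,
                       seed = NULL,
                       pvalue_method = c("target-shuffle", "none"),
                       pvalue_reps = 1000L) {
  pvalue_method <- match.arg(pvalue_method)
  if (K < 2L) stop("K must be at least 2")
  ws <- sdweat_workspace(ds, table, policy)
  if (length(ws$pool_terms) < 4L)
    stop("pool-too-small: need at least 4 pooled attribute words")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  obs <- sample_effect_sizes(ws$C, ws$n_x, K)
  score <- sd_of_effect_sizes(obs$d)
  p <- NA_real_
  if (pvalue_method == "target-shuffle")
    p <- target_shuffle_pvalue(ws, K, pvalue_reps, score)
  draws <- lapply(seq_len(K), function(i)
    list(A = ws$pool_terms[obs$idx[i, 1:2]],
         B = ws$pool_terms[obs$idx[i, 3:4]]))
  structure(list(score = score, effect_sizes = obs$d, p_value = p,
                 draws = draws, K = as.integer(K), seed = seed,
                 pvalue_reps = if (pvalue_method == "none") NA_integer_
                               else as.integer(pvalue_reps),
                 pvalue_method = pvalue_method, benchmark = ds$name),
            class = "sdweat_result")
}

# target-shuffle null: re-partition the target rows of the cosine matrix
# and recompute the K-draw score with fresh attribute draws (current RNG)
target_shuffle_pvalue <- function(ws, K, R, score_obs) {
  if (R < 99L) stop("pvalue_reps must be at least 99")
  n <- ws$n_x + ws$n_y
  ge <- 0L
  for (r in seq_len(R)) {
    perm <- sample.int(n)
    null_score <- sd_of_effect_sizes(
      sample_effect_sizes(ws$C[perm, , drop = FALSE], ws$n_x, K)$d)
    if (null_score >= score_obs - 1e-14) ge <- ge + 1L
  }
  (ge + 1L) / (R + 1L)
}

#' SD-WEAT resampling p-value
#'
#' Convenience wrapper around [run_sdweat()] returning only the
#' target-shuffle Monte-Carlo p-value. The null-resampling scheme is this
#' package's documented default and is pluggable in principle: it isolates
#' the p-value so an alternative formula can replace it without touching
#' score computation.
#'
#' @inheritParams run_sdweat
#' @return p-value in `[1/(R+1), 1]`.
#' @export
sdweat_pvalue <- function(ds, table, policy = embed_policy(), K = 100L,
                          seed = NULL, pvalue_reps = 1000L) {
  run_sdweat(ds, table, policy, K = K, seed = seed,
             pvalue_method = "target-shuffle",
             pvalue_reps = pvalue_reps)$p_value
}

#' @export
print.sdweat_result <- function(x, ...) {
  cat(sprintf("<sdweat_result %s> score = %.3f, p = %s (K = %d%s)\n",
              x$benchmark, x$score,
              if (is.na(x$p_value)) "NA" else sprintf("%.3g", x$p_value),
              x$K,
              if (is.na(x$pvalue_reps)) ""
              else sprintf(", R = %d", x$pvalue_reps)))
  invisible(x)
}
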