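#' Cosine similarity
#'
#' @param u,v numeric vectors of equal length, each with nonzero norm.
#' @return `u . v / (||u|| ||v||)`, in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("dimension mismatch")
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0) stop("degenerate-embedding: zero-norm vector")
  sum(u * v) / (nu * nv)
}

# stack a list of vectors into a rows matrix, checking shared dimension
as_vector_matrix <- function(vs, what) {
  if (length(vs) == 0L) stop("empty ", what, " set")
  m <- do.call(rbind, vs)
  if (any(rowSums(m * m) == 0))
    stop("degenerate-embedding: zero-norm vector in ", what)
  m
}

# rows of `m` L2-normalized
unit_rows <- function(m) m / sqrt(rowSums(m * m))

#' WEAT association score s(w, A, B)
#'
#' Mean cosine of `w` to the A vectors minus its mean cosine to the B
#' vectors; antisymmetric in (A, B).
#'
#' @param w numeric vector.
#' @param A,B lists of numeric vectors (or matrices with one vector per row).
#' @return real association score.
#' @export
weat_association <- function(w, A, B) {
  A <- if (is.matrix(A)) A else as_vector_matrix(A, "A")
  B <- if (is.matrix(B)) B else as_vector_matrix(B, "B")
  wu <- w / sqrt(sum(w * w))
  mean(unit_rows(A) %*% wu) - mean(unit_rows(B) %*% wu)
}

#' Assemble validated WEAT inputs
#'
#' @param X,Y lists of target vectors (equal, nonzero sizes).
#' @param A,B lists of attribute vectors (nonzero sizes).
#' @param labels optional named character vector for provenance.
#' @return a `weat_inputs` object.
#' @export
weat_inputs <- function(X, Y, A, B, labels = NULL) {
  X <- as_vector_matrix(X, "X"); Y <- as_vector_matrix(Y, "Y")
  A <- as_vector_matrix(A, "A"); B <- as_vector_matrix(B, "B")
  dims <- c(ncol(X), ncol(Y), ncol(A), ncol(B))
  if (length(unique(dims)) != 1L) stop("dimension mismatch across sets")
  if (nrow(X) != nrow(Y))
    stop("target sets must have equal size (|X| = ", nrow(X),
         ", |Y| = ", nrow(Y), ")")
  structure(list(X = X, Y = Y, A = A, B = B, labels = labels),
            class = "weat_inputs")
}

# s(w, A, B) for every w in X union Y, as one vectorized pass:
# rows 1..n are X's scores, rows n+1..2n are Y's
association_profile <- function(inputs) {
  W <- unit_rows(rbind(inputs$X, inputs$Y))
  A <- unit_rows(inputs$A); B <- unit_rows(inputs$B)
  cosA <- W %*% t(A); cosB <- W %*% t(B)
  rowMeans(cosA) - rowMeans(cosB)
}

#' WEAT test statistic S(X, Y, A, B)
#'
#' Sum of association scores over X minus the sum over Y; negated by
#' swapping X with Y or A with B.
#'
#' @param inputs a [weat_inputs()].
#' @return real statistic.
#' @export
weat_statistic <- function(inputs) {
  stopifnot(inherits(inputs, "weat_inputs"))
  s <- association_profile(inputs)
  n <- nrow(inputs$X)
  sum(s[seq_len(n)]) - sum(s[n + seq_len(nrow(inputs$Y))])
}

# population (divide-by-N) standard deviation
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' WEAT effect size d
#'
#' Standardized difference of mean association scores,
#' `d = (mean_X s - mean_Y s) / sigma_{X union Y} s`, with `sigma` the
#' population (divide-by-N) standard deviation — the convention that yields
#' the clean bound `|d| <= 2` for equal-size targets. The sample-SD variant
#' is available for sensitivity checks.
#'
#' @param inputs a [weat_inputs()].
#' @param sd_type `"population"` (canonical) or `"sample"`.
#' @return real effect size.
#' @export
weat_effect_size <- function(inputs, sd_type = c("population", "sample")) {
  stopifnot(inherits(inputs, "weat_inputs"))
  sd_type <- match.arg(sd_type)
  s <- association_profile(inputs)
  n <- nrow(inputs$X)
  sigma <- if (sd_type == "population") sd_pop(s) else stats::sd(s)
  if (sigma == 0)
    stop("zero-variance-association: association scores are constant",
         call. = FALSE)
  (mean(s[seq_len(n)]) - mean(s[n + seq_len(nrow(inputs$Y))])) / sigma
}

#' One-sided WEAT permutation p-value
#'
#' Over equal-size partitions (X', Y') of X union Y,
#' `p = Pr[S(X', Y', A, B) > S(X, Y, A, B)]` with strict inequality (ties at
#' the observed statistic count as not greater). All `choose(2n, n)` subsets
#' are enumerated when that count is at most `exhaustive_limit`; otherwise
#' `n_draws` uniform partitions are sampled (seeded) and the unsmoothed
#' proportion is reported.
#'
#' @param inputs a [weat_inputs()].
#' @param mode `"auto"`, `"exhaustive"` or `"monte-carlo"`.
#' @param n_draws Monte-Carlo partition count (minimum 100).
#' @param seed RNG seed for Monte-Carlo mode.
#' @param exhaustive_limit largest partition count enumerated under
#'   `mode = "auto"`/`"exhaustive"`.
#' @return list with `p`, `n_used`, `mode`, `tie_mass` (share of partitions
#'   tying the observed statistic, exhaustive mode only).
#' @export
weat_permutation_p <- function(inputs, mode = c("auto", "exhaustive",
                                                "monte-carlo"),
                               n_draws = 10000L, seed = NULL,
                               exhaustive_limit = 200000) {
  stopifnot(inherits(inputs, "weat_inputs"))
  mode <- match.arg(mode)
  n <- nrow(inputs$X)
  total <- choose(2L * n, n)
  if (mode == "auto")
    mode <- if (total <= exhaustive_limit) "exhaustive" else "monte-carlo"

  s <- association_profile(inputs)            # length 2n, X rows first
  s_total <- sum(s)
  s_obs <- sum(s[seq_len(n)]) - (s_total - sum(s[seq_len(n)]))

  if (mode == "exhaustive") {
    if (total > exhaustive_limit)
      stop("exhaustive enumeration of ", total, " partitions exceeds limit")
    idx <- utils::combn(2L * n, n)
    # S(X') = 2 * sum(s[X']) - sum(s)
    stats_all <- 2 * colSums(matrix(s[idx], nrow = n)) - s_total
    eps <- 1e-12 * max(1, abs(s_obs))
    p <- mean(stats_all > s_obs + eps)
    ties <- mean(abs(stats_all - s_obs) <= eps)
    list(p = p, n_used = as.integer(total), mode = "exhaustive",
         tie_mass = ties)
  } else {
    if (n_draws < 100L) stop("monte-carlo needs n_draws >= 100")
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    eps <- 1e-12 * max(1, abs(s_obs))
    greater <- 0L
    for (i in seq_len(n_draws)) {
      pick <- sample.int(2L * n, n)
      if (2 * sum(s[pick]) - s_total > s_obs + eps) greater <- greater + 1L
    }
    list(p = greater / n_draws, n_used = as.integer(n_draws),
         mode = "monte-carlo", tie_mass = NA_real_)
  }
}

#' Run a WEAT test on a benchmark
#'
#' Embeds the benchmark terms, assembles targets X/Y and the named attribute
#' group pair A/B, and returns effect size, statistic and permutation
#' p-value with full provenance.
#'
#' @param ds a [bias_benchmark()].
#' @param table an [embedding_table()].
#' @param group_pair character vector of two attribute group labels `(A, B)`;
#'   default: the benchmark's first two groups.
#' @param policy an [embed_policy()].
#' @param mode,n_draws,seed passed to [weat_permutation_p()].
#' @param sd_type passed to [weat_effect_size()].
#' @return a `weat_result`: list with `effect_size`, `statistic`, `p_value`,
#'   `n_permutations`, `mode`, `tie_mass`, `seed`, `benchmark`, `pair`.
#' @export
run_weat <- function(ds, table, group_pair = NULL, policy = embed_policy(),
                     mode = "auto", n_draws = 10000L, seed = NULL,
                     sd_type = "population") {
  emb <- embed_benchmark(ds, table, policy)
  labels <- names(emb$attribute_groups)
  if (is.null(group_pair)) {
    if (length(labels) < 2L)
      stop("benchmark has fewer than 2 attribute groups; name a pair")
    group_pair <- labels[1:2]
  }
  if (!all(group_pair %in% labels))
    stop("unknown attribute group(s): ",
         paste(setdiff(group_pair, labels), collapse = ", "))
  inputs <- weat_inputs(emb$targets[[1L]], emb$targets[[2L]],
                        emb$attribute_groups[[group_pair[1L]]],
                        emb$attribute_groups[[group_pair[2L]]],
                        labels = c(X = names(emb$targets)[1L],
                                   Y = names(emb$targets)[2L],
                                   A = group_pair[1L], B = group_pair[2L]))
  perm <- weat_permutation_p(inputs, mode = mode, n_draws = n_draws,
                             seed = seed)
  structure(list(effect_size = weat_effect_size(inputs, sd_type),
                 statistic = weat_statistic(inputs),
                 p_value = perm$p, n_permutations = perm$n_used,
                 mode = perm$mode, tie_mass = perm$tie_mass,
                 seed = seed, benchmark = ds$name, pair = group_pair),
            class = "weat_result")
}

#' @export
print.weat_result <- function(x, ...) {
  cat(sprintf("<weat_result %s [%s vs %s]> d = %.3f, S = %.3f, p = %.3g (%s, n = %d)\n",
              x$benchmark, x$pair[1L], x$pair[2L], x$effect_size,
              x$statistic, x$p_value, x$mode, x$n_permutations))
  invisible(x)
}

#' Pairwise WEAT over all ordered attribute-group pairs
#'
#' For a multi-class benchmark, runs a binary WEAT for every ordered pair of
#' distinct labelled attribute groups (both orders reported: the effect size
#' of (g2, g1) is the negation of (g1, g2)).
#'
#' @inheritParams run_weat
#' @return list of `weat_result`, one per ordered pair.
#' @export
pairwise_weat <- function(ds, table, policy = embed_policy(), mode = "auto",
                          n_draws = 10000L, seed = NULL,
                          sd_type = "population") {
  labels <- vapply(ds$attribute_groups, `[[`, "", "label")
  if (length(labels) < 2L)
    stop("pairwise analysis needs at least 2 labelled attribute groups")
  pairs <- expand.grid(A = labels, B = labels, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$A != pairs$B, , drop = FALSE]
  # Table-style ordering: by first group, then second, in declaration order
  pairs <- pairs[order(match(pairs$A, labels), match(pairs$B, labels)), ]
  out <- lapply(seq_len(nrow(pairs)), function(i)
    run_weat(ds, table, group_pair = c(pairs$A[i], pairs$B[i]),
             policy = policy, mode = mode, n_draws = n_draws, seed = seed,
             sd_type = sd_type))
  names(out) <- paste(pairs$A, pairs$B, sep = "-")
  out
}
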