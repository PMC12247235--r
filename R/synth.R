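#' Configuration for the synthetic embedding generator
#'
#' The generator plants a controllable bias: each word group may be assigned
#' one latent direction (orthonormal; the canonical basis vectors are used),
#' and in `"random"` mode every word vector is
#' `normalize(g + beta * u_k)` with `g` an iid standard-normal draw and
#' `u_k` its group's direction (`direction 0` = no direction, pure noise).
#' `beta = 0` gives an isotropic null table. In `"exact-geometry"` mode a
#' word's vector is its latent direction exactly (direction-0 words get a
#' seeded random unit vector), which realizes the analytic WEAT extremes
#' (effect size +/- 2).
#'
#' @param groups named list: group label -> character vector of tokens.
#' @param directions named integer vector: group label -> latent direction
#'   index (0 for none). Defaults to directions 1, 2, ... in group order.
#' @param dim embedding dimension (>= number of directions used).
#' @param beta planted-bias strength, >= 0.
#' @param seed RNG seed; output is bit-reproducible given the config.
#' @param mode `"random"` or `"exact-geometry"`.
#' @return a `synth_config`.
#' @export
synth_config <- function(groups, directions = NULL, dim = 50L, beta = 0,
                         seed = 1L, mode = c("random", "exact-geometry")) {
  mode <- match.arg(mode)
  stopifnot(is.list(groups), length(groups) >= 1L,
            !is.null(names(groups)), all(nzchar(names(groups))))
  if (is.null(directions)) {
    directions <- seq_along(groups)
    names(directions) <- names(groups)
  }
  if (!all(names(groups) %in% names(directions)))
    stop("every group needs a direction assignment (0 = none)")
  directions <- as.integer(directions[names(groups)])
  names(directions) <- names(groups)
  if (any(directions < 0L)) stop("direction indices must be >= 0")
  if (max(directions) > dim)
    stop("more latent directions (", max(directions),
         ") than dimensions (", dim, ")")
  if (beta < 0) stop("beta must be >= 0")
  words <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(words))
    stop("a word may belong to at most one group: ",
         paste(unique(words[duplicated(words)]), collapse = ", "))
  structure(list(groups = groups, directions = directions,
                 dim = as.integer(dim), beta = beta,
                 seed = as.integer(seed), mode = mode),
            class = "synth_config")
}

#' Generate a synthetic embedding table with planted bias
#'
#' @param config a [synth_config()].
#' @return an [embedding_table()] of unit-norm vectors with the generating
#'   config attached as attribute `"synth_config"`.
#' @export
generate_table <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  words <- unlist(config$groups, use.names = FALSE)
  dirs <- rep(config$directions,
              vapply(config$groups, length, integer(1L)))
  d <- config$dim
  mat <- matrix(0, nrow = length(words), ncol = d,
                dimnames = list(words, NULL))
  for (i in seq_along(words)) {
    u <- numeric(d)
    if (dirs[i] > 0L) u[dirs[i]] <- 1
    v <- if (config$mode == "exact-geometry") {
      if (dirs[i] > 0L) u else stats::rnorm(d)
    } else {
      stats::rnorm(d) + config$beta * u
    }
    mat[i, ] <- v / sqrt(sum(v * v))
  }
  out <- embedding_table(mat, name = sprintf("synth(beta=%g,seed=%d,%s)",
                                             config$beta, config$seed,
                                             config$mode))
  attr(out, "synth_config") <- config
  out
}

#' Build a generic benchmark for simulation studies
#'
#' Single-token terms, shaped like the bundled gender benchmarks by default
#' (two target sets, two or more attribute groups). Useful together with
#' [synth_table_for_benchmark()] for calibration and power experiments.
#'
#' @param n_targets terms per target set.
#' @param n_attributes terms per attribute group.
#' @param n_groups number of attribute groups.
#' @param name benchmark name.
#' @return a [bias_benchmark()].
#' @export
synthetic_benchmark <- function(n_targets = 6L, n_attributes = 8L,
                                n_groups = 2L, name = "SYN") {
  mk <- function(prefix, n) sprintf("%s-%02d", prefix, seq_len(n))
  bias_benchmark(
    name,
    description = "synthetic benchmark for simulation studies",
    targets = list(list(label = "T1", terms = mk("t1", n_targets)),
                   list(label = "T2", terms = mk("t2", n_targets))),
    attribute_groups = lapply(seq_len(n_groups), function(g)
      list(label = sprintf("A%d", g),
           terms = mk(sprintf("a%d", g), n_attributes))))
}

#' Synthetic embedding table covering a benchmark's tokens
#'
#' Assigns latent directions per benchmark structure: target set 1 and
#' attribute group 1 share direction 1, target set 2 and group 2 share
#' direction 2, and any further attribute groups get directions 3, 4, ...
#' (the multi-class layout). Terms are tokenized as the embedding layer will
#' tokenize them; a token appearing in more than one group (e.g. a disease
#' word shared by both target sets) is left neutral (direction 0), as is
#' every `extra_words` token.
#'
#' @param ds a [bias_benchmark()].
#' @param beta planted-bias strength.
#' @param dim embedding dimension.
#' @param seed RNG seed.
#' @param mode `"random"` or `"exact-geometry"`.
#' @param extra_words additional neutral tokens to cover (e.g. the noise
#'   lexicon).
#' @param split_hyphens tokenize hyphens as separators (match the policy
#'   used downstream).
#' @return an [embedding_table()].
#' @export
synth_table_for_benchmark <- function(ds, beta = 0, dim = 50L, seed = 1L,
                                      mode = "random",
                                      extra_words = character(),
                                      split_hyphens = FALSE) {
  stopifnot(inherits(ds, "bias_benchmark"))
  sets <- c(list(ds$targets[[1L]], ds$targets[[2L]]), ds$attribute_groups)
  # binary layout: A1 -> dir 1, A2 -> dir 2 (aligned with the targets);
  # multi-class layout: groups get their own directions 3, 4, ...
  dir_of_set <- if (length(ds$attribute_groups) == 2L)
    c(1L, 2L, 1L, 2L)
  else
    c(1L, 2L, 2L + seq_along(ds$attribute_groups))
  tok2dir <- list()
  for (i in seq_along(sets)) {
    for (term in sets[[i]]$terms) {
      for (tok in term_tokens(term, split_hyphens)) {
        prev <- tok2dir[[tok]]
        tok2dir[[tok]] <- if (is.null(prev) || prev == dir_of_set[i])
          dir_of_set[i] else 0L   # shared across groups -> neutral
      }
    }
  }
  for (tok in extra_words) tok2dir[[tok]] <- 0L
  toks <- names(tok2dir)
  dirs <- unlist(tok2dir, use.names = FALSE)
  groups <- split(toks, dirs)
  directions <- as.integer(names(groups))
  names(directions) <- names(groups) <- paste0("dir", names(groups))
  cfg <- synth_config(groups = groups, directions = directions,
                      dim = dim, beta = beta, seed = seed, mode = mode)
  generate_table(cfg)
}

#' Operating characteristics of the statistics on synthetic tables
#'
#' For each planted-bias strength in `betas`, generates `reps` independent
#' synthetic tables over a benchmark, and records the WEAT rejection rate at
#' `alpha` (exhaustive permutation p), the mean and SD of the SD-WEAT score,
#' and optionally the SD-WEAT target-shuffle rejection rate. Seeds are
#' paired across the beta grid (table `j` of every beta cell uses seed
#' `seed + j`): common random numbers, so grid comparisons of mean scores
#' are not drowned by between-table noise.
#'
#' @param betas numeric vector of planted-bias strengths.
#' @param reps tables per beta (a warning is logged below 50).
#' @param ds benchmark to score; default [synthetic_benchmark()].
#' @param dim embedding dimension.
#' @param seed base seed.
#' @param alpha significance threshold.
#' @param K SD-WEAT draws per table.
#' @param sdweat_pvalue_reps if > 0, also estimate the SD-WEAT rejection
#'   rate using this many null replicates per table (costly).
#' @return data.frame with one row per beta.
#' @export
calibration_experiment <- function(betas, reps = 100L,
                                   ds = synthetic_benchmark(), dim = 50L,
                                   seed = 1L, alpha = 0.05, K = 100L,
                                   sdweat_pvalue_reps = 0L) {
  if (reps < 50L) warning("reps < 50: estimates will be noisy")
  rows <- lapply(seq_along(betas), function(i) {
    weat_rej <- logical(reps)
    sd_scores <- numeric(reps)
    sd_rej <- rep(NA, reps)
    for (j in seq_len(reps)) {
      s <- seed + j
      tab <- synth_table_for_benchmark(ds, beta = betas[i], dim = dim,
                                       seed = s)
      weat_rej[j] <- run_weat(ds, tab, mode = "auto", seed = s)$p_value < alpha
      method <- if (sdweat_pvalue_reps > 0L) "target-shuffle" else "none"
      res <- run_sdweat(ds, tab, K = K, seed = s, pvalue_method = method,
                        pvalue_reps = max(sdweat_pvalue_reps, 99L))
      sd_scores[j] <- res$score
      if (sdweat_pvalue_reps > 0L) sd_rej[j] <- res$p_value < alpha
    }
    data.frame(beta = betas[i],
               weat_rejection = mean(weat_rej),
               mean_sdweat_score = mean(sd_scores),
               sd_sdweat_score = stats::sd(sd_scores),
               sdweat_rejection = mean(sd_rej),
               reps = reps)
  })
  do.call(rbind, rows)
}
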