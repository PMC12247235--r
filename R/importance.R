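#' The built-in noise lexicon
#'
#' Sixteen inanimate-object words appended to attribute pools to probe which
#' attribute words actually drive effect sizes: words with no plausible
#' interaction with medical conditions, against which the real attribute
#' words can be ranked.
#'
#' @return character vector of 16 words, in canonical order.
#' @export
noise_lexicon <- function() {
  c("rock", "dirt", "sand", "clay", "sky", "cloud", "water", "air",
    "car", "bicycle", "train", "plane", "pen", "paper", "book", "laptop")
}

#' Append a noise lexicon to a pooled attribute list
#'
#' @param pool character vector of pooled attribute terms.
#' @param lexicon character vector of noise words (default the built-in 16).
#' @return concatenated pool, original order preserved, noise appended.
#' @export
augment_pool <- function(pool, lexicon = noise_lexicon()) {
  ov <- intersect(pool, lexicon)
  if (length(ov))
    stop("noise lexicon overlaps the attribute pool: ",
         paste(ov, collapse = ", "))
  c(pool, lexicon)
}

#' Attribute-word importance analysis
#'
#' Augments the benchmark's pooled attribute list with noise words, runs `M`
#' SD-WEAT-style random 2+2 attribute draws, and attributes effect sizes to
#' words by the slot they occupied: for word `w` and slot 1 (resp. 2), the
#' cell value is the mean effect size over the tests where `w` landed in
#' attribute set A (resp. B) — its estimated pull on target set 1 (resp. 2).
#' Cells whose word never occupied the slot stay missing (`NA`), never
#' zero-filled, so sparse occupancy cannot masquerade as neutrality.
#'
#' @param ds a [bias_benchmark()].
#' @param table an [embedding_table()] covering the attribute and noise
#'   tokens.
#' @param policy an [embed_policy()].
#' @param M number of draws (canonical default 500).
#' @param seed RNG seed.
#' @param lexicon noise words to append; `character()` disables
#'   augmentation.
#' @return an `importance_matrix`: list with `values` (words x 2 slots,
#'   `NA` where unoccupied), `counts` (per-cell occupancy), `M`, `seed`,
#'   `benchmark`, `effect_sizes` (length M).
#' @export
run_importance <- function(ds, table, policy = embed_policy(), M = 500L,
                           seed = NULL, lexicon = noise_lexicon()) {
  if (M < 2L) stop("M must be at least 2")
  aug <- ds
  if (length(lexicon)) {
    pool <- pool_attributes(ds)
    augment_pool(pool, lexicon)   # overlap check
    aug$attribute_groups <- c(ds$attribute_groups,
                              list(list(label = ".noise", terms = lexicon)))
  }
  ws <- sdweat_workspace(aug, table, policy)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  res <- sample_effect_sizes(ws$C, ws$n_x, M)
  words <- ws$pool_terms
  values <- matrix(NA_real_, nrow = length(words), ncol = 2L,
                   dimnames = list(words, c("Target 1", "Target 2")))
  counts <- matrix(0L, nrow = length(words), ncol = 2L,
                   dimnames = dimnames(values))
  for (slot in 1:2) {
    cols <- if (slot == 1L) 1:2 else 3:4
    for (w in seq_along(words)) {
      hit <- res$idx[, cols[1L]] == w | res$idx[, cols[2L]] == w
      counts[w, slot] <- sum(hit)
      if (any(hit)) values[w, slot] <- mean(res$d[hit])
    }
  }
  structure(list(values = values, counts = counts, M = as.integer(M),
                 seed = seed, benchmark = ds$name, effect_sizes = res$d),
            class = "importance_matrix")
}

#' @export
print.importance_matrix <- function(x, ...) {
  cat(sprintf("<importance_matrix %s> %d words x 2 slots, M = %d\n",
              x$benchmark, nrow(x$values), x$M))
  top <- order(-abs(ifelse(is.na(x$values[, 2L]), 0, x$values[, 2L])))[1:min(5L, nrow(x$values))]
  for (w in top)
    cat(sprintf("  %-12s T1 %s  T2 %s\n", rownames(x$values)[w],
                formatC(x$values[w, 1L], format = "f", digits = 3),
                formatC(x$values[w, 2L], format = "f", digits = 3)))
  invisible(x)
}

#' Export an importance matrix
#'
#' CSV format writes two files: the values matrix (missing cells empty) and
#' a parallel `*.counts.csv` occupancy matrix. JSON format writes one file
#' carrying both.
#'
#' @param x an `importance_matrix`.
#' @param path destination path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
export_importance <- function(x, path, format = c("csv", "json")) {
  stopifnot(inherits(x, "importance_matrix"))
  format <- match.arg(format)
  if (format == "csv") {
    df <- data.frame(word = rownames(x$values), x$values, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, na = "")
    cdf <- data.frame(word = rownames(x$counts), x$counts, check.names = FALSE)
    utils::write.csv(cdf, sub("\\.csv$", ".counts.csv", path),
                     row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(benchmark = x$benchmark, M = x$M, seed = x$seed,
           words = rownames(x$values),
           slots = colnames(x$values),
           values = unname(apply(x$values, 1L, as.list, simplify = FALSE)),
           counts = unname(apply(x$counts, 1L, as.list, simplify = FALSE))),
      path, auto_unbox = TRUE, digits = NA, null = "null", na = "null",
      pretty = TRUE)
  }
  invisible(path)
}

#' Read back an exported importance matrix (CSV dialect)
#'
#' @param path path given to [export_importance()] with `format = "csv"`.
#' @return an `importance_matrix` (without effect sizes / seed provenance).
#' @export
read_importance <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  values <- as.matrix(df[, -1L, drop = FALSE])
  rownames(values) <- df$word
  cpath <- sub("\\.csv$", ".counts.csv", path)
  counts <- NULL
  if (file.exists(cpath)) {
    cdf <- utils::read.csv(cpath, check.names = FALSE)
    counts <- as.matrix(cdf[, -1L, drop = FALSE])
    rownames(counts) <- cdf$word
    storage.mode(counts) <- "integer"
  }
  structure(list(values = values, counts = counts,
                 M = if (!is.null(counts)) sum(counts[, 1L]) %/% 2L
                     else NA_integer_,
                 seed = NULL, benchmark = NA_character_,
                 effect_sizes = NULL),
            class = "importance_matrix")
}
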