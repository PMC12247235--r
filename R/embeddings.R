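#' Build an embedding table from a token-by-dimension matrix
#'
#' An embedding table maps tokens to fixed-dimension real vectors. Vectors
#' are stored as matrix rows (rownames = tokens). All-zero vectors are
#' rejected: they have no direction, so every cosine against them is
#' undefined.
#'
#' @param mat numeric matrix, one row per token, rownames set.
#' @param name identifier carried for provenance.
#' @return an `embedding_table`.
#' @export
embedding_table <- function(mat, name = "table") {
  mat <- as.matrix(mat)
  if (nrow(mat) < 1L) stop("embedding table is empty")
  if (is.null(rownames(mat)) || any(!nzchar(rownames(mat))))
    stop("embedding table rows must be named by token")
  if (anyDuplicated(rownames(mat)))
    stop("duplicate tokens in embedding table")
  if (!is.numeric(mat) || anyNA(mat)) stop("non-numeric or NA vector entries")
  zero <- rowSums(mat * mat) == 0
  if (any(zero))
    stop("all-zero vector(s) for token(s): ",
         paste(utils::head(rownames(mat)[zero], 5L), collapse = ", "))
  structure(list(vectors = mat, dim = ncol(mat), name = name),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table '%s'>: %d tokens x %d dims\n",
              x$name, nrow(x$vectors), x$dim))
  invisible(x)
}

#' Load word vectors from GloVe or word2vec text files
#'
#' The glove-text dialect is one `token v1 ... vD` line per token, dimension
#' inferred from the first line; word2vec-text prepends a `count dim` header
#' line. Gzip-compressed files are handled transparently. Duplicate tokens:
#' last occurrence wins, with a warning.
#'
#' @param path file path (optionally `.gz`).
#' @param dialect `"glove-text"` or `"word2vec-text"`.
#' @return an [embedding_table()].
#' @export
load_word_vectors <- function(path, dialect = c("glove-text", "word2vec-text")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt",
                                                                encoding = "UTF-8")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(lines)]
  offset <- 0L
  dim <- NA_integer_
  if (dialect == "word2vec-text") {
    if (length(lines) < 1L) stop("empty vector file: ", path)
    hdr <- strsplit(trimws(lines[1L]), "[[:space:]]+")[[1L]]
    if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr))))
      stop("malformed word2vec header line: '", lines[1L], "'")
    dim <- as.integer(hdr[2L])
    offset <- 1L
  }
  body <- lines[seq.int(offset + 1L, length.out = length(lines) - offset)]
  if (length(body) == 0L) stop("empty vector file: ", path)
  toks <- character(length(body))
  vecs <- vector("list", length(body))
  for (i in seq_along(body)) {
    parts <- strsplit(trimws(body[i]), "[[:space:]]+")[[1L]]
    v <- suppressWarnings(as.numeric(parts[-1L]))
    if (length(v) < 1L || anyNA(v))
      stop("unparseable vector row at line ", i + offset, " of ", path)
    if (is.na(dim)) dim <- length(v)
    if (length(v) != dim)
      stop("ragged row at line ", i + offset, " of ", path, ": ",
           length(v), " values, expected ", dim)
    toks[i] <- parts[1L]
    vecs[[i]] <- v
  }
  if (anyDuplicated(toks)) {
    warning("duplicate token(s) in ", path, "; keeping last occurrence")
    keep <- !duplicated(toks, fromLast = TRUE)
    toks <- toks[keep]; vecs <- vecs[keep]
  }
  mat <- do.call(rbind, vecs)
  rownames(mat) <- toks
  embedding_table(mat, name = basename(path))
}

#' Write an embedding table as glove-text
#'
#' @param table an [embedding_table()].
#' @param path destination; `.gz` suffix enables compression.
#' @param digits significant digits to print.
#' @return `path`, invisibly.
#' @export
write_word_vectors <- function(table, path, digits = 8) {
  stopifnot(inherits(table, "embedding_table"))
  m <- table$vectors
  lines <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], format(m[i, ], digits = digits,
                                   scientific = FALSE, trim = TRUE)),
          collapse = " "), character(1L))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt",
                                                                encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Term embedding policy
#'
#' Controls how benchmark terms are mapped to vectors. Multi-word terms are
#' mean-pooled over whitespace tokens (the static-table analogue of sub-word
#' mean pooling). Case: `"exact-then-lower"` retries a failed exact lookup in
#' lowercase (cased reference tables vs uncased models); `"exact"` does not.
#' Out-of-vocabulary handling is split by role, mirroring construction-time
#' practice: unrecognized target terms are skipped with a warning, while a
#' missing attribute term is an error (attribute lists are the instrument
#' itself).
#'
#' @param oov_targets `"skip"` or `"error"`.
#' @param oov_attributes `"error"` or `"skip"`.
#' @param case `"exact-then-lower"` or `"exact"`.
#' @param split_hyphens also split terms on hyphens before lookup.
#' @return an `embed_policy`.
#' @export
embed_policy <- function(oov_targets = c("skip", "error"),
                         oov_attributes = c("error", "skip"),
                         case = c("exact-then-lower", "exact"),
                         split_hyphens = FALSE) {
  structure(list(oov_targets = match.arg(oov_targets),
                 oov_attributes = match.arg(oov_attributes),
                 case = match.arg(case),
                 split_hyphens = isTRUE(split_hyphens)),
            class = "embed_policy")
}

# exact (then optionally lowercase) row lookup; NULL when absent
lookup_token <- function(token, table, case) {
  m <- table$vectors
  if (token %in% rownames(m)) return(m[token, ])
  if (case == "exact-then-lower") {
    lo <- tolower(token)
    if (lo %in% rownames(m)) return(m[lo, ])
  }
  NULL
}

#' Embed a single term
#'
#' Single-token terms resolve to their table vector; multi-word terms are the
#' arithmetic mean of their per-token vectors (mean pooling). Vectors are not
#' normalized here; cosine handles norms downstream.
#'
#' @param term term string (may contain spaces).
#' @param table an [embedding_table()].
#' @param policy an [embed_policy()].
#' @param oov `"error"` or `"skip"`: on a missing token, either fail naming
#'   the token or return `NULL`.
#' @return numeric vector of length `table$dim`, or `NULL` under
#'   `oov = "skip"`.
#' @export
embed_term <- function(term, table, policy = embed_policy(), oov = "error") {
  stopifnot(inherits(table, "embedding_table"))
  term <- trimws(term)
  if (!nzchar(term)) stop("empty term")
  toks <- term_tokens(term, policy$split_hyphens)
  rows <- vector("list", length(toks))
  for (i in seq_along(toks)) {
    v <- lookup_token(toks[i], table, policy$case)
    if (is.null(v)) {
      if (oov == "skip") return(NULL)
      stop("OOV token '", toks[i], "' in term '", term, "'", call. = FALSE)
    }
    rows[[i]] <- v
  }
  out <- colMeans(do.call(rbind, rows))
  if (sum(out * out) == 0)
    stop("degenerate-embedding: term '", term, "' mean-pools to the zero vector",
         call. = FALSE)
  out
}

#' Embed every term of a benchmark
#'
#' Deterministic: same inputs give identical output. OOV handling follows
#' the policy's per-role settings; a skipped term is dropped with a warning,
#' and a set whose terms are all dropped is an error.
#'
#' @param ds a [bias_benchmark()].
#' @param table an [embedding_table()].
#' @param policy an [embed_policy()].
#' @return list with `vectors` (named term -> vector list), `targets` and
#'   `attribute_groups` (labels -> retained term vectors), and `skipped`
#'   (character vector of dropped terms).
#' @export
embed_benchmark <- function(ds, table, policy = embed_policy()) {
  stopifnot(inherits(ds, "bias_benchmark"))
  skipped <- character()
  embed_set <- function(ts, oov) {
    vs <- list()
    for (term in ts$terms) {
      v <- embed_term(term, table, policy, oov = oov)
      if (is.null(v)) skipped <<- c(skipped, term) else vs[[term]] <- v
    }
    if (length(vs) == 0L)
      stop("empty-set-after-skip: every term of set '", ts$label,
           "' is out of vocabulary", call. = FALSE)
    vs
  }
  targets <- lapply(ds$targets, embed_set, oov = policy$oov_targets)
  names(targets) <- vapply(ds$targets, `[[`, "", "label")
  groups <- lapply(ds$attribute_groups, embed_set, oov = policy$oov_attributes)
  names(groups) <- vapply(ds$attribute_groups, `[[`, "", "label")
  if (length(skipped))
    warning("skipped out-of-vocabulary term(s): ",
            paste(skipped, collapse = ", "))
  list(vectors = c(do.call(c, unname(targets)), do.call(c, unname(groups))),
       targets = targets, attribute_groups = groups, skipped = skipped)
}

#' Mean-pool sub-word vectors from a contextual backend
#'
#' Contract for contextual models: a backend is a function
#' `function(term) -> matrix` whose rows are the term's sub-word vectors
#' (deterministic for a fixed term and model). This helper averages them
#' into the single term vector used by every statistic; the core never
#' touches a model library.
#'
#' @param term term string.
#' @param backend function returning a numeric matrix of sub-word vectors.
#' @return mean-pooled numeric vector.
#' @export
embed_term_contextual <- function(term, backend) {
  m <- backend(term)
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) < 1L)
    stop("backend must return a non-empty numeric matrix of sub-word vectors")
  out <- colMeans(m)
  if (sum(out * out) == 0)
    stop("degenerate-embedding: term '", term, "' mean-pools to the zero vector")
  out
}
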