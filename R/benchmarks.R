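#' Construct a bias benchmark dataset
#'
#' A benchmark couples exactly two target term sets (e.g. male-linked and
#' female-linked medical conditions) with one or more labelled attribute
#' groups (e.g. male/female gender terms, or several ethnicity term groups).
#' Binary benchmarks carry two attribute groups; multi-class benchmarks carry
#' three or more, which downstream analyses either pool (SD-WEAT) or compare
#' pairwise (WEAT on every ordered pair).
#'
#' Terms are trimmed, must be non-empty and contain no newline; comparison is
#' case-preserving (case handling belongs to the embedding layer). Within a
#' set terms must be unique; the two target sets must be disjoint, as must
#' all attribute groups taken pairwise. The two target sets must have equal
#' size.
#'
#' @param name benchmark identifier, e.g. `"G-1"`.
#' @param targets list of exactly two lists, each `list(label=, terms=)`.
#' @param attribute_groups list of one or more `list(label=, terms=)`.
#' @param description free-text description.
#' @param references character vector of citation strings.
#' @return an object of class `bias_benchmark`.
#' @export
bias_benchmark <- function(name, targets, attribute_groups,
                           description = "", references = character()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(targets) != 2L)
    stop("a benchmark needs exactly 2 target sets, got ", length(targets))
  if (length(attribute_groups) < 1L)
    stop("a benchmark needs at least 1 attribute group")
  targets <- lapply(targets, as_term_set, kind = "target")
  attribute_groups <- lapply(attribute_groups, as_term_set, kind = "attribute")
  ds <- structure(
    list(name = name,
         description = as.character(description)[1L],
         targets = targets,
         attribute_groups = attribute_groups,
         references = as.character(references)),
    class = "bias_benchmark")
  viol <- benchmark_violations(ds)
  if (length(viol))
    stop("invalid benchmark '", name, "': ",
         paste(vapply(viol, `[[`, "", "code"), collapse = ", "),
         call. = FALSE)
  ds
}

# normalize one {label, terms} record and enforce Term invariants
as_term_set <- function(x, kind) {
  if (is.null(x$label) || !nzchar(x$label))
    stop(kind, " set is missing a label")
  terms <- trimws(as.character(unlist(x$terms, use.names = FALSE)))
  if (length(terms) == 0L)
    stop(kind, " set '", x$label, "' is empty")
  if (any(!nzchar(terms)))
    stop(kind, " set '", x$label, "' contains an empty term")
  if (any(grepl("[\r\n]", terms)))
    stop(kind, " set '", x$label, "' contains a term with a newline")
  list(label = as.character(x$label)[1L], terms = terms)
}

# structural invariant checks shared by the constructor and the validator;
# returns a list of list(code=, message=)
benchmark_violations <- function(ds) {
  viol <- list()
  add <- function(code, message)
    viol[[length(viol) + 1L]] <<- list(code = code, message = message)

  for (ts in c(ds$targets, ds$attribute_groups)) {
    dup <- unique(ts$terms[duplicated(ts$terms)])
    if (length(dup))
      add("duplicate-terms", sprintf("set '%s' repeats: %s", ts$label,
                                     paste(dup, collapse = ", ")))
  }
  ov <- intersect(ds$targets[[1L]]$terms, ds$targets[[2L]]$terms)
  if (length(ov))
    add("overlapping-targets",
        sprintf("targets share terms: %s", paste(ov, collapse = ", ")))
  ng <- length(ds$attribute_groups)
  if (ng >= 2L) {
    for (i in seq_len(ng - 1L)) for (j in seq((i + 1L), ng)) {
      ov <- intersect(ds$attribute_groups[[i]]$terms,
                      ds$attribute_groups[[j]]$terms)
      if (length(ov))
        add("overlapping-attributes",
            sprintf("groups '%s' and '%s' share terms: %s",
                    ds$attribute_groups[[i]]$label,
                    ds$attribute_groups[[j]]$label,
                    paste(ov, collapse = ", ")))
    }
  }
  n1 <- length(ds$targets[[1L]]$terms); n2 <- length(ds$targets[[2L]]$terms)
  if (n1 != n2)
    add("unequal-targets", sprintf("target sizes differ: %d vs %d", n1, n2))
  viol
}

#' @export
print.bias_benchmark <- function(x, ...) {
  cat(sprintf("<bias_benchmark '%s'>\n", x$name))
  if (nzchar(x$description)) cat(" ", x$description, "\n")
  for (ts in x$targets)
    cat(sprintf("  target %-10s (%d): %s%s\n", ts$label, length(ts$terms),
                paste(utils::head(ts$terms, 3L), collapse = ", "),
                if (length(ts$terms) > 3L) ", ..." else ""))
  for (g in x$attribute_groups)
    cat(sprintf("  attr   %-10s (%d): %s%s\n", g$label, length(g$terms),
                paste(utils::head(g$terms, 3L), collapse = ", "),
                if (length(g$terms) > 3L) ", ..." else ""))
  invisible(x)
}

#' Read a benchmark dataset from disk
#'
#' Two plain-text dialects are supported. JSON: an object with fields
#' `name`, `description`, `targets` (array of `{label, terms}`),
#' `attribute_groups` (same shape) and `references`. CSV: UTF-8, columns
#' `set_kind` (`target`/`attribute`), `set_label`, `term`, with optional
#' `#`-prefixed header comment lines carrying name/description/references.
#' Term order in the file is preserved.
#'
#' @param path file path.
#' @param format `"json"` or `"csv"`; default guesses from the extension.
#' @return a [bias_benchmark()].
#' @export
read_benchmark <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "json") read_benchmark_json(path) else read_benchmark_csv(path)
}

read_benchmark_json <- function(path) {
  x <- tryCatch(jsonlite::read_json(path),
                error = function(e) stop("failed to parse JSON benchmark '",
                                         path, "': ", conditionMessage(e),
                                         call. = FALSE))
  for (f in c("name", "targets", "attribute_groups"))
    if (is.null(x[[f]])) stop("benchmark JSON '", path,
                              "' is missing field '", f, "'", call. = FALSE)
  bias_benchmark(
    name = x$name,
    description = if (is.null(x$description)) "" else x$description,
    targets = x$targets,
    attribute_groups = x$attribute_groups,
    references = unlist(x$references, use.names = FALSE))
}

read_benchmark_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta <- list(name = sub("\\.csv$", "", basename(path)),
               description = "", references = character())
  hdr <- grep("^#", lines, value = TRUE)
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*(name|description|reference):\\s*(.*)$", h))[[1L]]
    if (length(m) == 3L) {
      if (m[2L] == "reference") meta$references <- c(meta$references, m[3L])
      else meta[[m[2L]]] <- m[3L]
    }
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  df <- tryCatch(
    utils::read.csv(text = paste(body, collapse = "\n"),
                    stringsAsFactors = FALSE, encoding = "UTF-8"),
    error = function(e) stop("failed to parse CSV benchmark '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  need <- c("set_kind", "set_label", "term")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("CSV benchmark '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  split_sets <- function(kind) {
    sub <- df[df$set_kind == kind, , drop = FALSE]
    labs <- unique(sub$set_label)          # keep file order
    lapply(labs, function(l)
      list(label = l, terms = sub$term[sub$set_label == l]))
  }
  bias_benchmark(name = meta$name, description = meta$description,
                 targets = split_sets("target"),
                 attribute_groups = split_sets("attribute"),
                 references = meta$references)
}

#' Write a benchmark dataset to disk
#'
#' Inverse of [read_benchmark()]; `read_benchmark(write_benchmark(ds, p), p)`
#' round-trips exactly for both dialects. Files are UTF-8.
#'
#' @param ds a [bias_benchmark()].
#' @param path destination path.
#' @param format `"json"` or `"csv"`; default guesses from the extension.
#' @return `path`, invisibly.
#' @export
write_benchmark <- function(ds, path, format = c("auto", "json", "csv")) {
  stopifnot(inherits(ds, "bias_benchmark"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  if (format == "json") {
    obj <- list(name = ds$name, description = ds$description,
                targets = lapply(ds$targets, function(t)
                  list(label = t$label, terms = as.list(t$terms))),
                attribute_groups = lapply(ds$attribute_groups, function(g)
                  list(label = g$label, terms = as.list(g$terms))),
                references = as.list(ds$references))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    rows <- do.call(rbind, c(
      lapply(ds$targets, function(t)
        data.frame(set_kind = "target", set_label = t$label, term = t$terms)),
      lapply(ds$attribute_groups, function(g)
        data.frame(set_kind = "attribute", set_label = g$label, term = g$terms))))
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(c(sprintf("# name: %s", ds$name),
                 if (nzchar(ds$description))
                   sprintf("# description: %s", ds$description),
                 sprintf("# reference: %s", ds$references)), con)
    utils::write.csv(rows, con, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

#' Expected shapes of the bundled healthcare benchmarks
#'
#' Per-benchmark expected counts: number of terms per target set, number of
#' attribute groups, and terms per attribute group. The multi-class
#' benchmarks (E-2, H-1) store three labelled groups of four that pool to the
#' canonical 12-term attribute list; `pooled_attributes` records that total.
#'
#' @return data.frame with one row per benchmark name.
#' @export
benchmark_manifest <- function() {
  data.frame(
    name = c("G-1", "G-2", "G-3", "G-4", "E-1", "E-2", "H-1"),
    n_target_terms = c(6L, 11L, 5L, 10L, 5L, 4L, 6L),
    n_attribute_groups = c(2L, 2L, 2L, 2L, 2L, 3L, 3L),
    n_terms_per_group = c(8L, 8L, 8L, 8L, 7L, 4L, 4L),
    pooled_attributes = c(16L, 16L, 16L, 16L, 14L, 12L, 12L),
    stringsAsFactors = FALSE)
}

#' Validate a benchmark against the manifest
#'
#' Checks the structural invariants (duplicates, overlaps, equal target
#' sizes) and the expected Table-style counts for the named benchmark.
#'
#' @param ds a [bias_benchmark()].
#' @param manifest a data.frame as returned by [benchmark_manifest()].
#' @return a `validation_report`: list with `benchmark`, `violations`
#'   (each `list(code, message)`) and logical `pass`.
#' @export
validate_benchmark <- function(ds, manifest = benchmark_manifest()) {
  stopifnot(inherits(ds, "bias_benchmark"))
  row <- manifest[manifest$name == ds$name, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("unknown benchmark name '", ds$name, "' (not in manifest)")
  viol <- benchmark_violations(ds)
  add <- function(code, message)
    viol[[length(viol) + 1L]] <<- list(code = code, message = message)

  for (i in 1:2) {
    n <- length(ds$targets[[i]]$terms)
    if (n != row$n_target_terms)
      add("target-count", sprintf("target set %d: %d != %d expected",
                                  i, n, row$n_target_terms))
  }
  if (length(ds$attribute_groups) != row$n_attribute_groups)
    add("group-count", sprintf("attribute groups: %d != %d expected",
                               length(ds$attribute_groups),
                               row$n_attribute_groups))
  for (g in ds$attribute_groups)
    if (length(g$terms) != row$n_terms_per_group)
      add("attribute-count", sprintf("group '%s': %d != %d expected",
                                     g$label, length(g$terms),
                                     row$n_terms_per_group))
  pooled <- sum(vapply(ds$attribute_groups, function(g)
    length(g$terms), integer(1L)))
  if (pooled != row$pooled_attributes)
    add("pooled-count", sprintf("pooled attributes: %d != %d expected",
                                pooled, row$pooled_attributes))
  structure(list(benchmark = ds$name, violations = viol,
                 pass = length(viol) == 0L),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report '%s'>: %s\n", x$benchmark,
              if (x$pass) "PASS" else "FAIL"))
  for (v in x$violations) cat(sprintf("  [%s] %s\n", v$code, v$message))
  invisible(x)
}

#' Restrict a benchmark to embeddable terms
#'
#' Mirrors the construction-time rule that a term not recognized by the
#' reference embedding model is excluded. A multi-word term is representable
#' iff every whitespace token is in `vocab`. Dropping may break the
#' equal-target-size invariant; this is reported, never silently rebalanced.
#'
#' @param ds a [bias_benchmark()].
#' @param vocab character vector of known tokens.
#' @param split_hyphens also split tokens on hyphens before lookup.
#' @return list with `dataset` (filtered; carries attribute
#'   `"balanced"` = FALSE when target sizes now differ) and `dropped`
#'   (data.frame of term + originating set label).
#' @export
filter_by_vocabulary <- function(ds, vocab, split_hyphens = FALSE) {
  stopifnot(inherits(ds, "bias_benchmark"))
  if (length(vocab) == 0L) stop("vocab is empty")
  vocab <- as.character(vocab)
  representable <- function(term) {
    toks <- term_tokens(term, split_hyphens)
    all(toks %in% vocab)
  }
  dropped <- data.frame(term = character(), set_label = character())
  prune <- function(ts) {
    keep <- vapply(ts$terms, representable, logical(1L))
    if (!all(keep))
      dropped <<- rbind(dropped, data.frame(term = ts$terms[!keep],
                                            set_label = ts$label))
    if (!any(keep))
      stop("empty-set-after-filter: no term of set '", ts$label,
           "' is representable", call. = FALSE)
    ts$terms <- ts$terms[keep]
    ts
  }
  targets <- lapply(ds$targets, prune)
  groups <- lapply(ds$attribute_groups, prune)
  out <- structure(
    list(name = ds$name, description = ds$description, targets = targets,
         attribute_groups = groups, references = ds$references),
    class = "bias_benchmark")
  attr(out, "balanced") <-
    length(targets[[1L]]$terms) == length(targets[[2L]]$terms)
  list(dataset = out, dropped = dropped)
}

# whitespace tokenization of a term; hyphen splitting is opt-in
term_tokens <- function(term, split_hyphens = FALSE) {
  pat <- if (split_hyphens) "[[:space:]-]+" else "[[:space:]]+"
  toks <- strsplit(trimws(term), pat)[[1L]]
  toks[nzchar(toks)]
}

#' Load one of the bundled benchmark fixtures
#'
#' The seven bundled fixtures (G-1..G-4, E-1, E-2, H-1) carry the published
#' example terms plus clearly-labelled synthetic placeholder terms sized to
#' the manifest counts; the complete published word lists can be substituted
#' by pointing [read_benchmark()] at user-supplied files of the same shape.
#'
#' @param name benchmark name, e.g. `"G-1"`.
#' @return a [bias_benchmark()].
#' @export
load_bundled_benchmark <- function(name) {
  path <- system.file("extdata", "benchmarks", paste0(name, ".json"),
                      package = "medbias")
  if (!nzchar(path))
    stop("no bundled benchmark named '", name, "'; available: ",
         paste(benchmark_manifest()$name, collapse = ", "))
  read_benchmark(path, "json")
}
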