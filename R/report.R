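#' Score a grid of embedding sources against benchmarks
#'
#' Runs one statistic (SD-WEAT or WEAT) for every (embedding source,
#' benchmark) cell and collects a report table in the style of a
#' models-by-benchmarks summary: score to 3 decimals with the p-value in
#' parentheses and an asterisk marking significance at `alpha`. A failed
#' cell is recorded as an error cell and the suite continues.
#'
#' @param benchmarks named list of [bias_benchmark()] objects (or file paths
#'   accepted by [read_benchmark()]).
#' @param tables named list of [embedding_table()] objects (or glove-text
#'   file paths).
#' @param statistic `"sdweat"` or `"weat"`.
#' @param policy an [embed_policy()].
#' @param alpha significance threshold, in (0, 1).
#' @param seed base seed; cell (i, j) uses `seed + 100 * i + j`.
#' @param K SD-WEAT draws per cell.
#' @param pvalue_reps SD-WEAT null replicates.
#' @return a `report_table`: long data.frame (`source`, `benchmark`,
#'   `score`, `p_value`, `significant`, `error`) with `alpha`, `statistic`
#'   and seeds attached as attributes.
#' @export
run_suite <- function(benchmarks, tables, statistic = c("sdweat", "weat"),
                      policy = embed_policy(), alpha = 0.05, seed = 1L,
                      K = 100L, pvalue_reps = 1000L) {
  statistic <- match.arg(statistic)
  stopifnot(alpha > 0, alpha < 1,
            length(benchmarks) >= 1L, length(tables) >= 1L)
  benchmarks <- lapply(benchmarks, function(b)
    if (inherits(b, "bias_benchmark")) b else read_benchmark(b))
  if (is.null(names(benchmarks)))
    names(benchmarks) <- vapply(benchmarks, `[[`, "", "name")
  tables <- lapply(tables, function(t)
    if (inherits(t, "embedding_table")) t else load_word_vectors(t))
  if (is.null(names(tables)))
    names(tables) <- vapply(tables, `[[`, "", "name")
  rows <- list()
  for (i in seq_along(tables)) for (j in seq_along(benchmarks)) {
    cell_seed <- seed + 100L * i + j
    cell <- tryCatch({
      if (statistic == "sdweat") {
        r <- run_sdweat(benchmarks[[j]], tables[[i]], policy, K = K,
                        seed = cell_seed, pvalue_reps = pvalue_reps)
        list(score = r$score, p = r$p_value, error = NA_character_)
      } else {
        r <- run_weat(benchmarks[[j]], tables[[i]], policy = policy,
                      seed = cell_seed)
        list(score = r$effect_size, p = r$p_value, error = NA_character_)
      }
    }, error = function(e)
      list(score = NA_real_, p = NA_real_, error = conditionMessage(e)))
    rows[[length(rows) + 1L]] <- data.frame(
      source = names(tables)[i], benchmark = names(benchmarks)[j],
      score = cell$score, p_value = cell$p,
      significant = !is.na(cell$p) & cell$p < alpha,
      error = cell$error, seed = cell_seed)
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "statistic") <- statistic
  attr(out, "base_seed") <- seed
  class(out) <- c("report_table", "data.frame")
  out
}

# "0.727*(0.003)"-style rendering of one cell
format_report_cell <- function(score, p, significant) {
  if (is.na(score)) return("ERROR")
  sprintf("%.3f%s(%s)", score, if (isTRUE(significant)) "*" else "",
          if (is.na(p)) "NA"
          else if (p < 0.001) "< 0.001" else sprintf("%.3f", p))
}

#' Write a report table
#'
#' TSV and markdown render the sources-by-benchmarks grid with
#' `score*(p)`-style cells (asterisk iff `p < alpha`); JSON carries the long
#' table at full precision plus the run metadata.
#'
#' @param report a `report_table` from [run_suite()].
#' @param path destination path.
#' @param format `"tsv"`, `"json"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("tsv", "json", "markdown")) {
  stopifnot(inherits(report, "report_table"))
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(statistic = attr(report, "statistic"),
           alpha = attr(report, "alpha"),
           base_seed = attr(report, "base_seed"),
           cells = as.data.frame(report)),
      path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
    return(invisible(path))
  }
  sources <- unique(report$source)
  benches <- unique(report$benchmark)
  grid <- matrix("", nrow = length(sources), ncol = length(benches),
                 dimnames = list(sources, benches))
  for (k in seq_len(nrow(report)))
    grid[report$source[k], report$benchmark[k]] <-
      format_report_cell(report$score[k], report$p_value[k],
                         report$significant[k])
  lines <- if (format == "tsv") {
    c(paste(c("source", benches), collapse = "\t"),
      vapply(sources, function(s)
        paste(c(s, grid[s, ]), collapse = "\t"), character(1L)))
  } else {
    c(paste0("| source | ", paste(benches, collapse = " | "), " |"),
      paste0("|", paste(rep("---", length(benches) + 1L), collapse = "|"), "|"),
      vapply(sources, function(s)
        paste0("| ", s, " | ", paste(grid[s, ], collapse = " | "), " |"),
        character(1L)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path path written by [write_report()] with `format = "json"`.
#' @return a `report_table`.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- x$cells
  attr(out, "alpha") <- x$alpha
  attr(out, "statistic") <- x$statistic
  attr(out, "base_seed") <- x$base_seed
  class(out) <- c("report_table", "data.frame")
  out
}

#' @export
print.report_table <- function(x, ...) {
  cat(sprintf("<report_table: %s, alpha = %g>\n", attr(x, "statistic"),
              attr(x, "alpha")))
  print.data.frame(x)
  invisible(x)
}
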