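#' Read a KO abundance table from TSV
#'
#' Expects a header row of sample ids and a first column of feature (KO)
#' ids; all remaining cells numeric.
#'
#' @param path Path to a tab-separated file.
#' @return Numeric matrix, features x samples.
#' @export
read_abundance <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_validation("abundance table needs an id column plus samples: ", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids) || anyNA(ids) || any(ids == "")) {
    stop_validation("feature ids must be unique and non-empty: ", path)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop_validation("non-numeric or missing abundance cells: ", path)
  rownames(m) <- ids
  m
}

#' Read a sample metadata table from TSV
#'
#' @param path Tab-separated file with columns `sample` and `group`.
#' @return Data frame with character columns `sample` and `group`.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(df))) {
    stop_validation("metadata needs columns 'sample' and 'group': ", path)
  }
  df$sample <- as.character(df$sample)
  df$group <- as.character(df$group)
  df
}

#' Read a per-KO statistics table from TSV
#'
#' Accepts any tab-separated table with columns `ko` and `p_value`, and
#' optionally `statistic` (signed, needed for directed mode) and `test`.
#'
#' @param path Path to the TSV.
#' @return Data frame validated for the reporter pipeline.
#' @export
read_ko_stats <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  validate_ko_stats(df, need_statistic = FALSE)
}

#' Write a per-KO statistics table to TSV
#'
#' @param ko_stats Data frame as produced by [ko_diff_test()] or
#'   [simulate_pvalues()].
#' @param path Output path.
#' @export
write_ko_stats <- function(ko_stats, path) {
  write_tsv_6dp(ko_stats, path)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One pathway per line: `name TAB description TAB member TAB member ...`.
#' Duplicate members within a line are deduplicated with a warning;
#' duplicate pathway names are an error; a line with fewer than three fields
#' is a parse error naming the line.
#'
#' @param path Path to the GMT file.
#' @return A [pathway_set()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop_validation("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop_validation("malformed GMT line ", short[1L], " (fewer than 3 fields): ", path)
  }
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop_validation("duplicate pathway name(s) in GMT: ",
                    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  desc <- vapply(fields, `[[`, "", 2L)
  members <- lapply(fields, function(f) f[-(1:2)])
  dup <- vapply(members, anyDuplicated, 0L) > 0L
  if (any(dup)) {
    warning("duplicate members deduplicated in pathway(s): ",
            paste(ids[dup], collapse = ", "))
  }
  names(members) <- ids
  pathway_set(members, descriptions = desc)
}

#' Write gene sets in GMT format
#'
#' @param pathways A [pathway_set()].
#' @param path Output path.
#' @export
write_gmt <- function(pathways, path) {
  if (!inherits(pathways, "pathway_set")) pathways <- pathway_set(pathways)
  desc <- attr(pathways, "descriptions")
  lines <- vapply(names(pathways), function(id) {
    paste(c(id, desc[[id]], pathways[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column KO-to-pathway mapping
#'
#' Tab-separated `ko TAB pathway` pairs, one per line. A header row naming
#' the two columns (`ko`, `pathway`, any order) is auto-detected and
#' skipped. Duplicate pairs are deduplicated with a warning.
#'
#' @param path Path to the TSV.
#' @return A [pathway_set()].
#' @export
read_ko_pairs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop_validation("empty KO-pathway mapping: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad)) {
    stop_validation("malformed mapping line ", bad[1L], " (need exactly 2 fields): ", path)
  }
  ko_col <- 1L; pw_col <- 2L
  first <- tolower(fields[[1L]])
  if (setequal(first, c("ko", "pathway"))) {
    ko_col <- match("ko", first); pw_col <- match("pathway", first)
    fields <- fields[-1L]
    if (length(fields) == 0L) stop_validation("mapping contains only a header row: ", path)
  }
  ko <- vapply(fields, `[[`, "", ko_col)
  pw <- vapply(fields, `[[`, "", pw_col)
  if (anyDuplicated(paste(ko, pw, sep = "\r"))) {
    warning("duplicate (ko, pathway) pair(s) deduplicated: ", path)
  }
  members <- lapply(split(ko, pw), unique)
  pathway_set(members)
}

#' Write an enrichment result table to TSV (with full-precision sidecar)
#'
#' Numeric columns are serialized with six decimal places in the TSV for
#' readability and diffability; when `sidecar = TRUE` (default) a JSON file
#' `<path>.json` stores the same rows at full double precision, and
#' [read_results()] will prefer it.
#'
#' @param result A `reporter_result`, `ora_result` or plain data frame.
#' @param path Output TSV path.
#' @param sidecar Also write `<path>.json` at full precision.
#' @export
write_results <- function(result, path, sidecar = TRUE) {
  df <- as.data.frame(result)
  write_tsv_6dp(df, path)
  if (sidecar) {
    jsonlite::write_json(df, paste0(path, ".json"), digits = NA,
                         dataframe = "columns", na = "null")
  }
  invisible(path)
}

#' Read an enrichment result table written by [write_results()]
#'
#' Prefers the full-precision JSON sidecar `<path>.json` when present,
#' falling back to the 6-decimal TSV.
#'
#' @param path The TSV path given to [write_results()].
#' @return Data frame.
#' @export
read_results <- function(path) {
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    cols <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    as.data.frame(cols, stringsAsFactors = FALSE)
  } else {
    utils::read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  }
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run bit-identically: the
#' package version, R version, subcommand parameters and seed. Contains no
#' timestamp, so identical runs produce identical manifests.
#'
#' @param params Named list of run parameters (including the seed).
#' @param path Output JSON path.
#' @export
write_manifest <- function(params, path) {
  manifest <- list(
    package = "koreporter",
    package_version = as.character(utils::packageVersion("koreporter")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    params = params)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

# fixed 6-decimal serialisation for double columns; integers written as-is
write_tsv_6dp <- function(df, path) {
  out <- df
  dbl <- vapply(out, function(x) is.double(x), logical(1L))
  out[dbl] <- lapply(out[dbl], function(x) ifelse(is.na(x), "NA", sprintf("%.6f", x)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
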