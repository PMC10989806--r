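#' Two-group differential tests for a KO abundance table
#'
#' Runs a two-sided two-sample test per feature (KO) of an abundance table,
#' producing the per-KO P values and signed statistics that feed the
#' reporter-score pipeline. The statistic's sign is positive when the
#' treatment group's location exceeds the reference group's.
#'
#' Features with zero variance in *both* groups are degenerate for
#' variance-based tests; they are assigned p = 1 and statistic 0 with a
#' single collected warning, so one flat KO cannot abort a run.
#'
#' @param abundance Numeric matrix or data frame, features x samples, with
#'   unique feature row names and sample column names.
#' @param groups Two-group assignment: a data frame with columns `sample`
#'   and `group`, or a named character vector (names = samples). Exactly two
#'   distinct labels; every assigned sample must be a column of `abundance`.
#' @param method `"welch_t"` (default; unequal variances are the norm in
#'   abundance data), `"student_t"`, or `"wilcoxon"` (rank-sum; exact where
#'   [stats::wilcox.test()] supports it, normal approximation with tie
#'   correction otherwise).
#' @param reference Label of the reference group. Defaults to the first
#'   label in sort order, with a message.
#' @param log Log-transform abundances (`log(x + offset)`) before testing.
#'   Off by default.
#' @param log_offset Offset for the log transform; defaults to half the
#'   smallest positive value when zeros are present, else 0.
#' @return Data frame with one row per feature, in input feature order:
#'   columns `ko`, `p_value`, `statistic`, `test`.
#' @examples
#' ab <- rbind(K00001 = c(1, 2, 3, 4, 2, 3, 4, 5),
#'             K00002 = c(5, 6, 5, 6, 1, 2, 1, 2))
#' colnames(ab) <- paste0("s", 1:8)
#' grp <- data.frame(sample = paste0("s", 1:8),
#'                   group = rep(c("ctrl", "case"), each = 4))
#' ko_diff_test(ab, grp, method = "student_t", reference = "ctrl")
#' @export
ko_diff_test <- function(abundance, groups,
                         method = c("welch_t", "student_t", "wilcoxon"),
                         reference = NULL, log = FALSE, log_offset = NULL) {
  method <- match.arg(method)
  abundance <- as.matrix(abundance)
  if (!is.numeric(abundance)) stop_validation("'abundance' must be numeric")
  if (is.null(rownames(abundance)) || anyDuplicated(rownames(abundance))) {
    stop_validation("'abundance' needs unique feature row names")
  }
  if (is.null(colnames(abundance)) || anyDuplicated(colnames(abundance))) {
    stop_validation("'abundance' needs unique sample column names")
  }

  g <- as_group_assignment(groups)
  missing_samples <- setdiff(names(g), colnames(abundance))
  if (length(missing_samples)) {
    stop_validation("assigned sample(s) absent from the abundance table: ",
                    paste(missing_samples, collapse = ", "))
  }
  labels <- sort(unique(unname(g)))
  if (length(labels) != 2L) {
    stop_validation("'groups' must contain exactly two distinct labels, got: ",
                    paste(labels, collapse = ", "))
  }
  if (is.null(reference)) {
    reference <- labels[1L]
    message("no reference group given; using '", reference, "'")
  }
  if (!reference %in% labels) {
    stop_validation("reference group '", reference, "' not among the labels")
  }
  treatment <- setdiff(labels, reference)
  ref_samples <- names(g)[g == reference]
  trt_samples <- names(g)[g == treatment]
  min_n <- if (method == "wilcoxon") 1L else 2L
  if (length(ref_samples) < min_n || length(trt_samples) < min_n) {
    stop_validation("each group needs >= ", min_n, " samples for method '",
                    method, "'")
  }

  x <- abundance[, c(trt_samples, ref_samples), drop = FALSE]
  if (log) {
    if (any(x < 0)) stop_validation("negative abundances cannot be log-transformed")
    if (is.null(log_offset)) {
      log_offset <- if (any(x == 0)) min(x[x > 0]) / 2 else 0
    }
    x <- base::log(x + log_offset)
  }
  trt_idx <- seq_along(trt_samples)
  ref_idx <- length(trt_samples) + seq_along(ref_samples)

  n_feat <- nrow(x)
  p_value <- numeric(n_feat)
  statistic <- numeric(n_feat)
  degenerate <- character(0)
  for (i in seq_len(n_feat)) {
    a <- x[i, trt_idx]
    b <- x[i, ref_idx]
    if (method == "wilcoxon") {
      fit <- suppressWarnings(stats::wilcox.test(a, b))
      # centre W so the sign follows the treatment-vs-reference convention
      statistic[i] <- unname(fit$statistic) - length(a) * length(b) / 2
      p_value[i] <- fit$p.value
    } else {
      if (stats::var(a) == 0 && stats::var(b) == 0) {
        degenerate <- c(degenerate, rownames(x)[i])
        statistic[i] <- 0
        p_value[i] <- 1
        next
      }
      fit <- tryCatch(
        stats::t.test(a, b, var.equal = method == "student_t"),
        error = function(e) NULL)
      if (is.null(fit)) {  # essentially-constant data within t.test tolerance
        degenerate <- c(degenerate, rownames(x)[i])
        statistic[i] <- 0
        p_value[i] <- 1
      } else {
        statistic[i] <- unname(fit$statistic)
        p_value[i] <- fit$p.value
      }
    }
  }
  if (length(degenerate)) {
    warning(length(degenerate),
            " feature(s) with (near-)zero variance in both groups set to p = 1, statistic = 0: ",
            paste(utils::head(degenerate, 5L), collapse = ", "),
            if (length(degenerate) > 5L) ", ..." else "")
  }
  data.frame(ko = rownames(x), p_value = p_value, statistic = statistic,
             test = method, stringsAsFactors = FALSE)
}

# normalise a group assignment to a named character vector sample -> label
as_group_assignment <- function(groups) {
  if (is.data.frame(groups)) {
    if (!all(c("sample", "group") %in% names(groups))) {
      stop_validation("'groups' data frame needs columns 'sample' and 'group'")
    }
    g <- stats::setNames(as.character(groups$group), as.character(groups$sample))
  } else if (!is.null(names(groups))) {
    g <- stats::setNames(as.character(groups), names(groups))
  } else {
    stop_validation("'groups' must be a sample/group data frame or a named vector")
  }
  if (anyDuplicated(names(g))) stop_validation("duplicate sample ids in 'groups'")
  if (anyNA(g) || any(g == "")) stop_validation("missing group labels")
  g
}
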