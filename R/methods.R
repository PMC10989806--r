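#' @export
print.reporter_result <- function(x, n = 10L, digits = 4L, ...) {
  p <- attr(x, "params")
  cat(sprintf("Reporter-score enrichment (%s mode): %d row(s), %d KOs, cutoff %g\n",
              p$mode, nrow(x), p$n_kos, p$cutoff))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], round, digits = digits)
  print(utils::head(df, n), row.names = FALSE)
  if (nrow(x) > n) cat(sprintf("... %d more row(s)\n", nrow(x) - n))
  cat("Note: the score is undirected; a negative score means no evidence of\n",
      "enrichment, not down-regulation.\n", sep = "")
  invisible(x)
}

#' Summarise a reporter-score fit
#'
#' Reports, per mode, how many pathways exceed the cutoff, the score range
#' and the background method used for each size class.
#'
#' @param object A `reporter_result` from [reporter_score()].
#' @param ... Unused.
#' @export
summary.reporter_result <- function(object, ...) {
  p <- attr(object, "params")
  bg <- attr(object, "background")
  cat(sprintf("Reporter-score enrichment, %s mode\n", p$mode))
  cat(sprintf("  KO universe: %d; pathways scored: %d; min_k: %d\n",
              p$n_kos, p$n_pathways_scored, p$min_k))
  cat(sprintf("  background: %s, %d subsets per size class; seed: %s\n",
              paste(unique(bg$method), collapse = "/"),
              p$n_background, if (is.null(p$seed)) "none" else p$seed))
  for (m in unique(object$mode)) {
    i <- object$mode == m
    cat(sprintf("  [%s] %d/%d pathway(s) with score > %g; score range [%.3f, %.3f]\n",
                m, sum(object$significant[i]), sum(i), p$cutoff,
                min(object$reporter_score[i], na.rm = TRUE),
                max(object$reporter_score[i], na.rm = TRUE)))
  }
  invisible(object)
}

#' Bar plot of reporter scores
#'
#' One bar per pathway (per mode row in directed fits), ordered by score,
#' with the significance cutoff drawn as a dashed line. Bars are shaded by
#' significance only — deliberately not by sign, because the sign of an
#' undirected reporter score carries no regulation direction.
#'
#' @param x A `reporter_result`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.reporter_result <- function(x, ...) {
  p <- attr(x, "params")
  df <- as.data.frame(x)
  df <- df[!is.na(df$reporter_score), , drop = FALSE]
  lab <- if (all(df$mode == "undirected")) df$pathway else
    paste(df$pathway, df$mode, sep = ":")
  col <- ifelse(df$significant, "firebrick", "grey70")
  graphics::barplot(df$reporter_score, names.arg = lab, las = 2,
                    col = col, border = NA,
                    ylab = "reporter score (undirected)", ...)
  graphics::abline(h = p$cutoff, lty = 2)
  invisible(x)
}

#' @export
as.data.frame.reporter_result <- function(x, ...) {
  attr(x, "background") <- NULL
  attr(x, "params") <- NULL
  class(x) <- "data.frame"
  x
}

#' @export
print.ora_result <- function(x, n = 10L, digits = 4L, ...) {
  cat(sprintf("Hypergeometric over-representation: %d pathway(s), %d/%d KOs significant at alpha = %g\n",
              nrow(x), attr(x, "n_sig"), attr(x, "n_universe"), attr(x, "alpha")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], round, digits = digits)
  print(utils::head(df, n), row.names = FALSE)
  if (nrow(x) > n) cat(sprintf("... %d more row(s)\n", nrow(x) - n))
  invisible(x)
}

#' @export
as.data.frame.ora_result <- function(x, ...) {
  attr(x, "n_sig") <- NULL
  attr(x, "n_universe") <- NULL
  attr(x, "alpha") <- NULL
  class(x) <- "data.frame"
  x
}
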