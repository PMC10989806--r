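#' Upper-tail hypergeometric probability
#'
#' `P(X >= x)` for X ~ hypergeometric: the chance of drawing at least `x`
#' pathway members when `n` significant KOs are sampled from a universe of
#' `N` KOs of which `K` belong to the pathway. Exact (no approximation).
#'
#' @param x Observed overlap, `0 <= x <= min(K, n)`.
#' @param K Pathway size within the universe.
#' @param n Size of the significant-KO list.
#' @param N Universe size; `K <= N`, `n <= N`.
#' @return Upper-tail probability in (0, 1].
#' @examples
#' hypergeom_upper(5, 5, 10, 20)  # choose(10,5)/choose(20,5) = 0.01625387
#' @export
hypergeom_upper <- function(x, K, n, N) {
  bad <- x < 0 | K < 0 | n < 0 | N < 0 | K > N | n > N | x > pmin(K, n)
  if (any(!is.finite(c(x, K, n, N))) || any(bad)) {
    stop_validation("inconsistent hypergeometric counts (need 0 <= x <= min(K, n); K, n <= N)")
  }
  stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric over-representation analysis (ORA)
#'
#' The classical comparator to the reporter score: the universe is the set
#' of tested KOs, the "significant" list is the KOs with `p_value < alpha`,
#' and each pathway is tested for over-representation of significant KOs
#' with the one-sided (upper-tail) hypergeometric test. Unlike the reporter
#' score, ORA depends on the a-priori significance cutoff and ignores the
#' strength of evidence below it.
#'
#' @param ko_stats Data frame with columns `ko` and `p_value`.
#' @param pathways A [pathway_set()] or named list of KO-id vectors.
#' @param alpha Per-KO significance cutoff; default 0.05.
#' @param min_k Minimum pathway size after intersection with the universe;
#'   default 3 (matching [reporter_score()], so both methods score the same
#'   pathways).
#' @return An `ora_result` data frame, sorted by `p_hyper` ascending (ties
#'   by pathway id), with columns `pathway`, `k`, `n_sig`, `overlap`,
#'   `p_hyper`, `q_value` (BH across pathways). An empty significant list is
#'   not an error: every row then has overlap 0 and p = 1.
#' @examples
#' stats_df <- data.frame(ko = sprintf("K%05d", 1:20),
#'                        p_value = c(rep(0.01, 5), rep(0.5, 15)))
#' run_ora(stats_df, list(pwA = sprintf("K%05d", 1:5),
#'                        pwB = sprintf("K%05d", 10:15)))
#' @export
run_ora <- function(ko_stats, pathways, alpha = 0.05, min_k = 3L) {
  ko_stats <- validate_ko_stats(ko_stats)
  if (!inherits(pathways, "pathway_set")) pathways <- pathway_set(pathways)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_validation("'alpha' must be in (0, 1)")
  }
  universe <- ko_stats$ko
  kept <- intersect_pathways(pathways, universe, min_k)
  if (length(kept) == 0L) {
    stop_validation("no pathway retains >= ", min_k, " members in the KO universe")
  }
  sig <- universe[ko_stats$p_value < alpha]
  N <- length(universe)
  n <- length(sig)
  res <- do.call(rbind, lapply(names(kept), function(id) {
    members <- kept[[id]]
    K <- length(members)
    x <- length(intersect(members, sig))
    data.frame(pathway = id, k = K, n_sig = n, overlap = x,
               p_hyper = hypergeom_upper(x, K, n, N),
               stringsAsFactors = FALSE)
  }))
  res$q_value <- stats::p.adjust(res$p_hyper, method = "BH")
  res <- res[order(res$p_hyper, res$pathway), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, n_sig = n, n_universe = N, alpha = alpha,
            class = c("ora_result", "data.frame"))
}

#' Run reporter-score and ORA side by side
#'
#' Convenience wrapper for method comparison: fits [reporter_score()]
#' (undirected) and [run_ora()] on the same KO universe and pathway set and
#' joins the two result tables by pathway.
#'
#' @inheritParams reporter_score
#' @param alpha Per-KO cutoff for the ORA significant list.
#' @return Data frame keyed by `pathway` with the reporter columns
#'   (`reporter_score`, `p_equiv`, `q_reporter`) and the ORA columns
#'   (`overlap`, `p_hyper`, `q_hyper`), sorted by reporter score descending.
#' @export
compare_methods <- function(ko_stats, pathways, alpha = 0.05,
                            n_background = 1000L, min_k = 3L, cutoff = 1.64,
                            seed = NULL) {
  rep_fit <- reporter_score(ko_stats, pathways, mode = "undirected",
                            n_background = n_background, min_k = min_k,
                            cutoff = cutoff, seed = seed)
  ora_fit <- run_ora(ko_stats, pathways, alpha = alpha, min_k = min_k)
  r <- as.data.frame(rep_fit)[, c("pathway", "k", "z_pathway",
                                  "reporter_score", "p_equiv", "q_value",
                                  "significant")]
  names(r)[names(r) == "q_value"] <- "q_reporter"
  names(r)[names(r) == "significant"] <- "significant_reporter"
  o <- as.data.frame(ora_fit)[, c("pathway", "n_sig", "overlap", "p_hyper",
                                  "q_value")]
  names(o)[names(o) == "q_value"] <- "q_hyper"
  out <- merge(r, o, by = "pathway", sort = FALSE)
  out <- out[order(-out$reporter_score, out$pathway, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}
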