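#' Inverse-normal transform of a P value
#'
#' Converts a P value into a Z score through the inverse of the standard
#' normal cumulative distribution, `qnorm(1 - p)`. P values are clipped into
#' `[eps, 1 - eps]` first so that p = 0 or p = 1 yields a large finite Z
#' rather than an infinity.
#'
#' The transform depends on the P value only: a Z score above 0 means
#' p < 0.5, nothing more. In particular a *negative* Z arises from p > 0.5,
#' i.e. a feature with no evidence of differential abundance — it does not
#' mean the feature is down-regulated.
#'
#' @param p Numeric vector of P values in \[0, 1\].
#' @param eps Clipping bound; default `1e-15`.
#' @return Numeric vector of Z scores, strictly decreasing in `p`.
#' @examples
#' p_to_z(c(0.5, 0.05, 0.95))  # 0, 1.64, -1.64
#' @seealso [score_to_p()] for the reverse direction.
#' @export
p_to_z <- function(p, eps = 1e-15) {
  if (!is.numeric(p) || anyNA(p)) {
    stop_validation("'p' must be numeric with no missing values")
  }
  if (any(p < 0 | p > 1)) {
    stop_validation("P values must lie in [0, 1]")
  }
  p <- pmin(pmax(p, eps), 1 - eps)
  stats::qnorm(p, lower.tail = FALSE)
}

#' Size-independent aggregate of member Z scores
#'
#' Aggregates the Z scores of a pathway's k member KOs as
#' `sum(z) / sqrt(k)`. The `1/sqrt(k)` normalisation keeps the aggregate on
#' the standard normal scale when the members are independent standard
#' normals, which is what makes the statistic comparable across pathway
#' sizes ("size-independent"). See the methods vignette for why `1/sqrt(k)`
#' rather than `1/k` is the correct reading.
#'
#' @param z Non-empty numeric vector of finite Z scores.
#' @return The aggregate Z (scalar).
#' @examples
#' aggregate_z(c(1, 1, 1, 1))  # 2
#' @export
aggregate_z <- function(z) {
  if (length(z) == 0L) stop_validation("'z' must be non-empty")
  if (!is.numeric(z) || any(!is.finite(z))) {
    stop_validation("'z' must be finite numeric")
  }
  sum(z) / sqrt(length(z))
}

#' Background mean and standard deviation for pathways of size k
#'
#' Estimates the null location and scale of the aggregate Z for random KO
#' sets of size `k` drawn from the scored universe. When the number of
#' subsets `choose(n, k)` is at most `exhaustive_cap` every subset is
#' enumerated; otherwise `n_samples` subsets are drawn by Monte Carlo
#' (uniformly, without replacement within a subset, with replacement across
#' subsets). The standard deviation is the population (divide-by-n) form.
#'
#' @param all_z Numeric vector of Z scores for the whole KO universe.
#' @param k Subset size, `1 <= k <= length(all_z)`.
#' @param n_samples Number of Monte-Carlo subsets (ignored when exhaustive).
#' @param seed Optional RNG seed; `NULL` uses the current stream.
#' @param method `"auto"` (default), `"monte_carlo"` or `"exhaustive"`.
#' @param exhaustive_cap Enumerate exhaustively when `choose(n, k)` is at
#'   most this many subsets; default 1e5.
#' @return A list with elements `k`, `mu_k`, `sigma_k`, `n_samples` (number
#'   of subsets actually aggregated) and `method`.
#' @examples
#' background_stats(c(0, 1, 2), k = 2)  # exhaustive: mu 1.4142, sigma 0.5774
#' @export
background_stats <- function(all_z, k, n_samples = 1000L, seed = NULL,
                             method = c("auto", "monte_carlo", "exhaustive"),
                             exhaustive_cap = 1e5) {
  method <- match.arg(method)
  n <- length(all_z)
  if (!is.numeric(all_z) || n == 0L || any(!is.finite(all_z))) {
    stop_validation("'all_z' must be non-empty finite numeric")
  }
  if (k < 1L || k > n) stop_validation("'k' must be in [1, length(all_z)]")
  n_subsets <- choose(n, k)
  use_exhaustive <- method == "exhaustive" ||
    (method == "auto" && n_subsets <= exhaustive_cap)
  if (use_exhaustive) {
    agg <- utils::combn(all_z, k, FUN = sum) / sqrt(k)
    used <- length(agg)
    method_used <- "exhaustive"
  } else {
    if (n_samples < 2L) stop_validation("'n_samples' must be >= 2 for Monte Carlo")
    agg <- with_seed(seed, {
      vapply(seq_len(n_samples),
             function(i) sum(all_z[sample.int(n, k)]),
             numeric(1L))
    }) / sqrt(k)
    used <- n_samples
    method_used <- "monte_carlo"
  }
  list(k = as.integer(k), mu_k = mean(agg), sigma_k = pop_sd(agg),
       n_samples = as.integer(used), method = method_used)
}

#' Background-corrected reporter score
#'
#' `(z_pathway - mu_k) / sigma_k`, the reporter score of a pathway given the
#' background moments for its size class.
#'
#' @param z_pathway Aggregate Z of the pathway (see [aggregate_z()]).
#' @param mu_k,sigma_k Background mean and standard deviation for size k;
#'   `sigma_k` must be strictly positive.
#' @return The reporter score (scalar or vector, recycled element-wise).
#' @export
corrected_score <- function(z_pathway, mu_k, sigma_k) {
  if (any(!is.finite(sigma_k)) || any(sigma_k <= 0)) {
    stop_validation("degenerate background: 'sigma_k' must be > 0")
  }
  (z_pathway - mu_k) / sigma_k
}

#' Equivalent one-sided P value of a reporter score
#'
#' Upper-tail conversion `1 - pnorm(z)`. A score of 1.6449 corresponds to
#' P = 0.05; a score of 0 to P = 0.5; large negative scores approach P = 1,
#' i.e. no evidence of enrichment (never "depleted" or "down-regulated").
#'
#' @param z Finite numeric vector of reporter scores.
#' @return Upper-tail probabilities in (0, 1).
#' @export
score_to_p <- function(z) {
  if (!is.numeric(z) || any(!is.finite(z))) {
    stop_validation("'z' must be finite numeric")
  }
  stats::pnorm(z, lower.tail = FALSE)
}

#' Split a two-sided P value into directional one-tailed P values
#'
#' The directed (reporter-feature-style) workflow scores up- and
#' down-regulation separately. A two-sided P value `p` with direction `sign`
#' becomes `p_up = p/2` when the feature moved up (`sign > 0`) and
#' `p_up = 1 - p/2` when it moved down; `p_down = 1 - p_up`. A zero sign
#' (no direction information) gives the uninformative pair (0.5, 0.5).
#'
#' @param p Numeric vector of two-sided P values in \[0, 1\].
#' @param sign Direction indicator per element: -1, 0 or +1 (any numeric;
#'   only its sign is used). Recycled against `p`.
#' @return A list with numeric vectors `p_up` and `p_down`
#'   (`p_up + p_down == 1` element-wise).
#' @examples
#' split_directional(0.04, +1)  # p_up = 0.02, p_down = 0.98
#' @export
split_directional <- function(p, sign) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop_validation("'p' must be numeric in [0, 1]")
  }
  s <- base::sign(as.numeric(sign))
  n <- max(length(p), length(s))
  p <- rep_len(p, n); s <- rep_len(s, n)
  p_up <- ifelse(s > 0, p / 2, ifelse(s < 0, 1 - p / 2, 0.5))
  list(p_up = p_up, p_down = 1 - p_up)
}

#' Reporter-score pathway enrichment
#'
#' The main fitting function. Per-KO P values are transformed to Z scores
#' ([p_to_z()]), aggregated per pathway with the size-independent sum
#' ([aggregate_z()]) and corrected against a background of random KO sets of
#' the same size ([background_stats()], [corrected_score()]).
#'
#' **Interpretation rule.** The reporter score is *undirected*: it is a
#' function of the P values alone, so its sign does not encode the direction
#' of regulation. A pathway is enriched when its score exceeds `cutoff`
#' (default 1.64, the upper 5% point of the standard normal); a *negative*
#' score means the pathway's members have large P values — no evidence of
#' enrichment — and must never be read as "down-regulated". For directional
#' conclusions use `mode = "directed"`, which scores up- and down-regulation
#' separately from one-tailed P values ([split_directional()]).
#'
#' @param ko_stats Data frame with columns `ko` (unique ids) and `p_value`;
#'   a `statistic` column (signed, treatment vs reference) is required for
#'   `mode = "directed"`.
#' @param pathways A [pathway_set()] or named list of KO-id vectors.
#' @param mode `"undirected"` (default) or `"directed"` (two rows per
#'   pathway, modes `"up"` and `"down"`, each independently corrected).
#' @param n_background Monte-Carlo subsets per size class k; default 1000.
#' @param min_k Pathways with fewer members than this in the scored universe
#'   are dropped with a notice; default 3.
#' @param cutoff Significance cutoff on the reporter score (applies to the
#'   signed score, never its absolute value); default 1.64.
#' @param seed Optional RNG seed; one shared stream drives all background
#'   draws, taken in ascending-k order, so results do not depend on pathway
#'   input order.
#' @param exhaustive_cap Passed to [background_stats()].
#' @return A `reporter_result`: a data frame with one row per pathway (two
#'   in directed mode) and columns `pathway`, `mode`, `k`, `z_pathway`,
#'   `mu_k`, `sigma_k`, `reporter_score`, `p_equiv`, `q_value`,
#'   `significant`, sorted by score (descending, ties by pathway id).
#'   Attributes: `background` (per-k moments), `params`. A degenerate
#'   background (`sigma_k = 0`) yields `NA` scores with a warning.
#' @examples
#' set.seed(1)
#' stats_df <- data.frame(ko = sprintf("K%05d", 1:40),
#'                        p_value = runif(40),
#'                        statistic = rnorm(40))
#' ps <- pathway_set(list(pwA = sprintf("K%05d", 1:8),
#'                        pwB = sprintf("K%05d", 20:31)))
#' fit <- reporter_score(stats_df, ps, seed = 42)
#' fit
#' @export
reporter_score <- function(ko_stats, pathways,
                           mode = c("undirected", "directed"),
                           n_background = 1000L, min_k = 3L, cutoff = 1.64,
                           seed = NULL, exhaustive_cap = 1e5) {
  mode <- match.arg(mode)
  ko_stats <- validate_ko_stats(ko_stats, need_statistic = mode == "directed")
  if (!inherits(pathways, "pathway_set")) pathways <- pathway_set(pathways)
  if (cutoff <= 0) stop_validation("'cutoff' must be > 0")
  universe <- ko_stats$ko
  if (length(universe) == 0L) stop_validation("empty KO universe")
  kept <- intersect_pathways(pathways, universe, min_k)
  if (length(kept) == 0L) {
    stop_validation("no pathway retains >= ", min_k, " members in the KO universe")
  }

  p <- ko_stats$p_value
  names(p) <- universe
  if (mode == "undirected") {
    z_by_mode <- list(undirected = p_to_z(p))
  } else {
    d <- split_directional(p, ko_stats$statistic)
    z_by_mode <- list(up = p_to_z(d$p_up), down = p_to_z(d$p_down))
    for (m in names(z_by_mode)) names(z_by_mode[[m]]) <- universe
  }

  ks <- sort(unique(lengths(kept)))
  # one shared stream; per-k draws in ascending-k order (up before down in
  # directed mode) keep results independent of pathway input order
  backgrounds <- with_seed(seed, {
    out <- list()
    for (k in ks) {
      for (m in names(z_by_mode)) {
        out[[paste(m, k, sep = ".")]] <-
          background_stats(z_by_mode[[m]], k, n_samples = n_background,
                           seed = NULL, exhaustive_cap = exhaustive_cap)
      }
    }
    out
  })

  rows <- list()
  for (m in names(z_by_mode)) {
    z_all <- z_by_mode[[m]]
    for (id in names(kept)) {
      members <- kept[[id]]
      k <- length(members)
      bg <- backgrounds[[paste(m, k, sep = ".")]]
      zp <- aggregate_z(z_all[members])
      zc <- if (bg$sigma_k > 0) corrected_score(zp, bg$mu_k, bg$sigma_k) else NA_real_
      rows[[paste(m, id, sep = ".")]] <- data.frame(
        pathway = id, mode = m, k = k, z_pathway = zp,
        mu_k = bg$mu_k, sigma_k = bg$sigma_k, reporter_score = zc,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (anyNA(res$reporter_score)) {
    warning("degenerate background (sigma_k = 0) for ",
            sum(is.na(res$reporter_score)),
            " row(s); reporter scores reported as NA")
  }
  res$p_equiv <- ifelse(is.na(res$reporter_score), NA_real_,
                        stats::pnorm(res$reporter_score, lower.tail = FALSE))
  res$q_value <- NA_real_
  for (m in unique(res$mode)) {
    i <- res$mode == m
    res$q_value[i] <- stats::p.adjust(res$p_equiv[i], method = "BH")
  }
  res$significant <- !is.na(res$reporter_score) & res$reporter_score > cutoff
  ord <- order(-res$reporter_score, res$pathway, na.last = TRUE)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL

  bg_df <- do.call(rbind, Map(function(nm, b) {
    data.frame(mode = sub("\\.[0-9]+$", "", nm), k = b$k, mu_k = b$mu_k,
               sigma_k = b$sigma_k, n_samples = b$n_samples,
               method = b$method, stringsAsFactors = FALSE)
  }, names(backgrounds), backgrounds))
  rownames(bg_df) <- NULL

  structure(res,
            background = bg_df,
            params = list(mode = mode, n_background = n_background,
                          min_k = min_k, cutoff = cutoff, seed = seed,
                          exhaustive_cap = exhaustive_cap,
                          n_kos = length(universe),
                          n_pathways_scored = length(kept)),
            class = c("reporter_result", "data.frame"))
}

validate_ko_stats <- function(ko_stats, need_statistic = FALSE) {
  if (!is.data.frame(ko_stats)) stop_validation("'ko_stats' must be a data frame")
  req <- c("ko", "p_value", if (need_statistic) "statistic")
  miss <- setdiff(req, names(ko_stats))
  if (length(miss)) {
    stop_validation("'ko_stats' is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(ko_stats$ko)) stop_validation("duplicate KO ids in 'ko_stats'")
  if (anyNA(ko_stats$p_value) || any(ko_stats$p_value < 0 | ko_stats$p_value > 1)) {
    stop_validation("'p_value' must lie in [0, 1] with no missing values")
  }
  ko_stats$ko <- as.character(ko_stats$ko)
  ko_stats
}
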