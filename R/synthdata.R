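#' Configuration for the P-value-level simulation
#'
#' Parameters of the seeded simulator behind [simulate_pvalues()]: a universe
#' of `n_kos` KOs of which exactly `n_sig` are "significant" (P drawn
#' uniformly below `sig_alpha`, the rest uniformly above it), organised into
#' `n_pathways` pathways of random size. Defaults reproduce the classic
#' demonstration that the reporter score is undirected: 200 KOs, 50
#' significant at 0.05, 10 pathways, within-pathway consistent regulation
#' direction, and one designated pathway built from the least significant
#' KOs with all members "up-regulated".
#'
#' @param n_kos Number of KOs in the universe.
#' @param n_sig Number of KOs with P below `sig_alpha` (exact, by stratified
#'   draws, so it is an assertable generator contract).
#' @param sig_alpha Significance threshold separating the two strata.
#' @param n_pathways Number of pathways.
#' @param k_range Integer range for pathway sizes (uniform draw). Default
#'   `c(8, 30)` keeps size classes well populated at n_kos = 200.
#' @param least_sig_pathway Designate one pathway (the last; flagged in the
#'   truth table) as the k KOs with the largest P values, all with direction
#'   +1 — the "looks down-regulated but is merely unperturbed" pathway.
#' @param direction_consistent Give all members of a pathway one shared
#'   direction sign.
#' @param seed RNG seed (may also be supplied to [simulate_pvalues()]).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_kos = 200L, n_sig = 50L, sig_alpha = 0.05,
                       n_pathways = 10L, k_range = c(8L, 30L),
                       least_sig_pathway = TRUE, direction_consistent = TRUE,
                       seed = NULL) {
  n_kos <- as.integer(n_kos); n_sig <- as.integer(n_sig)
  n_pathways <- as.integer(n_pathways); k_range <- as.integer(k_range)
  if (n_kos < 1L || n_sig < 0L || n_sig > n_kos) {
    stop_validation("need 0 <= n_sig <= n_kos")
  }
  if (sig_alpha <= 0 || sig_alpha >= 1) stop_validation("'sig_alpha' must be in (0, 1)")
  if (n_pathways < 1L) stop_validation("'n_pathways' must be >= 1")
  if (length(k_range) != 2L || k_range[1L] < 1L || k_range[2L] < k_range[1L] ||
      k_range[2L] > n_kos) {
    stop_validation("'k_range' must satisfy 1 <= k_min <= k_max <= n_kos")
  }
  structure(list(n_kos = n_kos, n_sig = n_sig, sig_alpha = sig_alpha,
                 n_pathways = n_pathways, k_range = k_range,
                 least_sig_pathway = least_sig_pathway,
                 direction_consistent = direction_consistent, seed = seed),
            class = "sim_config")
}

#' Simulate per-KO P values and pathways
#'
#' Seeded generator of a KO-statistics table, a pathway set and a ground
#' truth table, following [sim_config()]. P values are drawn in two uniform
#' strata so that exactly `n_sig` KOs fall below `sig_alpha`. Each pathway
#' samples `k ~ Uniform{k_range}` members without replacement (pathways may
#' overlap). Per-pathway direction signs are drawn and, when
#' `direction_consistent`, written onto the members in pathway order; the
#' designated least-significant pathway is applied last with direction +1,
#' so its construction always wins on overlap. Signed statistics are
#' back-computed as `sign * qnorm(1 - p/2)`, the two-sided-consistent z
#' statistic.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed; overrides `config$seed` when given.
#' @return List with `ko_stats` (data frame: `ko`, `p_value`, `statistic`,
#'   `test`), `pathways` (a [pathway_set()]), and `truth` (data frame:
#'   `pathway`, `k`, `direction`, `least_significant`, `members`
#'   semicolon-separated) — so downstream checks read the construction from
#'   `truth` rather than re-deriving it.
#' @examples
#' sim <- simulate_pvalues(seed = 1)
#' sum(sim$ko_stats$p_value < 0.05)  # exactly 50
#' @export
simulate_pvalues <- function(config = sim_config(), seed = NULL) {
  if (!inherits(config, "sim_config")) stop_validation("'config' must be a sim_config")
  seed <- seed %||% config$seed
  with_seed(seed, {
    n <- config$n_kos
    ko_ids <- sprintf("K%05d", seq_len(n))
    sig_idx <- sample.int(n, config$n_sig)
    p <- numeric(n)
    p[sig_idx] <- stats::runif(config$n_sig, 0, config$sig_alpha)
    p[-sig_idx] <- stats::runif(n - config$n_sig, config$sig_alpha, 1)
    signs <- sample(c(-1, 1), n, replace = TRUE)

    np <- config$n_pathways
    pw_ids <- sprintf("pw%02d", seq_len(np))
    ks <- sample(seq(config$k_range[1L], config$k_range[2L]), np, replace = TRUE)
    dirs <- sample(c(-1, 1), np, replace = TRUE)
    designated <- if (config$least_sig_pathway) np else 0L
    members <- vector("list", np)
    names(members) <- pw_ids
    for (j in seq_len(np)) {
      members[[j]] <- if (j == designated) {
        dirs[j] <- 1
        ko_ids[order(p, decreasing = TRUE)[seq_len(ks[j])]]
      } else {
        sample(ko_ids, ks[j])
      }
    }
    if (config$direction_consistent) {
      apply_order <- c(setdiff(seq_len(np), designated), designated[designated > 0L])
      for (j in apply_order) signs[match(members[[j]], ko_ids)] <- dirs[j]
    }

    ko_stats <- data.frame(ko = ko_ids, p_value = p,
                           statistic = signs * stats::qnorm(1 - p / 2),
                           test = "simulated", stringsAsFactors = FALSE)
    truth <- data.frame(pathway = pw_ids, k = ks, direction = dirs,
                        least_significant = seq_len(np) == designated,
                        members = vapply(members, paste, "", collapse = ";"),
                        stringsAsFactors = FALSE)
    list(ko_stats = ko_stats, pathways = pathway_set(members), truth = truth)
  })
}

#' Simulate a two-group KO abundance table
#'
#' End-to-end plumbing for the differential-testing stage: log-normal
#' baseline abundances per KO, with a chosen subset of "effect" KOs shifted
#' upward in the treatment group by `effect_size` standard deviations on the
#' log scale.
#'
#' @param n_kos Number of KOs (features).
#' @param n_per_group Samples per group; must be >= 2.
#' @param effect_kos Character vector of KO ids to perturb (subset of the
#'   generated ids `K00001 ... K<n_kos>`), or an integer vector of indices.
#' @param effect_size Shift in units of the log-scale standard deviation.
#' @param seed RNG seed.
#' @param baseline_meanlog,sdlog Log-normal baseline: per-KO mean-log drawn
#'   from N(`baseline_meanlog`, 1); shared log-scale sd `sdlog`.
#' @return List with `abundance` (matrix, KOs x samples) and `groups`
#'   (data frame: `sample`, `group` in \{control, treatment\}; control is
#'   the intended reference).
#' @examples
#' sim <- simulate_abundance(n_kos = 50, n_per_group = 5,
#'                           effect_kos = 1:10, effect_size = 2, seed = 1)
#' dim(sim$abundance)
#' @export
simulate_abundance <- function(n_kos = 200L, n_per_group = 10L,
                               effect_kos = character(0), effect_size = 0,
                               seed = NULL, baseline_meanlog = 2, sdlog = 0.5) {
  n_kos <- as.integer(n_kos); n_per_group <- as.integer(n_per_group)
  if (n_per_group < 2L) stop_validation("'n_per_group' must be >= 2")
  ko_ids <- sprintf("K%05d", seq_len(n_kos))
  if (is.numeric(effect_kos)) effect_kos <- ko_ids[effect_kos]
  if (!all(effect_kos %in% ko_ids)) {
    stop_validation("'effect_kos' must be a subset of the generated KO ids")
  }
  with_seed(seed, {
    meanlog <- stats::rnorm(n_kos, baseline_meanlog, 1)
    shift <- ifelse(ko_ids %in% effect_kos, effect_size * sdlog, 0)
    ctrl <- matrix(stats::rlnorm(n_kos * n_per_group, meanlog, sdlog),
                   nrow = n_kos)
    trt <- matrix(stats::rlnorm(n_kos * n_per_group, meanlog + shift, sdlog),
                  nrow = n_kos)
    abundance <- cbind(ctrl, trt)
    dimnames(abundance) <- list(ko_ids,
                                c(sprintf("ctrl%02d", seq_len(n_per_group)),
                                  sprintf("trt%02d", seq_len(n_per_group))))
    groups <- data.frame(sample = colnames(abundance),
                         group = rep(c("control", "treatment"),
                                     each = n_per_group),
                         stringsAsFactors = FALSE)
    list(abundance = abundance, groups = groups)
  })
}
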