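# Independent oracles used across tests.

# Upper-tail hypergeometric probability by exhaustive enumeration of every
# placement of the significant list within the universe (feasible for
# N <= 12). Universe = 1..N, pathway = first K elements.
brute_hyper_upper <- function(x, K, n, N) {
  if (n == 0L) return(as.numeric(x <= 0))
  ov <- utils::combn(N, n, FUN = function(s) sum(s <= K))
  mean(ov >= x)
}

# Pooled two-sample t statistic and two-sided P value from the textbook
# formula (df = n1 + n2 - 2), independent of stats::t.test.
pooled_t_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), df = n1 + n2 - 2))
}

# A small KO-stats table with known structure, for reporter/ORA tests.
make_ko_stats <- function(n = 40, seed = 1) {
  set.seed(seed)
  data.frame(ko = sprintf("K%05d", seq_len(n)),
             p_value = runif(n),
             statistic = rnorm(n),
             test = "simulated",
             stringsAsFactors = FALSE)
}

make_pathways <- function(universe, sizes, seed = 2) {
  set.seed(seed)
  members <- lapply(sizes, function(k) sample(universe, k))
  names(members) <- sprintf("pw%02d", seq_along(sizes))
  pathway_set(members)
}
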