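# Independent reference implementations used to cross-check the package.
# These are deliberately naive (explicit loops, textbook formulas) and share
# no code with the implementations they verify.

# direct-summation ssGSEA: recompute both CDFs from scratch at every position
naive_ssgsea <- function(values, genes, set, alpha) {
  n <- length(values)
  ord <- order(-values, genes)
  g_ord <- genes[ord]
  v <- n:1
  ins <- g_ord %in% set
  denom_in <- sum(v[ins]^alpha)
  n_out <- n - sum(ins)
  score <- 0
  for (i in seq_len(n)) {
    p_in <- sum(v[seq_len(i)][ins[seq_len(i)]]^alpha) / denom_in
    p_out <- sum(!ins[seq_len(i)]) / n_out
    score <- score + p_in - p_out
  }
  score
}

# textbook Pearson chi-square from the margin product
textbook_chisq <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# Kruskal-Wallis H without ties, straight from the rank-sum formula
brute_kruskal <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  rbar <- mean(r)
  h <- 0
  for (g in unique(groups)) {
    idx <- groups == g
    h <- h + sum(idx) * (mean(r[idx]) - rbar)^2
  }
  12 / (n * (n + 1)) * h
}

# two-group log-rank chi-square by explicit tabulation over event times
hand_logrank <- function(time, event, group) {
  g1 <- levels(factor(group))[1]
  o_minus_e <- 0
  vsum <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1) vsum <- vsum + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / vsum
}

# adjusted Rand index between two labelings (Hubert & Arabie form)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# tiny deterministic expression fixture: values N:1 over genes g1..gN
rank_fixture <- function(n) {
  genes <- sprintf("g%02d", seq_len(n))
  expression_matrix(matrix(as.numeric(n:1), ncol = 1,
                           dimnames = list(genes, "s1")), unit = "COUNTS")
}
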