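# Independent brute-force oracles. These stay deliberately naive (direct
# formulas, explicit loops, enumeration) so they never share code with the
# implementation they check.

oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2)) * sqrt(sum((y - mean(y))^2))
  r <- num / den
  if (abs(r) >= 1) return(list(r = r, p = 0))
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(abs(t_stat), n - 2, lower.tail = FALSE))
}

# BH step-up by direct enumeration: q_(i) = min_{j >= i} p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(p[o][i:m] * m / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Exact upper binomial tail P(X >= k) by term-wise summation.
oracle_binom_tail <- function(k, m, p0) {
  if (k <= 0) return(1)
  sum(vapply(k:m, function(j) choose(m, j) * p0^j * (1 - p0)^(m - j), 1))
}

oracle_identity <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  matches <- 0L
  comparable <- 0L
  for (i in seq_along(av)) {
    if (av[i] == "-" || bv[i] == "-" || av[i] == "X" || bv[i] == "X") next
    comparable <- comparable + 1L
    if (av[i] == bv[i]) matches <- matches + 1L
  }
  if (comparable == 0L) NA_real_ else 100 * matches / comparable
}

# Shared fixtures ------------------------------------------------------------

# The 14 study species: 12 sensitive to the embryopathy, mouse + rat not.
study_groups <- function() {
  sens <- c("human", "zebrafish", "frog", "chicken", "opossum", "bushbaby",
            "armadillo", "sheep", "rabbit", "golden_hamster", "marmoset",
            "rhesus_macaque")
  setNames(c(rep("sensitive", length(sens)), "insensitive", "insensitive"),
           c(sens, "mouse", "rat"))
}

# 10 disjoint sign-flipping pairs, every delta_r >= 1.2.
flip_pairs_10 <- function(genes = paste0("g", 1:20)) {
  data.frame(
    gene_a = genes[1:10], gene_b = genes[11:20],
    r_control = c(0.75, 0.80, -0.70, 0.70, 0.78, 0.72, -0.75, 0.76, 0.74, -0.72),
    r_exposed = c(-0.48, -0.50, 0.55, -0.60, -0.52, -0.55, 0.50, -0.49, -0.51, 0.53),
    stringsAsFactors = FALSE
  )
}

# A 10-link hub realised as a single-factor closure: the hub's loading flips
# sign between conditions, so satellite-satellite correlations stay put.
hub_design <- function(n_genes = 100, n = 50, seed = 7) {
  sats <- paste0("g", 2:11)
  hub_links <- data.frame(gene_a = "g1", gene_b = sats,
                          r_control = 0.75, r_exposed = -0.75,
                          stringsAsFactors = FALSE)
  ss <- t(combn(sats, 2))
  sat_links <- data.frame(gene_a = ss[, 1], gene_b = ss[, 2],
                          r_control = 0.75^2, r_exposed = 0.75^2,
                          stringsAsFactors = FALSE)
  expression_design(n_genes, n, rbind(hub_links, sat_links), seed = seed,
                    allow_overlap = TRUE)
}

pair_key <- function(df) paste(df$gene_a, df$gene_b)

extdata <- function(name) {
  system.file("extdata", name, package = "coexcomp", mustWork = TRUE)
}
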