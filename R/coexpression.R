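# Differential co-expression: per-condition Pearson correlation, candidate
# filtering, Fisher z differential test, BH-FDR, edge classification, driver
# scoring and transcription-factor annotation.

#' Analysis configuration for differential co-expression
#'
#' Bundles the thresholds of the differential co-expression screen. The
#' defaults are the standard settings of this analysis: candidate pairs must
#' reach `|r| >= 0.5` in at least one condition, significance is declared at
#' FDR-adjusted `q < 0.05`, and a sign-flipping pair is called a *switched
#' opposite* only when its correlation difference exceeds 1.
#'
#' @param r_threshold Minimum absolute Pearson correlation (in either
#'   condition) for a pair to enter testing. Default 0.5.
#' @param alpha Significance level applied to BH-adjusted differential
#'   p-values (and to driver q-values). Default 0.05.
#' @param delta_threshold Correlation-difference cutoff separating
#'   `switched_opposite` from `diff_signed` among sign-flipping pairs; the
#'   flip must have `delta_r` strictly greater than this. Default 1.
#' @param pooling `"pooled"` (all samples of a condition correlated together,
#'   the default) or `"per_timepoint"` (correlations computed within each
#'   timepoint and combined on the Fisher z scale, weighted by `n - 3`).
#' @param diff_test Differential-correlation test; only `"fisher_z"` is
#'   currently implemented (the interface admits alternatives).
#' @param fdr_method Multiplicity correction; only `"benjamini_hochberg"`.
#'
#' @return An object of class `coexp_config`.
#' @export
#' @examples
#' coexp_config(r_threshold = 0.5, alpha = 0.05)
coexp_config <- function(r_threshold = 0.5, alpha = 0.05, delta_threshold = 1,
                         pooling = c("pooled", "per_timepoint"),
                         diff_test = "fisher_z",
                         fdr_method = "benjamini_hochberg") {
  pooling <- match.arg(pooling)
  diff_test <- match.arg(diff_test)
  fdr_method <- match.arg(fdr_method)
  stopifnot(
    is.numeric(r_threshold), length(r_threshold) == 1L,
    r_threshold >= 0, r_threshold <= 1,
    is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1,
    is.numeric(delta_threshold), length(delta_threshold) == 1L,
    delta_threshold >= 0
  )
  structure(
    list(
      r_threshold = r_threshold, alpha = alpha,
      delta_threshold = delta_threshold, pooling = pooling,
      diff_test = diff_test, fdr_method = fdr_method
    ),
    class = "coexp_config"
  )
}

#' Pearson correlation with a two-sided p-value
#'
#' Sample Pearson correlation of two equal-length vectors with the exact
#' two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom. A perfectly correlated pair (`|r| = 1`) returns
#' `p = 0`. A zero-variance input does not abort: the pair is flagged
#' degenerate (`r` and `p` are `NA`) so callers can drop it from testing.
#'
#' @param x,y Numeric vectors of equal length `n >= 4`, no missing values.
#' @return A list with elements `r`, `p`, `n`, and logical `degenerate`.
#' @export
#' @examples
#' pearson_with_p(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 6))
pearson_with_p <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  n <- length(x)
  if (n < 4L) stop("pearson_with_p() requires at least 4 samples")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  cx <- x - mean(x)
  cy <- y - mean(y)
  sxx <- sum(cx^2)
  syy <- sum(cy^2)
  if (sxx == 0 || syy == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  }
  r <- sum(cx * cy) / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  p <- .pearson_p(r, n)
  list(r = r, p = p, n = n, degenerate = FALSE)
}

# Vectorised two-sided p for a Pearson r at sample size n.
.pearson_p <- function(r, n) {
  p <- numeric(length(r))
  exact <- abs(r) >= 1 - 1e-15
  p[exact] <- 0
  t_stat <- r[!exact] * sqrt((n - 2) / (1 - r[!exact]^2))
  p[!exact] <- 2 * pt(abs(t_stat), df = n - 2, lower.tail = FALSE)
  p[is.na(r)] <- NA_real_
  p
}

#' Fisher z test for the difference of two correlations
#'
#' Tests whether two independent Pearson correlations differ, using the
#' variance-stabilising transform `z = atanh(r)`. The statistic is
#' `Z = (z1 - z2) / sqrt(1/(n1 - 3) + 1/(n2 - 3))` and the p-value is the
#' two-sided normal tail. Correlations at the boundary `|r| = 1` are clamped
#' to `+-(1 - 1e-7)` with a warning (the z transform diverges there).
#'
#' All arguments are vectorised.
#'
#' @param r1,r2 Sample correlations, `|r| < 1`.
#' @param n1,n2 Sample sizes, each at least 4.
#' @return Two-sided p-value(s) for the difference.
#' @export
#' @examples
#' fisher_z_diff_test(0.75, 9, -0.48, 9)
fisher_z_diff_test <- function(r1, n1, r2, n2) {
  stopifnot(is.numeric(r1), is.numeric(r2), all(n1 >= 4), all(n2 >= 4))
  clamp <- abs(r1) >= 1 | abs(r2) >= 1
  if (any(clamp, na.rm = TRUE)) {
    warning("correlation(s) at |r| = 1 clamped to 1 - 1e-7 for the z transform")
    lim <- 1 - 1e-7
    r1 <- pmax(-lim, pmin(lim, r1))
    r2 <- pmax(-lim, pmin(lim, r2))
  }
  z1 <- atanh(r1)
  z2 <- atanh(r2)
  se <- sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  z_stat <- (z1 - z2) / se
  2 * pnorm(abs(z_stat), lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' BH step-up q-values, in the input order. Thin wrapper around
#' [stats::p.adjust()] with input validation (p-values outside `[0, 1]` are
#' rejected rather than silently propagated).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values in the same order, each `>= p` and capped at 1.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1] with no missing values")
  }
  p.adjust(p, method = "BH")
}

#' Filter candidate gene pairs by correlation strength
#'
#' Retains pairs whose absolute Pearson correlation reaches `r_threshold` in
#' the control *or* the exposed condition (one side suffices). Degenerate
#' pairs (a zero-variance member; `NA` correlation) are dropped.
#'
#' @param pairs A data frame with numeric columns `r_control` and `r_exposed`.
#' @param config A [coexp_config()].
#' @return The retained subset of `pairs` (row order preserved).
#' @export
candidate_filter <- function(pairs, config = coexp_config()) {
  stopifnot(is.data.frame(pairs),
            all(c("r_control", "r_exposed") %in% names(pairs)))
  if (nrow(pairs) == 0L) return(pairs)
  ok <- !is.na(pairs$r_control) & !is.na(pairs$r_exposed)
  keep <- ok & (abs(pairs$r_control) >= config$r_threshold |
                  abs(pairs$r_exposed) >= config$r_threshold)
  pairs[keep, , drop = FALSE]
}

#' Classify a differential co-expression edge
#'
#' Classifies a pair by how its correlation changed between conditions:
#' a sign flip with `delta_r` strictly above `delta_threshold` is a
#' `switched_opposite`; a sign flip at or below the threshold is
#' `diff_signed`; no sign flip is `same_signed`. `delta_r` is
#' `|r_control - r_exposed|`. Zero correlation counts as non-negative, so a
#' move from 0 to a negative r is a sign flip. Vectorised.
#'
#' @param r_control,r_exposed Correlations in the two conditions.
#' @param config A [coexp_config()]; only `delta_threshold` is used.
#' @return A data frame with columns `delta_r` and `edge_class`.
#' @export
#' @examples
#' classify_edge(0.75, -0.48)  # delta_r 1.23, switched_opposite
classify_edge <- function(r_control, r_exposed, config = coexp_config()) {
  stopifnot(is.numeric(r_control), is.numeric(r_exposed),
            length(r_control) == length(r_exposed))
  delta_r <- abs(r_control - r_exposed)
  flip <- (r_control >= 0) != (r_exposed >= 0)
  edge_class <- ifelse(
    !flip, "same_signed",
    ifelse(delta_r > config$delta_threshold, "switched_opposite", "diff_signed")
  )
  data.frame(delta_r = delta_r, edge_class = edge_class,
             stringsAsFactors = FALSE)
}

# Correlation matrix of genes (rows of `values`) over sample columns `cols`,
# honouring the pooling mode. Returns list(r = matrix, n_eff = effective n).
.condition_cor <- function(values, cols, timepoint, pooling) {
  if (pooling == "pooled" || is.null(timepoint)) {
    return(list(r = cor(t(values[, cols, drop = FALSE])), n_eff = length(cols)))
  }
  tps <- split(cols, timepoint[cols])
  tps <- tps[vapply(tps, length, 1L) >= 4L]
  if (length(tps) == 0L) {
    stop("per_timepoint pooling needs at least 4 samples in some timepoint")
  }
  w <- vapply(tps, function(s) length(s) - 3, 1)
  zsum <- 0
  lim <- 1 - 1e-7
  for (i in seq_along(tps)) {
    r_t <- cor(t(values[, tps[[i]], drop = FALSE]))
    r_t[r_t > lim] <- lim
    r_t[r_t < -lim] <- -lim
    zsum <- zsum + w[i] * atanh(r_t)
  }
  r <- tanh(zsum / sum(w))
  diag(r) <- 1
  # n_eff chosen so the Fisher z variance 1/(n_eff - 3) matches the weighted
  # combination 1 / sum(n_t - 3).
  list(r = r, n_eff = sum(w) + 3)
}

#' Build the differential co-expression network
#'
#' Runs the full screen over all unordered pairs of the requested genes:
#' per-condition Pearson correlations, the candidate filter
#' (`|r| >= r_threshold` in either condition), the Fisher z differential
#' test, BH adjustment *within the candidate family*, and classification of
#' significant edges. Requested genes absent from the matrix are reported and
#' skipped (matching is case-insensitive); genes with zero variance in either
#' condition are excluded pairwise, with a message, rather than failing the
#' run.
#'
#' @param expr An [expression_matrix()].
#' @param genes Character vector of candidate genes; `NULL` means all genes
#'   in the matrix.
#' @param config A [coexp_config()].
#' @return An object of class `dc_network`: a list with `nodes`, the full
#'   `pairs` table (one row per computed pair, with per-condition r and p,
#'   a `candidate` flag, `p_diff` and `q_diff` for candidates), the
#'   significant `edges` table (with `delta_r`, `edge_class`, and a `driver`
#'   column filled by [attribute_drivers()]), the `config`, sample counts,
#'   and any dropped gene names.
#' @export
build_dc_network <- function(expr, genes = NULL, config = coexp_config()) {
  stopifnot(inherits(expr, "expression_matrix"))
  all_genes <- rownames(expr$values)
  if (is.null(genes)) genes <- all_genes
  idx <- match(tolower(genes), tolower(all_genes))
  missing_genes <- genes[is.na(idx)]
  if (length(missing_genes) > 0L) {
    warning("genes not found (skipped): ", paste(missing_genes, collapse = ", "))
  }
  idx <- unique(idx[!is.na(idx)])
  used <- all_genes[idx]

  empty_net <- function() {
    structure(
      list(nodes = used, pairs = .empty_pairs(), edges = .empty_edges(),
           config = config, n_control = NA_integer_, n_exposed = NA_integer_,
           dropped_genes = missing_genes, degenerate_genes = character(0)),
      class = "dc_network"
    )
  }
  if (length(used) < 2L) {
    warning("fewer than 2 usable genes; returning an empty network")
    return(empty_net())
  }

  vals <- expr$values[idx, , drop = FALSE]
  cond <- expr$condition
  ctrl <- which(cond == "control")
  expo <- which(cond == "exposed")
  stopifnot(length(ctrl) >= 4L, length(expo) >= 4L)

  # zero-variance genes in either condition are excluded pairwise
  sd0 <- apply(vals[, ctrl, drop = FALSE], 1, var) == 0 |
    apply(vals[, expo, drop = FALSE], 1, var) == 0
  degenerate_genes <- used[sd0]
  if (length(degenerate_genes) > 0L) {
    message(length(degenerate_genes),
            " zero-variance gene(s) excluded from correlation testing")
  }
  keep <- !sd0
  if (sum(keep) < 2L) {
    warning("fewer than 2 usable genes after variance filtering")
    net <- empty_net()
    net$degenerate_genes <- degenerate_genes
    return(net)
  }
  vals <- vals[keep, , drop = FALSE]
  used_ok <- used[keep]

  cc <- .condition_cor(vals, ctrl, expr$timepoint, config$pooling)
  ce <- .condition_cor(vals, expo, expr$timepoint, config$pooling)
  n1 <- cc$n_eff
  n2 <- ce$n_eff

  ut <- which(upper.tri(cc$r), arr.ind = TRUE)
  a <- used_ok[ut[, 1L]]
  b <- used_ok[ut[, 2L]]
  swap <- a > b   # store unordered pairs with gene_a < gene_b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp

  pairs <- data.frame(
    gene_a = a, gene_b = b,
    r_control = cc$r[ut], r_exposed = ce$r[ut],
    n_control = n1, n_exposed = n2,
    p_control = .pearson_p(cc$r[ut], n1),
    p_exposed = .pearson_p(ce$r[ut], n2),
    stringsAsFactors = FALSE
  )
  pairs$candidate <- abs(pairs$r_control) >= config$r_threshold |
    abs(pairs$r_exposed) >= config$r_threshold
  pairs$p_diff <- NA_real_
  pairs$q_diff <- NA_real_
  cand <- which(pairs$candidate)
  if (length(cand) > 0L) {
    pairs$p_diff[cand] <- suppressWarnings(fisher_z_diff_test(
      pairs$r_control[cand], n1, pairs$r_exposed[cand], n2
    ))
    pairs$q_diff[cand] <- bh_adjust(pairs$p_diff[cand])
  }

  sig <- which(pairs$candidate & !is.na(pairs$q_diff) &
                 pairs$q_diff < config$alpha)
  edges <- pairs[sig, , drop = FALSE]
  if (nrow(edges) > 0L) {
    cls <- classify_edge(edges$r_control, edges$r_exposed, config)
    edges$delta_r <- cls$delta_r
    edges$edge_class <- cls$edge_class
  } else {
    edges <- .empty_edges()
  }
  edges$driver <- rep(NA_character_, nrow(edges))
  rownames(edges) <- NULL

  structure(
    list(nodes = used_ok, pairs = pairs, edges = edges, config = config,
         n_control = n1, n_exposed = n2,
         dropped_genes = missing_genes, degenerate_genes = degenerate_genes),
    class = "dc_network"
  )
}

.empty_pairs <- function() {
  data.frame(
    gene_a = character(0), gene_b = character(0),
    r_control = numeric(0), r_exposed = numeric(0),
    n_control = integer(0), n_exposed = integer(0),
    p_control = numeric(0), p_exposed = numeric(0),
    candidate = logical(0), p_diff = numeric(0), q_diff = numeric(0),
    stringsAsFactors = FALSE
  )
}

.empty_edges <- function() {
  cbind(.empty_pairs(),
        data.frame(delta_r = numeric(0), edge_class = character(0),
                   stringsAsFactors = FALSE))
}

#' @export
print.dc_network <- function(x, ...) {
  cat("Differential co-expression network\n")
  cat("  genes:", length(x$nodes),
      " candidate pairs:", sum(x$pairs$candidate),
      " significant edges:", nrow(x$edges), "\n")
  if (nrow(x$edges) > 0L) {
    cat("  edge classes:\n")
    print(table(x$edges$edge_class))
  }
  invisible(x)
}

#' Score driver genes by binomial enrichment of differential links
#'
#' For each gene in the network, counts its candidate links (`m_links`) and
#' its significant differential links (`k_dc`), and asks whether `k_dc` is
#' surprisingly large given the global differential-link rate
#' `p0 = total edges / total candidate pairs`, using the exact binomial tail
#' `P(X >= k_dc)` with `X ~ Binomial(m_links, p0)`. BH adjustment is applied
#' across genes; drivers are genes with `q_binom < alpha`.
#'
#' @param network A [build_dc_network()] result.
#' @param config A [coexp_config()]; defaults to the network's own.
#' @return A data frame (`gene`, `k_dc`, `m_links`, `p0`, `p_binom`,
#'   `q_binom`, `is_driver`), sorted by `p_binom`, with attribute `p0`.
#' @export
identify_drivers <- function(network, config = network$config) {
  stopifnot(inherits(network, "dc_network"))
  cand <- network$pairs[network$pairs$candidate, , drop = FALSE]
  edges <- network$edges
  empty <- data.frame(
    gene = character(0), k_dc = integer(0), m_links = integer(0),
    p0 = numeric(0), p_binom = numeric(0), q_binom = numeric(0),
    is_driver = logical(0), stringsAsFactors = FALSE
  )
  if (nrow(edges) == 0L || nrow(cand) == 0L) return(empty)
  p0 <- nrow(edges) / nrow(cand)
  genes <- sort(unique(c(cand$gene_a, cand$gene_b)))
  m <- vapply(genes, function(g) sum(cand$gene_a == g | cand$gene_b == g), 1L)
  k <- vapply(genes, function(g) sum(edges$gene_a == g | edges$gene_b == g), 1L)
  p_binom <- pbinom(k - 1L, size = m, prob = p0, lower.tail = FALSE)
  q_binom <- bh_adjust(p_binom)
  res <- data.frame(
    gene = genes, k_dc = k, m_links = m, p0 = p0,
    p_binom = p_binom, q_binom = q_binom,
    is_driver = q_binom < config$alpha,
    stringsAsFactors = FALSE
  )
  res <- res[order(res$p_binom, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "p0") <- p0
  res
}

#' Attach driver attribution to network edges
#'
#' Fills each edge's `driver` column with the member gene(s) flagged as
#' significant drivers by [identify_drivers()], joined by `";"` when both
#' members qualify; edges with no driver member keep `NA`.
#'
#' @param network A `dc_network`.
#' @param drivers The result of [identify_drivers()].
#' @return The network with its `edges$driver` column populated.
#' @export
attribute_drivers <- function(network, drivers) {
  stopifnot(inherits(network, "dc_network"), is.data.frame(drivers))
  if (nrow(network$edges) == 0L) return(network)
  driver_genes <- drivers$gene[drivers$is_driver]
  network$edges$driver <- vapply(seq_len(nrow(network$edges)), function(i) {
    members <- c(network$edges$gene_a[i], network$edges$gene_b[i])
    hit <- members[members %in% driver_genes]
    if (length(hit) == 0L) NA_character_ else paste(hit, collapse = ";")
  }, character(1))
  network
}

#' Annotate network edges with shared transcription-factor regulators
#'
#' For each edge `(a, b)`, finds the transcription factors that regulate both
#' members in a TRRUST-style interaction table (matching is
#' case-insensitive), flags edges where one member itself regulates the
#' other, and ranks TFs by the number of edges they cover (ties broken
#' lexicographically).
#'
#' @param network A `dc_network`.
#' @param tf_table A data frame with columns `tf`, `target`, `mode` (see
#'   [read_tf_table()]).
#' @return A list with `edges` (per-edge `common_tfs`, `n_common`,
#'   `tf_in_pair`) and `ranking` (`tf`, `n_edges`).
#' @export
annotate_tf_regulators <- function(network, tf_table) {
  stopifnot(inherits(network, "dc_network"), is.data.frame(tf_table),
            all(c("tf", "target") %in% names(tf_table)))
  edges <- network$edges
  ann <- data.frame(
    gene_a = edges$gene_a, gene_b = edges$gene_b,
    common_tfs = character(nrow(edges)), n_common = integer(nrow(edges)),
    tf_in_pair = logical(nrow(edges)), stringsAsFactors = FALSE
  )
  tf_lo <- tolower(tf_table$tf)
  tg_lo <- tolower(tf_table$target)
  covered <- list()
  for (i in seq_len(nrow(edges))) {
    a <- tolower(edges$gene_a[i])
    b <- tolower(edges$gene_b[i])
    tf_a <- unique(tf_table$tf[tg_lo == a])
    tf_b <- unique(tf_table$tf[tg_lo == b])
    common <- sort(intersect(tf_a, tf_b))
    ann$common_tfs[i] <- paste(common, collapse = ",")
    ann$n_common[i] <- length(common)
    ann$tf_in_pair[i] <- any(tf_lo == a & tg_lo == b) ||
      any(tf_lo == b & tg_lo == a)
    for (t in common) covered[[t]] <- c(covered[[t]], i)
  }
  if (length(covered) > 0L) {
    ranking <- data.frame(
      tf = names(covered),
      n_edges = vapply(covered, function(v) length(unique(v)), 1L),
      stringsAsFactors = FALSE
    )
    ranking <- ranking[order(-ranking$n_edges, ranking$tf), , drop = FALSE]
    rownames(ranking) <- NULL
  } else {
    ranking <- data.frame(tf = character(0), n_edges = integer(0),
                          stringsAsFactors = FALSE)
  }
  list(edges = ann, ranking = ranking)
}
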