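# Synthetic-data generators with recorded ground truth: two-condition
# expression matrices with planted pairwise correlations, phenotype-
# partitioned protein alignments with planted group-exclusive columns, and
# anchored gene neighborhoods with planted exclusive genes.

#' Design a two-condition expression simulation
#'
#' Describes a genes-by-samples simulation in which selected gene pairs carry
#' designed population correlations that may differ between the control and
#' exposed conditions (including sign flips), against a common background
#' correlation. Values emulate continuous microarray-like log-intensities.
#'
#' Planted pairs are disjoint by default. Overlapping pairs (e.g. a hub gene
#' correlated with many partners) are allowed with `allow_overlap = TRUE`
#' provided the implied per-condition correlation matrix is positive
#' semidefinite; if it is not, the simulation is rejected unless
#' `repair = TRUE`, in which case the matrix is repaired by eigenvalue
#' clipping to the nearest PSD correlation matrix (the recorded truth then
#' refers to the designed, pre-repair values).
#'
#' @param n_genes Number of genes (ids `g1 ... gN` unless `gene_ids` given).
#' @param samples_per_condition Samples per condition, at least 4.
#' @param planted_pairs Data frame with columns `gene_a`, `gene_b`,
#'   `r_control`, `r_exposed` (each `|r| < 1`), or `NULL` for none.
#' @param background_r Population correlation of all unplanted pairs
#'   (default 0).
#' @param noise_sd Standard deviation of the simulated log-intensities.
#' @param seed Integer seed; fixed per design for reproducibility.
#' @param gene_ids Optional explicit gene identifiers (length `n_genes`).
#' @param allow_overlap Allow a gene to appear in more than one planted pair.
#' @param repair Repair a non-PSD implied correlation matrix by eigenvalue
#'   clipping instead of rejecting it.
#' @return An object of class `expression_design`.
#' @export
expression_design <- function(n_genes, samples_per_condition,
                              planted_pairs = NULL, background_r = 0,
                              noise_sd = 1, seed = 1, gene_ids = NULL,
                              allow_overlap = FALSE, repair = FALSE) {
  stopifnot(n_genes >= 2, samples_per_condition >= 4,
            abs(background_r) <= 1, noise_sd > 0)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(n_genes))
  stopifnot(length(gene_ids) == n_genes, !anyDuplicated(gene_ids))
  if (is.null(planted_pairs)) {
    planted_pairs <- data.frame(gene_a = character(0), gene_b = character(0),
                                r_control = numeric(0), r_exposed = numeric(0),
                                stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(planted_pairs),
            all(c("gene_a", "gene_b", "r_control", "r_exposed") %in%
                  names(planted_pairs)))
  if (nrow(planted_pairs) > 0L) {
    if (!all(c(planted_pairs$gene_a, planted_pairs$gene_b) %in% gene_ids)) {
      stop("planted pair genes must be among the design's gene_ids")
    }
    if (any(planted_pairs$gene_a == planted_pairs$gene_b)) {
      stop("a planted pair cannot pair a gene with itself")
    }
    if (any(abs(planted_pairs$r_control) >= 1) ||
        any(abs(planted_pairs$r_exposed) >= 1)) {
      stop("planted correlations must satisfy |r| < 1")
    }
    members <- c(planted_pairs$gene_a, planted_pairs$gene_b)
    if (!allow_overlap && anyDuplicated(members)) {
      stop("planted pairs must be disjoint (set allow_overlap = TRUE ",
           "for overlapping structures)")
    }
  }
  structure(
    list(n_genes = n_genes, samples_per_condition = samples_per_condition,
         planted_pairs = planted_pairs, background_r = background_r,
         noise_sd = noise_sd, seed = seed, gene_ids = gene_ids,
         allow_overlap = allow_overlap, repair = repair),
    class = "expression_design"
  )
}

# Implied correlation matrix for one condition; PSD-checked / repaired.
.design_sigma <- function(design, which_r) {
  g <- design$gene_ids
  sigma <- matrix(design$background_r, length(g), length(g),
                  dimnames = list(g, g))
  diag(sigma) <- 1
  pp <- design$planted_pairs
  for (i in seq_len(nrow(pp))) {
    r <- pp[[which_r]][i]
    sigma[pp$gene_a[i], pp$gene_b[i]] <- r
    sigma[pp$gene_b[i], pp$gene_a[i]] <- r
  }
  ev <- eigen(sigma, symmetric = TRUE)
  if (min(ev$values) < -1e-10) {
    if (!design$repair) {
      bad <- unique(c(pp$gene_a, pp$gene_b))
      stop("implied ", sub("r_", "", which_r),
           " correlation matrix is not positive semidefinite; ",
           "genes involved: ", paste(bad, collapse = ", "),
           " (set repair = TRUE to clip eigenvalues)")
    }
    vals <- pmax(ev$values, 1e-8)
    sigma <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    d <- sqrt(diag(sigma))
    sigma <- sigma / tcrossprod(d)
    dimnames(sigma) <- list(g, g)
  }
  sigma
}

#' Simulate a two-condition expression matrix with known truth
#'
#' Draws each condition's samples from a multivariate normal whose
#' correlation matrix carries the designed planted correlations (background
#' correlation elsewhere), scaled by `noise_sd` and shifted to a
#' microarray-like log-intensity baseline. The returned truth table records
#' every planted pair with its designed per-condition correlations.
#'
#' @param design An [expression_design()].
#' @return A list with `matrix` (an [expression_matrix()]) and `truth` (data
#'   frame `gene_a`, `gene_b`, `r_control`, `r_exposed`, with `gene_a <
#'   gene_b`).
#' @export
simulate_expression <- function(design) {
  stopifnot(inherits(design, "expression_design"))
  sigma_c <- .design_sigma(design, "r_control")
  sigma_e <- .design_sigma(design, "r_exposed")
  n <- design$samples_per_condition
  g <- design$gene_ids

  set.seed(design$seed)
  x_c <- MASS::mvrnorm(n, mu = rep(0, length(g)), Sigma = sigma_c)
  x_e <- MASS::mvrnorm(n, mu = rep(0, length(g)), Sigma = sigma_e)
  values <- t(rbind(x_c, x_e)) * design$noise_sd + 8  # log-intensity scale
  rownames(values) <- g
  colnames(values) <- c(paste0("ctrl_", seq_len(n)), paste0("exp_", seq_len(n)))
  condition <- rep(c("control", "exposed"), each = n)

  truth <- design$planted_pairs
  if (nrow(truth) > 0L) {
    swap <- truth$gene_a > truth$gene_b
    tmp <- truth$gene_a[swap]
    truth$gene_a[swap] <- truth$gene_b[swap]
    truth$gene_b[swap] <- tmp
    truth <- truth[order(truth$gene_a, truth$gene_b), , drop = FALSE]
    rownames(truth) <- NULL
  }
  list(matrix = expression_matrix(values, condition), truth = truth)
}

#' Design a phenotype-partitioned protein alignment simulation
#'
#' Describes an equal-length protein alignment over species split into a
#' `sensitive` and an `insensitive` group, with planted group-exclusive
#' columns (every insensitive residue differs from every sensitive residue),
#' optional shared polymorphic columns that are deliberately *not*
#' group-exclusive, and random gaps outside planted columns.
#'
#' @param species Character vector of species identifiers.
#' @param group_of Named character vector mapping every species to
#'   `"sensitive"` or `"insensitive"`; each group must be non-empty.
#' @param alignment_length Number of alignment columns.
#' @param planted_exclusive_columns Data frame with columns `column` (1-based
#'   index), `sensitive_residue` (one letter), `insensitive_residue` (one
#'   letter applied to all insensitive species, or a `/`-separated string
#'   giving one letter per insensitive species in order). `NULL` for none.
#' @param shared_polymorphic_columns Number of background columns carrying a
#'   second residue present in both groups (never group-exclusive).
#' @param gap_rate Per-cell gap probability outside planted columns.
#' @param seed Integer seed.
#' @param gene Gene symbol attached to the alignment (default "SYNTH").
#' @return An object of class `msa_design`.
#' @export
msa_design <- function(species, group_of, alignment_length,
                       planted_exclusive_columns = NULL,
                       shared_polymorphic_columns = 0, gap_rate = 0,
                       seed = 1, gene = "SYNTH") {
  stopifnot(length(species) >= 2, !anyDuplicated(species),
            all(species %in% names(group_of)),
            alignment_length >= 1, gap_rate >= 0, gap_rate < 1)
  group_of <- group_of[species]
  if (!all(group_of %in% c("sensitive", "insensitive"))) {
    stop("groups must be 'sensitive' or 'insensitive'")
  }
  if (!all(c("sensitive", "insensitive") %in% group_of)) {
    stop("each group needs at least one species")
  }
  pec <- planted_exclusive_columns
  if (is.null(pec)) {
    pec <- data.frame(column = integer(0), sensitive_residue = character(0),
                      insensitive_residue = character(0),
                      stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(pec),
            all(c("column", "sensitive_residue", "insensitive_residue") %in%
                  names(pec)))
  if (nrow(pec) > 0L) {
    pec$column <- as.integer(pec$column)
    if (any(pec$column < 1L | pec$column > alignment_length)) {
      stop("planted column index out of range [1, ", alignment_length, "]")
    }
    if (anyDuplicated(pec$column)) stop("planted column indices must be unique")
    n_ins <- sum(group_of == "insensitive")
    for (i in seq_len(nrow(pec))) {
      ins <- strsplit(pec$insensitive_residue[i], "/", fixed = TRUE)[[1]]
      if (!(length(ins) %in% c(1L, n_ins))) {
        stop("insensitive_residue must give 1 letter or one per insensitive ",
             "species")
      }
      if (pec$sensitive_residue[i] %in% ins) {
        stop("at a planted column no insensitive residue may equal the ",
             "sensitive residue (column ", pec$column[i], ")")
      }
    }
  }
  if (shared_polymorphic_columns + nrow(pec) > alignment_length) {
    stop("more planted + polymorphic columns than alignment columns")
  }
  structure(
    list(species = species, group_of = group_of,
         alignment_length = alignment_length,
         planted_exclusive_columns = pec,
         shared_polymorphic_columns = shared_polymorphic_columns,
         gap_rate = gap_rate, seed = seed, gene = gene),
    class = "msa_design"
  )
}

#' Simulate a protein alignment with planted group-exclusive columns
#'
#' Background columns carry one residue shared by all species; shared
#' polymorphic columns carry a second residue assigned to at least one
#' species of each group (so they are never group-exclusive); planted columns
#' follow the design exactly; gaps are placed only outside planted columns.
#' The returned truth is the planted column set in substitution-call form, so
#' the strict caller applied to the simulated alignment reproduces it exactly
#' (round-trip identity at `gap_rate = 0`).
#'
#' @param design An [msa_design()].
#' @return A list with `alignment` (an [ortholog_alignment()]) and `truth`
#'   (data frame in the shape of [call_group_exclusive()] output).
#' @export
simulate_msa <- function(design) {
  stopifnot(inherits(design, "msa_design"))
  set.seed(design$seed)
  sp <- design$species
  grp <- design$group_of
  len <- design$alignment_length
  ins_sp <- sp[grp == "insensitive"]
  sen_sp <- sp[grp == "sensitive"]

  base <- sample(AA_LETTERS, len, replace = TRUE)
  mat <- matrix(rep(base, each = length(sp)), nrow = length(sp),
                dimnames = list(sp, NULL))

  pec <- design$planted_exclusive_columns
  planted_cols <- pec$column
  free_cols <- setdiff(seq_len(len), planted_cols)

  # shared polymorphic columns: a second residue seen in both groups
  if (design$shared_polymorphic_columns > 0L) {
    poly_cols <- sample(free_cols, design$shared_polymorphic_columns)
    for (cl in poly_cols) {
      alt <- sample(setdiff(AA_LETTERS, base[cl]), 1L)
      carriers <- c(sample(sen_sp, 1L), sample(ins_sp, 1L))
      extra <- sp[runif(length(sp)) < 0.3]
      mat[unique(c(carriers, extra)), cl] <- alt
    }
  }

  for (i in seq_len(nrow(pec))) {
    cl <- pec$column[i]
    mat[sen_sp, cl] <- pec$sensitive_residue[i]
    ins <- strsplit(pec$insensitive_residue[i], "/", fixed = TRUE)[[1]]
    if (length(ins) == 1L) ins <- rep(ins, length(ins_sp))
    mat[ins_sp, cl] <- ins
  }

  # gaps never at planted columns, keeping the planted truth unambiguous
  if (design$gap_rate > 0 && length(free_cols) > 0L) {
    gap <- matrix(runif(length(sp) * length(free_cols)) < design$gap_rate,
                  nrow = length(sp))
    mat[, free_cols][gap] <- "-"
  }

  seqs <- apply(mat, 1L, paste, collapse = "")
  alignment <- ortholog_alignment(seqs, grp, gene = design$gene,
                                  reference_species = sen_sp[1L])

  truth <- .calls_from_design(design, alignment)
  list(alignment = alignment, truth = truth)
}

# Planted columns expressed in substitution-call form (gene, column,
# reference coordinates, residues, P72A-style label).
.calls_from_design <- function(design, alignment) {
  pec <- design$planted_exclusive_columns
  pec <- pec[order(pec$column), , drop = FALSE]
  n <- nrow(pec)
  ins_sp <- design$species[design$group_of == "insensitive"]
  ref_pos <- integer(n)
  alt <- character(n)
  ins_txt <- character(n)
  for (i in seq_len(n)) {
    ref_pos[i] <- map_column_to_ref(alignment, pec$column[i])
    ins <- strsplit(pec$insensitive_residue[i], "/", fixed = TRUE)[[1]]
    if (length(ins) == 1L) ins <- rep(ins, length(ins_sp))
    alt[i] <- if (length(unique(ins)) == 1L) ins[1L] else NA_character_
    ins_txt[i] <- paste(paste0(ins_sp, "=", ins), collapse = ";")
  }
  data.frame(
    gene = rep(design$gene, n), column = pec$column, ref_position = ref_pos,
    ref_residue = pec$sensitive_residue, alt_residue = alt,
    insensitive_residues = ins_txt,
    label = ifelse(is.na(alt), NA_character_,
                   paste0(pec$sensitive_residue, ref_pos, alt)),
    stringsAsFactors = FALSE
  )
}

#' Design an anchored gene-neighborhood simulation
#'
#' Describes the gene windows around an anchor locus for a set of species in
#' two phenotype groups: a shared core present in every species, planted
#' group-exclusive genes (present in every species of one group, absent from
#' the other), planted species-exclusive genes, and unique namespaced filler
#' (`FILLER_<k>`) padding each window. Planted content is placed upstream of
#' the anchor; downstream windows are filler.
#'
#' @param anchor Anchor gene symbol.
#' @param window Genes per side per species.
#' @param species Character vector of species.
#' @param group_of Named map species -> `"sensitive"` / `"insensitive"`.
#' @param shared_core Genes present upstream in every species.
#' @param group_exclusive Named list (`sensitive`, `insensitive`) of genes
#'   present in every species of that group only.
#' @param species_exclusive Named list keyed by species of genes present in
#'   that species only.
#' @param seed Integer seed (controls the within-window shuffle).
#' @return An object of class `synteny_design`.
#' @export
synteny_design <- function(anchor, window, species, group_of,
                           shared_core = character(0),
                           group_exclusive = list(), species_exclusive = list(),
                           seed = 1) {
  stopifnot(is.character(anchor), length(anchor) == 1L, window >= 1,
            length(species) >= 2, all(species %in% names(group_of)))
  group_of <- group_of[species]
  stopifnot(all(group_of %in% c("sensitive", "insensitive")),
            all(c("sensitive", "insensitive") %in% group_of))
  ge <- lapply(c(sensitive = "sensitive", insensitive = "insensitive"),
               function(g) as.character(group_exclusive[[g]] %||% character(0)))
  se <- lapply(setNames(species, species),
               function(s) as.character(species_exclusive[[s]] %||% character(0)))
  all_sets <- c(list(shared_core), ge, se)
  pooled <- unlist(all_sets, use.names = FALSE)
  if (anyDuplicated(pooled)) {
    stop("shared_core, group_exclusive, and species_exclusive must be ",
         "pairwise disjoint")
  }
  for (s in species) {
    need <- length(shared_core) + length(ge[[group_of[[s]]]]) +
      length(se[[s]])
    if (need > window) {
      stop("window (", window, ") smaller than planted content for ", s,
           " (", need, " genes)")
    }
  }
  structure(
    list(anchor = anchor, window = window, species = species,
         group_of = group_of, shared_core = as.character(shared_core),
         group_exclusive = ge, species_exclusive = se, seed = seed),
    class = "synteny_design"
  )
}

#' Simulate per-species gene neighborhoods with planted exclusives
#'
#' Builds the neighborhood table implied by a [synteny_design()]: each
#' species' upstream window holds the shared core, its group's exclusive
#' genes, and its own species-exclusive genes, shuffled deterministically by
#' the seed and padded to the window size with unique `FILLER_<k>` symbols;
#' downstream windows are filler only.
#'
#' @param design A [synteny_design()].
#' @return A data frame (`species`, `anchor`, `side`, `rank`, `gene`) with
#'   the species-to-group map attached as attribute `group_of`.
#' @export
simulate_synteny <- function(design) {
  stopifnot(inherits(design, "synteny_design"))
  set.seed(design$seed)
  filler_k <- 0L
  next_filler <- function(n) {
    out <- paste0("FILLER_", filler_k + seq_len(n))
    filler_k <<- filler_k + n
    out
  }
  rows <- list()
  for (s in design$species) {
    up <- c(design$shared_core,
            design$group_exclusive[[design$group_of[[s]]]],
            design$species_exclusive[[s]])
    up <- c(up, next_filler(design$window - length(up)))
    up <- sample(up)
    down <- next_filler(design$window)
    rows[[s]] <- data.frame(
      species = s, anchor = design$anchor,
      side = rep(c("upstream", "downstream"), each = design$window),
      rank = c(seq_len(design$window), seq_len(design$window)),
      gene = c(up, down), stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "group_of") <- design$group_of
  out
}
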