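# Comparative screens over phenotype-partitioned species: group-exclusive
# substitution calling from protein alignments, reference-coordinate
# mapping, human-variant cross-reference, codon differences, neighborhood
# comparison, and identity-thresholded paralog counting.

#' Construct a phenotype-partitioned ortholog alignment
#'
#' Equal-length aligned amino-acid sequences keyed by species (uppercase
#' letters, `-` for gaps, `X` for ambiguity), together with a two-group
#' phenotype partition and a designated reference species whose ungapped
#' coordinates anchor substitution calls.
#'
#' @param sequences Named character vector of aligned sequences, one per
#'   species.
#' @param group_of Named map species -> `"sensitive"` / `"insensitive"`;
#'   each group must be non-empty.
#' @param gene Gene symbol of the alignment.
#' @param reference_species Species supplying reference coordinates (default
#'   `"human"` when present, else the first sensitive species).
#' @return An object of class `ortholog_alignment`.
#' @export
ortholog_alignment <- function(sequences, group_of, gene = "GENE",
                               reference_species = NULL) {
  stopifnot(is.character(sequences), length(sequences) >= 2,
            !is.null(names(sequences)), !anyDuplicated(names(sequences)))
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop("aligned sequences must have equal length; got lengths ",
         paste(unique(lens), collapse = ", "))
  }
  sp <- names(sequences)
  if (!all(sp %in% names(group_of))) {
    stop("group_of is missing species: ",
         paste(setdiff(sp, names(group_of)), collapse = ", "))
  }
  group_of <- group_of[sp]
  stopifnot(all(group_of %in% c("sensitive", "insensitive")))
  if (!all(c("sensitive", "insensitive") %in% group_of)) {
    stop("each phenotype group needs at least one species")
  }
  if (is.null(reference_species)) {
    reference_species <- if ("human" %in% sp) "human" else
      sp[group_of == "sensitive"][1L]
  }
  if (!reference_species %in% sp) {
    stop("reference species '", reference_species, "' not in the alignment")
  }
  structure(
    list(gene = gene, sequences = sequences, group_of = group_of,
         reference_species = reference_species),
    class = "ortholog_alignment"
  )
}

#' @export
print.ortholog_alignment <- function(x, ...) {
  cat("ortholog_alignment:", x$gene, "-", length(x$sequences), "species x",
      nchar(x$sequences[[1L]]), "columns; reference:", x$reference_species,
      "\n")
  invisible(x)
}

#' Map an alignment column to a reference protein position
#'
#' Counts non-gap reference residues up to and including the column; returns
#' `NA` when the reference itself is gapped at that column.
#'
#' @param alignment An [ortholog_alignment()].
#' @param column 1-based alignment column.
#' @return 1-based ungapped reference position, or `NA`.
#' @export
map_column_to_ref <- function(alignment, column) {
  stopifnot(inherits(alignment, "ortholog_alignment"))
  ref <- strsplit(alignment$sequences[[alignment$reference_species]], "")[[1]]
  if (any(column < 1L | column > length(ref))) {
    stop("column out of range [1, ", length(ref), "]")
  }
  pos <- cumsum(ref != "-")
  ifelse(ref[column] == "-", NA_integer_, pos[column])
}

#' Call group-exclusive substitutions from a protein alignment
#'
#' Scans every alignment column for substitutions exclusive to the
#' insensitive group: a column is called when every insensitive species
#' carries a non-gap, non-`X` residue that is not observed in any sensitive
#' species at that column. In `strict` mode (the default) all insensitive
#' residues must additionally be identical; `loose` mode admits columns where
#' the insensitive species differ from each other as long as none of their
#' residues occurs in the sensitive group. Columns where any sensitive
#' species has a gap are skipped (a substitution and an indel are different
#' event classes); an ambiguous `X` in the sensitive group also disqualifies
#' the column, since absence from the sensitive group cannot then be
#' established. Calls carry reference coordinates via [map_column_to_ref()]
#' and a `P72A`-style label when a single alternate residue exists.
#'
#' @param alignment An [ortholog_alignment()].
#' @param mode `"strict"` or `"loose"`.
#' @param count_indels Also report, as attribute `indel_columns`, the columns
#'   skipped because gap states split the two groups (all of one group
#'   gapped, none of the other).
#' @return Data frame with columns `gene`, `column`, `ref_position`,
#'   `ref_residue` (the reference species' residue), `alt_residue` (strict
#'   consensus or `NA` in loose mode disagreement), `insensitive_residues`,
#'   `label`, `mode`.
#' @export
call_group_exclusive <- function(alignment, mode = c("strict", "loose"),
                                 count_indels = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(alignment, "ortholog_alignment"))
  sp <- names(alignment$sequences)
  grp <- alignment$group_of
  sen <- sp[grp == "sensitive"]
  ins <- sp[grp == "insensitive"]
  mat <- do.call(rbind, strsplit(alignment$sequences, ""))
  rownames(mat) <- sp

  calls <- list()
  indel_cols <- integer(0)
  for (cl in seq_len(ncol(mat))) {
    s_res <- mat[sen, cl]
    i_res <- mat[ins, cl]
    if (any(s_res == "-")) {
      if (all(s_res == "-") && all(i_res != "-")) {
        indel_cols <- c(indel_cols, cl)
      }
      next
    }
    if (all(i_res == "-") ) {
      indel_cols <- c(indel_cols, cl)
      next
    }
    if (any(i_res == "-") || any(i_res == "X") || any(s_res == "X")) next
    if (any(i_res %in% s_res)) next
    if (mode == "strict" && length(unique(i_res)) != 1L) next
    calls[[length(calls) + 1L]] <- cl
  }
  cols <- unlist(calls) %||% integer(0)

  n <- length(cols)
  out <- data.frame(
    gene = rep(alignment$gene, n), column = cols,
    ref_position = if (n) map_column_to_ref(alignment, cols) else integer(0),
    ref_residue = if (n) mat[alignment$reference_species, cols] else character(0),
    alt_residue = character(n), insensitive_residues = character(n),
    label = character(n), mode = rep(mode, n), stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    i_res <- mat[ins, out$column[i]]
    out$alt_residue[i] <- if (length(unique(i_res)) == 1L) i_res[[1L]] else
      NA_character_
    out$insensitive_residues[i] <- paste(paste0(ins, "=", i_res),
                                         collapse = ";")
    out$label[i] <- if (!is.na(out$alt_residue[i]) &&
                        !is.na(out$ref_position[i])) {
      paste0(out$ref_residue[i], out$ref_position[i], out$alt_residue[i])
    } else NA_character_
  }
  if (count_indels) attr(out, "indel_columns") <- indel_cols
  out
}

#' Cross-reference substitution calls against a human variant table
#'
#' A call matches a variant row when the gene (case-insensitive), protein
#' position, reference residue, and the call's strict-mode alternate residue
#' all agree. Call order is preserved; all matching variant identifiers are
#' attached, comma-separated.
#'
#' @param calls Output of [call_group_exclusive()] (rows without a reference
#'   position or a single alternate residue cannot match).
#' @param variant_table Data frame with columns `gene`, `protein_position`,
#'   `ref_aa`, `alt_aa`, `variant_id` (see [read_variant_table()]).
#' @return The matching subset of `calls` with columns `variant_ids` and
#'   `n_variants` appended.
#' @export
cross_reference_human <- function(calls, variant_table) {
  stopifnot(is.data.frame(calls), is.data.frame(variant_table),
            all(c("gene", "protein_position", "ref_aa", "alt_aa",
                  "variant_id") %in% names(variant_table)))
  ids <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    if (is.na(calls$ref_position[i]) || is.na(calls$alt_residue[i])) next
    hit <- tolower(variant_table$gene) == tolower(calls$gene[i]) &
      variant_table$protein_position == calls$ref_position[i] &
      variant_table$ref_aa == calls$ref_residue[i] &
      variant_table$alt_aa == calls$alt_residue[i]
    if (any(hit)) ids[i] <- paste(variant_table$variant_id[hit],
                                  collapse = ",")
  }
  out <- calls[ids != "", , drop = FALSE]
  out$variant_ids <- ids[ids != ""]
  out$n_variants <- lengths(strsplit(out$variant_ids, ",", fixed = TRUE))
  rownames(out) <- NULL
  out
}

#' Positions at which two codons differ
#'
#' @param codon_a,codon_b 3-letter DNA strings over `A`, `C`, `G`, `T`.
#' @return Integer vector of 1-based differing positions (possibly empty).
#' @export
#' @examples
#' codon_diff("CCC", "GCA")  # positions 1 and 3
codon_diff <- function(codon_a, codon_b) {
  .check_codon <- function(x, name) {
    if (!is.character(x) || length(x) != 1L || nchar(x) != 3L ||
        !grepl("^[ACGT]{3}$", x)) {
      stop(name, " must be a 3-letter DNA string over A/C/G/T")
    }
  }
  .check_codon(codon_a, "codon_a")
  .check_codon(codon_b, "codon_b")
  a <- strsplit(codon_a, "")[[1]]
  b <- strsplit(codon_b, "")[[1]]
  which(a != b)
}

#' Compare gene neighborhoods between phenotype groups
#'
#' Partitions the window gene sets of each species and reports, per phenotype
#' group, the group-exclusive genes; per species, the species-exclusive
#' genes; the shared core present in every species; and the pairwise Jaccard
#' similarity of the window gene sets.
#'
#' Under the default `"all"` semantics a gene is group-exclusive for group G
#' when it occurs in the window of *every* species of G and in *no* species
#' of the other group; the permissive `"any"` semantics requires only some
#' species of G (still none of the other group), accommodating partially
#' shared neighborhoods within a group.
#'
#' @param table Neighborhood table (`species`, `anchor`, `side`, `rank`,
#'   `gene`), e.g. from [simulate_synteny()] or [read_neighborhood_tsv()].
#' @param group_of Named map species -> group; defaults to the table's
#'   `group_of` attribute.
#' @param side `"upstream"`, `"downstream"`, or `"both"`.
#' @param semantics `"all"` (default) or `"any"`; see Details.
#' @return A list with `group_exclusive` (named list per group),
#'   `species_exclusive` (named list per species), `shared_core`, and
#'   `jaccard` (species x species matrix).
#' @export
compare_neighborhoods <- function(table, group_of = attr(table, "group_of"),
                                  side = c("both", "upstream", "downstream"),
                                  semantics = c("all", "any")) {
  side <- match.arg(side)
  semantics <- match.arg(semantics)
  stopifnot(is.data.frame(table),
            all(c("species", "anchor", "side", "rank", "gene") %in%
                  names(table)))
  if (length(unique(table$anchor)) != 1L) {
    stop("neighborhood table mixes anchors: ",
         paste(unique(table$anchor), collapse = ", "))
  }
  if (is.null(group_of)) stop("a species -> group map is required")
  if (side != "both") table <- table[table$side == side, , drop = FALSE]
  species <- sort(unique(table$species))
  if (!all(species %in% names(group_of))) {
    stop("group map is missing species: ",
         paste(setdiff(species, names(group_of)), collapse = ", "))
  }
  sets <- lapply(setNames(species, species),
                 function(s) unique(table$gene[table$species == s]))
  groups <- c("sensitive", "insensitive")
  group_sp <- lapply(setNames(groups, groups),
                     function(g) species[group_of[species] == g])
  stopifnot(all(lengths(group_sp) >= 1L))

  group_exclusive <- lapply(setNames(groups, groups), function(g) {
    own <- sets[group_sp[[g]]]
    other <- unique(unlist(sets[group_sp[[setdiff(groups, g)]]]))
    present <- if (semantics == "all") Reduce(intersect, own) else
      unique(unlist(own))
    sort(setdiff(present, other))
  })
  counts <- table(unlist(lapply(sets, unique)))
  once <- names(counts)[counts == 1L]
  species_exclusive <- lapply(sets, function(s) sort(intersect(s, once)))
  shared_core <- sort(Reduce(intersect, sets))

  jaccard <- matrix(1, length(species), length(species),
                    dimnames = list(species, species))
  for (i in seq_along(species)) {
    for (j in seq_along(species)) {
      if (j <= i) next
      u <- union(sets[[i]], sets[[j]])
      jac <- if (length(u) == 0L) 1 else
        length(intersect(sets[[i]], sets[[j]])) / length(u)
      jaccard[i, j] <- jaccard[j, i] <- jac
    }
  }
  list(group_exclusive = group_exclusive,
       species_exclusive = species_exclusive,
       shared_core = shared_core, jaccard = jaccard)
}

#' Percent identity of two aligned sequences
#'
#' Matches divided by comparable columns, times 100. Comparable columns are
#' those where neither sequence has a gap; columns with an `X` in either
#' sequence are excluded from both numerator and denominator. With no
#' comparable columns the identity is undefined and `NA` is returned.
#'
#' @param seq_a,seq_b Aligned strings of equal length.
#' @return Percent identity in `[0, 100]`, or `NA`.
#' @export
#' @examples
#' pairwise_identity("ACDEFG", "ACDE--")  # 100: gap columns excluded
pairwise_identity <- function(seq_a, seq_b) {
  stopifnot(is.character(seq_a), is.character(seq_b),
            length(seq_a) == 1L, length(seq_b) == 1L)
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("aligned sequences must have equal length")
  }
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  comparable <- a != "-" & b != "-" & a != "X" & b != "X"
  if (!any(comparable)) return(NA_real_)
  100 * sum(a[comparable] == b[comparable]) / sum(comparable)
}

#' Count paralogs above an identity threshold
#'
#' Computes the full pairwise identity matrix of an aligned paralog family
#' and counts the members (excluding the reference itself) whose identity to
#' the reference reaches the threshold.
#'
#' @param family Named character vector of equal-length aligned member
#'   sequences (at least the reference).
#' @param reference_member Name of the reference member.
#' @param identity_threshold Percent identity cutoff (default 70).
#' @return A list with `count` and the symmetric `identity` matrix (100 on
#'   the diagonal).
#' @export
count_paralogs <- function(family, reference_member, identity_threshold = 70) {
  stopifnot(is.character(family), length(family) >= 1L,
            !is.null(names(family)))
  if (!reference_member %in% names(family)) {
    stop("reference member '", reference_member, "' not in the family")
  }
  if (length(unique(nchar(family))) != 1L) {
    stop("family members must be aligned to equal length")
  }
  ids <- names(family)
  m <- matrix(100, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      m[i, j] <- m[j, i] <- pairwise_identity(family[[i]], family[[j]])
    }
  }
  others <- setdiff(ids, reference_member)
  count <- sum(m[reference_member, others] >= identity_threshold, na.rm = TRUE)
  list(count = count, identity = m)
}
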