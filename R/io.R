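# Readers and writers for the pipeline's external formats: expression TSV,
# condition maps, aligned FASTA, GEO series-matrix files, TRRUST-style TF
# tables, gnomAD-style variant tables, neighborhood tables, SIF exports,
# and JSON run reports. Readers reject malformed input with the offending
# file and line rather than silently coercing.

format_error <- function(file, line, message) {
  stop(structure(
    class = c("coexcomp_format_error", "error", "condition"),
    list(message = sprintf("%s:%s: %s", file, line %||% "?", message),
         call = NULL, file = file, line = line)
  ))
}

.split_fields <- function(lines, sep) strsplit(lines, sep, fixed = TRUE)

#' Read a tab-separated expression matrix
#'
#' Expects a header row of sample identifiers and one row per gene, first
#' column the gene identifier, remaining columns numeric. Ragged rows,
#' non-numeric cells, duplicate gene identifiers, and empty bodies are
#' rejected with the file and line number. Together with a condition map
#' (see [read_condition_map()]) the result is assembled into an
#' [expression_matrix()].
#'
#' @param path File path.
#' @param condition Optional condition labels (as in [expression_matrix()]);
#'   when supplied, an `expression_matrix` is returned.
#' @param timepoint Optional timepoints, passed through.
#' @param sep Field separator; tab is canonical, `","` accepted.
#' @return A numeric matrix, or an [expression_matrix()] when `condition` is
#'   given.
#' @export
read_expression_tsv <- function(path, condition = NULL, timepoint = NULL,
                                sep = "\t") {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]
  if (length(lines) < 1L) format_error(path, 1L, "empty file")
  fields <- .split_fields(lines, sep)
  header <- fields[[1L]]
  samples <- header[-1L]
  if (length(samples) < 1L) format_error(path, 1L, "no sample columns")
  if (length(fields) < 2L) format_error(path, 2L, "no genes")
  ncol_expect <- length(header)
  genes <- character(length(fields) - 1L)
  values <- matrix(NA_real_, length(fields) - 1L, length(samples))
  for (i in seq_along(fields)[-1L]) {
    row <- fields[[i]]
    if (length(row) != ncol_expect) {
      format_error(path, i, sprintf("expected %d fields, found %d",
                                    ncol_expect, length(row)))
    }
    genes[i - 1L] <- row[1L]
    num <- suppressWarnings(as.numeric(row[-1L]))
    if (anyNA(num)) {
      bad <- row[-1L][is.na(num)][1L]
      format_error(path, i, sprintf("non-numeric value '%s'", bad))
    }
    values[i - 1L, ] <- num
  }
  dup <- genes[duplicated(tolower(genes))]
  if (length(dup) > 0L) {
    format_error(path, NA, paste("duplicate gene id:", dup[1L]))
  }
  dimnames(values) <- list(genes, samples)
  if (is.null(condition)) values else
    expression_matrix(values, condition, timepoint)
}

#' Write an expression matrix as TSV
#'
#' Writes with enough precision that a read/write round trip is
#' value-identical to within 1e-12.
#'
#' @param x An [expression_matrix()] or a numeric matrix with dimnames.
#' @param path Output path.
#' @export
write_expression_tsv <- function(x, path) {
  values <- if (inherits(x, "expression_matrix")) x$values else x
  stopifnot(is.matrix(values))
  header <- paste(c("gene_id", colnames(values)), collapse = "\t")
  body <- vapply(seq_len(nrow(values)), function(i) {
    paste(c(rownames(values)[i], sprintf("%.15g", values[i, ])),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a sample-to-condition map
#'
#' TSV with columns `sample_id`, `condition` (`control` / `exposed`), and an
#' optional third `timepoint` column (hours). No header required; a header
#' line starting with `sample_id` is tolerated and skipped.
#'
#' @param path File path.
#' @return A list with named vectors `condition` and (possibly `NULL`)
#'   `timepoint`.
#' @export
read_condition_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- .split_fields(lines, "\t")
  if (length(fields) > 0L && fields[[1L]][1L] == "sample_id") {
    fields <- fields[-1L]
  }
  if (length(fields) == 0L) format_error(path, 1L, "empty condition map")
  n <- vapply(fields, length, 1L)
  if (any(n < 2L)) {
    format_error(path, which(n < 2L)[1L], "expected sample_id<TAB>condition")
  }
  ids <- vapply(fields, `[`, "", 1L)
  cond <- vapply(fields, `[`, "", 2L)
  if (!all(cond %in% c("control", "exposed"))) {
    format_error(path, which(!cond %in% c("control", "exposed"))[1L],
                 "condition must be 'control' or 'exposed'")
  }
  timepoint <- NULL
  if (all(n >= 3L)) {
    tp <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
    if (!anyNA(tp)) timepoint <- setNames(tp, ids)
  }
  list(condition = setNames(cond, ids), timepoint = timepoint)
}

#' Read (aligned) FASTA
#'
#' Reads a FASTA file into a named character vector, preserving record order
#' and uppercasing residues. In alignment mode (default) unequal sequence
#' lengths are rejected, naming the offending records.
#'
#' @param path File path.
#' @param alignment Require equal lengths (default `TRUE`).
#' @return Named character vector of sequences.
#' @export
read_aligned_fasta <- function(path, alignment = TRUE) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(setNames(as.character(set), names(set)))
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  if (alignment && length(seqs) > 1L) {
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      off <- names(seqs)[lens != lens[1L]][1L]
      format_error(path, NA,
                   sprintf("alignment length mismatch: '%s' (%d) vs '%s' (%d)",
                           names(seqs)[1L], lens[1L], off,
                           nchar(seqs[[off]])))
    }
  }
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_aligned_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 80L)
  invisible(path)
}

#' Read the expression table of a GEO series-matrix file
#'
#' Parses the block between `!series_matrix_table_begin` and
#' `!series_matrix_table_end` into a probe-by-sample numeric matrix and
#' attaches `!Sample_title` values (quotes stripped) when present. Condition
#' assignment is left to a user-supplied map. Offline files only.
#'
#' @param path File path.
#' @return A list with `values` (probes x samples) and `sample_titles`.
#' @export
read_series_matrix <- function(path) {
  lines <- readLines(path)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L) {
    format_error(path, NA, "missing !series_matrix_table_begin/end delimiters")
  }
  strip <- function(x) gsub('^"|"$', "", x)
  titles <- NULL
  tl <- grep("^!Sample_title", lines)
  if (length(tl) >= 1L) {
    titles <- strip(strsplit(lines[tl[1L]], "\t", fixed = TRUE)[[1L]][-1L])
  }
  block <- .split_fields(lines[(begin + 1L):(end - 1L)], "\t")
  header <- strip(block[[1L]])
  samples <- header[-1L]
  probes <- character(length(block) - 1L)
  values <- matrix(NA_real_, length(block) - 1L, length(samples))
  for (i in seq_along(block)[-1L]) {
    row <- strip(block[[i]])
    if (length(row) != length(header)) {
      format_error(path, begin + i,
                   sprintf("expected %d fields, found %d", length(header),
                           length(row)))
    }
    num <- suppressWarnings(as.numeric(row[-1L]))
    if (anyNA(num)) format_error(path, begin + i, "non-numeric value")
    probes[i - 1L] <- row[1L]
    values[i - 1L, ] <- num
  }
  dimnames(values) <- list(probes, samples)
  list(values = values, sample_titles = titles)
}

#' Collapse probe rows to gene rows
#'
#' Maps probe identifiers to gene symbols and keeps, for each gene, the probe
#' with the largest variance across samples (a standard, deliberately simple
#' collapsing rule; pass a different `choose` function to change it).
#'
#' @param values Probe-by-sample numeric matrix.
#' @param probe_to_gene Named character vector probe -> gene; unmapped probes
#'   are dropped.
#' @param choose Function selecting one row index from a gene's probe rows
#'   given the submatrix (default: max variance).
#' @return Gene-by-sample matrix.
#' @export
collapse_probes <- function(values, probe_to_gene,
                            choose = function(m) which.max(apply(m, 1, var))) {
  keep <- rownames(values) %in% names(probe_to_gene)
  values <- values[keep, , drop = FALSE]
  genes <- probe_to_gene[rownames(values)]
  out <- lapply(split(seq_len(nrow(values)), genes), function(idx) {
    values[idx[choose(values[idx, , drop = FALSE])], ]
  })
  do.call(rbind, out)
}

#' Read a TRRUST-style transcription-factor interaction table
#'
#' Columns `tf`, `target`, `mode` (activation / repression / unknown); the
#' raw TRRUST dialect (no header, extra PMID column) is tolerated, the extra
#' column ignored. Duplicate (tf, target) pairs are de-duplicated, keeping
#' the first mode.
#'
#' @param path File path.
#' @return Data frame with columns `tf`, `target`, `mode`.
#' @export
read_tf_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- .split_fields(lines, "\t")
  if (length(fields) > 0L && tolower(fields[[1L]][1L]) == "tf") {
    fields <- fields[-1L]
  }
  if (length(fields) == 0L) format_error(path, 1L, "empty TF table")
  n <- vapply(fields, length, 1L)
  if (any(n < 2L)) {
    format_error(path, which(n < 2L)[1L], "expected tf<TAB>target[<TAB>mode]")
  }
  tf <- vapply(fields, `[`, "", 1L)
  target <- vapply(fields, `[`, "", 2L)
  mode <- vapply(fields, function(f) if (length(f) >= 3L) f[[3L]] else "", "")
  mode <- tolower(mode)
  mode[!mode %in% c("activation", "repression")] <- "unknown"
  out <- data.frame(tf = tf, target = target, mode = mode,
                    stringsAsFactors = FALSE)
  out[!duplicated(out[c("tf", "target")]), , drop = FALSE]
}

#' Read a gnomAD-style human protein-variant table
#'
#' TSV with a header naming at least `gene`, `protein_position`, `ref_aa`,
#' `alt_aa`, `variant_id`; an optional `allele_frequency` column is carried
#' through and any extra columns are ignored.
#'
#' @param path File path.
#' @return Validated data frame.
#' @export
read_variant_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene", "protein_position", "ref_aa", "alt_aa", "variant_id")
  if (!all(need %in% names(df))) {
    format_error(path, 1L, paste("missing columns:",
                                 paste(setdiff(need, names(df)),
                                       collapse = ", ")))
  }
  keep <- intersect(c(need, "allele_frequency"), names(df))
  df <- df[keep]
  if (any(df$protein_position < 1L)) {
    format_error(path, NA, "protein positions must be positive")
  }
  aa_ok <- grepl("^[ACDEFGHIKLMNPQRSTVWY]$", df$ref_aa) &
    grepl("^[ACDEFGHIKLMNPQRSTVWY]$", df$alt_aa)
  if (!all(aa_ok)) {
    format_error(path, NA, "invalid amino-acid letter in ref_aa/alt_aa")
  }
  if ("allele_frequency" %in% names(df) &&
      any(df$allele_frequency < 0 | df$allele_frequency > 1, na.rm = TRUE)) {
    format_error(path, NA, "allele_frequency must lie in [0, 1]")
  }
  df
}

#' Read / write a gene-neighborhood table
#'
#' TSV with header `species`, `anchor`, `side`, `rank`, `gene`; `side` must
#' be `upstream` or `downstream`, and (species, anchor, side, rank) must be
#' unique.
#'
#' @param path File path.
#' @return Data frame of the table.
#' @export
read_neighborhood_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "anchor", "side", "rank", "gene")
  if (!all(need %in% names(df))) {
    format_error(path, 1L, paste("missing columns:",
                                 paste(setdiff(need, names(df)),
                                       collapse = ", ")))
  }
  if (!all(df$side %in% c("upstream", "downstream"))) {
    format_error(path, NA, "side must be 'upstream' or 'downstream'")
  }
  key <- df[c("species", "anchor", "side", "rank")]
  if (anyDuplicated(key)) {
    format_error(path, NA, "duplicate (species, anchor, side, rank) row")
  }
  df[need]
}

#' @rdname read_neighborhood_tsv
#' @param table Neighborhood data frame.
#' @export
write_neighborhood_tsv <- function(table, path) {
  write.table(table[c("species", "anchor", "side", "rank", "gene")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a network in Cytoscape SIF format
#'
#' One line per edge: `gene_a<TAB>edge_class<TAB>gene_b`.
#'
#' @param network A `dc_network`.
#' @param path Output path.
#' @export
write_sif <- function(network, path) {
  stopifnot(inherits(network, "dc_network"))
  e <- network$edges
  writeLines(if (nrow(e) > 0L)
    paste(e$gene_a, e$edge_class, e$gene_b, sep = "\t") else character(0),
    path)
  invisible(path)
}

#' Export the significant edges of a network as TSV
#'
#' @param network A `dc_network`.
#' @param path Output path.
#' @export
write_edges_tsv <- function(network, path) {
  stopifnot(inherits(network, "dc_network"))
  cols <- c("gene_a", "gene_b", "r_control", "r_exposed", "delta_r",
            "p_diff", "q_diff", "edge_class", "driver")
  e <- network$edges
  if (!"driver" %in% names(e)) e$driver <- NA_character_
  write.table(e[intersect(cols, names(e))], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a JSON run report
#'
#' Serialises a run summary (configuration echo, seeds, counts, and package
#' version) so a run can be reproduced from its report alone.
#'
#' @param summary Named list of report fields.
#' @param path Output path.
#' @export
write_report_json <- function(summary, path) {
  summary$package_version <- as.character(utils::packageVersion("coexcomp"))
  summary$r_version <- R.version.string
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
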