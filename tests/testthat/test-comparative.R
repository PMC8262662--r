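make_aln <- function(seqs, grp = NULL, gene = "GENE", ref = NULL) {
  if (is.null(grp)) {
    grp <- setNames(ifelse(grepl("^s", names(seqs)), "sensitive",
                           "insensitive"), names(seqs))
  }
  ortholog_alignment(seqs, grp, gene = gene, reference_species = ref)
}

test_that("group-exclusive calling follows the column rules", {
  # identical sequences: nothing to call
  aln <- make_aln(c(s1 = "MKTAY", s2 = "MKTAY", i1 = "MKTAY", i2 = "MKTAY"))
  expect_equal(nrow(call_group_exclusive(aln)), 0)

  # sensitive all P, both insensitive A: one strict call
  aln <- make_aln(c(s1 = "MPT", s2 = "MPT", i1 = "MAT", i2 = "MAT"))
  calls <- call_group_exclusive(aln, "strict")
  expect_equal(calls$column, 2L)
  expect_equal(calls$label, "P2A")

  # one insensitive residue matching the sensitive set: no call in either mode
  aln <- make_aln(c(s1 = "MAT", s2 = "MAT", i1 = "MPT", i2 = "MST"))
  expect_equal(nrow(call_group_exclusive(aln, "strict")), 0)
  aln2 <- make_aln(c(s1 = "MAT", s2 = "MAT", i1 = "MAT", i2 = "MST"))
  expect_equal(nrow(call_group_exclusive(aln2, "strict")), 0)
  expect_equal(nrow(call_group_exclusive(aln2, "loose")), 0)

  # differing insensitive residues, both absent from sensitive: loose only
  calls_loose <- call_group_exclusive(aln, "loose")
  expect_equal(calls_loose$column, 2L)
  expect_true(is.na(calls_loose$alt_residue))
  expect_equal(nrow(call_group_exclusive(aln, "strict")), 0)

  # gaps and ambiguity never support a call
  aln <- make_aln(c(s1 = "M-T", s2 = "MPT", i1 = "MAT", i2 = "MAT"))
  expect_equal(nrow(call_group_exclusive(aln)), 0)  # sensitive gap: skipped
  aln <- make_aln(c(s1 = "MPT", s2 = "MPT", i1 = "M-T", i2 = "MAT"))
  expect_equal(nrow(call_group_exclusive(aln)), 0)
  aln <- make_aln(c(s1 = "MPT", s2 = "MPT", i1 = "MXT", i2 = "MXT"))
  expect_equal(nrow(call_group_exclusive(aln)), 0)
  aln <- make_aln(c(s1 = "MXT", s2 = "MPT", i1 = "MAT", i2 = "MAT"))
  expect_equal(nrow(call_group_exclusive(aln)), 0)

  # indel columns reported separately on request, never as substitutions
  aln <- make_aln(c(s1 = "MPTK", s2 = "MPTK", i1 = "MA-K", i2 = "MA-K"))
  calls <- call_group_exclusive(aln, count_indels = TRUE)
  expect_equal(calls$column, 2L)
  expect_equal(attr(calls, "indel_columns"), 3L)
})

test_that("a Trp53-style mini-alignment yields the P72A call", {
  # reference position 72 with one alignment gap upstream in the reference
  ref_prefix <- paste(rep("M", 70), collapse = "")
  mk <- function(aa) paste0(ref_prefix, "-K", aa, "LL")  # column 73 -> pos 72
  grp <- study_groups()
  seqs <- setNames(rep(mk("P"), length(grp)), names(grp))
  seqs[c("mouse", "rat")] <- mk("A")
  aln <- ortholog_alignment(seqs, grp, gene = "TP53")
  calls <- call_group_exclusive(aln, "strict")
  expect_equal(calls$ref_position, 72L)
  expect_equal(calls$label, "P72A")
})

test_that("group labels are symmetric: swapping groups swaps the direction", {
  seqs <- c(a1 = "MPTKY", a2 = "MPTKY", b1 = "MATKY", b2 = "MATKY")
  grp_fwd <- setNames(c("sensitive", "sensitive", "insensitive", "insensitive"),
                      names(seqs))
  grp_rev <- setNames(c("insensitive", "insensitive", "sensitive", "sensitive"),
                      names(seqs))
  fwd <- call_group_exclusive(ortholog_alignment(seqs, grp_fwd, ref = NULL))
  rev <- call_group_exclusive(ortholog_alignment(seqs, grp_rev, ref = NULL))
  expect_equal(fwd$column, rev$column)
  expect_equal(fwd$ref_residue, "P")
  expect_equal(rev$ref_residue, "A")
})

test_that("strict calls are a subset of loose calls on random alignments", {
  grp <- study_groups()
  for (seed in 1:5) {
    set.seed(seed)
    cols <- sample(60, 8)
    pec <- data.frame(
      column = sort(cols),
      sensitive_residue = "A",
      insensitive_residue = sample(c("P", "S", "P/S"), 8, replace = TRUE)
    )
    sim <- simulate_msa(msa_design(names(grp), grp, 60, pec,
                                   shared_polymorphic_columns = 10,
                                   seed = seed))
    strict <- call_group_exclusive(sim$alignment, "strict")$column
    loose <- call_group_exclusive(sim$alignment, "loose")$column
    expect_true(all(strict %in% loose))
    expect_setequal(loose, sim$truth$column)
  }
})

test_that("column-to-reference mapping counts ungapped reference positions", {
  aln <- make_aln(c(s1 = "MKT", i1 = "MAT"), ref = "s1")
  expect_equal(map_column_to_ref(aln, 1:3), 1:3)      # ungapped: identity
  aln <- make_aln(c(s1 = "M-KT", i1 = "MAKT"), ref = "s1")
  expect_equal(map_column_to_ref(aln, 3), 2L)
  expect_true(is.na(map_column_to_ref(aln, 2)))       # reference gap
  expect_error(map_column_to_ref(aln, 5), "out of range")
  # non-decreasing and surjective onto 1..ungapped length
  aln <- make_aln(c(s1 = "M--KTA-YP", i1 = "MAAKTAAYP"), ref = "s1")
  pos <- map_column_to_ref(aln, 1:9)
  expect_true(all(diff(pos[!is.na(pos)]) >= 0))
  expect_setequal(pos[!is.na(pos)], 1:6)
})

test_that("human variant cross-reference matches gene, position, and residues", {
  tab <- read_variant_table(extdata("human_variants_synthetic.tsv"))
  calls <- data.frame(
    gene = c("TP53", "TP53", "CRBN"), column = c(73, 80, 5),
    ref_position = c(72L, 80L, 112L), ref_residue = c("P", "K", "R"),
    alt_residue = c("A", "R", "Q"),
    insensitive_residues = "", label = c("P72A", "K80R", "R112Q"),
    mode = "strict", stringsAsFactors = FALSE
  )
  hits <- cross_reference_human(calls, tab)
  expect_equal(hits$label, c("P72A", "R112Q"))
  expect_equal(hits$variant_ids[1], "rs587782769,rs1042522")
  expect_equal(hits$n_variants, c(2L, 1L))
  # same substitution at a different position does not match
  calls73 <- transform(calls[1, ], ref_position = 73L)
  expect_equal(nrow(cross_reference_human(calls73, tab)), 1)  # matches pos 73 row
  calls74 <- transform(calls[1, ], ref_position = 74L)
  expect_equal(nrow(cross_reference_human(calls74, tab)), 0)
  expect_equal(nrow(cross_reference_human(calls, tab[0, ])), 0)
})

test_that("codon differences report 1-based differing positions", {
  expect_equal(codon_diff("CCC", "GCA"), c(1L, 3L))
  expect_equal(codon_diff("ATG", "ATG"), integer(0))
  expect_equal(codon_diff("AAA", "TTT"), 1:3)
  expect_error(codon_diff("AC", "GCA"), "3-letter")
  expect_error(codon_diff("ACU", "GCA"), "3-letter")
})

test_that("neighborhood comparison partitions shared, group, and species genes", {
  grp <- setNames(c("sensitive", "sensitive", "insensitive", "insensitive"),
                  c("human", "rabbit", "mouse", "rat"))
  mk_rows <- function(species, genes) {
    data.frame(species = species, anchor = "NOS3", side = "upstream",
               rank = seq_along(genes), gene = genes, stringsAsFactors = FALSE)
  }
  # identical windows: no exclusives, all Jaccard 1
  tab <- do.call(rbind, lapply(names(grp), mk_rows, genes = c("A", "B", "C")))
  cmp <- compare_neighborhoods(tab, grp)
  expect_equal(lengths(cmp$group_exclusive), c(sensitive = 0L, insensitive = 0L))
  expect_true(all(cmp$jaccard == 1))
  expect_setequal(cmp$shared_core, c("A", "B", "C"))

  # group- and species-exclusive separation (rabbit-only gene block)
  rabbit_only <- c("WDR60", "ESYT2", "NCAPG2", "UBE3C", "LMBR1", "RNF32",
                   "SHH", "RBM33", "NOM1")
  tab <- rbind(
    mk_rows("human", c("KCNH2", "SEN1")),
    mk_rows("rabbit", c("KCNH2", "SEN1", rabbit_only)),
    mk_rows("mouse", c("KCNH2", "INS1")),
    mk_rows("rat", c("KCNH2", "INS1"))
  )
  cmp <- compare_neighborhoods(tab, grp)
  expect_setequal(cmp$species_exclusive$rabbit, rabbit_only)
  expect_false(any(rabbit_only %in% unlist(cmp$group_exclusive)))
  expect_equal(cmp$group_exclusive$insensitive, "INS1")
  expect_equal(cmp$group_exclusive$sensitive, "SEN1")
  expect_equal(cmp$shared_core, "KCNH2")
  # Jaccard symmetric with unit diagonal
  expect_equal(cmp$jaccard, t(cmp$jaccard))
  expect_true(all(diag(cmp$jaccard) == 1))

  # permissive semantics: present in some of the group, none of the other
  tab2 <- rbind(
    mk_rows("human", c("KCNH2", "GIMAP1")),
    mk_rows("rabbit", c("KCNH2")),
    mk_rows("mouse", c("KCNH2")),
    mk_rows("rat", c("KCNH2"))
  )
  expect_equal(compare_neighborhoods(tab2, grp)$group_exclusive$sensitive,
               character(0))
  expect_equal(
    compare_neighborhoods(tab2, grp, semantics = "any")$group_exclusive$sensitive,
    "GIMAP1"
  )

  # mixed anchors rejected
  bad <- rbind(tab, data.frame(species = "human", anchor = "SHH",
                               side = "upstream", rank = 99, gene = "Z"))
  expect_error(compare_neighborhoods(bad, grp), "anchors")
})

test_that("percent identity excludes gaps and ambiguity from both counts", {
  expect_equal(pairwise_identity("ACDEFG", "ACDEFG"), 100)
  expect_equal(pairwise_identity("ACDEFG", "ACDE--"), 100)
  expect_equal(pairwise_identity("ACDEFGHIKL", "ACDEFGHIAA"), 80)
  expect_equal(pairwise_identity("ACDEFGHIKL", "ACDEFGHIAA"),
               oracle_identity("ACDEFGHIKL", "ACDEFGHIAA"))
  expect_equal(pairwise_identity("AXDE", "AADE"), 100)  # X column excluded
  expect_true(is.na(pairwise_identity("--", "AA")))
  # symmetric; invariant to a column gapped in both
  set.seed(14)
  for (i in 1:10) {
    a <- paste(sample(c(AA_LETTERS, "-"), 30, replace = TRUE), collapse = "")
    b <- paste(sample(c(AA_LETTERS, "-"), 30, replace = TRUE), collapse = "")
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
    expect_equal(pairwise_identity(paste0(a, "-"), paste0(b, "-")),
                 pairwise_identity(a, b))
    expect_equal(pairwise_identity(a, b), oracle_identity(a, b))
  }
})

test_that("paralog counting applies the identity threshold to the reference", {
  expect_equal(count_paralogs(c(only = "MKT"), "only")$count, 0)
  # identities to reference: 72% and 65% over 100 columns
  ref <- paste(rep("A", 100), collapse = "")
  mk <- function(n_diff) paste(c(rep("A", 100 - n_diff), rep("C", n_diff)),
                               collapse = "")
  fam <- c(ref = ref, a = mk(28), b = mk(35))
  res <- count_paralogs(fam, "ref", identity_threshold = 70)
  expect_equal(res$count, 1)
  expect_equal(res$identity["ref", "a"], 72)
  expect_equal(res$identity, t(res$identity))
  expect_true(all(diag(res$identity) == 100))

  # synthetic family mutated at controlled rates matches its design
  set.seed(21)
  base <- sample(AA_LETTERS, 200, replace = TRUE)
  mutate <- function(rate) {
    s <- base
    idx <- which(runif(200) < rate)
    s[idx] <- vapply(s[idx], function(x) sample(setdiff(AA_LETTERS, x), 1), "")
    paste(s, collapse = "")
  }
  fam <- c(ref = paste(base, collapse = ""),
           near1 = mutate(0.1), near2 = mutate(0.2), far1 = mutate(0.5),
           far2 = mutate(0.6))
  res <- count_paralogs(fam, "ref", identity_threshold = 70)
  expect_equal(res$count, 2)
  expect_error(count_paralogs(fam, "absent"), "not in the family")
})
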