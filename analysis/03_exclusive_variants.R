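#!/usr/bin/env Rscript
# Comparative screen of the ortholog alignments: call substitutions
# exclusive to the insensitive species (strict mode), summarise per gene in
# descending order, cross-reference against the synthetic human-variant
# table, and work the TP53 codon example. Reads results/synthetic/, writes
# results/comparative/.

suppressMessages(library(coexcomp))
indir <- "results/synthetic"
out <- "results/comparative"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

groups_df <- read.delim(file.path(indir, "species_groups.tsv"))
groups <- setNames(groups_df$group, groups_df$species)
truth <- read.delim(file.path(indir, "msa_truth.tsv"))

fastas <- list.files(indir, pattern = "^msa_.*\\.fasta$", full.names = TRUE)
calls <- do.call(rbind, lapply(fastas, function(f) {
  gene <- sub("^msa_(.*)\\.fasta$", "\\1", basename(f))
  aln <- ortholog_alignment(read_aligned_fasta(f), groups, gene = gene)
  call_group_exclusive(aln, mode = "strict")
}))
write.table(calls, file.path(out, "calls.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

per_gene <- sort(table(calls$gene), decreasing = TRUE)
summary_df <- data.frame(gene = names(per_gene),
                         n_exclusive = as.integer(per_gene))
write.table(summary_df, file.path(out, "per_gene_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("group-exclusive substitutions per gene (descending):\n")
print(summary_df)
planted <- table(truth$gene)[summary_df$gene]
cat(sprintf("planted truth recovered exactly: %s\n",
            identical(as.integer(planted), summary_df$n_exclusive)))

variants <- read_variant_table(system.file(
  "extdata", "human_variants_synthetic.tsv", package = "coexcomp"))
matches <- cross_reference_human(calls, variants)
write.table(matches, file.path(out, "matches.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("calls matching human variant records: %d\n", nrow(matches)))

# codon-level view of the human P -> rodent A exchange at TP53 codon 72
cat("TP53 codon 72, human CCC vs rodent GCA: positions changed =",
    paste(codon_diff("CCC", "GCA"), collapse = ","), "\n")

write_report_json(list(stage = "exclusive_variants",
                       n_alignments = length(fastas),
                       n_calls = nrow(calls),
                       n_variant_matches = nrow(matches)),
                  file.path(out, "report.json"))
cat("wrote", out, "\n")
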