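#!/usr/bin/env Rscript
# Generate every synthetic input of the workflow, with recorded truth:
#  - a two-condition expression matrix planting differential co-expression
#    (a moderate positive pair flipping negative, a wider companion, and a
#    10-link hub) among background genes;
#  - ortholog protein alignments for five genes with planted group-exclusive
#    columns (65/35/22/18/17) over the 14 study species;
#  - an anchored NOS3-style neighborhood with 20 insensitive-exclusive genes
#    and a 9-gene rabbit-only block.
# Outputs under results/synthetic/.

suppressMessages(library(coexcomp))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

groups <- setNames(
  c(rep("sensitive", 12), "insensitive", "insensitive"),
  c("human", "zebrafish", "frog", "chicken", "opossum", "bushbaby",
    "armadillo", "sheep", "rabbit", "golden_hamster", "marmoset",
    "rhesus_macaque", "mouse", "rat")
)
write.table(data.frame(species = names(groups), group = unname(groups)),
            file.path(out, "species_groups.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## Expression matrix with planted differential co-expression ----------------
# Crbn's links to four limb-development partners flip from moderate
# positive to negative; the partner-partner correlations (the single-factor
# closure of the control condition) stay put, and 15 stable background
# pairs provide the co-expressed-but-undisturbed majority.
loadings_c <- c(Sall4 = 0.75, Recql4 = 0.80, Tbx5 = 0.72, Esco2 = 0.70)
loadings_e <- c(Sall4 = -0.48, Recql4 = -0.57, Tbx5 = -0.50, Esco2 = -0.52)
direct <- data.frame(gene_a = "Crbn", gene_b = names(loadings_c),
                     r_control = unname(loadings_c),
                     r_exposed = unname(loadings_e))
cl <- t(combn(names(loadings_c), 2))
closure <- data.frame(gene_a = cl[, 1], gene_b = cl[, 2],
                      r_control = loadings_c[cl[, 1]] * loadings_c[cl[, 2]],
                      r_exposed = loadings_c[cl[, 1]] * loadings_c[cl[, 2]])
stable <- data.frame(gene_a = paste0("bg", 1:15), gene_b = paste0("bg", 16:30),
                     r_control = 0.65, r_exposed = 0.65)
genes <- c("Crbn", names(loadings_c), "Rbm8a", "Sall4l", paste0("bg", 1:44))
design <- expression_design(51, 200, rbind(direct, closure, stable),
                            seed = seed + 11L, gene_ids = genes,
                            allow_overlap = TRUE)
sim <- simulate_expression(design)
write_expression_tsv(sim$matrix, file.path(out, "expression.tsv"))
write.table(data.frame(sample_id = colnames(sim$matrix$values),
                       condition = sim$matrix$condition),
            file.path(out, "condition_map.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$truth, file.path(out, "expression_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("expression: %d genes x %d samples, %d planted pairs\n",
            nrow(sim$matrix$values), ncol(sim$matrix$values),
            nrow(sim$truth)))

## Ortholog alignments with planted exclusive columns ------------------------
planted_counts <- c(RECQL4 = 65, SALL4 = 35, CDH5 = 22, KDR = 18, NOS2 = 17,
                    TP53 = 12)
set.seed(seed + 51L)
msa_truth <- list()
for (g in names(planted_counts)) {
  k <- planted_counts[[g]]
  cols <- sort(sample(1200, k))
  sens <- sample(AA_LETTERS, k, replace = TRUE)
  pec <- data.frame(
    column = cols, sensitive_residue = sens,
    insensitive_residue = vapply(sens, function(a)
      sample(setdiff(AA_LETTERS, a), 1), "")
  )
  if (g == "TP53") {  # place the P72A exemplar at reference position 72
    pec <- pec[pec$column != 72, ]
    pec <- rbind(pec[0, ],
                 data.frame(column = 72, sensitive_residue = "P",
                            insensitive_residue = "A"),
                 pec)[seq_len(k), ]
    pec <- pec[order(pec$column), ]
  }
  sm <- simulate_msa(msa_design(names(groups), groups, 1200, pec,
                                shared_polymorphic_columns = 40,
                                seed = seed + 60L + match(g, names(planted_counts)),
                                gene = g))
  write_aligned_fasta(sm$alignment$sequences,
                      file.path(out, paste0("msa_", g, ".fasta")))
  msa_truth[[g]] <- sm$truth
}
truth_all <- do.call(rbind, msa_truth)
write.table(truth_all, file.path(out, "msa_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("alignments: %d genes, %d planted exclusive columns in total\n",
            length(planted_counts), nrow(truth_all)))

## Neighborhood table ---------------------------------------------------------
rabbit_only <- c("WDR60", "ESYT2", "NCAPG2", "UBE3C", "LMBR1", "RNF32",
                 "SHH", "RBM33", "NOM1")
dsyn <- synteny_design(
  "NOS3", 40, names(groups), groups, shared_core = c("KCNH2", "ABCB8"),
  group_exclusive = list(insensitive = paste0("IEX", 1:20)),
  species_exclusive = list(rabbit = rabbit_only), seed = seed + 71L
)
tab <- simulate_synteny(dsyn)
write_neighborhood_tsv(tab, file.path(out, "neighborhood_nos3.tsv"))
cat(sprintf("neighborhood: %d species, window 40/side, 20 group-exclusive + %d rabbit-only genes planted\n",
            length(groups), length(rabbit_only)))

write_report_json(list(stage = "simulate", seed = seed,
                       n_genes = nrow(sim$matrix$values),
                       n_planted_pairs = nrow(sim$truth),
                       n_planted_columns = nrow(truth_all)),
                  file.path(out, "report.json"))
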