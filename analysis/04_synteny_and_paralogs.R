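#!/usr/bin/env Rscript
# Neighborhood comparison around the NOS3-style anchor (group-exclusive,
# species-exclusive, shared core, Jaccard similarity) and identity-
# thresholded paralog counting for a synthetic 10-copy CYP-style family.
# Reads results/synthetic/, writes results/synteny/.

suppressMessages(library(coexcomp))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
indir <- "results/synthetic"
out <- "results/synteny"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

groups_df <- read.delim(file.path(indir, "species_groups.tsv"))
groups <- setNames(groups_df$group, groups_df$species)
tab <- read_neighborhood_tsv(file.path(indir, "neighborhood_nos3.tsv"))

cmp <- compare_neighborhoods(tab, groups, side = "upstream")
cat(sprintf("upstream of %s: %d insensitive-exclusive genes, %d sensitive-exclusive\n",
            tab$anchor[1], length(cmp$group_exclusive$insensitive),
            length(cmp$group_exclusive$sensitive)))
rabbit_planted <- cmp$species_exclusive$rabbit[
  !grepl("^FILLER_", cmp$species_exclusive$rabbit)]
cat("rabbit-only genes (filler excluded):",
    paste(rabbit_planted, collapse = ", "), "\n")
cat("shared core:", paste(cmp$shared_core, collapse = ", "), "\n")

mk_set <- function(set, genes) {
  data.frame(set = rep(set, length(genes)), gene = genes,
             stringsAsFactors = FALSE)
}
excl <- rbind(
  mk_set("insensitive_group", cmp$group_exclusive$insensitive),
  mk_set("sensitive_group", cmp$group_exclusive$sensitive),
  mk_set("rabbit_only", rabbit_planted),
  mk_set("shared_core", cmp$shared_core)
)
write.table(excl, file.path(out, "exclusives.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(round(cmp$jaccard, 4), file.path(out, "jaccard.tsv"),
            sep = "\t", quote = FALSE, col.names = NA)

# paralog counting: 10-copy family, 7 close (>70% id) + 2 distant copies
set.seed(seed + 81L)
base <- sample(AA_LETTERS, 400, replace = TRUE)
mutate <- function(rate) {
  s <- base
  idx <- which(runif(length(s)) < rate)
  s[idx] <- vapply(s[idx], function(x) sample(setdiff(AA_LETTERS, x), 1), "")
  paste(s, collapse = "")
}
fam <- c(CYP2C68 = paste(base, collapse = ""),
         setNames(vapply(c(rep(0.12, 7), rep(0.55, 2)), mutate, ""),
                  paste0("copy", 1:9)))
pg <- count_paralogs(fam, "CYP2C68", identity_threshold = 70)
cat(sprintf("CYP-style family: %d of %d copies exceed 70%% identity to the reference\n",
            pg$count, length(fam) - 1))
write.table(round(pg$identity, 2), file.path(out, "paralog_identity.tsv"),
            sep = "\t", quote = FALSE, col.names = NA)

write_report_json(list(
  stage = "synteny", seed = seed,
  n_group_exclusive_insensitive = length(cmp$group_exclusive$insensitive),
  n_rabbit_only = length(rabbit_planted),
  paralogs_over_70 = pg$count
), file.path(out, "report.json"))
cat("wrote", out, "\n")
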