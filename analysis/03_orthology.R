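#!/usr/bin/env Rscript
# Orthology and gene-family analysis on a planted five-genome hit table:
# one focal genome, two pathogens, two non-pathogens. Filters all-vs-all
# hits (E <= 1e-5, identity >= 30%, coverage >= 60% of both lengths),
# derives bidirectional best hits, classifies every focal gene into the
# four sharing categories, builds single-linkage families within the focal
# proteome, and annotates focal genes against a reference set by best hit.
#
# Writes: results/hits.tsv, results/genome_map.tsv, results/bbh.tsv,
#         results/categories.tsv, results/families.tsv,
#         results/annotation.tsv

suppressPackageStartupMessages(library(nemtrap))
dir.create("results", showWarnings = FALSE)

groups <- c(ao = "focal", p1 = "pathogen", p2 = "pathogen",
            n1 = "nonpathogen", n2 = "nonpathogen")
sim <- simulate_hit_table(
  genome_groups = groups,
  n_per_category = c(specific = 10, with_pathogen = 10,
                     shared_both_groups = 10, with_nonpathogen = 10),
  n_families = 4, family_size = 5, n_decoys = 12, seed = 20110903L)

# round-trip through the on-disk tabular format so the run exercises I/O
utils::write.table(sim$hits[, 1:14], "results/hits.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE, col.names = FALSE)
utils::write.table(sim$genome_map, "results/genome_map.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
hits <- read_hit_table("results/hits.tsv", sim$genome_map)

pairs <- filter_homologs(hits)
bb <- bbh_all_pairs(pairs)
utils::write.table(bb, "results/bbh.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

cats <- classify_categories(sim$focal_genes, bb, groups)
utils::write.table(cats, "results/categories.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
counts <- table(cats$category)
cat("focal gene categories:\n")
print(counts)
cat(sprintf("partition identity: %d category assignments = %d focal genes\n",
            sum(counts), length(sim$focal_genes)))

focal_pairs <- pairs[pairs$genome_a == "ao" & pairs$genome_b == "ao", ]
fam <- single_linkage_families(focal_pairs, universe = sim$focal_genes)
utils::write.table(fam$families, "results/families.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("multigene families: %d genes in %d families (%.1f%% of proteome)\n",
            nrow(fam$families), length(unique(fam$families$family_id)),
            100 * nrow(fam$families) / length(sim$focal_genes)))

# seed expansion by transitive closure, as done for pathogenicity candidates
seeds <- fam$families$gene_id[fam$families$family_id == 1][1]
expanded <- expand_family_by_linkage(seeds, focal_pairs,
                                     universe = sim$focal_genes)
cat(sprintf("closure expansion: %d seed -> %d genes\n",
            length(seeds), length(expanded)))

# best-hit annotation of the focal proteome against genome p1 as a stand-in
# reference protein set
ann <- annotate_by_reference(hits, "ao", "p1")
utils::write.table(ann, "results/annotation.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("reference annotation: %d focal genes with a best hit\n",
            nrow(ann)))
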