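#!/usr/bin/env Rscript
# Build the synthetic study genome: 100 kb of 50% GC sequence carrying five
# identical 2 kb repeat copies, then expose those copies to RIP-style
# CpA/TpG-context C->T mutation at rate 0.3. A small deterministic gene
# annotation (40 two-exon genes) provides the coding/noncoding/exon/intron
# classes for the feature-class RIP summary.
#
# Writes: results/genome.fa, results/repeats.bed, results/genes.gff3,
#         results/multigene_ids.txt

suppressPackageStartupMessages(library(nemtrap))
dir.create("results", showWarnings = FALSE)
seed <- 20110901L  # fixed study seed for the narrative run

g <- random_genome(1e5, gc_fraction = 0.5, seed = seed)
pl <- plant_repeats(g, repeat_length = 2000, copies = 5, seed = seed + 1L)
mut <- simulate_rip(pl$genome, pl$repeats, rate = 0.3, seed = seed + 2L)

write_fasta(c(genome = mut), "results/genome.fa")
utils::write.table(
  data.frame("genome", pl$repeats$start, pl$repeats$end),
  "results/repeats.bed", sep = "\t", quote = FALSE,
  row.names = FALSE, col.names = FALSE)

# 40 genes of 1.5 kb on a 2.5 kb grid, two exons with a 200 bp intron,
# kept clear of the repeat copies so feature classes stay interpretable
grid <- seq(0, 1e5 - 2500, by = 2500)
in_repeat <- vapply(grid, function(s) {
  any(s < pl$repeats$end & (s + 1500) > pl$repeats$start)
}, logical(1))
starts <- head(grid[!in_repeat], 40)
gff <- c("##gff-version 3")
for (i in seq_along(starts)) {
  s <- starts[i] + 1L  # GFF3 is 1-based closed
  gid <- sprintf("gene%02d", i)
  gff <- c(gff,
    sprintf("genome\tsim\tgene\t%d\t%d\t.\t+\t.\tID=%s", s, s + 1499L, gid),
    sprintf("genome\tsim\tmRNA\t%d\t%d\t.\t+\t.\tID=%s.t1;Parent=%s",
            s, s + 1499L, gid, gid),
    sprintf("genome\tsim\texon\t%d\t%d\t.\t+\t.\tParent=%s.t1", s, s + 649L, gid),
    sprintf("genome\tsim\texon\t%d\t%d\t.\t+\t.\tParent=%s.t1",
            s + 850L, s + 1499L, gid),
    sprintf("genome\tsim\tCDS\t%d\t%d\t.\t+\t0\tParent=%s.t1", s, s + 649L, gid),
    sprintf("genome\tsim\tCDS\t%d\t%d\t.\t+\t0\tParent=%s.t1",
            s + 850L, s + 1499L, gid))
}
writeLines(gff, "results/genes.gff3")
# first ten genes declared members of multigene families for the summary
writeLines(sprintf("gene%02d", 1:10), "results/multigene_ids.txt")

cat(sprintf("genome: %d bp, %d repeat copies of %d bp, %d genes annotated\n",
            nchar(mut), nrow(pl$repeats), 2000, length(starts)))
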