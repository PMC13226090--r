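#!/usr/bin/env Rscript
# Stage 5: cross-species program matching. Top-20 gene signatures per
# consensus program, translated through the one-to-one ortholog map, are
# compared by Jaccard index with two-sided Fisher's exact significance
# over the universe of genes eligible in both analyses.

library(tmecrossmap)

W_a <- as.matrix(read.delim("results/W_con_a.tsv", row.names = 1))
W_b <- as.matrix(read.delim("results/W_con_b.tsv", row.names = 1))
map <- read.delim("results/ortholog_map.tsv")

sig_a <- top_genes(W_a, 20)
sig_b <- top_genes(W_b, 20)

multi <- map$gene_a %in% map$gene_a[duplicated(map$gene_a)] |
  map$gene_b %in% map$gene_b[duplicated(map$gene_b)]
m1 <- map[!multi, ]
universe <- m1$gene_a[m1$gene_a %in% rownames(W_a) &
                        m1$gene_b %in% rownames(W_b)]
cat("Fisher universe:", length(universe), "one-to-one mapped genes\n")

mt <- jaccard_matrix(sig_a, sig_b, ortholog_map = map, universe = universe)
write.table(mt$pairs, "results/gep_match_table.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Jaccard matrix (A programs x B programs):\n")
print(round(mt$jaccard, 3))
hits <- mt$pairs[mt$pairs$significant & !is.na(mt$pairs$jaccard) &
                   mt$pairs$jaccard > 0, ]
hits <- hits[order(-hits$jaccard), ]
cat(nrow(hits), "significant cross-species pairs (Fisher p <= 0.05):\n")
print(hits[, c("program_a", "program_b", "overlap", "jaccard", "fisher_p")],
      row.names = FALSE)
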