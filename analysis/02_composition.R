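#!/usr/bin/env Rscript
# Stage 2: compartment-frequency harmonization and archetype mapping.
# Pools human and mouse frequency tables, z-scores jointly, aggregates by
# group (median), and maps each mouse model onto its most similar human
# archetype by cosine similarity; also reports relative variance (CV^2)
# and the Pearson/BH compartment-compartment correlation matrices.

library(tmecrossmap)

read_freq <- function(path) {
  df <- read.delim(path, row.names = 1, check.names = FALSE)
  list(freq = as.matrix(df[, -1]), group = df$group)
}
hum <- read_freq("results/frequencies_human.tsv")
mus <- read_freq("results/frequencies_mouse.tsv")

z <- combined_zscore(list(hum$freq, mus$freq))
cat("pooled z-scoring over", nrow(z$zscores), "samples;",
    "max |column mean| =", format(max(abs(colMeans(z$zscores))), digits = 2), "\n")

groups <- c(hum$group, mus$group)
med <- aggregate_by_group(rbind(hum$freq, mus$freq), groups, "median")
sm <- cosine_similarity_matrix(med[unique(mus$group), , drop = FALSE],
                               med[unique(hum$group), , drop = FALSE])
write.table(sm$similarity, "results/cosine_mouse_vs_archetype.tsv",
            sep = "\t", quote = FALSE, col.names = NA)
for (m in rownames(sm$similarity)) {
  best <- colnames(sm$similarity)[which.max(sm$similarity[m, ])]
  cat(sprintf("model %-5s -> archetype %-12s (cosine %.3f)\n",
              m, best, max(sm$similarity[m, ])))
}

rv <- relative_variance(rbind(hum$freq, mus$freq),
                        ifelse(seq_along(groups) <= nrow(hum$freq),
                               "human", "mouse"))
write.table(rv, "results/relative_variance.tsv", sep = "\t",
            quote = FALSE, col.names = NA)
cat("median CV^2 human:", format(median(rv["human", ], na.rm = TRUE), digits = 3),
    "| mouse:", format(median(rv["mouse", ], na.rm = TRUE), digits = 3), "\n")

cm_h <- pairwise_pearson_bh(hum$freq)
cm_m <- pairwise_pearson_bh(mus$freq)
write.table(cm_h$pearson_r, "results/feature_cor_human.tsv", sep = "\t",
            quote = FALSE, col.names = NA)
write.table(cm_m$pearson_r, "results/feature_cor_mouse.tsv", sep = "\t",
            quote = FALSE, col.names = NA)
cat("significant compartment pairs (BH < 0.05): human",
    sum(cm_h$p_adjusted < 0.05, na.rm = TRUE) / 2, "| mouse",
    sum(cm_m$p_adjusted < 0.05, na.rm = TRUE) / 2, "\n")
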