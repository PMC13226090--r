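#!/usr/bin/env Rscript
# Stage 6: coordinated program "movements" and survival stratification.
# Treats half the species-A consensus programs as T-cell programs and
# half as myeloid (labels are arbitrary in the synthetic world), scores
# samples, correlates T vs myeloid scores with BH correction, bins
# subjects on the strongest movement pair, and stratifies planted
# survival by the joint high/low groups.

library(tmecrossmap)

H <- as.matrix(read.delim("results/H_con_a.tsv", row.names = 1))
k <- nrow(H)
t_idx <- seq_len(ceiling(k / 2))
t_scores <- t(H[t_idx, , drop = FALSE])
my_scores <- t(H[-t_idx, , drop = FALSE])
colnames(t_scores) <- paste0("T", t_idx)
colnames(my_scores) <- paste0("My", seq_len(k - length(t_idx)))

cm <- movement_correlation(t_scores, my_scores)
write.table(cm$pearson_r, "results/movement_pearson.tsv", sep = "\t",
            quote = FALSE, col.names = NA)
write.table(cm$p_adjusted, "results/movement_padj.tsv", sep = "\t",
            quote = FALSE, col.names = NA)
best <- arrayInd(which.min(cm$p_adjusted), dim(cm$p_adjusted))
bt <- rownames(cm$p_adjusted)[best[1]]; bm <- colnames(cm$p_adjusted)[best[2]]
cat(sprintf("strongest movement: %s ~ %s (r = %.3f, BH p = %.2e)\n",
            bt, bm, cm$pearson_r[best], cm$p_adjusted[best]))

pair <- cbind(t_scores[, bt], my_scores[, bm])
colnames(pair) <- c(bt, bm)
binned <- bin_by_quantile(pair, 0.5, 0.5)
cat("joint bins:", paste(names(table(binned$joint)),
                         table(binned$joint), collapse = " | "), "\n")

# planted survival: both scores protective (negative log-hazard)
surv <- generate_survival_cohort(scale(pair), coefficients = c(-0.7, -0.7),
                                 baseline_hazard = 0.1, censor_rate = 0.2,
                                 seed = 7L)
km <- kaplan_meier(surv, binned$joint)
med <- km$median_survival
cat("KM median survival by joint group:\n")
print(round(med, 2))
cat(sprintf("log-rank chi-square = %.2f (df %d), p = %.3g\n",
            km$logrank_statistic, length(km$groups) - 1, km$logrank_p))
curves <- do.call(rbind, lapply(names(km$curves), function(g)
  cbind(group = g, km$curves[[g]])))
write.table(curves, "results/km_curves.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
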