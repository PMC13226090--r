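#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs with planted ground truth.
# Two species' expression cohorts share 3 of 6 gene expression programs;
# compartment-frequency cohorts carry archetype structure with a
# macrophage-biased "mouse-like" group; survival times depend on planted
# program scores. Everything downstream consumes these tables.

library(tmecrossmap)

seed <- 1L
dir.create("results", showWarnings = FALSE)

cfg <- synthetic_cohort_config(seed = seed)   # 1000 genes, 2 x 200 samples,
ds <- generate_planted_gep_dataset(cfg)       # k_true 6, k_shared 3

write.table(ds$expression_a, "results/expression_a.tsv", sep = "\t",
            quote = FALSE, col.names = NA)
write.table(ds$expression_b, "results/expression_b.tsv", sep = "\t",
            quote = FALSE, col.names = NA)
write.table(ds$ortholog_map, "results/ortholog_map.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ds$true_W_a, "results/true_W_a.tsv", sep = "\t",
            quote = FALSE, col.names = NA)
write.table(ds$true_W_b, "results/true_W_b.tsv", sep = "\t",
            quote = FALSE, col.names = NA)

cat("expression A:", dim(ds$expression_a)[1], "genes x",
    dim(ds$expression_a)[2], "samples; shared programs:",
    paste(ds$shared_program_ids, collapse = ", "), "\n")
cat("ortholog map:", nrow(ds$ortholog_map), "pairs (",
    sum(duplicated(ds$ortholog_map$gene_a)), "many-to-many )\n")

# archetype-structured compartment frequencies: an immune-rich and a
# macrophage-rich immune-desert human archetype plus mouse-like groups
feats <- c("tumor", "stroma", "t_cell", "b_cell", "nk", "macrophage",
           "monocyte", "cdc1", "cdc2", "neutrophil")
arche <- rbind(
  immune_rich = c(0.20, 0.10, 0.30, 0.10, 0.05, 0.10, 0.05, 0.03, 0.04, 0.03),
  desert_mac  = c(0.45, 0.15, 0.03, 0.02, 0.02, 0.20, 0.08, 0.01, 0.02, 0.02),
  stroma_rich = c(0.25, 0.40, 0.08, 0.04, 0.03, 0.08, 0.06, 0.02, 0.02, 0.02))
colnames(arche) <- feats
mouse <- arche[c("desert_mac", "desert_mac"), ]
rownames(mouse) <- c("B16", "MC38")
mouse["B16", c("macrophage", "tumor")] <-
  mouse["B16", c("macrophage", "tumor")] + c(0.05, -0.05)
mouse["MC38", c("monocyte", "tumor")] <-
  mouse["MC38", c("monocyte", "tumor")] + c(0.04, -0.04)

hum <- generate_frequency_cohort(arche, n_per_group = 20,
                                 concentration = 150, seed = seed + 1L)
mus <- generate_frequency_cohort(mouse, n_per_group = 10,
                                 concentration = 150, seed = seed + 2L)
write.table(cbind(group = hum$group_label, as.data.frame(hum$frequencies)),
            "results/frequencies_human.tsv", sep = "\t", quote = FALSE,
            col.names = NA)
write.table(cbind(group = mus$group_label, as.data.frame(mus$frequencies)),
            "results/frequencies_mouse.tsv", sep = "\t", quote = FALSE,
            col.names = NA)
cat("frequency cohorts:", nrow(hum$frequencies), "human +",
    nrow(mus$frequencies), "mouse samples over", length(feats),
    "compartments\n")
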