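#!/usr/bin/env Rscript
# Step 3: principal component analysis of population allele frequencies
# with randomization significance of the leading axes, and a two-axis
# ordination plot of the populations.

library(introgressr)

tab <- read_structure_file("results/scenario/genotypes.str")
tab <- read_sample_metadata(tab, "results/scenario/samples.csv")

res <- pca_randomization_test(tab, n_rand = 999, n_axes = 4, seed = 3)
print(res)

scores <- data.frame(population = rownames(res$scores), res$scores[, 1:2])
sp <- tapply(tab$samples$species, tab$samples$population, function(x) x[1])
scores$species <- sp[scores$population]
region <- tapply(tab$samples$region, tab$samples$population, function(x) x[1])
scores$region <- region[scores$population]
write.table(scores, "results/pca_scores.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

axes <- data.frame(axis = paste0("PC", seq_along(res$eigenvalues)),
                   pct_inertia = 100 * res$axis_inertia_fraction,
                   axis_fst = res$axis_fst,
                   p = res$axis_p_values)
write.table(axes, "results/pca_axes.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

pdf("results/pca_populations.pdf", width = 6, height = 6)
cols <- c(graellsii = "black", elegans = "grey50")
pch <- ifelse(scores$region == "Spain", 17, 16)
plot(scores$PC1, scores$PC2, col = cols[scores$species], pch = pch,
     xlab = sprintf("PC1 (%.0f%%)", axes$pct_inertia[1]),
     ylab = sprintf("PC2 (%.0f%%)", axes$pct_inertia[2]),
     main = "Population allele-frequency PCA")
legend("topright", c("graellsii", "elegans (allopatric)", "elegans (Spain)"),
       col = c("black", "grey50", "grey50"), pch = c(16, 16, 17), bty = "n")
dev.off()

cat("\nThe first two axes summarise",
    sprintf("%.0f%%", sum(axes$pct_inertia[1:2])),
    "of the total between-population variation.\n")
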