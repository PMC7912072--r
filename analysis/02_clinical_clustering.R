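#!/usr/bin/env Rscript

# Stage 2: the clinical component.
#
# Screens the monitored clinical parameters for differences across the
# five BMI groups (Kruskal-Wallis), then clusters the samples on the
# z-scored significant parameters (Euclidean distance, Ward linkage)
# and scores the 5-cluster partition against the BMI-group labels with
# the Adjusted Rand Index. An ARI near zero says clinical profiles
# alone do not delineate the weight strata.

suppressPackageStartupMessages(library(plasmapattern))

cohort <- read_cohort_table("results/cohort.tsv")

screen <- screen_parameters(cohort, alpha = 0.05)
write.table(screen, "results/parameter_screen.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("parameters significant at 0.05:",
    paste(screen$parameter[screen$significant], collapse = ", "), "\n")

sel <- screen$parameter[screen$significant]
clin <- as.matrix(cohort[sel])
rownames(clin) <- cohort$sample_id
z <- zscore_normalize(clin)

pc <- pca_scores(z, 2)
cat(sprintf("PC1/PC2 explain %.1f%% / %.1f%% of clinical variance\n",
            100 * pc$explained[1], 100 * pc$explained[2]))

part <- cut_tree(ward_linkage(dist(z)), k = nlevels(cohort$group))
groups <- setNames(as.integer(cohort$group), cohort$sample_id)
ari <- adjusted_rand_index(part, groups)
cat(sprintf("clinical clustering vs BMI groups: ARI = %.3f\n", ari))

write.table(data.frame(sample_id = names(part), cluster = part),
            "results/clinical_partition.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(sprintf("clinical_ari\t%.6f", ari), "results/clinical_ari.tsv")
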