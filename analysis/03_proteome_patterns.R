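#!/usr/bin/env Rscript

# Stage 3: the proteomic component.
#
# Summarises the protein catalog, removes unrepresentative (single
# occurrence) and non-specific (ubiquitous) proteins, clusters the
# samples on their presence/absence profiles (Jaccard distance, Ward
# linkage), and extracts the protein pattern that discriminates the
# high-BMI sample cluster (Fisher exact tests with Benjamini-Hochberg
# control). The whole analysis is then repeated with the borderline OW
# group removed.

suppressPackageStartupMessages(library(plasmapattern))

cohort <- read_cohort_table("results/cohort.tsv")
m <- read_presence_matrix("results/presence_matrix.tsv")
truth <- readLines("results/informative_proteins.tsv")

cat_sum <- summarize_catalog(m, cohort,
  merge_groups = list(OWOB = c("OW", "OB1", "OB2", "OB3")))
cat(sprintf("catalog: %d proteins; %d in every sample; NORM union %d; OW+OB union %d\n",
            cat_sum$n_total, cat_sum$n_core,
            cat_sum$per_group_union[["NORM"]],
            cat_sum$per_group_union[["OWOB"]]))

run_patterns <- function(mat, co, tag) {
  part <- cut_tree(ward_linkage(jaccard_dist_matrix(mat)), k = 2)
  hi <- high_bmi_cluster(part, co)
  pat <- extract_discriminative_pattern(mat, part, hi, alpha = 0.05,
                                        cohort = co)
  cat(sprintf("[%s] matrix %d x %d; high-BMI cluster: %d samples; pattern: %d proteins\n",
              tag, nrow(mat), ncol(mat), pat$bmi$n_in, length(pat$pattern)))
  cat(sprintf("[%s] cluster mean BMI %.1f vs %.1f (Mann-Whitney p = %.3g)\n",
              tag, pat$bmi$mean_in, pat$bmi$mean_out, pat$bmi$p_value))
  cat(sprintf("[%s] planted proteins recovered in pattern: %d of %d\n",
              tag, sum(truth %in% pat$pattern), length(truth)))
  write.table(pat$table, sprintf("results/pattern_%s.tsv", tag), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = names(part), cluster = part),
              sprintf("results/proteome_partition_%s.tsv", tag), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

filtered <- filter_proteins(m)
run_patterns(filtered, cohort, "all")

sub <- subset_samples(m, cohort, exclude_groups = "OW")
run_patterns(sub$matrix, sub$cohort, "noOW")
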