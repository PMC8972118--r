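#!/usr/bin/env Rscript
# Group comparison: (a) subject-label permutation test of every edge, each
# node's in-/out-strength, and overall connectivity between the two stages;
# (b) Welch t-tests on the person means of the raw scales.
#
# Outputs: results/compare/{permutation.csv,permutation.json,
#          group_comparison.csv}

library(emanet)

out <- "results/compare"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260920L

tab <- read.csv("results/preprocess/analysis_table.csv")
labels <- setdiff(names(tab), c("subject_id", "group", "day", "beep",
                                "timestamp"))
groups <- unique(tab$group)
pick <- function(g) {
  structure(tab[tab$group == g, ], node_labels = labels,
            class = c("analysis_table", "data.frame"))
}

res <- permutation_compare(pick(groups[1]), pick(groups[2]),
                           n_permutations = 2000, seed = seed,
                           engine = "ols")
print(res)
write_permutation_csv(res, file.path(out, "permutation.csv"))
write_permutation_json(res, file.path(out, "permutation.json"))

tgt <- res$table[res$table$statistic == "edge:loneliness->restriction", ]
message(sprintf("loneliness -> restriction difference (%s - %s): %.3f, p = %.3f",
                groups[1], groups[2], tgt$observed, tgt$p))
ost <- res$table[res$table$statistic == "out_strength:loneliness", ]
message(sprintf("loneliness out-strength difference: %.3f, p = %.3f",
                ost$observed, ost$p))

raw_tab <- read.csv("results/preprocess/analysis_table_raw.csv")
raw_tab <- structure(raw_tab, node_labels = labels,
                     class = c("analysis_table", "data.frame"))
pm <- person_means(raw_tab)
cmp <- group_comparison_table(pm)
write.csv(cmp, file.path(out, "group_comparison.csv"), row.names = FALSE)
message("person-mean Welch comparisons:")
print(cmp, digits = 3)
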