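#!/usr/bin/env Rscript
# Structural-variant junction reconstruction on synthetic inversions.
#
# Generate 25 inversion junction cases with the archetype mix observed for
# validated inversions (3 without microhomology, 12 with an intact
# microhomologous overlap, 6 with deletions on/near the overlap, 4 with
# long adjacent resections), run the junction analyzer on each, verify the
# planted anatomy is recovered exactly, and produce the per-group
# junction-characteristics table plus the inferred end-joining mechanism
# tally (cNHEJ vs microhomology-guided cNHEJ vs MMEJ candidates).

library(radmut)

cfg <- generator_config()
mix <- c(rep("A", 3), rep("B", 12), rep("C", 6), rep("D", 4))
jc <- gen_junction_cases(cfg, n = length(mix), seed = 201, classes = mix)
reports <- lapply(jc$cases, analyze_junction)
tab <- junction_report_table(reports)

exact <- all(tab$mh_length == jc$truth$mh_length,
             tab$del_on_overlap == jc$truth$del_on_overlap,
             tab$del_adjacent_left == jc$truth$del_adjacent_left,
             tab$del_adjacent_right == jc$truth$del_adjacent_right,
             tab$archetype == jc$truth$class)
cat(sprintf("Planted junction anatomy recovered exactly: %s (%d cases)\n",
            exact, nrow(tab)))

summary_tab <- tabulate_junctions(reports, group = rep("simulated", nrow(tab)))
print(summary_tab[, c("group", "n_total", "overlap_label",
                      "del_on_overlap_label", "del_adjacent_label")])
cat(sprintf("%d of %d inversions carry a microhomologous overlap\n",
            summary_tab$overlap, summary_tab$n_total))
print(table(tab$mechanism))

dir.create("results", showWarnings = FALSE)
write.table(tab, "results/junction_reports.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(summary_tab, "results/junction_summary.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("Wrote results/junction_reports.tsv and results/junction_summary.tsv\n")
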