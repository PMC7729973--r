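#!/usr/bin/env Rscript
# Quality filtering of the simulated SV table: short SVs (< 375 bases),
# shallow specimens (< 2000 reads), weakly supported SVs (< 10 reads), and
# control-based contaminant removal (mock-community rule on the positive
# controls, prevalence+enrichment rule on the negative controls).
# Reads results/data/, writes the filtered table and a filter report.

suppressPackageStartupMessages(library(quartermilk))

ind <- "results/data"
out <- "results/qc"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tab <- read_sv_table(file.path(ind, "sv_counts.tsv"), "tsv",
                     lengths = file.path(ind, "sv_lengths.tsv"))
tax <- read_taxonomy(file.path(ind, "taxonomy.tsv"))
md <- read_metadata(file.path(ind, "metadata.tsv"))
mock <- readLines(file.path(ind, "mock_reference.txt"))

qc <- qc_chain(tab, md, tax, mock)
write_sv_table(qc$table, file.path(out, "filtered_sv_table.tsv"),
               file.path(out, "filtered_sv_lengths.tsv"))
write.table(qc$report$removed, file.path(out, "removed_entities.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(n_sv_in = qc$report$n_sv_in, n_sv_out = qc$report$n_sv_out,
       n_samples_in = qc$report$n_samples_in,
       n_samples_out = qc$report$n_samples_out,
       reads_removed_pct = qc$report$reads_removed_pct,
       removed_by_rule = as.list(table(qc$report$removed$rule))),
  file.path(out, "filter_report.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

print(qc$report)
ds <- depth_summary(qc$table)
cat(sprintf("Retained depth: mean %.0f, median %.0f, min %.0f, max %.0f.\n",
            ds$mean, ds$median, ds$min, ds$max))
cat("Filtered table written under", out, "\n")
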