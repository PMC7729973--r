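#!/usr/bin/env Rscript
# Generate the synthetic herd dataset that drives the rest of the analysis:
# 60 cows on two farms, four quarters each, sampled in two periods, with
# known injected dysbiosis events, contaminants and culture results.
# Writes all tables in the package's exchange formats under results/data/.

suppressPackageStartupMessages(library(quartermilk))

seed <- 20231
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

config <- generator_config(seed = seed)
dataset <- generate_dataset(config)

write_sv_table(dataset$table, file.path(out, "sv_counts.tsv"),
               file.path(out, "sv_lengths.tsv"))
write_taxonomy(dataset$taxonomy, file.path(out, "taxonomy.tsv"))
for (nm in c("metadata", "colony", "isolates")) {
  write.table(dataset[[nm]], file.path(out, paste0(nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
writeLines(dataset$mock, file.path(out, "mock_reference.txt"))
jsonlite::write_json(dataset$truth, file.path(out, "truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

md <- dataset$metadata
ev <- dataset$truth$dysbiosis_events
cat(sprintf("Simulated %d samples (%d specimens, %d controls), %d SVs.\n",
            nrow(dataset$table$counts),
            sum(md$role == "specimen"), sum(md$role != "specimen"),
            ncol(dataset$table$counts)))
cat(sprintf("Injected %d dysbiosis events (%s).\n", nrow(ev),
            paste(sprintf("%s: %d", names(table(ev$family)),
                          table(ev$family)), collapse = ", ")))
cat(sprintf("Depth: mean %.0f, median %.0f reads per specimen.\n",
            mean(dataset$truth$depths), median(dataset$truth$depths)))
cat("Tables written under", out, "\n")
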