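#!/usr/bin/env Rscript
# Close the loop against the generator's ground truth: how many injected
# dysbiosis events were recovered by the caller after QC, and how the main
# summary statistics compare with the study-scale values the generator was
# configured to emulate. Writes results/report.json.

suppressPackageStartupMessages(library(quartermilk))

truth <- jsonlite::read_json("results/data/truth.json",
                             simplifyVector = TRUE)
calls <- read.delim("results/dysbiosis/dysbiosis_calls.tsv")
summ <- jsonlite::read_json("results/dysbiosis/summary.json",
                            simplifyVector = TRUE)
qc <- jsonlite::read_json("results/qc/filter_report.json",
                          simplifyVector = TRUE)
md <- read_metadata("results/data/metadata.tsv")
filtered <- read_sv_table("results/qc/filtered_sv_table.tsv", "tsv",
                          lengths = "results/qc/filtered_sv_lengths.tsv")

ev <- truth$dysbiosis_events
surviving <- rownames(filtered$counts)
mds <- md[md$role == "specimen" & md$sample_id %in% surviving, ]
cp_sizes <- table(paste(mds$cow_id, mds$period))
recoverable <- ev$sample_id %in% surviving &
  cp_sizes[paste(ev$cow_id, ev$period)] >= 3
call_key <- paste(calls$cow_id, calls$period, calls$quarter, calls$family)
ev_key <- paste(ev$cow_id, ev$period, ev$quarter, ev$family)
recovered <- ev_key[recoverable] %in% call_key

cat(sprintf("Injected events: %d; recoverable after QC: %d; recovered: %d (%.0f%%).\n",
            nrow(ev), sum(recoverable), sum(recovered),
            100 * mean(recovered)))
extra <- sum(!call_key %in% ev_key)
cat(sprintf("Calls not matching an injected event: %d (naturally arising dominance).\n",
            extra))
cat(sprintf("QC: %d -> %d SVs, %d -> %d samples, %.1f%% of reads removed.\n",
            qc$n_sv_in, qc$n_sv_out, qc$n_samples_in, qc$n_samples_out,
            qc$reads_removed_pct))
cat(sprintf("Dysbiotic quarters %d/%d evaluable; %.0f%% quarters culture-infected; concordance %.0f%%.\n",
            summ$dysbiosis$n_dysbiotic, summ$dysbiosis$n_evaluated,
            100 * summ$imi$n_infected / summ$imi$n_known,
            100 * summ$concordance_rate))

jsonlite::write_json(
  list(n_injected = nrow(ev),
       n_recoverable = sum(recoverable),
       n_recovered = sum(recovered),
       recall_on_recoverable = mean(recovered),
       n_extra_calls = extra,
       qc = qc,
       dysbiosis = summ$dysbiosis,
       imi = summ$imi,
       concordance_rate = summ$concordance_rate),
  "results/report.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("Report written to results/report.json\n")
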