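#!/usr/bin/env Rscript
# Core-microbiota profiles and the dysbiotic-quarter analysis: family-level
# prevalence (Table-1-style), the one-vs-rest dominance caller (> 60% of
# reads in one quarter, < 20% in the cow's other quarters), infection
# classification from colony counts, association between infection and
# community composition, and culture-sequencing concordance.

suppressPackageStartupMessages(library(quartermilk))

ind <- "results/data"
qcd <- "results/qc"
out <- "results/dysbiosis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20234

tab <- read_sv_table(file.path(qcd, "filtered_sv_table.tsv"), "tsv",
                     lengths = file.path(qcd, "filtered_sv_lengths.tsv"))
tax <- read_taxonomy(file.path(ind, "taxonomy.tsv"))
md <- read_metadata(file.path(ind, "metadata.tsv"))
colony <- read_colony(file.path(ind, "colony.tsv"))
isolates <- read_isolates(file.path(ind, "isolates.tsv"))

profiles <- family_profiles(tab, tax, md, min_pct = 0.5)
write.table(profiles, file.path(out, "family_profiles.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
core <- profiles[profiles$pct_cows_any == 100 &
                   profiles$family != "other", "family"]
cat(sprintf("%d families above 0.5%% of reads; detected in all cows: %s.\n",
            sum(profiles$family != "other"), paste(core, collapse = ", ")))

fam <- aggregate_to_family(tab, tax)
relab <- relative_abundance(fam)
dysb <- call_dysbiosis(relab, md)
write.table(dysb$calls, file.path(out, "dysbiosis_calls.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
ds <- dysbiosis_summary(dysb)
cat(sprintf("Dysbiotic quarters: %d out of %d evaluable cow-periods (%s).\n",
            ds$n_dysbiotic, ds$n_evaluated,
            paste(sprintf("%s: %d", names(ds$per_family), ds$per_family),
                  collapse = ", ")))

imi <- classify_imi(colony, sample_ids = rownames(tab$counts))
write.table(imi, file.path(out, "imi_status.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
known <- imi$status[imi$status != "unknown"]
cat(sprintf("Culture-infected quarters: %d of %d (%.0f%%).\n",
            sum(known == "infected"), length(known),
            100 * mean(known == "infected")))

css <- css_normalize(tab)
d_bray <- distance_matrix(css$normalized, "bray")
assoc <- imi_microbiota_association(d_bray, imi, n_perm = 999, seed = seed)
cat(sprintf("PERMANOVA infected vs not infected: F = %.2f, p = %.3g.\n",
            assoc$pseudo_f, assoc$p_value))

conc <- concordance(dysb$calls, isolates, md)
write.table(conc$records, file.path(out, "concordance.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("Concordance between called family and cultured isolates: %.0f%% of %d calls.\n",
            100 * conc$rate, nrow(conc$records)))
if (length(conc$unmapped_genera) > 0)
  cat("Isolate genera without a family mapping:",
      paste(conc$unmapped_genera, collapse = ", "), "\n")

jsonlite::write_json(
  list(n_families_reported = sum(profiles$family != "other"),
       core_families = core,
       dysbiosis = list(n_evaluated = ds$n_evaluated,
                        n_dysbiotic = ds$n_dysbiotic,
                        per_family = as.list(ds$per_family)),
       imi = list(n_infected = sum(known == "infected"),
                  n_known = length(known),
                  association_p = assoc$p_value),
       concordance_rate = conc$rate),
  file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
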