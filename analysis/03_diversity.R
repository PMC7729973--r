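#!/usr/bin/env Rscript
# Diversity structure of the filtered table: Chao1/Shannon alpha diversity
# with rank-sum comparisons between farms and periods; CSS normalization;
# Bray-Curtis and Jaccard dissimilarities; PCoA ordinations compared by
# Procrustes/PROTEST; PERMANOVA and multivariate dispersion by farm and
# period; Pearson correlations among the most abundant families.

suppressPackageStartupMessages(library(quartermilk))

ind <- "results/data"
qcd <- "results/qc"
out <- "results/diversity"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20233

tab <- read_sv_table(file.path(qcd, "filtered_sv_table.tsv"), "tsv",
                     lengths = file.path(qcd, "filtered_sv_lengths.tsv"))
tax <- read_taxonomy(file.path(ind, "taxonomy.tsv"))
md <- read_metadata(file.path(ind, "metadata.tsv"))

alpha <- alpha_diversity(tab)
write.table(alpha, file.path(out, "alpha_diversity.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
farm <- setNames(md$farm, md$sample_id)[alpha$sample_id]
period <- setNames(md$period, md$sample_id)[alpha$sample_id]
wf <- compare_alpha(alpha$chao1[farm == "A"], alpha$chao1[farm == "K"])
wp <- compare_alpha(alpha$chao1[period == 1], alpha$chao1[period == 2])
cat(sprintf("Chao1: mean %.1f, median %.1f SVs per sample.\n",
            mean(alpha$chao1), median(alpha$chao1)))
cat(sprintf("Chao1 farm A vs K medians %.1f / %.1f, rank-sum p = %.3g.\n",
            median(alpha$chao1[farm == "A"]),
            median(alpha$chao1[farm == "K"]), wf$p_value))
cat(sprintf("Chao1 period 1 vs 2 rank-sum p = %.3g.\n", wp$p_value))

css <- css_normalize(tab)
d_bray <- distance_matrix(css$normalized, "bray")
d_jac <- distance_matrix(tab$counts, "jaccard")
for (nm in c("bray", "jaccard")) {
  d <- if (nm == "bray") d_bray else d_jac
  write.table(data.frame(sample_id = rownames(d), unclass(d),
                         check.names = FALSE),
              file.path(out, paste0("distance_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

ord_b <- pcoa(d_bray)
ord_j <- pcoa(d_jac)
write.table(data.frame(sample_id = rownames(ord_b$coordinates),
                       ord_b$coordinates[, 1:5]),
            file.path(out, "pcoa_bray.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
proc <- procrustes_protest(ord_b$coordinates[, 1:10],
                           ord_j$coordinates[, 1:10],
                           n_perm = 999, seed = seed)
cat(sprintf("Procrustes m2 between the two ordinations: %.3f (p = %.3g).\n",
            proc$m2, proc$p_value))

stats <- list(procrustes = list(m2 = proc$m2, p = proc$p_value))
for (grp in c("farm", "period")) {
  g <- if (grp == "farm") farm else period
  for (nm in c("bray", "jaccard")) {
    d <- if (nm == "bray") d_bray else d_jac
    pr <- permanova(d, g, n_perm = 999, seed = seed)
    stats[[paste("permanova", grp, nm, sep = "_")]] <-
      list(pseudo_f = pr$pseudo_f, p = pr$p_value)
    cat(sprintf("PERMANOVA %s (%s): F = %.2f, p = %.3g.\n", grp, nm,
                pr$pseudo_f, pr$p_value))
  }
  bd <- beta_dispersion(d_bray, g, n_perm = 999, seed = seed)
  stats[[paste("dispersion", grp, sep = "_")]] <-
    list(f = bd$f_value, p = bd$p_value)
  cat(sprintf("Dispersion homogeneity by %s: F = %.2f, p = %.3g.\n",
              grp, bd$f_value, bd$p_value))
}

fam <- aggregate_to_family(tab, tax)
relab <- relative_abundance(fam)
cors <- family_correlations(relab)
write.table(data.frame(family = rownames(cors), round(cors, 4),
                       check.names = FALSE),
            file.path(out, "family_correlations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("Strongest negative family correlation: %s vs %s, r = %.2f.\n",
            "Corynebacteriaceae", "Staphylococcaceae",
            cors["Corynebacteriaceae", "Staphylococcaceae"]))
jsonlite::write_json(stats, file.path(out, "stats.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
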