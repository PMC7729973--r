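#' Genus-to-family dictionary for isolate mapping
#'
#' Maps the genera seen among cultured milk isolates onto the 16S family
#' nomenclature used by the SV taxonomy, so dysbiosis calls (family level)
#' can be matched against MALDI species identifications (binomial level).
#' Isolate genera missing from the map are reported, not fatal.
#'
#' @return named character vector genus -> family.
#' @export
genus_family_map <- function() {
  c(Staphylococcus = "Staphylococcaceae",
    Streptococcus = "Streptococcaceae",
    Lactococcus = "Streptococcaceae",
    Enterococcus = "Enterococcaceae",
    Aerococcus = "Aerococcaceae",
    Corynebacterium = "Corynebacteriaceae",
    Micrococcus = "Micrococcaceae",
    Kocuria = "Micrococcaceae",
    Lactobacillus = "Lactobacillaceae",
    Leuconostoc = "Leuconostocaceae",
    Weissella = "Leuconostocaceae",
    Carnobacterium = "Carnobacteriaceae",
    Bacillus = "Bacillaceae",
    Acinetobacter = "Moraxellaceae",
    Moraxella = "Moraxellaceae",
    Psychrobacter = "Moraxellaceae",
    Pseudomonas = "Pseudomonadaceae",
    Escherichia = "Enterobacteriaceae",
    Citrobacter = "Enterobacteriaceae",
    Pantoea = "Erwiniaceae",
    Aeromonas = "Aeromonadaceae",
    Saccharopolyspora = "Pseudonocardiaceae",
    Prevotella = "Prevotellaceae",
    Bacteroides = "Bacteroidaceae")
}

#' Concordance between dysbiosis calls and cultured isolates
#'
#' A call is concordant when at least one isolate cultured from the same
#' (cow, period, quarter) milk sample belongs to the called family, via the
#' genus-to-family dictionary. Calls from quarters with no isolates are
#' non-concordant and flagged `no isolates`.
#'
#' @param calls call table from [call_dysbiosis] (`$calls`).
#' @param isolates validated [isolate_records].
#' @param metadata [sample_metadata] linking sample ids to cow/period/quarter.
#' @param family_map named genus -> family vector; default
#'   [genus_family_map()].
#' @return list with `records` (per-call data.frame: cow_id, period, quarter,
#'   family, isolate_species, isolate_families, concordant, note),
#'   `rate` (fraction of calls concordant) and `unmapped_genera`.
#' @export
concordance <- function(calls, isolates, metadata,
                        family_map = genus_family_map()) {
  md <- metadata[metadata$role == "specimen", , drop = FALSE]
  iso_gen <- genus_of(isolates$species)
  unmapped <- sort(unique(iso_gen[!iso_gen %in% names(family_map)]))
  iso_fam <- unname(family_map[iso_gen])
  iso_key <- stats::setNames(
    paste(md$cow_id, md$period, md$quarter, sep = "|"), md$sample_id
  )[isolates$sample_id]
  if (is.null(calls) || nrow(calls) == 0L) {
    return(list(records = data.frame(), rate = NA_real_,
                unmapped_genera = unmapped))
  }
  records <- do.call(rbind, lapply(seq_len(nrow(calls)), function(i) {
    key <- paste(calls$cow_id[i], calls$period[i], calls$quarter[i],
                 sep = "|")
    hit <- !is.na(iso_key) & iso_key == key
    spp <- isolates$species[hit]
    fams <- unique(iso_fam[hit][!is.na(iso_fam[hit])])
    conc <- calls$family[i] %in% fams
    data.frame(cow_id = calls$cow_id[i], period = calls$period[i],
               quarter = calls$quarter[i], family = calls$family[i],
               isolate_species = paste(spp, collapse = "/"),
               isolate_families = paste(fams, collapse = "/"),
               concordant = conc,
               note = if (length(spp) == 0L) "no isolates" else "",
               stringsAsFactors = FALSE)
  }))
  list(records = records, rate = mean(records$concordant),
       unmapped_genera = unmapped)
}
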