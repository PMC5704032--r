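#' Bundled worked-example tables
#'
#' The package ships small plain-text tables transcribed from a published
#' whole-genome study of two monozygotic twin pairs discordant for
#' schizophrenia: the per-twin small-variant, CNV and SV sharing counts,
#' the CNVs unique to each affected twin, the two affected twins' top-20
#' enriched pathway lists with cross-individual membership flags, and the
#' per-patient affected-gene lists of the two final disease pathways.
#' They drive worked-example tests and the acceptance checks.
#'
#' @param name one of `"affected_top20_pathways"`, `"gpd_pathway_genes"`,
#'   `"family1_unique_cnvs"`, `"family2_unique_cnvs"`,
#'   `"twin_small_variant_counts"`, `"twin_cnv_counts"`,
#'   `"twin_sv_counts"`.
#' @return the table as a data.frame.
#' @export
study_table <- function(name) {
  path <- system.file("extdata", paste0(name, ".tsv"), package = "twinquad",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
}

#' Pathway profiles from the published top-20 lists
#'
#' Builds the four individuals' pathway profiles from the bundled top-20
#' table: the two affected twins' profiles are the printed ranked lists;
#' each unaffected twin's profile is reconstructed from the printed
#' membership flags (`1U` / `2U`) across both lists.
#'
#' @return list with elements `affected` and `unaffected`, each a list of
#'   two [pathway_profile()]s (family "1" and "2").
#' @export
study_pathway_profiles <- function() {
  tb <- study_table("affected_top20_pathways")
  tb <- tb[order(tb$family, tb$rank), , drop = FALSE]
  flags <- strsplit(ifelse(is.na(tb$shared_with), "", tb$shared_with), ",")
  has_flag <- function(f) vapply(flags, function(x) f %in% x, logical(1))
  affected <- lapply(c(1, 2), function(fam)
    pathway_profile(paste0("patient", fam), "affected", as.character(fam),
                    tb$pathway[tb$family == fam]))
  unaffected <- lapply(c(1, 2), function(fam)
    pathway_profile(paste0("cotwin", fam), "unaffected", as.character(fam),
                    unique(tb$pathway[has_flag(paste0(fam, "U"))])))
  list(affected = affected, unaffected = unaffected)
}

#' Affected-twin unique CNVs as package call tables
#'
#' Returns the published CNVs unique to the affected twin of a family in
#' the package CNV format (0-based half-open intervals, so `end - start`
#' equals the printed size).  For family 1 the printed identity column is
#' kept, allowing the parental sets of the worked inheritance example to be
#' reconstructed from the rows marked inherited.
#'
#' @param family 1 or 2.
#' @return CNV data.frame with `sample_id`, `chrom`, `start`, `end`,
#'   `cnv_type` plus the printed `cytoband`, `size_bp` and (family 1)
#'   `identity` columns.
#' @export
study_cnv_fixture <- function(family = 1) {
  name <- if (family == 1) "family1_unique_cnvs" else "family2_unique_cnvs"
  tb <- study_table(name)
  tb$sample_id <- "twin_affected"
  tb[c("sample_id", setdiff(names(tb), "sample_id"))]
}
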