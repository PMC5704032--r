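#' Pipeline configuration
#'
#' Houses every analysis threshold: the high-confidence filter (depth 50,
#' quality 100), the 50% reciprocal-overlap rule, the 500-bp junction
#' bound, the top-20 pathway comparison, and the annotation windows.
#'
#' @param min_depth,min_quality high-confidence small-variant filter.
#' @param overlap_threshold CNV/SV reciprocal-overlap threshold.
#' @param junction_dist strict junction-distance bound (bp).
#' @param top_k pathway list length for the threshold-model comparison.
#' @param promoter_bp,splice_bp annotation windows.
#' @return list of class `twinquad_pipeline_config`.
#' @export
pipeline_config <- function(min_depth = 50, min_quality = 100,
                            overlap_threshold = 0.5, junction_dist = 500,
                            top_k = 20, promoter_bp = 2000, splice_bp = 2) {
  cfg <- as.list(environment())
  if (any(unlist(cfg) <= 0)) stop("all pipeline thresholds must be positive")
  structure(cfg, class = "twinquad_pipeline_config")
}

## gene list of one twin's unique (de novo / provisional) variants across
## all variant classes, deduplicated
unique_variant_genes <- function(small_calls, cnv_lab, sv_lab, models,
                                 promoter_bp = 2000, splice_bp = 2) {
  uniq <- small_calls[small_calls$origin %in%
                        c("de_novo", "provisional_de_novo"), , drop = FALSE]
  g_small <- if (nrow(uniq)) {
    hits <- assign_region(uniq, models, promoter_bp, splice_bp)
    unique(hits$gene_id)
  } else character(0)
  pick_iv <- function(lab, start_col, end_col, chrom_col) {
    u <- lab[lab$origin %in% c("de_novo", "provisional_de_novo") &
               !is.na(lab[[end_col]]), , drop = FALSE]
    if (!nrow(u)) return(character(0))
    iv <- data.frame(chrom = u[[chrom_col]], start = u[[start_col]],
                     end = u[[end_col]], stringsAsFactors = FALSE)
    unique(genes_hit_by_intervals(iv, models)$gene_id)
  }
  g_cnv <- if (!is.null(cnv_lab)) pick_iv(cnv_lab, "start", "end", "chrom")
  else character(0)
  g_sv <- if (!is.null(sv_lab)) pick_iv(sv_lab, "startA", "endA", "chromA")
  else character(0)
  sort(unique(c(g_small, g_cnv, g_sv)))
}

#' Run the full discordance analysis for one family
#'
#' Filters and classifies both twins' small variants against the co-twin and
#' parents, classifies CNV and SV events under the category matching rules,
#' collects each twin's unique-variant gene list, runs over-representation
#' against the pathway collection and builds each twin's top-k pathway
#' profile and the within-family GP/GPD split.
#'
#' @param sim a `twinquad_sim`, or any list with the same `small`, `cnv`,
#'   `sv`, `reference` and `parents_present` elements (call sets read from
#'   files fit after [small_variants()]).
#' @param family family identifier used in profiles.
#' @param config a [pipeline_config()].
#' @return object of class `twinquad_family`.
#' @export
analyze_family <- function(sim, family = "family1",
                           config = pipeline_config()) {
  small <- sim$small
  pp <- isTRUE(sim$parents_present)
  father <- if (pp) small$father
  mother <- if (pp) small$mother
  twins <- c("twin_affected", "twin_unaffected")
  classified <- lapply(twins, function(role) {
    co <- setdiff(twins, role)
    classify_small_variants(small[[role]], small[[co]], father, mother,
                            config$min_depth, config$min_quality)
  })
  names(classified) <- twins

  split_ev <- function(df) split(df, df$sample_id)
  cnv_by <- split_ev(sim$cnv); sv_by <- split_ev(sim$sv)
  pick <- function(lst, role, template) {
    d <- lst[[role]]
    if (is.null(d)) template[0, , drop = FALSE] else d
  }
  ev_lab <- lapply(twins, function(role) {
    co <- setdiff(twins, role)
    list(cnv = classify_event_inheritance(
      pick(cnv_by, role, sim$cnv), pick(cnv_by, co, sim$cnv),
      father = if (pp) pick(cnv_by, "father", sim$cnv),
      mother = if (pp) pick(cnv_by, "mother", sim$cnv),
      kind = "cnv", overlap_threshold = config$overlap_threshold,
      junction_dist = config$junction_dist),
      sv = classify_event_inheritance(
        pick(sv_by, role, sim$sv), pick(sv_by, co, sim$sv),
        father = if (pp) pick(sv_by, "father", sim$sv),
        mother = if (pp) pick(sv_by, "mother", sim$sv),
        kind = "sv", overlap_threshold = config$overlap_threshold,
        junction_dist = config$junction_dist))
  })
  names(ev_lab) <- twins

  models <- sim$reference$genes
  gene_lists <- lapply(twins, function(role)
    unique_variant_genes(classified[[role]]$calls, ev_lab[[role]]$cnv,
                         ev_lab[[role]]$sv, models,
                         config$promoter_bp, config$splice_bp))
  names(gene_lists) <- twins

  collection <- sim$reference$gene_sets
  enr <- lapply(gene_lists, function(g)
    suppressWarnings(enrich(g, collection)))
  profiles <- lapply(twins, function(role)
    pathway_profile(paste(family, role, sep = "."),
                    role = sub("twin_", "", role), family = family,
                    pathways = top_pathways(enr[[role]], config$top_k)))
  names(profiles) <- twins

  structure(list(
    family = family, config = config, parents_present = pp,
    classified = classified,
    event_labels = ev_lab,
    small_summary = do.call(rbind, lapply(twins, function(r)
      data.frame(role = r, t(classified[[r]]$summary),
                 stringsAsFactors = FALSE))),
    cnv_summary = event_sharing_summary(sim$cnv, "cnv", pp,
                                        config$overlap_threshold,
                                        config$junction_dist),
    sv_summary = event_sharing_summary(sim$sv, "sv", pp,
                                       config$overlap_threshold,
                                       config$junction_dist),
    gene_lists = gene_lists,
    enrichment = enr,
    profiles = profiles,
    gp_gpd = label_gp_gpd(profiles$twin_affected, profiles$twin_unaffected)),
    class = "twinquad_family")
}

#' @export
print.twinquad_family <- function(x, ...) {
  cat("twinquad_family", x$family,
      if (x$parents_present) "(quad mode)" else "(twin-only mode)", "\n")
  cat("small-variant sharing:\n")
  print(x$small_summary, row.names = FALSE)
  cat("GP:", length(x$gp_gpd$gp), " GPD:", length(x$gp_gpd$gpd), "\n")
  invisible(x)
}

#' @export
summary.twinquad_family <- function(object, ...) {
  cat("Family", object$family, "\n\nSmall sequence changes:\n")
  print(object$small_summary, row.names = FALSE)
  cat("\nCNVs:\n"); print(object$cnv_summary, row.names = FALSE)
  cat("\nSVs:\n"); print(object$sv_summary, row.names = FALSE)
  cat("\nAffected-twin unique-variant genes:",
      length(object$gene_lists$twin_affected), "\n")
  cat("Within-family GP:", length(object$gp_gpd$gp),
      "GPD:", length(object$gp_gpd$gpd), "\n")
  invisible(object)
}

#' Compare affected-specific pathways across families
#'
#' Applies [cross_family()] to the per-family pipeline results: the
#' affected twins' profiles are intersected and every pathway present in
#' any unaffected twin's profile is removed.
#'
#' @param families list of `twinquad_family` results (two or more).
#' @return a `threshold_comparison`.
#' @export
compare_families <- function(families) {
  cross_family(
    affected = lapply(families, function(f) f$profiles$twin_affected),
    unaffected = lapply(families, function(f) f$profiles$twin_unaffected))
}

#' Simulate-and-analyze convenience wrapper
#'
#' Generates a reference and quad for the config, optionally withholds the
#' parents and applies mosaic dropout, and runs the family analysis.
#' Deterministic for a given config seed.
#'
#' @param config a `twinquad_config`.
#' @param family family identifier.
#' @param pipeline a [pipeline_config()].
#' @param twin_only withhold the parental call sets.
#' @param mosaic_dropout apply [apply_mosaic_dropout()] before analysis.
#' @return list with elements `sim` and `result`.
#' @export
run_quad_pipeline <- function(config = sim_config(), family = "family1",
                              pipeline = pipeline_config(),
                              twin_only = FALSE, mosaic_dropout = FALSE) {
  ref <- simulate_reference(config)
  sim <- simulate_quad(config, ref)
  if (mosaic_dropout) sim <- apply_mosaic_dropout(sim)
  if (twin_only) sim <- drop_parents(sim)
  list(sim = sim, result = analyze_family(sim, family, pipeline))
}
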