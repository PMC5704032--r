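#' Per-individual ranked pathway profile
#'
#' Holds an individual's ordered top-k enriched pathway names with their
#' pedigree role; names are canonicalized on construction so profile set
#' operations are robust to case and spacing variants.
#'
#' @param id individual identifier.
#' @param role `"affected"` or `"unaffected"`.
#' @param family family identifier.
#' @param pathways ordered character vector of pathway names.
#' @return object of class `pathway_profile`.
#' @export
pathway_profile <- function(id, role = c("affected", "unaffected"),
                            family, pathways) {
  role <- match.arg(role)
  structure(list(id = id, role = role, family = family,
                 pathways = canonical_pathway_name(pathways)),
            class = "pathway_profile")
}

#' @export
print.pathway_profile <- function(x, ...) {
  cat(sprintf("pathway_profile %s (family %s, %s): %d pathways\n",
              x$id, x$family, x$role, length(x$pathways)))
  invisible(x)
}

#' Split one family's pathways into GP and GPD
#'
#' Under the liability-threshold reading of twin discordance, pathways
#' found in both co-twins' top lists represent shared genetic
#' predisposition (GP) — necessary but not sufficient for disease — while
#' pathways unique to the affected twin (GPD) carry the additional load
#' that crossed the disease threshold.
#'
#' @param affected,unaffected `pathway_profile`s of one twin pair (or plain
#'   character vectors of pathway names).
#' @return list with character-vector elements `gp` (intersection) and
#'   `gpd` (affected-only); the two are disjoint by construction.
#' @export
label_gp_gpd <- function(affected, unaffected) {
  a <- profile_names(affected); u <- profile_names(unaffected)
  list(gp = intersect(a, u), gpd = setdiff(a, u))
}

profile_names <- function(x) {
  if (inherits(x, "pathway_profile")) x$pathways
  else canonical_pathway_name(as.character(x))
}

#' Cross-family threshold-model comparison
#'
#' Intersects the affected twins' top-pathway lists across families and
#' removes every pathway that appears in any unaffected co-twin's list.
#' What remains (`final_gpd`) is the set of pathways unique to the affected
#' individuals of all families — the candidate disease pathways of the
#' threshold model.  With more than two families the intersection runs over
#' all affected profiles and the subtraction over the union of all
#' unaffected profiles.
#'
#' @param affected list of two or more affected `pathway_profile`s (or name
#'   vectors).
#' @param unaffected list of zero or more unaffected profiles; with none,
#'   `final_gpd` equals the shared affected set.
#' @return object of class `threshold_comparison`: list with
#'   `shared_affected`, `removed_by_unaffected`, `final_gpd`, and `per_family`
#'   GP/GPD splits when matching unaffected profiles are available.
#' @export
cross_family <- function(affected, unaffected = list()) {
  if (length(affected) < 2L)
    stop("cross_family requires at least two affected profiles")
  a_names <- lapply(affected, profile_names)
  u_names <- lapply(unaffected, profile_names)
  shared <- Reduce(intersect, a_names)
  u_all <- unique(unlist(u_names))
  final <- setdiff(shared, u_all)
  per_family <- NULL
  fams_a <- vapply(affected, function(p)
    if (inherits(p, "pathway_profile")) as.character(p$family) else NA_character_,
    character(1))
  fams_u <- vapply(unaffected, function(p)
    if (inherits(p, "pathway_profile")) as.character(p$family) else NA_character_,
    character(1))
  if (!anyNA(fams_a) && length(unaffected) && !anyNA(fams_u)) {
    per_family <- lapply(seq_along(affected), function(i) {
      j <- match(fams_a[i], fams_u)
      if (is.na(j)) return(NULL)
      label_gp_gpd(affected[[i]], unaffected[[j]])
    })
    names(per_family) <- fams_a
  }
  structure(list(shared_affected = shared,
                 removed_by_unaffected = intersect(shared, u_all),
                 final_gpd = final,
                 per_family = per_family),
            class = "threshold_comparison")
}

#' @export
print.threshold_comparison <- function(x, ...) {
  cat("threshold_comparison\n")
  cat("  shared across affected:   ", length(x$shared_affected), "\n")
  cat("  removed (in unaffected):  ", length(x$removed_by_unaffected), "\n")
  cat("  final GPD:                ", length(x$final_gpd), "\n")
  for (p in x$final_gpd) cat("    -", p, "\n")
  invisible(x)
}

#' Per-pathway affected-gene overlap across patients
#'
#' For each final GPD pathway, reports each patient's affected genes that
#' are members of the pathway and the genes common to all patients.
#'
#' @param final_gpd character vector of pathway names (canonical).
#' @param gene_lists named list: per patient, the character vector of that
#'   patient's affected genes.
#' @param collection named gene-set list containing every pathway in
#'   `final_gpd`.
#' @return named list (per pathway) of lists with per-patient member-gene
#'   vectors and `common`, their intersection.
#' @export
gene_overlap_report <- function(final_gpd, gene_lists, collection) {
  keys <- canonical_pathway_name(names(collection))
  out <- lapply(final_gpd, function(pw) {
    j <- match(canonical_pathway_name(pw), keys)
    if (is.na(j)) stop("pathway absent from collection: ", pw)
    members <- collection[[j]]
    per <- lapply(gene_lists, function(g) sort(intersect(g, members)))
    c(per, list(common = sort(Reduce(intersect, per))))
  })
  names(out) <- final_gpd
  out
}
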