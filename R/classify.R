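#' Partition a twin's calls into shared and unshared with the co-twin
#'
#' A call is shared exactly when its canonical key occurs in the co-twin's
#' call set; the two returned frames partition the subject's calls.
#' Duplicate keys within one sample are deduplicated with a warning.
#'
#' @param subject,cotwin small-variant data.frames (keyed; see
#'   [small_variants()]).
#' @return list with elements `shared` and `unshared`, each a small-variant
#'   data.frame with a `sharing` column added.
#' @export
partition_by_cotwin <- function(subject, cotwin) {
  if (anyDuplicated(subject$key)) {
    warning("duplicate variant keys within sample; deduplicating")
    subject <- subject[!duplicated(subject$key), , drop = FALSE]
  }
  is_shared <- subject$key %in% cotwin$key
  subject$sharing <- ifelse(is_shared, "shared", "unshared")
  list(shared = subject[is_shared, , drop = FALSE],
       unshared = subject[!is_shared, , drop = FALSE])
}

#' Label unshared calls as inherited or de novo by parental presence
#'
#' A twin-unshared variant present in at least one parent is inherited; a
#' variant absent from both parents is a post-zygotic de novo candidate.
#'
#' @param unshared unshared calls of one twin.
#' @param father,mother parental call sets (by default the unfiltered sets,
#'   so a true parental variant that merely failed the depth filter does not
#'   create a false de novo).
#' @return `unshared` with an `origin` column (`"inherited"`/`"de_novo"`).
#' @export
classify_inheritance <- function(unshared, father, mother) {
  if (is.null(father) || is.null(mother))
    stop("classify_inheritance requires both parental call sets ",
         "(use classify_provisional in twin-only mode)")
  parent_keys <- c(father$key, mother$key)
  unshared$origin <- ifelse(unshared$key %in% parent_keys,
                            "inherited", "de_novo")
  unshared
}

#' Label unshared calls in twin-only mode
#'
#' Without parental genomes the inherited/de novo split cannot be made;
#' every twin-unshared variant is labeled a provisional de novo.
#'
#' @param unshared unshared calls of one twin.
#' @return `unshared` with `origin = "provisional_de_novo"` throughout.
#' @export
classify_provisional <- function(unshared) {
  unshared$origin <- rep("provisional_de_novo", nrow(unshared))
  unshared
}

#' Classify one twin's small variants within the quad
#'
#' Applies the high-confidence filter to the subject twin, partitions the
#' surviving calls against the co-twin and labels the unshared calls by
#' parental presence (or as provisional de novo when parents are absent).
#' Presence in the co-twin and parents is checked against their unfiltered
#' call sets by default.
#'
#' @param subject,cotwin,father,mother small-variant data.frames; parents
#'   may be `NULL` (twin-only mode).
#' @param min_depth,min_quality high-confidence thresholds for the subject.
#' @param filter_others logical; also filter co-twin/parents before the
#'   presence checks (default `FALSE`).
#' @return list with `calls` (classified subject calls: columns `sharing`
#'   and `origin`, shared calls carry origin `"not_applicable"`) and
#'   `summary` (named counts: `total`, `high_confidence`, `shared`,
#'   `unshared`, `inherited`, `de_novo`, `provisional_de_novo`).
#' @export
classify_small_variants <- function(subject, cotwin, father = NULL,
                                    mother = NULL, min_depth = 50,
                                    min_quality = 100,
                                    filter_others = FALSE) {
  total <- nrow(subject)
  filt <- filter_high_confidence(subject, min_depth, min_quality)
  if (filter_others) {
    cotwin <- filter_high_confidence(cotwin, min_depth, min_quality)
    if (!is.null(father))
      father <- filter_high_confidence(father, min_depth, min_quality)
    if (!is.null(mother))
      mother <- filter_high_confidence(mother, min_depth, min_quality)
  }
  parts <- partition_by_cotwin(filt, cotwin)
  parents_present <- !is.null(father) && !is.null(mother)
  unshared <- if (parents_present)
    classify_inheritance(parts$unshared, father, mother)
  else classify_provisional(parts$unshared)
  shared <- parts$shared
  shared$origin <- rep("not_applicable", nrow(shared))
  calls <- rbind(shared, unshared)
  rownames(calls) <- NULL
  summary <- c(total = total,
               high_confidence = nrow(filt),
               shared = nrow(parts$shared),
               unshared = nrow(parts$unshared),
               inherited = sum(unshared$origin == "inherited"),
               de_novo = sum(unshared$origin == "de_novo"),
               provisional_de_novo =
                 sum(unshared$origin == "provisional_de_novo"))
  list(calls = calls, summary = summary)
}

#' Twin-pair sharing summary matrix
#'
#' Runs [classify_small_variants()] for both twins of a family and collects
#' the per-twin count rows (total calls, high-confidence, shared/unshared
#' with the co-twin, inherited vs de novo), the shape in which twin studies
#' tabulate discordance.
#'
#' @param small named list of call frames with roles `twin_affected`,
#'   `twin_unaffected` and optionally `father`, `mother`.
#' @inheritParams classify_small_variants
#' @return data.frame with one row per twin.
#' @export
sharing_summary <- function(small, min_depth = 50, min_quality = 100,
                            filter_others = FALSE) {
  father <- small$father; mother <- small$mother
  rows <- lapply(c("twin_affected", "twin_unaffected"), function(role) {
    co <- setdiff(c("twin_affected", "twin_unaffected"), role)
    cl <- classify_small_variants(small[[role]], small[[co]], father, mother,
                                  min_depth, min_quality, filter_others)
    data.frame(role = role, t(cl$summary), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
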