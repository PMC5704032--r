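#' Reciprocal overlap of two genomic intervals
#'
#' Computes the overlap fraction of each interval (overlap length divided by
#' that interval's own length, 0-based half-open coordinates).  Two events
#' are the same under the 50% reciprocal-overlap rule only when *both*
#' fractions reach the threshold; intervals on different chromosomes never
#' match.
#'
#' @param a,b lists or one-row data.frames with `chrom`, `start`, `end`.
#' @param threshold matching threshold (default 0.5, inclusive).
#' @return list with `fraction_a`, `fraction_b` and logical `matched`.
#' @export
reciprocal_overlap <- function(a, b, threshold = 0.5) {
  la <- a$end - a$start; lb <- b$end - b$start
  if (la <= 0 || lb <= 0) stop("zero-length interval")
  if (!identical(as.character(a$chrom), as.character(b$chrom)))
    return(list(fraction_a = 0, fraction_b = 0, matched = FALSE))
  ov <- max(0L, min(a$end, b$end) - max(a$start, b$start))
  fa <- ov / la; fb <- ov / lb
  list(fraction_a = fa, fraction_b = fb,
       matched = min(fa, fb) >= threshold)
}

#' Match two inter-chromosomal events by junction proximity
#'
#' Two inter-chromosomal events are the same when their origin chromosomes
#' match, their destination chromosomes match, and both junction positions
#' are less than `max_dist` bp apart (strict, per the "less than 500 bp"
#' rule).
#'
#' @param a,b events with `chromA`, `startA` (junction A) and `chromB`,
#'   `posB` (junction B).
#' @param max_dist strict distance bound in bp.
#' @return logical.
#' @export
match_interchromosomal <- function(a, b, max_dist = 500) {
  identical(as.character(a$chromA), as.character(b$chromA)) &&
    identical(as.character(a$chromB), as.character(b$chromB)) &&
    abs(a$startA - b$startA) < max_dist &&
    abs(a$posB - b$posB) < max_dist
}

#' Match two inversions
#'
#' Inversions are the same when they share the same direction and their
#' inverted intervals show 50% or more reciprocal overlap (inclusive).
#'
#' @param a,b inversion events with `chromA`, `startA`, `endA`,
#'   `orientation`.
#' @param threshold inclusive overlap threshold.
#' @return logical.
#' @export
match_inversion <- function(a, b, threshold = 0.5) {
  if (!identical(as.character(a$orientation), as.character(b$orientation)))
    return(FALSE)
  reciprocal_overlap(list(chrom = a$chromA, start = a$startA, end = a$endA),
                     list(chrom = b$chromA, start = b$startA, end = b$endA),
                     threshold)$matched
}

## Pairwise matcher for two rows of a unified event frame.  CNV rows carry
## kind "cnv" (type must agree); SV rows carry kind "sv" and dispatch on
## category.  Cross-category (or cross-kind) pairs never match.
event_pair_matches <- function(a, b, overlap_threshold = 0.5,
                               junction_dist = 500) {
  if (!identical(a$kind, b$kind)) return(FALSE)
  if (identical(a$kind, "cnv")) {
    if (!identical(a$cnv_type, b$cnv_type)) return(FALSE)
    return(reciprocal_overlap(
      list(chrom = a$chromA, start = a$startA, end = a$endA),
      list(chrom = b$chromA, start = b$startA, end = b$endA),
      overlap_threshold)$matched)
  }
  if (!identical(a$category, b$category)) return(FALSE)
  switch(a$category,
         interchromosomal = match_interchromosomal(a, b, junction_dist),
         inversion = match_inversion(a, b, overlap_threshold),
         reciprocal_overlap(
           list(chrom = a$chromA, start = a$startA, end = a$endA),
           list(chrom = b$chromA, start = b$startA, end = b$endA),
           overlap_threshold)$matched)
}

## Normalize CNV / SV frames to the unified event frame used by the
## matchers.
as_event_frame <- function(df, kind = c("cnv", "sv")) {
  kind <- match.arg(kind)
  if (!nrow(df))
    return(data.frame(sample_id = character(0), kind = character(0),
                      category = character(0), cnv_type = character(0),
                      chromA = character(0), startA = integer(0),
                      endA = integer(0), chromB = character(0),
                      posB = integer(0), orientation = character(0),
                      stringsAsFactors = FALSE))
  if (kind == "cnv") {
    data.frame(sample_id = df$sample_id, kind = "cnv", category = "cnv",
               cnv_type = df$cnv_type, chromA = df$chrom, startA = df$start,
               endA = df$end, chromB = NA_character_, posB = NA_integer_,
               orientation = NA_character_, stringsAsFactors = FALSE)
  } else {
    data.frame(sample_id = df$sample_id, kind = "sv", category = df$category,
               cnv_type = NA_character_, chromA = df$chromA,
               startA = df$startA, endA = df$endA, chromB = df$chromB,
               posB = df$posB, orientation = df$orientation,
               stringsAsFactors = FALSE)
  }
}

## Candidate pruning: a pair can only match if it shares chromA and the A
## anchors lie within the largest span in play (or the junction bound).
candidate_idx <- function(a, others, junction_dist) {
  spans <- others$endA - others$startA
  win <- max(junction_dist, a$endA - a$startA, spans, na.rm = TRUE)
  which(others$chromA == a$chromA & abs(others$startA - a$startA) <= win)
}

## TRUE if event row `a` matches any row of event frame `others`
matches_any <- function(a, others, overlap_threshold = 0.5,
                        junction_dist = 500) {
  if (!nrow(others)) return(FALSE)
  for (j in candidate_idx(a, others, junction_dist)) {
    if (event_pair_matches(a, others[j, , drop = FALSE],
                           overlap_threshold, junction_dist)) return(TRUE)
  }
  FALSE
}

#' Merge events of one category into match groups
#'
#' All pairwise comparisons are made under the category-appropriate rule and
#' matched events are merged into groups taken as the connected components
#' of the match graph (the reciprocal-overlap relation is not transitive, so
#' a chain A~B~C lands in one group even when A and C do not match
#' directly).  An event matching nothing is a singleton group.
#'
#' @param events unified event frame (see [classify_event_inheritance()]
#'   inputs), or a CNV/SV frame together with `kind`.
#' @param kind `"cnv"` or `"sv"`; required when `events` is a raw CNV/SV
#'   table.
#' @param overlap_threshold,junction_dist matching parameters.
#' @return data.frame with one row per event: `group`, `sample_id` and the
#'   event columns; groups are numbered in order of first appearance.
#' @export
build_match_groups <- function(events, kind = NULL, overlap_threshold = 0.5,
                               junction_dist = 500) {
  ev <- if (!is.null(kind)) as_event_frame(events, kind) else events
  n <- nrow(ev)
  if (!n) return(cbind(group = integer(0), ev))
  edges <- list()
  for (i in seq_len(n - 1L)) {
    a <- ev[i, , drop = FALSE]
    rest <- ev[seq(i + 1L, n), , drop = FALSE]
    for (j in (i + candidate_idx(a, rest, junction_dist))) {
      if (event_pair_matches(a, ev[j, , drop = FALSE],
                             overlap_threshold, junction_dist))
        edges[[length(edges) + 1L]] <- c(i, j)
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, unlist(edges))
  comp <- igraph::components(g)$membership
  out <- cbind(group = match(comp, unique(comp)), ev)
  out[order(out$group), , drop = FALSE]
}

#' Classify CNV/SV events of one twin as shared/unshared and by inheritance
#'
#' Each event of the subject twin is shared when it matches any co-twin
#' event under the category rule (50% reciprocal overlap for interval
#' events, type-matched for CNVs, junction distance for inter-chromosomal
#' events, direction plus overlap for inversions).  Unshared events are
#' inherited when they match an event in at least one parent, de novo
#' otherwise; without parents every unshared event is a provisional de
#' novo.
#'
#' @param subject,cotwin,father,mother CNV or SV data.frames (parents may be
#'   `NULL` for twin-only mode).
#' @param kind `"cnv"` or `"sv"`.
#' @param overlap_threshold,junction_dist matching parameters.
#' @return the subject frame with `sharing` and `origin` columns.
#' @export
classify_event_inheritance <- function(subject, cotwin, father = NULL,
                                       mother = NULL,
                                       kind = c("cnv", "sv"),
                                       overlap_threshold = 0.5,
                                       junction_dist = 500) {
  kind <- match.arg(kind)
  ev <- as_event_frame(subject, kind)
  co <- as_event_frame(cotwin, kind)
  parents_present <- !is.null(father) && !is.null(mother)
  pa <- if (parents_present)
    rbind(as_event_frame(father, kind), as_event_frame(mother, kind))
  sharing <- character(nrow(ev)); origin <- character(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    a <- ev[i, , drop = FALSE]
    if (matches_any(a, co, overlap_threshold, junction_dist)) {
      sharing[i] <- "shared"; origin[i] <- "not_applicable"
    } else {
      sharing[i] <- "unshared"
      origin[i] <- if (!parents_present) "provisional_de_novo"
      else if (matches_any(a, pa, overlap_threshold, junction_dist))
        "inherited" else "de_novo"
    }
  }
  subject$sharing <- sharing
  subject$origin <- origin
  subject
}

#' Per-twin event sharing summary
#'
#' Tabulates total, shared, unshared, inherited and de novo event counts for
#' both twins, the shape in which twin studies report CNV/SV discordance.
#'
#' @param events CNV or SV data.frame over all samples (roles as
#'   `sample_id`).
#' @param kind `"cnv"` or `"sv"`.
#' @param parents_present logical.
#' @inheritParams classify_event_inheritance
#' @return data.frame with one row per twin.
#' @export
event_sharing_summary <- function(events, kind, parents_present = TRUE,
                                  overlap_threshold = 0.5,
                                  junction_dist = 500) {
  by_sample <- split(events, events$sample_id)
  pick <- function(role) {
    d <- by_sample[[role]]
    if (is.null(d)) events[0, , drop = FALSE] else d
  }
  rows <- lapply(c("twin_affected", "twin_unaffected"), function(role) {
    co <- setdiff(c("twin_affected", "twin_unaffected"), role)
    lab <- classify_event_inheritance(
      pick(role), pick(co),
      father = if (parents_present) pick("father"),
      mother = if (parents_present) pick("mother"),
      kind = kind, overlap_threshold = overlap_threshold,
      junction_dist = junction_dist)
    data.frame(role = role,
               total = nrow(lab),
               shared = sum(lab$sharing == "shared"),
               unshared = sum(lab$sharing == "unshared"),
               inherited = sum(lab$origin == "inherited"),
               de_novo = sum(lab$origin == "de_novo"),
               provisional_de_novo =
                 sum(lab$origin == "provisional_de_novo"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
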