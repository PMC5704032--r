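region_precedence <- c(splice_site = 5L, exonic = 4L, utr5 = 3L, utr3 = 3L,
                       promoter = 2L, intronic = 1L)

## Decompose one gene into labeled 1-based inclusive region intervals.
gene_regions <- function(gene, feats, promoter_bp = 2000, splice_bp = 2) {
  ex <- feats[feats$type == "exon", , drop = FALSE]
  ex <- ex[order(ex$start), , drop = FALSE]
  cds <- feats[feats$type == "CDS", , drop = FALSE]
  ir_ex <- IRanges::IRanges(ex$start, ex$end)
  ir_cds <- IRanges::reduce(IRanges::IRanges(cds$start, cds$end))
  utr <- IRanges::setdiff(ir_ex, ir_cds)
  introns <- IRanges::setdiff(
    IRanges::IRanges(min(ex$start), max(ex$end)), ir_ex)
  splice <- if (length(introns)) {
    IRanges::reduce(c(
      IRanges::IRanges(IRanges::start(introns),
                       pmin(IRanges::start(introns) + splice_bp - 1L,
                            IRanges::end(introns))),
      IRanges::IRanges(pmax(IRanges::end(introns) - splice_bp + 1L,
                            IRanges::start(introns)),
                       IRanges::end(introns))))
  } else IRanges::IRanges()
  plus <- gene$strand == "+"
  promoter <- if (plus)
    IRanges::IRanges(max(1L, gene$tx_start - promoter_bp),
                     gene$tx_start - 1L)
  else IRanges::IRanges(gene$tx_end + 1L, gene$tx_end + promoter_bp)
  ## UTR side: 5' UTR lies before the CDS in transcript orientation
  cds_lo <- if (length(ir_cds)) min(IRanges::start(ir_cds)) else NA_integer_
  utr_label <- function(s) {
    if (is.na(cds_lo)) return("utr5")
    before <- s < cds_lo
    if (plus) ifelse(before, "utr5", "utr3") else ifelse(before, "utr3", "utr5")
  }
  pieces <- list(
    data.frame(region = "intronic", start = IRanges::start(introns),
               end = IRanges::end(introns)),
    data.frame(region = "promoter", start = IRanges::start(promoter),
               end = IRanges::end(promoter)),
    if (length(utr)) data.frame(
      region = vapply(IRanges::start(utr), utr_label, character(1)),
      start = IRanges::start(utr), end = IRanges::end(utr)),
    data.frame(region = "exonic", start = IRanges::start(ir_cds),
               end = IRanges::end(ir_cds)),
    data.frame(region = "splice_site", start = IRanges::start(splice),
               end = IRanges::end(splice)))
  out <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  out <- out[out$end >= out$start, , drop = FALSE]
  out$gene_id <- gene$gene_id
  out$chrom <- gene$chrom
  out
}

build_region_index <- function(models, promoter_bp = 2000, splice_bp = 2) {
  regs <- do.call(rbind, lapply(seq_len(nrow(models$genes)), function(i) {
    gid <- models$genes$gene_id[i]
    gene_regions(models$genes[i, ], models$features[
      models$features$gene_id == gid, , drop = FALSE],
      promoter_bp, splice_bp)
  }))
  GenomicRanges::GRanges(
    seqnames = regs$chrom,
    ranges = IRanges::IRanges(regs$start, regs$end),
    gene_id = regs$gene_id, region = regs$region)
}

#' Assign gene region annotations to variants
#'
#' For every variant (the reference span `pos .. pos + nchar(ref) - 1`) and
#' every overlapping gene, reports the highest-precedence region hit:
#' splice site (2 bp intronic flanks by default) over coding exon over
#' 5'/3' UTR over promoter (2 kb upstream of the transcript start by
#' default) over intron.  Variants touching no gene territory get no row
#' (intergenic).
#'
#' @param variants small-variant data.frame, or any frame with `chrom`,
#'   `pos` and optionally `ref` (CNV/SV intervals can be annotated through
#'   [genes_hit_by_intervals()]).
#' @param models a `gene_models` object.
#' @param promoter_bp,splice_bp window sizes in bp.
#' @return data.frame with `variant` (row index into `variants`), `key` (if
#'   present), `gene_id`, `region`.
#' @export
assign_region <- function(variants, models, promoter_bp = 2000,
                          splice_bp = 2) {
  if (!nrow(variants))
    return(data.frame(variant = integer(0), gene_id = character(0),
                      region = character(0), stringsAsFactors = FALSE))
  idx <- build_region_index(models, promoter_bp, splice_bp)
  width <- if (!is.null(variants$ref)) nchar(variants$ref) else 1L
  q <- GenomicRanges::GRanges(
    seqnames = variants$chrom,
    ranges = IRanges::IRanges(variants$pos, variants$pos + width - 1L))
  hits <- GenomicRanges::findOverlaps(q, idx, ignore.strand = TRUE)
  if (!length(hits))
    return(data.frame(variant = integer(0), gene_id = character(0),
                      region = character(0), stringsAsFactors = FALSE))
  d <- data.frame(
    variant = S4Vectors::queryHits(hits),
    gene_id = idx$gene_id[S4Vectors::subjectHits(hits)],
    region = idx$region[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE)
  d$prec <- region_precedence[d$region]
  d <- d[order(d$variant, d$gene_id, -d$prec), , drop = FALSE]
  d <- d[!duplicated(d[c("variant", "gene_id")]), , drop = FALSE]
  d$prec <- NULL
  if (!is.null(variants$key)) d$key <- variants$key[d$variant]
  rownames(d) <- NULL
  d
}

#' Genes overlapped by larger-variant intervals
#'
#' Interval-stabbing of CNV/SV intervals (0-based half-open) against
#' transcript spans; an event spanning several genes yields one row per
#' gene.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param models a `gene_models` object.
#' @return data.frame with `interval` (row index) and `gene_id`.
#' @export
genes_hit_by_intervals <- function(intervals, models) {
  if (!nrow(intervals))
    return(data.frame(interval = integer(0), gene_id = character(0),
                      stringsAsFactors = FALSE))
  q <- GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(intervals$start + 1L, intervals$end))
  s <- GenomicRanges::GRanges(
    seqnames = models$genes$chrom,
    ranges = IRanges::IRanges(models$genes$tx_start, models$genes$tx_end))
  hits <- GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE)
  data.frame(interval = S4Vectors::queryHits(hits),
             gene_id = models$genes$gene_id[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

## CDS geometry of one gene: transcript-order genomic positions.
cds_positions <- function(models, gene_id) {
  g <- models$genes[models$genes$gene_id == gene_id, , drop = FALSE]
  cds <- models$features[models$features$gene_id == gene_id &
                           models$features$type == "CDS", , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  pos <- unlist(Map(seq.int, cds$start, cds$end), use.names = FALSE)
  if (g$strand == "-") pos <- rev(pos)
  list(pos = pos, strand = g$strand, chrom = g$chrom)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Translational impact of a coding variant
#'
#' SNVs are resolved by translating the affected codon before and after the
#' change (strand-aware, standard genetic code): an unchanged amino acid is
#' synonymous, a gained stop is a stop gain, anything else missense.  Length
#' -changing variants fully inside the CDS are frameshift when the net
#' length change is not a multiple of 3 and in-frame otherwise; equal-length
#' block substitutions are in-frame.  A variant whose reference span crosses
#' the CDS boundary is reported `"complex"` with a warning.
#'
#' @param variant one-row small-variant data.frame (normalized).
#' @param gene_id gene to assess.
#' @param models `gene_models`.
#' @param reference named character vector of chromosome sequences.
#' @return one of `"synonymous"`, `"missense"`, `"stop_gain"`,
#'   `"frameshift"`, `"in_frame"`, `"complex"`, `"none"`.
#' @export
translational_impact <- function(variant, gene_id, models, reference) {
  geom <- cds_positions(models, gene_id)
  span <- seq.int(variant$pos, variant$pos + nchar(variant$ref) - 1L)
  inside <- span %in% geom$pos
  if (!any(inside)) return("none")
  if (variant$vclass == "SNV") {
    seqs <- named_sequences(reference)
    cds_seq <- strsplit(substr_many(seqs[[geom$chrom]], geom$pos), "")[[1]]
    ## bases are in transcript order; complement them on the minus strand
    if (geom$strand == "-") cds_seq <- unname(COMPLEMENT[cds_seq])
    i <- match(variant$pos, geom$pos)
    alt_base <- variant$alt
    if (geom$strand == "-") alt_base <- COMPLEMENT[[alt_base]]
    codon_i <- (i - 1L) %/% 3L
    cidx <- codon_i * 3L + 1:3
    if (max(cidx) > length(cds_seq)) return("complex")
    before <- paste(cds_seq[cidx], collapse = "")
    after_seq <- cds_seq; after_seq[i] <- alt_base
    after <- paste(after_seq[cidx], collapse = "")
    aa1 <- Biostrings::GENETIC_CODE[[before]]
    aa2 <- Biostrings::GENETIC_CODE[[after]]
    if (aa1 == aa2) return("synonymous")
    if (aa2 == "*") return("stop_gain")
    return("missense")
  }
  ## length-changing / block variants: the changed bases must lie in the CDS
  changed <- if (variant$vclass %in% c("insertion", "deletion"))
    span[-1L] else span  # anchor base itself is unchanged for pure indels
  if (length(changed) && !all(changed %in% geom$pos)) {
    warning("variant spans a CDS boundary; impact reported as complex")
    return("complex")
  }
  net <- nchar(variant$alt) - nchar(variant$ref)
  if (net %% 3L != 0L) "frameshift" else "in_frame"
}

## Extract single bases at a vector of positions from one sequence string,
## in the order given.
substr_many <- function(s, pos) {
  paste(vapply(pos, function(p) substr(s, p, p), character(1)),
        collapse = "")
}

#' Flag variants as novel or polymorphic from population frequency tables
#'
#' A variant is polymorphic when it appears with frequency above zero in at
#' least one supplied table (e.g. large-cohort and public-genome frequency
#' columns); otherwise it is novel.
#'
#' @param keys canonical variant keys.
#' @param freq_tables list of data.frames with columns `key` and `freq`.
#' @return data.frame with `key`, `population_flag`, and one frequency
#'   column per table (NA when absent).
#' @export
flag_population <- function(keys, freq_tables = list()) {
  out <- data.frame(key = keys, stringsAsFactors = FALSE)
  flag <- rep(FALSE, length(keys))
  for (i in seq_along(freq_tables)) {
    tb <- freq_tables[[i]]
    f <- tb$freq[match(keys, tb$key)]
    nm <- names(freq_tables)[i]
    if (is.null(nm) || !nzchar(nm)) nm <- paste0("freq", i)
    out[[nm]] <- f
    flag <- flag | (!is.na(f) & f > 0)
  }
  out$population_flag <- ifelse(flag, "polymorphic", "novel")
  out
}

#' Annotate classified variants
#'
#' Adds, per variant: overlapping genes (collapsed `;`-separated),
#' highest-precedence region, translational impact for coding hits (first
#' overlapping gene with a CDS hit), and the population flag.
#' Classification labels (`sharing`, `origin`) pass through untouched.
#'
#' @param variants classified small-variant data.frame.
#' @param models `gene_models`.
#' @param reference chromosome sequences (needed for SNV impact; without it
#'   SNV impact is `NA`).
#' @param freq_tables list of frequency tables for [flag_population()].
#' @param promoter_bp,splice_bp region windows.
#' @return the data.frame with `genes`, `region`, `impact`,
#'   `population_flag` columns added.
#' @export
annotate_variants <- function(variants, models, reference = NULL,
                              freq_tables = list(), promoter_bp = 2000,
                              splice_bp = 2) {
  hits <- assign_region(variants, models, promoter_bp, splice_bp)
  variants$genes <- NA_character_
  variants$region <- "intergenic"
  variants$impact <- "none"
  if (nrow(hits)) {
    gg <- split(hits$gene_id, hits$variant)
    variants$genes[as.integer(names(gg))] <-
      vapply(gg, paste, character(1), collapse = ";")
    best <- hits[order(hits$variant,
                       -region_precedence[hits$region]), , drop = FALSE]
    best <- best[!duplicated(best$variant), , drop = FALSE]
    variants$region[best$variant] <- best$region
    cds_hits <- hits[hits$region == "exonic", , drop = FALSE]
    cds_hits <- cds_hits[!duplicated(cds_hits$variant), , drop = FALSE]
    for (r in seq_len(nrow(cds_hits))) {
      i <- cds_hits$variant[r]
      variants$impact[i] <- if (is.null(reference) &&
                                variants$vclass[i] == "SNV") NA_character_
      else translational_impact(variants[i, , drop = FALSE],
                                cds_hits$gene_id[r], models, reference)
    }
  }
  pop <- flag_population(variants$key, freq_tables)
  variants$population_flag <- pop$population_flag
  for (cn in setdiff(names(pop), c("key", "population_flag")))
    variants[[cn]] <- pop[[cn]]
  variants
}

#' Keep variants whose genes carry one of the requested phenotype tags
#'
#' A flat gene-to-tag lookup standing in for a knowledge-base "direct
#' connection" filter: a variant survives when any of its overlapping genes
#' carries any listed tag.  Intergenic variants never survive.  An empty tag
#' list disables the filter with a warning.
#'
#' @param annotated output of [annotate_variants()].
#' @param tags character vector of tags to keep.
#' @param gene_tags data.frame with columns `gene_id`, `tag`.
#' @return the filtered data.frame.
#' @export
phenotype_tag_filter <- function(annotated, tags, gene_tags) {
  if (!length(tags)) {
    warning("empty tag list; phenotype filter is the identity")
    return(annotated)
  }
  tagged <- unique(gene_tags$gene_id[gene_tags$tag %in% tags])
  keep <- vapply(annotated$genes, function(g) {
    if (is.na(g)) return(FALSE)
    any(strsplit(g, ";", fixed = TRUE)[[1]] %in% tagged)
  }, logical(1))
  out <- annotated[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
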