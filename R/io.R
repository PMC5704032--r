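#' Read small-variant calls from a VCF file
#'
#' Parses a VCF 4.2 file, splits multi-allelic records into one call per
#' alternate allele, takes the call quality from the `QUAL` column and the
#' read depth from the `DP` FORMAT field (falling back to an INFO `DP`), and
#' normalizes every record (left alignment requires `reference`).  Calls with
#' no recoverable depth are kept with `depth = NA`, which fails the
#' high-confidence filter downstream.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param sample_id sample name to stamp on the calls; defaults to the first
#'   genotype column of the file, or the file name if the VCF has none.
#' @param reference optional chromosome sequences for left alignment.
#' @return a canonical small-variant data.frame (see [small_variants()]).
#' @export
read_small_variants <- function(path, sample_id = NULL, reference = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (is.null(sample_id)) {
    sample_id <- if (ncol(v@gt) >= 2L) colnames(v@gt)[2L] else
      tools::file_path_sans_ext(basename(path))
  }
  dp <- rep(NA_integer_, nrow(fix))
  if (!is.null(v@gt) && ncol(v@gt) >= 2L) {
    dpm <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
    if (!is.null(dpm)) dp <- as.integer(dpm[, 1L])
  }
  if (all(is.na(dp)) && "INFO" %in% names(fix)) {
    m <- regmatches(fix$INFO, regexpr("(?:^|;)DP=([0-9]+)", fix$INFO))
    has <- lengths(regmatches(fix$INFO, gregexpr("(?:^|;)DP=[0-9]+", fix$INFO))) > 0
    dp[has] <- as.integer(sub(".*DP=", "", m))
  }
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  alt_split <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alt_split)
  idx <- rep(seq_len(nrow(fix)), n_alt)
  df <- data.frame(
    sample_id = sample_id,
    chrom = fix$CHROM[idx],
    pos = as.integer(fix$POS[idx]),
    ref = fix$REF[idx],
    alt = unlist(alt_split),
    depth = dp[idx],
    quality = qual[idx],
    stringsAsFactors = FALSE
  )
  normalize_variants(df, reference)
}

#' Write a small-variant call set as VCF 4.2
#'
#' Emits one genotype column named after the sample, with `GT` (presence is
#' coded `0/1`; the pipeline compares presence only) and `DP` FORMAT fields
#' and the call quality in `QUAL`.  Output is deterministic: no date or
#' program header lines are written.
#'
#' @param calls small-variant data.frame for one sample.
#' @param path output file path.
#' @param contigs optional named vector of contig lengths for the header.
#' @return `path`, invisibly.
#' @export
write_small_variants <- function(calls, path, contigs = NULL) {
  sample_id <- if (nrow(calls)) calls$sample_id[1L] else "sample"
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=twinquad",
    if (!is.null(contigs))
      sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t")
  )
  ord <- order(calls$chrom, calls$pos, calls$ref, calls$alt)
  calls <- calls[ord, , drop = FALSE]
  body <- if (nrow(calls)) {
    paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt,
          ifelse(is.na(calls$quality), ".", format(calls$quality, trim = TRUE,
                                                   scientific = FALSE)),
          "PASS", ".", "GT:DP",
          paste0("0/1:", ifelse(is.na(calls$depth), ".", calls$depth)),
          sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read and write CNV call tables
#'
#' CNV calls are tab-separated with columns `sample_id`, `chrom`, `start`,
#' `end`, `copy_state`, `cnv_type`.  Intervals are 0-based half-open, so the
#' event length is exactly `end - start`.  `cnv_type` is `"amp"` (copy state
#' above diploid 2) or `"del"` (below).
#'
#' @param path TSV file.
#' @return data.frame of CNV calls.
#' @export
read_cnv_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_cnv(df)
}

#' @rdname read_cnv_table
#' @param cnv CNV data.frame.
#' @export
write_cnv_table <- function(cnv, path) {
  utils::write.table(validate_cnv(cnv), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_cnv <- function(df) {
  needed <- c("sample_id", "chrom", "start", "end", "copy_state", "cnv_type")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("CNV table lacks columns: ", paste(miss, collapse = ", "))
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(df$end <= df$start)) stop("CNV intervals must satisfy end > start")
  if (any(df$copy_state < 0 | df$copy_state > 10))
    stop("copy_state must lie in 0..10")
  bad <- (df$copy_state > 2 & df$cnv_type != "amp") |
    (df$copy_state < 2 & df$cnv_type != "del")
  if (any(bad)) stop("cnv_type inconsistent with copy_state")
  df
}

#' Read and write SV event tables
#'
#' SV events are tab-separated with columns `sample_id`, `category`
#' (`deletion`, `tandem_duplication`, `distal_duplication`,
#' `interchromosomal`, `inversion`), `chromA`, `startA`, `endA`, `chromB`,
#' `posB`, `orientation`.  Interval-bearing categories use
#' `chromA:[startA,endA)` (0-based half-open); inter-chromosomal events carry
#' junction A at `(chromA, startA)` and junction B at `(chromB, posB)` with
#' `endA` empty; inversions additionally carry an `orientation` of
#' `"forward"` or `"reverse"`.
#'
#' @param path TSV file.
#' @return data.frame of SV events.
#' @export
read_sv_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  validate_sv(df)
}

#' @rdname read_sv_table
#' @param sv SV data.frame.
#' @export
write_sv_table <- function(sv, path) {
  utils::write.table(validate_sv(sv), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

sv_categories <- c("deletion", "tandem_duplication", "distal_duplication",
                   "interchromosomal", "inversion")

validate_sv <- function(df) {
  needed <- c("sample_id", "category", "chromA", "startA", "endA",
              "chromB", "posB", "orientation")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("SV table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(df$category %in% sv_categories))
    stop("unknown SV category: ",
         paste(setdiff(unique(df$category), sv_categories), collapse = ", "))
  inter <- df$category == "interchromosomal"
  if (any(inter & (is.na(df$chromB) | is.na(df$posB))))
    stop("interchromosomal events need both junctions")
  if (any(inter & df$chromA == df$chromB))
    stop("interchromosomal junctions must lie on different chromosomes")
  if (any(!inter & !is.na(df$endA) & df$endA <= df$startA))
    stop("SV intervals must satisfy end > start")
  df
}

#' Read and write gene-set collections (GMT)
#'
#' @param path GMT file (one set per line: name, description, member genes,
#'   tab-separated).
#' @return named list of character vectors of gene ids.
#' @export
read_gene_sets <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gene_sets
#' @param sets named list of character vectors.
#' @export
write_gene_sets <- function(sets, path) {
  if (any(!lengths(sets))) stop("gene sets must be non-empty")
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Gene-set universe
#'
#' The default enrichment background: the union of all member genes of a
#' collection.
#'
#' @param sets named list of gene sets.
#' @return character vector of unique gene ids.
#' @export
gene_set_universe <- function(sets) {
  sort(unique(unlist(sets, use.names = FALSE)))
}

#' Read a quad call-set directory
#'
#' Loads a directory in the layout written by [write_quad()]: per-role VCFs
#' (`father.vcf`, `mother.vcf`, `twin_affected.vcf`,
#' `twin_unaffected.vcf`), combined `cnv.tsv` and `sv.tsv`, the reference
#' FASTA, gene models GFF3 and gene sets GMT.  Parental VCFs may be absent
#' (twin-only mode); the twins' files are required.
#'
#' @param dir directory path.
#' @return a list with the same shape as a `twinquad_sim` (minus the truth
#'   tables), ready for [analyze_family()].
#' @export
read_quad <- function(dir) {
  reference <- as.character(read_reference(file.path(dir, "reference.fa")))
  roles <- c("father", "mother", "twin_affected", "twin_unaffected")
  paths <- file.path(dir, paste0(roles, ".vcf"))
  present <- file.exists(paths)
  if (!all(present[3:4]))
    stop("both twin VCFs are required in ", dir)
  if (xor(present[1], present[2]))
    stop("parents must be both present or both absent")
  small <- lapply(which(present), function(i)
    read_small_variants(paths[i], sample_id = roles[i],
                        reference = reference))
  names(small) <- roles[present]
  structure(list(
    reference = structure(list(
      sequences = reference,
      genes = read_gene_models(file.path(dir, "genes.gff3")),
      gene_sets = read_gene_sets(file.path(dir, "gene_sets.gmt"))),
      class = "twinquad_reference"),
    small = small,
    cnv = read_cnv_table(file.path(dir, "cnv.tsv")),
    sv = read_sv_table(file.path(dir, "sv.tsv")),
    parents_present = all(present[1:2])),
    class = "twinquad_sim")
}
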