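#' Gene models
#'
#' Gene models are held as a list of two data.frames: `genes` (one row per
#' gene: `gene_id`, `chrom`, `strand`, `tx_start`, `tx_end`, 1-based
#' inclusive coordinates) and `features` (`gene_id`, `type` in
#' `{"exon","CDS"}`, `start`, `end`).  Exons lie within the transcript span
#' and CDS intervals within exons; in synthetic references the total CDS
#' length of each gene is a multiple of 3.
#'
#' @param genes,features the two data.frames described above.
#' @return an object of class `gene_models`.
#' @export
gene_models <- function(genes, features) {
  stopifnot(all(c("gene_id", "chrom", "strand", "tx_start", "tx_end") %in%
                  names(genes)),
            all(c("gene_id", "type", "start", "end") %in% names(features)),
            all(features$type %in% c("exon", "CDS")))
  if (any(features$end < features$start)) stop("degenerate feature interval")
  structure(list(genes = genes, features = features), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes on",
      length(unique(x$genes$chrom)), "chromosome(s);",
      sum(x$features$type == "exon"), "exons,",
      sum(x$features$type == "CDS"), "CDS segments\n")
  invisible(x)
}

#' Write gene models as GFF3
#'
#' Emits `gene`, `mRNA`, `exon` and `CDS` records (one transcript per gene,
#' id `<gene_id>.t1`) via rtracklayer.
#'
#' @param models a `gene_models` object.
#' @param path output GFF3 path.
#' @export
write_gene_models <- function(models, path) {
  g <- models$genes
  f <- models$features
  rows <- list()
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    tid <- paste0(gid, ".t1")
    fi <- f[f$gene_id == gid, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = g$chrom[i], start = g$tx_start[i], end = g$tx_end[i],
      strand = g$strand[i], type = c("gene", "mRNA"),
      ID = c(gid, tid), Parent = c(NA, gid), phase = NA_integer_,
      stringsAsFactors = FALSE)
    if (nrow(fi)) {
      ## frame of each CDS segment from the cumulative coding length
      ## upstream of it in translation order
      fi$phase <- NA_integer_
      cds_i <- which(fi$type == "CDS")
      cds_i <- cds_i[order(fi$start[cds_i],
                           decreasing = g$strand[i] == "-")]
      lens <- fi$end[cds_i] - fi$start[cds_i] + 1L
      fi$phase[cds_i] <- (3L - (cumsum(c(0L, lens[-length(lens)])) %% 3L)) %% 3L
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = g$chrom[i], start = fi$start, end = fi$end,
        strand = g$strand[i], type = fi$type,
        ID = NA_character_, Parent = tid, phase = fi$phase,
        stringsAsFactors = FALSE)
    }
  }
  d <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = d$chrom,
    ranges = IRanges::IRanges(d$start, d$end),
    strand = d$strand, type = d$type, ID = d$ID, Parent = d$Parent,
    phase = d$phase)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Accepts GFF3 with `gene`/`exon`/`CDS` records where exons and CDS point at
#' a transcript whose parent is the gene (or directly at the gene).
#'
#' @param path GFF3 file.
#' @return a `gene_models` object.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  d <- as.data.frame(gr, stringsAsFactors = FALSE)
  d$Parent <- vapply(d$Parent, function(p)
    if (length(p)) as.character(p)[1] else NA_character_, character(1))
  gen <- d[d$type == "gene", , drop = FALSE]
  tx <- d[d$type == "mRNA" | d$type == "transcript", , drop = FALSE]
  tx2gene <- stats::setNames(tx$Parent, tx$ID)
  feats <- d[d$type %in% c("exon", "CDS"), , drop = FALSE]
  owner <- feats$Parent
  mapped <- !is.na(tx2gene[owner])
  owner[mapped] <- tx2gene[owner[mapped]]
  gene_models(
    genes = data.frame(gene_id = gen$ID, chrom = as.character(gen$seqnames),
                       strand = as.character(gen$strand),
                       tx_start = gen$start, tx_end = gen$end,
                       stringsAsFactors = FALSE),
    features = data.frame(gene_id = owner, type = as.character(feats$type),
                          start = feats$start, end = feats$end,
                          stringsAsFactors = FALSE))
}

#' Write and read reference sequences (FASTA)
#'
#' @param reference named character vector or DNAStringSet.
#' @param path FASTA path.
#' @export
write_reference <- function(reference, path) {
  if (!methods::is(reference, "DNAStringSet"))
    reference <- Biostrings::DNAStringSet(reference)
  Biostrings::writeXStringSet(reference, path)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  Biostrings::readDNAStringSet(path)
}
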