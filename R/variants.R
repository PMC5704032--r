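#' Small sequence change (SSC) call sets
#'
#' A call set is a plain `data.frame` with one row per called small variant
#' (SNV, insertion, deletion or block substitution) in one sample, holding at
#' least the columns `sample_id`, `chrom`, `pos` (1-based, VCF convention),
#' `ref`, `alt`, `vclass`, `depth` and `quality`.  `small_variants()` validates
#' and canonicalizes such a frame: alleles are upper-cased, the variant class
#' is (re)derived from the allele lengths and the canonical `key` column is
#' added.
#'
#' @param df data.frame with columns `sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`, and optionally `depth` and `quality` (missing values are kept as
#'   `NA` and fail the high-confidence filter).
#' @return the canonicalized data.frame, with `vclass` and `key` columns.
#' @seealso [normalize_variants()], [filter_high_confidence()], [variant_key()]
#' @export
small_variants <- function(df) {
  stopifnot(is.data.frame(df))
  needed <- c("sample_id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop("small variant frame lacks columns: ", paste(miss, collapse = ", "))
  df$ref <- toupper(as.character(df$ref))
  df$alt <- toupper(as.character(df$alt))
  df$pos <- as.integer(df$pos)
  if (any(df$ref == df$alt))
    stop("ref must differ from alt for every call (ref == alt found)")
  if (is.null(df$depth)) df$depth <- NA_integer_
  if (is.null(df$quality)) df$quality <- NA_real_
  df$vclass <- variant_class(df$ref, df$alt)
  df$key <- variant_key(df)
  rownames(df) <- NULL
  df
}

#' Classify a ref/alt pair as SNV, insertion, deletion or substitution
#'
#' The class is derived from the allele lengths of the (normalized,
#' VCF-anchored) representation: equal single bases are SNVs; `ref` a strict
#' prefix of `alt` is an insertion; `alt` a strict prefix of `ref` is a
#' deletion; anything else (including equal-length multi-base replacements) is
#' a block substitution.
#'
#' @param ref,alt character vectors of upper-case alleles.
#' @return character vector in `{"SNV","insertion","deletion","substitution"}`.
#' @export
variant_class <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  out <- rep("substitution", length(ref))
  out[lr == 1L & la == 1L] <- "SNV"
  ins <- lr < la & substr(alt, 1L, lr) == ref
  del <- la < lr & substr(ref, 1L, la) == alt
  out[ins] <- "insertion"
  out[del] <- "deletion"
  out
}

#' Canonical variant identity key
#'
#' Two calls in different samples denote the same variant exactly when their
#' keys are equal; all sharing and inheritance comparisons reduce to key
#' membership.  Calls must be normalized first so that alternative
#' representations of one indel collapse to one key.
#'
#' @param df small-variant data.frame (needs `chrom`, `pos`, `ref`, `alt`).
#' @return character vector `"chrom:pos:ref:alt"`.
#' @export
variant_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

## Normalize one allele pair: trim shared flanks (keeping the VCF anchor
## base) and, when a reference sequence is available, left-align indels.
## `refseq` is a character string of the whole chromosome, or NULL.
normalize_one <- function(pos, ref, alt, refseq = NULL) {
  repeat {
    lr <- nchar(ref); la <- nchar(alt)
    ## shared trailing base: chop, re-anchoring on the left if emptied
    if (lr > 1L && la > 1L &&
        substr(ref, lr, lr) == substr(alt, la, la)) {
      ref <- substr(ref, 1L, lr - 1L)
      alt <- substr(alt, 1L, la - 1L)
      next
    }
    if (!is.null(refseq) && (lr == 0L || la == 0L ||
        (min(lr, la) >= 1L && lr != la &&
         substr(ref, lr, lr) == substr(alt, la, la)))) {
      ## left-extend for pure indels whose last bases still agree
      if (pos <= 1L) break
      prev <- substr(refseq, pos - 1L, pos - 1L)
      ref <- paste0(prev, substr(ref, 1L, lr - 1L))
      alt <- paste0(prev, substr(alt, 1L, la - 1L))
      pos <- pos - 1L
      next
    }
    ## shared leading base beyond the anchor: chop and advance
    lr <- nchar(ref); la <- nchar(alt)
    if (lr > 1L && la > 1L && substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
      ref <- substr(ref, 2L, lr)
      alt <- substr(alt, 2L, la)
      pos <- pos + 1L
      next
    }
    break
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Normalize variant representations
#'
#' Trims shared flanking bases (always retaining the single VCF anchor base
#' for indels) and, when the reference sequence is supplied, left-aligns
#' indels by the usual shift-left algorithm, so that every representation of
#' one variant maps to a single canonical `(chrom, pos, ref, alt)` key.
#'
#' @param df small-variant data.frame.
#' @param reference optional named character vector or
#'   [Biostrings::DNAStringSet] of chromosome sequences; without it only
#'   flank trimming is performed.
#' @return the data.frame with normalized `pos`, `ref`, `alt`, refreshed
#'   `vclass` and `key`.
#' @export
normalize_variants <- function(df, reference = NULL) {
  if (!nrow(df)) return(small_variants(df))
  seqs <- if (!is.null(reference)) named_sequences(reference)
  for (i in seq_len(nrow(df))) {
    rs <- if (!is.null(seqs)) seqs[[df$chrom[i]]] else NULL
    nv <- normalize_one(df$pos[i], df$ref[i], df$alt[i], rs)
    df$pos[i] <- nv$pos; df$ref[i] <- nv$ref; df$alt[i] <- nv$alt
  }
  small_variants(df)
}

#' High-confidence filter for small-variant calls
#'
#' Keeps calls with read depth and call quality at or above the configured
#' floors (both thresholds are inclusive; the defaults of 50 reads and a
#' phred-scaled quality of 100 are the stringent settings used for
#' whole-genome twin comparisons).  Calls with unknown depth or quality fail
#' the filter.  Row order is preserved and the number of removed calls is
#' recorded in the `"n_removed"` attribute.
#'
#' @param calls small-variant data.frame.
#' @param min_depth,min_quality non-negative thresholds.
#' @return the filtered data.frame.
#' @export
filter_high_confidence <- function(calls, min_depth = 50, min_quality = 100) {
  if (min_depth < 0 || min_quality < 0)
    stop("thresholds must be non-negative")
  keep <- !is.na(calls$depth) & !is.na(calls$quality) &
    calls$depth >= min_depth & calls$quality >= min_quality
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

## Coerce a reference (named character vector, list or DNAStringSet) to a
## named character vector of chromosome sequences.
named_sequences <- function(reference) {
  seqs <- if (is.list(reference)) unlist(reference) else
    as.character(reference)
  names(seqs) <- names(reference)
  if (is.null(names(seqs))) stop("reference sequences must be named")
  seqs
}
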