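# Independent brute-force oracles used to freeze expected values.

# Apply a small variant to a chromosome string; two representations denote
# the same variant iff the mutated strings are equal.
apply_variant_to_seq <- function(s, pos, ref, alt) {
  stopifnot(substr(s, pos, pos + nchar(ref) - 1L) == ref)
  paste0(substr(s, 1L, pos - 1L), alt,
         substr(s, pos + nchar(ref), nchar(s)))
}

# Base-by-base reciprocal overlap: count shared integer positions of two
# 0-based half-open intervals.
overlap_oracle <- function(a, b) {
  shared <- length(intersect(seq.int(a[1], a[2] - 1L),
                             seq.int(b[1], b[2] - 1L)))
  c(fa = shared / (a[2] - a[1]), fb = shared / (b[2] - b[1]))
}

# Exact hypergeometric right tail by direct term summation of
# C(K,j) C(N-K, n-j) / C(N, n).
hyper_oracle <- function(N, K, n, k) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Exact binomial tail for mosaic retention.
retention_oracle <- function(depth, f, floor) {
  p <- f / 2
  sum(vapply(floor:depth, function(r)
    choose(depth, r) * p^r * (1 - p)^(depth - r), numeric(1)))
}

# Connected components by explicit breadth-first search over an adjacency
# predicate.
components_oracle <- function(n, is_edge) {
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      for (w in seq_len(n))
        if (is.na(comp[w]) && is_edge(v, w)) queue <- c(queue, w)
    }
  }
  comp
}

# Small call-set builder for classifier tests.
mk_calls <- function(sample_id, keys, depth = 60, quality = 200) {
  if (!length(keys))
    return(small_variants(data.frame(
      sample_id = character(0), chrom = character(0), pos = integer(0),
      ref = character(0), alt = character(0), depth = integer(0),
      quality = numeric(0), stringsAsFactors = FALSE)))
  parts <- strsplit(keys, ":", fixed = TRUE)
  small_variants(data.frame(
    sample_id = sample_id,
    chrom = vapply(parts, `[`, character(1), 1L),
    pos = as.integer(vapply(parts, `[`, character(1), 2L)),
    ref = vapply(parts, `[`, character(1), 3L),
    alt = vapply(parts, `[`, character(1), 4L),
    depth = depth, quality = quality, stringsAsFactors = FALSE))
}

iv <- function(chrom, start, end) list(chrom = chrom, start = start, end = end)

# A small deterministic quad simulation shared by several test files.
tiny_sim <- function(seed = 3, ...) {
  args <- list(seed = seed, n_chromosomes = 2,
               chromosome_length_bp = 400000L, n_genes = 20,
               n_gene_sets = 4, genes_per_set = 5,
               n_inherited_snv = 300, n_inherited_indel = 30,
               n_inherited_blocksub = 8, n_germline_denovo = 3,
               n_somatic_per_twin = 5, n_cnv_shared = 20,
               n_cnv_unique = 3,
               n_sv_by_category = c(deletion = 8, tandem_duplication = 4,
                                    interchromosomal = 4, inversion = 2),
               n_sv_unique_per_twin = 3)
  args <- utils::modifyList(args, list(...))
  cfg <- do.call(sim_config, args)
  simulate_quad(cfg, simulate_reference(cfg))
}
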