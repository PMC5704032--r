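#' Simulation configuration for a synthetic twin-quad study
#'
#' Builds the configuration driving [simulate_reference()] and
#' [simulate_quad()].  Defaults are desk-scaled to about 1/1000 of the
#' per-genome totals seen in whole-genome twin studies (roughly 3.6 thousand
#' SNVs, 400 indels and 75 block substitutions per parental pool, with a
#' transition/transversion ratio of 2.1), while CNV and SV counts are kept
#' near their real per-genome magnitudes (~150 CNVs, ~100 SVs) since those
#' are already small.
#'
#' @param seed integer seed; the single source of randomness for the run.
#' @param n_chromosomes,chromosome_length_bp synthetic genome dimensions.
#' @param n_genes,n_gene_sets,genes_per_set gene-model and pathway-collection
#'   sizing; sets are disjoint.
#' @param n_inherited_snv,n_inherited_indel,n_inherited_blocksub inherited
#'   small variants per parental pool (each appears in the owning parent and
#'   both twins).
#' @param p_both_parents probability an inherited variant is carried by both
#'   parents.
#' @param n_germline_denovo germline de novo variants (both twins, neither
#'   parent).
#' @param n_somatic_per_twin post-zygotic variants planted per twin (present
#'   in that twin only), each with a mosaic cell fraction.
#' @param n_discordant_inherited variants present in one parent and one twin
#'   only (inherited yet discordant between twins).
#' @param n_decoy_low_quality low-quality decoy calls per twin (quality 50,
#'   shallow depth) for exercising the high-confidence filter.
#' @param n_cnv_shared,n_cnv_unique CNVs present in both twins / unique to
#'   each twin.
#' @param p_cnv_shared_inherited,p_cnv_unique_inherited probability a shared
#'   (resp. twin-unique) CNV is also present in a parent.
#' @param n_sv_by_category named integer vector of twin-shared SV counts per
#'   category.
#' @param n_sv_unique_per_twin twin-unique SVs (drawn from the non-inversion
#'   categories).
#' @param p_sv_shared_inherited,p_sv_unique_inherited as for CNVs.
#' @param titv_ratio SNV transition/transversion ratio.
#' @param mosaic_model either `list(type = "fixed", f = <fraction>)` or
#'   `list(type = "beta", shape1, shape2)` for post-zygotic cell fractions.
#' @param depth_mean nominal read depth per call.
#' @param depth_model `"constant"` (noiseless: every planted call carries
#'   exactly `depth_mean` reads, so it deterministically meets a depth-50
#'   filter) or `"poisson"` (per-call Poisson depths).
#' @param quality_value constant call quality for planted calls (default 200,
#'   comfortably above the quality-100 filter).
#' @param spike named list (role -> `list(gene_set =, n_variants =)`) forcing
#'   that many of the role's post-zygotic variants into coding sequence of
#'   distinct genes of the named set; used to plant pathway signal.
#' @return an object of class `twinquad_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chromosome_length_bp = 1000000L,
                       n_genes = 60L,
                       n_gene_sets = 10L,
                       genes_per_set = 5L,
                       n_inherited_snv = 1800L,
                       n_inherited_indel = 200L,
                       n_inherited_blocksub = 38L,
                       p_both_parents = 0.05,
                       n_germline_denovo = 8L,
                       n_somatic_per_twin = 30L,
                       n_discordant_inherited = 0L,
                       n_decoy_low_quality = 0L,
                       n_cnv_shared = 140L,
                       n_cnv_unique = 7L,
                       p_cnv_shared_inherited = 0.9,
                       p_cnv_unique_inherited = 0.3,
                       n_sv_by_category = c(deletion = 40L,
                                            tandem_duplication = 25L,
                                            distal_duplication = 10L,
                                            interchromosomal = 10L,
                                            inversion = 3L),
                       n_sv_unique_per_twin = 8L,
                       p_sv_shared_inherited = 0.9,
                       p_sv_unique_inherited = 0.3,
                       titv_ratio = 2.1,
                       mosaic_model = list(type = "beta",
                                           shape1 = 2, shape2 = 4),
                       depth_mean = 50,
                       depth_model = c("constant", "poisson"),
                       quality_value = 200,
                       spike = list()) {
  cfg <- as.list(environment())
  cfg$depth_model <- match.arg(depth_model)
  counts <- c(cfg$n_inherited_snv, cfg$n_inherited_indel,
              cfg$n_inherited_blocksub, cfg$n_germline_denovo,
              cfg$n_somatic_per_twin, cfg$n_discordant_inherited,
              cfg$n_decoy_low_quality, cfg$n_cnv_shared, cfg$n_cnv_unique,
              cfg$n_sv_by_category, cfg$n_sv_unique_per_twin)
  if (any(counts < 0)) stop("all simulated counts must be >= 0")
  if (cfg$titv_ratio <= 0) stop("titv_ratio must be positive")
  if (cfg$depth_mean <= 0) stop("depth_mean must be positive")
  if (!all(names(cfg$n_sv_by_category) %in% sv_categories))
    stop("unknown SV category in n_sv_by_category")
  if (identical(cfg$mosaic_model$type, "fixed")) {
    f <- cfg$mosaic_model$f
    if (is.null(f) || f <= 0 || f > 1)
      stop("fixed mosaic fraction must lie in (0, 1]")
  } else if (!identical(cfg$mosaic_model$type, "beta")) {
    stop("mosaic_model$type must be 'fixed' or 'beta'")
  }
  structure(cfg, class = "twinquad_config")
}

#' @export
print.twinquad_config <- function(x, ...) {
  cat("twinquad_config:", x$n_chromosomes, "x",
      format(x$chromosome_length_bp, big.mark = ","), "bp;",
      x$n_genes, "genes;",
      2L * (x$n_inherited_snv + x$n_inherited_indel + x$n_inherited_blocksub),
      "inherited SSCs;", x$n_somatic_per_twin, "post-zygotic per twin\n")
  invisible(x)
}

TWIN_ROLES <- c("father", "mother", "twin_affected", "twin_unaffected")

## --- reference -------------------------------------------------------------

#' Generate a synthetic reference: sequence, gene models and gene sets
#'
#' Deterministic for a given config seed.  Genes are multi-exon, lie on both
#' strands, carry 5'/3' UTRs and a CDS whose length is a multiple of 3.  The
#' pathway collection partitions a subset of the genes into disjoint named
#' sets.
#'
#' @param config a `twinquad_config`.
#' @return a list of class `twinquad_reference` with elements `sequences`
#'   (named character vector), `genes` (a `gene_models` object) and
#'   `gene_sets` (named list).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "twinquad_config"))
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  seqs <- vapply(chroms, function(ch)
    paste(sample(c("A", "C", "G", "T"), config$chromosome_length_bp,
                 replace = TRUE), collapse = ""), character(1))
  genes <- list(); feats <- list()
  cursor <- stats::setNames(rep(5000L, length(chroms)), chroms)
  for (i in seq_len(config$n_genes)) {
    ch <- chroms[1L + (i - 1L) %% length(chroms)]
    n_ex <- sample(2:4, 1L)
    ex_len <- sample(40:120, n_ex, replace = TRUE) * 3L
    in_len <- sample(200:600, n_ex - 1L, replace = TRUE)
    tx_start <- cursor[[ch]] + sample(2500:6000, 1L)
    tx_end <- tx_start + sum(ex_len) + sum(in_len) - 1L
    if (tx_end > config$chromosome_length_bp - 5000L)
      stop("chromosome too short for requested gene count")
    cursor[[ch]] <- tx_end
    strand <- sample(c("+", "-"), 1L)
    ex_start <- tx_start + c(0L, cumsum(ex_len[-n_ex] + in_len))
    ex_end <- ex_start + ex_len - 1L
    u5 <- sample(10:30, 1L) * 3L  # UTR lengths multiples of 3 keep CDS %% 3 == 0
    u3 <- sample(10:30, 1L) * 3L
    gid <- sprintf("gene%03d", i)
    ## transcript-order exonic genomic positions
    pos_vec <- unlist(Map(seq.int, ex_start, ex_end), use.names = FALSE)
    if (strand == "-") pos_vec <- rev(pos_vec)
    cds_pos <- sort(pos_vec[(u5 + 1L):(length(pos_vec) - u3)])
    runs <- cumsum(c(1L, diff(cds_pos) != 1L))
    cds_start <- tapply(cds_pos, runs, min)
    cds_end <- tapply(cds_pos, runs, max)
    genes[[i]] <- data.frame(gene_id = gid, chrom = ch, strand = strand,
                             tx_start = tx_start, tx_end = tx_end,
                             stringsAsFactors = FALSE)
    feats[[i]] <- rbind(
      data.frame(gene_id = gid, type = "exon", start = ex_start,
                 end = ex_end, stringsAsFactors = FALSE),
      data.frame(gene_id = gid, type = "CDS", start = as.integer(cds_start),
                 end = as.integer(cds_end), stringsAsFactors = FALSE))
  }
  models <- gene_models(do.call(rbind, genes), do.call(rbind, feats))
  n_member <- config$n_gene_sets * config$genes_per_set
  if (n_member > config$n_genes)
    stop("not enough genes for the requested disjoint gene sets")
  member <- sample(models$genes$gene_id, n_member)
  sets <- split(member, rep(seq_len(config$n_gene_sets),
                            each = config$genes_per_set))
  names(sets) <- sprintf("pathway_%02d", seq_len(config$n_gene_sets))
  structure(list(sequences = seqs, genes = models, gene_sets = sets),
            class = "twinquad_reference")
}

## --- small-variant construction -------------------------------------------

transition_of <- c(A = "G", G = "A", C = "T", T = "C")

make_snv <- function(refbase, titv) {
  if (stats::runif(1) < titv / (1 + titv)) {
    transition_of[[refbase]]
  } else {
    sample(setdiff(c("A", "C", "G", "T"),
                   c(refbase, transition_of[[refbase]])), 1L)
  }
}

make_small_variant <- function(vclass, chrom, pos, seqs, titv) {
  s <- seqs[[chrom]]
  base_at <- function(p, n = 1L) substr(s, p, p + n - 1L)
  if (vclass == "SNV") {
    ref <- base_at(pos); alt <- make_snv(ref, titv)
  } else if (vclass == "insertion") {
    ref <- base_at(pos)
    ins <- paste(sample(c("A", "C", "G", "T"), sample(1:8, 1L),
                        replace = TRUE), collapse = "")
    alt <- paste0(ref, ins)
  } else if (vclass == "deletion") {
    len <- sample(1:8, 1L)
    ref <- base_at(pos, len + 1L); alt <- base_at(pos)
  } else {  # block substitution
    len <- sample(2:5, 1L)
    ref <- base_at(pos, len)
    repeat {
      alt <- paste(sample(c("A", "C", "G", "T"), sample(2:5, 1L),
                          replace = TRUE), collapse = "")
      ## distinct first/last bases keep the pair irreducible under trimming
      if (alt != ref &&
          substr(alt, 1, 1) != substr(ref, 1, 1) &&
          substr(alt, nchar(alt), nchar(alt)) != substr(ref, nchar(ref),
                                                        nchar(ref))) break
    }
  }
  list(ref = ref, alt = alt)
}

draw_mosaic_fraction <- function(n, model) {
  if (identical(model$type, "fixed")) rep(model$f, n)
  else pmin(pmax(stats::rbeta(n, model$shape1, model$shape2), 1e-3), 1)
}

## choose a CDS position (codon-aligned interior) of each target gene
spike_positions <- function(gene_ids, models) {
  out <- data.frame(chrom = character(0), pos = integer(0),
                    gene_id = character(0), stringsAsFactors = FALSE)
  for (gid in gene_ids) {
    cds <- models$features[models$features$gene_id == gid &
                             models$features$type == "CDS", , drop = FALSE]
    cds <- cds[which.max(cds$end - cds$start), ]
    g <- models$genes[models$genes$gene_id == gid, ]
    out <- rbind(out, data.frame(
      chrom = g$chrom, pos = as.integer(cds$start + 5L), gene_id = gid,
      stringsAsFactors = FALSE))
  }
  out
}

## --- quad simulation -------------------------------------------------------

#' Simulate the four call sets of a family quad with ground truth
#'
#' Plants inherited, germline de novo and post-zygotic (twin-specific) small
#' variants plus shared/unique CNVs and SVs on the synthetic reference, and
#' records the origin of every planted variant.  In this noiseless output
#' every variant is present in exactly its expected samples; mosaicism-driven
#' detection loss is applied separately by [apply_mosaic_dropout()].
#'
#' Sample ids equal the pedigree roles: `father`, `mother`, `twin_affected`,
#' `twin_unaffected`.
#'
#' @param config a `twinquad_config`.
#' @param reference output of [simulate_reference()] for the same config.
#' @return an object of class `twinquad_sim`: list with `config`,
#'   `reference`, `small` (named list of per-role call frames), `cnv`, `sv`
#'   (frames over all samples) and `truth` (list of `small`, `cnv`, `sv`
#'   ground-truth frames).
#' @export
simulate_quad <- function(config, reference) {
  stopifnot(inherits(config, "twinquad_config"),
            inherits(reference, "twinquad_reference"))
  set.seed(config$seed + 1L)
  seqs <- reference$sequences
  chroms <- names(seqs)
  L <- config$chromosome_length_bp

  ## ---- small variants: positions from a 25-bp grid (planted spans are
  ##      < 13 bp, so grid slots can never collide)
  grid <- expand.grid(chrom = chroms,
                      pos = seq(200L, L - 200L, by = 25L),
                      stringsAsFactors = FALSE)
  class_counts <- function(n) {
    ## class mix for de novo pools: mostly SNVs
    sample(c("SNV", "deletion", "insertion", "substitution"), n,
           replace = TRUE, prob = c(0.88, 0.05, 0.05, 0.02))
  }
  pool <- function(n_snv, n_indel, n_bsub) {
    c(rep("SNV", n_snv),
      rep(c("deletion", "insertion"), length.out = n_indel),
      rep("substitution", n_bsub))
  }
  mk <- function(vclasses, origin)
    data.frame(vclass = vclasses, origin = rep(origin, length(vclasses)),
               stringsAsFactors = FALSE)
  plan <- list(
    father = mk(pool(config$n_inherited_snv, config$n_inherited_indel,
                     config$n_inherited_blocksub), "transmitted_father"),
    mother = mk(pool(config$n_inherited_snv, config$n_inherited_indel,
                     config$n_inherited_blocksub), "transmitted_mother"),
    germ = mk(class_counts(config$n_germline_denovo), "germline_denovo"),
    somA = mk(class_counts(config$n_somatic_per_twin),
              "postzygotic_twin_affected"),
    somB = mk(class_counts(config$n_somatic_per_twin),
              "postzygotic_twin_unaffected"),
    discA = mk(class_counts(config$n_discordant_inherited),
               "transmitted_discordant_twin_affected"),
    discB = mk(class_counts(config$n_discordant_inherited),
               "transmitted_discordant_twin_unaffected"),
    decoyA = mk(class_counts(config$n_decoy_low_quality),
                "decoy_twin_affected"),
    decoyB = mk(class_counts(config$n_decoy_low_quality),
                "decoy_twin_unaffected"))
  truth <- do.call(rbind, plan)
  n_total <- nrow(truth)
  if (n_total > nrow(grid))
    stop("chromosome too short for the requested variant counts")
  slot <- grid[sample.int(nrow(grid), n_total), , drop = FALSE]
  truth$chrom <- slot$chrom
  truth$pos <- slot$pos
  truth$gene_id <- NA_character_

  ## spiked post-zygotic variants relocated into CDS of target gene sets;
  ## each role accepts one spec or a list of specs
  for (role in names(config$spike)) {
    sp <- config$spike[[role]]
    specs <- if (!is.null(sp$gene_set)) list(sp) else sp
    origin <- paste0("postzygotic_", role)
    idx <- which(truth$origin == origin)
    for (spec in specs) {
      if (!length(idx)) break
      genes_in_set <- reference$gene_sets[[spec$gene_set]]
      if (is.null(genes_in_set))
        stop("spike gene set not found: ", spec$gene_set)
      k <- min(spec$n_variants, length(idx), length(genes_in_set))
      tgt <- spike_positions(genes_in_set[seq_len(k)], reference$genes)
      take <- idx[seq_len(k)]
      idx <- idx[-seq_len(k)]
      truth$chrom[take] <- tgt$chrom
      truth$pos[take] <- tgt$pos
      truth$gene_id[take] <- tgt$gene_id
      truth$vclass[take] <- "SNV"
    }
  }
  ## drop grid variants colliding with relocated spike positions
  spiked <- !is.na(truth$gene_id)
  if (any(spiked)) {
    kk <- paste(truth$chrom, truth$pos)
    clash <- !spiked & kk %in% kk[spiked]
    near <- !spiked & vapply(seq_len(nrow(truth)), function(i) {
      any(truth$chrom[spiked] == truth$chrom[i] &
            abs(truth$pos[spiked] - truth$pos[i]) < 15L)
    }, logical(1))
    truth <- truth[!(clash | near), , drop = FALSE]
  }

  alle <- lapply(seq_len(nrow(truth)), function(i)
    make_small_variant(truth$vclass[i], truth$chrom[i], truth$pos[i],
                       seqs, config$titv_ratio))
  truth$ref <- vapply(alle, `[[`, character(1), "ref")
  truth$alt <- vapply(alle, `[[`, character(1), "alt")
  truth$key <- variant_key(truth)

  ## membership
  both_parents <- grepl("^transmitted_(father|mother)$", truth$origin) &
    stats::runif(nrow(truth)) < config$p_both_parents
  truth$origin[both_parents] <- "transmitted_both"
  disc_parent <- sample(c("father", "mother"), nrow(truth), replace = TRUE)
  membership <- function(origin, i) switch(
    origin,
    transmitted_father = c("father", "twin_affected", "twin_unaffected"),
    transmitted_mother = c("mother", "twin_affected", "twin_unaffected"),
    transmitted_both = c("father", "mother", "twin_affected",
                         "twin_unaffected"),
    germline_denovo = c("twin_affected", "twin_unaffected"),
    postzygotic_twin_affected = "twin_affected",
    postzygotic_twin_unaffected = "twin_unaffected",
    transmitted_discordant_twin_affected = c(disc_parent[i], "twin_affected"),
    transmitted_discordant_twin_unaffected = c(disc_parent[i],
                                               "twin_unaffected"),
    decoy_twin_affected = c("twin_affected", "twin_unaffected"),
    decoy_twin_unaffected = c("twin_affected", "twin_unaffected"))
  mem <- lapply(seq_len(nrow(truth)), function(i)
    membership(truth$origin[i], i))
  truth$samples <- vapply(mem, paste, character(1), collapse = ",")
  truth$cell_fraction <- NA_real_
  pz <- grepl("^postzygotic_", truth$origin)
  truth$cell_fraction[pz] <- draw_mosaic_fraction(sum(pz),
                                                  config$mosaic_model)
  decoy <- grepl("^decoy_", truth$origin)

  small <- lapply(TWIN_ROLES, function(role) {
    take <- vapply(mem, function(m) role %in% m, logical(1))
    d <- truth[take, c("chrom", "pos", "ref", "alt"), drop = FALSE]
    is_decoy <- decoy[take]
    depth <- if (config$depth_model == "constant")
      rep(as.integer(round(config$depth_mean)), nrow(d))
    else stats::rpois(nrow(d), config$depth_mean)
    depth[is_decoy] <- pmin(depth[is_decoy], sample(5:30, sum(is_decoy),
                                                    replace = TRUE))
    quality <- rep(config$quality_value, nrow(d))
    quality[is_decoy] <- 50
    small_variants(data.frame(sample_id = role, d, depth = depth,
                              quality = quality, stringsAsFactors = FALSE))
  })
  names(small) <- TWIN_ROLES

  rownames(truth) <- NULL
  truth$retained <- TRUE

  ## ---- CNVs on a 4-kb slot grid (event sizes <= 3 kb)
  cnv_sizes <- c(500L, 1000L, 1500L, 2000L, 2500L, 3000L)
  cnv_grid <- expand.grid(chrom = chroms,
                          start = seq(1000L, L - 4000L, by = 4000L),
                          stringsAsFactors = FALSE)
  n_cnv <- config$n_cnv_shared + 2L * config$n_cnv_unique
  if (n_cnv > nrow(cnv_grid))
    stop("chromosome too short for the requested CNV counts")
  cslot <- cnv_grid[sample.int(nrow(cnv_grid), n_cnv), , drop = FALSE]
  cnv_truth <- data.frame(
    event_id = sprintf("cnv%03d", seq_len(n_cnv)),
    chrom = cslot$chrom,
    start = cslot$start,
    end = cslot$start + sample(cnv_sizes, n_cnv, replace = TRUE),
    copy_state = sample(c(0L, 1L, 3L, 4L), n_cnv, replace = TRUE),
    stringsAsFactors = FALSE)
  cnv_truth$cnv_type <- ifelse(cnv_truth$copy_state > 2L, "amp", "del")
  grp <- rep(c("shared", "unique_twin_affected", "unique_twin_unaffected"),
             c(config$n_cnv_shared, config$n_cnv_unique, config$n_cnv_unique))
  p_inh <- ifelse(grp == "shared", config$p_cnv_shared_inherited,
                  config$p_cnv_unique_inherited)
  inh <- stats::runif(n_cnv) < p_inh
  cnv_parent <- sample(c("father", "mother"), n_cnv, replace = TRUE)
  cnv_truth$origin <- ifelse(
    grp == "shared", ifelse(inh, "inherited_shared", "germline_denovo"),
    ifelse(inh, paste0("inherited_", sub("unique_", "", grp)),
           paste0("postzygotic_", sub("unique_", "", grp))))
  cmem <- lapply(seq_len(n_cnv), function(i) {
    tw <- switch(grp[i],
                 shared = c("twin_affected", "twin_unaffected"),
                 unique_twin_affected = "twin_affected",
                 unique_twin_unaffected = "twin_unaffected")
    if (inh[i]) c(cnv_parent[i], tw) else tw
  })
  cnv_truth$samples <- vapply(cmem, paste, character(1), collapse = ",")
  cnv <- do.call(rbind, lapply(seq_len(n_cnv), function(i) {
    data.frame(sample_id = cmem[[i]], chrom = cnv_truth$chrom[i],
               start = cnv_truth$start[i], end = cnv_truth$end[i],
               copy_state = cnv_truth$copy_state[i],
               cnv_type = cnv_truth$cnv_type[i],
               event_id = cnv_truth$event_id[i], stringsAsFactors = FALSE)
  }))
  rownames(cnv) <- NULL

  ## ---- SVs: interval slots offset from the CNV grid; junction slots 2 kb
  sv_shared <- rep(names(config$n_sv_by_category), config$n_sv_by_category)
  uniq_cats <- setdiff(sv_categories, "inversion")
  sv_uni_A <- sample(uniq_cats, config$n_sv_unique_per_twin, replace = TRUE)
  sv_uni_B <- sample(uniq_cats, config$n_sv_unique_per_twin, replace = TRUE)
  sv_cat <- c(sv_shared, sv_uni_A, sv_uni_B)
  sv_grp <- rep(c("shared", "unique_twin_affected", "unique_twin_unaffected"),
                c(length(sv_shared), length(sv_uni_A), length(sv_uni_B)))
  n_sv <- length(sv_cat)
  sv_grid <- expand.grid(chrom = chroms,
                         start = seq(3000L, L - 4000L, by = 4000L) + 1500L,
                         stringsAsFactors = FALSE)
  if (n_sv > nrow(sv_grid))
    stop("chromosome too short for the requested SV counts")
  sslot <- sv_grid[sample.int(nrow(sv_grid), n_sv), , drop = FALSE]
  jgrid <- expand.grid(chrom = chroms,
                       pos = seq(2000L, L - 2000L, by = 2000L),
                       stringsAsFactors = FALSE)
  jslot <- jgrid[sample.int(nrow(jgrid), 2L * n_sv), , drop = FALSE]
  sv_truth <- data.frame(
    event_id = sprintf("sv%03d", seq_len(n_sv)),
    category = sv_cat, chromA = sslot$chrom, startA = sslot$start,
    endA = sslot$start + sample(c(400L, 800L, 1200L, 2000L), n_sv,
                                replace = TRUE),
    chromB = rep(NA_character_, n_sv), posB = rep(NA_integer_, n_sv),
    orientation = rep(NA_character_, n_sv), stringsAsFactors = FALSE)
  inter <- sv_cat == "interchromosomal"
  if (any(inter)) {
    ji <- which(inter)
    a <- jslot[seq_along(ji), , drop = FALSE]
    b <- jslot[length(ji) + seq_along(ji), , drop = FALSE]
    flip <- a$chrom == b$chrom
    b$chrom[flip] <- chroms[1L + (match(b$chrom[flip], chroms) %% length(chroms))]
    sv_truth$chromA[ji] <- a$chrom; sv_truth$startA[ji] <- a$pos
    sv_truth$endA[ji] <- NA_integer_
    sv_truth$chromB[ji] <- b$chrom; sv_truth$posB[ji] <- b$pos
  }
  sv_truth$orientation[sv_cat == "inversion"] <-
    sample(c("forward", "reverse"), sum(sv_cat == "inversion"),
           replace = TRUE)
  p_inh <- ifelse(sv_grp == "shared", config$p_sv_shared_inherited,
                  config$p_sv_unique_inherited)
  inh <- stats::runif(n_sv) < p_inh
  sv_parent <- sample(c("father", "mother"), n_sv, replace = TRUE)
  sv_truth$origin <- ifelse(
    sv_grp == "shared", ifelse(inh, "inherited_shared", "germline_denovo"),
    ifelse(inh, paste0("inherited_", sub("unique_", "", sv_grp)),
           paste0("postzygotic_", sub("unique_", "", sv_grp))))
  smem <- lapply(seq_len(n_sv), function(i) {
    tw <- switch(sv_grp[i],
                 shared = c("twin_affected", "twin_unaffected"),
                 unique_twin_affected = "twin_affected",
                 unique_twin_unaffected = "twin_unaffected")
    if (inh[i]) c(sv_parent[i], tw) else tw
  })
  sv_truth$samples <- vapply(smem, paste, character(1), collapse = ",")
  sv <- do.call(rbind, lapply(seq_len(n_sv), function(i) {
    data.frame(sample_id = smem[[i]], category = sv_truth$category[i],
               chromA = sv_truth$chromA[i], startA = sv_truth$startA[i],
               endA = sv_truth$endA[i], chromB = sv_truth$chromB[i],
               posB = sv_truth$posB[i],
               orientation = sv_truth$orientation[i],
               event_id = sv_truth$event_id[i], stringsAsFactors = FALSE)
  }))
  rownames(sv) <- NULL

  structure(list(config = config, reference = reference, small = small,
                 cnv = cnv, sv = sv,
                 truth = list(small = truth, cnv = cnv_truth, sv = sv_truth),
                 parents_present = TRUE),
            class = "twinquad_sim")
}

#' @export
print.twinquad_sim <- function(x, ...) {
  cat("twinquad_sim (", if (x$parents_present) "quad" else "twin-only",
      " mode)\n", sep = "")
  for (r in names(x$small))
    cat(sprintf("  %-16s %6d SSCs, %4d CNVs, %4d SVs\n", r,
                nrow(x$small[[r]]), sum(x$cnv$sample_id == r),
                sum(x$sv$sample_id == r)))
  invisible(x)
}

#' Withhold the parental genomes (twin-only mode)
#'
#' Mirrors a family analyzed without parents: downstream classification then
#' produces provisional de novo labels.
#'
#' @param sim a `twinquad_sim`.
#' @return the sim with parental call sets removed and
#'   `parents_present = FALSE`.
#' @export
drop_parents <- function(sim) {
  sim$small <- sim$small[c("twin_affected", "twin_unaffected")]
  sim$cnv <- sim$cnv[!sim$cnv$sample_id %in% c("father", "mother"), ,
                     drop = FALSE]
  sim$sv <- sim$sv[!sim$sv$sample_id %in% c("father", "mother"), ,
                   drop = FALSE]
  sim$parents_present <- FALSE
  sim
}

## --- mosaic dropout --------------------------------------------------------

#' Probability a mosaic variant survives detection
#'
#' A post-zygotic variant present in a fraction `cell_fraction` of cells has
#' expected allele fraction `cell_fraction / 2` (heterozygous in carrier
#' cells).  With binomially sampled supporting reads at the given depth, the
#' variant is detected when at least `floor` reads carry the alternate
#' allele.
#'
#' @param depth read depth (vectorized).
#' @param cell_fraction fraction of carrier cells in (0, 1].
#' @param floor minimum supporting reads for a call (default 3).
#' @return detection probability.
#' @export
retention_probability <- function(depth, cell_fraction, floor = 3L) {
  stats::pbinom(floor - 1L, size = depth, prob = cell_fraction / 2,
                lower.tail = FALSE)
}

#' Apply mosaicism-driven detection loss to post-zygotic calls
#'
#' For every post-zygotic small variant, supporting reads are drawn
#' binomially from the call's depth at allele fraction `cell_fraction / 2`;
#' calls with fewer than `floor` supporting reads are dropped from the
#' carrier twin's call set.  The retention outcome is recorded in the truth
#' table (`retained` column).
#'
#' @param sim a `twinquad_sim` (noiseless).
#' @param floor detection floor in reads.
#' @param seed seed for the dropout draws (default derives from the config
#'   seed so a rerun reproduces the same pattern).
#' @return the degraded `twinquad_sim`.
#' @export
apply_mosaic_dropout <- function(sim, floor = 3L, seed = NULL) {
  if (is.null(seed)) seed <- sim$config$seed + 2L
  set.seed(seed)
  tr <- sim$truth$small
  pz <- which(grepl("^postzygotic_", tr$origin))
  for (i in pz) {
    role <- sub("^postzygotic_", "", tr$origin[i])
    cs <- sim$small[[role]]
    j <- match(tr$key[i], cs$key)
    if (is.na(j)) next
    reads <- stats::rbinom(1L, cs$depth[j], tr$cell_fraction[i] / 2)
    if (reads < floor) {
      sim$small[[role]] <- cs[-j, , drop = FALSE]
      tr$retained[i] <- FALSE
    }
  }
  rownames(sim$truth$small) <- NULL
  sim$truth$small <- tr
  sim
}

## --- writers ---------------------------------------------------------------

#' Write a simulated quad to a directory
#'
#' Emits per-sample VCFs, combined CNV and SV TSVs, the reference FASTA,
#' gene models (GFF3), gene sets (GMT), the ground-truth table and a YAML
#' echo of the configuration.  Output is deterministic byte for byte for a
#' given config.
#'
#' @param sim a `twinquad_sim`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_quad <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  contigs <- vapply(sim$reference$sequences, nchar, integer(1))
  for (role in names(sim$small))
    write_small_variants(sim$small[[role]],
                         file.path(dir, paste0(role, ".vcf")), contigs)
  write_cnv_table(sim$cnv[setdiff(names(sim$cnv), "event_id")],
                  file.path(dir, "cnv.tsv"))
  write_sv_table(sim$sv[setdiff(names(sim$sv), "event_id")],
                 file.path(dir, "sv.tsv"))
  write_reference(sim$reference$sequences, file.path(dir, "reference.fa"))
  write_gene_models(sim$reference$genes, file.path(dir, "genes.gff3"))
  write_gene_sets(sim$reference$gene_sets, file.path(dir, "gene_sets.gmt"))
  utils::write.table(sim$truth$small, file.path(dir, "truth_small.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$cnv, file.path(dir, "truth_cnv.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$sv, file.path(dir, "truth_sv.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- unclass(sim$config)
  cfg$n_sv_by_category <- as.list(cfg$n_sv_by_category)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
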