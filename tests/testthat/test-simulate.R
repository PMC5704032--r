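test_that("synthetic references are structurally sound and deterministic", {
  cfg <- sim_config(seed = 1, n_chromosomes = 2,
                    chromosome_length_bp = 1000000L, n_genes = 50,
                    n_gene_sets = 4, genes_per_set = 5)
  ref <- simulate_reference(cfg)
  expect_length(ref$sequences, 2L)
  expect_equal(nrow(ref$genes$genes), 50L)
  expect_setequal(unique(ref$genes$genes$strand), c("+", "-"))
  cds_len <- tapply(
    ref$genes$features$end - ref$genes$features$start + 1L,
    list(ref$genes$features$gene_id, ref$genes$features$type), sum)
  expect_true(all(cds_len[, "CDS"] %% 3L == 0L))
  # same seed twice: byte-identical emitted files
  ref2 <- simulate_reference(cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (x in list(list(ref, d1), list(ref2, d2))) {
    write_reference(x[[1]]$sequences, file.path(x[[2]], "ref.fa"))
    write_gene_models(x[[1]]$genes, file.path(x[[2]], "genes.gff3"))
    write_gene_sets(x[[1]]$gene_sets, file.path(x[[2]], "sets.gmt"))
  }
  for (f in c("ref.fa", "genes.gff3", "sets.gmt"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
})

test_that("gene-set collections partition the requested genes", {
  cfg <- sim_config(seed = 2, n_genes = 20, n_gene_sets = 4,
                    genes_per_set = 5, chromosome_length_bp = 500000L)
  ref <- simulate_reference(cfg)
  sets <- ref$gene_sets
  expect_length(sets, 4L)
  expect_true(all(lengths(sets) == 5L))
  expect_equal(anyDuplicated(unlist(sets)), 0L)  # disjoint
  p <- withr::local_tempfile(fileext = ".gmt")
  write_gene_sets(sets, p)
  expect_length(readLines(p), 4L)
})

test_that("a too-small genome for the requested genes is a sizing error", {
  cfg <- sim_config(seed = 1, n_genes = 100, n_chromosomes = 1,
                    chromosome_length_bp = 60000L, n_gene_sets = 2,
                    genes_per_set = 3)
  expect_error(simulate_reference(cfg), "too short")
})

test_that("planted variants appear in exactly their expected samples", {
  sim <- tiny_sim(seed = 3)
  tr <- sim$truth$small
  keysets <- lapply(sim$small, `[[`, "key")
  for (i in seq_len(nrow(tr))) {
    expected <- strsplit(tr$samples[i], ",", fixed = TRUE)[[1]]
    present <- names(keysets)[vapply(keysets, function(k)
      tr$key[i] %in% k, logical(1))]
    expect_setequal(present, expected)
  }
  # twin-unique counts equal the planted post-zygotic counts
  unsA <- setdiff(keysets$twin_affected, keysets$twin_unaffected)
  unsB <- setdiff(keysets$twin_unaffected, keysets$twin_affected)
  expect_equal(length(unsA), 5L)
  expect_equal(length(unsB), 5L)
  # germline de novo: both twins, neither parent
  germ <- tr$key[tr$origin == "germline_denovo"]
  expect_length(germ, 3L)
  expect_true(all(germ %in% keysets$twin_affected) &&
                all(germ %in% keysets$twin_unaffected))
  expect_false(any(germ %in% c(keysets$father, keysets$mother)))
  # role consistency: transmitted variants are never absent from both parents
  trans <- tr$key[grepl("^transmitted_(father|mother|both)$", tr$origin)]
  expect_true(all(trans %in% c(keysets$father, keysets$mother)))
})

test_that("doubling the inherited pool doubles the shared emitted count", {
  base <- tiny_sim(seed = 4)
  dbl <- tiny_sim(seed = 4, n_inherited_snv = 600)
  shared_inherited <- function(sim)
    sum(grepl("^transmitted_(father|mother|both)$", sim$truth$small$origin) &
          sim$truth$small$vclass == "SNV")
  expect_equal(shared_inherited(dbl), 2L * shared_inherited(base))
})

test_that("SNV transition fraction matches the configured Ti/Tv ratio", {
  cfg <- sim_config(seed = 6, n_inherited_snv = 5000, n_inherited_indel = 0,
                    n_inherited_blocksub = 0, n_germline_denovo = 0,
                    n_somatic_per_twin = 0, n_cnv_shared = 0,
                    n_cnv_unique = 0, n_sv_by_category = c(deletion = 0),
                    n_sv_unique_per_twin = 0, titv_ratio = 2.1,
                    chromosome_length_bp = 2000000L)
  sim <- simulate_quad(cfg, simulate_reference(cfg))
  snv <- sim$truth$small[sim$truth$small$vclass == "SNV", ]
  is_ti <- with(snv, (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
                  (ref == "C" & alt == "T") | (ref == "T" & alt == "C"))
  p0 <- 2.1 / 3.1
  tol <- 3 * sqrt(p0 * (1 - p0) / nrow(snv))
  expect_lt(abs(mean(is_ti) - p0), tol)
})

test_that("simulation output files are byte-identical across reruns", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_quad(tiny_sim(seed = 8), d1)
  write_quad(tiny_sim(seed = 8), d2)
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
})

test_that("mosaic retention probability matches the exact binomial tail", {
  for (case in list(c(50, 1.0, 3), c(50, 0.2, 3), c(30, 0.5, 5),
                    c(80, 0.05, 3))) {
    expect_equal(retention_probability(case[1], case[2], case[3]),
                 retention_oracle(case[1], case[2], case[3]),
                 tolerance = 1e-12)
  }
  expect_gt(retention_probability(50, 1.0, 3), 0.999)
  expect_lt(retention_probability(50, 1e-4, 3), 1e-6)  # f -> 0 limit
})

test_that("mosaic dropout removes only post-zygotic calls, reproducibly", {
  sim0 <- tiny_sim(seed = 12, n_somatic_per_twin = 40,
                   mosaic_model = list(type = "fixed", f = 0.12))
  sim1 <- apply_mosaic_dropout(sim0)
  sim2 <- apply_mosaic_dropout(sim0)
  expect_identical(sim1$truth$small$retained, sim2$truth$small$retained)
  tr <- sim1$truth$small
  dropped <- tr$key[!tr$retained]
  expect_gt(length(dropped), 0L)
  expect_true(all(grepl("^postzygotic_", tr$origin[!tr$retained])))
  expect_false(any(dropped %in% c(sim1$small$twin_affected$key,
                                  sim1$small$twin_unaffected$key)))
  # non-post-zygotic calls are untouched
  expect_equal(nrow(sim0$small$father), nrow(sim1$small$father))
})

test_that("retention falls monotonically as the cell fraction shrinks", {
  fracs <- c(1.0, 0.5, 0.2, 0.1, 0.05)
  recall <- vapply(seq_along(fracs), function(i) {
    sim <- tiny_sim(seed = 20 + i, n_somatic_per_twin = 150,
                    mosaic_model = list(type = "fixed", f = fracs[i]))
    sim <- apply_mosaic_dropout(sim)
    mean(sim$truth$small$retained[
      grepl("^postzygotic_", sim$truth$small$origin)])
  }, numeric(1))
  expect_true(all(diff(recall) <= 0))
  # and tracks the exact binomial retention probability
  expected <- retention_probability(50L, fracs, 3L)
  expect_true(all(abs(recall - expected) < 0.08))
})
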