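test_that("reciprocal overlap fractions match the counting oracle", {
  r <- reciprocal_overlap(iv("chr1", 0, 100), iv("chr1", 50, 150))
  expect_equal(c(r$fraction_a, r$fraction_b), c(0.5, 0.5))
  expect_true(r$matched)  # exactly 50% meets the inclusive >= 0.5 rule
  r2 <- reciprocal_overlap(iv("chr1", 0, 100), iv("chr1", 0, 1000))
  expect_equal(c(r2$fraction_a, r2$fraction_b), c(1.0, 0.1))
  expect_false(r2$matched)  # reciprocity: both fractions must clear 50%
  r3 <- reciprocal_overlap(iv("chr2", 10, 60), iv("chr2", 10, 60))
  expect_equal(c(r3$fraction_a, r3$fraction_b), c(1, 1))
  expect_true(r3$matched)
  r4 <- reciprocal_overlap(iv("chr1", 0, 100), iv("chr2", 0, 100))
  expect_false(r4$matched)
  expect_equal(r4$fraction_a, 0)
  expect_error(reciprocal_overlap(iv("chr1", 5, 5), iv("chr1", 0, 10)),
               "zero-length")
})

test_that("overlap agrees with a base-by-base oracle on random pairs", {
  set.seed(101)
  for (rep in 1:1000) {
    s1 <- sample(0:9900, 1); e1 <- s1 + sample(1:(10000 - s1), 1)
    s2 <- sample(0:9900, 1); e2 <- s2 + sample(1:(10000 - s2), 1)
    got <- reciprocal_overlap(iv("chr1", s1, e1), iv("chr1", s2, e2))
    want <- overlap_oracle(c(s1, e1), c(s2, e2))
    expect_equal(c(got$fraction_a, got$fraction_b), unname(want))
    expect_equal(got$matched, min(want) >= 0.5)
  }
})

test_that("matching is reflexive, symmetric, and monotone in the threshold", {
  set.seed(102)
  pairs <- replicate(200, {
    s1 <- sample(0:900, 1); e1 <- s1 + sample(1:100, 1)
    s2 <- sample(0:900, 1); e2 <- s2 + sample(1:100, 1)
    c(s1, e1, s2, e2)
  })
  for (i in seq_len(ncol(pairs))) {
    a <- iv("chr1", pairs[1, i], pairs[2, i])
    b <- iv("chr1", pairs[3, i], pairs[4, i])
    expect_true(reciprocal_overlap(a, a)$matched)
    expect_equal(reciprocal_overlap(a, b)$matched,
                 reciprocal_overlap(b, a)$matched)
    matched_at <- vapply(c(0.25, 0.5, 0.75, 1.0), function(th)
      reciprocal_overlap(a, b, th)$matched, logical(1))
    expect_true(all(diff(matched_at) <= 0))  # raising th never adds matches
  }
})

test_that("inter-chromosomal events match on ordered chromosomes and < 500 bp", {
  ev <- function(cA, pA, cB, pB)
    list(chromA = cA, startA = pA, chromB = cB, posB = pB)
  a <- ev("chr2", 10000, "chr17", 5000)
  expect_true(match_interchromosomal(a, a))
  expect_true(match_interchromosomal(a, ev("chr2", 10499, "chr17", 5499)))
  expect_false(match_interchromosomal(a, ev("chr2", 10500, "chr17", 5000)))
  expect_false(match_interchromosomal(a, ev("chr2", 10000, "chr16", 5000)))
})

test_that("inversions require the same direction plus 50% identity", {
  inv <- function(s, e, o)
    list(chromA = "chr3", startA = s, endA = e, orientation = o)
  expect_true(match_inversion(inv(100, 300, "forward"),
                              inv(100, 300, "forward")))
  expect_false(match_inversion(inv(100, 300, "forward"),
                               inv(100, 300, "reverse")))
  # exactly 50% reciprocal overlap passes ("50% or more")
  expect_true(match_inversion(inv(0, 200, "forward"),
                              inv(100, 300, "forward")))
})

test_that("match groups are the connected components of the match graph", {
  # chain: A~B and B~C but A and C do not match directly
  cnv <- data.frame(sample_id = c("s1", "s2", "s3"), chrom = "chr1",
                    start = c(0L, 50L, 100L), end = c(100L, 150L, 200L),
                    cnv_type = "amp", stringsAsFactors = FALSE)
  expect_false(reciprocal_overlap(iv("chr1", 0, 100),
                                  iv("chr1", 100, 200))$matched)
  g <- build_match_groups(cnv, kind = "cnv")
  expect_equal(length(unique(g$group)), 1L)
  # oracle: explicit graph search over the pairwise predicate
  is_edge <- function(i, j) reciprocal_overlap(
    iv("chr1", cnv$start[i], cnv$end[i]),
    iv("chr1", cnv$start[j], cnv$end[j]))$matched
  expect_equal(length(unique(components_oracle(3, is_edge))), 1L)
  # disjoint events are singletons
  far <- data.frame(sample_id = c("s1", "s2"), chrom = "chr1",
                    start = c(0L, 5000L), end = c(100L, 5100L),
                    cnv_type = "amp", stringsAsFactors = FALSE)
  expect_equal(length(unique(build_match_groups(far, "cnv")$group)), 2L)
})

test_that("amp and del copy directions never merge", {
  cnv <- data.frame(sample_id = c("s1", "s2"), chrom = "chr1",
                    start = 0L, end = 100L,
                    cnv_type = c("amp", "del"), stringsAsFactors = FALSE)
  expect_equal(length(unique(build_match_groups(cnv, "cnv")$group)), 2L)
})

test_that("shared planted CNVs form groups holding both twins", {
  sim <- tiny_sim(seed = 41)
  g <- build_match_groups(sim$cnv, kind = "cnv")
  shared_ids <- sim$truth$cnv$event_id[
    sim$truth$cnv$origin %in% c("inherited_shared", "germline_denovo")]
  for (id in shared_ids) {
    rows <- which(sim$cnv$event_id == id)
    grp <- unique(g$group[as.integer(rownames(g)) %in% rows])
    expect_length(grp, 1L)
    members <- sim$cnv$sample_id[as.integer(rownames(g))[g$group == grp]]
    expect_true(all(c("twin_affected", "twin_unaffected") %in% members))
  }
})

test_that("published unique-CNV fixture classifies five of seven de novo", {
  cnv <- study_cnv_fixture(1)
  subject <- data.frame(sample_id = "twin_affected", chrom = cnv$chrom,
                        start = cnv$start, end = cnv$end,
                        cnv_type = cnv$cnv_type, stringsAsFactors = FALSE)
  inh <- cnv$identity == "inherited"
  father <- subject[inh, , drop = FALSE][1, , drop = FALSE]
  mother <- subject[inh, , drop = FALSE][2, , drop = FALSE]
  father$sample_id <- "father"; mother$sample_id <- "mother"
  cotwin <- subject[0, , drop = FALSE]  # unique to the affected twin
  lab <- classify_event_inheritance(subject, cotwin, father, mother,
                                    kind = "cnv")
  expect_equal(sum(lab$origin == "de_novo"), 5L)
  expect_equal(sum(lab$origin == "inherited"), 2L)
  expect_equal(lab$origin[inh], c("inherited", "inherited"))
})

test_that("a 60% reciprocal co-twin interval makes an event shared", {
  subject <- data.frame(sample_id = "tA", chrom = "chr1", start = 0L,
                        end = 1000L, cnv_type = "del",
                        stringsAsFactors = FALSE)
  at60 <- data.frame(sample_id = "tB", chrom = "chr1", start = 400L,
                     end = 1400L, cnv_type = "del",
                     stringsAsFactors = FALSE)
  expect_equal(classify_event_inheritance(
    subject, at60, kind = "cnv")$sharing, "shared")
  at40 <- data.frame(sample_id = "tB", chrom = "chr1", start = 600L,
                     end = 1600L, cnv_type = "del",
                     stringsAsFactors = FALSE)
  expect_equal(classify_event_inheritance(
    subject, at40, kind = "cnv")$sharing, "unshared")
})

test_that("event labels on a noiseless quad equal the planted truth", {
  sim <- tiny_sim(seed = 42)
  for (kind in c("cnv", "sv")) {
    ev <- if (kind == "cnv") sim$cnv else sim$sv
    tr <- sim$truth[[kind]]
    by <- split(ev, ev$sample_id)
    for (role in c("twin_affected", "twin_unaffected")) {
      co <- setdiff(c("twin_affected", "twin_unaffected"), role)
      lab <- classify_event_inheritance(by[[role]], by[[co]],
                                        by$father, by$mother, kind = kind)
      truth_rows <- tr[match(lab$event_id, tr$event_id), ]
      expect_equal(lab$sharing == "shared",
                   grepl("shared|germline", truth_rows$origin))
      uns <- lab$sharing == "unshared"
      expect_equal(lab$origin[uns] == "inherited",
                   grepl("^inherited_", truth_rows$origin[uns]))
    }
    s <- event_sharing_summary(ev, kind)
    expect_equal(s$inherited + s$de_novo, s$unshared)
  }
})
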