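test_that("directionality is the signed tag balance with a strict 0.8 gate", {
  expect_equal(directionality(5, 5), 0)
  expect_equal(directionality(10, 0), 1)
  expect_equal(directionality(9, 1), 0.8)   # exactly 0.8 fails |D| < 0.8
  expect_false(abs(directionality(9, 1)) < 0.8)
  expect_equal(directionality(3, 7), -directionality(7, 3))
  expect_true(all(abs(directionality(c(1, 8, 100), c(9, 2, 1))) <= 1))
  expect_error(directionality(0, 0), "both zero")
})

divergent_ctss <- function() {
  # a reverse-strand cluster at 1000-1010 and a forward cluster at
  # 1200-1210 (gap 190), plus a convergent pair that must not pair
  make_ctss(list(
    data.frame(chrom = "chr1",
               pos = c(1000, 1010, 1200, 1210, 5000, 5400),
               strand = c("-", "-", "+", "+", "+", "-"),
               count = c(3, 4, 5, 2, 9, 9)),
    data.frame(chrom = "chr1",
               pos = c(1000, 1205), strand = c("-", "+"), count = c(2, 6))))
}

test_that("divergent cluster pairs become loci at the gap midpoint", {
  loci <- find_bidirectional_loci(divergent_ctss(), pairing_max_gap = 400,
                                  window_half = 200)
  expect_equal(nrow(loci$loci), 1)   # convergent pair at 5000/5400 ignored
  expect_equal(loci$loci$midpoint, floor((1011 + 1200) / 2))
  expect_equal(unname(loci$F[1, ]), c(7, 6))
  expect_equal(unname(loci$R[1, ]), c(7, 2))
  expect_equal(loci$loci$samples_bidirectional, 2)
  expect_equal(loci$loci$D_pooled, (13 - 9) / (13 + 9))
})

test_that("stringency tiers implement the strict sample-count gates", {
  loci <- find_bidirectional_loci(divergent_ctss())
  # both flanks have > 1 tag in both samples, bidirectional in only 2
  lenient <- apply_stringency(loci, "lenient")
  stringent <- apply_stringency(loci, "stringent")
  expect_equal(nrow(lenient$loci), 1)
  expect_equal(nrow(stringent$loci), 0)  # needs "more than two" samples
  expect_true(all(stringent$loci$locus_id %in% lenient$loci$locus_id))
})

test_that("the stringent set is a subset of the lenient set on simulated data", {
  sim <- default_sim()
  ctss <- read_ctss(sim$paths$ctss, sim$metadata)
  loci <- find_bidirectional_loci(ctss)
  stringent <- apply_stringency(loci, "stringent")
  lenient <- apply_stringency(loci, "lenient")
  expect_true(all(stringent$loci$locus_id %in% lenient$loci$locus_id))
  expect_true(all(abs(stringent$loci$D_pooled) < 0.8))
  expect_true(all(stringent$loci$samples_bidirectional > 2))
})

test_that("masking removes loci strictly closer than the distance gates", {
  ctss <- make_ctss(list(data.frame(
    chrom = "chr1", pos = c(2000, 2100, 8000, 8100), strand = c("-", "+"),
    count = 5)))
  loci <- find_bidirectional_loci(ctss)
  expect_equal(nrow(loci$loci), 2)
  mids <- loci$loci$midpoint
  ann499 <- list(tss = data.frame(gene = "g", chrom = "chr1",
                                  pos = mids[1] - 499, strand = "+"),
                 exons = NULL)
  ann500 <- list(tss = data.frame(gene = "g", chrom = "chr1",
                                  pos = mids[1] - 500, strand = "+"),
                 exons = NULL)
  expect_equal(nrow(mask_annotated(loci, ann499)$loci), 1)  # 499 bp: removed
  expect_equal(nrow(mask_annotated(loci, ann500)$loci), 2)  # 500 bp: kept
  # exon gate, including distance 0 inside the interval
  ann_ex <- list(tss = NULL, exons = data.frame(chrom = "chr1",
                                                start = mids[2] - 10,
                                                end = mids[2] + 10))
  expect_equal(nrow(mask_annotated(loci, ann_ex)$loci), 1)
  # empty annotation keeps everything
  expect_equal(nrow(mask_annotated(loci, list(tss = NULL, exons = NULL))$loci), 2)
})

test_that("widening mask distances never increases the surviving count", {
  sim <- default_sim()
  ctss <- read_ctss(sim$paths$ctss, sim$metadata)
  loci <- find_bidirectional_loci(ctss)
  ann <- read_annotation(sim$paths$gtf)
  n <- vapply(c(0, 200, 500, 2000, 10000), function(d)
    nrow(mask_annotated(loci, ann, tss_dist = d, exon_dist = d / 5)$loci),
    numeric(1))
  expect_true(all(diff(n) <= 0))
})

test_that("reference overlap uses half-open 1 bp intersection", {
  ctss <- make_ctss(list(data.frame(
    chrom = "chr1", pos = c(2000, 2100), strand = c("-", "+"), count = 5)))
  loci <- find_bidirectional_loci(ctss, window_half = 200)
  mid <- loci$loci$midpoint
  same <- data.frame(chrom = "chr1", start = mid - 200, end = mid + 200)
  expect_equal(overlap_reference(loci, same)$count, 1)
  adjacent <- data.frame(chrom = "chr1", start = mid + 200,
                         end = mid + 300)
  expect_equal(overlap_reference(loci, adjacent)$count, 0)
  touch <- data.frame(chrom = "chr1", start = mid + 199, end = mid + 300)
  expect_equal(overlap_reference(loci, touch)$fraction, 1)
})

test_that("planted enhancers are recovered before masking on the small genome", {
  cfg <- small_config()
  sim <- simulate_timecourse(cfg, file.path(tempdir(), "enhsmall"))
  ctss <- read_ctss(sim$paths$ctss, sim$metadata)
  loci <- find_bidirectional_loci(ctss)
  te <- sim$truth$enhancers
  hit <- vapply(seq_len(nrow(te)), function(i)
    any(loci$loci$chrom == te$chrom[i] &
          abs(loci$loci$midpoint - te$pos[i]) <= 200), logical(1))
  expect_gte(mean(hit), 0.8)
})
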