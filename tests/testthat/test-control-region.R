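test_that("motif search finds exact and overlapping occurrences", {
  hits <- find_motifs("TTATACTAATT", "ATACTAA")
  expect_equal(hits$start, 3L)
  expect_equal(nrow(find_motifs("AAAA", "ATAGA")), 0L)
  # overlapping matches are all reported
  expect_equal(find_motifs("ATATA", "ATA")$start, c(1L, 3L))
  expect_error(find_motifs("ACGT", "AT"), "at least 3")
  expect_error(find_motifs("ACGT", "ANA"), "A/C/G/T")
  # reverse-complement search
  both <- find_motifs("TTTAGTATTT", "ATACTAA", both_strands = TRUE)
  expect_equal(both$strand, "reverse-complement")
  expect_equal(both$start, 2L)
})

test_that("poly-tract detection reports maximal runs only", {
  tr <- find_poly_tracts(paste0("C", strrep("T", 18), "C"), "T")
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$start, 2L)
  expect_equal(tr$length, 18L)
  expect_equal(nrow(find_poly_tracts(strrep("T", 9), "T", min_len = 10)), 0L)
  # run at the sequence boundary is still maximal
  tr2 <- find_poly_tracts(paste0(strrep("A", 12), "T"), "A")
  expect_equal(tr2$length, 12L)
  expect_equal(tr2$start, 1L)
})

test_that("microsatellite scanner reports canonical maximal repeats", {
  ms <- find_microsatellites(strrep("AT", 8))
  expect_equal(nrow(ms), 1L)
  expect_equal(ms$unit, "AT")
  expect_equal(ms$copies, 8L)
  expect_equal(ms$span, 16L)
  expect_equal(nrow(find_microsatellites(strrep("AT", 3))), 0L)
  # canonical rotation: TA-phase repeats report as AT
  ms2 <- find_microsatellites(paste0("CC", strrep("TA", 7), "CC"))
  expect_equal(ms2$unit, "AT")
})

test_that("microsatellite scanner agrees with the quadratic brute force", {
  for (i in 1:20) {
    r <- random_genome(sample(100:300, 1), seed = 400 + i, at = 0.9)
    fast <- find_microsatellites(r)
    slow <- brute_microsatellites(r)
    rownames(fast) <- rownames(slow) <- NULL
    expect_equal(fast[order(fast$start, fast$unit), ],
                 slow[order(slow$start, slow$unit), ],
                 info = paste("region", i))
  }
})

test_that("exactly duplicated elements are found as tandem repeats", {
  set.seed(421)
  mk <- function(u) paste(sample(c("A","T","G","C"), u, TRUE,
                                 prob = c(.45,.45,.05,.05)), collapse = "")
  flank <- function(n, s) random_genome(n, seed = s, at = 0.5)
  unit <- mk(51)
  region <- paste0(flank(60, 1), "G", strrep(unit, 2), "G", flank(60, 2))
  tr <- find_tandem_repeats(region)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$period, 51L)
  expect_equal(tr$copies, 2.0)
  expect_equal(tr$identity, 1.0)
  expect_equal(tr$start, 62L)
  # two planted duplications of different sizes in one region
  u25 <- mk(25); u31 <- mk(31)
  region2 <- paste0(flank(40, 3), "G", strrep(u25, 2), "G",
                    flank(40, 4), "G", strrep(u31, 2), "G", flank(40, 5))
  tr2 <- find_tandem_repeats(region2)
  expect_true(any(tr2$period == 25L & tr2$identity == 1))
  expect_true(any(tr2$period == 31L & tr2$identity == 1))
})

test_that("a near-exact duplication is found with reduced identity", {
  set.seed(423)
  unit <- paste(sample(c("A","T","G","C"), 40, TRUE), collapse = "")
  copy2 <- unit
  substr(copy2, 20, 20) <- setdiff(c("A","C","G","T"),
                                   substr(unit, 20, 20))[1]
  region <- paste0(random_genome(50, 6, at = 0.5), "G", unit, copy2, "G",
                   random_genome(50, 7, at = 0.5))
  tr <- find_tandem_repeats(region)
  expect_true(any(tr$period == 40L & tr$identity >= 0.9 & tr$identity < 1))
})

test_that("random regions yield no tandem repeats, agreeing with brute force", {
  for (i in 1:10) {
    r <- random_genome(sample(150:300, 1), seed = 430 + i, at = 0.5)
    expect_equal(nrow(find_tandem_repeats(r)), 0L)
    expect_equal(nrow(brute_exact_tandem(r)), 0L)
  }
  # too-short region is degenerate
  expect_equal(nrow(find_tandem_repeats("ATATAT")), 0L)
})

test_that("scanner hits re-validate by direct substring checks", {
  sd <- synthetic_default()
  cr_feat <- sd$table[sd$table$cls == "control", ]
  region <- extract_gene_sequence(sd$genome, cr_feat)
  for (h in seq_len(nrow(find_motifs(region, "ATAGA")))) {
    hit <- find_motifs(region, "ATAGA")[h, ]
    expect_equal(substring(region, hit$start, hit$start + 4L), "ATAGA")
  }
  ms <- find_microsatellites(region)
  for (h in seq_len(nrow(ms)))
    expect_equal(nchar(gsub(paste0("(", ms$unit[h], ")+"), "",
                            substring(region, ms$start[h],
                                      ms$start[h] + ms$span[h] - 1L))),
                 0L)
})

test_that("scanners shift coordinates under non-matching flanks", {
  set.seed(440)
  region <- paste0("C", strrep("T", 15), "G", strrep("AT", 6), "C")
  shifted <- paste0("GCGCG", region, "GCGCG")
  t1 <- find_poly_tracts(region, "T")
  t2 <- find_poly_tracts(shifted, "T")
  expect_equal(t2$start, t1$start + 5L)
  expect_equal(t2$length, t1$length)
  m1 <- find_microsatellites(region)
  m2 <- find_microsatellites(shifted)
  expect_equal(m2$start, m1$start + 5L)
  expect_equal(m2$unit, m1$unit)
})

test_that("the composite report recovers all planted features", {
  sd <- synthetic_default()
  cr_feat <- sd$table[sd$table$cls == "control", ]
  region <- extract_gene_sequence(sd$genome, cr_feat)
  truth <- sd$truth$cr
  rep <- control_region_report(region)
  expect_true(truth$motif$start %in% rep$motif_hits$start)
  expect_true(any(rep$poly_T$start == truth$poly_t$start &
                    rep$poly_T$length == truth$poly_t$length))
  expect_true(any(rep$poly_A$start == truth$poly_a$start &
                    rep$poly_A$length == truth$poly_a$length))
  expect_true(any(rep$microsatellites$unit == "AT" &
                    rep$microsatellites$start == truth$microsat$start &
                    rep$microsatellites$copies == truth$microsat$copies))
  # empty region degenerates to an empty report
  expect_equal(control_region_report("")$length, 0L)
})

test_that("reverse-complement scanning mirrors coordinates", {
  sd <- synthetic_default()
  cr_feat <- sd$table[sd$table$cls == "control", ]
  region <- extract_gene_sequence(sd$genome, cr_feat)
  fwd <- control_region_report(region)
  mirrored <- control_region_report(revcomp(region), revcomp = TRUE)
  expect_equal(mirrored$motif_hits$start, fwd$motif_hits$start)
  expect_equal(mirrored$poly_T$start, fwd$poly_T$start)
  expect_equal(mirrored$orientation, "reverse-complement")
})
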