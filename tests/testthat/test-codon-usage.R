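code <- invertebrate_mito_code()

test_that("the genetic code has mitochondrial reassignments and 62 sense codons", {
  expect_length(code$family, 62L)
  expect_equal(sort(code$stops), c("TAA", "TAG"))
  expect_equal(unname(code$family[c("AGA", "AGG")]), c("Ser1", "Ser1"))
  expect_equal(unname(code$codon_to_aa["ATA"]), "M")
  expect_equal(unname(code$codon_to_aa["TGA"]), "W")
  expect_equal(sum(lengths(code$families)), 62L)
  expect_equal(sort(code$families$Leu1), c("CTA", "CTC", "CTG", "CTT"))
  expect_equal(sort(code$families$Leu2), c("TTA", "TTG"))
  expect_equal(sort(code$families$Ser2), c("TCA", "TCC", "TCG", "TCT"))
})

test_that("start codons classify by the ATN pattern", {
  expect_equal(classify_start("ATTATAGGG"),
               list(codon = "ATT", class = "ATN-canonical"))
  expect_equal(classify_start("CGAGGAATT")$class, "noncanonical")
  expect_equal(classify_start("CGAGGAATT")$codon, "CGA")
  expect_equal(classify_start("GTGAAAGGG")$class, "noncanonical")
  expect_error(classify_start("ATG"), "too short")
})

test_that("stop codons classify by frame remainder", {
  expect_equal(classify_stop("ATGAAATAA")[c("stop", "class")],
               list(stop = "TAA", class = "complete"))
  expect_equal(classify_stop("ATGAAAT")[c("stop", "class")],
               list(stop = "T", class = "incomplete"))
  expect_equal(classify_stop("ATGAAATA")[c("stop", "class")],
               list(stop = "TA", class = "incomplete"))
  expect_equal(classify_stop("ATGAAAGGG")$class, "unresolved")
  expect_equal(classify_stop("ATGAAAG")$class, "unresolved")
})

test_that("polyadenylation completes incomplete stops to TAA", {
  set.seed(31)
  sense <- names(code$family)
  sense_noT <- setdiff(sense, c("TAA", "TAG"))
  for (i in 1:20) {
    body <- paste(sample(sense_noT, 10, replace = TRUE), collapse = "")
    cds_t <- paste0(body, "T")
    expect_equal(classify_stop(cds_t)$class, "incomplete")
    completed <- classify_stop(paste0(cds_t, "AA"))
    expect_equal(completed$stop, "TAA")
    expect_equal(completed$class, "complete")
  }
})

test_that("codon census counts, per-thousand and missing set are exact", {
  tbl <- codon_census(list(toy = "ATGAAATAA"), code)
  expect_equal(unname(tbl$counts[c("ATG", "AAA")]), c(1L, 1L))
  expect_equal(tbl$total, 2L)
  expect_equal(unname(tbl$per_thousand[c("ATG", "AAA")]), c(500, 500))
  expect_equal(unname(tbl$stop_counts["TAA"]), 1L)
  expect_equal(length(tbl$missing), 60L)

  # a CDS holding every sense codon exactly once has no missing codons
  all62 <- paste(names(code$family), collapse = "")
  full <- codon_census(list(all = paste0(all62, "TAA")), code)
  expect_equal(length(full$missing), 0L)
  expect_equal(unname(full$counts), rep(1L, 62L))
  expect_equal(sum(full$aa_totals), sum(full$counts))

  expect_error(codon_census(list(bad = "ATGTAAAAATAA"), code),
               "internal in-frame stop")
})

test_that("per-thousand values sum to 1000", {
  set.seed(32)
  sense <- names(code$family)
  cds <- paste(sample(sense, 400, replace = TRUE), collapse = "")
  tbl <- codon_census(list(cds), code)
  expect_equal(sum(tbl$per_thousand), 1000, tolerance = 1e-9)
})

test_that("RSCU matches its formula on forced families", {
  counts <- stats::setNames(integer(62), names(code$family))
  counts[c("TTT", "TTC")] <- 3L                 # Phe family, equal use
  counts[code$families$Pro] <- c(4L, 0L, 0L, 0L)
  tbl <- list(counts = counts)
  r <- rscu(tbl, code)
  expect_equal(unname(r[c("TTT", "TTC")]), c(1, 1))
  expect_equal(sort(unname(r[code$families$Pro])), c(0, 0, 0, 4))
  expect_true(all(is.na(r[code$families$Gly])))  # empty family -> NA
})

test_that("mean RSCU is 1 in every nonempty family (brute-force check)", {
  set.seed(33)
  for (rep in 1:5) {
    counts <- stats::setNames(
      as.integer(stats::rpois(62, lambda = stats::runif(1, 1, 20))),
      names(code$family))
    r <- rscu(list(counts = counts), code)
    for (fam in names(code$families)) {
      cs <- code$families[[fam]]
      if (sum(counts[cs]) == 0L) {
        expect_true(all(is.na(r[cs])))
      } else {
        # independent per-family loop
        manual <- counts[cs] / (sum(counts[cs]) / length(cs))
        expect_equal(unname(r[cs]), unname(manual))
        expect_equal(mean(r[cs]), 1, tolerance = 1e-12)
      }
    }
  }
})

test_that("amino-acid ranking is descending with alphabetical tie-break", {
  counts <- stats::setNames(integer(62), names(code$family))
  counts["AAT"] <- 30L   # Asn
  counts["ATT"] <- 20L   # Ile
  counts["TGT"] <- 1L    # Cys
  tbl <- codon_census(list(), code)  # empty census for structure
  tbl$counts <- counts
  tbl$aa_totals <- vapply(code$families, function(cs) sum(counts[cs]),
                          numeric(1))
  rk <- rank_amino_acids(tbl)
  expect_equal(rk$aa[1:2], c("Asn", "Ile"))
  expect_false(any(rk$tied[1:2]))
  # all-equal counts rank alphabetically and are flagged
  tbl$aa_totals[] <- 5
  rk2 <- rank_amino_acids(tbl)
  expect_equal(rk2$aa, sort(rk2$aa))
  expect_true(all(rk2$tied))
})

test_that("start/stop report on the synthetic genome matches its plan", {
  sd <- synthetic_default()
  rep <- start_stop_report(sd$genome, sd$table)
  plan <- sd$table[sd$table$cls == "PCG", ]
  expect_equal(rep$start_codon, plan$start_codon)
  expect_equal(rep$stop_codon, plan$stop_codon)
  expect_equal(rep$start_class[rep$gene == "cox1"], "noncanonical")
  expect_true(all(rep$start_class[rep$gene != "cox1"] == "ATN-canonical"))
  expect_false(any(rep$stop_class == "unresolved"))
})
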