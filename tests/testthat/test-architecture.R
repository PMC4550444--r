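test_that("junction gaps follow the coordinate formula", {
  tab <- focal_table()
  led <- junction_ledger(tab, circular = TRUE)
  gap <- function(p, n) led$gap_bp[led$prev_gene == p & led$next_gene == n]
  expect_equal(gap("trnI", "trnQ"), -3L)
  expect_equal(gap("atp8", "atp6"), -7L)
  expect_equal(gap("trnM", "trnI"), 0L)       # abutting
  expect_equal(gap("trnQ", "nad2"), 57L)
  expect_equal(gap("nad6", "cob"), 14L)       # coordinate-derived
  expect_equal(sum(led$wrap), 1L)
  expect_equal(led$gap_bp[led$wrap], 0L)      # CR ends where trnM begins
})

test_that("verbatim-column mode reproduces the declared intergenic column", {
  tab <- focal_table()
  led <- junction_ledger(tab, circular = FALSE, use_declared = TRUE)
  expect_equal(led$gap_bp[led$prev_gene == "nad6"], 13L)  # printed value
  expect_equal(led$gap_bp, tab$intergenic[-nrow(tab)])
})

test_that("unsorted annotations are rejected", {
  df <- data.frame(gene = c("trnM", "trnI"), cls = "tRNA",
                   strand = "major", start = c(1, 69), end = c(68, 134),
                   anticodon = c("CAT", "GAT"))
  tab <- annotation_table(df, genome_length = 200)
  shuffled <- tab[c(2, 1), ]
  attr(shuffled, "genome_length") <- 200L
  expect_error(junction_ledger(shuffled), "sorted")
})

test_that("ledger summaries reduce to sign-filtered recomputation", {
  set.seed(41)
  for (rep in 1:10) {
    n <- 12
    gaps <- sample(-8:20, n - 1, replace = TRUE)
    starts <- integer(n); ends <- integer(n)
    starts[1] <- 1L; ends[1] <- 50L
    for (i in 2:n) {
      starts[i] <- ends[i - 1] + gaps[i - 1] + 1L
      ends[i] <- starts[i] + sample(30:60, 1)
    }
    df <- data.frame(gene = paste0("g", seq_len(n)), cls = "PCG",
                     strand = "major", start = starts, end = ends)
    tab <- annotation_table(df, genome_length = max(ends) + 10L)
    led <- junction_ledger(tab, circular = FALSE)
    s <- summarize_ledger(led)
    expect_equal(s$n_overlaps, sum(gaps < 0))
    expect_equal(s$total_overlap_bp, sum(-gaps[gaps < 0]))
    expect_equal(s$n_spacers, sum(gaps > 0))
    expect_equal(s$total_spacer_bp, sum(gaps[gaps > 0]))
    if (s$n_spacers > 0) expect_equal(s$max_spacer, max(gaps[gaps > 0]))
    if (s$n_overlaps > 0) expect_equal(s$max_overlap, max(-gaps[gaps < 0]))
  }
})

test_that("an all-abutting annotation summarizes to zero everywhere", {
  df <- data.frame(gene = paste0("g", 1:5), cls = "PCG", strand = "major",
                   start = c(1, 101, 201, 301, 401),
                   end = c(100, 200, 300, 400, 500))
  tab <- annotation_table(df, genome_length = 500)
  s <- summarize_ledger(junction_ledger(tab, circular = TRUE),
                        include_wrap = TRUE)
  expect_equal(s$n_overlaps + s$n_spacers, 0L)
  expect_equal(s$total_spacer_bp + s$total_overlap_bp, 0L)
})

test_that("gaps plus spans telescope to the genome length on a circle", {
  sd <- synthetic_default()
  led <- junction_ledger(sd$table, circular = TRUE)
  spans <- sd$table$end - sd$table$start + 1L
  expect_equal(sum(led$gap_bp) + sum(spans),
               attr(sd$table, "genome_length"))
})

test_that("the gap multiset is invariant under rotation of the circle", {
  df <- data.frame(gene = paste0("g", 1:6), cls = "PCG", strand = "major",
                   start = c(3, 60, 118, 180, 240, 301),
                   end = c(55, 110, 175, 230, 295, 350))
  L <- 360L
  tab <- annotation_table(df, genome_length = L)
  base_gaps <- sort(junction_ledger(tab, circular = TRUE)$gap_bp)
  for (k in 2:6) {
    shift <- df$start[k] - 1L
    s2 <- ((df$start - 1L - shift) %% L) + 1L
    e2 <- s2 + (df$end - df$start)
    rot <- annotation_table(
      data.frame(gene = df$gene, cls = "PCG", strand = "major",
                 start = s2, end = e2), genome_length = L)
    expect_equal(sort(junction_ledger(rot, circular = TRUE)$gap_bp),
                 base_gaps)
  }
})

test_that("the derived arrangement differs from the ancestral order at trnM", {
  tab <- focal_table()
  ref <- read_gene_order(extdata("ancestral_insect_order.txt"))
  cmp <- compare_order(tab, ref)
  expect_true("trnM" %in% cmp$displaced)
  expect_gte(cmp$breakpoints, 2L)
  # adjacency-set arithmetic: only the trnM move separates the two orders
  expect_equal(cmp$breakpoints, 3L)
})

test_that("identical circular orders have zero breakpoints under rotation", {
  genes <- data.frame(gene = paste0("g", 1:8),
                      strand = rep(c("major", "minor"), 4),
                      stringsAsFactors = FALSE)
  for (k in c(1, 3, 6)) {
    rot <- genes[c(k:8, seq_len(k - 1))[1:8], ]
    cmp <- compare_order(rot, genes)
    expect_equal(cmp$breakpoints, 0L)
    expect_length(cmp$displaced, 0L)
  }
})

test_that("breakpoint counts agree with a brute-force adjacency diff", {
  set.seed(43)
  genes <- paste0("g", 1:10)
  ref <- data.frame(gene = genes, strand = "major", stringsAsFactors = FALSE)
  for (rep in 1:20) {
    perm <- sample(genes)
    obs <- data.frame(gene = perm, strand = "major", stringsAsFactors = FALSE)
    cmp <- compare_order(obs, ref)
    # independent oracle: enumerate unordered neighbour pairs directly
    adj <- function(g) {
      p <- cbind(g, c(g[-1], g[1]))
      apply(p, 1, function(x) paste(sort(x), collapse = "+"))
    }
    oracle <- sum(!(adj(perm) %in% adj(genes)))
    expect_equal(cmp$breakpoints, oracle)
  }
})

test_that("differing gene sets are rejected with the symmetric difference", {
  obs <- data.frame(gene = c("a", "b"), strand = "major")
  ref <- data.frame(gene = c("a", "c"), strand = "major")
  expect_error(compare_order(obs, ref), "symmetric difference")
})

test_that("signed comparison detects an inversion that unsigned misses", {
  genes <- data.frame(gene = paste0("g", 1:6), strand = "major",
                      stringsAsFactors = FALSE)
  flipped <- genes
  flipped$strand[3] <- "minor"
  expect_equal(compare_order(flipped, genes, signed = FALSE)$breakpoints, 0L)
  expect_gt(compare_order(flipped, genes, signed = TRUE)$breakpoints, 0L)
})
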