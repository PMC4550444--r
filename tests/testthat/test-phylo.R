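# small hand-made supermatrix helper
toy_matrix <- function(seqs) {
  structure(list(taxa = names(seqs), seqs = seqs,
                 blocks = data.frame(gene = "toy", start = 1L,
                                     end = nchar(seqs[1])),
                 width = nchar(seqs[1])), class = "supermatrix")
}

test_that("the supermatrix concatenates trimmed PCG blocks in fixed order", {
  fam <- generate_taxon_family(sim_params(seed = 11), n_taxa = 4)
  sm <- build_supermatrix(fam$genomes)
  expect_equal(length(sm$taxa), 4L)
  tab <- fam$genomes[[1]]$table
  spans <- tab$end[tab$cls == "PCG"] - tab$start[tab$cls == "PCG"] + 1L
  expect_equal(sm$width, sum(spans - spans %% 3L))
  expect_equal(sm$blocks$gene, pcg_gene_order())
  expect_true(all(nchar(sm$seqs) == sm$width))
  # identical genomes give identical rows
  two <- fam$genomes[c(1, 1)]
  names(two) <- c("a", "b")
  sm2 <- build_supermatrix(two)
  expect_equal(unname(sm2$seqs[1]), unname(sm2$seqs[2]))
})

test_that("a taxon missing a gene is reported by name", {
  fam <- generate_taxon_family(sim_params(seed = 12), n_taxa = 3)
  broken <- fam$genomes
  tab <- broken[[2]]$table
  tab2 <- annotation_table(as.data.frame(tab[tab$gene != "atp8", ]),
                           genome_length = attr(tab, "genome_length"))
  broken[[2]]$table <- tab2
  expect_error(build_supermatrix(broken), "atp8")
})

test_that("pairwise distances match closed forms", {
  sm <- toy_matrix(c(a = "AAAA", b = "AAAT"))
  expect_equal(unname(pairwise_distance(sm, "p")["a", "b"]), 0.25)
  expect_equal(unname(pairwise_distance(sm, "JC69")["a", "b"]),
               -0.75 * log(1 - 4 * 0.25 / 3))
  # identical rows are at distance zero under every model
  sm0 <- toy_matrix(c(x = "ACGTACGTAC", y = "ACGTACGTAC"))
  for (m in c("p", "JC69", "K2P"))
    expect_equal(unname(pairwise_distance(sm0, m)["x", "y"]), 0)
  # K2P with known transition/transversion counts
  s1 <- strrep("ACGT", 25)                       # 100 sites
  s2 <- s1
  substr(s2, 1, 1) <- "G"                        # A->G transition
  substr(s2, 2, 2) <- "T"                        # C->T transition
  substr(s2, 7, 7) <- "T"                        # G->T transversion
  P <- 2 / 100; Q <- 1 / 100
  k2p <- -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
  sm2 <- toy_matrix(c(u = s1, v = s2))
  expect_equal(unname(pairwise_distance(sm2, "K2P")["u", "v"]), k2p,
               tolerance = 1e-12)
})

test_that("NJ recovers a 4-taxon additive tree exactly", {
  # tree ((A:1,B:2):1,(C:3,D:4)) -> additive distances
  d <- matrix(0, 4, 4, dimnames = list(c("A","B","C","D"), c("A","B","C","D")))
  d["A","B"] <- d["B","A"] <- 3
  d["A","C"] <- d["C","A"] <- 5
  d["A","D"] <- d["D","A"] <- 6
  d["B","C"] <- d["C","B"] <- 6
  d["B","D"] <- d["D","B"] <- 7
  d["C","D"] <- d["D","C"] <- 7
  tr <- nj_tree(d)
  expect_equal(sum(tr$edge.length), 11)
  # path distances on the tree reproduce the input matrix exactly
  coph <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(coph, d, tolerance = 1e-12)
})

test_that("three taxa resolve by the closed three-point formula", {
  d <- matrix(0, 3, 3, dimnames = list(c("x","y","z"), c("x","y","z")))
  d["x","y"] <- d["y","x"] <- 3
  d["x","z"] <- d["z","x"] <- 4
  d["y","z"] <- d["z","y"] <- 5
  tr <- nj_tree(d)
  len <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(len[c("x","y","z")]), c(1, 2, 3))
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("NJ is exact on random additive matrices (additivity oracle)", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(6:10, 1)
    true <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 1))
    d <- ape::cophenetic.phylo(true)
    est <- nj_tree(d)
    expect_equal(ape::dist.topo(ape::unroot(true), est), 0,
                 ignore_attr = TRUE)
    coph <- ape::cophenetic.phylo(est)[rownames(d), colnames(d)]
    expect_equal(coph, d, tolerance = 1e-8)
  }
})

test_that("distances are equivariant under taxon relabeling", {
  set.seed(61)
  seqs <- c(a = random_genome(600, 71), b = random_genome(600, 72),
            c = random_genome(600, 73))
  sm <- toy_matrix(seqs)
  d1 <- pairwise_distance(sm, "K2P")
  sm_perm <- toy_matrix(seqs[c("c", "a", "b")])
  d2 <- pairwise_distance(sm_perm, "K2P")
  expect_equal(d2[c("a","b","c"), c("a","b","c")],
               d1[c("a","b","c"), c("a","b","c")])
})

test_that("JC simulation recovers the simulated branch length", {
  tree <- ape::read.tree(text = "(t1:0.05,t2:0.05);")
  fam <- generate_taxon_family(sim_params(seed = 21), tree = tree)
  sm <- build_supermatrix(fam$genomes)
  dj <- unname(pairwise_distance(sm, "JC69")["t1", "t2"])
  dp <- unname(pairwise_distance(sm, "p")["t1", "t2"])
  n <- sm$width
  d_true <- 0.1
  p_exp <- 0.75 * (1 - exp(-4 * d_true / 3))
  se_p <- sqrt(p_exp * (1 - p_exp) / n)
  expect_lt(abs(dp - p_exp), 3 * se_p)
  se_d <- se_p / (1 - 4 * p_exp / 3)
  expect_lt(abs(dj - d_true), 3 * se_d)
})

test_that("bootstrap supports clean clades at 100% and is seed-stable", {
  set.seed(62)
  base <- random_genome(800, 81)
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(length(ch), k)
    ch[idx] <- vapply(ch[idx], function(x)
      sample(setdiff(c("A","C","G","T"), x), 1), character(1))
    paste(ch, collapse = "")
  }
  cladeA <- base
  cladeB <- mut(base, 200)   # far-apart clades
  seqs <- c(a1 = cladeA, a2 = mut(cladeA, 5),
            b1 = cladeB, b2 = mut(cladeB, 5))
  sm <- toy_matrix(seqs)
  tr <- bootstrap_support(sm, model = "JC69", replicates = 50, seed = 7)
  labs <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(labs[!is.na(labs)] >= 99))
  tr2 <- bootstrap_support(sm, model = "JC69", replicates = 50, seed = 7)
  expect_identical(tr$node.label, tr2$node.label)
  tr0 <- bootstrap_support(sm, replicates = 0)
  expect_null(tr0$node.label)
})

test_that("trees round-trip through Newick idempotently", {
  set.seed(63)
  tr <- ape::rtree(6)
  f1 <- tempfile(fileext = ".nwk")
  f2 <- tempfile(fileext = ".nwk")
  write_newick(tr, f1)
  write_newick(read_newick(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("NJ on synthetic clades recovers the true topology", {
  tree <- ape::read.tree(
    text = "((t1:0.02,t2:0.02):0.08,(t3:0.02,t4:0.02):0.08);")
  fam <- generate_taxon_family(sim_params(seed = 31), tree = tree)
  sm <- build_supermatrix(fam$genomes)
  est <- nj_tree(pairwise_distance(sm, "K2P"))
  expect_equal(ape::dist.topo(ape::unroot(tree), est), 0,
               ignore_attr = TRUE)
})
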