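# Concatenated-PCG distance phylogeny: supermatrix assembly, p/JC69/K2P
# pairwise distances, neighbor joining and bootstrap support.  This is a
# desk-scale, fully reproducible stand-in for heavier maximum-likelihood
# analyses: the tree-building machinery is delegated to ape, with the
# package supplying the mitogenome-specific plumbing around it.

#' Canonical protein-coding gene order used for concatenation
#' @return Character vector of the 13 PCG names in concatenation order.
#' @export
pcg_gene_order <- function() PCG_NAMES

#' Build a concatenated-PCG supermatrix
#'
#' Extracts the 13 protein-coding genes of every genome in a fixed
#' canonical gene order, trims incomplete-stop remnants (1-2 trailing nt)
#' so each block is a whole number of codons, and concatenates.  Per-gene
#' sequences must be equal-length across taxa (pre-aligned, or synthetic
#' data where homology is by construction).
#'
#' @param genomes Named list; each element a list with \code{genome}
#'   (a \code{mitogenome}) and \code{table} (an \code{annotation_table}).
#' @return An object of class \code{"supermatrix"}: list with \code{taxa},
#'   \code{seqs} (named character, equal lengths), \code{blocks}
#'   (data.frame gene/start/end of each block), \code{width}.
#' @export
build_supermatrix <- function(genomes) {
  taxa <- names(genomes)
  if (is.null(taxa) || any(!nzchar(taxa)))
    taxa <- paste0("taxon", seq_along(genomes))
  genes <- pcg_gene_order()
  per_gene <- lapply(genes, function(g) {
    vapply(seq_along(genomes), function(i) {
      tab <- genomes[[i]]$table
      row <- which(tab$gene == g)
      if (length(row) == 0L)
        stop("taxon ", taxa[i], " is missing gene ", g)
      s <- extract_gene_sequence(genomes[[i]]$genome, tab[row, ])
      rem <- nchar(s) %% 3L
      if (rem > 0L) s <- substring(s, 1L, nchar(s) - rem)  # stop remnant
      s
    }, character(1))
  })
  names(per_gene) <- genes
  for (g in genes) {
    w <- nchar(per_gene[[g]])
    if (length(unique(w)) != 1L)
      stop("unequal lengths for gene ", g,
           " across taxa; align per-gene sequences externally first")
  }
  widths <- vapply(per_gene, function(x) nchar(x[1]), integer(1))
  ends <- cumsum(widths)
  blocks <- data.frame(gene = genes, start = ends - widths + 1L, end = ends,
                       stringsAsFactors = FALSE)
  seqs <- stats::setNames(
    vapply(seq_along(genomes), function(i)
      paste(vapply(per_gene, `[`, character(1), i), collapse = ""),
      character(1)), taxa)
  structure(list(taxa = taxa, seqs = seqs, blocks = blocks,
                 width = sum(widths)), class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d taxa x %d columns (%d gene blocks)\n",
              length(x$taxa), x$width, nrow(x$blocks)))
  invisible(x)
}

supermatrix_char_matrix <- function(matrix) {
  m <- t(vapply(matrix$seqs, function(s) seq_chars(s),
                character(matrix$width)))
  rownames(m) <- matrix$taxa
  m
}

#' Pairwise distances from a supermatrix
#'
#' p (raw mismatch fraction), JC69 or K2P distances over non-gap columns,
#' computed with \code{ape::dist.dna} (pairwise deletion).  Pairs whose
#' correction is undefined (log of a nonpositive number, i.e. saturated
#' divergence) are flagged and set to the maximum observed finite distance
#' plus one.
#'
#' @param matrix A \code{supermatrix}.
#' @param model "p", "JC69" or "K2P".
#' @return A symmetric numeric matrix with zero diagonal and taxa
#'   dimnames; attribute \code{"undefined_pairs"} lists any flagged pairs.
#' @export
pairwise_distance <- function(matrix, model = c("p", "JC69", "K2P")) {
  model <- match.arg(model)
  apemodel <- c(p = "raw", JC69 = "JC69", K2P = "K80")[[model]]
  chm <- supermatrix_char_matrix(matrix)
  dna <- ape::as.DNAbin(tolower(chm))
  d <- ape::dist.dna(dna, model = apemodel, pairwise.deletion = TRUE,
                     as.matrix = TRUE)
  undef <- which(!is.finite(d) & row(d) < col(d), arr.ind = TRUE)
  flagged <- NULL
  if (nrow(undef) > 0L) {
    mx <- max(d[is.finite(d)], 0)
    flagged <- data.frame(taxon1 = rownames(d)[undef[, 1]],
                          taxon2 = colnames(d)[undef[, 2]],
                          stringsAsFactors = FALSE)
    d[!is.finite(d)] <- mx + 1
  }
  diag(d) <- 0
  attr(d, "undefined_pairs") <- flagged
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \code{ape::nj}); negative branch
#' lengths, which NJ can produce on non-additive matrices, are clamped to
#' zero and noted in the \code{"clamped"} attribute.
#'
#' @param d Symmetric distance matrix with taxa dimnames (>= 3 taxa).
#' @param outgroup Optional taxon name to root the tree on.
#' @return An \code{ape::phylo} tree.
#' @export
nj_tree <- function(d, outgroup = NULL) {
  if (nrow(as.matrix(d)) < 3L) stop("need at least 3 taxa")
  tr <- ape::nj(stats::as.dist(d))
  n_neg <- sum(tr$edge.length < 0)
  if (n_neg > 0L) tr$edge.length[tr$edge.length < 0] <- 0
  if (!is.null(outgroup)) {
    if (!outgroup %in% tr$tip.label)
      stop("outgroup ", outgroup, " not among taxa")
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  }
  attr(tr, "clamped") <- n_neg
  tr
}

#' Bootstrap support for an NJ tree
#'
#' Resamples supermatrix columns with replacement; support of each
#' internal bipartition is the percentage of replicates containing it
#' (via \code{ape::prop.clades} on unrooted splits).  Seeded and
#' reproducible.
#'
#' @param matrix A \code{supermatrix}.
#' @param model Distance model passed to \code{\link{pairwise_distance}}.
#' @param replicates Number of bootstrap replicates; 0 returns the tree
#'   without labels.
#' @param seed Integer RNG seed.
#' @param outgroup Optional rooting taxon (applied after support is
#'   computed).
#' @return The NJ tree with \code{node.label} percentages (NA at the
#'   root), or unlabelled when \code{replicates = 0}.
#' @export
bootstrap_support <- function(matrix, model = "K2P", replicates = 100L,
                              seed = 1L, outgroup = NULL) {
  tr <- nj_tree(pairwise_distance(matrix, model))
  if (replicates <= 0L) {
    if (!is.null(outgroup))
      tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
    return(tr)
  }
  set.seed(seed)
  boot <- vector("list", replicates)
  for (b in seq_len(replicates)) {
    cols <- sample.int(matrix$width, matrix$width, replace = TRUE)
    res <- matrix
    res$seqs <- vapply(matrix$seqs, function(s)
      paste(seq_chars(s)[cols], collapse = ""), character(1))
    boot[[b]] <- nj_tree(pairwise_distance(res, model))
  }
  counts <- ape::prop.clades(tr, boot, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  tr$node.label <- round(100 * counts / replicates)
  if (!is.null(outgroup))
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  tr
}

#' Write a tree to Newick
#' @param tree An \code{ape::phylo}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Input path.
#' @return An \code{ape::phylo}.
#' @export
read_newick <- function(path) ape::read.tree(path)
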