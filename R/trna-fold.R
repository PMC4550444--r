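# Constrained cloverleaf folding of mitochondrial tRNA genes.
#
# The fold is a maximum-score search over an exhaustive enumeration of arm
# boundary placements (not a thermodynamic fold): acceptor stem 6-7 pairs,
# D stem 0-4 (0 = DHU arm reduced to a loop), anticodon stem fixed at 5
# with a 7-nt loop, T stem 2-5, short spacers and a variable region.
# Watson-Crick pairs score highest, G-U wobble pairs are allowed, and
# mismatches are tolerated inside stems at a penalty.

#' Folding parameters for the cloverleaf search
#'
#' @param wc Score of a Watson-Crick pair (default +2).
#' @param wobble Score of a G-U wobble pair (default +1).
#' @param mismatch Score of a tolerated in-stem mismatch (default -1).
#' @param var_max Maximum variable-region length (default 9).
#' @return A list of parameters; validated so that
#'   \code{wc > wobble > 0 > mismatch}.
#' @export
fold_params <- function(wc = 2, wobble = 1, mismatch = -1, var_max = 9) {
  if (!(wc > wobble && wobble > 0 && 0 > mismatch))
    stop("require wc > wobble > 0 > mismatch")
  list(wc = wc, wobble = wobble, mismatch = mismatch, var_max = var_max,
       acc_len = 6:7, d_len = 0:4, t_len = 2:5, d_loop = 3:13,
       t_loop = 3:9, spacer1 = 1:2, spacer2 = 0:1, tail = 0:2)
}

# pair score matrix over A,C,G,T,N (T treated as U for pairing)
pair_score_matrix <- function(params) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(params$mismatch, 5, 5, dimnames = list(b, b))
  m["A", "T"] <- m["T", "A"] <- params$wc
  m["G", "C"] <- m["C", "G"] <- params$wc
  m["G", "T"] <- m["T", "G"] <- params$wobble
  m["N", ] <- m[, "N"] <- params$mismatch
  m
}

pair_type <- function(b5, b3) {
  key <- paste0(b5, b3)
  ifelse(key %in% c("AT", "TA", "GC", "CG"), "WC",
         ifelse(key %in% c("GT", "TG"), "GU", "mismatch"))
}

# enumerate all boundary vectors compatible with a sequence length
enumerate_boundaries <- function(n, params) {
  g <- expand.grid(a = params$acc_len, s1 = params$spacer1, d = params$d_len,
                   dl = params$d_loop, s2 = params$spacer2,
                   v = seq_len(params$var_max), t = params$t_len,
                   tl = params$t_loop, KEEP.OUT.ATTRS = FALSE)
  used <- 2L * g$a + g$s1 + 2L * g$d + g$dl + g$s2 + 17L + g$v +
    2L * g$t + g$tl
  g$tail <- n - used
  g <- g[g$tail >= min(params$tail) & g$tail <= max(params$tail), ,
         drop = FALSE]
  # a 1-bp helix is not a stem; the D arm either pairs (>=2) or is a loop
  g <- g[g$d != 1L, , drop = FALSE]
  # canonical form for D-armless structures: the spacer/loop split is not
  # identifiable when d = 0, so s1 is fixed at its minimum
  g <- g[g$d > 0L | g$s1 == 1L, , drop = FALSE]
  # deterministic tie-break order: lexicographically smallest boundary vector
  g[order(g$a, g$s1, g$d, g$dl, g$s2, g$v, g$t, g$tl, g$tail), , drop = FALSE]
}

# vectorized score of every candidate boundary vector
score_boundaries <- function(enc, g, PS) {
  m <- nrow(g)
  n <- length(enc)
  total <- numeric(m)
  for (k in 1:7) {     # acceptor stem
    act <- g$a >= k
    b3 <- enc[n - g$tail - k + 1L]
    total <- total + ifelse(act, PS[cbind(enc[k], b3)], 0)
  }
  p <- g$a + g$s1 + 1L
  for (k in 1:4) {     # D stem
    act <- g$d >= k
    p5 <- p + k - 1L
    p3 <- p + 2L * g$d + g$dl - k
    sc <- PS[cbind(enc[pmin(p5, n)], enc[pmin(pmax(p3, 1L), n)])]
    total <- total + ifelse(act, sc, 0)
  }
  u <- g$a + g$s1 + 2L * g$d + g$dl + g$s2 + 1L
  for (k in 1:5) {     # anticodon stem (fixed 5)
    total <- total + PS[cbind(enc[u + k - 1L], enc[u + 17L - k])]
  }
  w <- u + 17L + g$v
  for (k in 1:5) {     # T stem
    act <- g$t >= k
    p5 <- w + k - 1L
    p3 <- w + 2L * g$t + g$tl - k
    sc <- PS[cbind(enc[pmin(p5, n)], enc[pmin(pmax(p3, 1L), n)])]
    total <- total + ifelse(act, sc, 0)
  }
  total
}

structure_from_boundaries <- function(seq, b, params) {
  ch <- seq_chars(seq)
  n <- length(ch)
  PS <- pair_score_matrix(params)
  pairs <- NULL
  add_pairs <- function(p5, p3, stem) {
    if (length(p5) == 0L) return(NULL)
    data.frame(pos5 = p5, pos3 = p3, stem = stem,
               base5 = ch[p5], base3 = ch[p3],
               type = pair_type(ch[p5], ch[p3]), stringsAsFactors = FALSE)
  }
  acc <- add_pairs(1:b$a, n - b$tail - (1:b$a) + 1L, "acceptor")
  p <- b$a + b$s1 + 1L
  dp <- if (b$d > 0L) add_pairs(p + (1:b$d) - 1L,
                                p + 2L * b$d + b$dl - (1:b$d), "DHU") else NULL
  u <- b$a + b$s1 + 2L * b$d + b$dl + b$s2 + 1L
  ac <- add_pairs(u + (1:5) - 1L, u + 17L - (1:5), "anticodon")
  w <- u + 17L + b$v
  tp <- add_pairs(w + (1:b$t) - 1L, w + 2L * b$t + b$tl - (1:b$t), "T")
  pairs <- rbind(acc, dp, ac, tp)
  score <- sum(PS[cbind(match(pairs$base5, rownames(PS)),
                        match(pairs$base3, rownames(PS)))])
  anticodon_start <- u + 7L
  acc_ok <- sum(pairs$type[pairs$stem == "acceptor"] != "mismatch")
  structure(list(
    boundaries = b,
    length = n,
    seq = seq,
    pairs = pairs,
    d_arm_is_loop = b$d == 0L,
    d_loop_span = c(p + b$d, p + b$d + b$dl - 1L),
    anticodon_loop_span = c(u + 5L, u + 11L),
    anticodon_span = c(anticodon_start, anticodon_start + 2L),
    anticodon = paste(ch[anticodon_start:(anticodon_start + 2L)],
                      collapse = ""),
    t_loop_span = c(w + b$t, w + b$t + b$tl - 1L),
    variable_span = if (b$v > 0L) c(u + 17L, u + 17L + b$v - 1L) else NULL,
    wobble_pairs = pairs[pairs$type == "GU", c("pos5", "pos3"), drop = FALSE],
    mismatches = pairs[pairs$type == "mismatch",
                       c("pos5", "pos3", "base5", "base3", "stem"),
                       drop = FALSE],
    score = score,
    non_cloverleaf = acc_ok < 6L), class = "cloverleaf")
}

#' Fold a tRNA gene into a cloverleaf
#'
#' Exhaustively enumerates all arm-boundary placements permitted by the
#' parameter bounds, scores each candidate (WC pairs +2, G-U wobble +1,
#' in-stem mismatch -1 by default) and returns the maximum-score
#' structure.  Ties are broken deterministically in favour of the
#' lexicographically smallest boundary vector, so re-folding is
#' bit-identical.  A structure whose acceptor stem holds fewer than 6
#' paired (WC or wobble) positions is flagged \code{non_cloverleaf}.
#'
#' @param seq tRNA gene sequence (DNA, gene orientation), 60-80 nt.
#' @param params Parameters from \code{\link{fold_params}}.
#' @return An object of class \code{"cloverleaf"}; see
#'   \code{structure_from_boundaries} fields, notably \code{pairs},
#'   \code{wobble_pairs}, \code{mismatches}, \code{d_arm_is_loop},
#'   \code{anticodon}, \code{score}.
#' @export
fold_cloverleaf <- function(seq, params = fold_params()) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 60L || n > 80L)
    stop("tRNA sequence length ", n, " outside the supported 60-80 nt range")
  enc <- match(seq_chars(seq), c("A", "C", "G", "T", "N"))
  if (anyNA(enc)) stop("sequence contains characters outside A/C/G/T/N")
  PS <- pair_score_matrix(params)
  g <- enumerate_boundaries(n, params)
  if (nrow(g) == 0L) stop("no admissible boundary placement for length ", n)
  sc <- score_boundaries(enc, g, PS)
  best <- g[which.max(sc), ]    # g is in tie-break order; first max wins
  structure_from_boundaries(seq, as.list(best), params)
}

#' Build the cloverleaf structure at given boundaries
#'
#' Constructs the structure a given boundary vector implies, without
#' searching; used to inspect planted (ground-truth) structures or any
#' specific candidate.
#'
#' @param seq tRNA gene sequence.
#' @param boundaries List with elements \code{a, s1, d, dl, s2, v, t, tl,
#'   tail} (as in \code{fold_cloverleaf}'s result).
#' @param params Parameters from \code{\link{fold_params}}.
#' @return A \code{cloverleaf} object.
#' @export
cloverleaf_at <- function(seq, boundaries, params = fold_params()) {
  structure_from_boundaries(toupper(seq), boundaries, params)
}

#' @export
print.cloverleaf <- function(x, ...) {
  b <- x$boundaries
  cat(sprintf(
    "<cloverleaf> %d nt, score %d%s | acceptor %d, D stem %d%s, anticodon %s, T stem %d\n",
    x$length, x$score, if (x$non_cloverleaf) " (non-cloverleaf)" else "",
    b$a, b$d, if (x$d_arm_is_loop) " (loop only)" else "", x$anticodon, b$t))
  if (nrow(x$wobble_pairs) > 0L)
    cat("  G-U wobble pairs at:",
        paste(sprintf("%d:%d", x$wobble_pairs$pos5, x$wobble_pairs$pos3),
              collapse = ", "), "\n")
  if (nrow(x$mismatches) > 0L)
    cat("  mismatches:",
        paste(sprintf("%s-%s in %s stem (%d:%d)", x$mismatches$base5,
                      x$mismatches$base3, x$mismatches$stem,
                      x$mismatches$pos5, x$mismatches$pos3),
              collapse = "; "), "\n")
  invisible(x)
}

#' Dot-bracket string of a cloverleaf structure
#'
#' @param structure A \code{cloverleaf}.
#' @param pairs_only Omit mismatched stem positions (render them as dots)?
#' @return Character scalar of "(", ")" and "." of the sequence length.
#' @export
dot_bracket <- function(structure, pairs_only = TRUE) {
  v <- rep(".", structure$length)
  p <- structure$pairs
  if (pairs_only) p <- p[p$type != "mismatch", , drop = FALSE]
  v[p$pos5] <- "("
  v[p$pos3] <- ")"
  paste(v, collapse = "")
}

#' Locate and decode the anticodon of a folded tRNA
#'
#' The anticodon occupies positions 3-5 of the 7-nt anticodon loop; the
#' decoded amino acid is the translation of its reverse complement under
#' the invertebrate mitochondrial code, labelled with the conventional
#' Leu1/Leu2/Ser1/Ser2 family splits.
#'
#' @param structure A \code{cloverleaf}.
#' @param code Genetic code from \code{\link{invertebrate_mito_code}}.
#' @return List with \code{anticodon}, \code{codon} (reverse complement)
#'   and \code{aa} (family label, e.g. "Met", "Ser1").
#' @export
locate_anticodon <- function(structure, code = invertebrate_mito_code()) {
  span <- structure$anticodon_loop_span
  if (span[2] - span[1] + 1L != 7L) stop("anticodon loop is not 7 nt")
  anticodon <- structure$anticodon
  codon <- revcomp(anticodon)
  aa <- unname(code$family[codon])
  if (is.na(aa)) aa <- "stop"
  list(anticodon = anticodon, codon = codon, aa = aa)
}

#' Wobble and mismatch census over a set of folded tRNAs
#'
#' @param structures Named list of \code{cloverleaf} objects (names are
#'   tRNA gene names).
#' @return List with \code{n_wobble} (total G-U pairs), \code{n_mismatch},
#'   \code{wobble} and \code{mismatches} data.frames (tRNA, stem,
#'   positions, bases), and \code{by_stem} tabulation of mismatch sites.
#' @export
mismatch_census <- function(structures) {
  nm <- names(structures)
  if (is.null(nm)) nm <- paste0("trna", seq_along(structures))
  wob <- list(); mis <- list()
  for (i in seq_along(structures)) {
    s <- structures[[i]]
    p <- s$pairs
    w <- p[p$type == "GU", , drop = FALSE]
    m <- p[p$type == "mismatch", , drop = FALSE]
    if (nrow(w) > 0L) { w$trna <- nm[i]; wob[[length(wob) + 1L]] <- w }
    if (nrow(m) > 0L) { m$trna <- nm[i]; mis[[length(mis) + 1L]] <- m }
  }
  empty <- data.frame(pos5 = integer(0), pos3 = integer(0),
                      stem = character(0), base5 = character(0),
                      base3 = character(0), type = character(0),
                      trna = character(0), stringsAsFactors = FALSE)
  wob <- if (length(wob) > 0L) do.call(rbind, wob) else empty
  mis <- if (length(mis) > 0L) do.call(rbind, mis) else empty
  list(n_wobble = nrow(wob), n_mismatch = nrow(mis),
       wobble = wob, mismatches = mis,
       by_stem = table(factor(mis$stem,
                              levels = c("acceptor", "DHU", "anticodon", "T"))))
}
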