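# Base composition and strand-asymmetry (skew) statistics.

#' Round half away from zero
#'
#' Presentation rounding used for percentages (2 dp) and skews (3 dp);
#' differs from \code{round()}'s round-half-even at exact .5 boundaries.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Composition skew
#'
#' \code{skew(x, y) = (x - y) / (x + y)}: with A and T counts (or
#' percentages) this is the AT skew, with G and C the GC skew.  Returns
#' \code{NA} when the denominator is zero.
#'
#' @param x_count,y_count Nonnegative counts or percentages.
#' @return \code{(x - y)/(x + y)}, or \code{NA} if \code{x + y == 0}.
#' @export
skew <- function(x_count, y_count) {
  if (any(x_count < 0, na.rm = TRUE) || any(y_count < 0, na.rm = TRUE))
    stop("skew inputs must be nonnegative")
  denom <- x_count + y_count
  ifelse(denom == 0, NA_real_, (x_count - y_count) / denom)
}

#' Base composition of a sequence
#'
#' Counts A/C/G/T (N excluded from percentage denominators), A+T content,
#' and AT/GC skews.  Percentages are exact; rounding is left to
#' presentation.
#'
#' @param seq DNA string.
#' @param partition Label for the partition the sequence represents.
#' @return An object of class \code{"composition_stats"}: a list with
#'   \code{n_A, n_C, n_G, n_T, n_N, pct_A, pct_C, pct_G, pct_T,
#'   at_content, at_skew, gc_skew, length, partition}.
#' @export
base_composition <- function(seq, partition = "whole") {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) stop("empty sequence")
  ch <- seq_chars(seq)
  n <- c(A = sum(ch == "A"), C = sum(ch == "C"),
         G = sum(ch == "G"), T = sum(ch == "T"))
  n_N <- sum(ch == "N")
  denom <- sum(n)
  pct <- if (denom > 0) 100 * n / denom else rep(NA_real_, 4)
  structure(list(
    n_A = unname(n["A"]), n_C = unname(n["C"]),
    n_G = unname(n["G"]), n_T = unname(n["T"]), n_N = n_N,
    pct_A = unname(pct[1]), pct_C = unname(pct[2]),
    pct_G = unname(pct[3]), pct_T = unname(pct[4]),
    at_content = unname(pct[1] + pct[4]),
    at_skew = skew(n[["A"]], n[["T"]]),
    gc_skew = skew(n[["G"]], n[["C"]]),
    length = length(ch), partition = partition), class = "composition_stats")
}

#' @export
print.composition_stats <- function(x, ...) {
  cat(sprintf(
    "<composition> %s: %d bp | A %.2f%% C %.2f%% G %.2f%% T %.2f%% | A+T %.2f%% | AT skew %.3f | GC skew %.3f\n",
    x$partition, x$length, x$pct_A, x$pct_C, x$pct_G, x$pct_T,
    x$at_content, x$at_skew, x$gc_skew))
  invisible(x)
}

#' Composition by annotation partition
#'
#' Whole-genome statistics are computed on the major strand; each feature
#' class (PCG, tRNA, rRNA, control) on the concatenation of its features'
#' sequences in table order.  By default class sequences are taken in gene
#' (sense) orientation; \code{partition_strand = "major"} uses the
#' major-strand slice for every feature instead.  Overlapping features
#' contribute their full spans to their class.
#'
#' @param genome A \code{mitogenome}.
#' @param table An \code{annotation_table}.
#' @param partition_strand "sense" (default) or "major".
#' @return Named list of \code{composition_stats}, one per available
#'   partition: whole, PCG, tRNA, rRNA, control.
#' @export
partition_composition <- function(genome, table,
                                  partition_strand = c("sense", "major")) {
  partition_strand <- match.arg(partition_strand)
  out <- list(whole = base_composition(genome$seq, "whole"))
  for (k in FEATURE_CLASSES) {
    idx <- which(table$cls == k)
    if (length(idx) == 0L) {
      warning("no features of class ", k, "; partition omitted")
      next
    }
    seqs <- vapply(idx, function(i) {
      f <- table[i, ]
      if (partition_strand == "major") f$strand <- "major"
      extract_gene_sequence(genome, f)
    }, character(1))
    out[[k]] <- base_composition(paste(seqs, collapse = ""), k)
  }
  out
}

#' Percentage of the genome covered by a partition
#'
#' @param part_len Partition length in bp.
#' @param genome_len Genome length in bp (> 0).
#' @param digits Presentation rounding (default 2 dp).
#' @return \code{100 * part_len / genome_len}, rounded half-up.
#' @export
coverage_fraction <- function(part_len, genome_len, digits = 2) {
  if (genome_len <= 0) stop("genome length must be positive")
  if (part_len < 0) stop("partition length must be nonnegative")
  round_half_up(100 * part_len / genome_len, digits)
}

#' Composition table in report form
#'
#' Flattens \code{partition_composition} output into a data.frame with the
#' conventional column order (size, A\%, G\%, T\%, C\%, A+T\%, AT skew,
#' GC skew), rounded at presentation precision.
#'
#' @param stats A list of \code{composition_stats}.
#' @return A data.frame, one row per partition.
#' @export
composition_report <- function(stats) {
  do.call(rbind, lapply(stats, function(s) data.frame(
    partition = s$partition, size_bp = s$length,
    pct_A = round_half_up(s$pct_A, 2), pct_G = round_half_up(s$pct_G, 2),
    pct_T = round_half_up(s$pct_T, 2), pct_C = round_half_up(s$pct_C, 2),
    at_content = round_half_up(s$at_content, 2),
    at_skew = round_half_up(s$at_skew, 3),
    gc_skew = round_half_up(s$gc_skew, 3),
    stringsAsFactors = FALSE)))
}
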