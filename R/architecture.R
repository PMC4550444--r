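# Circular genome architecture: the overlap/spacer ledger over adjacent
# annotated features, its summaries, and gene-order comparison against a
# reference arrangement via circular adjacency (breakpoint) analysis.

#' Junction ledger of an ordered annotation
#'
#' One record per adjacent feature pair in listed order.  The gap is
#' \code{next.start - prev.end - 1}: negative values are overlaps of
#' \code{|gap|} bp, 0 is abutting, positive values are spacer lengths.  On
#' a circular genome the wrap junction (last feature back to the first) is
#' appended with the gap computed modulo the genome length.
#'
#' @param table An \code{annotation_table}, sorted by start (enforced).
#' @param circular Append the wrap junction? Default TRUE.
#' @param use_declared Use the table's declared \code{intergenic} column
#'   verbatim instead of coordinate arithmetic (for reproducing printed
#'   tables whose column disagrees with the coordinates).
#' @return Data.frame with columns \code{prev_gene}, \code{next_gene},
#'   \code{gap_bp}, \code{wrap} (logical).
#' @export
junction_ledger <- function(table, circular = TRUE, use_declared = FALSE) {
  if (is.unsorted(table$start))
    stop("annotation table must be sorted by start coordinate")
  n <- nrow(table)
  if (n < 2L) stop("need at least two features for a ledger")
  glen <- attr(table, "genome_length")
  prev <- table$gene[-n]
  nxt <- table$gene[-1L]
  gap <- table$start[-1L] - table$end[-n] - 1L
  wrap <- rep(FALSE, n - 1L)
  if (use_declared) {
    decl <- table$intergenic[-n]
    if (all(is.na(decl)))
      stop("use_declared = TRUE but the table has no intergenic column")
    gap <- ifelse(is.na(decl), gap, decl)
  }
  if (circular) {
    wgap <- (table$start[1L] + glen) - table$end[n] - 1L
    prev <- c(prev, table$gene[n])
    nxt <- c(nxt, table$gene[1L])
    gap <- c(gap, wgap)
    wrap <- c(wrap, TRUE)
  }
  data.frame(prev_gene = prev, next_gene = nxt, gap_bp = as.integer(gap),
             wrap = wrap, stringsAsFactors = FALSE)
}

#' Summarize a junction ledger
#'
#' Overlap statistics over negative gaps and spacer statistics over
#' positive gaps.  Following the usual presentation of mitogenome tables,
#' junctions involving the control region and the wrap junction are
#' excluded by default.
#'
#' @param ledger Output of \code{\link{junction_ledger}}.
#' @param include_control Include junctions touching \code{control_region}?
#' @param include_wrap Include the wrap junction?
#' @return List with \code{n_overlaps}, \code{total_overlap_bp},
#'   \code{max_overlap}, \code{longest_overlap_pair}, \code{n_spacers},
#'   \code{total_spacer_bp}, \code{max_spacer}, \code{min_spacer},
#'   \code{longest_spacer_pair}.
#' @export
summarize_ledger <- function(ledger, include_control = FALSE,
                             include_wrap = FALSE) {
  keep <- rep(TRUE, nrow(ledger))
  if (!include_control)
    keep <- keep & ledger$prev_gene != "control_region" &
      ledger$next_gene != "control_region"
  if (!include_wrap) keep <- keep & !ledger$wrap
  led <- ledger[keep, , drop = FALSE]
  ov <- led[led$gap_bp < 0L, , drop = FALSE]
  sp <- led[led$gap_bp > 0L, , drop = FALSE]
  pair_of <- function(df, i) if (nrow(df) == 0L) c(NA_character_, NA_character_)
                             else c(df$prev_gene[i], df$next_gene[i])
  i_ov <- if (nrow(ov) > 0L) which.max(-ov$gap_bp) else NA_integer_
  i_sp <- if (nrow(sp) > 0L) which.max(sp$gap_bp) else NA_integer_
  list(
    n_overlaps = nrow(ov),
    total_overlap_bp = sum(-ov$gap_bp),
    max_overlap = if (nrow(ov) > 0L) max(-ov$gap_bp) else 0L,
    longest_overlap_pair = pair_of(ov, i_ov),
    n_spacers = nrow(sp),
    total_spacer_bp = sum(sp$gap_bp),
    max_spacer = if (nrow(sp) > 0L) max(sp$gap_bp) else 0L,
    min_spacer = if (nrow(sp) > 0L) min(sp$gap_bp) else 0L,
    longest_spacer_pair = pair_of(sp, i_sp))
}

# circular adjacency set (unsigned): set of unordered neighbor pairs
circular_adjacencies <- function(genes) {
  n <- length(genes)
  a <- genes
  b <- genes[c(2:n, 1L)]
  apply(cbind(a, b), 1L, function(p) paste(sort(p), collapse = "|"))
}

# signed circular adjacencies: oriented gene ends, invariant to rotation
# and to reflection with global strand flip
signed_adjacencies <- function(genes, strands) {
  n <- length(genes)
  head_of <- paste0(genes, ifelse(strands == "minor", ":t", ":h"))
  tail_of <- paste0(genes, ifelse(strands == "minor", ":h", ":t"))
  adj <- character(n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    adj[i] <- paste(sort(c(tail_of[i], head_of[j])), collapse = "|")
  }
  adj
}

#' Read a reference gene-order file
#'
#' Plain text, one gene per line; a leading "-" marks the minor strand.
#' Blank lines and lines starting with "#" are ignored.
#'
#' @param path File path.
#' @return Data.frame with columns \code{gene} and \code{strand}.
#' @export
read_gene_order <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  minor <- startsWith(lines, "-")
  gene <- normalize_gene_name(sub("^-", "", lines))
  data.frame(gene = gene, strand = ifelse(minor, "minor", "major"),
             stringsAsFactors = FALSE)
}

#' Compare an observed circular gene order against a reference
#'
#' Circular, rotation-invariant adjacency-set comparison.  The breakpoint
#' count is the number of adjacencies present in the observed order but
#' not in the reference; displaced genes are those with at least one
#' changed neighbourhood.  By default adjacencies are unsigned (order
#' only); \code{signed = TRUE} additionally distinguishes orientation.
#'
#' @param observed An \code{annotation_table} or a data.frame with columns
#'   \code{gene} and \code{strand} in circular order.
#' @param reference A data.frame as returned by \code{\link{read_gene_order}}.
#' @param signed Use strand-aware adjacencies?
#' @return List with \code{breakpoints}, \code{displaced} (character
#'   vector), \code{observed}, \code{reference}.
#' @export
compare_order <- function(observed, reference, signed = FALSE) {
  obs <- data.frame(gene = observed$gene, strand = observed$strand,
                    stringsAsFactors = FALSE)
  ref <- data.frame(gene = reference$gene, strand = reference$strand,
                    stringsAsFactors = FALSE)
  dif <- union(setdiff(obs$gene, ref$gene), setdiff(ref$gene, obs$gene))
  if (length(dif) > 0L)
    stop("gene sets differ; symmetric difference: ",
         paste(dif, collapse = ", "))
  if (signed) {
    a_obs <- signed_adjacencies(obs$gene, obs$strand)
    a_ref <- signed_adjacencies(ref$gene, ref$strand)
  } else {
    a_obs <- circular_adjacencies(obs$gene)
    a_ref <- circular_adjacencies(ref$gene)
  }
  broken <- !(a_obs %in% a_ref)
  n <- length(a_obs)
  displaced <- unique(unlist(lapply(which(broken), function(i)
    c(obs$gene[i], obs$gene[if (i == n) 1L else i + 1L]))))
  list(breakpoints = sum(broken), displaced = displaced,
       observed = obs, reference = ref)
}
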