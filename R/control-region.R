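# Feature scanning of A+T-rich control regions and intergenic spacers:
# exact motif search, maximal poly-tract detection, perfect-microsatellite
# detection, and a simplified (ungapped) tandem-repeat finder.

#' Find exact motif occurrences
#'
#' All exact, possibly overlapping, occurrences of a motif in a region;
#' optionally also of its reverse complement.
#'
#' @param region DNA string to scan.
#' @param motif Motif (>= 3 nt, A/C/G/T only).
#' @param both_strands Also report reverse-complement matches?
#' @return Data.frame with columns \code{motif}, \code{start} (1-based
#'   within the region), \code{strand} ("given" or "reverse-complement").
#' @export
find_motifs <- function(region, motif, both_strands = FALSE) {
  motif <- toupper(motif)
  if (nchar(motif) < 3L) stop("motif must be at least 3 nt")
  if (grepl("[^ACGT]", motif)) stop("motif must contain only A/C/G/T")
  region <- toupper(region)
  hits <- function(m, strand) {
    n <- nchar(region); k <- nchar(m)
    if (n < k) return(NULL)
    at <- which(substring(region, 1:(n - k + 1L), k:n) == m)
    if (length(at) == 0L) return(NULL)
    data.frame(motif = motif, start = at, strand = strand,
               stringsAsFactors = FALSE)
  }
  out <- hits(motif, "given")
  if (both_strands) {
    rc <- revcomp(motif)
    if (rc != motif) out <- rbind(out, hits(rc, "reverse-complement"))
  }
  if (is.null(out))
    return(data.frame(motif = character(0), start = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  out[order(out$start), , drop = FALSE]
}

#' Find maximal homopolymer tracts
#'
#' @param region DNA string.
#' @param base Single base A/C/G/T.
#' @param min_len Minimum run length to report (default 10).
#' @return Data.frame with columns \code{base}, \code{start}, \code{length};
#'   only maximal (non-extendable) runs are reported.
#' @export
find_poly_tracts <- function(region, base, min_len = 10L) {
  stopifnot(base %in% c("A", "C", "G", "T"))
  ch <- seq_chars(region)
  if (length(ch) == 0L)
    return(data.frame(base = character(0), start = integer(0),
                      length = integer(0), stringsAsFactors = FALSE))
  r <- rle(ch == base)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(base = rep(base, sum(keep)), start = starts[keep],
             length = r$lengths[keep], row.names = NULL,
             stringsAsFactors = FALSE)
}

# lexicographically smallest rotation of a repeat unit (canonical form)
canonical_rotation <- function(unit) {
  k <- nchar(unit)
  if (k == 1L) return(unit)
  rot <- vapply(seq_len(k), function(i)
    paste0(substring(unit, i, k), substring(unit, 1, i - 1L)), character(1))
  sort(rot)[1]
}

# smallest period of a string (k if primitive)
smallest_period <- function(s) {
  k <- nchar(s)
  for (p in seq_len(k)) {
    if (k %% p != 0L) next
    if (identical(s, strrep(substring(s, 1, p), k %/% p))) return(p)
  }
  k
}

#' Find perfect microsatellites
#'
#' Maximal perfect tandem repeats of a 1-6 nt unit with at least
#' \code{min_copies} full copies.  Each locus is reported once, at its
#' smallest (primitive) unit length, with the unit given in canonical
#' form (the lexicographically smallest rotation, so "AT", never "TA").
#'
#' @param region DNA string.
#' @param max_unit Maximum unit length (default 6).
#' @param min_copies Minimum number of full copies (default 5).
#' @return Data.frame with columns \code{unit}, \code{copies},
#'   \code{start}, \code{span} (= copies * unit length).
#' @export
find_microsatellites <- function(region, max_unit = 6L, min_copies = 5L) {
  region <- toupper(region)
  ch <- seq_chars(region)
  n <- length(ch)
  out <- list()
  for (u in seq_len(min(max_unit, max(0L, n %/% 2L)))) {
    m <- ch[seq_len(n - u)] == ch[seq_len(n - u) + u]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      run <- r$lengths[i]            # consecutive offset-u self-matches
      total <- run + u               # full repeated span (may be partial copy)
      copies <- total %/% u
      if (copies < min_copies) next
      start <- starts[i]
      span <- copies * u
      unit0 <- substring(region, start, start + u - 1L)
      if (smallest_period(unit0) != u) next   # keep primitive units only
      out[[length(out) + 1L]] <- data.frame(
        unit = canonical_rotation(unit0), copies = copies,
        start = start, span = span, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(unit = character(0), copies = integer(0),
                      start = integer(0), span = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, out)
  # drop hits wholly contained in another hit with the same canonical unit
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(nrow(out))) {
      if (i == j || !keep[i]) next
      if (out$unit[i] == out$unit[j] &&
          out$start[i] >= out$start[j] &&
          out$start[i] + out$span[i] <= out$start[j] + out$span[j] &&
          out$span[i] < out$span[j])
        keep[i] <- FALSE
    }
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start, out$unit), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find tandem repeats (simplified, ungapped)
#'
#' Period-autocorrelation candidate generation with greedy extension: for
#' each period p, maximal runs of offset-p matches are chained across
#' short mismatch gaps while the ungapped identity stays at or above
#' \code{min_identity}.  Overlapping reports across periods are merged,
#' keeping the hit with the highest identity (then the longest span, then
#' the smallest period).
#'
#' @param region DNA string.
#' @param min_period Minimum repeat period (default 10).
#' @param min_copies Minimum copy number, span/period (default 2.0).
#' @param min_identity Minimum ungapped identity between offset copies
#'   (default 0.9).
#' @return Data.frame with columns \code{period}, \code{copies} (real),
#'   \code{start}, \code{span}, \code{identity}.
#' @export
find_tandem_repeats <- function(region, min_period = 10L, min_copies = 2.0,
                                min_identity = 0.9) {
  region <- toupper(region)
  ch <- seq_chars(region)
  n <- length(ch)
  empty <- data.frame(period = integer(0), copies = numeric(0),
                      start = integer(0), span = integer(0),
                      identity = numeric(0), stringsAsFactors = FALSE)
  if (n < 2L * min_period) return(empty)
  cand <- list()
  for (p in seq.int(min_period, n %/% 2L)) {
    m <- ch[seq_len(n - p)] == ch[seq_len(n - p) + p]
    r <- rle(m)
    len <- r$lengths; val <- r$values
    ends <- cumsum(len); starts <- ends - len + 1L
    runs <- which(val)
    if (length(runs) == 0L) next
    for (i in seq_along(runs)) {
      # chain match runs across mismatch gaps while identity holds,
      # emitting every chain prefix; the merge below keeps the best
      a <- runs[i]; lo <- starts[a]; hi <- ends[a]
      matches <- len[a]
      j <- i
      repeat {
        span <- hi - lo + 1L + p
        if (span >= min_copies * p) {
          cand[[length(cand) + 1L]] <- data.frame(
            period = p, copies = span / p, start = lo, span = span,
            identity = matches / (hi - lo + 1L), stringsAsFactors = FALSE)
        }
        if (j >= length(runs)) break
        b <- runs[j + 1L]
        new_hi <- ends[b]
        new_matches <- matches + len[b]
        if (new_matches / (new_hi - lo + 1L) < min_identity) break
        hi <- new_hi; matches <- new_matches; j <- j + 1L
      }
    }
  }
  if (length(cand) == 0L) return(empty)
  out <- do.call(rbind, cand)
  # merge overlapping reports: highest identity, then longest, then smallest p
  out <- out[order(-out$identity, -out$span, out$period, out$start), ,
             drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(out))) {
      if (j <= i || !keep[j]) next
      ov <- min(out$start[i] + out$span[i], out$start[j] + out$span[j]) -
        max(out$start[i], out$start[j])
      if (ov > 0L) keep[j] <- FALSE
    }
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Composite control-region feature report
#'
#' Runs all scanners with the conventional defaults: the replication-origin
#' motif (default ATAGA), poly-T and poly-A tracts, microsatellites (unit
#' <= 6, >= 5 copies) and tandem repeats (period >= 10, >= 2 copies,
#' identity >= 0.9).  The region is scanned in the orientation supplied;
#' set \code{revcomp = TRUE} to scan the opposite strand (coordinates then
#' refer to the reverse-complemented region).
#'
#' @param region Control-region DNA string.
#' @param motif Origin motif to search (default "ATAGA").
#' @param revcomp Scan the reverse complement instead?
#' @param poly_min Minimum poly-tract length (default 10).
#' @return List with \code{orientation}, \code{motif_hits},
#'   \code{poly_T}, \code{poly_A}, \code{microsatellites},
#'   \code{tandem_repeats}, \code{length}.
#' @export
control_region_report <- function(region, motif = "ATAGA", revcomp = FALSE,
                                  poly_min = 10L) {
  if (nchar(region) == 0L)
    return(list(orientation = "given", length = 0L,
                motif_hits = find_motifs("AAA", "AAA")[0, ],
                poly_T = NULL, poly_A = NULL,
                microsatellites = NULL, tandem_repeats = NULL))
  if (revcomp) region <- revcomp(region)
  list(orientation = if (revcomp) "reverse-complement" else "given",
       length = nchar(region),
       motif_hits = find_motifs(region, motif),
       poly_T = find_poly_tracts(region, "T", poly_min),
       poly_A = find_poly_tracts(region, "A", poly_min),
       microsatellites = find_microsatellites(region),
       tandem_repeats = find_tandem_repeats(region))
}
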