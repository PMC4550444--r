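# Codon usage of mitochondrial protein-coding genes under the invertebrate
# mitochondrial genetic code (NCBI translation table 5): start/stop
# classification including incomplete stops, codon counts, codons per
# thousand, RSCU, missing codons and amino-acid ranking.

#' The invertebrate mitochondrial genetic code
#'
#' Wraps NCBI translation table 5 (Biostrings), under which AGA/AGG encode
#' Ser, ATA Met and TGA Trp, leaving TAA and TAG as the only stops.
#' Synonymous families carry the conventional mitochondrial split labels:
#' Leu1 = CTN, Leu2 = TTR, Ser1 = AGN, Ser2 = TCN.
#'
#' @return A list with \code{codon_to_aa} (named character over 64 codons,
#'   "*" for stops), \code{family} (codon -> family label over the 62 sense
#'   codons), \code{families} (family label -> codon vector), and
#'   \code{stops} (c("TAA", "TAG")).
#' @export
invertebrate_mito_code <- function() {
  gc5 <- Biostrings::getGeneticCode("5")  # invertebrate mitochondrial
  codons <- names(gc5)
  aa <- unname(gc5)
  fam <- character(length(codons))
  names(fam) <- codons
  for (i in seq_along(codons)) {
    cdn <- codons[i]
    fam[i] <- if (aa[i] == "*") NA_character_
    else if (aa[i] == "L") { if (substr(cdn, 1, 1) == "C") "Leu1" else "Leu2" }
    else if (aa[i] == "S") { if (substr(cdn, 1, 2) == "AG") "Ser1" else "Ser2" }
    else AA_LABELS[[aa[i]]]
  }
  sense <- codons[aa != "*"]
  families <- split(sense, fam[sense])
  list(id = "transl_table=5", codon_to_aa = stats::setNames(aa, codons),
       family = fam[sense], families = families,
       stops = codons[aa == "*"])
}

AA_LABELS <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
               Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
               K = "Lys", M = "Met", F = "Phe", P = "Pro", T = "Thr",
               W = "Trp", Y = "Tyr", V = "Val")

split_codons <- function(cds) {
  n <- nchar(cds) %/% 3L
  if (n == 0L) return(character(0))
  substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Classify the start codon of a CDS
#'
#' @param cds In-frame CDS string (gene orientation), length >= 6.
#' @return List with \code{codon} (first triplet) and \code{class}
#'   ("ATN-canonical" if the triplet matches AT[ACGT], else "noncanonical").
#' @export
classify_start <- function(cds) {
  if (nchar(cds) < 6L) stop("CDS too short to classify (need >= 6 nt)")
  codon <- toupper(substring(cds, 1L, 3L))
  list(codon = codon,
       class = if (grepl("^AT[ACGT]$", codon)) "ATN-canonical" else "noncanonical")
}

#' Classify the stop codon of a CDS
#'
#' Mitochondrial CDSs may end in a complete TAA/TAG, or in an incomplete
#' stop (T or TA) completed to TAA by post-transcriptional polyadenylation.
#' The frame remainder determines which is expected: a length divisible by
#' 3 must end in a complete stop, remainder 1 in a terminal T, remainder 2
#' in a terminal TA.  Anything else is reported as "unresolved".
#'
#' @param cds In-frame CDS string, length >= 6.
#' @return List with \code{stop} (token: "TAA", "TAG", "TA", "T" or the
#'   observed tail), \code{class} ("complete", "incomplete" or
#'   "unresolved") and \code{detail} diagnostics for unresolved cases.
#' @export
classify_stop <- function(cds) {
  if (nchar(cds) < 6L) stop("CDS too short to classify (need >= 6 nt)")
  cds <- toupper(cds)
  n <- nchar(cds)
  rem <- n %% 3L
  if (rem == 0L) {
    last <- substring(cds, n - 2L, n)
    if (last %in% c("TAA", "TAG"))
      return(list(stop = last, class = "complete", detail = NA_character_))
    return(list(stop = last, class = "unresolved",
                detail = "length divisible by 3 but no terminal TAA/TAG"))
  }
  if (rem == 1L) {
    last <- substring(cds, n, n)
    if (last == "T")
      return(list(stop = "T", class = "incomplete", detail = NA_character_))
    return(list(stop = last, class = "unresolved",
                detail = "frame remainder 1 but terminal base is not T"))
  }
  last <- substring(cds, n - 1L, n)
  if (last == "TA")
    return(list(stop = "TA", class = "incomplete", detail = NA_character_))
  list(stop = last, class = "unresolved",
       detail = "frame remainder 2 but terminal bases are not TA")
}

#' Start/stop codon report for all protein-coding genes
#'
#' @param genome A \code{mitogenome}.
#' @param table An \code{annotation_table}.
#' @return Data.frame with one row per PCG: gene, start_codon, start_class,
#'   stop_codon, stop_class.
#' @export
start_stop_report <- function(genome, table) {
  idx <- which(table$cls == "PCG")
  rows <- lapply(idx, function(i) {
    cds <- extract_gene_sequence(genome, table[i, ])
    st <- classify_start(cds)
    sp <- classify_stop(cds)
    data.frame(gene = table$gene[i], start_codon = st$codon,
               start_class = st$class, stop_codon = sp$stop,
               stop_class = sp$class, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Codon census over a set of CDSs
#'
#' Counts the 62 sense codons across in-frame CDSs.  Incomplete stop
#' remnants (a trailing 1-2 nt) are excluded; a trailing complete stop
#' codon is excluded from the sense counts and tallied separately.  An
#' internal in-frame stop raises an error naming the offending CDS.
#'
#' @param cds_list Named (or unnamed) character vector/list of CDS strings.
#' @param code Genetic code from \code{invertebrate_mito_code()}.
#' @return An object of class \code{"codon_usage_table"}: list with
#'   \code{counts} (named over 62 sense codons), \code{per_thousand},
#'   \code{rscu}, \code{missing}, \code{aa_totals} (family label ->
#'   count), \code{stop_counts}, \code{total}.
#' @export
codon_census <- function(cds_list, code = invertebrate_mito_code()) {
  cds_list <- as.list(cds_list)
  nm <- names(cds_list)
  if (is.null(nm)) nm <- paste0("cds", seq_along(cds_list))
  sense <- names(code$family)
  counts <- stats::setNames(integer(length(sense)), sense)
  stop_counts <- stats::setNames(integer(length(code$stops)), code$stops)
  for (j in seq_along(cds_list)) {
    cds <- toupper(cds_list[[j]])
    cods <- split_codons(cds)     # drops any incomplete-stop remnant
    if (length(cods) == 0L) next
    is_stop <- cods %in% code$stops
    if (any(is_stop[-length(cods)]))
      stop("internal in-frame stop codon in ", nm[j], " at codon ",
           which(is_stop[-length(cods)])[1])
    if (is_stop[length(cods)]) {
      stop_counts[cods[length(cods)]] <- stop_counts[cods[length(cods)]] + 1L
      cods <- cods[-length(cods)]
    }
    tab <- table(factor(cods, levels = sense))
    counts <- counts + as.integer(tab)
  }
  total <- sum(counts)
  per_thousand <- if (total > 0) 1000 * counts / total else counts * NA_real_
  aa_totals <- vapply(code$families, function(cs) sum(counts[cs]), numeric(1))
  tbl <- structure(list(counts = counts, per_thousand = per_thousand,
                        rscu = NULL, missing = sense[counts == 0L],
                        aa_totals = aa_totals, stop_counts = stop_counts,
                        total = total), class = "codon_usage_table")
  tbl$rscu <- rscu(tbl, code)
  tbl
}

#' Relative synonymous codon usage
#'
#' Standard definition: a codon's count divided by the mean count of its
#' synonymous family, \code{RSCU(c) = count(c) * |family| / sum(family)}.
#' Families with zero total usage yield \code{NA} for all members.  Stop
#' codons are excluded from all families.
#'
#' @param table A \code{codon_usage_table}.
#' @param code Genetic code from \code{invertebrate_mito_code()}.
#' @return Named numeric vector of RSCU values over the 62 sense codons.
#' @export
rscu <- function(table, code = invertebrate_mito_code()) {
  counts <- table$counts
  out <- stats::setNames(rep(NA_real_, length(counts)), names(counts))
  for (cs in code$families) {
    fam_total <- sum(counts[cs])
    out[cs] <- if (fam_total == 0L) NA_real_
               else counts[cs] * length(cs) / fam_total
  }
  out
}

#' Rank amino acids by usage
#'
#' @param table A \code{codon_usage_table}.
#' @return Data.frame of (aa, count) sorted by descending count, ties broken
#'   alphabetically; a logical \code{tied} column flags tied counts.
#' @export
rank_amino_acids <- function(table) {
  aa <- table$aa_totals
  ord <- order(-aa, names(aa))
  counts <- aa[ord]
  tied <- counts %in% counts[duplicated(counts)]
  data.frame(aa = names(counts), count = unname(counts), tied = tied,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Codon usage of the protein-coding genes of an annotated genome
#'
#' Convenience wrapper: extracts all PCG sequences and runs
#' \code{\link{codon_census}}.
#'
#' @param genome A \code{mitogenome}.
#' @param table An \code{annotation_table}.
#' @param code Genetic code.
#' @return A \code{codon_usage_table}.
#' @export
genome_codon_usage <- function(genome, table, code = invertebrate_mito_code()) {
  idx <- which(table$cls == "PCG")
  if (length(idx) == 0L) stop("no protein-coding genes in annotation")
  cds <- lapply(idx, function(i) extract_gene_sequence(genome, table[i, ]))
  names(cds) <- table$gene[idx]
  codon_census(cds, code)
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat(sprintf("<codon_usage_table> %d sense codons counted; %d missing codon(s)\n",
              x$total, length(x$missing)))
  top <- utils::head(rank_amino_acids(x), 6)
  cat("most used amino acids:",
      paste(sprintf("%s (%d)", top$aa, top$count), collapse = ", "), "\n")
  invisible(x)
}
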