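# -- sequence utilities -------------------------------------------------------

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Reverse complement of a DNA string
#'
#' Plain-character reverse complement over the alphabet A/C/G/T/N.
#'
#' @param seq A single DNA string.
#' @return The reverse complement as a character scalar.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

seq_chars <- function(seq) strsplit(toupper(seq), "", fixed = TRUE)[[1]]

# -- Mitogenome ---------------------------------------------------------------

#' Construct a mitogenome object
#'
#' A minimal container for a (typically circular) mitochondrial genome
#' sequence: identifier, DNA string over A/C/G/T/N, and circularity flag.
#'
#' @param id Sequence identifier.
#' @param seq DNA string (A/C/G/T/N, case-insensitive).
#' @param circular Logical; is the molecule circular?
#' @return An object of class \code{"mitogenome"} with fields \code{id},
#'   \code{seq}, \code{length}, \code{circular}.
#' @export
mitogenome <- function(id, seq, circular = TRUE) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("genome sequence must be non-empty")
  bad <- setdiff(unique(seq_chars(seq)), DNA_ALPHABET)
  if (length(bad) > 0L)
    stop("genome sequence contains characters outside A/C/G/T/N: ",
         paste(bad, collapse = ", "))
  structure(list(id = id, seq = seq, length = nchar(seq),
                 circular = isTRUE(circular)),
            class = "mitogenome")
}

#' @export
print.mitogenome <- function(x, ...) {
  cat(sprintf("<mitogenome> %s: %d bp, %s\n", x$id, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Read a single-record FASTA file as a mitogenome
#'
#' @param path Path to a FASTA file with exactly one record.
#' @param circular Logical; circularity flag to attach.
#' @return A \code{mitogenome}.
#' @export
read_genome_fasta <- function(path, circular = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L)
    stop("expected exactly one FASTA record, found ", length(ss))
  mitogenome(id = sub("\\s.*$", "", names(ss)[1]),
             seq = as.character(ss[[1]]), circular = circular)
}

#' Write a mitogenome to FASTA
#'
#' @param genome A \code{mitogenome}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$seq)
  names(ss) <- genome$id
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

# -- gene name normalization --------------------------------------------------

# Common GenBank aliases -> controlled vocabulary used throughout the package.
GENE_ALIASES <- c(
  ND1 = "nad1", ND2 = "nad2", ND3 = "nad3", ND4 = "nad4", ND4L = "nad4L",
  ND5 = "nad5", ND6 = "nad6",
  COI = "cox1", COII = "cox2", COIII = "cox3",
  COX1 = "cox1", COX2 = "cox2", COX3 = "cox3",
  CYTB = "cob", COB = "cob", `CYT B` = "cob",
  ATP6 = "atp6", ATP8 = "atp8", ATPASE6 = "atp6", ATPASE8 = "atp8",
  `16S` = "rrnL", `12S` = "rrnS", `L-RRNA` = "rrnL", `S-RRNA` = "rrnS",
  RRNL = "rrnL", RRNS = "rrnS",
  `A+T-RICH REGION` = "control_region", `D-LOOP` = "control_region",
  `CONTROL REGION` = "control_region"
)

PCG_NAMES <- c("nad2", "cox1", "cox2", "atp8", "atp6", "cox3", "nad3",
               "nad5", "nad4", "nad4L", "nad6", "cob", "nad1")
RRNA_NAMES <- c("rrnL", "rrnS")

KNOWN_GENES <- c(PCG_NAMES, RRNA_NAMES, "control_region",
                 paste0("trn", c("A", "C", "D", "E", "F", "G", "H", "I", "K",
                                 "M", "N", "P", "Q", "R", "T", "V", "W", "Y")),
                 "trnL1", "trnL2", "trnS1", "trnS2")

#' Normalize a gene name to the package vocabulary
#'
#' Maps common GenBank-style aliases (ND1, COI, 16S, D-loop, ...) onto the
#' controlled names nad1..nad6/nad4L, cox1..cox3, atp6/atp8, cob, rrnL/rrnS,
#' trnX, control_region.  Isoacceptor decorations such as "trnL2(UUR)" are
#' stripped to "trnL2".  Unknown names are returned unchanged.
#'
#' @param name Character vector of gene names.
#' @return Character vector of normalized names.
#' @export
normalize_gene_name <- function(name) {
  vapply(name, function(nm) {
    raw <- trimws(nm)
    key <- toupper(raw)
    if (key %in% names(GENE_ALIASES)) return(unname(GENE_ALIASES[[key]]))
    # strip isoacceptor parenthetical: trnS1(AGN) -> trnS1
    stripped <- sub("\\s*\\([A-Za-z]+\\)\\s*$", "", raw)
    if (grepl("^trn", stripped, ignore.case = TRUE))
      return(paste0("trn", sub("^trn", "", stripped, ignore.case = TRUE)))
    low <- tolower(stripped)
    if (low %in% KNOWN_GENES) return(low)
    if (stripped %in% KNOWN_GENES) return(stripped)
    stripped
  }, character(1), USE.NAMES = FALSE)
}

# -- AnnotationTable ----------------------------------------------------------

FEATURE_CLASSES <- c("PCG", "tRNA", "rRNA", "control")

#' Construct an annotation table
#'
#' An ordered table of 1-based inclusive gene features (the in-memory form
#' of a mitogenome feature table).  Origin-spanning features on a circular
#' genome are expressed with \code{end > genome_length}.
#'
#' @param features A data.frame with columns \code{gene}, \code{cls}
#'   (PCG/tRNA/rRNA/control), \code{strand} ("major"/"minor"), \code{start},
#'   \code{end}; optionally \code{size} (declared size as printed),
#'   \code{anticodon}, \code{start_codon}, \code{stop_codon},
#'   \code{intergenic} (declared gap to the next listed feature).
#' @param genome_length Positive integer length of the genome.
#' @param source Free-text provenance label.
#' @return An object of class \code{"annotation_table"} (a data.frame with
#'   attributes \code{genome_length} and \code{source}).
#' @export
annotation_table <- function(features, genome_length, source = "manual") {
  stopifnot(is.data.frame(features), genome_length > 0)
  req <- c("gene", "cls", "strand", "start", "end")
  miss <- setdiff(req, names(features))
  if (length(miss) > 0L)
    stop("missing required columns: ", paste(miss, collapse = ", "))
  opt <- c("size", "anticodon", "start_codon", "stop_codon", "intergenic")
  for (cc in opt) if (!cc %in% names(features)) features[[cc]] <- NA
  features$gene <- as.character(features$gene)
  features$cls <- as.character(features$cls)
  features$strand <- as.character(features$strand)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features$size <- as.integer(features$size)
  features$intergenic <- suppressWarnings(as.integer(features$intergenic))

  if (anyDuplicated(features$gene))
    stop("duplicate gene name(s): ",
         paste(unique(features$gene[duplicated(features$gene)]), collapse = ", "))
  if (!all(features$cls %in% FEATURE_CLASSES))
    stop("unknown feature class: ",
         paste(setdiff(features$cls, FEATURE_CLASSES), collapse = ", "))
  if (!all(features$strand %in% c("major", "minor")))
    stop("strand must be 'major' or 'minor'")
  if (any(features$start < 1L) || any(features$start > genome_length))
    stop("feature start outside [1, genome_length]")
  if (any(features$end < features$start))
    stop("feature end < start (origin-spanning features use end > genome_length)")
  if (sum(features$cls == "control") > 1L)
    stop("at most one control-region feature allowed")
  tr <- features$cls == "tRNA"
  if (any(tr & (is.na(features$anticodon) | !nzchar(features$anticodon))))
    stop("tRNA features require an anticodon")
  ord <- order(features$start, features$end)
  if (!identical(ord, seq_len(nrow(features))))
    features <- features[ord, , drop = FALSE]
  rownames(features) <- NULL
  structure(features, genome_length = as.integer(genome_length),
            source = source,
            class = c("annotation_table", "data.frame"))
}

#' @export
print.annotation_table <- function(x, ...) {
  cat(sprintf("<annotation_table> %d features on a %d bp genome (%s)\n",
              nrow(x), attr(x, "genome_length"), attr(x, "source")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Feature-class census of an annotation table
#'
#' @param table An \code{annotation_table}.
#' @return Named integer vector with counts for PCG, tRNA, rRNA, control.
#' @export
class_census <- function(table) {
  vapply(FEATURE_CLASSES, function(k) sum(table$cls == k), integer(1))
}

# -- readers / writers --------------------------------------------------------

#' Read a feature table (TSV or GenBank-flat-file subset)
#'
#' The TSV dialect expects a header with at least
#' \code{gene class direction start end}; optional columns
#' \code{size anticodon start_codon stop_codon intergenic} are preserved.
#' Direction is F (major) or R (minor); "." or blank is treated as major
#' (used by control regions printed without a direction).  The GenBank
#' dialect parses LOCUS for the genome length and the FEATURES block
#' (CDS, tRNA, rRNA, misc_feature, D-loop) with \code{complement(a..b)}
#' locations for minor-strand features.
#'
#' @param path File path.
#' @param dialect "tsv" or "genbank".
#' @return A validated \code{annotation_table}.
#' @export
read_feature_table <- function(path, dialect = c("tsv", "genbank")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (dialect == "tsv") read_feature_tsv(path) else read_feature_genbank(path)
}

read_feature_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("parse error: empty or header-only table: ", path)
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          colClasses = "character", check.names = FALSE,
                          strip.white = TRUE)
  names(df) <- tolower(names(df))
  if ("direction" %in% names(df) && !"strand" %in% names(df))
    df$strand <- df$direction
  req <- c("gene", "direction", "start", "end")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L)
    stop("parse error: missing column(s) ", paste(miss, collapse = ", "))
  n_start <- suppressWarnings(as.integer(gsub(",", "", df$start)))
  n_end <- suppressWarnings(as.integer(gsub(",", "", df$end)))
  bad <- which(is.na(n_start) | is.na(n_end))
  if (length(bad) > 0L)
    stop("parse error: malformed coordinates at line ", bad[1] + 1L,
         " (gene ", df$gene[bad[1]], ")")
  df$start <- n_start
  df$end <- n_end
  df$gene <- normalize_gene_name(df$gene)
  dir <- toupper(trimws(df$strand %||% df$direction))
  df$strand <- ifelse(dir == "R", "minor", "major")
  if (!"class" %in% names(df)) {
    df$class <- infer_class(df$gene)
  }
  df$cls <- trimws(df$class)
  blank <- !nzchar(df$cls) | df$cls == "."
  df$cls[blank] <- infer_class(df$gene[blank])
  for (cc in c("size", "intergenic"))
    if (cc %in% names(df))
      df[[cc]] <- suppressWarnings(as.integer(gsub(",", "", df[[cc]])))
  for (cc in c("anticodon", "start_codon", "stop_codon"))
    if (cc %in% names(df)) {
      v <- toupper(trimws(df[[cc]]))
      v[v %in% c("", "-", ".", "—")] <- NA
      df[[cc]] <- v
    }
  # genome length: largest coordinate seen; callers with an origin-spanning
  # last feature can override the attribute afterwards.
  glen <- max(df$end)
  keep <- intersect(c("gene", "cls", "strand", "start", "end", "size",
                      "anticodon", "start_codon", "stop_codon", "intergenic"),
                    names(df))
  annotation_table(df[keep], genome_length = glen, source = path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

infer_class <- function(gene) {
  ifelse(gene %in% PCG_NAMES, "PCG",
         ifelse(gene %in% RRNA_NAMES, "rRNA",
                ifelse(grepl("^trn", gene), "tRNA",
                       ifelse(gene == "control_region", "control", "PCG"))))
}

read_feature_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("parse error: empty file: ", path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  glen <- NA_integer_
  if (length(locus) > 0L) {
    m <- regmatches(locus[1], regexpr("[0-9]+(?=\\s+bp)", locus[1], perl = TRUE))
    if (length(m) > 0L) glen <- as.integer(m)
  }
  fstart <- grep("^FEATURES", lines)
  if (length(fstart) == 0L) stop("parse error: no FEATURES block in ", path)
  fend <- grep("^(ORIGIN|//)", lines)
  fend <- if (length(fend) > 0L) min(fend[fend > fstart[1]]) - 1L else length(lines)
  flines <- lines[(fstart[1] + 1L):fend]

  keytypes <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                misc_feature = "control", D_loop = "control",
                `D-loop` = "control")
  feats <- list()
  cur <- NULL
  for (ln in flines) {
    if (grepl("^\\s{1,10}\\S", ln) && !grepl("^\\s*/", ln)) {
      # new feature key line
      key <- sub("^\\s*(\\S+)\\s.*$", "\\1", ln)
      loc <- sub("^\\s*\\S+\\s+", "", ln)
      if (key == "source" || !key %in% names(keytypes)) { cur <- NULL; next }
      minor <- grepl("complement", loc)
      nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
      if (length(nums) < 2L)
        stop("parse error: malformed location '", trimws(loc), "'")
      cur <- list(cls = unname(keytypes[key]),
                  strand = if (minor) "minor" else "major",
                  start = as.integer(nums[1]), end = as.integer(nums[2]),
                  gene = NA, anticodon = NA, size = NA,
                  start_codon = NA, stop_codon = NA)
      feats[[length(feats) + 1L]] <- cur
    } else if (!is.null(cur) && grepl("^\\s*/", ln)) {
      q <- trimws(ln)
      val <- sub('^/[a-z_]+="?([^"]*)"?$', "\\1", q)
      i <- length(feats)
      if (grepl("^/gene=", q) || grepl("^/product=", q)) {
        if (is.na(feats[[i]]$gene)) feats[[i]]$gene <- normalize_gene_name(val)
      } else if (grepl("^/anticodon=", q)) {
        feats[[i]]$anticodon <- toupper(val)
      } else if (grepl("^/note=", q)) {
        for (kv in strsplit(val, ";", fixed = TRUE)[[1]]) {
          kv <- trimws(kv)
          if (grepl("^declared_size=", kv))
            feats[[i]]$size <- as.integer(sub("^declared_size=", "", kv))
          if (grepl("^start_codon=", kv))
            feats[[i]]$start_codon <- sub("^start_codon=", "", kv)
          if (grepl("^stop_codon=", kv))
            feats[[i]]$stop_codon <- sub("^stop_codon=", "", kv)
        }
      }
    }
  }
  if (length(feats) == 0L) stop("parse error: no features parsed from ", path)
  df <- do.call(rbind, lapply(feats, function(f)
    data.frame(gene = f$gene, cls = f$cls, strand = f$strand,
               start = f$start, end = f$end, size = f$size,
               anticodon = f$anticodon, start_codon = f$start_codon,
               stop_codon = f$stop_codon, stringsAsFactors = FALSE)))
  ctrl <- df$cls == "control" & is.na(df$gene)
  df$gene[ctrl] <- "control_region"
  if (is.na(glen)) glen <- max(df$end)
  annotation_table(df, genome_length = glen, source = path)
}

#' Write a feature table (TSV or GenBank-flat-file subset)
#'
#' Both dialects round-trip all fields through \code{read_feature_table};
#' the GenBank writer stores declared size and start/stop codons in a
#' \code{/note} qualifier.
#'
#' @param table An \code{annotation_table}.
#' @param path Output path.
#' @param dialect "tsv" or "genbank".
#' @return Invisibly, \code{path}.
#' @export
write_feature_table <- function(table, path, dialect = c("tsv", "genbank")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- as.data.frame(table)
    df$direction <- ifelse(df$strand == "minor", "R", "F")
    df$class <- df$cls
    cols <- c("gene", "class", "direction", "start", "end", "size",
              "anticodon", "start_codon", "stop_codon")
    if (any(!is.na(df$intergenic))) cols <- c(cols, "intergenic")
    out <- df[cols]
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  } else {
    glen <- attr(table, "genome_length")
    keymap <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                control = "misc_feature")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("LOCUS       %s %d bp    DNA     circular",
                       "annotation", glen), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    for (i in seq_len(nrow(table))) {
      f <- table[i, ]
      loc <- sprintf("%d..%d", f$start, f$end)
      if (f$strand == "minor") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     %-16s%s", keymap[[f$cls]], loc), con)
      writeLines(sprintf('                     /gene="%s"', f$gene), con)
      if (!is.na(f$anticodon))
        writeLines(sprintf('                     /anticodon="%s"', f$anticodon), con)
      notes <- character(0)
      if (!is.na(f$size)) notes <- c(notes, sprintf("declared_size=%d", f$size))
      if (!is.na(f$start_codon))
        notes <- c(notes, sprintf("start_codon=%s", f$start_codon))
      if (!is.na(f$stop_codon))
        notes <- c(notes, sprintf("stop_codon=%s", f$stop_codon))
      if (length(notes) > 0L)
        writeLines(sprintf('                     /note="%s"',
                           paste(notes, collapse = ";")), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

# -- coordinate arithmetic ----------------------------------------------------

#' Extract the (gene-strand) sequence of a feature
#'
#' Returns the major-strand slice \code{[start..end]} (1-based inclusive);
#' minor-strand features are reverse-complemented.  On a circular genome a
#' feature whose end exceeds the genome length wraps through position 1.
#'
#' @param genome A \code{mitogenome}.
#' @param feature A single-row slice of an \code{annotation_table}, or any
#'   list with fields \code{start}, \code{end}, \code{strand}.
#' @return The feature sequence (gene orientation) as a character scalar.
#' @export
extract_gene_sequence <- function(genome, feature) {
  start <- as.integer(feature$start)
  end <- as.integer(feature$end)
  if (is.na(start) || is.na(end) || start < 1L || end < start)
    stop("invalid feature coordinates")
  L <- genome$length
  if (end > L && !genome$circular)
    stop("coordinate error: feature end ", end,
         " exceeds length ", L, " of a non-circular genome")
  if (end <= L) {
    s <- substring(genome$seq, start, end)
  } else {
    if (end - start + 1L > L) stop("coordinate error: feature longer than genome")
    s <- paste0(substring(genome$seq, start, L),
                substring(genome$seq, 1L, end - L))
  }
  if (identical(feature$strand, "minor")) revcomp(s) else s
}

#' Validate an annotation table
#'
#' Reports, without raising: (i) declared-size vs coordinate-span mismatches,
#' (ii) features running past the genome end on a non-wrapping (linear)
#' genome, and (iii) a feature-class census that deviates from the canonical
#' 13 PCG / 22 tRNA / 2 rRNA / 1 control region.
#'
#' @param table An \code{annotation_table}.
#' @param circular Logical; whether origin-spanning coordinates are allowed.
#' @return A data.frame of violation records (zero rows when clean) with
#'   columns \code{type}, \code{gene}, \code{detail}.
#' @export
validate_annotation <- function(table, circular = TRUE) {
  glen <- attr(table, "genome_length")
  out <- list()
  span <- table$end - table$start + 1L
  has_size <- !is.na(table$size)
  bad <- which(has_size & table$size != span)
  for (i in bad)
    out[[length(out) + 1L]] <- data.frame(
      type = "size_mismatch", gene = table$gene[i],
      detail = sprintf("coordinates %d-%d imply %d, declared %d",
                       table$start[i], table$end[i], span[i], table$size[i]),
      stringsAsFactors = FALSE)
  over <- which(table$end > glen)
  for (i in over) {
    if (!circular)
      out[[length(out) + 1L]] <- data.frame(
        type = "exceeds_length", gene = table$gene[i],
        detail = sprintf("end %d > genome length %d on a linear genome",
                         table$end[i], glen), stringsAsFactors = FALSE)
    else
      out[[length(out) + 1L]] <- data.frame(
        type = "origin_spanning", gene = table$gene[i],
        detail = sprintf("end %d > genome length %d (wraps through origin)",
                         table$end[i], glen), stringsAsFactors = FALSE)
  }
  expected <- c(PCG = 13L, tRNA = 22L, rRNA = 2L, control = 1L)
  census <- class_census(table)
  for (k in names(expected))
    if (census[[k]] != expected[[k]])
      out[[length(out) + 1L]] <- data.frame(
        type = "census", gene = NA_character_,
        detail = sprintf("%s count %d, expected %d", k, census[[k]],
                         expected[[k]]), stringsAsFactors = FALSE)
  unknown <- setdiff(table$gene, KNOWN_GENES)
  for (g in unknown)
    out[[length(out) + 1L]] <- data.frame(
      type = "unknown_gene", gene = g, detail = "name outside vocabulary",
      stringsAsFactors = FALSE)
  if (length(out) == 0L)
    return(data.frame(type = character(0), gene = character(0),
                      detail = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
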