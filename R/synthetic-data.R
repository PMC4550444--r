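# Seeded synthetic mitogenome generator.
#
# Builds a fully annotated circular mitogenome gene-by-gene with the
# structural and statistical properties the analysis modules assume --
# a ~15.4 kb A+T-rich molecule with 13 PCGs / 22 tRNAs / 2 rRNAs / one
# control region, the trnM-trnI-trnQ arrangement, real overlap geometry
# (including the 7 bp atp8/atp6 overlap), incomplete stop codons, planted
# cloverleaf tRNAs with a recorded wobble/mismatch plan, and a control
# region carrying an origin motif, poly-T tract, (AT)n microsatellite and
# poly-A element.  Every planted feature is recorded in a machine-readable
# ground-truth object, and generation is bit-reproducible under a seed.

COMP_BASE <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

rand_bases <- function(n, at) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2))
}

#' Default gene template for the synthetic mitogenome
#'
#' The ordered 38-feature layout (gene, class, strand, coordinates,
#' anticodons, start/stop plan) of a typical lepidopteran mitogenome with
#' the derived trnM-trnI-trnQ arrangement.  Coordinates are internally
#' consistent (declared sizes equal coordinate spans) on a 15,370 bp
#' circle.
#'
#' @return A data.frame usable as the \code{template} field of
#'   \code{\link{sim_params}}.
#' @export
default_gene_template <- function() {
  txt <- "gene cls strand start end anticodon start_codon stop_codon
trnM tRNA major 1 68 CAT NA NA
trnI tRNA major 69 134 GAT NA NA
trnQ tRNA minor 132 200 TTG NA NA
nad2 PCG major 258 1271 NA ATT TAA
trnW tRNA major 1289 1361 TCA NA NA
trnC tRNA minor 1354 1422 GCA NA NA
trnY tRNA minor 1425 1490 GTA NA NA
cox1 PCG major 1496 3026 NA CGA T
trnL2 tRNA major 3027 3093 TAA NA NA
cox2 PCG major 3094 3775 NA ATG T
trnK tRNA major 3776 3846 CTT NA NA
trnD tRNA major 3846 3911 GTC NA NA
atp8 PCG major 3912 4070 NA ATC TAA
atp6 PCG major 4064 4741 NA ATG TAA
cox3 PCG major 4741 5529 NA ATG TAA
trnG tRNA major 5532 5597 TCC NA NA
nad3 PCG major 5598 5951 NA ATC TAA
trnA tRNA major 6005 6074 TGC NA NA
trnR tRNA major 6074 6137 TCG NA NA
trnN tRNA major 6141 6205 GTT NA NA
trnS1 tRNA major 6207 6276 GCT NA NA
trnE tRNA major 6278 6345 TTC NA NA
trnF tRNA minor 6344 6410 GAA NA NA
nad5 PCG minor 6409 8152 NA ATT T
trnH tRNA minor 8151 8216 GTG NA NA
nad4 PCG minor 8215 9557 NA ATA TA
nad4L PCG minor 9554 9841 NA ATT TAA
trnT tRNA major 9856 9920 TGT NA NA
trnP tRNA minor 9921 9985 TGG NA NA
nad6 PCG major 9994 10524 NA ATT TAA
cob PCG major 10539 11687 NA ATG TAA
trnS2 tRNA major 11692 11758 TGA NA NA
nad1 PCG minor 11777 12716 NA ATT T
trnL1 tRNA minor 12724 12794 TAG NA NA
rrnL rRNA minor 12795 14152 NA NA NA
trnV tRNA minor 14153 14219 TAC NA NA
rrnS rRNA minor 14220 14998 NA NA NA
control_region control major 14999 15370 NA NA NA"
  df <- utils::read.table(text = txt, header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "NA")
  df
}

# default wobble/mismatch plant plan: one G-U in ten tRNAs (D stem, or the
# anticodon stem for the D-armless trnS1), plus a U-U mismatch in the
# acceptor stem of trnA
default_trna_plants <- function() {
  gu_d <- c("trnA", "trnC", "trnQ", "trnG", "trnL1", "trnL2", "trnF",
            "trnP", "trnV")
  plants <- lapply(gu_d, function(g)
    list(trna = g, stem = "DHU", pair = 2L, type = "GU"))
  plants <- c(plants, list(
    list(trna = "trnS1", stem = "anticodon", pair = 2L, type = "GU"),
    list(trna = "trnA", stem = "acceptor", pair = 4L, type = "UU")))
  plants
}

#' Simulation parameters for the synthetic mitogenome
#'
#' The defaults encode the study conditions the generator emulates: a
#' ~15.4 kb circle at ~80\% A+T, partition-typical A+T levels, an
#' AT-biased codon distribution, the canonical start/stop plan (CGA start
#' for cox1, incomplete T/T/TA stops), ten planted G-U wobble pairs plus a
#' U-U acceptor mismatch, and a control region with ATAGA + 18 bp poly-T +
#' (AT)8 + poly-A.
#'
#' @param seed Integer RNG seed.
#' @param template Gene template (see \code{\link{default_gene_template}}).
#' @param trna_at,rrna_at,spacer_at,cr_at A+T fraction used for tRNA
#'   loops/stems, rRNAs, intergenic spacers and the control region.
#' @param gamma Codon-weight exponent: sense-codon weight is
#'   proportional to (A+T fraction of the codon)^gamma.
#' @param cr_plan List: \code{motif}, \code{poly_t} length, \code{at_copies}
#'   of the AT microsatellite, \code{poly_a} length, optional
#'   \code{repeats} (integer vector of unit lengths to plant as exact
#'   duplications, e.g. c(51)).
#' @param spacer_motif Motif planted in the trnS2-nad1 spacer.
#' @param trna_plants List of planted wobble/mismatch records
#'   (\code{trna}, \code{stem}, \code{pair}, \code{type} "GU"/"UU").
#' @return A list of validated parameters.
#' @export
sim_params <- function(seed = 1L, template = default_gene_template(),
                       trna_at = 0.82, rrna_at = 0.84, spacer_at = 0.94,
                       cr_at = 0.94, gamma = 2.5,
                       cr_plan = list(motif = "ATAGA", poly_t = 18L,
                                      at_copies = 8L, poly_a = 12L,
                                      repeats = integer(0)),
                       spacer_motif = "ATACTAA",
                       trna_plants = default_trna_plants()) {
  stopifnot(trna_at > 0, trna_at < 1, cr_at > 0, cr_at < 1, gamma >= 0)
  glen <- max(template$end)
  list(seed = as.integer(seed), template = template, genome_length = glen,
       trna_at = trna_at, rrna_at = rrna_at, spacer_at = spacer_at,
       cr_at = cr_at, gamma = gamma, cr_plan = cr_plan,
       spacer_motif = spacer_motif, trna_plants = trna_plants)
}

# -- gene-space <-> genome-space helpers -------------------------------------

gene_idx <- function(f, k) if (f$strand == "minor") f$end - k + 1L else f$start + k - 1L

read_gene_slice <- function(gv, f) {
  k <- seq_len(f$end - f$start + 1L)
  b <- gv[gene_idx(f, k)]
  if (f$strand == "minor") unname(COMP_BASE[b]) else b
}

# write gene-space bases into the genome vector; already-written positions
# must agree (they act as fixed constraints honoured by the caller)
write_gene <- function(gv, f, bases) {
  k <- seq_along(bases)
  idx <- gene_idx(f, k)
  out <- if (f$strand == "minor") unname(COMP_BASE[bases]) else bases
  ex <- !is.na(gv[idx])
  if (any(ex & gv[idx] != out))
    stop("inconsistent plan: conflicting bases for ", f$gene)
  gv[idx] <- out
  gv
}

# impose a gene-space triplet/token at given gene positions as constraints
impose_gene_bases <- function(gv, f, positions, bases) {
  idx <- gene_idx(f, positions)
  out <- if (f$strand == "minor") unname(COMP_BASE[bases]) else bases
  ex <- !is.na(gv[idx])
  if (any(ex & gv[idx] != out))
    stop("inconsistent plan: start/stop imposition conflict at ", f$gene)
  gv[idx] <- out
  gv
}

# -- PCG generation -----------------------------------------------------------

sense_codon_info <- function(code) {
  sense <- names(code$family)
  chars <- do.call(rbind, strsplit(sense, ""))
  n_at <- rowSums(chars == "A" | chars == "T")
  list(codons = sense, chars = chars, n_at = n_at)
}

sample_sense_codon <- function(pattern, info, gamma) {
  ok <- rep(TRUE, length(info$codons))
  for (j in 1:3) if (!is.na(pattern[j])) ok <- ok & info$chars[, j] == pattern[j]
  cand <- which(ok)
  if (length(cand) == 0L)
    stop("inconsistent plan: no sense codon matches pattern ",
         paste(ifelse(is.na(pattern), ".", pattern), collapse = ""))
  if (length(cand) == 1L) return(info$codons[cand])
  w <- (info$n_at[cand] / 3)^gamma
  if (sum(w) <= 0) w <- rep(1, length(cand))
  info$codons[sample(cand, 1L, prob = w)]
}

generate_pcg <- function(gv, f, info, gamma) {
  len <- f$end - f$start + 1L
  n_cod <- len %/% 3L
  rem <- len %% 3L
  fixed <- read_gene_slice(gv, f)
  bases <- character(len)
  tally <- stats::setNames(integer(length(info$codons)), info$codons)
  for (ci in seq_len(n_cod)) {
    pos <- (3L * ci - 2L):(3L * ci)
    pat <- fixed[pos]
    if (ci == n_cod && rem == 0L) {
      # complete stop, already imposed as constraints
      if (anyNA(pat)) stop("stop codon not imposed for ", f$gene)
      bases[pos] <- pat
      next
    }
    cdn <- sample_sense_codon(pat, info, gamma)
    bases[pos] <- strsplit(cdn, "")[[1]]
    tally[cdn] <- tally[cdn] + 1L
  }
  if (rem > 0L) {
    pos <- (3L * n_cod + 1L):len
    pat <- fixed[pos]
    if (anyNA(pat)) stop("incomplete stop remnant not imposed for ", f$gene)
    bases[pos] <- pat
  }
  list(gv = write_gene(gv, f, bases), tally = tally)
}

# -- tRNA generation ----------------------------------------------------------

# deterministic boundary allocation for a planted tRNA of a given length
allocate_trna_boundaries <- function(n, d = 3L) {
  b <- list(a = 7L, s1 = if (d > 0L) 2L else 1L, d = as.integer(d),
            dl = if (d > 0L) 7L else 9L,
            s2 = 1L, v = 4L, t = 5L, tl = 7L, tail = 1L)
  used <- function(b) 2L * b$a + b$s1 + 2L * b$d + b$dl + b$s2 + 17L +
    b$v + 2L * b$t + b$tl + b$tail
  delta <- n - used(b)
  slots <- list(c("tl", 3L, 9L), c("dl", 3L, 13L), c("v", 1L, 9L),
                c("t", 2L, 5L), c("s1", 1L, 2L))
  for (s in slots) {
    if (delta == 0L) break
    nm <- s[1]; lo <- as.integer(s[2]); hi <- as.integer(s[3])
    mult <- if (nm == "t") 2L else 1L
    room <- if (delta > 0L) (hi - b[[nm]]) else (b[[nm]] - lo)
    take <- sign(delta) * min(abs(delta) %/% mult, room)
    b[[nm]] <- b[[nm]] + take
    delta <- delta - take * mult
  }
  if (delta != 0L)
    stop("cannot allocate cloverleaf boundaries for length ", n)
  b
}

trna_pair_table <- function(b, n) {
  p <- b$a + b$s1 + 1L
  u <- b$a + b$s1 + 2L * b$d + b$dl + b$s2 + 1L
  w <- u + 17L + b$v
  rows <- list()
  for (k in seq_len(b$a))
    rows[[length(rows) + 1L]] <- c(k, n - b$tail - k + 1L, "acceptor", k)
  if (b$d > 0L)
    for (k in seq_len(b$d))
      rows[[length(rows) + 1L]] <- c(p + k - 1L, p + 2L * b$d + b$dl - k, "DHU", k)
  for (k in 1:5)
    rows[[length(rows) + 1L]] <- c(u + k - 1L, u + 17L - k, "anticodon", k)
  for (k in seq_len(b$t))
    rows[[length(rows) + 1L]] <- c(w + k - 1L, w + 2L * b$t + b$tl - k, "T", k)
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("pos5", "pos3", "stem", "k")
  df$pos5 <- as.integer(df$pos5); df$pos3 <- as.integer(df$pos3)
  df$k <- as.integer(df$k)
  df
}

#' Generate a single planted cloverleaf tRNA sequence
#'
#' Builds a tRNA gene arm-by-arm at deterministic boundaries: stems are
#' Watson-Crick paired (A+T-biased), loops and spacers are random, the
#' anticodon occupies loop positions 3-5, and requested G-U wobble or
#' mismatch pairs are planted at recorded coordinates.  Positions listed
#' in \code{fixed} are honoured (used when the gene overlaps a neighbour).
#'
#' @param length Gene length in nt (must admit a cloverleaf; 60-80).
#' @param anticodon Anticodon triplet (DNA letters).
#' @param d_stem D-stem length (0 builds a D-arm-less tRNA whose DHU
#'   region is a plain loop).
#' @param fixed Optional named character vector: gene-space position ->
#'   base, treated as hard constraints.
#' @param plants List of plant records: \code{stem}, \code{pair} (index
#'   within stem), \code{type} ("GU" or "UU").
#' @param at A+T fraction for random draws.
#' @return List with \code{seq}, \code{boundaries}, \code{pairs} (the
#'   planted pair table with realized types), \code{plants} (records with
#'   realized positions; a plant whose site was constrained by
#'   \code{fixed} is dropped with a note).
#' @export
generate_trna <- function(length, anticodon, d_stem = 3L, fixed = NULL,
                          plants = list(), at = 0.82) {
  b <- allocate_trna_boundaries(length, d_stem)
  n <- length
  ch <- rep(NA_character_, n)
  if (!is.null(fixed) && length(fixed) > 0L)
    ch[as.integer(names(fixed))] <- unname(fixed)
  u <- b$a + b$s1 + 2L * b$d + b$dl + b$s2 + 1L
  ac_pos <- (u + 7L):(u + 9L)
  ac <- strsplit(toupper(anticodon), "")[[1]]
  if (any(!is.na(ch[ac_pos]) & ch[ac_pos] != ac))
    stop("anticodon conflicts with fixed bases")
  ch[ac_pos] <- ac
  pt <- trna_pair_table(b, n)
  pt$planted <- "WC"
  for (pl in plants) {
    hit <- which(pt$stem == pl$stem & pt$k == pl$pair)
    if (length(hit) != 1L) next
    i <- hit
    if (!is.na(ch[pt$pos5[i]]) || !is.na(ch[pt$pos3[i]])) next  # constrained
    pt$planted[i] <- pl$type
  }
  # fill stems; the 5' side alternates purine/pyrimidine so that one-step
  # shifted pairings cannot score (keeps the planted fold the optimum)
  for (stem in unique(pt$stem)) {
    rows <- which(pt$stem == stem)
    rows <- rows[order(pt$k[rows])]
    prev5 <- NA_character_
    prev5_2 <- NA_character_
    for (i in rows) {
      p5 <- pt$pos5[i]; p3 <- pt$pos3[i]
      b5 <- ch[p5]; b3 <- ch[p3]
      type <- pt$planted[i]
      if (type == "UU") {
        if (is.na(b5)) ch[p5] <- "T"
        if (is.na(b3)) ch[p3] <- "T"
      } else if (type == "GU") {
        if (is.na(b5) && is.na(b3)) {
          gu <- if (stats::runif(1) < 0.5) c("G", "T") else c("T", "G")
          ch[p5] <- gu[1]; ch[p3] <- gu[2]
        } else if (is.na(b5)) {
          ch[p5] <- if (b3 == "G") "T" else "G"
        } else if (is.na(b3)) {
          ch[p3] <- if (b5 == "G") "T" else "G"
        }
      } else {
        if (is.na(b5) && is.na(b3)) {
          pool <- setdiff(c("A", "T", "G", "C"), c(prev5, prev5_2))
          wts <- ifelse(pool %in% c("A", "T"), at / 2, (1 - at) / 2)
          ch[p5] <- sample(pool, 1L, prob = wts)
          ch[p3] <- unname(COMP_BASE[ch[p5]])
        } else if (is.na(b5)) {
          ch[p5] <- unname(COMP_BASE[b3])
        } else if (is.na(b3)) {
          ch[p3] <- unname(COMP_BASE[b5])
        }
      }
      prev5_2 <- prev5
      prev5 <- ch[p5]
    }
  }
  free <- which(is.na(ch))
  if (length(free) > 0L) ch[free] <- rand_bases(length(free), at)
  # keep the planted structure locally optimal for the folder:
  # the D region of a D-armless tRNA is an unpairable poly-A loop, and a
  # planted D stem must not be extendable into its loop boundary bases
  p <- b$a + b$s1 + 1L
  untouched <- if (is.null(fixed)) integer(0) else as.integer(names(fixed))
  if (b$d == 0L) {
    # D-armless: the whole D region plus its flanking spacers are poly-A,
    # which cannot pair with itself, so no spurious D stem can form
    dspan <- c((b$a + 1L):(p - 1L), p:(p + b$dl - 1L), p + b$dl)
    ch[setdiff(dspan, untouched)] <- "A"
  } else {
    lo <- p + b$d
    hi <- p + b$d + b$dl - 1L
    if (pair_type(ch[lo], ch[hi]) != "mismatch") {
      blocked <- c(COMP_BASE[[ch[lo]]],
                   if (ch[lo] == "G") "T" else if (ch[lo] == "T") "G")
      ch[hi] <- setdiff(c("A", "C", "G", "T"), blocked)[1]
    }
    # the spacer base between the D arm and the anticodon stem must not
    # pair with the bases a one-step stem extension would recruit
    if (b$s2 == 1L) {
      pairs_with <- list(A = "T", C = "G", G = c("C", "T"), T = c("A", "G"))
      s2pos <- p + 2L * b$d + b$dl
      if (!s2pos %in% untouched) {
        partners <- ch[c(p, p + b$d)]
        safe <- Filter(function(x) !any(partners %in% pairs_with[[x]]),
                       c("A", "C", "G", "T"))
        ch[s2pos] <- if (length(safe) > 0L) safe[1] else "C"
      }
      # a one-step D-stem extension into the spacers pairs the last
      # spacer-1 base with the spacer-2 base: force that to mismatch
      if (!(p - 1L) %in% untouched) {
        banned <- c(pairs_with[[ch[s2pos]]], ch[p], ch[p + 1L])
        safe <- setdiff(c("A", "C", "G", "T"), banned)
        if (length(safe) > 0L) {
          wts <- ifelse(safe %in% c("A", "T"), at / 2, (1 - at) / 2)
          ch[p - 1L] <- safe[sample.int(length(safe), 1L, prob = wts)]
        }
      }
    }
  }
  pt$type <- pair_type(ch[pt$pos5], ch[pt$pos3])
  list(seq = paste(ch, collapse = ""), boundaries = b, pairs = pt,
       plants = plants)
}

# -- control region -----------------------------------------------------------

generate_control_region <- function(len, plan, at) {
  rep_units <- plan$repeats %||% integer(0)
  rep_blocks <- lapply(rep_units, function(u) {
    unit <- paste(rand_bases(u, at), collapse = "")
    paste0("G", strrep(unit, 2L), "G")   # guards stop outside extension
  })
  rep_len <- sum(vapply(rep_blocks, nchar, integer(1)))
  core <- nchar(plan$motif) + plan$poly_t + 1L +   # ATAGA + T-run + guard
    (2L + 2L * plan$at_copies + 2L) +              # guarded (AT)n
    (1L + plan$poly_a + 1L)                        # guarded poly-A
  head_fill <- 30L
  tail_fill <- 8L
  slack <- len - core - rep_len - head_fill - tail_fill
  if (slack < 2L)
    stop("control region too short for the planted feature plan")
  f2 <- slack %/% 2L
  f3 <- slack - f2
  truth <- list()
  pieces <- character(0)
  pos <- 0L
  add <- function(s) { pieces[[length(pieces) + 1L]] <<- s; pos <<- pos + nchar(s) }
  add(paste(rand_bases(head_fill, at), collapse = ""))
  truth$motif <- list(motif = plan$motif, start = pos + 1L)
  add(plan$motif)
  truth$poly_t <- list(start = pos + 1L, length = plan$poly_t)
  add(strrep("T", plan$poly_t))
  add("A")                                        # stops the T run
  for (i in seq_along(rep_blocks)) {
    add(substring(rep_blocks[[i]], 1L, 1L))       # leading guard G
    truth$repeats <- c(truth$repeats, list(list(
      period = rep_units[i], start = pos + 1L, span = 2L * rep_units[i])))
    add(substring(rep_blocks[[i]], 2L, nchar(rep_blocks[[i]])))
  }
  add(paste(rand_bases(f2, at), collapse = ""))
  add("AA")                                       # blocks left AT extension
  truth$microsat <- list(unit = "AT", start = pos + 1L,
                         copies = plan$at_copies)
  add(strrep("AT", plan$at_copies))
  add("AA")                                       # blocks right AT extension
  add(paste(rand_bases(f3, at), collapse = ""))
  add("T")
  truth$poly_a <- list(start = pos + 1L, length = plan$poly_a)
  add(strrep("A", plan$poly_a))
  add("T")
  add(paste(rand_bases(tail_fill, at), collapse = ""))
  seq <- paste(pieces, collapse = "")
  stopifnot(nchar(seq) == len)
  list(seq = seq, truth = truth)
}

# -- main generator -----------------------------------------------------------

#' Generate a synthetic annotated mitogenome with ground truth
#'
#' See \code{\link{sim_params}} for the study conditions the defaults
#' encode.  Generation is deterministic under the seed: identical
#' parameters reproduce the genome, annotation and ground truth
#' bit-exactly.
#'
#' @param params Parameters from \code{\link{sim_params}}.
#' @return List with \code{genome} (a \code{mitogenome}), \code{table}
#'   (an \code{annotation_table} with sizes, anticodons, start/stop codons
#'   and coordinate-derived intergenic column), and \code{truth}: a list
#'   with \code{codon_tally} (per-PCG sense-codon counts), \code{trna}
#'   (per-tRNA boundaries, pair tables and plants), \code{cr} (planted
#'   control-region feature coordinates), \code{spacer_motif},
#'   \code{gaps} (true junction gaps) and \code{seed}.
#' @export
generate_mitogenome <- function(params = sim_params()) {
  set.seed(params$seed)
  tmpl <- params$template
  L <- params$genome_length
  code <- invertebrate_mito_code()
  info <- sense_codon_info(code)
  gv <- rep(NA_character_, L)

  feats <- lapply(seq_len(nrow(tmpl)), function(i) as.list(tmpl[i, ]))

  # overlap sanity: no planted overlap may consume a whole gene
  for (i in seq_len(length(feats) - 1L)) {
    gap <- feats[[i + 1L]]$start - feats[[i]]$end - 1L
    if (gap < 0L) {
      ov <- -gap
      len_i <- feats[[i]]$end - feats[[i]]$start + 1L
      len_j <- feats[[i + 1L]]$end - feats[[i + 1L]]$start + 1L
      if (ov >= len_i || ov >= len_j)
        stop("inconsistent plan: overlap of ", ov, " bp at ",
             feats[[i]]$gene, "/", feats[[i + 1L]]$gene,
             " exceeds a gene length")
    }
  }

  # impose every PCG start codon and stop token as genome constraints so
  # that overlapping neighbours are generated consistently
  for (f in feats) {
    if (f$cls != "PCG") next
    len <- f$end - f$start + 1L
    st <- strsplit(f$start_codon, "")[[1]]
    gv <- impose_gene_bases(gv, f, 1:3, st)
    sp <- strsplit(f$stop_codon, "")[[1]]
    gv <- impose_gene_bases(gv, f, (len - length(sp) + 1L):len, sp)
  }

  codon_tally <- list()
  trna_truth <- list()
  cr_truth <- NULL

  for (f in feats) {
    len <- f$end - f$start + 1L
    if (f$cls == "PCG") {
      res <- generate_pcg(gv, f, info, params$gamma)
      gv <- res$gv
      codon_tally[[f$gene]] <- res$tally
    } else if (f$cls == "tRNA") {
      fixed_b <- read_gene_slice(gv, f)
      fixed <- stats::setNames(fixed_b[!is.na(fixed_b)],
                               which(!is.na(fixed_b)))
      plants <- Filter(function(p) p$trna == f$gene, params$trna_plants)
      d_stem <- if (f$gene == "trnS1") 0L else 3L
      tr <- generate_trna(len, f$anticodon, d_stem = d_stem,
                          fixed = fixed, plants = plants,
                          at = params$trna_at)
      gv <- write_gene(gv, f, seq_chars(tr$seq))
      trna_truth[[f$gene]] <- list(boundaries = tr$boundaries,
                                   pairs = tr$pairs,
                                   anticodon = f$anticodon)
    } else if (f$cls == "rRNA") {
      fixed_b <- read_gene_slice(gv, f)
      bases <- ifelse(is.na(fixed_b), rand_bases(len, params$rrna_at),
                      fixed_b)
      gv <- write_gene(gv, f, bases)
    } else if (f$cls == "control") {
      cr <- generate_control_region(len, params$cr_plan, params$cr_at)
      gv <- write_gene(gv, f, seq_chars(cr$seq))
      cr_truth <- cr$truth
    }
  }

  # spacers: plant the conserved motif in the trnS2 -> nad1 spacer, then
  # fill every remaining position with A+T-rich sequence
  spacer_truth <- NULL
  i_s2 <- which(tmpl$gene == "trnS2")
  i_n1 <- which(tmpl$gene == "nad1")
  if (length(i_s2) == 1L && length(i_n1) == 1L && i_n1 == i_s2 + 1L) {
    gap_lo <- tmpl$end[i_s2] + 1L
    gap_hi <- tmpl$start[i_n1] - 1L
    motif <- params$spacer_motif
    if (gap_hi - gap_lo + 1L >= nchar(motif) + 2L) {
      off <- gap_lo + ((gap_hi - gap_lo + 1L - nchar(motif)) %/% 2L)
      idx <- off:(off + nchar(motif) - 1L)
      if (all(is.na(gv[idx]))) {
        gv[idx] <- strsplit(motif, "")[[1]]
        spacer_truth <- list(motif = motif, genome_start = off,
                             spacer_start = off - gap_lo + 1L)
      }
    }
  }
  free <- which(is.na(gv))
  if (length(free) > 0L) gv[free] <- rand_bases(length(free), params$spacer_at)

  genome <- mitogenome("synthetic_mitogenome", paste(gv, collapse = ""),
                       circular = TRUE)
  tab <- annotation_table(
    data.frame(gene = tmpl$gene, cls = tmpl$cls, strand = tmpl$strand,
               start = tmpl$start, end = tmpl$end,
               size = tmpl$end - tmpl$start + 1L,
               anticodon = tmpl$anticodon,
               start_codon = tmpl$start_codon, stop_codon = tmpl$stop_codon,
               intergenic = c(tmpl$start[-1L] - tmpl$end[-nrow(tmpl)] - 1L,
                              NA),
               stringsAsFactors = FALSE),
    genome_length = L, source = sprintf("synthetic(seed=%d)", params$seed))
  gaps <- tab$start[-1L] - tab$end[-nrow(tab)] - 1L
  truth <- list(codon_tally = codon_tally, trna = trna_truth, cr = cr_truth,
                spacer_motif = spacer_truth, gaps = gaps,
                seed = params$seed)
  list(genome = genome, table = tab, truth = truth)
}

# -- taxon families (tree mode) ----------------------------------------------

# Jukes-Cantor evolution of a sequence along one branch of expected
# substitutions/site b: each site changes with prob 3/4(1 - exp(-4b/3)),
# uniformly to one of the other three bases
evolve_jc <- function(seq, b) {
  if (b < 0) stop("branch length must be nonnegative")
  ch <- seq_chars(seq)
  p <- 0.75 * (1 - exp(-4 * b / 3))
  hit <- which(stats::runif(length(ch)) < p)
  if (length(hit) > 0L) {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    ch[hit] <- vapply(ch[hit], function(x)
      sample(alt[[x]], 1L), character(1))
  }
  paste(ch, collapse = "")
}

#' Generate a family of related synthetic mitogenomes along a tree
#'
#' Evolves the root synthetic genome along a (given or random) rooted
#' tree under the Jukes-Cantor model on all sites; annotation coordinates
#' are preserved across taxa, so per-gene sequences stay positionally
#' homologous.
#'
#' @param params Parameters from \code{\link{sim_params}} (seeds both the
#'   root genome and the evolution).
#' @param n_taxa Number of taxa for a random tree (ignored when
#'   \code{tree} is supplied).
#' @param tree Optional rooted \code{ape::phylo} with branch lengths in
#'   expected substitutions/site.
#' @return List with \code{genomes} (named list of \code{list(genome,
#'   table)}, ready for \code{\link{build_supermatrix}}) and \code{tree}
#'   (the true tree).
#' @export
generate_taxon_family <- function(params = sim_params(), n_taxa = 8L,
                                  tree = NULL) {
  root <- generate_mitogenome(params)
  if (is.null(tree)) {
    tree <- ape::rtree(n_taxa, br = function(n) stats::runif(n, 0.01, 0.08))
  }
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("branch length must be nonnegative")
  n_tip <- length(tree$tip.label)
  root_node <- n_tip + 1L
  seqs <- list()
  assign_seq <- function(node, seq) seqs[[as.character(node)]] <<- seq
  assign_seq(root_node, root$genome$seq)
  # preorder traversal
  edges <- tree$edge[order(tree$edge[, 1L]), , drop = FALSE]
  ord <- ape::reorder.phylo(tree, "cladewise")$edge
  for (e in seq_len(nrow(ord))) {
    parent <- ord[e, 1L]; child <- ord[e, 2L]
    bl <- tree$edge.length[which(tree$edge[, 1L] == parent &
                                   tree$edge[, 2L] == child)]
    seqs[[as.character(child)]] <-
      evolve_jc(seqs[[as.character(parent)]], bl)
  }
  genomes <- lapply(seq_len(n_tip), function(i) {
    g <- mitogenome(tree$tip.label[i], seqs[[as.character(i)]],
                    circular = TRUE)
    list(genome = g, table = root$table)
  })
  names(genomes) <- tree$tip.label
  list(genomes = genomes, tree = tree, root = root)
}
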