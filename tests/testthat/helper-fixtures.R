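# Shared fixtures and independent brute-force oracles used across tests.

extdata <- function(f) {
  p <- system.file("extdata", f, package = "mitochar")
  if (!nzchar(p)) p <- file.path("..", "..", "inst", "extdata", f)
  p
}

focal_table <- function() read_feature_table(extdata("table3_focal_annotation.tsv"))

composition_table <- function() {
  utils::read.delim(extdata("lepidoptera_composition.tsv"),
                    stringsAsFactors = FALSE)
}

random_genome <- function(len, seed = 1, at = 0.8) {
  set.seed(seed)
  paste(sample(c("A", "T", "G", "C"), len, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

# memoized default synthetic genome so many tests can share one build
synthetic_default <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_mitogenome(sim_params(seed = 1))
    cache
  }
})

# -- brute-force oracles ------------------------------------------------------

# quadratic perfect-microsatellite scanner: direct substring comparison
brute_microsatellites <- function(region, max_unit = 6L, min_copies = 5L) {
  region <- toupper(region)
  n <- nchar(region)
  hits <- list()
  for (u in seq_len(min(max_unit, n %/% 2L))) {
    i <- 1L
    while (i + u - 1L <= n) {
      unit <- substring(region, i, i + u - 1L)
      copies <- 1L
      while (i + (copies + 1L) * u - 1L <= n &&
             substring(region, i + copies * u,
                       i + (copies + 1L) * u - 1L) == unit)
        copies <- copies + 1L
      if (copies >= min_copies &&
          !(i > u && substring(region, i - u, i - 1L) == unit)) {
        # left-maximal; keep only primitive units
        prim <- TRUE
        for (p in seq_len(u - 1L)) {
          if (u %% p == 0L &&
              identical(unit, strrep(substring(unit, 1L, p), u %/% p))) {
            prim <- FALSE
            break
          }
        }
        if (prim) {
          k <- nchar(unit)
          rot <- vapply(seq_len(k), function(j)
            paste0(substring(unit, j, k), substring(unit, 1L, j - 1L)),
            character(1))
          hits[[length(hits) + 1L]] <- data.frame(
            unit = sort(rot)[1], copies = copies, start = i,
            span = copies * u, stringsAsFactors = FALSE)
        }
      }
      i <- i + 1L
    }
  }
  if (length(hits) == 0L)
    return(data.frame(unit = character(0), copies = integer(0),
                      start = integer(0), span = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  # same-unit hits overlapping by >= one unit length are phase variants of
  # a single perfect tract: keep the most-copied (then leftmost) phase
  keep <- rep(TRUE, nrow(out))
  u_len <- nchar(out$unit)
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(nrow(out))) {
      if (i == j || !keep[i]) next
      ov <- min(out$start[i] + out$span[i], out$start[j] + out$span[j]) -
        max(out$start[i], out$start[j])
      if (out$unit[i] == out$unit[j] && ov >= u_len[i] &&
          (out$copies[i] < out$copies[j] ||
             (out$copies[i] == out$copies[j] &&
                out$start[i] > out$start[j])))
        keep[i] <- FALSE
    }
  }
  out <- unique(out[keep, , drop = FALSE])
  out <- out[order(out$start, out$unit), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exact (identity-1) tandem repeats by direct run scanning: maximal
# intervals where region[k] == region[k + p] throughout, span >= 2p
brute_exact_tandem <- function(region, min_period = 10L) {
  region <- toupper(region)
  ch <- strsplit(region, "")[[1]]
  n <- length(ch)
  hits <- list()
  for (p in seq.int(min_period, max(min_period, n %/% 2L))) {
    if (2L * p > n) break
    i <- 1L
    while (i <= n - p) {
      if (ch[i] == ch[i + p]) {
        j <- i
        while (j < n - p && ch[j + 1L] == ch[j + 1L + p]) j <- j + 1L
        if (j - i + 1L >= p)
          hits[[length(hits) + 1L]] <- data.frame(
            period = p, start = i, span = j - i + 1L + p,
            stringsAsFactors = FALSE)
        i <- j + 1L
      }
      i <- i + 1L
    }
  }
  if (length(hits) == 0L)
    return(data.frame(period = integer(0), start = integer(0),
                      span = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

# independent plain-loop cloverleaf enumeration (oracle for fold scores)
brute_fold_score <- function(seq, params = fold_params()) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  psc <- function(x, y) {
    if ((x == "A" && y == "T") || (x == "T" && y == "A") ||
        (x == "G" && y == "C") || (x == "C" && y == "G")) return(params$wc)
    if ((x == "G" && y == "T") || (x == "T" && y == "G")) return(params$wobble)
    params$mismatch
  }
  best <- -Inf
  for (a in 6:7) for (s1 in 1:2) for (d in c(0L, 2:4)) for (dl in 3:13)
    for (s2 in 0:1) for (v in 1:params$var_max) for (t in 2:5)
      for (tl in 3:9) {
        tail <- n - (2L * a + s1 + 2L * d + dl + s2 + 17L + v + 2L * t + tl)
        if (tail < 0L || tail > 2L) next
        sc <- 0
        for (k in seq_len(a)) sc <- sc + psc(ch[k], ch[n - tail - k + 1L])
        p <- a + s1 + 1L
        if (d > 0L)
          for (k in seq_len(d)) sc <- sc + psc(ch[p + k - 1L],
                                               ch[p + 2L * d + dl - k])
        u <- a + s1 + 2L * d + dl + s2 + 1L
        for (k in 1:5) sc <- sc + psc(ch[u + k - 1L], ch[u + 17L - k])
        w <- u + 17L + v
        for (k in seq_len(t)) sc <- sc + psc(ch[w + k - 1L],
                                             ch[w + 2L * t + tl - k])
        if (sc > best) best <- sc
      }
  best
}

same_boundaries <- function(b1, b2) {
  all(vapply(c("a", "s1", "d", "dl", "s2", "v", "t", "tl", "tail"),
             function(k) identical(as.integer(b1[[k]]), as.integer(b2[[k]])),
             logical(1)))
}
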