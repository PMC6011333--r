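# Independent brute-force / closed-form oracles used to cross-check the
# package implementations. These deliberately share no code with R/.

BASES <- c("A", "C", "G", "T")

random_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

rc_chars <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
}

# --- nearest-neighbor Tm: direct re-summation from an independently typed
# copy of the unified parameter table (only the 10 unique duplexes; other
# dinucleotides resolved through the reverse-complement identity)
oracle_tm <- function(seq, conc = 1e-6, salt = 0.05) {
  tab <- list(  # dinucleotide -> c(dH kcal/mol, dS cal/mol/K)
    AA = c(-7.9, -22.2), AT = c(-7.2, -20.4), TA = c(-7.2, -21.3),
    CA = c(-8.5, -22.7), GT = c(-8.4, -22.4), CT = c(-7.8, -21.0),
    GA = c(-8.2, -22.2), CG = c(-10.6, -27.2), GC = c(-9.8, -24.4),
    GG = c(-8.0, -19.9))
  lookup <- function(di) {
    if (!is.null(tab[[di]])) return(tab[[di]])
    tab[[rc_chars(di)]]
  }
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  dh <- 0; ds <- 0
  for (i in seq_len(n - 1)) {
    v <- lookup(paste0(ch[i], ch[i + 1]))
    dh <- dh + v[1]; ds <- ds + v[2]
  }
  for (end in c(ch[1], ch[n])) {
    if (end %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  selfc <- identical(seq, rc_chars(seq))
  if (selfc) ds <- ds - 1.4
  ds <- ds + 0.368 * (n - 1) * log(salt)
  dh * 1000 / (ds + 1.9872 * log(conc / if (selfc) 1 else 4)) - 273.15
}

# --- hairpin: exhaustive scan over all (stem1 start, stem2 start, length)
oracle_hairpin <- function(seq, min_stem = 4L, min_loop = 3L) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  best <- 0L
  for (L in seq.int(min_stem, n)) {
    for (s1 in seq_len(n - L + 1L)) {
      for (s2 in seq_len(n - L + 1L)) {
        if (s2 - (s1 + L - 1L) - 1L < min_loop) next
        a <- substr(seq, s1, s1 + L - 1L)
        b <- substr(seq, s2, s2 + L - 1L)
        if (b == rc_chars(a) && L > best) best <- L
      }
    }
  }
  list(hairpin = best >= min_stem, stem = best)
}

# --- dimer: all-offset scan for antiparallel complementary runs
oracle_dimer <- function(a, b, min_run = 8L, min_run_3p = 4L) {
  rb <- rc_chars(b)
  na <- nchar(a); nb <- nchar(rb)
  best <- 0L; best3 <- 0L
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      L <- 0L
      while (i + L <= na && j + L <= nb &&
             substr(a, i + L, i + L) == substr(rb, j + L, j + L)) {
        L <- L + 1L
      }
      if (L > best) best <- L
      if (L > 0L && (i + L - 1L == na || j == 1L) && L > best3) best3 <- L
    }
  }
  list(dimer = best >= min_run || best3 >= min_run_3p,
       run = best, three_prime_run = best3)
}

# --- site scan helpers for in-silico PCR / coverage oracles
oracle_mm <- function(x, y) {
  sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
}

oracle_sites <- function(seq, primer, max_mm, tpe) {
  k <- nchar(primer)
  n <- nchar(seq)
  starts <- integer(0); mms <- integer(0)
  if (k > n) return(data.frame(start = starts, mm = mms))
  for (s in seq_len(n - k + 1L)) {
    site <- substr(seq, s, s + k - 1L)
    mm <- oracle_mm(primer, site)
    if (mm > max_mm) next
    if (tpe > 0L &&
        substr(primer, k - tpe + 1L, k) != substr(site, k - tpe + 1L, k)) next
    starts <- c(starts, s - 1L); mms <- c(mms, mm)
  }
  data.frame(start = starts, mm = mms)
}

oracle_ispcr <- function(fwd, rev, template, max_mm = 3L, max_product = 300L,
                         tpe = 3L) {
  n <- nchar(template)
  one <- function(s, strand) {
    fs <- oracle_sites(s, fwd, max_mm, tpe)
    # reverse primer site on this strand is rc(rev); its 3' end is the
    # site's first base, so the exact-match rule applies to the site head
    rcr <- rc_chars(rev)
    k <- nchar(rev)
    rs <- integer(0); rmm <- integer(0)
    if (k <= nchar(s)) {
      for (t in seq_len(nchar(s) - k + 1L)) {
        site <- substr(s, t, t + k - 1L)
        mm <- oracle_mm(rcr, site)
        if (mm > max_mm) next
        if (tpe > 0L && substr(rcr, 1L, tpe) != substr(site, 1L, tpe)) next
        rs <- c(rs, t - 1L); rmm <- c(rmm, mm)
      }
    }
    out <- list()
    for (i in seq_along(fs$start)) {
      for (j in seq_along(rs)) {
        a <- fs$start[i]; b <- rs[j]
        if (b < a + nchar(fwd)) next
        len <- b + k - a
        if (len > max_product) next
        out[[length(out) + 1L]] <- data.frame(
          start = a, end = b + k, length = len,
          fwd_mismatches = fs$mm[i], rev_mismatches = rmm[j],
          strand = strand)
      }
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  plus <- one(template, "+")
  minus <- one(rc_chars(template), "-")
  if (!is.null(minus)) {
    s0 <- n - minus$end
    minus$end <- n - minus$start
    minus$start <- s0
  }
  hits <- rbind(plus, minus)
  if (is.null(hits)) {
    return(data.frame(start = integer(), end = integer(),
                      length = integer(), fwd_mismatches = integer(),
                      rev_mismatches = integer(), strand = character()))
  }
  hits <- hits[order(hits$start, hits$end), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

oracle_best_mm <- function(seq, primer) {
  k <- nchar(primer)
  best <- Inf
  for (s in c(seq, rc_chars(seq))) {
    if (k > nchar(s)) next
    for (p in seq_len(nchar(s) - k + 1L)) {
      best <- min(best, oracle_mm(primer, substr(s, p, p + k - 1L)))
    }
  }
  best
}

# --- end-gap-free global alignment: plain-R DP mirroring the scoring and
# tie-break contract (diagonal > up > left; best start on last row/column)
oracle_align <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  S <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      S[i + 1L, j + 1L] <- max(S[i, j] + (x[i] == y[j]),
                               S[i, j + 1L] - 1L,
                               S[i + 1L, j] - 1L)
    }
  }
  bi <- n; bj <- m; bscore <- S[n + 1L, m + 1L]
  for (i in seq_len(n)) {
    if (S[i + 1L, m + 1L] > bscore) { bscore <- S[i + 1L, m + 1L]; bi <- i; bj <- m }
  }
  for (j in seq_len(m)) {
    if (S[n + 1L, j + 1L] > bscore) { bscore <- S[n + 1L, j + 1L]; bi <- n; bj <- j }
  }
  i <- bi; j <- bj; matches <- 0L; columns <- 0L
  while (i > 0L && j > 0L) {
    if (S[i + 1L, j + 1L] == S[i, j] + (x[i] == y[j])) {
      if (x[i] == y[j]) matches <- matches + 1L
      i <- i - 1L; j <- j - 1L
    } else if (S[i + 1L, j + 1L] == S[i, j + 1L] - 1L) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
    columns <- columns + 1L
  }
  list(score = bscore, matches = matches, columns = columns,
       identity = if (columns) matches / columns else 0)
}

oracle_classify <- function(seq, db) {
  best <- -1; best_id <- NA; best_tax <- NA
  for (r in order(db$id)) {
    idy <- oracle_align(seq, db$seq[r])$identity
    if (idy > best) { best <- idy; best_id <- db$id[r]; best_tax <- db$taxon[r] }
  }
  list(taxon = strsplit(best_tax, "\\s+")[[1]][1], id = best_id,
       identity = best)
}

oracle_cluster <- function(seqs, abundances, ids, radius = 0.03) {
  ord <- order(-abundances, ids)
  centroids <- character(0)
  assign <- integer(length(seqs))
  for (i in ord) {
    hit <- 0L
    for (k in seq_along(centroids)) {
      if (oracle_align(seqs[i], centroids[k])$identity >= 1 - radius) {
        hit <- k; break
      }
    }
    if (hit == 0L) { centroids <- c(centroids, seqs[i]); hit <- length(centroids) }
    assign[i] <- hit
  }
  list(centroids = centroids, assign = assign)
}

# --- expected rarefied richness (hypergeometric closed form)
oracle_rarefaction_expect <- function(counts, depth) {
  N <- sum(counts)
  sum(1 - exp(lchoose(N - counts, depth) - lchoose(N, depth)))
}
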