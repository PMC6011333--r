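# Deterministic construction of single-violation primer-pair assays.
# Each assay consists of a primer pair, a database built so that every
# template contains both primer sites exactly (perfect coverage, known
# product), and diverged random non-targets.

find_oligo <- function(ok, max_tries = 20000L) {
  for (i in seq_len(max_tries)) {
    s <- random_seq(25)
    if (ok(s)) return(s)
  }
  stop("no oligo found satisfying the constraints")
}

oligo_clean <- function(s) {
  !hairpin_check(s)$hairpin && !dimer_check(s, s)$dimer
}

tm_c <- function(s) melt_temp(oligo(s))$tm_c

make_assay <- function(fwd, rev, core_len = 83L, n_templates = 10L,
                       n_nontargets = 4L) {
  db <- do.call(rbind, lapply(seq_len(n_templates), function(i) {
    data.frame(id = sprintf("t%02d", i), taxon = sprintf("Genus%d sp", i),
               seq = paste0(fwd, random_seq(core_len), revcomp(rev)),
               kind = "nucleotide", stringsAsFactors = FALSE)
  }))
  class(db) <- c("seq_records", "data.frame")
  nt <- do.call(rbind, lapply(seq_len(n_nontargets), function(i) {
    data.frame(id = sprintf("nt%02d", i), taxon = "Outgroup sp",
               seq = random_seq(400), kind = "nucleotide",
               stringsAsFactors = FALSE)
  }))
  class(nt) <- c("seq_records", "data.frame")
  list(pair = primer_pair(fwd, rev,
                          product_len_ref = 50L + core_len),
       db = db, nontargets = nt)
}

# a pair passing all six criteria plus five single-violation variants
build_criterion_assays <- function(seed = 100L) {
  set.seed(seed)
  in_window <- function(s, lo, hi) { t <- tm_c(s); t >= lo && t <= hi }
  fwd0 <- find_oligo(function(s) in_window(s, 62, 65) && oligo_clean(s))
  rev0 <- find_oligo(function(s) {
    in_window(s, 62, 65) && oligo_clean(s) &&
      abs(tm_c(s) - tm_c(fwd0)) <= 0.8 && !dimer_check(fwd0, s)$dimer
  })
  base <- make_assay(fwd0, rev0)

  # (i) both primers melt below the window; everything else intact
  f1 <- find_oligo(function(s) in_window(s, 56, 58.5) && oligo_clean(s))
  r1 <- find_oligo(function(s) {
    in_window(s, 56, 58.5) && oligo_clean(s) &&
      abs(tm_c(s) - tm_c(f1)) <= 0.8 && !dimer_check(f1, s)$dimer
  })
  low_tm <- make_assay(f1, r1)

  # (ii) forward primer carries a hairpin stem; Tm window and balance kept
  f2 <- NULL
  for (i in 1:20000) {
    s <- random_seq(25)
    stem <- substr(s, 3, 7)
    cand <- paste0(substr(s, 1, 11), revcomp(stem), substr(s, 17, 25))
    if (hairpin_check(cand)$hairpin && in_window(cand, 60.5, 66.5) &&
        abs(tm_c(cand) - tm_c(rev0)) <= 0.8 &&
        !dimer_check(fwd0, cand)$dimer) { f2 <- cand; break }
  }
  stopifnot(!is.null(f2))
  hairpin <- make_assay(f2, rev0)

  # (iii) Tm difference around 1.5 degC with both primers in the window
  f3 <- find_oligo(function(s) in_window(s, 61, 64.5) && oligo_clean(s))
  r3 <- find_oligo(function(s) {
    t <- tm_c(s)
    t >= 60.5 && t <= 66.5 && oligo_clean(s) &&
      abs(t - tm_c(f3)) >= 1.3 && abs(t - tm_c(f3)) <= 1.7 &&
      !dimer_check(f3, s)$dimer
  })
  unbalanced <- make_assay(f3, r3)

  # (iv) product of 301 bp: core stretched to 251 nt
  long_product <- make_assay(fwd0, rev0, core_len = 251L)

  # (v) one template carries 4 substitutions in the forward footprint
  partial <- make_assay(fwd0, rev0)
  ch <- strsplit(partial$db$seq[1], "")[[1]]
  for (k in c(2L, 7L, 12L, 17L)) ch[k] <- setdiff(BASES, ch[k])[1]
  partial$db$seq[1] <- paste(ch, collapse = "")

  # (vi) one non-target is a perfect template
  offtarget <- make_assay(fwd0, rev0)
  offtarget$nontargets$seq[1] <- offtarget$db$seq[1]

  list(base = base, low_tm = low_tm, hairpin = hairpin,
       unbalanced = unbalanced, long_product = long_product,
       partial = partial, offtarget = offtarget)
}
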