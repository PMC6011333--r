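#' Per-column conservation profile of a nucleotide alignment
#'
#' For every alignment column, the majority base among A/C/G/T (ties broken
#' A < C < G < T), the fraction of rows carrying it, and the gap fraction.
#'
#' @param aln gapped nucleotide [seq_records], >= 2 rows.
#' @return Data frame: `column` (0-based), `base`, `fraction`, `gap_fraction`.
#' @export
conservation_profile <- function(aln) {
  if (nrow(aln) < 2L) stop("alignment must have at least 2 rows")
  mat <- do.call(rbind, strsplit(aln$seq, ""))
  if (is.null(dim(mat)) || length(unique(nchar(aln$seq))) != 1L) {
    stop("alignment rows must have equal length")
  }
  n <- nrow(mat)
  res <- apply(mat, 2L, function(col) {
    counts <- c(A = sum(col == "A"), C = sum(col == "C"),
                G = sum(col == "G"), T = sum(col == "T"))
    best <- which.max(counts)  # first max: ties resolve A < C < G < T
    c(base = best, fraction = counts[best] / n,
      gap_fraction = sum(col == "-") / n)
  })
  data.frame(column = seq_len(ncol(mat)) - 1L,
             base = c("A", "C", "G", "T")[res[1, ]],
             fraction = unname(res[2, ]),
             gap_fraction = unname(res[3, ]),
             stringsAsFactors = FALSE)
}

#' Enumerate conserved-window primer candidates
#'
#' Every alignment window of an allowed length whose columns all reach the
#' conservation threshold and stay under the gap-fraction cap yields a
#' forward candidate (the majority consensus, 5'->3') and a reverse
#' candidate (its reverse complement). This makes explicit and reproducible
#' the conserved-region selection that is often done by eye.
#'
#' @param aln gapped nucleotide [seq_records].
#' @param len_range candidate length window, default 25-30 nt.
#' @param min_conservation minimum per-column majority fraction (default 0.80).
#' @param max_gap_fraction maximum per-column gap fraction (default 0.10).
#' @return Data frame of candidates ordered by (aln_start, length, strand):
#'   `seq`, `aln_start` (0-based column of the window's first base),
#'   `strand` (`forward`/`reverse`), `length`.
#' @export
enumerate_candidates <- function(aln, len_range = c(25L, 30L),
                                 min_conservation = 0.80,
                                 max_gap_fraction = 0.10) {
  prof <- conservation_profile(aln)
  ok <- prof$fraction >= min_conservation &
    prof$gap_fraction <= max_gap_fraction
  ncols <- nrow(prof)
  consensus_full <- paste(prof$base, collapse = "")
  bad_csum <- cumsum(!ok)  # window clean iff no failing column inside
  starts <- integer(0); lens <- integer(0)
  for (len in seq.int(len_range[1], len_range[2])) {
    if (len > ncols) break
    s <- seq_len(ncols - len + 1L)
    clean <- (bad_csum[s + len - 1L] - c(0L, bad_csum)[s]) == 0L
    starts <- c(starts, s[clean])
    lens <- c(lens, rep(len, sum(clean)))
  }
  if (!length(starts)) {
    return(data.frame(seq = character(), aln_start = integer(),
                      strand = character(), length = integer(),
                      stringsAsFactors = FALSE))
  }
  ord <- order(starts, lens)
  starts <- starts[ord]; lens <- lens[ord]
  fwd_seq <- substring(consensus_full, starts, starts + lens - 1L)
  out <- data.frame(
    seq = as.vector(rbind(fwd_seq, revcomp(fwd_seq))),
    aln_start = rep(starts - 1L, each = 2L),
    strand = rep(c("forward", "reverse"), length(starts)),
    length = rep(lens, each = 2L), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Pair a forward and a reverse primer
#'
#' @param fwd,rev primer sequences 5'->3' (the reverse primer as it would
#'   be synthesized, i.e. the reverse complement of its plus-strand site).
#' @param product_len_ref expected product length on the ungapped
#'   reference, if known.
#' @return List of class `primer_pair`.
#' @export
primer_pair <- function(fwd, rev, product_len_ref = NA_integer_) {
  fwd <- toupper(if (is.list(fwd)) fwd$seq else fwd)
  rev <- toupper(if (is.list(rev)) rev$seq else rev)
  if (grepl("[^ACGT]", fwd) || grepl("[^ACGT]", rev)) {
    stop("primers must be unambiguous A/C/G/T sequences")
  }
  if (!is.na(product_len_ref) && product_len_ref <= 0) {
    stop("product_len_ref must be positive")
  }
  structure(list(fwd = fwd, rev = rev,
                 product_len_ref = as.integer(product_len_ref)),
            class = "primer_pair")
}

#' Count mismatches between a primer and an equal-length site
#'
#' Hamming distance under exact character comparison: an ambiguity symbol
#' (e.g. `N`) in the template counts as a mismatch.
#'
#' @param primer primer sequence.
#' @param site template site, same length.
#' @return Integer mismatch count.
#' @export
count_mismatches <- function(primer, site) {
  primer <- toupper(primer); site <- toupper(site)
  if (nchar(primer) != nchar(site)) {
    stop("primer and site lengths differ (", nchar(primer), " vs ",
         nchar(site), ")")
  }
  cpp_mm_scan(site, primer)[1]
}

# Best (minimum) mismatch count of `primer` anywhere on `seq`, one strand.
.best_site <- function(seq, primer) {
  mm <- cpp_mm_scan(seq, primer)
  if (!length(mm)) return(list(mm = NA_integer_, start = NA_integer_))
  i <- which.min(mm)
  list(mm = mm[i], start = i - 1L)
}

#' Database coverage of a primer under mismatch tolerance
#'
#' For each database sequence, the best (minimum-mismatch) site over both
#' orientations is found; the sequence is covered if that best site has at
#' most `max_mm` mismatches.
#'
#' @param primer primer sequence (5'->3').
#' @param db nucleotide [seq_records].
#' @param max_mm mismatch tolerance, default 3.
#' @return List: `fraction` covered, `per_sequence` data frame
#'   (id, best_mm, start, orientation, covered).
#' @export
coverage <- function(primer, db, max_mm = 3L) {
  if (nrow(db) == 0L) stop("empty database")
  primer <- toupper(if (is.list(primer)) primer$seq else primer)
  rows <- lapply(seq_len(nrow(db)), function(r) {
    plus <- .best_site(db$seq[r], primer)
    minus <- .best_site(revcomp(db$seq[r]), primer)
    if (!is.na(plus$mm) && (is.na(minus$mm) || plus$mm <= minus$mm)) {
      data.frame(id = db$id[r], best_mm = plus$mm, start = plus$start,
                 orientation = "plus", stringsAsFactors = FALSE)
    } else {
      data.frame(id = db$id[r], best_mm = minus$mm, start = minus$start,
                 orientation = if (is.na(minus$mm)) NA_character_ else "minus",
                 stringsAsFactors = FALSE)
    }
  })
  per <- do.call(rbind, rows)
  per$covered <- !is.na(per$best_mm) & per$best_mm <= max_mm
  list(fraction = mean(per$covered), per_sequence = per)
}

# Primer binding sites on the plus strand of `seq`: starts (0-based) where
# overall mismatches <= max_mm and, if three_prime_exact > 0, the
# 3'-terminal `three_prime_exact` bases match exactly.
.binding_sites <- function(seq, primer, max_mm, three_prime_exact) {
  k <- nchar(primer)
  mm <- cpp_mm_scan(seq, primer)
  if (!length(mm)) return(data.frame(start = integer(), mm = integer()))
  ok <- mm <= max_mm
  if (three_prime_exact > 0L) {
    tail_p <- substring(primer, k - three_prime_exact + 1L, k)
    starts <- which(ok)
    if (length(starts)) {
      tail_t <- substring(seq, starts + k - three_prime_exact,
                          starts + k - 1L)
      ok[starts] <- tail_t == tail_p
    }
  }
  data.frame(start = which(ok) - 1L, mm = mm[ok])
}

#' In-silico PCR of a primer pair against a template
#'
#' Finds all amplicons in either template orientation: the forward primer
#' bound to one strand, the reverse primer bound downstream on the other,
#' each with at most `max_mm` mismatches and (by default) an exactly
#' matched 3'-terminal trinucleotide, and a product of at most
#' `max_product` bases. Coordinates are 0-based half-open on the input
#' (plus) strand and include both primer footprints.
#'
#' @param pair a [primer_pair].
#' @param template single-row nucleotide [seq_records] (or plain string).
#' @param max_mm per-primer mismatch tolerance.
#' @param max_product maximum product length.
#' @param three_prime_exact number of 3'-terminal bases required to match
#'   exactly (0 disables the 3'-end rule).
#' @return Data frame of hits sorted by start: `template_id`, `start`,
#'   `end`, `length`, `fwd_mismatches`, `rev_mismatches`, `strand`.
#' @export
insilico_pcr <- function(pair, template, max_mm = 3L, max_product = 300L,
                         three_prime_exact = 3L) {
  stopifnot(inherits(pair, "primer_pair"))
  if (is.character(template)) template <- seq_records("template", template)
  tid <- template$id[1]
  seq <- template$seq[1]
  n <- nchar(seq)
  scan_orientation <- function(s, strand) {
    fs <- .binding_sites(s, pair$fwd, max_mm, three_prime_exact)
    # reverse primer binds the opposite strand; its plus-strand site is the
    # reverse complement of the primer, whose 3' end maps to the site start
    rc_rev <- revcomp(pair$rev)
    k <- nchar(pair$rev)
    mm <- cpp_mm_scan(s, rc_rev)
    rok <- if (length(mm)) mm <= max_mm else logical(0)
    if (three_prime_exact > 0L && any(rok)) {
      head_t <- substring(s, which(rok), which(rok) + three_prime_exact - 1L)
      rok[rok] <- head_t == substring(rc_rev, 1L, three_prime_exact)
    }
    rs <- data.frame(start = which(rok) - 1L, mm = mm[rok])
    hits <- list()
    for (i in seq_len(nrow(fs))) {
      for (j in seq_len(nrow(rs))) {
        a <- fs$start[i]; b <- rs$start[j]
        if (b < a + nchar(pair$fwd)) next  # rev site strictly downstream
        len <- b + k - a
        if (len > max_product) next
        hits[[length(hits) + 1L]] <- data.frame(
          start = a, end = b + k, length = len,
          fwd_mismatches = fs$mm[i], rev_mismatches = rs$mm[j],
          strand = strand, stringsAsFactors = FALSE)
      }
    }
    if (length(hits)) do.call(rbind, hits) else NULL
  }
  plus <- scan_orientation(seq, "+")
  minus <- scan_orientation(revcomp(seq), "-")
  if (!is.null(minus)) {
    # map minus-orientation hits back to plus-strand coordinates
    s0 <- n - minus$end
    minus$end <- n - minus$start
    minus$start <- s0
  }
  hits <- rbind(plus, minus)
  if (is.null(hits)) {
    hits <- data.frame(start = integer(), end = integer(), length = integer(),
                       fwd_mismatches = integer(), rev_mismatches = integer(),
                       strand = character(), stringsAsFactors = FALSE)
  }
  hits <- cbind(template_id = rep(tid, nrow(hits)), hits)
  hits[order(hits$start, hits$end), , drop = FALSE]
}

#' Specificity of a pair against non-target homologs
#'
#' Fails if any non-target template yields an in-silico amplicon under the
#' same binding rules used for targets.
#'
#' @param pair a [primer_pair].
#' @param nontargets nucleotide [seq_records] of non-target homologs.
#' @inheritParams insilico_pcr
#' @return List: `pass` flag, `hits` data frame of offending amplicons.
#' @export
specificity <- function(pair, nontargets, max_mm = 3L, max_product = 300L,
                        three_prime_exact = 3L) {
  if (nrow(nontargets) == 0L) stop("empty non-target set")
  hits <- do.call(rbind, lapply(seq_len(nrow(nontargets)), function(r) {
    insilico_pcr(pair, nontargets[r, , drop = FALSE], max_mm = max_mm,
                 max_product = max_product,
                 three_prime_exact = three_prime_exact)
  }))
  list(pass = nrow(hits) == 0L, hits = hits)
}

#' Screening configuration for primer-pair evaluation
#'
#' Defaults follow the assay's design rules: per-primer Tm within
#' 60-67 deg C, Tm difference at most 1 deg C, product at most 300 bp, at
#' most 3 mismatches per primer against every database sequence, and no
#' predicted hairpin or dimer.
#'
#' @param tm_min,tm_max allowed primer Tm window (deg C).
#' @param dtm_max maximum |Tm difference| between primers (deg C).
#' @param max_product maximum amplicon length (bp).
#' @param max_mm mismatch tolerance per primer (criterion v and in-silico PCR).
#' @param min_coverage required covered fraction of the database (both primers).
#' @param conc_molar,salt_molar reaction conditions for Tm.
#' @param min_stem,min_loop,min_run,min_run_3p structure-check thresholds.
#' @param three_prime_exact 3'-end exact-match rule for in-silico PCR.
#' @return List of class `pair_config`.
#' @export
pair_config <- function(tm_min = 60, tm_max = 67, dtm_max = 1,
                        max_product = 300L, max_mm = 3L, min_coverage = 1.0,
                        conc_molar = 1e-6, salt_molar = 0.05,
                        min_stem = 4L, min_loop = 3L, min_run = 8L,
                        min_run_3p = 4L, three_prime_exact = 3L) {
  structure(as.list(environment()), class = "pair_config")
}

#' Evaluate a primer pair against the six design criteria
#'
#' (i) each primer's nearest-neighbor Tm within the allowed window;
#' (ii) no predicted hairpin in either primer and no self- or cross-dimer;
#' (iii) Tm difference within `dtm_max`; (iv) product length within
#' `max_product`; (v) database coverage at `max_mm` mismatches for both
#' primers; (vi) no in-silico amplicon from any non-target homolog. The
#' verdict is the conjunction of all six.
#'
#' @param pair a [primer_pair].
#' @param db curated target database ([seq_records]).
#' @param nontargets non-target homolog [seq_records].
#' @param config a [pair_config].
#' @return A `primer_pair_report`: data frame (criterion, description,
#'   measured, pass) with attribute `verdict`.
#' @export
evaluate_pair <- function(pair, db, nontargets, config = pair_config()) {
  cf <- config
  tm_f <- melt_temp(oligo(pair$fwd, cf$conc_molar, cf$salt_molar))$tm_c
  tm_r <- melt_temp(oligo(pair$rev, cf$conc_molar, cf$salt_molar))$tm_c
  pass_i <- tm_f >= cf$tm_min && tm_f <= cf$tm_max &&
    tm_r >= cf$tm_min && tm_r <= cf$tm_max

  hp_f <- hairpin_check(pair$fwd, cf$min_stem, cf$min_loop)
  hp_r <- hairpin_check(pair$rev, cf$min_stem, cf$min_loop)
  dm_ff <- dimer_check(pair$fwd, pair$fwd, cf$min_run, cf$min_run_3p)
  dm_rr <- dimer_check(pair$rev, pair$rev, cf$min_run, cf$min_run_3p)
  dm_fr <- dimer_check(pair$fwd, pair$rev, cf$min_run, cf$min_run_3p)
  pass_ii <- !hp_f$hairpin && !hp_r$hairpin &&
    !dm_ff$dimer && !dm_rr$dimer && !dm_fr$dimer

  dtm <- abs(tm_f - tm_r)
  pass_iii <- dtm <= cf$dtm_max

  prod_len <- pair$product_len_ref
  if (is.na(prod_len)) {
    lens <- unlist(lapply(seq_len(nrow(db)), function(r) {
      insilico_pcr(pair, db[r, , drop = FALSE], max_mm = cf$max_mm,
                   max_product = .Machine$integer.max %/% 2L,
                   three_prime_exact = cf$three_prime_exact)$length
    }))
    prod_len <- if (length(lens)) as.integer(stats::median(lens)) else NA_integer_
  }
  pass_iv <- !is.na(prod_len) && prod_len <= cf$max_product

  cov_f <- coverage(pair$fwd, db, cf$max_mm)
  cov_r <- coverage(pair$rev, db, cf$max_mm)
  cov_min <- min(cov_f$fraction, cov_r$fraction)
  pass_v <- cov_min >= cf$min_coverage

  spec <- specificity(pair, nontargets, max_mm = cf$max_mm,
                      max_product = cf$max_product,
                      three_prime_exact = cf$three_prime_exact)
  pass_vi <- spec$pass

  report <- data.frame(
    criterion = c("i", "ii", "iii", "iv", "v", "vi"),
    description = c(
      sprintf("primer Tm within [%g, %g] degC", cf$tm_min, cf$tm_max),
      "no hairpin, self-dimer or cross-dimer",
      sprintf("|dTm| <= %g degC", cf$dtm_max),
      sprintf("product <= %d bp", cf$max_product),
      sprintf("coverage at <= %d mismatches >= %g", cf$max_mm,
              cf$min_coverage),
      "no non-target amplicon"),
    measured = c(
      sprintf("Tm %.2f / %.2f", tm_f, tm_r),
      sprintf("stem %d/%d, run %d/%d/%d", hp_f$stem, hp_r$stem,
              dm_ff$run, dm_rr$run, dm_fr$run),
      sprintf("%.2f", dtm),
      sprintf("%s bp", ifelse(is.na(prod_len), "NA", prod_len)),
      sprintf("%.4f / %.4f", cov_f$fraction, cov_r$fraction),
      sprintf("%d non-target hit(s)", nrow(spec$hits))),
    pass = c(pass_i, pass_ii, pass_iii, pass_iv, pass_v, pass_vi),
    stringsAsFactors = FALSE)
  structure(report, class = c("primer_pair_report", "data.frame"),
            verdict = all(report$pass),
            tm = c(fwd = tm_f, rev = tm_r), product_len = prod_len,
            coverage = c(fwd = cov_f$fraction, rev = cov_r$fraction))
}

#' @export
print.primer_pair_report <- function(x, ...) {
  cat("Primer pair report (verdict:",
      if (attr(x, "verdict")) "PASS" else "FAIL", ")\n")
  print.data.frame(x)
  invisible(x)
}

#' Enumerate and screen primer pairs from an alignment
#'
#' Convenience driver: enumerates conserved-window candidates, forms all
#' forward/reverse combinations whose product (in alignment columns) is
#' within the cap, pre-filters on the cheap thermodynamic criteria (Tm
#' window, Tm balance, structure), and fully evaluates up to `max_pairs`
#' surviving pairs against the database and non-targets.
#'
#' @param aln gapped nucleotide [seq_records] of the curated targets.
#' @param db ungapped target database for coverage (defaults to the
#'   ungapped alignment rows).
#' @param nontargets non-target homolog [seq_records].
#' @param config a [pair_config].
#' @param min_conservation,max_gap_fraction,len_range candidate
#'   enumeration thresholds (see [enumerate_candidates]).
#' @param max_pairs cap on fully evaluated pairs.
#' @param stride minimum column spacing between forward starts of
#'   successive evaluated pairs, so the screen samples distinct regions
#'   instead of near-identical shifted windows.
#' @return Data frame, one row per evaluated pair: primer sequences and
#'   windows, Tm values, product length, the six per-criterion passes
#'   (`crit_i` .. `crit_vi`) and the overall `verdict`.
#' @export
design_pairs <- function(aln, db = NULL, nontargets,
                         config = pair_config(),
                         min_conservation = 0.80, max_gap_fraction = 0.10,
                         len_range = c(25L, 30L), max_pairs = 50L,
                         stride = 10L) {
  if (is.null(db)) {
    db <- aln
    db$seq <- ungap(db$seq)
  }
  cand <- enumerate_candidates(aln, len_range = len_range,
                               min_conservation = min_conservation,
                               max_gap_fraction = max_gap_fraction)
  if (!nrow(cand)) return(data.frame())
  fwd <- cand[cand$strand == "forward", , drop = FALSE]
  rev <- cand[cand$strand == "reverse", , drop = FALSE]
  # Tm is invariant under reverse complement, so one value per window
  uniq_f <- unique(fwd$seq)
  tm_of <- vapply(uniq_f, function(s) {
    melt_temp(oligo(s, config$conc_molar, config$salt_molar))$tm_c
  }, numeric(1))
  fwd_tm <- unname(tm_of[fwd$seq])
  rev_tm <- unname(tm_of[revcomp(rev$seq)])
  keep_f <- fwd_tm >= config$tm_min & fwd_tm <= config$tm_max
  keep_r <- rev_tm >= config$tm_min & rev_tm <= config$tm_max
  fwd <- fwd[keep_f, , drop = FALSE]; fwd_tm <- fwd_tm[keep_f]
  rev <- rev[keep_r, , drop = FALSE]; rev_tm <- rev_tm[keep_r]
  if (!nrow(fwd) || !nrow(rev)) return(data.frame())
  # cache per-oligo structure checks so the screen skips candidates that
  # would fail criterion (ii) regardless of the partner
  struct_cache <- new.env(parent = emptyenv())
  struct_ok <- function(s) {
    v <- struct_cache[[s]]
    if (is.null(v)) {
      v <- !hairpin_check(s, config$min_stem, config$min_loop)$hairpin &&
        !dimer_check(s, s, config$min_run, config$min_run_3p)$dimer
      assign(s, v, envir = struct_cache)
    }
    v
  }
  out <- list()
  next_start <- 0L
  for (i in seq_len(nrow(fwd))) {
    a <- fwd$aln_start[i]
    if (a < next_start) next
    if (!struct_ok(fwd$seq[i])) next
    span <- rev$aln_start + rev$length - a
    js <- which(rev$aln_start >= a + fwd$length[i] &
                  span <= config$max_product &
                  abs(fwd_tm[i] - rev_tm) <= config$dtm_max)
    if (!length(js)) next
    js <- js[order(abs(fwd_tm[i] - rev_tm[js]), rev$aln_start[js],
                   rev$length[js])]
    j <- NA_integer_
    for (cand_j in js) {
      if (struct_ok(rev$seq[cand_j])) { j <- cand_j; break }
    }
    if (is.na(j)) next
    pp <- primer_pair(fwd$seq[i], rev$seq[j], product_len_ref = span[j])
    rep <- evaluate_pair(pp, db, nontargets, config)
    out[[length(out) + 1L]] <- data.frame(
      fwd_seq = fwd$seq[i], rev_seq = rev$seq[j],
      fwd_start = a, rev_start = rev$aln_start[j],
      product_len = span[j],
      tm_fwd = fwd_tm[i], tm_rev = rev_tm[j],
      stats::setNames(as.list(rep$pass), paste0("crit_", rep$criterion)),
      verdict = attr(rep, "verdict"), stringsAsFactors = FALSE)
    next_start <- a + stride
    if (length(out) >= max_pairs) break
  }
  if (!length(out)) return(data.frame())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
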