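aln_from <- function(seqs) {
  recs <- data.frame(id = sprintf("s%02d", seq_along(seqs)), taxon = "",
                     seq = seqs, kind = "nucleotide",
                     stringsAsFactors = FALSE)
  class(recs) <- c("seq_records", "data.frame")
  recs
}

test_that("conservation profile tallies majority base, ties A<C<G<T", {
  aln <- aln_from(c("AAC-", "AAG-", "ACT-", "AAAT"))
  prof <- conservation_profile(aln)
  expect_equal(prof$base[1], "A")
  expect_equal(prof$fraction[1], 1.0)
  expect_equal(prof$gap_fraction[1], 0.0)
  expect_equal(prof$fraction[2], 0.75)
  # column 3: C/G/T/A one each -> tie resolved to A
  expect_equal(prof$base[3], "A")
  expect_equal(prof$fraction[3], 0.25)
  expect_equal(prof$gap_fraction[4], 0.75)
  # 50/50 tie resolves to the alphabetically first base
  prof2 <- conservation_profile(aln_from(c("AC", "AC", "CA", "CA")))
  expect_equal(prof2$base, c("A", "A"))
  expect_equal(prof2$fraction, c(0.5, 0.5))
  expect_error(conservation_profile(aln_from("ACGT")), "2 rows")
})

test_that("conservation equals a direct per-column tally on random alignments", {
  set.seed(3)
  seqs <- vapply(1:10, function(i) random_seq(40), character(1))
  prof <- conservation_profile(aln_from(seqs))
  mat <- do.call(rbind, strsplit(seqs, ""))
  for (j in seq_len(40)) {
    counts <- table(factor(mat[, j], levels = c("A", "C", "G", "T")))
    expect_equal(prof$fraction[j], max(counts) / 10)
    expect_equal(prof$base[j], names(counts)[which.max(counts)])
  }
})

test_that("candidate enumeration yields all clean windows and only those", {
  aln <- aln_from(rep(paste(rep("ACGTA", 6), collapse = ""), 3))  # 30 cols
  cand <- enumerate_candidates(aln)
  # lengths 25..30 in 30 columns: 6+5+4+3+2+1 = 21 windows per strand
  expect_equal(sum(cand$strand == "forward"), 21L)
  expect_equal(sum(cand$strand == "reverse"), 21L)
  expect_equal(cand$seq[cand$strand == "reverse" & cand$length == 30],
               revcomp(cand$seq[cand$strand == "forward" & cand$length == 30]))
  # all columns under threshold -> empty
  mixed <- aln_from(c("AAAA", "CCCC", "GGGG", "TTTT"))
  expect_equal(nrow(enumerate_candidates(mixed, len_range = c(2, 3),
                                         min_conservation = 0.5)), 0L)
  # no candidate footprint may include a high-gap or low-conservation column
  set.seed(11)
  seqs <- replicate(8, random_seq(60))
  seqs <- vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]; ch[1:30] <- strsplit(seqs[[1]], "")[[1]][1:30]
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  cand2 <- enumerate_candidates(aln_from(seqs), len_range = c(10, 12),
                                min_conservation = 0.9)
  prof <- conservation_profile(aln_from(seqs))
  for (r in seq_len(nrow(cand2))) {
    cols <- cand2$aln_start[r] + seq_len(cand2$length[r])
    expect_true(all(prof$fraction[cols] >= 0.9))
    expect_true(all(prof$gap_fraction[cols] <= 0.10))
  }
})

test_that("mismatch counting is Hamming with ambiguity counted as mismatch", {
  expect_equal(count_mismatches("ACGT", "ACGT"), 0L)
  expect_equal(count_mismatches("ACGT", "ACCT"), 1L)
  expect_gte(count_mismatches("ACGT", "ACNT"), 1L)
  expect_error(count_mismatches("ACGT", "ACG"), "lengths differ")
})

test_that("coverage finds best sites on either strand and applies the cap", {
  set.seed(5)
  primer <- random_seq(25)
  exact <- paste0(random_seq(30), primer, random_seq(30))
  onrc <- revcomp(exact)
  ch <- strsplit(primer, "")[[1]]
  for (k in c(5, 10, 15, 20)) ch[k] <- setdiff(BASES, ch[k])[1]
  four_mm <- paste0(random_seq(30), paste(ch, collapse = ""), random_seq(30))
  db <- aln_from(c(exact, onrc, four_mm))
  cov <- coverage(primer, db, max_mm = 3)
  expect_equal(cov$per_sequence$best_mm, c(0L, 0L, 4L))
  expect_equal(cov$per_sequence$covered, c(TRUE, TRUE, FALSE))
  expect_equal(cov$fraction, 2 / 3)
  # brute-force equivalence on a synthetic family
  fam <- gen_family(n_target = 6, n_paralog = 3, length_codons = 60,
                    policy = residue_policy("REF", c(5, 20), c("K", "S")),
                    conserved_regions = list(c(10, 40)), seed = 5)
  for (p in c(primer, substr(fam$nucleotide$seq[1], 11, 35))) {
    cov2 <- coverage(p, fam$nucleotide, max_mm = 3)
    for (r in seq_len(nrow(fam$nucleotide))) {
      expect_equal(cov2$per_sequence$best_mm[r],
                   oracle_best_mm(fam$nucleotide$seq[r], p))
    }
  }
})

test_that("in-silico PCR recovers constructed amplicons with plus-strand coordinates", {
  set.seed(23)
  fwd <- random_seq(25); rev <- random_seq(25)
  pair <- primer_pair(fwd, rev)
  tmpl <- paste0(fwd, random_seq(83), revcomp(rev))
  hit <- insilico_pcr(pair, tmpl)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 0L)
  expect_equal(hit$end, 133L)
  expect_equal(hit$length, 133L)
  expect_equal(hit$fwd_mismatches + hit$rev_mismatches, 0L)
  # no reverse site -> no amplicon
  expect_equal(nrow(insilico_pcr(pair, paste0(fwd, random_seq(100)))), 0L)
  # minus-strand template found with mapped coordinates
  pad <- paste0(random_seq(17), tmpl, random_seq(10))
  h2 <- insilico_pcr(pair, revcomp(pad))
  expect_equal(h2$strand, "-")
  expect_equal(h2$length, 133L)
  expect_equal(h2$start, 10L)
})

test_that("in-silico PCR equals the exhaustive site-pair scan on random templates", {
  set.seed(11)
  fwd <- random_seq(20); rev <- random_seq(20)
  pair <- primer_pair(fwd, rev)
  for (i in 1:50) {
    tmpl <- random_seq(500)
    # plant sites with varying mismatch loads to exercise the thresholds
    if (i %% 2 == 0) {
      f2 <- strsplit(fwd, "")[[1]]
      nmut <- sample(0:4, 1)
      for (k in sample(1:17, nmut)) f2[k] <- sample(setdiff(BASES, f2[k]), 1)
      ins <- sample(1:300, 1)
      substr(tmpl, ins, ins + 19) <- paste(f2, collapse = "")
      ins2 <- ins + 20 + sample(10:150, 1)
      substr(tmpl, ins2, ins2 + 19) <- revcomp(rev)
    }
    got <- insilico_pcr(pair, tmpl, max_mm = 3, max_product = 300)
    want <- oracle_ispcr(fwd, rev, tmpl, max_mm = 3, max_product = 300)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$fwd_mismatches, want$fwd_mismatches)
      expect_equal(got$rev_mismatches, want$rev_mismatches)
    }
  }
})

test_that("specificity fails on target-like non-targets and passes on diverged ones", {
  set.seed(31)
  fwd <- random_seq(25); rev <- random_seq(25)
  pair <- primer_pair(fwd, rev)
  target_like <- paste0(fwd, random_seq(83), revcomp(rev))
  expect_false(specificity(pair, aln_from(target_like))$pass)
  diverged <- aln_from(replicate(5, random_seq(400)))
  sp <- specificity(pair, diverged)
  brute <- any(vapply(diverged$seq, function(s) {
    nrow(oracle_ispcr(fwd, rev, s)) > 0
  }, logical(1)))
  expect_equal(sp$pass, !brute)
})

test_that("pair evaluation passes a clean constructed assay end to end", {
  set.seed(61)
  fam <- gen_family(seed = 61)
  targets <- fam$nucleotide[fam$truth$class != "paralog", , drop = FALSE]
  nont <- fam$nucleotide[fam$truth$class == "paralog", , drop = FALSE]
  res <- design_pairs(targets, nontargets = nont, max_pairs = 15)
  expect_gt(nrow(res), 0)
  expect_true(any(res$verdict))
  ok <- res[res$verdict, ][1, ]
  rep <- evaluate_pair(primer_pair(ok$fwd_seq, ok$rev_seq,
                                   product_len_ref = ok$product_len),
                       targets, nont)
  expect_true(all(rep$pass))
  expect_true(attr(rep, "verdict"))
  # verdict is the conjunction of the six criteria
  expect_equal(attr(rep, "verdict"), all(rep$pass))
  # relaxing thresholds never flips a pass to fail (monotonicity)
  relaxed <- pair_config(tm_min = 55, tm_max = 72, dtm_max = 2,
                         max_product = 400, max_mm = 4, min_coverage = 0.5)
  rep2 <- evaluate_pair(primer_pair(ok$fwd_seq, ok$rev_seq,
                                    product_len_ref = ok$product_len),
                        targets, nont, relaxed)
  expect_true(all(rep2$pass >= rep$pass))
})
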