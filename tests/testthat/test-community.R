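make_reads <- function(seqs, sample = "s1") {
  data.frame(id = sprintf("%s_%03d", sample, seq_along(seqs)), seq = seqs,
             sample = sample, stringsAsFactors = FALSE)
}

test_that("read filter applies the length window and ambiguity rule", {
  set.seed(2)
  reads <- make_reads(c(random_seq(133), random_seq(119), random_seq(160),
                        random_seq(161),
                        paste0(random_seq(100), "N", random_seq(29))))
  out <- filter_reads(reads)
  expect_equal(nrow(out$kept), 2L)
  expect_setequal(out$rejected$reason, c("too_short", "too_long", "ambiguous"))
  expect_equal(out$rejected$reason[out$rejected$id == "s1_002"], "too_short")
  expect_equal(out$rejected$reason[nchar(out$rejected$seq) == 130],
               "ambiguous")
})

test_that("denoising dereplicates and optionally drops singletons", {
  set.seed(4)
  a <- random_seq(133); b <- random_seq(133)
  reads <- make_reads(c(a, a, b))
  kept <- denoise(reads, drop_singletons = TRUE)
  expect_equal(nrow(kept$uniques), 1L)
  expect_equal(kept$uniques$seq, a)
  expect_equal(kept$uniques$abundance, 2L)
  # flag off: nothing lost
  all_u <- denoise(reads)
  expect_equal(sum(all_u$uniques$abundance), 3L)
  expect_setequal(all_u$uniques$seq, c(a, b))
  # all identical -> one unique with abundance n
  same <- denoise(make_reads(rep(a, 7)))
  expect_equal(nrow(same$uniques), 1L)
  expect_equal(same$uniques$abundance, 7L)
  # per-sample counts preserved across samples
  two <- denoise(rbind(make_reads(c(a, a), "s1"), make_reads(c(a, b), "s2")))
  expect_equal(unname(two$sample_counts[two$uniques$uid[two$uniques$seq == a], ]),
               c(2L, 1L))
})

test_that("OTU clustering respects the 3% divergence radius", {
  set.seed(6)
  a <- random_seq(133)
  # 3 substitutions in 133 nt = 2.26% divergence -> same OTU
  ch <- strsplit(a, "")[[1]]
  for (k in c(10, 60, 110)) ch[k] <- setdiff(BASES, ch[k])[1]
  near <- paste(ch, collapse = "")
  far <- strsplit(a, "")[[1]]
  for (k in seq(1, 131, by = 10)) far[k] <- setdiff(BASES, far[k])[1]
  far <- paste(far, collapse = "")  # ~10% divergent
  uniq <- denoise(make_reads(c(a, a, near, far)))
  tab <- cluster_otus(uniq)
  expect_equal(ncol(tab$counts), 2L)
  uid_of <- function(s) uniq$uniques$uid[uniq$uniques$seq == s]
  expect_equal(unname(tab$membership[uid_of(a)]), "OTU_1")
  expect_equal(unname(tab$membership[uid_of(near)]), "OTU_1")
  expect_equal(unname(tab$membership[uid_of(far)]), "OTU_2")
  # identical sequences collapse to one OTU
  tab1 <- cluster_otus(denoise(make_reads(rep(a, 5))))
  expect_equal(ncol(tab1$counts), 1L)
  # table total equals surviving reads
  expect_equal(sum(tab$counts), 4L)
})

test_that("clustering is invariant to input order and matches the greedy oracle", {
  set.seed(17)
  core <- replicate(4, random_seq(120))
  seqs <- unlist(lapply(core, function(s) {
    c(s, vapply(1:3, function(i) {
      ch <- strsplit(s, "")[[1]]
      for (k in sample(120, sample(1:3, 1))) ch[k] <- sample(setdiff(BASES, ch[k]), 1)
      paste(ch, collapse = "")
    }, character(1)))
  }))
  reads <- make_reads(rep(seqs, times = rep_len(c(3, 2, 1, 1), length(seqs))))
  uniq <- denoise(reads)
  tab <- cluster_otus(uniq)
  want <- oracle_cluster(uniq$uniques$seq, uniq$uniques$abundance,
                         uniq$uniques$uid)
  expect_equal(tab$centroids$seq, want$centroids)
  expect_equal(unname(tab$membership[uniq$uniques$uid]),
               sprintf("OTU_%d", want$assign))
  # permuting read order leaves the table unchanged
  perm <- reads[sample(nrow(reads)), , drop = FALSE]
  tab2 <- cluster_otus(denoise(perm))
  expect_equal(tab2$centroids$seq, tab$centroids$seq)
  expect_equal(tab2$counts, tab$counts)
})

test_that("classification is best-hit by identity with lexicographic ties", {
  set.seed(8)
  db_seqs <- replicate(6, random_seq(133))
  db <- seq_records(sprintf("db%02d", 1:6), db_seqs,
                    taxon = sprintf("Genus%d species%d", 1:6, 1:6))
  hit <- classify(db_seqs[3], db)
  expect_equal(hit$id, "db03")
  expect_equal(hit$taxon, "Genus3")
  expect_equal(hit$identity, 1.0)
  # equidistant duplicate entries: smaller id wins
  db2 <- seq_records(c("zz", "aa"), c(db_seqs[1], db_seqs[1]),
                     taxon = c("Zgenus sp", "Agenus sp"))
  expect_equal(classify(db_seqs[1], db2)$id, "aa")
  # oracle equivalence on random centroids vs a 20-entry database
  set.seed(17)
  big <- seq_records(sprintf("r%02d", 1:20), replicate(20, random_seq(133)),
                     taxon = sprintf("G%d sp", 1:20))
  for (i in 1:10) {
    q <- strsplit(big$seq[sample(20, 1)], "")[[1]]
    for (k in sample(133, sample(0:6, 1))) q[k] <- sample(setdiff(BASES, q[k]), 1)
    q <- paste(q, collapse = "")
    got <- classify(q, big)
    want <- oracle_classify(q, big)
    expect_equal(got$id, want$id)
    expect_equal(got$identity, want$identity, tolerance = 1e-12)
  }
})

test_that("subsampling hits the exact depth and hypergeometric expectation", {
  counts <- matrix(c(50L, 30L, 20L, 10L,
                     5L, 0L, 3L, 2L), nrow = 2, byrow = TRUE,
                   dimnames = list(c("deep", "shallow"),
                                   sprintf("OTU_%d", 1:4)))
  tab <- structure(list(counts = counts, centroids = NULL, membership = NULL,
                        taxonomy = NULL), class = "otu_table")
  expect_warning(sub <- subsample(tab, 60, seed = 1), "shallow")
  expect_equal(rownames(sub$counts), "deep")
  expect_equal(sum(sub$counts), 60L)
  # depth equal to the total leaves counts unchanged
  full <- suppressWarnings(subsample(tab, 110, seed = 1))
  expect_equal(unname(full$counts["deep", ]), c(50L, 30L, 20L, 10L))
  # mean subsampled count approaches depth * p_i
  tab1 <- structure(list(counts = counts["deep", , drop = FALSE]),
                    class = "otu_table")
  draws <- vapply(1:300, function(s) subsample(tab1, 55, seed = s)$counts[1, 1],
                  numeric(1))
  p <- 50 / 110
  sd_hyp <- sqrt(55 * p * (1 - p) * (110 - 55) / (110 - 1))
  expect_lt(abs(mean(draws) - 55 * p), 3 * sd_hyp / sqrt(300))
})

test_that("alpha diversity matches hand-computed Shannon, Simpson and Chao1", {
  one <- alpha_diversity(c(10))
  expect_equal(one$shannon, 0)
  expect_equal(one$simpson, 1)
  expect_equal(one$chao1, 1)
  d <- alpha_diversity(c(5, 3, 2))
  expect_equal(d$shannon, 1.0297, tolerance = 1e-4)
  expect_equal(d$simpson, 0.38, tolerance = 1e-10)
  expect_equal(alpha_diversity(c(5, 3, 2), simpson_form = "gini")$simpson,
               0.62, tolerance = 1e-10)
  # S_obs = 10, n1 = 4, n2 = 2 -> 10 + 16/4 = 14
  counts <- c(1, 1, 1, 1, 2, 2, 3, 4, 5, 6)
  expect_equal(alpha_diversity(counts)$chao1, 14)
  # no doubletons -> bias-corrected form
  counts2 <- c(1, 1, 1, 5, 7)
  expect_equal(alpha_diversity(counts2)$chao1, 5 + 3 * 2 / 2)
  expect_error(alpha_diversity(c(0, 0)), "no reads")
  # cross-check Shannon against vegan on random vectors
  set.seed(9)
  for (i in 1:10) {
    v <- rpois(15, 8) + 1
    expect_equal(alpha_diversity(v)$shannon,
                 unname(vegan::diversity(v, "shannon")), tolerance = 1e-12)
    expect_equal(alpha_diversity(v)$simpson,
                 1 - unname(vegan::diversity(v, "simpson")),
                 tolerance = 1e-12)
  }
  # Shannon bounded by ln(S_obs); Chao1 never below observed richness
  set.seed(10)
  for (i in 1:10) {
    v <- rpois(12, 3); v <- v[v > 0]
    if (!length(v)) next
    a <- alpha_diversity(v)
    expect_lte(a$shannon, log(a$s_obs) + 1e-12)
    expect_gte(a$chao1, a$s_obs)
  }
})

test_that("rarefaction endpoints are exact and the mean tracks the closed form", {
  counts <- c(40, 25, 20, 10, 4, 1)
  total <- sum(counts)
  rc <- rarefaction_curve(counts, c(1, total), reps = 5, seed = 1)
  expect_equal(rc$mean_otus[rc$depth == 1], 1)
  expect_equal(rc$mean_otus[rc$depth == total], 6)
  mid <- rarefaction_curve(counts, 30, reps = 400, seed = 2)$mean_otus
  expected <- oracle_rarefaction_expect(counts, 30)
  expect_lt(abs(mid - expected), 0.15)  # Monte-Carlo tolerance, ~3 SE
  expect_error(rarefaction_curve(counts, total + 1), "exceeds")
})

test_that("Bray-Curtis matches the definitional formula", {
  m <- rbind(s1 = c(2, 0, 4), s2 = c(2, 4, 0), s3 = c(2, 0, 4))
  d <- bray_curtis(m)
  expect_equal(d["s1", "s2"], 8 / 12, tolerance = 1e-10)
  expect_equal(d["s1", "s3"], 0)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))
  disjoint <- rbind(a = c(5, 5, 0, 0), b = c(0, 0, 3, 3))
  expect_equal(bray_curtis(disjoint)["a", "b"], 1)
  expect_error(bray_curtis(rbind(a = c(0, 0), b = c(1, 1))), "zero total")
})
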