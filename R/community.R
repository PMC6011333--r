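#' Length/ambiguity filtering of amplicon reads
#'
#' Keeps reads whose length lies within the accepted window (default
#' 120-160 nt around the 133-nt amplicon) and which contain no ambiguous
#' base call (only A/C/G/T).
#'
#' @param reads data frame with columns `id`, `seq` and optionally
#'   `sample`.
#' @param min_len,max_len accepted length window (nt).
#' @return List: `kept` (data frame) and `rejected` (data frame with a
#'   `reason` column: `too_short`, `too_long` or `ambiguous`).
#' @export
filter_reads <- function(reads, min_len = 120L, max_len = 160L) {
  len <- nchar(reads$seq)
  ambiguous <- grepl("[^ACGT]", toupper(reads$seq))
  reason <- rep(NA_character_, nrow(reads))
  reason[ambiguous] <- "ambiguous"
  reason[len > max_len] <- "too_long"
  reason[len < min_len] <- "too_short"
  keep <- is.na(reason)
  list(kept = reads[keep, , drop = FALSE],
       rejected = cbind(reads[!keep, , drop = FALSE],
                        reason = reason[!keep]))
}

#' Dereplicate reads into abundance-annotated unique sequences
#'
#' A simplified denoising step: identical reads are collapsed into unique
#' sequences with per-sample counts; with `drop_singletons = TRUE` unique
#' sequences observed exactly once in the whole dataset are discarded (the
#' singleton-free dataset is the one used for rarefaction and diversity).
#'
#' @param reads filtered read data frame (`id`, `seq`, optional `sample`).
#' @param drop_singletons discard globally unique single-observation
#'   sequences.
#' @return List of class `unique_reads`: `uniques` (data frame `uid`,
#'   `seq`, `abundance`, decreasing abundance with ties by uid) and
#'   `sample_counts` (uniques x samples integer matrix).
#' @export
denoise <- function(reads, drop_singletons = FALSE) {
  if (!"sample" %in% names(reads)) reads$sample <- "sample1"
  seqs <- toupper(reads$seq)
  samples <- sort(unique(reads$sample))
  uniq <- sort(unique(seqs))
  counts <- table(factor(seqs, levels = uniq),
                  factor(reads$sample, levels = samples))
  counts <- matrix(as.integer(counts), nrow = length(uniq),
                   dimnames = list(NULL, samples))
  abundance <- rowSums(counts)
  if (drop_singletons) {
    keep <- abundance > 1L
    uniq <- uniq[keep]
    counts <- counts[keep, , drop = FALSE]
    abundance <- abundance[keep]
  }
  uid <- sprintf("u%05d", seq_along(uniq))
  ord <- order(-abundance, uid, method = "radix")
  rownames(counts) <- uid
  structure(list(
    uniques = data.frame(uid = uid[ord], seq = uniq[ord],
                         abundance = abundance[ord],
                         stringsAsFactors = FALSE),
    sample_counts = counts[ord, , drop = FALSE]),
    class = "unique_reads")
}

#' Pairwise identity from end-gap-free global alignment
#'
#' Scoring: match +1, mismatch 0, gap -1, terminal gaps free; identity is
#' matches over alignment columns of the aligned region. Deterministic
#' traceback (diagonal preferred over up over left).
#'
#' @param a,b nucleotide sequences.
#' @return List: `score`, `matches`, `columns`, `identity`.
#' @export
align_identity <- function(a, b) {
  cpp_align_identity(toupper(a), toupper(b))
}

#' Greedy centroid OTU clustering at a divergence radius
#'
#' Unique sequences are processed in decreasing abundance (ties by id); a
#' sequence joins the first existing centroid with pairwise identity of at
#' least `1 - radius` (default 3% divergence), otherwise it founds a new
#' OTU. Deterministic and invariant to input row order.
#'
#' @param uniques a `unique_reads` object from [denoise].
#' @param radius divergence radius (default 0.03, i.e. 97% identity).
#' @return List of class `otu_table`: `counts` (samples x OTUs integer
#'   matrix), `centroids` (data frame `otu`, `seq`), `membership`
#'   (uid -> otu), `taxonomy` (filled by [classify_otus]).
#' @export
cluster_otus <- function(uniques, radius = 0.03) {
  stopifnot(inherits(uniques, "unique_reads"))
  u <- uniques$uniques
  ord <- order(-u$abundance, u$uid, method = "radix")  # enforced ordering
  u <- u[ord, , drop = FALSE]
  centroid_seq <- character(0)
  assignment <- integer(nrow(u))
  for (i in seq_len(nrow(u))) {
    hit <- 0L
    for (k in seq_along(centroid_seq)) {
      if (align_identity(u$seq[i], centroid_seq[k])$identity >= 1 - radius) {
        hit <- k
        break
      }
    }
    if (hit == 0L) {
      centroid_seq <- c(centroid_seq, u$seq[i])
      hit <- length(centroid_seq)
    }
    assignment[i] <- hit
  }
  otu_ids <- sprintf("OTU_%d", seq_along(centroid_seq))
  sc <- uniques$sample_counts[u$uid, , drop = FALSE]
  agg <- rowsum(sc, group = assignment)  # groups sort ascending = OTU order
  counts <- matrix(as.integer(agg), nrow = length(centroid_seq),
                   dimnames = list(otu_ids, colnames(sc)))
  structure(list(
    counts = t(counts),  # samples x OTUs
    centroids = data.frame(otu = otu_ids, seq = centroid_seq,
                           stringsAsFactors = FALSE),
    membership = stats::setNames(otu_ids[assignment], u$uid),
    taxonomy = NULL),
    class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat("OTU table:", ncol(x$counts), "OTUs x", nrow(x$counts), "samples,",
      sum(x$counts), "reads",
      if (!is.null(x$taxonomy)) "(classified)" else "", "\n")
  invisible(x)
}

#' Best-hit classification of a sequence against the core database
#'
#' Global-alignment identity against every database entry; the best hit's
#' genus (first token of the taxonomy label) is assigned, with ties broken
#' by lexicographically smallest id.
#'
#' @param seq query sequence (an OTU centroid).
#' @param core_db core-region [seq_records] with taxonomy labels.
#' @return List: `taxon` (genus), `id` (best hit), `identity`.
#' @export
classify <- function(seq, core_db) {
  if (nrow(core_db) == 0L) stop("empty reference database")
  ord <- order(core_db$id, method = "radix")
  best_id <- NA_character_; best_tax <- NA_character_; best <- -1
  for (r in ord) {  # lexicographic id order makes ties deterministic
    idy <- align_identity(seq, core_db$seq[r])$identity
    if (idy > best) {
      best <- idy
      best_id <- core_db$id[r]
      best_tax <- core_db$taxon[r]
    }
  }
  genus <- strsplit(best_tax, "\\s+")[[1]][1]
  list(taxon = genus, id = best_id, identity = best)
}

#' Classify every OTU centroid of a table
#'
#' @param table an `otu_table`.
#' @param core_db core-region [seq_records].
#' @return The table with `taxonomy` filled (data frame `otu`, `taxon`,
#'   `best_hit`, `identity`).
#' @export
classify_otus <- function(table, core_db) {
  hits <- lapply(table$centroids$seq, classify, core_db = core_db)
  table$taxonomy <- data.frame(
    otu = table$centroids$otu,
    taxon = vapply(hits, `[[`, "", "taxon"),
    best_hit = vapply(hits, `[[`, "", "id"),
    identity = vapply(hits, `[[`, 0, "identity"),
    stringsAsFactors = FALSE)
  table
}

#' Subsample an OTU table to even depth
#'
#' Draws `depth` reads per sample without replacement (hypergeometric
#' subsampling); samples shallower than `depth` are excluded with a
#' warning. Reproducible under `seed`.
#'
#' @param table an `otu_table`.
#' @param depth target reads per sample.
#' @param seed RNG seed.
#' @return The subsampled `otu_table` (possibly fewer samples).
#' @export
subsample <- function(table, depth, seed = 1L) {
  totals <- rowSums(table$counts)
  shallow <- totals < depth
  if (any(shallow)) {
    warning("excluding sample(s) shallower than depth: ",
            paste(rownames(table$counts)[shallow], collapse = ", "))
  }
  counts <- table$counts[!shallow, , drop = FALSE]
  if (nrow(counts) == 0L) stop("no sample reaches the requested depth")
  set.seed(seed)
  # rrarefy emits an advisory note when the smallest count exceeds 1
  sub <- suppressWarnings(vegan::rrarefy(counts, depth))
  table$counts <- matrix(as.integer(sub), nrow = nrow(sub),
                         dimnames = dimnames(counts))
  table
}

#' Alpha diversity of one sample
#'
#' Shannon `H = -sum p_i ln p_i` (nats), Simpson reported as dominance
#' `lambda = sum p_i^2` (higher = less diverse; `form = "gini"` gives
#' `1 - lambda`), and Chao1 richness `S_obs + n1^2 / (2 n2)` with the
#' bias-corrected `S_obs + n1 (n1 - 1) / (2 (n2 + 1))` when no doubletons
#' are present.
#'
#' @param counts non-negative integer vector of OTU counts for one sample.
#' @param simpson_form `"dominance"` (default) or `"gini"`.
#' @return Data frame: `s_obs`, `shannon`, `simpson`, `chao1`.
#' @export
alpha_diversity <- function(counts, simpson_form = c("dominance", "gini")) {
  simpson_form <- match.arg(simpson_form)
  counts <- counts[counts > 0]
  if (!length(counts)) stop("sample has no reads")
  p <- counts / sum(counts)
  shannon <- -sum(p * log(p))
  lambda <- sum(p^2)
  s_obs <- length(counts)
  n1 <- sum(counts == 1L)
  n2 <- sum(counts == 2L)
  chao1 <- if (n2 > 0L) {
    s_obs + n1^2 / (2 * n2)
  } else {
    s_obs + n1 * (n1 - 1) / 2
  }
  data.frame(s_obs = s_obs, shannon = shannon,
             simpson = if (simpson_form == "dominance") lambda else 1 - lambda,
             chao1 = chao1)
}

#' Rarefaction curve by repeated subsampling
#'
#' Mean number of observed OTUs across `reps` random subsamples at each
#' depth.
#'
#' @param counts OTU count vector for one sample.
#' @param depths subsampling depths (each <= total reads).
#' @param reps subsamples per depth.
#' @param seed RNG seed.
#' @return Data frame: `depth`, `mean_otus`.
#' @export
rarefaction_curve <- function(counts, depths, reps = 10L, seed = 1L) {
  total <- sum(counts)
  if (any(depths > total)) stop("depth exceeds sample total")
  set.seed(seed)
  pool <- rep(seq_along(counts), counts)
  mean_otus <- vapply(depths, function(d) {
    mean(vapply(seq_len(reps), function(r) {
      length(unique(sample(pool, d)))
    }, numeric(1)))
  }, numeric(1))
  data.frame(depth = depths, mean_otus = mean_otus)
}

#' Bray-Curtis dissimilarity between samples of an OTU table
#'
#' `BC(a, b) = sum |a_i - b_i| / sum (a_i + b_i)`.
#'
#' @param table an `otu_table`, or a samples x OTUs count matrix.
#' @return Symmetric labeled distance matrix with zero diagonal.
#' @export
bray_curtis <- function(table) {
  counts <- if (inherits(table, "otu_table")) table$counts else table
  if (nrow(counts) < 2L) stop("at least 2 samples are required")
  if (any(rowSums(counts) == 0)) stop("sample with zero total reads")
  as.matrix(vegan::vegdist(counts, method = "bray"))
}
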