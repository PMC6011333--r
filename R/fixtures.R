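#' Synthetic gene family with controlled key-residue violations
#'
#' Emulates the structure of a functional-gene database curated against a
#' paralogous family: `n_target` orthologs conserve all policy residues
#' (background substitutions avoid the policy codons and two conserved
#' primer-site windows), while `n_paralog` homologs diverge faster and
#' carry forced amino-acid violations at `violation_positions` — the
#' ortholog/paralog situation of ACC deaminases versus D-cysteine
#' desulfhydrases. The reference is emitted as the first record.
#'
#' @param n_target number of true-target sequences.
#' @param n_paralog number of paralog-like non-targets.
#' @param length_codons protein length in codons; must cover the largest
#'   policy position (default 340, enough for the canonical positions up
#'   to 322).
#' @param sub_rate per-nucleotide substitution probability in targets.
#' @param paralog_rate per-nucleotide substitution probability in paralogs
#'   (default 0.30, i.e. roughly 70% nucleotide identity, the ballpark of a
#'   diverged paralogous family).
#' @param policy a [residue_policy]; its `reference_id` names the anchor.
#' @param violation_positions subset of `policy$positions` forced to a
#'   non-matching residue in every paralog.
#' @param conserved_regions list of 1-based nucleotide ranges kept free of
#'   substitutions in targets (primer landing sites); the default two
#'   windows are 133 nt apart, mirroring the assay's product size.
#' @param seed RNG seed.
#' @return List: `nucleotide` (equal-length [seq_records], a gap-free
#'   alignment), `protein` (frame-0 translations), `truth` (data frame
#'   id/class), `policy`, `conserved_regions`.
#' @export
gen_family <- function(n_target = 30L, n_paralog = 8L, length_codons = 340L,
                       sub_rate = 0.02, paralog_rate = 0.30,
                       policy = residue_policy("REF"),
                       violation_positions = policy$positions,
                       conserved_regions = list(c(301L, 333L), c(401L, 433L)),
                       seed = 1L) {
  if (max(policy$positions) > length_codons) {
    stop("length_codons must cover the largest policy position")
  }
  if (!all(violation_positions %in% policy$positions)) {
    stop("violation_positions must be a subset of the policy positions")
  }
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  codon_for <- function(aa) {
    cands <- names(code)[code == aa]
    cands[sample.int(length(cands), 1L)]
  }
  other_residue <- function(aa) {
    pool <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], aa)
    pool[sample.int(length(pool), 1L)]
  }
  ref_codons <- sense[sample.int(length(sense), length_codons, replace = TRUE)]
  for (k in seq_along(policy$positions)) {
    ref_codons[policy$positions[k]] <- codon_for(policy$residues[k])
  }
  L <- 3L * length_codons
  protected <- rep(FALSE, L)  # no background substitutions here, in targets
  for (p in policy$positions) protected[(3L * p - 2L):(3L * p)] <- TRUE
  conserved_regions <- Filter(function(rg) rg[1] <= L, conserved_regions)
  for (rg in conserved_regions) protected[rg[1]:min(rg[2], L)] <- TRUE
  ref_nt <- strsplit(paste(ref_codons, collapse = ""), "")[[1]]

  mutate <- function(nt, rate, mask) {
    hit <- which(stats::runif(L) < rate & !mask)
    for (i in hit) {
      nt[i] <- sample(setdiff(bases, nt[i]), 1L)
    }
    nt
  }
  ids <- c(policy$reference_id,
           sprintf("T%03d", seq_len(n_target)),
           sprintf("P%03d", seq_len(n_paralog)))
  class <- c("reference", rep("target", n_target), rep("paralog", n_paralog))
  taxa <- c("Pseudomonas reference",
            sprintf("Genus%d target%d", 1L + (seq_len(n_target) - 1L) %% 6L,
                    seq_len(n_target)),
            sprintf("Outgenus%d paralog%d",
                    1L + (seq_len(n_paralog) - 1L) %% 3L, seq_len(n_paralog)))
  seqs <- character(length(ids))
  seqs[1] <- paste(ref_nt, collapse = "")
  for (t in seq_len(n_target)) {
    seqs[1L + t] <- paste(mutate(ref_nt, sub_rate, protected), collapse = "")
  }
  viol_idx <- match(violation_positions, policy$positions)
  for (p in seq_len(n_paralog)) {
    nt <- mutate(ref_nt, paralog_rate, rep(FALSE, L))
    for (k in viol_idx) {
      pos <- policy$positions[k]
      wrong <- other_residue(policy$residues[k])
      nt[(3L * pos - 2L):(3L * pos)] <-
        strsplit(codon_for(wrong), "")[[1]]
    }
    seqs[1L + n_target + p] <- paste(nt, collapse = "")
  }
  nuc <- seq_records(ids, seqs, taxon = taxa)
  prot <- do.call(rbind, lapply(seq_len(nrow(nuc)), function(r) {
    translate_cds(nuc[r, , drop = FALSE])
  }))
  class(prot) <- c("seq_records", "data.frame")
  list(nucleotide = nuc, protein = prot,
       truth = data.frame(id = ids, class = class, stringsAsFactors = FALSE),
       policy = policy, conserved_regions = conserved_regions)
}

#' Synthetic amplicon reads from a core-region database
#'
#' Draws reads multinomially over database entries with the given weights,
#' applies independent per-base substitution errors, and optionally trims
#' up to `length_jitter` bases from the 3' end.
#'
#' @param db core-region [seq_records].
#' @param abundances per-entry weights (recycled; default uniform).
#' @param n_reads reads to generate.
#' @param error_rate per-base substitution probability.
#' @param length_jitter maximum random 3' trim (0 = exact copies).
#' @param sample sample label attached to the reads.
#' @param seed RNG seed.
#' @return Data frame: `id`, `seq`, `sample`, `truth_id`, `truth_taxon`.
#' @export
gen_reads <- function(db, abundances = NULL, n_reads = 1000L,
                      error_rate = 0.005, length_jitter = 0L,
                      sample = "sample1", seed = 1L) {
  if (is.null(abundances)) abundances <- rep(1, nrow(db))
  abundances <- rep_len(abundances, nrow(db))
  if (any(abundances < 0) || all(abundances == 0)) {
    stop("weights must be non-negative and not all zero")
  }
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  src <- sample.int(nrow(db), n_reads, replace = TRUE,
                    prob = abundances / sum(abundances))
  seqs <- vapply(src, function(r) {
    nt <- strsplit(db$seq[r], "")[[1]]
    hit <- which(stats::runif(length(nt)) < error_rate)
    for (i in hit) nt[i] <- sample(setdiff(bases, nt[i]), 1L)
    if (length_jitter > 0L) {
      trim <- sample.int(length_jitter + 1L, 1L) - 1L
      if (trim > 0L) nt <- nt[seq_len(length(nt) - trim)]
    }
    paste(nt, collapse = "")
  }, character(1))
  data.frame(id = sprintf("%s_r%05d", sample, seq_len(n_reads)),
             seq = seqs, sample = sample,
             truth_id = db$id[src], truth_taxon = db$taxon[src],
             stringsAsFactors = FALSE)
}

#' Synthetic qPCR standard-curve points
#'
#' Ct values generated from a known line on log10 concentration with
#' Gaussian noise, for the assay's dilution scheme (default
#' 5e-9 .. 5e-15 g/uL in triplicate).
#'
#' @param conc concentrations (g/uL).
#' @param slope,intercept true curve parameters (cycles per log10(conc),
#'   cycles).
#' @param noise_sd Gaussian Ct noise (cycles).
#' @param replicates replicates per concentration.
#' @param seed RNG seed.
#' @return Data frame: `conc`, `replicate`, `ct`.
#' @export
gen_standards <- function(conc = 5 * 10^seq(-9, -15),
                          slope = -1 / log10(2), intercept = -5,
                          noise_sd = 0, replicates = 3L, seed = 1L) {
  set.seed(seed)
  grid <- expand.grid(replicate = seq_len(replicates), conc = conc)
  ct <- intercept + slope * log10(grid$conc) +
    stats::rnorm(nrow(grid), 0, noise_sd)
  data.frame(conc = grid$conc, replicate = grid$replicate, ct = ct)
}

#' Synthetic sample Ct values from known copy numbers
#'
#' Converts true copies per reaction to template mass and concentration,
#' then draws Ct from the curve with Gaussian noise; the round trip
#' through [quantify_sample] recovers the copies exactly at zero noise.
#'
#' @param copies true copies per reaction (named vector = sample labels).
#' @param template_bp template length in bp.
#' @param slope,intercept curve parameters on log10(conc g/uL).
#' @param reaction_volume_ul template volume per reaction (uL).
#' @param noise_sd Gaussian Ct noise (cycles).
#' @param seed RNG seed.
#' @return Data frame: `sample`, `copies_true`, `ct`.
#' @export
gen_ct <- function(copies, template_bp, slope = -1 / log10(2),
                   intercept = -5, reaction_volume_ul = 2, noise_sd = 0,
                   seed = 1L) {
  if (any(copies <= 0)) stop("copies must be positive")
  set.seed(seed)
  labels <- if (is.null(names(copies))) {
    sprintf("s%03d", seq_along(copies))
  } else names(copies)
  conc <- mass_from_copies(copies, template_bp) / reaction_volume_ul
  ct <- intercept + slope * log10(conc) +
    stats::rnorm(length(copies), 0, noise_sd)
  data.frame(sample = labels, copies_true = unname(copies), ct = ct,
             stringsAsFactors = FALSE)
}
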