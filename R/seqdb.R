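#' Translate a coding sequence with the standard genetic code
#'
#' Database entries are in-frame CDS, so the default frame is 0; a trailing
#' partial codon is dropped, stop codons are rendered `*`, and any codon
#' containing an ambiguity symbol (such as `N`) is rendered `X`.
#'
#' @param record a single-row [seq_records] nucleotide record (or a plain
#'   nucleotide string).
#' @param frame 0, 1 or 2: bases skipped before the first codon.
#' @param best_orf if `TRUE`, translate all three frames and return the one
#'   with the fewest internal stop codons (ties to the lowest frame).
#' @return A single-row protein [seq_records] data frame.
#' @export
translate_cds <- function(record, frame = 0L, best_orf = FALSE) {
  if (is.character(record)) {
    record <- seq_records("seq1", record)
  }
  stopifnot(nrow(record) == 1L, record$kind == "nucleotide")
  if (best_orf) {
    cands <- lapply(0:2, function(f) translate_cds(record, frame = f))
    stops <- vapply(cands, function(x) {
      aa <- sub("\\*$", "", x$seq)  # a terminal stop is not penalized
      lengths(regmatches(aa, gregexpr("*", aa, fixed = TRUE)))
    }, integer(1))
    return(cands[[which.min(stops)]])
  }
  frame <- as.integer(frame)
  stopifnot(frame %in% 0:2)
  s <- substring(record$seq, frame + 1L)
  if (nchar(s) < 3L) stop("sequence shorter than one codon after frame offset")
  bad <- regexpr("[^ACGTRYSWKMBDHVN]", s)
  if (bad > 0L) {
    stop(sprintf("non-IUPAC symbol '%s' at position %d of '%s'",
                 substring(s, bad, bad), bad + frame, record$id))
  }
  n_codon <- nchar(s) %/% 3L
  starts <- seq.int(1L, by = 3L, length.out = n_codon)
  codons <- substring(s, starts, starts + 2L)
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"  # codons with ambiguity symbols
  out <- seq_records(record$id, paste(aa, collapse = ""),
                     taxon = record$taxon, kind = "protein")
  out
}

#' Define reference-anchored key-residue requirements
#'
#' The catalytic residues that distinguish ACC deaminases from the closely
#' related D-cysteine desulfhydrases are specified as 1-based positions in
#' the ungapped reference protein together with the expected amino acid;
#' the defaults are Lys51, Ser78, Tyr295, Glu296 and Leu322.
#'
#' @param reference_id id of the anchor sequence in the alignment.
#' @param positions integer vector of ungapped 1-based residue positions,
#'   strictly increasing.
#' @param residues expected single-letter amino acids, same length.
#' @return A list of class `residue_policy`.
#' @export
residue_policy <- function(reference_id,
                           positions = c(51L, 78L, 295L, 296L, 322L),
                           residues = c("K", "S", "Y", "E", "L")) {
  positions <- as.integer(positions)
  residues <- toupper(as.character(residues))
  if (length(positions) != length(residues)) {
    stop("positions and residues must have equal length")
  }
  if (any(diff(positions) <= 0L)) stop("positions must be strictly increasing")
  if (any(!residues %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])) {
    stop("residues must be standard amino acids")
  }
  structure(list(reference_id = reference_id, positions = positions,
                 residues = residues),
            class = "residue_policy")
}

#' Map reference residue positions to alignment columns
#'
#' @param aln gapped protein [seq_records] (all rows equal length).
#' @param policy a [residue_policy].
#' @return Integer vector of 0-based alignment column indices, one per
#'   required position.
#' @export
map_reference_columns <- function(aln, policy) {
  stopifnot(inherits(policy, "residue_policy"))
  i <- match(policy$reference_id, aln$id)
  if (is.na(i)) stop("reference '", policy$reference_id, "' not in alignment")
  chars <- strsplit(aln$seq[i], "")[[1]]
  ungapped_pos <- cumsum(chars != "-")
  cols <- match(policy$positions, ungapped_pos)
  if (anyNA(cols)) {
    missing <- policy$positions[is.na(cols)][1]
    stop("reference shorter than required position ", missing)
  }
  cols - 1L
}

#' Filter aligned sequences by catalytic key residues
#'
#' A sequence is kept only if, at every alignment column holding one of the
#' reference's key residues, it carries exactly the expected amino acid.
#' Sequences with a different residue are discarded as likely paralogs
#' (status `"mismatch"`); sequences with a gap at a required column lack
#' coverage of that residue and are discarded with status `"incomplete"`.
#' The reference itself is always kept.
#'
#' @param aln gapped protein [seq_records].
#' @param policy a [residue_policy].
#' @return A `curation_report`: list with `kept` (ids), `discarded`
#'   (data frame id/position/observed/status) and `dereplicated_away`.
#' @export
filter_by_key_residues <- function(aln, policy) {
  if (nrow(aln) == 0L) stop("empty alignment")
  cols0 <- map_reference_columns(aln, policy)
  keep <- logical(nrow(aln))
  disc <- vector("list", nrow(aln))
  for (r in seq_len(nrow(aln))) {
    if (aln$id[r] == policy$reference_id) {
      keep[r] <- TRUE
      next
    }
    obs <- substring(aln$seq[r], cols0 + 1L, cols0 + 1L)
    bad <- which(obs != policy$residues)
    if (length(bad) == 0L) {
      keep[r] <- TRUE
    } else {
      b <- bad[1]
      disc[[r]] <- data.frame(
        id = aln$id[r], position = policy$positions[b], observed = obs[b],
        status = if (obs[b] == "-") "incomplete" else "mismatch",
        stringsAsFactors = FALSE)
    }
  }
  curation_report(kept = aln$id[keep], discarded = do.call(rbind, disc))
}

#' Dereplicate a nucleotide database at 100% identity within species
#'
#' Among entries with identical nucleotide sequence and identical species
#' label, only one (the lexicographically smallest id) is retained;
#' identical sequences from different species are all retained.
#'
#' @param records nucleotide [seq_records].
#' @return A `curation_report`; removed ids appear in `discarded` with
#'   status `"duplicate"` and in `dereplicated_away` paired with the
#'   retained id.
#' @export
dereplicate <- function(records) {
  stopifnot(all(records$kind == "nucleotide"))
  key <- paste(records$seq, records$taxon, sep = "\r")
  ord <- order(key, records$id, method = "radix")
  first_of_group <- !duplicated(key[ord])
  retained_idx <- ord[first_of_group]
  retained_for <- retained_idx[cumsum(first_of_group)]  # per ordered row
  removed <- ord[!first_of_group]
  pairs <- if (length(removed)) {
    data.frame(removed = records$id[removed],
               retained = records$id[retained_for[!first_of_group]],
               stringsAsFactors = FALSE)
  } else NULL
  disc <- if (length(removed)) {
    data.frame(id = records$id[removed], position = NA_integer_,
               observed = NA_character_, status = "duplicate",
               stringsAsFactors = FALSE)
  } else NULL
  curation_report(kept = records$id[sort(retained_idx)], discarded = disc,
                  dereplicated_away = pairs)
}

curation_report <- function(kept, discarded = NULL, dereplicated_away = NULL) {
  if (is.null(discarded)) {
    discarded <- data.frame(id = character(), position = integer(),
                            observed = character(), status = character(),
                            stringsAsFactors = FALSE)
  }
  if (is.null(dereplicated_away)) {
    dereplicated_away <- data.frame(removed = character(),
                                    retained = character(),
                                    stringsAsFactors = FALSE)
  }
  if (length(intersect(kept, discarded$id))) {
    stop("internal error: id both kept and discarded")
  }
  structure(list(kept = kept, discarded = discarded,
                 dereplicated_away = dereplicated_away),
            class = "curation_report")
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Curation report:", length(x$kept), "kept,",
      nrow(x$discarded), "discarded,",
      nrow(x$dereplicated_away), "dereplicated away\n")
  invisible(x)
}

#' Write a curation report as TSV (id, status, detail)
#'
#' @param report a `curation_report`.
#' @param path output file.
#' @export
write_curation_report <- function(report, path) {
  kept <- data.frame(id = report$kept, status = "kept", detail = "",
                     stringsAsFactors = FALSE)
  disc <- report$discarded
  detail <- ifelse(disc$status == "duplicate",
                   paste0("retained=", report$dereplicated_away$retained[
                     match(disc$id, report$dereplicated_away$removed)]),
                   paste0("pos", disc$position, "=", disc$observed))
  disc_out <- data.frame(id = disc$id, status = disc$status,
                         detail = if (nrow(disc)) detail else character(),
                         stringsAsFactors = FALSE)
  utils::write.table(rbind(kept, disc_out), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract the amplified core region from each database entry
#'
#' Runs in-silico PCR on every template and returns, for templates with a
#' unique amplicon, the primer-inclusive amplicon subsequence (for the
#' acdSF5/acdSR8-style assay this is the 133-nt core region). Templates
#' without an amplicon, or with several, are omitted and logged via the
#' `"log"` attribute (id, status in `no_amplicon`/`ambiguous`).
#'
#' @param db nucleotide [seq_records] templates.
#' @param pair a [primer_pair].
#' @param max_mismatch per-primer mismatch tolerance.
#' @param max_product maximum product length considered.
#' @return Core-region [seq_records] with attribute `log`.
#' @export
extract_core_region <- function(db, pair, max_mismatch = 3L,
                                max_product = 300L) {
  out <- vector("list", nrow(db))
  log <- character(nrow(db))
  for (r in seq_len(nrow(db))) {
    hits <- insilico_pcr(pair, db[r, , drop = FALSE],
                         max_mm = max_mismatch, max_product = max_product)
    if (nrow(hits) == 0L) {
      log[r] <- "no_amplicon"
    } else if (nrow(hits) > 1L) {
      log[r] <- "ambiguous"
    } else {
      log[r] <- "extracted"
      out[[r]] <- data.frame(
        id = db$id[r], taxon = db$taxon[r],
        seq = substring(db$seq[r], hits$start + 1L, hits$end),
        kind = "nucleotide", stringsAsFactors = FALSE)
    }
  }
  core <- do.call(rbind, out)
  core <- if (is.null(core)) {
    seq_records(character(0), character(0))
  } else {
    structure(core, class = c("seq_records", "data.frame"))
  }
  attr(core, "log") <- data.frame(id = db$id, status = log,
                                  stringsAsFactors = FALSE)
  core
}
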