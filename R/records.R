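#' Construct a collection of labeled sequence records
#'
#' The basic container used throughout the package: a data frame with one
#' row per sequence and columns `id`, `taxon`, `seq` and `kind`. Nucleotide
#' records are restricted to IUPAC symbols; gapped (aligned) sequences may
#' additionally contain `-`.
#'
#' @param id character vector of unique, non-empty identifiers.
#' @param seq character vector of sequences (upper-cased on input).
#' @param taxon free-text genus/species labels (recycled if length 1).
#' @param kind `"nucleotide"` or `"protein"`.
#' @param gapped logical; allow the alignment gap symbol `-`.
#' @return A `data.frame` of class `seq_records`.
#' @export
seq_records <- function(id, seq, taxon = "", kind = c("nucleotide", "protein"),
                        gapped = FALSE) {
  kind <- match.arg(kind)
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) stop("id and seq must have equal length")
  if (any(!nzchar(id))) stop("sequence ids must be non-empty")
  if (anyDuplicated(id)) {
    stop("duplicate sequence ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(!nzchar(seq))) stop("sequences must be non-empty")
  if (kind == "nucleotide") {
    alphabet <- "ACGTRYSWKMBDHVN"
    if (gapped) alphabet <- paste0(alphabet, "-")
    bad <- grepl(sprintf("[^%s]", alphabet), seq)
    if (any(bad)) {
      stop("non-IUPAC symbol in nucleotide sequence(s): ",
           paste(id[bad], collapse = ", "))
    }
  }
  taxon <- rep_len(as.character(taxon), length(id))
  out <- data.frame(id = id, taxon = taxon, seq = seq, kind = kind,
                    stringsAsFactors = FALSE)
  class(out) <- c("seq_records", "data.frame")
  out
}

#' Read sequences from a FASTA file
#'
#' The identifier is the header token before the first whitespace; the
#' remainder of the header line is carried as the taxonomy label.
#'
#' @param path FASTA file.
#' @param kind `"nucleotide"` or `"protein"`.
#' @param gapped logical; allow `-` in sequences (aligned FASTA).
#' @return A [seq_records] data frame.
#' @export
read_fasta <- function(path, kind = c("nucleotide", "protein"), gapped = FALSE) {
  kind <- match.arg(kind)
  set <- if (kind == "protein") {
    Biostrings::readAAStringSet(path)
  } else {
    Biostrings::readBStringSet(path)
  }
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  taxon <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seq_records(id, as.character(set), taxon = taxon, kind = kind, gapped = gapped)
}

#' Write sequence records to FASTA (wrapped at 60 columns)
#'
#' @param records a [seq_records] data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  headers <- ifelse(nzchar(records$taxon),
                    paste(records$id, records$taxon),
                    records$id)
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Reverse complement of nucleotide sequences
#'
#' @param seq character vector of nucleotide sequences (IUPAC symbols).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  plain <- !grepl("[^ACGT]", seq)
  out <- character(length(seq))
  if (any(plain)) {
    comp <- chartr("ACGT", "TGCA", seq[plain])
    out[plain] <- vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))),
                         character(1), USE.NAMES = FALSE)
  }
  if (any(!plain)) {
    out[!plain] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seq[!plain])))
  }
  out
}

# Drop alignment gaps from a gapped sequence.
ungap <- function(seq) gsub("-", "", seq, fixed = TRUE)
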