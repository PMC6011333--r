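#' Kimura two-parameter distance between two aligned sequences
#'
#' `K = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)` where `P` and `Q` are the
#' transition and transversion fractions over retained sites; sites where
#' either sequence carries a gap or an ambiguity symbol are excluded.
#'
#' @param a,b aligned nucleotide sequences of equal length.
#' @return Distance in substitutions per site.
#' @export
k2p_distance <- function(a, b) {
  a <- strsplit(toupper(a), "")[[1]]
  b <- strsplit(toupper(b), "")[[1]]
  if (length(a) != length(b)) stop("sequences must be of equal length")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("no comparable sites")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  purine <- c("A", "G")
  transition <- a != b & ((a %in% purine) == (b %in% purine))
  transversion <- a != b & !transition
  P <- sum(transition) / n
  Q <- sum(transversion) / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) {
    stop("saturated pair: K2P distance undefined (P=", round(P, 3),
         ", Q=", round(Q, 3), ")")
  }
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

#' K2P distance matrix for a set of aligned sequences
#'
#' @param aln gapped nucleotide [seq_records].
#' @return Symmetric labeled distance matrix.
#' @export
k2p_matrix <- function(aln) {
  n <- nrow(aln)
  d <- matrix(0, n, n, dimnames = list(aln$id, aln$id))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      d[i, j] <- d[j, i] <- k2p_distance(aln$seq[i], aln$seq[j])
    }
  }
  d
}

#' Pairwise Euclidean (absolute) distances of per-sample quantities
#'
#' For scalar qPCR/qRT-PCR quantities the pairwise Euclidean distance
#' reduces to `|x_i - x_j|`, optionally on log10-transformed values.
#'
#' @param values named numeric vector (label -> quantity).
#' @param log_transform take log10 first (values must be positive).
#' @return Symmetric labeled distance matrix.
#' @export
euclidean_pairwise <- function(values, log_transform = FALSE) {
  if (length(values) < 2L) stop("at least 2 labels are required")
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    stop("values must be named by sample/genotype label")
  }
  if (log_transform) {
    if (any(values <= 0)) stop("log transform requires positive values")
    values <- log10(values)
  }
  d <- as.matrix(stats::dist(values, method = "euclidean"))
  dimnames(d) <- list(names(values), names(values))
  d
}

# Upper-triangle vectorization in matching label order.
.upper_vec <- function(d, labels) d[labels, labels][upper.tri(d)]

#' Correlation between two distance matrices
#'
#' `method = "spearman"` ranks the vectorized upper triangles and reports
#' the Spearman coefficient with asymptotic and (for small n, tie-free)
#' exact two-sided p-values, treating the pairwise distances as if
#' independent — the convention of the assay this package reproduces.
#' `method = "mantel_spearman"` keeps the same statistic but derives the
#' p-value by permuting one matrix's labels, `p = (count + 1)/(perms + 1)`
#' (one-sided, positive association), which respects the non-independence
#' of pairwise distances.
#'
#' @param dx,dy symmetric labeled distance matrices over the same label set.
#' @param method `"spearman"` or `"mantel_spearman"`.
#' @param permutations permutation count for the Mantel test.
#' @param seed RNG seed for permutations.
#' @return List of class `correlation_result`: `rho`, `p`, `p_exact`
#'   (spearman only, NA when ties prevent it), `n` pairs, `method`.
#' @export
distance_correlation <- function(dx, dy,
                                 method = c("spearman", "mantel_spearman"),
                                 permutations = 999L, seed = 1L) {
  method <- match.arg(method)
  labels <- rownames(dx)
  if (is.null(labels) || is.null(rownames(dy)) ||
      !setequal(labels, rownames(dy))) {
    stop("distance matrices must share an identical label set")
  }
  labels <- sort(labels)
  if (length(labels) < 3L) stop("need at least 3 labels (3 pairs)")
  x <- .upper_vec(dx, labels)
  y <- .upper_vec(dy, labels)
  rho <- stats::cor(x, y, method = "spearman")
  if (method == "spearman") {
    asym <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
    p_exact <- NA_real_
    if (!anyDuplicated(x) && !anyDuplicated(y) && length(x) <= 9) {
      p_exact <- stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
    }
    out <- list(rho = unname(rho), p = asym$p.value, p_exact = p_exact,
                n = length(x), method = method)
  } else {
    set.seed(seed)
    count <- 0L
    n <- length(labels)
    dy_o <- dy[labels, labels]
    for (i in seq_len(permutations)) {
      perm <- sample.int(n)
      yp <- dy_o[perm, perm][upper.tri(dy_o)]
      if (stats::cor(x, yp, method = "spearman") >= rho) count <- count + 1L
    }
    out <- list(rho = unname(rho), p = (count + 1) / (permutations + 1),
                p_exact = NA_real_, n = length(x), method = method)
  }
  structure(out, class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f, p = %.4g (%s, n = %d pairs)\n",
              x$rho, x$p, x$method, x$n))
  invisible(x)
}

#' Read/write square labeled distance matrices as TSV
#'
#' @param path TSV file with row and column labels.
#' @return Numeric matrix with dimnames.
#' @export
read_distance_tsv <- function(path) {
  d <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  storage.mode(d) <- "double"
  d
}

#' @rdname read_distance_tsv
#' @param d labeled square matrix.
#' @export
write_distance_tsv <- function(d, path) {
  utils::write.table(data.frame(label = rownames(d), d, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
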