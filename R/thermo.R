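#' Construct an oligonucleotide with reaction conditions
#'
#' @param seq 5'->3' sequence over A/C/G/T (no ambiguity codes).
#' @param conc_molar total single-strand concentration (mol/L); default
#'   1e-6 (1 uM, the assay's primer concentration).
#' @param salt_molar monovalent cation concentration (mol/L); default 0.05.
#' @return A list of class `oligo`.
#' @export
oligo <- function(seq, conc_molar = 1e-6, salt_molar = 0.05) {
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) {
    stop("oligo contains ambiguous or invalid base: ", seq)
  }
  if (conc_molar <= 0 || salt_molar <= 0) stop("concentrations must be > 0")
  structure(list(seq = seq, conc_molar = conc_molar, salt_molar = salt_molar),
            class = "oligo")
}

as_oligo <- function(x, ...) if (inherits(x, "oligo")) x else oligo(x, ...)

# Unified nearest-neighbor parameters (SantaLucia 1998).
# dh in kcal/mol, ds in cal/(mol K), keyed by the top-strand dinucleotide.
.nn_dh <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.nn_ds <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
# Duplex initiation, per terminal base pair.
.init_dh <- c(G = 0.1, C = 0.1, A = 2.3, T = 2.3)
.init_ds <- c(G = -2.8, C = -2.8, A = 4.1, T = 4.1)

#' Two-state nearest-neighbor melting temperature
#'
#' Computes duplex enthalpy and entropy by summing unified nearest-neighbor
#' stacking parameters plus initiation terms, applies the monovalent-salt
#' entropy correction `dS + 0.368 (N-1) ln[Na+]`, and converts to a melting
#' temperature via the two-state relation
#' `Tm = 1000 dH / (dS + R ln(C/x)) - 273.15` with `x = 4` for
#' non-self-complementary oligos (`x = 1` plus a symmetry entropy term for
#' self-complementary ones).
#'
#' @param x an [oligo] (or plain sequence, taken at default conditions).
#' @return List of class `thermo_result`: `tm_c` (deg C), `dh` (kcal/mol),
#'   `ds` (cal/mol/K, salt-corrected).
#' @export
melt_temp <- function(x) {
  x <- as_oligo(x)
  n <- nchar(x$seq)
  if (n < 8L) stop("oligo too short for a meaningful duplex Tm")
  chars <- strsplit(x$seq, "")[[1]]
  steps <- paste0(chars[-n], chars[-1])
  dh <- sum(.nn_dh[steps]) + .init_dh[chars[1]] + .init_dh[chars[n]]
  ds <- sum(.nn_ds[steps]) + .init_ds[chars[1]] + .init_ds[chars[n]]
  self_comp <- identical(x$seq, revcomp(x$seq))
  if (self_comp) ds <- ds - 1.4
  ds_salt <- ds + 0.368 * (n - 1L) * log(x$salt_molar)
  conc_div <- if (self_comp) 1 else 4
  R <- 1.9872
  tm_k <- dh * 1000 / (ds_salt + R * log(x$conc_molar / conc_div))
  structure(list(tm_c = unname(tm_k - 273.15), dh = unname(dh),
                 ds = unname(ds_salt)),
            class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("Tm = %.2f degC (dH = %.1f kcal/mol, dS = %.1f cal/mol/K)\n",
              x$tm_c, x$dh, x$ds))
  invisible(x)
}

#' Detect intramolecular hairpin potential
#'
#' Flags an oligo if two antiparallel reverse-complementary runs of at
#' least `min_stem` bases are separated by a loop of at least `min_loop`
#' unpaired bases. Detection is complementarity-run based, as in classical
#' primer-design heuristics, not free-energy folding.
#'
#' @param x an [oligo] or sequence.
#' @param min_stem minimum paired stem length (>= 3).
#' @param min_loop minimum loop length (>= 3).
#' @return List: `hairpin` (flag), `stem` (longest qualifying stem, 0 if none).
#' @export
hairpin_check <- function(x, min_stem = 4L, min_loop = 3L) {
  x <- as_oligo(x)
  stopifnot(min_stem >= 3L, min_loop >= 3L)
  s <- strsplit(x$seq, "")[[1]]
  n <- length(s)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  best <- 0L
  # run[i, j]: length of the antiparallel complementary run whose innermost
  # pair is (i, j); extends outward to (i-1, j+1) etc.
  run <- matrix(0L, n + 1L, n + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i && s[j] == comp[[s[i]]]) {
        run[i + 1L, j] <- if (i > 1L && j < n) run[i, j + 1L] + 1L else 1L
        # recurrence indexed with offset: run[i+1, j] holds value for (i, j)
      }
    }
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      L <- run[i + 1L, j]
      if (L >= min_stem && (j - i - 1L) >= min_loop && L > best) best <- L
    }
  }
  list(hairpin = best >= min_stem, stem = best)
}

# Longest antiparallel complementary run between a and b; returns overall
# longest and the longest run anchored at either oligo's 3' terminus.
.dimer_runs <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(revcomp(b), "")[[1]]  # common substring with rc(b) = duplex run
  n <- length(x); m <- length(y)
  best <- 0L; best3 <- 0L
  prev <- integer(m + 1L)
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    for (j in seq_len(m)) {
      if (x[i] == y[j]) {
        L <- prev[j] + 1L
        cur[j + 1L] <- L
        if (L > best) best <- L
        # anchored at a's 3' end (i == n) or at b's 3' end (j == 1 in rc(b)
        # coordinates corresponds to the run covering b's 3' base)
        if (i == n && L > best3) best3 <- L
        if (j - L + 1L == 1L && L > best3) best3 <- L
      }
    }
    prev <- cur
  }
  list(run = best, three_prime_run = best3)
}

#' Detect primer-dimer potential between two oligos
#'
#' Flags a pair if they share an antiparallel complementary run of at least
#' `min_run` bases anywhere, or a run of at least `min_run_3p` bases that
#' includes either primer's 3'-terminal base (extension-competent dimers).
#' Self-dimers are checked by passing the same oligo twice.
#'
#' @param a,b [oligo]s or sequences.
#' @param min_run minimum internal complementary run (>= 4).
#' @param min_run_3p minimum 3'-anchored run.
#' @return List: `dimer` (flag), `run` (longest complementary run),
#'   `three_prime_run` (longest run anchored at a 3' terminus).
#' @export
dimer_check <- function(a, b = a, min_run = 8L, min_run_3p = 4L) {
  stopifnot(min_run >= 4L)
  a <- as_oligo(a); b <- as_oligo(b)
  r <- .dimer_runs(a$seq, b$seq)
  list(dimer = r$run >= min_run || r$three_prime_run >= min_run_3p,
       run = r$run, three_prime_run = r$three_prime_run)
}
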