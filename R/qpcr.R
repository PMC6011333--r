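#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10(template concentration). By
#' default the mean Ct of the replicates at each concentration is
#' regressed (one point per dilution, as standard curves are usually
#' built); `per_replicate = TRUE` switches to fitting all points.
#' Amplification efficiency is derived from the slope as
#' `E = 10^(-1/slope) - 1`.
#'
#' @param points data frame with columns `conc` (g/uL, > 0) and `ct`
#'   (cycles, > 0); an optional `replicate` column is carried through.
#' @param per_replicate fit on all replicate points instead of means.
#' @return List of class `standard_curve`: `slope` (cycles per
#'   log10(conc)), `intercept`, `r2`, `mse` (residual mean square,
#'   divisor n-2), `efficiency` (fraction), `ct_range`, `conc_range`, `n`.
#' @export
fit_standard_curve <- function(points, per_replicate = FALSE) {
  stopifnot(all(c("conc", "ct") %in% names(points)))
  if (any(points$conc <= 0)) stop("concentrations must be > 0")
  if (any(points$ct <= 0)) stop("Ct values must be > 0")
  if (length(unique(points$conc)) < 3L) {
    stop("at least 3 distinct concentrations are required")
  }
  if (per_replicate) {
    dat <- data.frame(x = log10(points$conc), y = points$ct)
  } else {
    agg <- stats::aggregate(ct ~ conc, data = points, FUN = mean)
    dat <- data.frame(x = log10(agg$conc), y = agg$ct)
  }
  fit <- stats::lm(y ~ x, data = dat)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  r2 <- summary(fit)$r.squared
  mse <- sum(stats::residuals(fit)^2) / (nrow(dat) - 2L)
  eff <- NA_real_
  if (slope >= 0) {
    warning("non-negative slope: efficiency undefined")
  } else {
    eff <- 10^(-1 / slope) - 1
  }
  structure(list(slope = slope, intercept = intercept, r2 = r2, mse = mse,
                 efficiency = eff,
                 ct_range = range(dat$y), conc_range = range(points$conc),
                 n = nrow(dat)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "Standard curve: Ct = %.4f log10(conc) + %.4f | R2 = %.4f, MSE = %.4g, E = %s\n",
    x$slope, x$intercept, x$r2, x$mse,
    if (is.na(x$efficiency)) "undefined"
    else sprintf("%.1f%%", 100 * x$efficiency)))
  invisible(x)
}

#' Amplification efficiency from a standard-curve slope
#'
#' `E = 100 (10^(-1/slope) - 1)` percent. A slope of -3.32 corresponds to
#' perfect doubling (100%); slopes of -3.0 and -3.9 bracket the usual
#' 80-115% acceptance window.
#'
#' @param slope standard-curve slope (cycles per log10 concentration).
#' @return Efficiency in percent.
#' @export
efficiency_from_slope <- function(slope) {
  if (any(slope == 0)) stop("slope must be non-zero")
  100 * (10^(-1 / slope) - 1)
}

#' Convert template DNA mass to gene copy number
#'
#' copies = mass (g) x Avogadro's number / (template length (bp) x
#' 660 g/mol per bp), for a single-copy template.
#'
#' @param mass_g template mass in grams.
#' @param template_bp template length in base pairs (the amplicon or the
#'   genome carrying one copy).
#' @return List: `copies` (real) and `rounded` (nearest integer).
#' @export
copies_from_mass <- function(mass_g, template_bp) {
  if (any(mass_g <= 0) || any(template_bp <= 0)) {
    stop("mass and template length must be positive")
  }
  avogadro <- 6.02214076e23
  copies <- mass_g * avogadro / (template_bp * 660)
  list(copies = copies, rounded = round(copies))
}

# Inverse of copies_from_mass, used by the synthetic Ct generator.
mass_from_copies <- function(copies, template_bp) {
  copies * template_bp * 660 / 6.02214076e23
}

#' Quantify a sample from its Ct via a standard curve
#'
#' Inverts the curve (`conc = 10^((ct - intercept)/slope)`), converts the
#' per-reaction template mass to copies, and scales to copies per gram of
#' soil given the fraction of the extract in the reaction. Samples whose
#' Ct falls beyond the Ct of the most dilute standard are flagged as below
#' the quantification limit (reported, not zeroed).
#'
#' @param ct observed quantification cycle(s).
#' @param curve a [standard_curve].
#' @param template_bp template length in bp (see [copies_from_mass]).
#' @param reaction_volume_ul template volume per reaction (uL), used to
#'   turn the curve's g/uL into grams per reaction.
#' @param reaction_fraction fraction of the total extract in the reaction.
#' @param soil_g grams of soil the extract derives from.
#' @return Data frame: `ct`, `conc_g_per_ul`, `copies_per_reaction`,
#'   `copies_per_g`, `below_limit`.
#' @export
quantify_sample <- function(ct, curve, template_bp,
                            reaction_volume_ul = 2, reaction_fraction = NULL,
                            soil_g = NULL) {
  stopifnot(inherits(curve, "standard_curve"))
  if (is.na(curve$efficiency) || curve$slope >= 0) {
    stop("invalid standard curve (non-negative slope)")
  }
  conc <- 10^((ct - curve$intercept) / curve$slope)
  mass <- conc * reaction_volume_ul
  copies <- copies_from_mass(mass, template_bp)$copies
  below <- ct > max(curve$ct_range)
  per_g <- rep(NA_real_, length(ct))
  if (!is.null(reaction_fraction) && !is.null(soil_g)) {
    per_g <- copies / reaction_fraction / soil_g
  }
  data.frame(ct = ct, conc_g_per_ul = conc, copies_per_reaction = copies,
             copies_per_g = per_g, below_limit = below)
}
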