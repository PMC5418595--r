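# Assay arithmetic: plate-based growth-inhibition percentages, LCMS
# calibration-curve quantification with LOD/LOQ flags, and yield fold-changes
# with unit normalisation. Concentrations are normalised internally to
# pg per ml.

.UNIT_FACTORS <- c(pg = 1, ng = 1e3, ug = 1e6, mg = 1e9)

# "ng/ml", "ng ml-1", "ng.ml^-1", unicode mu variants -> pg/ml factor
parse_conc_unit <- function(unit) {
  u <- tolower(trimws(unit))
  u <- gsub("µ|μ", "u", u)
  prefix <- sub("^\\s*([pnum]?g).*$", "\\1", u)
  if (!prefix %in% names(.UNIT_FACTORS) || !grepl("ml", u))
    stop("unrecognised concentration unit: '", unit,
         "' (expected pg/ng/ug/mg per ml)")
  .UNIT_FACTORS[[prefix]]
}

#' Growth-inhibition percentage from OD600 fold-changes
#'
#' Inhibition is computed by dividing the overnight OD600 fold-change caused
#' by the sample (spent culture media) by the fold-change caused by the
#' control media and subtracting from 100\%:
#' `100 * (1 - (od18_s/od0_s) / (od18_c/od0_c))`.
#' Negative values (growth promotion) are reported as computed, with a
#' warning flag, never clamped.
#'
#' @param sample,control Each a numeric vector `c(od600_t0, od600_t18)` or a
#'   list/row with elements `od600_t0`, `od600_t18`.
#' @return A numeric scalar (percent) with attribute `flag = "negative"` when
#'   below zero.
#' @examples
#' growth_inhibition(c(0.1, 0.1), c(0.1, 0.5))   # no growth vs 5x: 80%
#' @export
growth_inhibition <- function(sample, control) {
  fc <- function(x) {
    x <- unlist(x)
    od0 <- if (!is.null(names(x)) && "od600_t0" %in% names(x))
      x[["od600_t0"]] else x[[1]]
    od18 <- if (!is.null(names(x)) && "od600_t18" %in% names(x))
      x[["od600_t18"]] else x[[2]]
    if (!is.finite(od0) || !is.finite(od18) || od0 <= 0 || od18 < 0)
      stop("OD600 readings must be positive (baseline) and nonnegative")
    od18 / od0
  }
  fcs <- fc(sample); fcc <- fc(control)
  if (fcc <= 0) stop("control fold-change must be positive")
  pct <- 100 * (1 - fcs / fcc)
  if (pct < 0) attr(pct, "flag") <- "negative"
  pct
}

#' Growth inhibition for a whole plate
#'
#' @param plate data.frame with columns `well`, `strain`, `role`
#'   (`"sample"`/`"control"`), `od600_t0`, `od600_t18` (see the plate CSV
#'   interface).
#' @return `plate` with added columns `fold_change`, `inhibition_pct`, `flag`;
#'   the control fold-change is the mean over control wells.
#' @export
plate_inhibition <- function(plate) {
  need <- c("role", "od600_t0", "od600_t18")
  stopifnot(all(need %in% names(plate)))
  if (any(plate$od600_t0 <= 0)) stop("OD600 baseline must be positive")
  plate$fold_change <- plate$od600_t18 / plate$od600_t0
  ctrl <- mean(plate$fold_change[plate$role == "control"])
  if (!is.finite(ctrl) || ctrl <= 0)
    stop("no usable control wells (need role == 'control')")
  plate$inhibition_pct <- 100 * (1 - plate$fold_change / ctrl)
  plate$flag <- ifelse(plate$inhibition_pct < 0, "negative", "")
  plate
}

#' Fit an LCMS calibration curve
#'
#' Ordinary least squares of instrument counts on concentration, restricted
#' to the detected linear range: the largest contiguous run of standards
#' (sorted by concentration) whose consecutive log-log slopes deviate from 1
#' by less than `slope_tol`. This automates the by-eye range selection of a
#' spreadsheet workflow; a saturated top standard (flat counts, log-log slope
#' near 0) is excluded automatically.
#'
#' @param concentration Standard concentrations (same unit, strictly
#'   positive); defaults assume the four-standard series 10 ng/ml, 100 ng/ml,
#'   10 ug/ml, 100 ug/ml expressed in one unit.
#' @param counts Nonnegative instrument counts, parallel to `concentration`.
#' @param slope_tol Log-log slope tolerance (default 0.1).
#' @param analyte Label carried through.
#' @return An object of class `calibration_curve`: `analyte`, `points`
#'   (data.frame concentration/counts), `range_idx` (indices used), `slope`,
#'   `intercept`.
#' @export
fit_calibration <- function(concentration, counts, slope_tol = 0.1,
                            analyte = "analyte") {
  stopifnot(length(concentration) == length(counts),
            length(concentration) >= 2)
  if (any(concentration <= 0)) stop("concentrations must be strictly positive")
  if (any(counts < 0)) stop("counts must be nonnegative")
  ord <- order(concentration)
  conc <- concentration[ord]; cnt <- counts[ord]
  if (anyDuplicated(conc)) stop("duplicate standard concentrations")
  ok <- rep(FALSE, length(conc) - 1)
  pos <- cnt > 0
  for (i in seq_along(ok)) {
    if (pos[i] && pos[i + 1]) {
      s <- (log(cnt[i + 1]) - log(cnt[i])) / (log(conc[i + 1]) - log(conc[i]))
      ok[i] <- abs(s - 1) < slope_tol
    }
  }
  runs <- rle(ok)
  if (!any(runs$values))
    stop("fewer than 2 points in the linear range")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  cand <- which(runs$values)
  best <- cand[which.max(runs$lengths[cand])]   # ties: first (lowest conc)
  idx <- starts[best]:(ends[best] + 1)          # L slopes -> L+1 points
  fit <- lm(cnt[idx] ~ conc[idx])
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  if (!is.finite(slope) || slope <= 0)
    stop("calibration slope must be positive")
  structure(list(analyte = analyte,
                 points = data.frame(concentration = conc, counts = cnt),
                 range_idx = idx, slope = slope, intercept = intercept),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration curve [%s]: counts = %.6g * conc + %.6g (%d/%d standards in linear range)\n",
              x$analyte, x$slope, x$intercept, length(x$range_idx),
              nrow(x$points)))
  invisible(x)
}

#' Quantify samples against a calibration curve
#'
#' Inverts the line of best fit, `concentration = (counts - intercept) /
#' slope`, and flags detectability by signal-to-noise: below the limit of
#' detection when `counts/noise < 3`, below the limit of quantification when
#' `counts/noise < 10`. Counts below the intercept give concentration 0 with
#' a `below_intercept` flag.
#'
#' @param counts Sample counts (vector).
#' @param curve A [fit_calibration()] result.
#' @param noise Instrument noise level (same scale as counts); `NA` disables
#'   the S/N flags.
#' @param lod_snr,loq_snr Signal-to-noise thresholds (defaults 3 and 10).
#' @return data.frame: `counts`, `concentration` (unit of the standards),
#'   `snr`, `flag` (semicolon-joined tags among `below_intercept`,
#'   `below_lod`, `below_loq`).
#' @export
quantify <- function(counts, curve, noise = NA_real_, lod_snr = 3,
                     loq_snr = 10) {
  stopifnot(inherits(curve, "calibration_curve"))
  conc <- (counts - curve$intercept) / curve$slope
  flag <- lapply(seq_along(counts), function(i) {
    f <- character()
    if (conc[i] < 0) f <- c(f, "below_intercept")
    if (!is.na(noise)) {
      snr <- counts[i] / noise
      if (snr < lod_snr) f <- c(f, "below_lod")
      if (snr < loq_snr) f <- c(f, "below_loq")
    }
    paste(f, collapse = ";")
  })
  conc <- pmax(conc, 0)
  data.frame(counts = counts, concentration = conc,
             snr = if (is.na(noise)) NA_real_ else counts / noise,
             flag = unlist(flag), stringsAsFactors = FALSE)
}

#' Yield fold-change with unit normalisation
#'
#' Ratio of two concentrations after converting both to pg per ml; supports
#' pg/ng/ug/mg per ml unit strings (e.g. `"ng/ml"`, `"pg ml-1"`).
#'
#' @param yield_a,yield_b Positive concentrations.
#' @param units_a,units_b Their units.
#' @return `yield_a / yield_b` as a dimensionless ratio.
#' @examples
#' fold_change(3, 90, "ng/ml", "pg/ml")   # ~33.3
#' @export
fold_change <- function(yield_a, yield_b, units_a = "ng/ml",
                        units_b = "ng/ml") {
  stopifnot(yield_a > 0, yield_b > 0)
  (yield_a * parse_conc_unit(units_a)) / (yield_b * parse_conc_unit(units_b))
}
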