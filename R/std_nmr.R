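#' STD difference intensity
#'
#' Intensity of the saturation-transfer difference spectrum,
#' `I_STD = I_off - I_on`. A negative value (on-resonance brighter than
#' off-resonance) is nonphysical for a true saturation transfer and is
#' flagged with a warning.
#'
#' @param i_off Off-resonance (reference) peak intensity.
#' @param i_on On-resonance (saturated) peak intensity.
#' @return The difference intensity.
#' @export
std_intensity <- function(i_off, i_on) {
  d <- i_off - i_on
  if (any(d < 0))
    warning("negative STD intensity (I_on > I_off): nonphysical saturation transfer")
  d
}

#' STD amplification factor
#'
#' Ratio of the difference-spectrum intensity to the off-resonance
#' reference, `A_STD = I_STD / I_0 = (I_0 - I_SAT) / I_0`, per ligand
#' proton. Protons close to the protein surface receive more saturation
#' transfer and show larger values.
#'
#' @param i_std Difference-spectrum intensity.
#' @param i_off Off-resonance reference intensity I0 (> 0).
#' @return The dimensionless ratio.
#' @export
amplification_factor <- function(i_std, i_off) {
  if (any(i_off <= 0)) stop("reference intensity I0 must be positive")
  i_std / i_off
}

#' Normalized epitope map
#'
#' Normalizes per-proton STD values so the largest equals exactly 100%,
#' each other value scaled proportionally: `pct = 100 * raw / max(raw)`.
#' The map is invariant under positive rescaling of all raw values and
#' idempotent on already-normalized input. Nonpositive raw values are
#' excluded with a warning.
#'
#' @param labels Proton labels (character or coercible).
#' @param raw Raw STD values (I_STD or A_STD ratios), > 0.
#' @param chemical_shift Optional chemical shifts in ppm.
#' @param condition Optional condition label (e.g. "pH 7").
#' @return An object of class `epitope_map`: a data.frame with columns
#'   `label`, `chemical_shift`, `raw`, `pct`, plus a `condition` attribute.
#' @export
normalize_epitope <- function(labels, raw, chemical_shift = NA_real_,
                              condition = NULL) {
  if (length(raw) < 1L) stop("insufficient data: empty epitope table")
  if (length(labels) != length(raw)) stop("labels and raw lengths differ")
  chemical_shift <- rep_len(chemical_shift, length(raw))
  ok <- is.finite(raw) & raw > 0
  if (!any(ok)) stop("insufficient data: no positive STD values")
  if (!all(ok)) warning(sprintf("%d nonpositive STD value(s) excluded", sum(!ok)))
  d <- data.frame(label = as.character(labels)[ok],
                  chemical_shift = chemical_shift[ok],
                  raw = raw[ok],
                  stringsAsFactors = FALSE)
  d$pct <- 100 * d$raw / max(d$raw)
  structure(d, class = c("epitope_map", "data.frame"), condition = condition)
}

#' Round half away from zero
#'
#' Display rounding used for reported epitope percentages (half-up at a
#' given number of decimals); full precision is kept internally.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' @export
print.epitope_map <- function(x, ...) {
  cond <- attr(x, "condition")
  cat("STD epitope map", if (!is.null(cond)) paste0("(", cond, ")"), "\n")
  d <- as.data.frame(x)
  d$pct <- round_half_up(d$pct, 1)
  print(d, row.names = FALSE)
  invisible(x)
}

#' Build an epitope map from an STD peak table
#'
#' Accepts a table with per-proton off/on-resonance intensities, or the
#' difference intensity directly. When both `i_on` and `i_std` are present
#' their consistency (`i_std = i_off - i_on`) is checked. When `i_off` is
#' present the map is built from the amplification factor `I_STD/I_0`;
#' when only `i_std` is given the raw difference intensities are normalized
#' directly (the two differ per proton by the factor I_0).
#'
#' @param peaks data.frame with columns `proton`, optionally `shift_ppm`,
#'   and intensity columns among `i_off`, `i_on`, `i_std`.
#' @param condition Optional condition label.
#' @param tol Relative tolerance for the i_std vs (i_off - i_on) check.
#' @return An `epitope_map`.
#' @export
epitope_from_peaks <- function(peaks, condition = NULL, tol = 1e-6) {
  if (!"proton" %in% names(peaks)) stop("peak table needs a 'proton' column")
  has_off <- "i_off" %in% names(peaks)
  has_on <- "i_on" %in% names(peaks)
  has_std <- "i_std" %in% names(peaks)
  if (!has_std && !(has_off && has_on))
    stop("need either i_std or both i_off and i_on")
  istd <- if (has_std) peaks$i_std else std_intensity(peaks$i_off, peaks$i_on)
  if (has_std && has_off && has_on) {
    ref <- std_intensity(peaks$i_off, peaks$i_on)
    if (any(abs(istd - ref) > tol * pmax(abs(peaks$i_off), 1)))
      stop("inconsistent peak table: i_std != i_off - i_on")
  }
  raw <- if (has_off) amplification_factor(istd, peaks$i_off) else istd
  shift <- if ("shift_ppm" %in% names(peaks)) peaks$shift_ppm else NA_real_
  normalize_epitope(peaks$proton, raw, chemical_shift = shift,
                    condition = condition)
}

#' Compare two epitope maps
#'
#' Per-proton difference in normalized percentage between two conditions,
#' counts of protons above a saturation-transfer threshold in each map, and
#' the Kendall rank concordance of the two epitope orderings.
#'
#' @param map_a,map_b `epitope_map` objects sharing proton labels.
#' @param threshold Percentage threshold for the "strongly saturated" count
#'   (default 90).
#' @return A list with `table` (label, pct_a, pct_b, delta), `count_a`,
#'   `count_b` (protons with pct > threshold, over the full maps), and
#'   `rank_concordance` (Kendall tau over shared labels).
#' @export
compare_epitopes <- function(map_a, map_b, threshold = 90) {
  shared <- intersect(map_a$label, map_b$label)
  if (length(shared) == 0L) stop("no shared proton labels between maps")
  a <- map_a$pct[match(shared, map_a$label)]
  b <- map_b$pct[match(shared, map_b$label)]
  tau <- if (length(shared) >= 2L)
    unname(stats::cor(a, b, method = "kendall")) else NA_real_
  list(table = data.frame(label = shared, pct_a = a, pct_b = b,
                          delta = b - a, stringsAsFactors = FALSE),
       count_a = sum(map_a$pct > threshold),
       count_b = sum(map_b$pct > threshold),
       threshold = threshold,
       rank_concordance = tau)
}
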