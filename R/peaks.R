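#' Estimate a chromatographic baseline
#'
#' Morphological baseline: a rolling-minimum erosion followed by a
#' rolling-maximum dilation (an "opening", which removes features narrower
#' than `window` while reproducing flat and linearly drifting baselines
#' exactly in the interior), then a short rolling-mean smooth.
#'
#' @param chrom A [chromatogram()].
#' @param wavelength Wavelength in nm.
#' @param window Structuring-element width in minutes; must exceed the base
#'   width of real peaks (default 2 min vs the ~1.2 min base width of a
#'   0.12 min sigma peak).
#' @return Numeric baseline on the chromatogram's grid.
#' @export
estimate_baseline <- function(chrom, wavelength, window = 2) {
  if (window <= 0) stop("window must be > 0")
  y <- chrom_trace(chrom, wavelength)
  dt <- mean(diff(chrom$times))
  w <- max(3L, as.integer(round(window / dt)))
  if (w %% 2L == 0L) w <- w + 1L
  ero <- zoo::rollapply(y, w, min, partial = TRUE)
  dil <- zoo::rollapply(ero, w, max, partial = TRUE)
  sw <- max(3L, as.integer(round(w / 4)))
  if (sw %% 2L == 0L) sw <- sw + 1L
  base <- zoo::rollapply(dil, sw, mean, partial = TRUE)
  # the opening tracks the noise floor rather than its centre; recentre on
  # the residual median (peaks are sparse, so the median sits on baseline)
  base + stats::median(y - base)
}

#' Detect peaks in one trace
#'
#' Local maxima of the baseline-subtracted signal above a height threshold
#' and with sufficient topographic prominence. Peak bounds are set at the
#' valley minimum towards a neighbouring peak, or where the flank has decayed
#' to the 5-sigma-equivalent level (`height * exp(-12.5)`, floored at half the
#' height threshold to stay above baseline noise), whichever comes first.
#' Areas are trapezoidal integrals of the baseline-subtracted signal between
#' the bounds; an apex sigma estimate from the full width at half maximum is
#' attached for resolution calculations.
#'
#' @param chrom A [chromatogram()].
#' @param wavelength Wavelength in nm.
#' @param min_height Minimum baseline-subtracted apex height (default 0.1,
#'   i.e. 5 x the default baseline noise sd).
#' @param min_prominence Minimum prominence (default 0.06, 3 x the default
#'   baseline noise sd).
#' @param baseline Numeric baseline to subtract, a scalar, or `NULL` to
#'   estimate one with [estimate_baseline()].
#' @param baseline_window Passed to [estimate_baseline()] when `baseline` is
#'   `NULL`.
#' @return A `peak_table` data frame (possibly 0 rows) ordered by apex time
#'   with columns `injection_id`, `apex_time`, `left_bound`, `right_bound`,
#'   `height`, `area`, `wavelength`, `sigma_est`, `assigned`,
#'   `coelution_group`, `ambiguous`.
#' @export
detect_peaks <- function(chrom, wavelength, min_height = 0.1,
                         min_prominence = 0.06, baseline = NULL,
                         baseline_window = 2) {
  if (min_height < 0 || min_prominence < 0) stop("thresholds must be >= 0")
  if (is.null(baseline))
    baseline <- estimate_baseline(chrom, wavelength, baseline_window)
  s <- chrom_trace(chrom, wavelength) - baseline
  t <- chrom$times
  n <- length(s)

  apex <- which(s[-c(1, n)] > s[-c(n - 1, n)] & s[-c(1, n)] >= s[-c(1, 2)]) + 1L
  apex <- apex[s[apex] >= min_height]
  if (!length(apex)) return(empty_peak_table())

  # prominence: drop to the highest saddle separating the peak from higher ground
  prom <- vapply(apex, function(i) {
    h <- s[i]
    left_hi <- which(s[seq_len(i - 1)] > h)
    lmin <- if (length(left_hi)) min(s[(max(left_hi) + 1):i]) else min(s[1:i])
    right_hi <- which(s[(i + 1):n] > h)
    rmin <- if (length(right_hi)) min(s[i:(i + min(right_hi))]) else min(s[i:n])
    h - max(lmin, rmin)
  }, numeric(1))
  apex <- apex[prom >= min_prominence]
  if (!length(apex)) return(empty_peak_table())

  bounds <- matrix(NA_integer_, length(apex), 2)
  for (k in seq_along(apex)) {
    i <- apex[k]
    cutoff <- max(s[i] * exp(-12.5), 0.5 * min_height)
    li <- if (k > 1) apex[k - 1] else 1L
    ri <- if (k < length(apex)) apex[k + 1] else n
    seg <- s[li:i]
    below <- which(seg <= cutoff)
    bounds[k, 1] <- if (length(below)) li + max(below) - 1L
                    else li + which.min(seg) - 1L
    seg <- s[i:ri]
    below <- which(seg <= cutoff)
    bounds[k, 2] <- if (length(below)) i + min(below) - 1L
                    else i + which.min(seg) - 1L
  }

  sigma_est <- vapply(seq_along(apex), function(k) {
    i <- apex[k]; half <- s[i] / 2
    l <- i; while (l > bounds[k, 1] && s[l] > half) l <- l - 1L
    r <- i; while (r < bounds[k, 2] && s[r] > half) r <- r + 1L
    tl <- if (s[l] <= half && l < i)
      stats::approx(s[c(l, l + 1)], t[c(l, l + 1)], half)$y else t[l]
    tr <- if (s[r] <= half && r > i)
      stats::approx(s[c(r, r - 1)], t[c(r, r - 1)], half)$y else t[r]
    (tr - tl) / (2 * sqrt(2 * log(2)))
  }, numeric(1))

  area <- vapply(seq_along(apex), function(k) {
    idx <- bounds[k, 1]:bounds[k, 2]
    max(0, pracma::trapz(t[idx], s[idx]))
  }, numeric(1))

  out <- data.frame(injection_id = chrom$meta$injection_id,
                    apex_time = t[apex], left_bound = t[bounds[, 1]],
                    right_bound = t[bounds[, 2]], height = s[apex],
                    area = area, wavelength = as.numeric(wavelength),
                    sigma_est = sigma_est, assigned = NA_character_,
                    ambiguous = FALSE, stringsAsFactors = FALSE)
  out$coelution_group <- replicate(nrow(out), character(0), simplify = FALSE)
  class(out) <- c("peak_table", "data.frame")
  out[order(out$apex_time), , drop = FALSE]
}

empty_peak_table <- function() {
  out <- data.frame(injection_id = character(0), apex_time = numeric(0),
                    left_bound = numeric(0), right_bound = numeric(0),
                    height = numeric(0), area = numeric(0),
                    wavelength = numeric(0), sigma_est = numeric(0),
                    assigned = character(0), ambiguous = logical(0),
                    stringsAsFactors = FALSE)
  out$coelution_group <- list()
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Integrate a trace between bounds
#'
#' Trapezoidal integral of the baseline-subtracted signal between two times,
#' with linear interpolation at the exact bounds (second-order accurate: the
#' error against the closed-form Gaussian area falls with the square of the
#' grid step).
#'
#' @param chrom A [chromatogram()].
#' @param wavelength Wavelength in nm.
#' @param bounds Numeric `c(left, right)` in minutes, inside the time grid.
#' @param baseline Baseline to subtract (scalar or per-point vector).
#' @return Non-negative area in area units.
#' @export
integrate_peak <- function(chrom, wavelength, bounds, baseline = 0) {
  if (length(bounds) != 2 || bounds[1] >= bounds[2])
    stop("bounds must be c(left, right) with left < right")
  t <- chrom$times
  if (bounds[1] < t[1] || bounds[2] > t[length(t)])
    stop("bounds outside the time grid")
  s <- chrom_trace(chrom, wavelength) - baseline
  inside <- which(t > bounds[1] & t < bounds[2])
  tt <- c(bounds[1], t[inside], bounds[2])
  ss <- c(stats::approx(t, s, bounds[1])$y, s[inside],
          stats::approx(t, s, bounds[2])$y)
  max(0, pracma::trapz(tt, ss))
}

#' Assign detected peaks to library analytes
#'
#' Each peak is matched to the library analytes whose retention times lie
#' within `tolerance` of its apex. A single match assigns the peak; several
#' matches (the co-eluting formic acid / glyceraldehyde pair at 19.46 min)
#' fill `coelution_group` with all members, ordered by retention-time
#' distance then alphabetically, and `assigned` carries the first. Unmatched
#' peaks stay unassigned. If two detected peaks claim the same analyte both
#' are flagged ambiguous.
#'
#' @param peaks A `peak_table` from [detect_peaks()].
#' @param library A compound library.
#' @param tolerance Retention-time window in minutes (> 0; default 0.15 min,
#'   safe against the closest validated pair, 1.18 min apart, and against the
#'   salt peak 0.99 min before oxalic acid).
#' @return The peak table with `assigned`, `coelution_group` and `ambiguous`
#'   filled in.
#' @export
assign_peaks <- function(peaks, library, tolerance = 0.15) {
  if (tolerance <= 0) stop("tolerance must be > 0")
  if (!nrow(peaks)) return(peaks)
  for (k in seq_len(nrow(peaks))) {
    d <- abs(library$retention_time - peaks$apex_time[k])
    hit <- which(d <= tolerance)
    if (length(hit)) {
      ord <- hit[order(d[hit], library$analyte[hit])]
      peaks$coelution_group[[k]] <- library$analyte[ord]
      peaks$assigned[k] <- library$analyte[ord[1]]
    } else {
      peaks$coelution_group[[k]] <- character(0)
      peaks$assigned[k] <- NA_character_
    }
  }
  dup <- peaks$assigned[!is.na(peaks$assigned)]
  dup <- unique(dup[duplicated(dup)])
  peaks$ambiguous <- !is.na(peaks$assigned) & peaks$assigned %in% dup
  if (length(dup))
    warning("multiple peaks compete for: ", paste(dup, collapse = ", "))
  peaks
}

#' Chromatographic resolution of two peaks
#'
#' Standard resolution `Rs = 2 (t2 - t1) / (w1 + w2)` with `w = 4 sigma`
#' base widths; `Rs >= 1.5` is conventionally baseline-resolved. Peaks may be
#' rows of a `peak_table` (using `sigma_est`) or lists built with
#' [peak_shape()].
#'
#' @param p1,p2 Peaks (any order; identical apexes give 0).
#' @return Non-negative dimensionless resolution.
#' @examples
#' resolution(peak_shape(17.88, 0.12), peak_shape(18.31, 0.12))
#' @export
resolution <- function(p1, p2) {
  g <- function(p) {
    sig <- if (!is.null(p$sigma_est)) p$sigma_est else p$sigma
    if (is.null(sig) || !is.finite(sig))
      sig <- (p$right_bound - p$left_bound) / 10  # bounds span ~10 sigma
    list(t = p$apex_time, w = 4 * sig)
  }
  a <- g(p1); b <- g(p2)
  abs(b$t - a$t) * 2 / (a$w + b$w)
}

#' Minimal peak descriptor
#' @param apex_time Apex time in minutes.
#' @param sigma Gaussian width in minutes.
#' @return List usable with [resolution()].
#' @export
peak_shape <- function(apex_time, sigma) {
  list(apex_time = apex_time, sigma = sigma)
}

#' Fit two overlapped Gaussian components
#'
#' Nonlinear least squares of a two-Gaussian model on a baseline-subtracted
#' region, for partially overlapped pairs such as lactic (17.88 min) and
#' glycolic (18.31 min) acid, which share wavelengths and cannot be separated
#' spectrally. Areas and widths are bounded positive. Non-convergence never
#' throws: the best-so-far parameters are returned with `converged = FALSE`.
#'
#' @param chrom A [chromatogram()].
#' @param wavelength Wavelength in nm.
#' @param region Numeric `c(left, right)` minutes containing both components.
#' @param init Numeric length-2 initial centres (min).
#' @param baseline Baseline to subtract (scalar or vector on the full grid).
#' @param init_sigma Initial width guess (min).
#' @return An `overlap_fit`: list with `components` (data frame of `center`,
#'   `sigma`, `area`), `rss` and `converged`.
#' @export
fit_overlapped_pair <- function(chrom, wavelength, region, init,
                                baseline = 0, init_sigma = 0.12) {
  if (length(region) != 2 || region[1] >= region[2])
    stop("region must be c(left, right) with left < right")
  if (length(init) != 2) stop("init must give two centres")
  if (any(init < region[1] | init > region[2]))
    stop("region must contain both initial centres")
  t_all <- chrom$times
  s_all <- chrom_trace(chrom, wavelength) - baseline
  idx <- which(t_all >= region[1] & t_all <= region[2])
  tt <- t_all[idx]; ss <- s_all[idx]

  h <- vapply(init, function(ci) max(ss[which.min(abs(tt - ci))], 0), 0)
  start <- list(a1 = max(h[1], 1e-6) * init_sigma * sqrt(2 * pi),
                a2 = max(h[2], 1e-6) * init_sigma * sqrt(2 * pi),
                c1 = init[1], c2 = init[2],
                s1 = init_sigma, s2 = init_sigma)
  lower <- c(0, 0, region[1], region[1], init_sigma / 10, init_sigma / 10)
  upper <- c(Inf, Inf, region[2], region[2], diff(region), diff(region))

  result <- tryCatch({
    fit <- minpack.lm::nlsLM(
      ss ~ a1 * stats::dnorm(tt, c1, s1) + a2 * stats::dnorm(tt, c2, s2),
      start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(fit)
    list(cf = cf, rss = sum(stats::resid(fit)^2),
         converged = isTRUE(fit$convInfo$isConv))
  }, error = function(e) {
    cf <- unlist(start)
    pred <- cf["a1"] * stats::dnorm(tt, cf["c1"], cf["s1"]) +
            cf["a2"] * stats::dnorm(tt, cf["c2"], cf["s2"])
    list(cf = cf, rss = sum((ss - pred)^2), converged = FALSE)
  })
  cf <- result$cf
  structure(list(
    components = data.frame(center = c(cf[["c1"]], cf[["c2"]]),
                            sigma = c(cf[["s1"]], cf[["s2"]]),
                            area = c(cf[["a1"]], cf[["a2"]])),
    rss = result$rss, converged = result$converged),
    class = "overlap_fit")
}

#' @export
print.overlap_fit <- function(x, ...) {
  cat(sprintf("two-component fit (%s, rss = %.4g)\n",
              if (x$converged) "converged" else "NOT converged", x$rss))
  print(x$components)
  invisible(x)
}
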