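#' Construct an amplification curve
#'
#' One qPCR well: a fluorescence trajectory over cycles, labelled with the
#' strain, gene and replicate structure of the plate. Fluorescence is in
#' arbitrary relative units; only differences of threshold cycles (dCt) are
#' comparable across instruments.
#'
#' @param well_id well label (opaque).
#' @param strain_id strain label, e.g. `"CCMP1005"`.
#' @param gene_id gene label; `"petF"`, `"tef1a"` and `"rbcS"` have special
#'   roles downstream, any other label is carried through untouched.
#' @param bio_replicate,tech_replicate positive integer replicate indices.
#' @param cycles strictly increasing integer cycle numbers.
#' @param fluorescence numeric fluorescence per cycle, finite.
#' @return An object of class `amp_curve`.
#' @export
amp_curve <- function(well_id, strain_id, gene_id, bio_replicate, tech_replicate,
                      cycles, fluorescence) {
  cycles <- as.numeric(cycles)
  fluorescence <- as.numeric(fluorescence)
  if (length(cycles) != length(fluorescence))
    stop_petfloc("invalid_curve", "cycles and fluorescence must have equal length")
  if (any(!is.finite(fluorescence)) || any(!is.finite(cycles)))
    stop_petfloc("invalid_curve", "non-finite cycle or fluorescence value")
  if (is.unsorted(cycles, strictly = TRUE))
    stop_petfloc("invalid_curve", "cycles must be strictly increasing")
  structure(
    list(well_id = as.character(well_id), strain_id = as.character(strain_id),
         gene_id = as.character(gene_id),
         bio_replicate = as.integer(bio_replicate),
         tech_replicate = as.integer(tech_replicate),
         cycles = cycles, fluorescence = fluorescence),
    class = "amp_curve")
}

#' @export
print.amp_curve <- function(x, ...) {
  cat(sprintf("amp_curve well=%s strain=%s gene=%s bio=%d tech=%d (%d cycles)\n",
              x$well_id, x$strain_id, x$gene_id, x$bio_replicate,
              x$tech_replicate, length(x$cycles)))
  invisible(x)
}

#' Read a long-format qPCR plate CSV
#'
#' Expects a UTF-8 comma-separated file with header columns
#' `well,strain,gene,bio_rep,tech_rep,cycle,fluorescence`, one row per
#' (well, cycle). Rows are grouped by well and sorted by cycle.
#'
#' @param path path to the CSV file.
#' @return A list of [amp_curve] objects, one per distinct well, ordered by
#'   well label.
#' @export
read_plate_csv <- function(path) {
  if (!file.exists(path))
    stop_petfloc("file_not_found", sprintf("plate file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  needed <- c("well", "strain", "gene", "bio_rep", "tech_rep", "cycle", "fluorescence")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop_petfloc("format", sprintf("plate CSV is missing column(s): %s",
                                   paste(missing, collapse = ", ")))
  for (col in c("cycle", "fluorescence")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (length(bad))
      stop_petfloc("format", sprintf("non-numeric %s value at data line %d: '%s'",
                                     col, bad[1] + 1L, df[[col]][bad[1]]))
    df[[col]] <- v
  }
  wells <- unique(df$well)
  curves <- lapply(wells, function(w) {
    sub <- df[df$well == w, , drop = FALSE]
    sub <- sub[order(sub$cycle), , drop = FALSE]
    amp_curve(w, sub$strain[1], sub$gene[1],
              as.integer(sub$bio_rep[1]), as.integer(sub$tech_rep[1]),
              sub$cycle, sub$fluorescence)
  })
  curves[order(vapply(curves, `[[`, "", "well_id"))]
}

#' Baseline-correct an amplification curve
#'
#' Subtracts the mean fluorescence of the first `baseline_cycles` cycles
#' from the whole trajectory, mimicking the background subtraction that
#' instrument software applies before threshold calling.
#'
#' @param curve an [amp_curve].
#' @param baseline_cycles number of leading cycles defining the baseline
#'   (at least 3, fewer than the curve length).
#' @return The corrected [amp_curve].
#' @export
baseline_correct <- function(curve, baseline_cycles = 5L) {
  stopifnot(inherits(curve, "amp_curve"))
  n <- length(curve$cycles)
  if (baseline_cycles < 3L || baseline_cycles >= n)
    stop_petfloc("parameter", "baseline_cycles must be >= 3 and < number of cycles")
  curve$fluorescence <- curve$fluorescence - mean(curve$fluorescence[seq_len(baseline_cycles)])
  curve
}

#' Call the threshold cycle (Ct) of a baseline-corrected curve
#'
#' Finds the fractional cycle at which fluorescence first crosses
#' `threshold`. Between the bracketing cycles the crossing is interpolated
#' linearly in log(fluorescence), which is exact for exponential
#' amplification; when the lower bracketing value is non-positive the
#' interpolation falls back to the linear scale. A curve that never reaches
#' the threshold yields a no-amplification call (`ct = NA`), a value that
#' flows through the pipeline rather than an error.
#'
#' @param curve a baseline-corrected [amp_curve] with at least 10 cycles.
#' @param threshold positive fluorescence threshold (default 0.2, in
#'   baseline-corrected units).
#' @return A list of class `ct_call` with elements `ct` (fractional cycle,
#'   `NA` for no amplification), `threshold` and `crossed`.
#' @export
call_ct <- function(curve, threshold = 0.2) {
  stopifnot(inherits(curve, "amp_curve"))
  if (!is.numeric(threshold) || threshold <= 0)
    stop_petfloc("parameter", "threshold must be > 0")
  cyc <- curve$cycles; fl <- curve$fluorescence
  if (length(cyc) < 10L)
    stop_petfloc("invalid_curve", "need >= 10 cycles for Ct calling")
  k <- min(3L, length(fl))
  if (abs(mean(fl[seq_len(k)])) > 0.25 * threshold)
    warn_petfloc("not_baselined",
                 "curve does not look baseline-corrected; Ct may be biased")
  idx <- which(fl >= threshold)
  if (!length(idx))
    return(structure(list(ct = NA_real_, threshold = threshold, crossed = FALSE),
                     class = "ct_call"))
  i <- idx[1]
  ct <- if (fl[i] == threshold || i == 1L) {
    cyc[i]
  } else {
    f0 <- fl[i - 1L]; f1 <- fl[i]
    frac <- if (f0 > 0) (log(threshold) - log(f0)) / (log(f1) - log(f0))
            else (threshold - f0) / (f1 - f0)
    cyc[i - 1L] + frac * (cyc[i] - cyc[i - 1L])
  }
  structure(list(ct = ct, threshold = threshold, crossed = TRUE), class = "ct_call")
}

#' Estimate per-reaction amplification efficiency (window of linearity)
#'
#' Fits log10(fluorescence) against cycle over every contiguous window of
#' `min_window` to `max_window` points whose fluorescence lies in the
#' exponential phase -- above a noise floor (a fraction of the plateau) and
#' below half the plateau -- and keeps the window with the highest r-squared.
#' Efficiency is `10^slope`: per-cycle fold increase, 2.0 for perfect
#' doubling.
#'
#' @param curve a baseline-corrected [amp_curve].
#' @param min_window,max_window window sizes in points (default 4 to 6).
#' @param noise_floor_frac fraction of the plateau (maximum fluorescence)
#'   below which points are considered noise (default 0.01).
#' @return A list of class `efficiency_estimate` with `efficiency_mult`,
#'   `efficiency_pct`, `window_start`, `window_end` (cycle numbers) and
#'   `r_squared`.
#' @export
estimate_efficiency <- function(curve, min_window = 4L, max_window = 6L,
                                noise_floor_frac = 0.01) {
  stopifnot(inherits(curve, "amp_curve"))
  if (min_window < 2L || max_window < min_window)
    stop_petfloc("parameter", "need 2 <= min_window <= max_window")
  cyc <- curve$cycles; fl <- curve$fluorescence
  plateau <- max(fl)
  eligible <- which(fl > noise_floor_frac * plateau & fl <= plateau / 2 & fl > 0)
  if (length(eligible) < min_window)
    stop_petfloc("no_exponential_phase",
                 sprintf("only %d point(s) in the exponential phase (need >= %d)",
                         length(eligible), min_window))
  best <- NULL
  for (w in seq(min_window, max_window)) {
    if (w > length(eligible)) break
    for (s in seq_len(length(eligible) - w + 1L)) {
      win <- eligible[s:(s + w - 1L)]
      if (win[w] - win[1L] != w - 1L) next  # must be contiguous cycles
      x <- cyc[win]; y <- log10(fl[win])
      fit <- stats::lm.fit(cbind(1, x), y)
      ssr <- sum(fit$residuals^2)
      sst <- sum((y - mean(y))^2)
      r2 <- if (sst == 0) 1 else 1 - ssr / sst
      # prefer higher r2; on near-ties prefer the larger window
      if (is.null(best) || r2 > best$r_squared + 1e-12 ||
          (abs(r2 - best$r_squared) <= 1e-12 && w > best$w)) {
        best <- list(slope = fit$coefficients[2], r_squared = r2,
                     window_start = cyc[win[1L]], window_end = cyc[win[w]], w = w)
      }
    }
  }
  if (is.null(best))
    stop_petfloc("no_exponential_phase", "no contiguous window in the exponential phase")
  eff <- unname(10^best$slope)
  structure(list(efficiency_mult = eff, efficiency_pct = (eff - 1) * 100,
                 window_start = best$window_start, window_end = best$window_end,
                 r_squared = best$r_squared),
            class = "efficiency_estimate")
}

#' Relative copy number from a pair of Ct values
#'
#' Computes `dCt = ct_reference - ct_interest` and the fold difference
#' `2^dCt` in starting copies assuming perfect doubling; a gene compared
#' with itself yields exactly 1. Either input being a no-amplification call
#' (`NA`) propagates an undefined result rather than raising an error.
#'
#' @param ct_reference,ct_interest Ct values (numeric, or `ct_call`
#'   objects), `NA` for no amplification.
#' @return A list of class `relative_copy_number` with `delta_ct`, `fold`,
#'   `fold_rounded` (round-half-up integer) and `undefined`.
#' @export
relative_copy_number <- function(ct_reference, ct_interest) {
  if (inherits(ct_reference, "ct_call")) ct_reference <- ct_reference$ct
  if (inherits(ct_interest, "ct_call")) ct_interest <- ct_interest$ct
  if (is.na(ct_reference) || is.na(ct_interest))
    return(structure(list(delta_ct = NA_real_, fold = NA_real_,
                          fold_rounded = NA_integer_, undefined = TRUE),
                     class = "relative_copy_number"))
  d <- ct_reference - ct_interest
  fold <- 2^d
  structure(list(delta_ct = d, fold = fold,
                 fold_rounded = as.integer(round_half_up(fold)),
                 undefined = FALSE),
            class = "relative_copy_number")
}
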