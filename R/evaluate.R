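#' Keep only thermally neutral records of a vote series
#'
#' Filters a measured skin-temperature series to the records whose overall
#' thermal sensation vote lies in the neutral window -0.5 to +0.5
#' (bounds inclusive).
#'
#' @param series data.frame with a numeric `tsv` column (nine-point scale,
#'   -4..+4) and arbitrary further columns (typically `timestamp`,
#'   `subject_id` and one skin-temperature column per segment).
#' @return The filtered data.frame; warns when nothing survives.
#' @export
filter_neutral <- function(series) {
  if (!"tsv" %in% names(series)) stop("series needs a tsv column", call. = FALSE)
  if (any(abs(series$tsv) > 4, na.rm = TRUE)) {
    stop("tsv outside the nine-point scale [-4, 4]", call. = FALSE)
  }
  keep <- !is.na(series$tsv) & series$tsv >= -0.5 & series$tsv <= 0.5
  out <- series[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("no thermally neutral records", call. = FALSE)
  out
}

#' Interquartile skin-temperature range
#'
#' The measured counterpart of a simulated range: the 25th to 75th
#' percentile of the selected samples (linear-interpolation percentile
#' convention), trimming measurement fluctuation at both ends.
#'
#' @param samples Numeric vector of skin temperatures, degC; at least 4
#'   values.
#' @return A `temp_range`: list with `lo`, `hi` (degC).
#' @export
#' @examples
#' iqr_range(1:5) # (2, 4)
iqr_range <- function(samples) {
  samples <- samples[!is.na(samples)]
  if (length(samples) < 4) {
    stop("need at least 4 samples for an interquartile range", call. = FALSE)
  }
  q <- stats::quantile(samples, c(0.25, 0.75), names = FALSE, type = 7)
  temp_range(q[1L], q[2L])
}

#' A closed temperature interval
#'
#' @param lo,hi Interval endpoints, degC, `lo <= hi`.
#' @return Object of class `temp_range`.
#' @export
temp_range <- function(lo, hi) {
  stopifnot(is.finite(lo), is.finite(hi))
  if (lo > hi) stop("temp_range needs lo <= hi", call. = FALSE)
  structure(list(lo = lo, hi = hi), class = "temp_range")
}

#' @export
print.temp_range <- function(x, ...) {
  cat(sprintf("[%.3f, %.3f] degC\n", x$lo, x$hi))
  invisible(x)
}

#' Jaccard similarity of two temperature intervals
#'
#' Intersection-over-union of closed intervals:
#' `|a  intersect b| / (|a| + |b| - |a intersect b|)` using interval lengths.
#' Degenerate (zero-width) intervals: two equal points give 1, otherwise any
#' comparison involving a point has zero overlap length and gives 0.
#'
#' @param a,b `temp_range` objects (or lists with `lo`, `hi`).
#' @return Similarity in [0, 1].
#' @export
#' @examples
#' jaccard(temp_range(1, 3), temp_range(2, 4)) # 1/3
jaccard <- function(a, b) {
  la <- a$hi - a$lo
  lb <- b$hi - b$lo
  if (la == 0 && lb == 0) return(as.numeric(a$lo == b$lo))
  ov <- max(0, min(a$hi, b$hi) - max(a$lo, b$lo))
  un <- la + lb - ov
  if (un == 0) return(0) # only reachable for degenerate pairs
  ov / un
}

#' Per-segment Jaccard similarity report
#'
#' Compares one set of measured per-segment ranges against one or more
#' named sets of simulated ranges (variants), computing the Jaccard
#' similarity per segment, the unweighted mean across segments per variant,
#' and all pairwise variant deltas of the mean — the headline number when
#' contrasting local-insulation simulations against the uniform-overall
#' simplification. Segments missing from a variant are excluded from that
#' variant's mean with a warning.
#'
#' @param measured data.frame `segment, lo, hi` of measured ranges.
#' @param simulated Named list of data.frames `segment, lo, hi`, one per
#'   simulation variant.
#' @return List of class `jsc_report`: `per_segment` (data.frame of JSC by
#'   segment and variant), `mean` (named vector of per-variant means),
#'   `deltas` (data.frame `variant_a, variant_b, delta_mean_jsc`).
#' @export
jsc_report <- function(measured, simulated) {
  stopifnot(is.list(simulated), length(simulated) >= 1,
            !is.null(names(simulated)))
  check_range_frame <- function(df) {
    stopifnot(all(c("segment", "lo", "hi") %in% names(df)))
    df$segment <- canonical_segment(df$segment)
    df
  }
  measured <- check_range_frame(measured)
  per <- data.frame(segment = measured$segment, stringsAsFactors = FALSE)
  means <- stats::setNames(numeric(length(simulated)), names(simulated))
  for (vn in names(simulated)) {
    sim <- check_range_frame(simulated[[vn]])
    idx <- match(measured$segment, sim$segment)
    if (anyNA(idx)) {
      warning("variant '", vn, "' lacks segment(s): ",
              paste(measured$segment[is.na(idx)], collapse = ", "),
              "; excluded from its mean", call. = FALSE)
    }
    jsc <- rep(NA_real_, nrow(measured))
    for (i in which(!is.na(idx))) {
      jsc[i] <- jaccard(temp_range(measured$lo[i], measured$hi[i]),
                        temp_range(sim$lo[idx[i]], sim$hi[idx[i]]))
    }
    per[[vn]] <- jsc
    means[vn] <- mean(jsc, na.rm = TRUE)
  }
  deltas <- NULL
  if (length(simulated) > 1) {
    cmb <- utils::combn(names(simulated), 2)
    deltas <- data.frame(
      variant_a = cmb[1, ], variant_b = cmb[2, ],
      delta_mean_jsc = means[cmb[1, ]] - means[cmb[2, ]],
      row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(list(per_segment = per, mean = means, deltas = deltas),
            class = "jsc_report")
}

#' @export
print.jsc_report <- function(x, ...) {
  cat("Jaccard similarity of measured vs simulated skin-temperature ranges\n")
  print(x$per_segment, row.names = FALSE, digits = 3)
  cat("\nMean JSC per variant:\n")
  print(round(x$mean, 3))
  if (!is.null(x$deltas)) {
    cat("\nPairwise mean deltas:\n")
    print(x$deltas, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Measured ranges from a vote series
#'
#' Convenience wrapper: neutral-vote filtering followed by per-segment
#' interquartile ranges, pooling all subjects' neutral samples.
#'
#' @param series Vote series data.frame (`tsv` plus one numeric column per
#'   segment).
#' @param segments Segments to extract; default all present canonical ones.
#' @return data.frame `segment, lo, hi`.
#' @export
measured_ranges <- function(series, segments = NULL) {
  neutral <- filter_neutral(series)
  if (is.null(segments)) {
    segments <- intersect(body_segments(), names(series))
  }
  do.call(rbind, lapply(segments, function(s) {
    r <- iqr_range(neutral[[s]])
    data.frame(segment = s, lo = r$lo, hi = r$hi, stringsAsFactors = FALSE)
  }))
}
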