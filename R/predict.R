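#' Overall insulation of a garment ensemble
#'
#' The whole-body clothing insulation of an ensemble is the sum of the
#' effective insulation values of its garments,
#' `I_cl = sum_j I_clu,j` (standard-tabulated values).
#'
#' @param garments A data.frame with a numeric `i_clu_clo` column (e.g. rows
#'   of [read_garments()]), or a numeric vector of effective insulations,
#'   clo.
#' @return Overall clothing insulation, clo.
#' @export
#' @examples
#' ensemble_overall(c(0.1, 0.15, 0.02, 0.03)) # 0.3
ensemble_overall <- function(garments) {
  vals <- if (is.data.frame(garments)) {
    if (!"i_clu_clo" %in% names(garments)) {
      stop("garment table needs an i_clu_clo column", call. = FALSE)
    }
    garments$i_clu_clo
  } else {
    garments
  }
  if (length(vals) == 0) return(0)
  check_insulation(vals)
  sum(vals)
}

#' Read a garment catalog
#'
#' CSV columns `name, category, i_clu_clo` with `category` one of top,
#' bottom, socks, shoes. The packaged default lists standard-tabulated
#' effective insulation values for common garments.
#'
#' @param path CSV path; default the packaged catalog.
#' @return data.frame of garments.
#' @export
read_garments <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "garments.csv", package = "localclo")
  }
  g <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "category", "i_clu_clo")
  if (!all(need %in% names(g))) {
    stop("garment catalog must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  check_insulation(g$i_clu_clo)
  g
}

#' Predict the full local-insulation distribution
#'
#' Evaluates every segment model of a table at the given overall insulation
#' and assembles the 11-segment distribution. Segments with no model in the
#' table (the neck, in the packaged set) default to `unmodeled_value`
#' (0 clo — a bare neck, the convention used when feeding multi-node
#' thermoregulation simulations).
#'
#' @param i_cl Overall clothing insulation, clo (scalar).
#' @param posture `"standing"`, `"sitting"`, or `"generic"`.
#' @param table A `clo_model_table`; default the packaged set.
#' @param unmodeled_value Value assigned to segments without a model, clo.
#' @return An object of class `clo_distribution`: a named numeric vector over
#'   [body_segments()] with attributes `posture` and `source_overall`.
#' @export
#' @examples
#' predict_distribution(0.3, "generic")
predict_distribution <- function(i_cl, posture = c("generic", "standing", "sitting"),
                                 table = default_model_table(),
                                 unmodeled_value = 0) {
  posture <- match.arg(posture)
  check_insulation(i_cl)
  stopifnot(length(i_cl) == 1L, inherits(table, "clo_model_table"))
  if (!posture %in% table_postures(table)) {
    stop("posture '", posture, "' not in model table; available: ",
         paste(sort(table_postures(table)), collapse = ", "), call. = FALSE)
  }
  warn_out_of_range(i_cl)
  vals <- vapply(body_segments(), function(s) {
    m <- lookup_model(table, s, posture)
    if (is.null(m)) unmodeled_value
    else suppressWarnings(predict_local(m, i_cl)) # range warning issued once above
  }, numeric(1))
  new_distribution(vals, posture, i_cl)
}

new_distribution <- function(values, posture, source_overall) {
  stopifnot(setequal(names(values), body_segments()))
  structure(values[body_segments()], posture = posture,
            source_overall = source_overall, class = "clo_distribution")
}

#' @export
print.clo_distribution <- function(x, ...) {
  cat(sprintf("<clo_distribution> posture %s, overall %.3f clo\n",
              attr(x, "posture"), attr(x, "source_overall")))
  print(round(unclass(x), 3))
  invisible(x)
}

#' @export
as.data.frame.clo_distribution <- function(x, ...) {
  data.frame(segment = names(x), i_cl_i_clo = as.numeric(x),
             stringsAsFactors = FALSE)
}

#' Override selected segments of a distribution
#'
#' Replaces listed segment values (e.g. a footwear-preference correction:
#' sports shoes with ankle socks instead of the predicted sandals). All
#' other segments are untouched.
#'
#' @param dist A `clo_distribution`.
#' @param overrides Named numeric vector or list, names being canonical
#'   segments, values >= 0 clo.
#' @return The modified `clo_distribution`.
#' @export
#' @examples
#' d <- predict_distribution(0.3, "generic")
#' apply_overrides(d, c(foot = 1.580))
apply_overrides <- function(dist, overrides) {
  stopifnot(inherits(dist, "clo_distribution"))
  if (length(overrides) == 0) return(dist)
  vals <- unlist(overrides)
  names(vals) <- canonical_segment(names(vals))
  check_insulation(vals)
  out <- unclass(dist)
  out[names(vals)] <- vals
  new_distribution(out, attr(dist, "posture"), attr(dist, "source_overall"))
}

#' Read wind-correction coefficients
#'
#' Per-segment coefficients `(d, e)` of a natural-logarithmic correction of
#' local clothing insulation in relative air speed, tagged by wind direction
#' (`upwind` / `downstream`). The package ships no numeric coefficients —
#' they are measurement-campaign specific — so users supply a CSV with
#' columns `segment, direction, d, e`.
#'
#' @param path CSV path.
#' @return data.frame of coefficients with canonical segment names.
#' @export
read_wind_coeffs <- function(path) {
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("segment", "direction", "d", "e")
  if (!all(need %in% names(w))) {
    stop("wind coefficient file must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  w$segment <- canonical_segment(w$segment)
  w$direction <- tolower(trimws(w$direction))
  w
}

#' Correct a distribution for air movement
#'
#' Applies the log-law correction
#' `I_corrected = max(0, I_static + d * ln(v_rel) + e)` segment by segment.
#' Segments without coefficients for the requested direction pass through
#' unchanged. Note the contract is the formula itself: whether insulation
#' decreases with wind speed is a property of the supplied coefficient set,
#' not enforced here; only the physical floor at 0 clo is.
#'
#' @param dist A `clo_distribution` (already thresholded static values).
#' @param v_rel Relative air speed, m/s (> 0).
#' @param coeffs Coefficients data.frame as from [read_wind_coeffs()].
#' @param direction `"upwind"` or `"downstream"`.
#' @return The corrected `clo_distribution`.
#' @export
apply_wind_correction <- function(dist, v_rel, coeffs,
                                  direction = c("downstream", "upwind")) {
  stopifnot(inherits(dist, "clo_distribution"))
  direction <- match.arg(direction)
  if (!is.numeric(v_rel) || length(v_rel) != 1L || !is.finite(v_rel) || v_rel <= 0) {
    stop("v_rel must be a single positive air speed in m/s", call. = FALSE)
  }
  cc <- coeffs[coeffs$direction == direction, , drop = FALSE]
  out <- unclass(dist)
  idx <- match(names(out), cc$segment)
  hit <- !is.na(idx)
  out[hit] <- pmax(0, out[hit] + cc$d[idx[hit]] * log(v_rel) + cc$e[idx[hit]])
  new_distribution(out, attr(dist, "posture"), attr(dist, "source_overall"))
}
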