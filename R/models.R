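#' Construct a segment regression model
#'
#' One body segment's rule for predicting local clothing insulation from the
#' overall value. Three kinds:
#' * `constant` — a fixed value (`b1`), used for segments whose insulation
#'   does not track the overall value (head, hand);
#' * `linear` — `max(a1 * I_cl + b1, minimum)`;
#' * `piecewise` — a continuous two-branch linear function, branch 1 below
#'   `breakpoint` and branch 2 at/above it, then the same minimum threshold.
#'
#' The minimum threshold `c` reflects the thinnest ensemble observed for the
#' segment: predictions are never allowed below it.
#'
#' @param segment Canonical segment name.
#' @param posture `"standing"`, `"sitting"`, or `"generic"`.
#' @param kind `"constant"`, `"linear"`, or `"piecewise"`.
#' @param a1,b1 Slope (clo/clo) and intercept (clo) of the (first) branch.
#'   For `constant`, `a1 = 0` and `b1` is the constant.
#' @param breakpoint,a2,b2 Piecewise only: breakpoint (clo of overall
#'   insulation) and second-branch slope/intercept. Branches must agree at
#'   the breakpoint to within 0.01 clo.
#' @param minimum Minimum threshold `c`, clo.
#' @param r2 Optional coefficient of determination of the fit.
#' @return An object of class `clo_segment_model`.
#' @export
segment_model <- function(segment, posture, kind, a1, b1,
                          breakpoint = NA_real_, a2 = NA_real_, b2 = NA_real_,
                          minimum = 0, r2 = NA_real_) {
  segment <- canonical_segment(segment)
  posture <- match.arg(posture, c("standing", "sitting", "generic"))
  kind <- match.arg(kind, c("constant", "linear", "piecewise"))
  if (!is.finite(minimum) || minimum < 0) stop("minimum must be >= 0", call. = FALSE)
  if (kind == "constant" && a1 != 0) stop("constant models must have a1 = 0", call. = FALSE)
  if (kind == "piecewise") {
    if (!all(is.finite(c(breakpoint, a2, b2)))) {
      stop("piecewise models need breakpoint, a2, b2", call. = FALSE)
    }
    gap <- abs((a1 * breakpoint + b1) - (a2 * breakpoint + b2))
    if (gap > 0.01) {
      stop(sprintf("piecewise branches disagree by %.4f clo at the breakpoint (> 0.01)",
                   gap), call. = FALSE)
    }
  }
  structure(
    list(segment = segment, posture = posture, kind = kind,
         a1 = a1, b1 = b1, breakpoint = breakpoint, a2 = a2, b2 = b2,
         minimum = minimum, r2 = r2),
    class = "clo_segment_model"
  )
}

#' @export
print.clo_segment_model <- function(x, ...) {
  eq <- switch(x$kind,
    constant = sprintf("I_cl,i = %.3f", x$b1),
    linear = sprintf("I_cl,i = max(%.3f * I_cl %+.3f, %.3f)", x$a1, x$b1, x$minimum),
    piecewise = sprintf(
      "I_cl,i = max(%.3f * I_cl %+.3f  [I_cl < %.3f] | %.3f * I_cl %+.3f  [I_cl >= %.3f], %.3f)",
      x$a1, x$b1, x$breakpoint, x$a2, x$b2, x$breakpoint, x$minimum))
  cat(sprintf("<clo_segment_model> %s (%s, %s)\n  %s\n", x$segment, x$posture,
              x$kind, eq))
  if (is.finite(x$r2)) cat(sprintf("  R^2 = %.3f\n", x$r2))
  invisible(x)
}

#' Predict local insulation for one segment
#'
#' Evaluates the active branch of a segment model at the given overall
#' clothing insulation, then applies the minimum threshold
#' `max(a * I_cl + b, c)`. Values of `i_cl` above 2.17 clo — the top of the
#' range of the ensembles the packaged models were trained on — trigger a
#' warning but are still evaluated.
#'
#' @param model A `clo_segment_model`.
#' @param i_cl Overall clothing insulation, clo (vectorized).
#' @return Predicted local clothing insulation, clo.
#' @export
#' @examples
#' m <- segment_model("chest", "standing", "linear", 2.975, -0.540, minimum = 0.400)
#' predict_local(m, c(0.25, 1.0))
predict_local <- function(model, i_cl) {
  stopifnot(inherits(model, "clo_segment_model"))
  check_insulation(i_cl)
  warn_out_of_range(i_cl)
  raw <- segment_model_line(model, i_cl)
  pmax(raw, model$minimum)
}

# unclipped branch evaluation (used for prediction and for r2)
segment_model_line <- function(model, i_cl) {
  if (model$kind == "piecewise") {
    ifelse(i_cl < model$breakpoint,
           model$a1 * i_cl + model$b1,
           model$a2 * i_cl + model$b2)
  } else {
    model$a1 * i_cl + model$b1
  }
}

warn_out_of_range <- function(i_cl) {
  if (any(i_cl > 2.17)) {
    warning("overall insulation above 2.17 clo exceeds the training range ",
            "of the packaged models; predictions for heavy clothing ",
            "(I_cl > 2 clo) may be unreliable", call. = FALSE)
  }
}

#' @export
predict.clo_segment_model <- function(object, i_cl, ...) {
  predict_local(object, i_cl)
}

#' Build a model table
#'
#' A model table maps `(segment, posture)` to a [segment_model()]. Segments
#' whose rule is posture-independent (constant head/hand models) may be
#' registered under `"generic"` only; lookup falls back from a specific
#' posture to `"generic"`.
#'
#' @param models List of `clo_segment_model` objects.
#' @param provenance Free-text description of where the coefficients come from.
#' @return An object of class `clo_model_table`.
#' @export
model_table <- function(models, provenance = "user") {
  stopifnot(all(vapply(models, inherits, logical(1), "clo_segment_model")))
  keys <- vapply(models, function(m) paste(m$segment, m$posture, sep = "."), "")
  if (anyDuplicated(keys)) {
    stop("duplicate (segment, posture) entries: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "), call. = FALSE)
  }
  structure(list(models = stats::setNames(models, keys), provenance = provenance),
            class = "clo_model_table")
}

#' @export
print.clo_model_table <- function(x, ...) {
  cat(sprintf("<clo_model_table> %d models (%s)\n", length(x$models), x$provenance))
  df <- as.data.frame(x)
  print(df[, c("segment", "posture", "kind", "a1", "b1", "breakpoint",
               "a2", "b2", "minimum", "r2")], row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.clo_model_table <- function(x, ...) {
  do.call(rbind, lapply(unname(x$models), function(m) {
    data.frame(segment = m$segment, posture = m$posture, kind = m$kind,
               a1 = m$a1, b1 = m$b1, breakpoint = m$breakpoint,
               a2 = m$a2, b2 = m$b2, minimum = m$minimum, r2 = m$r2,
               stringsAsFactors = FALSE)
  }))
}

#' Look up a segment model, falling back to the generic posture
#'
#' @param table A `clo_model_table`.
#' @param segment Canonical segment name.
#' @param posture Requested posture.
#' @return The `clo_segment_model`, or `NULL` if the table has no model for
#'   the segment at all.
#' @export
lookup_model <- function(table, segment, posture) {
  stopifnot(inherits(table, "clo_model_table"))
  segment <- canonical_segment(segment)
  m <- table$models[[paste(segment, posture, sep = ".")]]
  if (is.null(m)) m <- table$models[[paste(segment, "generic", sep = ".")]]
  m
}

table_postures <- function(table) {
  unique(vapply(table$models, `[[`, "", "posture"))
}

#' The packaged segment regression models
#'
#' Loads the coefficient set shipped with the package: thresholded linear
#' and continuous piecewise-linear models for chest, back, pelvis, shoulder,
#' arm, thigh, leg and foot in standing, sitting and generic (pooled)
#' postures, plus the fixed head (0.13 clo) and hand (0 clo) values. These
#' were fitted to 240 harmonized thermal-manikin clothing ensembles spanning
#' 0.22–2.17 clo overall insulation.
#'
#' @param path JSON file to load; default is the packaged set.
#' @return A `clo_model_table`.
#' @export
#' @examples
#' tab <- default_model_table()
#' predict_local(lookup_model(tab, "foot", "generic"), 0.3) # 0.425
default_model_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "segment_models.json", package = "localclo")
  }
  read_model_table(path)
}

#' Read / write model tables as JSON
#'
#' One JSON object per model with keys `segment, posture, kind, a1, b1,
#' breakpoint, a2, b2, minimum, r2` (unused keys null), plus a top-level
#' `provenance` string.
#'
#' @param path JSON file path.
#' @return `read_model_table()` returns a `clo_model_table`;
#'   `write_model_table()` returns `path` invisibly.
#' @export
read_model_table <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  models <- lapply(j$models, function(m) {
    num <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
    segment_model(m$segment, m$posture, m$kind,
                  a1 = num(m$a1), b1 = num(m$b1),
                  breakpoint = num(m$breakpoint), a2 = num(m$a2), b2 = num(m$b2),
                  minimum = num(m$minimum), r2 = num(m$r2))
  })
  model_table(models, provenance = j$provenance %||% "unknown")
}

#' @rdname read_model_table
#' @param table A `clo_model_table`.
#' @export
write_model_table <- function(table, path) {
  stopifnot(inherits(table, "clo_model_table"))
  models <- lapply(unname(table$models), function(m) {
    list(segment = m$segment, posture = m$posture, kind = m$kind,
         a1 = round6(m$a1), b1 = round6(m$b1),
         breakpoint = round6(m$breakpoint), a2 = round6(m$a2),
         b2 = round6(m$b2), minimum = round6(m$minimum), r2 = round6(m$r2))
  })
  jsonlite::write_json(list(provenance = table$provenance, models = models),
                       path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

round6 <- function(x) if (is.numeric(x)) signif(x, 6) else x
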