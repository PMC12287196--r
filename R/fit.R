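#' Fit a thresholded linear segment model
#'
#' Ordinary least squares of local insulation on overall insulation. The
#' minimum threshold defaults to the smallest observed local value in the
#' data — predictions should not fall below the thinnest ensemble actually
#' measured. R-squared is computed on the unclipped line, before the
#' threshold is applied.
#'
#' @param x Overall clothing insulation values, clo (>= 3 points, not all
#'   equal).
#' @param y Local clothing insulation values, clo (same length).
#' @param segment,posture Metadata for the resulting model.
#' @param minimum Threshold, clo; default `min(y)`.
#' @return A `clo_segment_model` of kind `"linear"`.
#' @export
fit_linear <- function(x, y, segment = "chest", posture = "generic",
                       minimum = NULL) {
  check_fit_points(x, y, min_n = 3L)
  if (is.null(minimum)) minimum <- max(min(y), 0) # thresholds are physical
  fit <- stats::lm.fit(cbind(1, x), y)
  b1 <- unname(fit$coefficients[1L])
  a1 <- unname(fit$coefficients[2L])
  segment_model(segment, posture, "linear", a1 = a1, b1 = b1,
                minimum = minimum, r2 = r_squared(y, a1 * x + b1))
}

#' Fit a continuous two-branch piecewise-linear segment model
#'
#' Fits a hinge (broken-stick) function that is continuous at the
#' breakpoint: `y = a1*x + b1` below it and `y = a2*x + b2` at/above it with
#' `b2 = (a1 - a2)*breakpoint + b1`. For each candidate breakpoint the model
#' is linear in its remaining parameters and solved by least squares; the
#' breakpoint is chosen by grid search over the observed `x` values strictly
#' inside the 10th–90th percentiles, minimizing total SSE. If no interior
#' candidate exists the fit falls back to [fit_linear()] with a warning.
#'
#' @inheritParams fit_linear
#' @return A `clo_segment_model` of kind `"piecewise"` (or `"linear"` on
#'   fallback).
#' @export
fit_piecewise <- function(x, y, segment = "chest", posture = "generic",
                          minimum = NULL) {
  check_fit_points(x, y, min_n = 6L)
  if (is.null(minimum)) minimum <- max(min(y), 0)
  qs <- stats::quantile(x, c(0.1, 0.9), names = FALSE)
  cand <- sort(unique(x[x > qs[1L] & x < qs[2L]]))
  # a breakpoint needs data strictly on both sides
  cand <- cand[vapply(cand, function(b) any(x < b) && any(x >= b) &&
                        length(unique(x[x < b])) >= 2 &&
                        length(unique(x[x >= b])) >= 2, logical(1))]
  if (!length(cand)) {
    warning("no interior breakpoint candidate; falling back to a linear fit",
            call. = FALSE)
    return(fit_linear(x, y, segment, posture, minimum))
  }
  best <- NULL
  best_sse <- Inf
  for (b in cand) {
    X <- cbind(1, x, pmax(x - b, 0))
    fit <- stats::lm.fit(X, y)
    sse <- sum(fit$residuals^2)
    if (sse < best_sse) {
      best_sse <- sse
      best <- list(b = b, coef = fit$coefficients)
    }
  }
  b1 <- unname(best$coef[1L]); a1 <- unname(best$coef[2L])
  a2 <- a1 + unname(best$coef[3L])
  bp <- best$b
  b2 <- (a1 - a2) * bp + b1
  yhat <- ifelse(x < bp, a1 * x + b1, a2 * x + b2)
  segment_model(segment, posture, "piecewise", a1 = a1, b1 = b1,
                breakpoint = bp, a2 = a2, b2 = b2,
                minimum = minimum, r2 = r_squared(y, yhat))
}

#' Choose between a linear and a piecewise segment model
#'
#' Fits both forms and keeps the piecewise model only when it reduces the
#' sum of squared errors by more than `sse_improve` (relative, default 10%).
#' At exactly the threshold the simpler linear model wins.
#'
#' @inheritParams fit_linear
#' @param sse_improve Minimum relative SSE reduction required to prefer the
#'   piecewise model.
#' @return A `clo_segment_model`.
#' @export
select_model <- function(x, y, segment = "chest", posture = "generic",
                         minimum = NULL, sse_improve = 0.1) {
  lin <- fit_linear(x, y, segment, posture, minimum)
  pw <- withCallingHandlers(
    fit_piecewise(x, y, segment, posture, minimum),
    warning = function(w) invokeRestart("muffleWarning"))
  if (pw$kind != "piecewise") return(lin)
  sse_lin <- sum((y - segment_model_line(lin, x))^2)
  sse_pw <- sum((y - segment_model_line(pw, x))^2)
  # absolute guard so floating-point dust on an exact linear fit (both SSEs
  # ~ 1e-28) cannot masquerade as a relative improvement
  if (sse_pw < (1 - sse_improve) * sse_lin - 1e-12) pw else lin
}

check_fit_points <- function(x, y, min_n) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < min_n) stop("need at least ", min_n, " points", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite points", call. = FALSE)
  if (length(unique(x)) < 2L) {
    stop("degenerate design: all overall insulation values equal", call. = FALSE)
  }
  invisible(NULL)
}

r_squared <- function(y, yhat) {
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(NA_real_)
  1 - sum((y - yhat)^2) / tss
}

#' Fit segment models for a harmonized clothing dataset
#'
#' The top-level fitting interface: takes a harmonized wide-format dataset
#' (one row per clothing ensemble, overall insulation plus the 11 per-segment
#' local values, as produced by [harmonize_dataset()] or
#' [gen_clothing_dataset()]) and fits one regression model per requested
#' segment relating local to overall insulation, selecting between the
#' linear and continuous piecewise form per segment via [select_model()].
#'
#' Head and hand are not refitted by default — their local insulation does
#' not track the overall value, and the packaged table fixes them at
#' 0.13 and 0 clo — and the neck is never fitted (set to 0 downstream).
#'
#' @param data Wide data.frame with columns `overall_clo` and one column per
#'   fitted segment; optionally `posture` used for filtering.
#' @param posture `"standing"`, `"sitting"`, or `"generic"`. Generic pools
#'   all rows; the others keep only matching rows (when a `posture` column
#'   exists).
#' @param segments Segments to fit; default the 8 posture-dependent ones.
#' @param sse_improve Piecewise-selection threshold, see [select_model()].
#' @return An object of class `local_clo_fit` with components `table`
#'   (a [model_table()]), `posture`, `data`, and `n`.
#' @seealso [default_model_table()] for the packaged coefficients,
#'   [predict.local_clo_fit()].
#' @export
local_clo_fit <- function(data, posture = c("generic", "standing", "sitting"),
                          segments = c("chest", "back", "pelvis", "shoulder",
                                       "arm", "thigh", "leg", "foot"),
                          sse_improve = 0.1) {
  posture <- match.arg(posture)
  if (!"overall_clo" %in% names(data)) {
    stop("data must have an overall_clo column", call. = FALSE)
  }
  segments <- canonical_segment(segments)
  if (posture != "generic" && "posture" %in% names(data)) {
    data <- data[tolower(data$posture) == posture, , drop = FALSE]
  }
  missing <- setdiff(segments, names(data))
  if (length(missing)) {
    stop("data lacks segment column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  models <- lapply(segments, function(s) {
    select_model(data$overall_clo, data[[s]], segment = s, posture = posture,
                 sse_improve = sse_improve)
  })
  structure(
    list(table = model_table(models,
                             provenance = sprintf("fitted to %d ensembles (%s)",
                                                  nrow(data), posture)),
         posture = posture, data = data, n = nrow(data)),
    class = "local_clo_fit")
}

#' @export
print.local_clo_fit <- function(x, ...) {
  cat(sprintf("Local clothing insulation fit (%s posture, %d ensembles)\n\n",
              x$posture, x$n))
  print(coef(x))
  invisible(x)
}

#' @export
summary.local_clo_fit <- function(object, ...) {
  df <- as.data.frame(object$table)
  df$rmse <- vapply(df$segment, function(s) {
    m <- lookup_model(object$table, s, object$posture)
    sqrt(mean((object$data[[s]] - predict_local(m, object$data$overall_clo))^2))
  }, numeric(1))
  structure(list(table = df, posture = object$posture, n = object$n),
            class = "summary.local_clo_fit")
}

#' @export
print.summary.local_clo_fit <- function(x, ...) {
  cat(sprintf("Local clothing insulation fit: %d segments, %s posture, %d ensembles\n",
              nrow(x$table), x$posture, x$n))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.local_clo_fit <- function(object, ...) {
  df <- as.data.frame(object$table)
  rownames(df) <- df$segment
  df[, c("kind", "a1", "b1", "breakpoint", "a2", "b2", "minimum", "r2")]
}

#' Predict per-segment local insulation from a fit
#'
#' @param object A `local_clo_fit`.
#' @param i_cl Overall clothing insulation values, clo. Defaults to the
#'   training values.
#' @param ... Unused.
#' @return Matrix with one row per `i_cl` value and one column per fitted
#'   segment, clo.
#' @export
predict.local_clo_fit <- function(object, i_cl = NULL, ...) {
  if (is.null(i_cl)) i_cl <- object$data$overall_clo
  segs <- vapply(object$table$models, `[[`, "", "segment")
  out <- vapply(object$table$models,
                function(m) predict_local(m, i_cl), numeric(length(i_cl)))
  out <- matrix(out, nrow = length(i_cl),
                dimnames = list(NULL, unname(segs)))
  out
}

#' @export
fitted.local_clo_fit <- function(object, ...) {
  predict(object)
}

#' @export
residuals.local_clo_fit <- function(object, ...) {
  fit <- fitted(object)
  obs <- as.matrix(object$data[, colnames(fit), drop = FALSE])
  obs - fit
}

#' Plot observed vs fitted local insulation per segment
#'
#' One panel per fitted segment: observed local insulation against overall
#' insulation, with the fitted thresholded (piecewise-)linear curve overlaid.
#'
#' @param x A `local_clo_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.local_clo_fit <- function(x, ...) {
  segs <- vapply(x$table$models, `[[`, "", "segment")
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(segs)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  grid <- seq(min(x$data$overall_clo), max(x$data$overall_clo), length.out = 200)
  for (i in seq_along(segs)) {
    m <- x$table$models[[i]]
    graphics::plot(x$data$overall_clo, x$data[[segs[i]]],
                   xlab = "overall insulation (clo)",
                   ylab = "local insulation (clo)", main = segs[i],
                   col = "grey40", pch = 16, cex = 0.6, ...)
    graphics::lines(grid, predict_local(m, grid), col = "firebrick", lwd = 2)
  }
  invisible(x)
}
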