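#' Thermoregulation backend contract
#'
#' A backend wraps a multi-node thermoregulation model behind a uniform
#' interface so the clothing pipeline does not depend on any particular
#' implementation. A backend is a list of class `thermo_backend` with:
#'
#' * `name` — backend identifier;
#' * `segments` — character vector of the backend's segment scheme;
#' * `run(env, subject, insulation, duration_h)` — returns the per-segment
#'   skin temperatures (degC, named by the backend's segments) at the end of
#'   a run: `env` has `t_op` (degC), `v` (m/s), `rh` (%), `met`, `posture`;
#'   `subject` has at least `sex` (`"male"`/`"female"`); `insulation` is a
#'   named clo vector on the backend's segments. Must be deterministic for
#'   fixed inputs. Default duration 2 h (long enough for a steady state).
#'
#' An external multi-node model (e.g. a JOS-3 wrapper) can be plugged in by
#' implementing this contract; the packaged [stub_backend()] is a
#' deterministic affine stand-in used for testing and demonstration.
#'
#' @param name Identifier.
#' @param segments Segment scheme.
#' @param run Run function as described above.
#' @return An object of class `thermo_backend`.
#' @export
thermo_backend <- function(name, segments, run) {
  stopifnot(is.character(name), is.character(segments), is.function(run))
  structure(list(name = name, segments = segments, run = run),
            class = "thermo_backend")
}

#' @export
print.thermo_backend <- function(x, ...) {
  cat(sprintf("<thermo_backend> %s (%d segments)\n", x$name, length(x$segments)))
  invisible(x)
}

#' Deterministic affine stub thermoregulation backend
#'
#' A closed-form backend for testing and demonstration. Per segment `i` the
#' end-of-run skin temperature is
#' `T_i = T0_i + alpha_i * (t_op - 27) + beta_i * I_cl,i + sex_offset`,
#' i.e. a baseline at 27 degC operative temperature, a linear environmental
#' response, and a linear clothing response. It reproduces the qualitative
#' behaviour the pipeline relies on (skin temperature rising with both
#' operative temperature and local insulation) while every pipeline output
#' stays computable in closed form.
#'
#' @param segments Segment scheme; default the left/right-expanded
#'   11-segment scheme (see [expand_to_backend()]).
#' @param t0 Baseline skin temperatures at 27 degC, nude, degC. Scalar or
#'   named per-segment vector.
#' @param alpha Environmental sensitivities, degC per degC. Scalar or named
#'   vector.
#' @param beta Clothing sensitivities, degC per clo. Scalar or named vector.
#' @param sex_offset Named additive offsets for `male` / `female` subjects,
#'   degC.
#' @return A `thermo_backend`.
#' @export
stub_backend <- function(segments = expand_to_backend(), t0 = 33.5,
                         alpha = 0.25, beta = 0.6,
                         sex_offset = c(male = 0.15, female = -0.15)) {
  expand <- function(p) {
    if (length(p) == 1L) stats::setNames(rep(p, length(segments)), segments)
    else p[segments]
  }
  t0 <- expand(t0); alpha <- expand(alpha); beta <- expand(beta)
  stopifnot(!anyNA(t0), !anyNA(alpha), !anyNA(beta))
  thermo_backend(
    name = "stub-affine",
    segments = segments,
    run = function(env, subject, insulation, duration_h = 2) {
      stopifnot(all(segments %in% names(insulation)))
      off <- sex_offset[[subject$sex]]
      t0 + alpha * (env$t_op - 27) + beta * insulation[segments] + off
    })
}

#' Expand an 11-segment distribution to a backend's segment scheme
#'
#' Multi-node models typically distinguish left and right limbs; the
#' 11-segment scheme does not. Lateral segments are duplicated
#' (`arm -> left_arm, right_arm`, etc.); axial segments (head, neck, chest,
#' back, pelvis) pass through.
#'
#' @param dist A `clo_distribution` (or named clo vector on
#'   [body_segments()]); if missing, the expanded segment name vector is
#'   returned instead.
#' @return Named clo vector on the expanded scheme, or the scheme itself if
#'   `dist` is missing.
#' @export
expand_to_backend <- function(dist) {
  axial <- c("head", "neck", "chest", "back", "pelvis")
  lateral <- c("shoulder", "arm", "hand", "thigh", "leg", "foot")
  scheme <- c(axial, as.vector(rbind(paste0("left_", lateral),
                                     paste0("right_", lateral))))
  if (missing(dist)) return(scheme)
  v <- unclass(dist)
  out <- stats::setNames(numeric(length(scheme)), scheme)
  out[axial] <- v[axial]
  for (s in lateral) out[paste0(c("left_", "right_"), s)] <- v[[s]]
  out
}

# collapse backend temperatures back to the 11-segment scheme (left/right mean)
collapse_from_backend <- function(temps) {
  segs <- body_segments()
  out <- stats::setNames(numeric(length(segs)), segs)
  for (s in segs) {
    lr <- paste0(c("left_", "right_"), s)
    if (all(lr %in% names(temps))) out[s] <- mean(temps[lr])
    else out[s] <- temps[[s]]
  }
  out
}

#' Simulate skin-temperature ranges at the neutral-band endpoints
#'
#' Runs the backend at the lower and upper ends of the neutral
#' operative-temperature band, for a male and a female standard subject,
#' and builds one simulated skin-temperature range per body segment. At
#' each band endpoint the male and female outputs are averaged per segment;
#' the range is then the min/max of the two endpoint averages (min/max
#' rather than (lower-run, upper-run) so that a non-monotone backend still
#' yields a valid interval).
#'
#' @param backend A `thermo_backend` (`NULL` raises an error pointing at
#'   [stub_backend()]).
#' @param dist A `clo_distribution` on the 11-segment scheme.
#' @param band A `neutral_band` (or list with `t_lower`, `t_upper`).
#' @param env Environment defaults for the runs: list with `v` (m/s), `rh`
#'   (%), `met`, `posture`. Defaults to the still-air reference conditions
#'   (0.1 m/s, 50%, 1 met, sitting).
#' @param duration_h Run length, hours; default 2 (steady state).
#' @return data.frame with columns `segment, lo, hi` (degC).
#' @export
run_neutral_endpoints <- function(backend, dist, band,
                                  env = list(v = 0.1, rh = 50, met = 1,
                                             posture = "sitting"),
                                  duration_h = 2) {
  if (is.null(backend)) {
    stop("no thermoregulation backend supplied; use stub_backend() for the ",
         "bundled deterministic backend, or wrap an external multi-node ",
         "model with thermo_backend()", call. = FALSE)
  }
  stopifnot(inherits(backend, "thermo_backend"))
  ins <- expand_to_backend(dist)
  if (!all(backend$segments %in% names(ins))) {
    stop("backend segments not covered by the insulation distribution: ",
         paste(setdiff(backend$segments, names(ins)), collapse = ", "),
         call. = FALSE)
  }
  endpoint_mean <- function(t_op) {
    e <- c(env, list(t_op = t_op))
    male <- backend$run(e, list(sex = "male"), ins, duration_h)
    female <- backend$run(e, list(sex = "female"), ins, duration_h)
    sanity_check_temps(male, backend$name)
    sanity_check_temps(female, backend$name)
    collapse_from_backend((male + female) / 2)
  }
  a <- endpoint_mean(band$t_lower)
  b <- endpoint_mean(band$t_upper)
  data.frame(segment = body_segments(),
             lo = pmin(a, b)[body_segments()],
             hi = pmax(a, b)[body_segments()],
             row.names = NULL, stringsAsFactors = FALSE)
}

sanity_check_temps <- function(temps, backend_name) {
  if (any(temps < 20 | temps > 45)) {
    warning("backend '", backend_name, "' returned skin temperatures outside ",
            "the 20-45 degC sanity band", call. = FALSE)
  }
  invisible(temps)
}

#' Dorsal hand skin temperature from the palmar value
#'
#' Multi-node models with arteriovenous-anastomosis (AVA) blood flow
#' represent palm-side hand temperatures, while field sensors usually sit on
#' the back of the hand. The published carpometacarpal relation
#' `T_dorsal = 0.88 * T_palmar + 2.9` converts between the two.
#'
#' @param t_palmar Palmar skin temperature, degC. Values outside 20–45 degC
#'   warn but are still converted.
#' @return Dorsal skin temperature, degC.
#' @export
#' @examples
#' hand_dorsal_correction(35) # 33.7
hand_dorsal_correction <- function(t_palmar) {
  if (any(t_palmar < 20 | t_palmar > 45)) {
    warning("palmar temperature outside the 20-45 degC band; correction ",
            "applied anyway", call. = FALSE)
  }
  0.88 * t_palmar + 2.9
}

#' Simulate a clothing scenario end to end
#'
#' One call from an overall clothing insulation value to per-segment
#' simulated skin-temperature ranges under thermal neutrality. Variants:
#'
#' * `"local"` — per-segment insulation from the regression models (the
#'   method under assessment);
#' * `"uniform-overall"` — every segment carries the single overall value
#'   (the conventional simplification the method replaces);
#' * `"with-wind"` — local variant plus the log-law wind correction;
#' * `"with-overrides"` — local variant plus explicit segment overrides
#'   (e.g. footwear preference).
#'
#' @param config List with elements: `backend` (a `thermo_backend`),
#'   `variant` (above), `overall_clo`, `posture`, `table` (model table,
#'   default packaged), `overrides` (named clo vector, with-overrides only),
#'   `wind` (list `v_rel`, `coeffs`, `direction`; with-wind only),
#'   `hand_correction` (logical, apply [hand_dorsal_correction()] to the
#'   simulated hand range; default `FALSE`), `band` (a `neutral_band`;
#'   computed from `env` and `overall_clo` when absent), `env` (see
#'   [run_neutral_endpoints()]), `duration_h`.
#' @return List with `ranges` (data.frame `segment, lo, hi`), `variant`,
#'   `distribution`, `band`, and `provenance` (text notes on the steps
#'   applied).
#' @export
simulate_scenario <- function(config) {
  variant <- config$variant
  if (is.null(variant) ||
      !variant %in% c("local", "uniform-overall", "with-wind", "with-overrides")) {
    stop("config$variant must be one of: local, uniform-overall, with-wind, ",
         "with-overrides", call. = FALSE)
  }
  overall <- config$overall_clo
  check_insulation(overall)
  posture <- config$posture %||% "generic"
  table <- config$table %||% default_model_table()
  env <- config$env %||% list(v = 0.1, rh = 50, met = 1, posture = "sitting")
  duration_h <- config$duration_h %||% 2
  prov <- character(0)

  if (variant == "uniform-overall") {
    dist <- new_distribution(
      stats::setNames(rep(overall, 11), body_segments()), posture, overall)
    prov <- c(prov, "uniform overall insulation on every segment")
  } else {
    dist <- predict_distribution(overall, posture, table)
    prov <- c(prov, sprintf("local distribution from model table (%s)", posture))
  }
  if (variant == "with-wind") {
    w <- config$wind
    if (is.null(w)) stop("with-wind variant needs config$wind", call. = FALSE)
    dist <- apply_wind_correction(dist, w$v_rel, w$coeffs,
                                  w$direction %||% "downstream")
    prov <- c(prov, sprintf("wind correction at %.2f m/s (%s)", w$v_rel,
                            w$direction %||% "downstream"))
  }
  if (variant == "with-overrides") {
    if (is.null(config$overrides)) {
      stop("with-overrides variant needs config$overrides", call. = FALSE)
    }
    dist <- apply_overrides(dist, config$overrides)
    prov <- c(prov, paste("overrides:",
                          paste(names(config$overrides), unlist(config$overrides),
                                sep = "=", collapse = ", ")))
  }

  band <- config$band %||% neutral_band(env$v, env$rh, env$met, overall)
  ranges <- run_neutral_endpoints(config$backend, dist, band, env, duration_h)
  if (isTRUE(config$hand_correction)) {
    i <- ranges$segment == "hand"
    ranges$lo[i] <- hand_dorsal_correction(ranges$lo[i])
    ranges$hi[i] <- hand_dorsal_correction(ranges$hi[i])
    prov <- c(prov, "dorsal hand correction applied")
  }
  list(ranges = ranges, variant = variant, distribution = dist, band = band,
       provenance = prov)
}
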