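# shared fixtures, all built in code

# packaged table restricted to generic-posture models; any posture request
# falls back to these, which makes it a convenient single-truth table
generic_table <- function() {
  tab <- default_model_table()
  keep <- vapply(tab$models, function(m) m$posture == "generic", logical(1))
  model_table(unname(tab$models[keep]), provenance = "generic subset")
}

# generic-posture truth table idealized to exact branch continuity
# (printed coefficient pairs meet only to ~1e-3 clo at their breakpoints;
# machine-precision recovery needs a truth inside the continuous-hinge family)
exact_generic_table <- function() {
  models <- lapply(generic_table()$models, function(m) {
    if (m$kind == "piecewise") {
      segment_model(m$segment, m$posture, "piecewise", m$a1, m$b1,
                    breakpoint = m$breakpoint, a2 = m$a2,
                    b2 = (m$a1 - m$a2) * m$breakpoint + m$b1,
                    minimum = m$minimum, r2 = m$r2)
    } else m
  })
  model_table(unname(models), provenance = "generic, exact continuity")
}

# overall-insulation grid for noiseless recovery: dense at the low end so
# every truth breakpoint (smallest: leg, 0.450) lies strictly inside the
# 10th-90th percentile candidate window, and no clipping threshold binds
# (all unclipped lines exceed their minima for overall >= 0.35 clo)
recovery_grid <- function(tab) {
  bps <- unlist(lapply(tab$models, `[[`, "breakpoint"))
  sort(c(seq(0.35, 0.55, length.out = 60),
         seq(0.56, 2.17, length.out = 80),
         bps[is.finite(bps)]))
}

# unclipped truth line of a segment model
segment_truth_line <- function(m, x) {
  if (m$kind == "piecewise") {
    ifelse(x < m$breakpoint, m$a1 * x + m$b1, m$a2 * x + m$b2)
  } else {
    m$a1 * x + m$b1
  }
}

# fixed-point iteration oracle for inverting I_t = x + I_a / (1 + 0.28 x)
total_to_local_fixed_point <- function(i_t, i_a, iter = 200) {
  x <- max(i_t - i_a, 0)
  for (k in seq_len(iter)) x <- max(i_t - i_a / (1 + 0.28 * x), 0)
  x
}

# forward map: local + nude baseline -> regional total
local_to_total <- function(x, i_a) x + i_a / (1 + 0.28 * x)

# long-format raw records for one ensemble, canonical segments
make_raw_ensemble <- function(id, convention, values, nude = NULL,
                              posture = "standing", sex = "male",
                              overall = NA_real_,
                              segments = body_segments()) {
  data.frame(ensemble_id = id, posture = posture, sex = sex,
             segment = segments, convention = convention,
             value_clo = values,
             nude_baseline_clo = if (is.null(nude)) NA_real_ else nude,
             overall_clo = overall, stringsAsFactors = FALSE)
}

# noiseless points on a continuous hinge, breakpoint included in the data
hinge_points <- function(a1, b1, bp, a2, n = 40, lo = 0.2, hi = 2.2) {
  x <- sort(c(seq(lo, hi, length.out = n), bp))
  b2 <- (a1 - a2) * bp + b1
  y <- ifelse(x < bp, a1 * x + b1, a2 * x + b2)
  list(x = x, y = y)
}

# brute-force interval Jaccard by counting 0.001-degC grid cells;
# endpoints are expected on the 0.001 grid
grid_jaccard <- function(a, b, h = 0.001) {
  cells <- function(lo, hi) round((hi - lo) / h)
  ov <- max(0, min(a$hi, b$hi) - max(a$lo, b$lo))
  n_ov <- cells(0, ov)
  n_un <- cells(a$lo, a$hi) + cells(b$lo, b$hi) - n_ov
  if (n_un == 0) return(as.numeric(a$lo == b$lo))
  n_ov / n_un
}
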