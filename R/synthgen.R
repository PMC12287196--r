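# run code under a local RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Generate a synthetic clothing-ensemble dataset
#'
#' Draws ensembles with the statistical structure the regression method
#' assumes: overall insulation uniform over the observed ensemble range
#' (default 0.22–2.17 clo), and per-segment local insulation equal to a
#' truth model table's prediction plus Gaussian noise, clipped below at the
#' model's minimum threshold (and at 0). Segments without a truth model
#' (the neck) get 0. Fully reproducible for a fixed seed.
#'
#' With `convention = "harmonized"` the wide harmonized format is returned
#' directly; with `"regional_total"` or `"effective_local"` the records are
#' forward-converted through the ISO 9920 relations (nude baselines drawn
#' uniform on 0.4–0.7 clo) and returned in the long raw format, to exercise
#' the ingestion pipeline.
#'
#' @param n_ensembles Number of ensembles.
#' @param posture_mix Named proportions over `standing` / `sitting`.
#' @param clo_range Overall-insulation range (lo, hi), clo.
#' @param overall Optional explicit vector of overall insulation values
#'   (overrides `n_ensembles`/`clo_range`); useful for noiseless-recovery
#'   checks on a designed grid.
#' @param noise_sd Per-segment Gaussian noise, clo.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param table Truth model table; default the packaged set.
#' @param convention Output convention (see above).
#' @return Wide data.frame (`ensemble_id, posture, sex, overall_clo`, one
#'   column per segment) or long raw-format data.frame (see
#'   [harmonize_dataset()]).
#' @export
gen_clothing_dataset <- function(n_ensembles = 240,
                                 posture_mix = c(standing = 0.67, sitting = 0.33),
                                 clo_range = c(0.22, 2.17),
                                 overall = NULL,
                                 noise_sd = 0.05,
                                 seed = NULL,
                                 table = default_model_table(),
                                 convention = c("harmonized", "regional_total",
                                                "effective_local")) {
  convention <- match.arg(convention)
  stopifnot(n_ensembles >= 1, noise_sd >= 0, clo_range[1] < clo_range[2],
            all(names(posture_mix) %in% c("standing", "sitting")))
  with_seed(seed, {
    if (!is.null(overall)) n_ensembles <- length(overall)
    posture <- sample(names(posture_mix), n_ensembles, replace = TRUE,
                      prob = posture_mix)
    sex <- sample(c("male", "female"), n_ensembles, replace = TRUE)
    if (is.null(overall)) {
      overall <- stats::runif(n_ensembles, clo_range[1], clo_range[2])
    }
    segs <- body_segments()
    wide <- data.frame(
      ensemble_id = sprintf("synth_%04d", seq_len(n_ensembles)),
      posture = posture, sex = sex, overall_clo = overall,
      stringsAsFactors = FALSE)
    for (s in segs) {
      wide[[s]] <- vapply(seq_len(n_ensembles), function(i) {
        mm <- lookup_model(table, s, posture[i])
        if (is.null(mm)) return(0) # unmodeled segment (neck)
        truth <- suppressWarnings(predict_local(mm, overall[i]))
        max(truth + stats::rnorm(1, 0, noise_sd), mm$minimum, 0)
      }, numeric(1))
    }
    if (convention == "harmonized") return(wide)

    # forward-convert to a raw long format through the ISO 9920 relations
    long <- do.call(rbind, lapply(seq_len(n_ensembles), function(i) {
      i_a <- stats::runif(length(segs), 0.4, 0.7)
      local <- as.numeric(wide[i, segs])
      i_t <- local + i_a / (1 + 0.28 * local)
      value <- if (convention == "regional_total") i_t else i_t - i_a
      data.frame(
        ensemble_id = wide$ensemble_id[i], posture = wide$posture[i],
        sex = wide$sex[i], segment = segs, convention = convention,
        value_clo = value, nude_baseline_clo = i_a,
        overall_clo = wide$overall_clo[i], stringsAsFactors = FALSE)
    }))
    long
  })
}

#' Generate a synthetic skin-temperature and vote series
#'
#' Emulates a field series: thermally neutral records draw each segment's
#' skin temperature uniformly inside that segment's true range (plus
#' Gaussian sensor noise) with a vote uniform in [-0.5, 0.5]; non-neutral
#' records are shifted outside the true range in the direction of their
#' (warm or cool) vote. Seeded and reproducible.
#'
#' @param true_ranges data.frame `segment, lo, hi` (degC).
#' @param n_samples Number of records.
#' @param neutral_fraction Proportion of neutral records.
#' @param noise_sd Sensor noise, degC.
#' @param seed Integer seed; `NULL` uses the current stream.
#' @return data.frame `timestamp, subject_id, tsv` plus one column per
#'   segment.
#' @export
gen_skin_series <- function(true_ranges, n_samples = 200,
                            neutral_fraction = 0.7, noise_sd = 0.1,
                            seed = NULL) {
  stopifnot(all(c("segment", "lo", "hi") %in% names(true_ranges)),
            all(true_ranges$lo <= true_ranges$hi),
            n_samples >= 1, neutral_fraction >= 0, neutral_fraction <= 1)
  with_seed(seed, {
    neutral <- stats::runif(n_samples) < neutral_fraction
    warm <- stats::runif(n_samples) < 0.5
    tsv <- ifelse(neutral, stats::runif(n_samples, -0.5, 0.5),
                  ifelse(warm, stats::runif(n_samples, 1, 3),
                         stats::runif(n_samples, -3, -1)))
    out <- data.frame(
      timestamp = seq_len(n_samples),
      subject_id = sprintf("S%02d", 1 + (seq_len(n_samples) - 1) %% 10),
      tsv = tsv, stringsAsFactors = FALSE)
    for (k in seq_len(nrow(true_ranges))) {
      lo <- true_ranges$lo[k]; hi <- true_ranges$hi[k]
      base <- stats::runif(n_samples, lo, hi)
      shift <- ifelse(neutral, 0,
                      ifelse(warm, (hi - lo) + stats::runif(n_samples, 0.5, 2),
                             -((hi - lo) + stats::runif(n_samples, 0.5, 2))))
      out[[true_ranges$segment[k]]] <-
        base + shift + stats::rnorm(n_samples, 0, noise_sd)
    }
    out
  })
}
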