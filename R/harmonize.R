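#' Regional total insulation from effective local insulation
#'
#' A segment's effective clothing insulation `I_clu,i` is its increment over
#' the nude condition, so the regional total (which includes the air boundary
#' layer) is the sum of the effective value and the nude-manikin baseline
#' `I_a,i`.
#'
#' @param i_clu_i Effective local clothing insulation, clo.
#' @param i_a_i Air-boundary-layer (nude manikin) insulation, clo.
#' @return Regional total insulation `I_t,i`, clo.
#' @export
#' @examples
#' effective_to_total(0.3, 0.5) # 0.8
effective_to_total <- function(i_clu_i, i_a_i) {
  check_insulation(i_clu_i)
  check_insulation(i_a_i)
  i_clu_i + i_a_i
}

#' Local clothing area factor
#'
#' Empirical relation between the local clothing insulation of a segment and
#' the ratio of its clothed to nude surface area:
#' `f_cl,i = 1 + 0.28 * I_cl,i`.
#'
#' @param i_cl_i Local clothing insulation, clo.
#' @return Clothing area factor (unitless, >= 1).
#' @export
#' @examples
#' fcl_from_local(1) # 1.28
fcl_from_local <- function(i_cl_i) {
  check_insulation(i_cl_i)
  1 + 0.28 * i_cl_i
}

#' Local clothing insulation from regional total insulation
#'
#' Inverts the ISO 9920 relation
#' `I_t,i = I_cl,i + I_a,i / f_cl,i` with `f_cl,i = 1 + 0.28 * I_cl,i`,
#' which is implicit in `I_cl,i`. Substituting the area factor gives the
#' quadratic `0.28 x^2 + (1 - 0.28 I_t) x - (I_t - I_a) = 0`; the unique
#' non-negative root is returned in closed form. A total below the nude
#' baseline would imply negative clothing insulation and is clipped to 0
#' with a warning.
#'
#' @param i_t_i Regional total insulation, clo.
#' @param i_a_i Nude-manikin baseline insulation, clo. Recycled.
#' @return Local clothing insulation `I_cl,i`, clo.
#' @export
#' @examples
#' total_to_local(1.0, 0.5)  # ~0.5687
#' total_to_local(0.5, 0.5)  # 0 (nude)
total_to_local <- function(i_t_i, i_a_i) {
  check_insulation(i_t_i)
  check_insulation(i_a_i)
  n <- max(length(i_t_i), length(i_a_i))
  i_t_i <- rep_len(i_t_i, n)
  i_a_i <- rep_len(i_a_i, n)
  clipped <- i_t_i < i_a_i
  if (any(clipped)) {
    warning(sum(clipped), " record(s) with total insulation below the nude ",
            "baseline; local insulation clipped to 0", call. = FALSE)
  }
  b <- 1 - 0.28 * i_t_i
  cc <- -(i_t_i - i_a_i)
  x <- (-b + sqrt(b^2 - 4 * 0.28 * cc)) / (2 * 0.28)
  x[clipped] <- 0
  # guard against tiny negative roots from floating point at I_t == I_a
  pmax(x, 0)
}

#' Merge segment insulations with the parallel (harmonic-mean) rule
#'
#' For a manikin operated at uniform surface temperature, the regional total
#' insulation of a merged segment is the area-weighted harmonic mean of its
#' parts: `I_t,i' = sum(A_i) / sum(A_i / I_t,i)`. The result always lies
#' between the smallest and largest input value and is invariant to
#' rescaling all areas by a constant.
#'
#' @param areas Surface areas (or area fractions) of the original segments;
#'   all > 0.
#' @param values Regional total insulations of the original segments, clo;
#'   all > 0 (a zero would mean infinite conductance).
#' @return Merged insulation, clo (scalar).
#' @export
#' @examples
#' remap_parallel(c(1, 1), c(1, 2)) # 4/3
remap_parallel <- function(areas, values) {
  if (length(areas) != length(values) || length(areas) == 0) {
    stop("areas and values must be non-empty and of equal length", call. = FALSE)
  }
  if (any(!is.finite(areas)) || any(areas <= 0)) {
    stop("all areas must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("all insulation values must be positive and finite for the ",
         "parallel rule (zero implies infinite conductance)", call. = FALSE)
  }
  sum(areas) / sum(areas / values)
}

#' Read an area map
#'
#' An area map tells the harmonizer how original manikin segments map onto
#' the 11-segment scheme and with what surface-area fractions (used as the
#' weights of the parallel merging rule). CSV columns:
#' `original_segment, area_fraction, target_segment`.
#'
#' @param path CSV file; default is the map packaged with localclo, which
#'   covers a typical left/right-split manikin segmentation with
#'   conventional body-surface-area fractions.
#' @return A data.frame with columns `original_segment`, `area_fraction`,
#'   `target_segment`.
#' @export
read_area_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "area_map_default.csv", package = "localclo")
  }
  am <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("original_segment", "area_fraction", "target_segment")
  if (!all(need %in% names(am))) {
    stop("area map must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  am$original_segment <- tolower(trimws(am$original_segment))
  am$target_segment <- canonical_segment(am$target_segment)
  if (any(!is.finite(am$area_fraction)) || any(am$area_fraction <= 0)) {
    stop("area fractions must be positive", call. = FALSE)
  }
  if (anyDuplicated(am$original_segment)) {
    stop("each original segment may map to exactly one target", call. = FALSE)
  }
  am
}

#' Harmonize a raw clothing dataset to local insulation on the 11-segment scheme
#'
#' Takes long-format per-segment records in any of the three published value
#' conventions and produces one harmonized ensemble record per `ensemble_id`
#' with local clothing insulation for all 11 segments. Pipeline, per
#' ensemble:
#'
#' 1. effective-local records are converted to regional totals
#'    (`I_t = I_clu + I_a`);
#' 2. original segments are merged onto the 11-segment scheme with the
#'    parallel rule, applied to totals and (by the same physics) to the nude
#'    baselines;
#' 3. totals are converted to local insulation by inverting the implicit
#'    clothing-area-factor relation.
#'
#' Records already in the `local` convention pass through untouched, but
#' merging is disallowed for them (local values cannot be combined by the
#' parallel rule, which applies to totals): their segment labels must already
#' be canonical. Ensembles that mix conventions, lack full segment coverage,
#' or contain non-positive totals are rejected individually with a reason —
#' one bad ensemble never aborts the run.
#'
#' @param records Long-format data.frame with columns `ensemble_id, posture,
#'   sex, segment, convention, value_clo, nude_baseline_clo` and optionally
#'   `overall_clo` (the dataset's reported whole-body insulation; carried
#'   through, never recomputed from locals). `convention` is one of
#'   `"local"`, `"regional_total"`, `"effective_local"`.
#' @param area_map An area map (see [read_area_map()]); `NULL` for the
#'   identity map on canonical segments.
#' @return A list with components `ensembles` (wide data.frame:
#'   `ensemble_id, posture, sex, overall_clo`, then one column per segment)
#'   and `log` (data.frame of per-ensemble status and conversions applied /
#'   rejection reasons).
#' @export
harmonize_dataset <- function(records, area_map = NULL) {
  need <- c("ensemble_id", "posture", "sex", "segment", "convention", "value_clo")
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!"nude_baseline_clo" %in% names(records)) records$nude_baseline_clo <- NA_real_
  if (!"overall_clo" %in% names(records)) records$overall_clo <- NA_real_
  records$convention <- tolower(trimws(records$convention))

  segs <- body_segments()
  out <- vector("list", 0L)
  log <- vector("list", 0L)

  for (eid in unique(records$ensemble_id)) {
    rec <- records[records$ensemble_id == eid, , drop = FALSE]
    res <- tryCatch(
      harmonize_one(rec, area_map, segs),
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) {
      log[[length(log) + 1L]] <- data.frame(
        ensemble_id = eid, status = "rejected", detail = res,
        stringsAsFactors = FALSE)
    } else {
      out[[length(out) + 1L]] <- res$row
      log[[length(log) + 1L]] <- data.frame(
        ensemble_id = eid, status = "ok", detail = res$detail,
        stringsAsFactors = FALSE)
    }
  }
  list(
    ensembles = if (length(out)) do.call(rbind, out) else NULL,
    log = do.call(rbind, log)
  )
}

# one ensemble; errors carry the rejection reason
harmonize_one <- function(rec, area_map, segs) {
  conv <- unique(rec$convention)
  if (length(conv) != 1L) {
    stop("mixed conventions within ensemble: ", paste(conv, collapse = ", "),
         call. = FALSE)
  }
  if (!conv %in% c("local", "regional_total", "effective_local")) {
    stop("unknown convention: ", conv, call. = FALSE)
  }
  if (any(!is.finite(rec$value_clo)) || any(rec$value_clo < 0)) {
    stop("non-finite or negative insulation value", call. = FALSE)
  }
  steps <- character(0)

  if (conv == "local") {
    # pass-through; parallel merging is undefined for local values
    seg <- canonical_segment(rec$segment, strict = FALSE)
    if (anyNA(seg)) {
      stop("local-convention records must use canonical segments ",
           "(merging is only defined for totals); unknown: ",
           paste(unique(rec$segment[is.na(seg)]), collapse = ", "), call. = FALSE)
    }
    locals <- stats::setNames(rec$value_clo, seg)
    steps <- "pass-through (local convention)"
  } else {
    if (any(!is.finite(rec$nude_baseline_clo)) || any(rec$nude_baseline_clo <= 0)) {
      stop("convention '", conv, "' requires a positive nude_baseline_clo ",
           "for every record", call. = FALSE)
    }
    tot <- rec$value_clo
    if (conv == "effective_local") {
      tot <- effective_to_total(rec$value_clo, rec$nude_baseline_clo)
      steps <- c(steps, "effective->total")
    }
    if (any(tot <= 0)) stop("non-positive regional total insulation", call. = FALSE)

    # segment remapping on totals (and, by the same rule, nude baselines)
    orig <- tolower(trimws(rec$segment))
    if (is.null(area_map)) {
      target <- canonical_segment(rec$segment, strict = FALSE)
      if (anyNA(target)) {
        stop("no area map supplied and segment labels are not canonical: ",
             paste(unique(rec$segment[is.na(target)]), collapse = ", "),
             call. = FALSE)
      }
      area <- rep(1, length(orig))
    } else {
      idx <- match(orig, area_map$original_segment)
      if (anyNA(idx)) {
        stop("segment(s) missing from area map: ",
             paste(unique(orig[is.na(idx)]), collapse = ", "), call. = FALSE)
      }
      target <- area_map$target_segment[idx]
      area <- area_map$area_fraction[idx]
    }
    if (anyDuplicated(orig)) stop("duplicate original segment", call. = FALSE)
    merged_t <- tapply(seq_along(target), target, function(i) {
      remap_parallel(area[i], tot[i])
    })
    merged_a <- tapply(seq_along(target), target, function(i) {
      remap_parallel(area[i], rec$nude_baseline_clo[i])
    })
    steps <- c(steps, "parallel segment remap", "total->local")
    locals <- total_to_local(as.numeric(merged_t), as.numeric(merged_a))
    names(locals) <- names(merged_t)
  }

  missing <- setdiff(segs, names(locals))
  if (length(missing)) {
    stop("incomplete segment coverage; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(names(locals))) stop("duplicate target segment", call. = FALSE)

  row <- data.frame(
    ensemble_id = rec$ensemble_id[1L],
    posture = tolower(rec$posture[1L]),
    sex = tolower(rec$sex[1L]),
    overall_clo = rec$overall_clo[1L],
    stringsAsFactors = FALSE
  )
  for (s in segs) row[[s]] <- unname(locals[s])
  list(row = row, detail = paste(steps, collapse = "; "))
}
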