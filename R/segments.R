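#' The 11-segment body scheme
#'
#' Segment labels used throughout the package: head, neck, chest, back,
#' pelvis, shoulder, arm, hand, thigh, leg, foot. Left/right symmetric parts
#' are collapsed into a single label. The scheme matches the placement of
#' skin-temperature sensors in field work and the segmentation of common
#' multi-node thermoregulation models (lateral parts duplicated on export,
#' see [expand_to_backend()]).
#'
#' @return Character vector of the 11 canonical segment names, in order.
#' @export
#' @examples
#' body_segments()
body_segments <- function() {
  c("head", "neck", "chest", "back", "pelvis", "shoulder",
    "arm", "hand", "thigh", "leg", "foot")
}

#' Canonicalize a segment label
#'
#' Case-insensitive and plural-insensitive: `"Thighs"` and `"thigh"` both map
#' to `"thigh"`. Labels that do not resolve to one of the 11 canonical
#' segments raise an error (or return `NA` with `strict = FALSE`).
#'
#' @param x Character vector of segment labels.
#' @param strict Error on unknown labels? Default `TRUE`.
#' @return Character vector of canonical labels.
#' @export
#' @examples
#' canonical_segment(c("Head", "thighs", "FEET"))
canonical_segment <- function(x, strict = TRUE) {
  lx <- tolower(trimws(as.character(x)))
  # irregular plural first, then trailing "s"
  lx[lx == "feet"] <- "foot"
  segs <- body_segments()
  out <- ifelse(lx %in% segs, lx, sub("s$", "", lx))
  out[!out %in% segs] <- NA_character_
  if (strict && anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown body segment label(s): ", paste(bad, collapse = ", "),
         "; expected one of: ", paste(segs, collapse = ", "), call. = FALSE)
  }
  out
}

#' Convert clothing insulation between clo and SI units
#'
#' 1 clo = 0.155 m2.K/W. All package-internal arithmetic is in clo; these
#' helpers are for I/O boundaries.
#'
#' @param x Numeric insulation values (clo for `clo_to_si`, m2.K/W for
#'   `si_to_clo`). Must be finite and non-negative.
#' @return Numeric vector in the other unit.
#' @export
#' @examples
#' clo_to_si(1)    # 0.155
#' si_to_clo(0.31) # 2
clo_to_si <- function(x) {
  check_insulation(x)
  x * 0.155
}

#' @rdname clo_to_si
#' @export
si_to_clo <- function(x) {
  check_insulation(x)
  x / 0.155
}

# shared domain check for insulation-like quantities
check_insulation <- function(x, what = deparse(substitute(x))) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop(what, " must be finite and non-negative", call. = FALSE)
  }
  invisible(x)
}
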