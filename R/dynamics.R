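# Nine model-free enhancement-curve features.
#
# The curve is split at its peak (earliest maximum): wash-in = samples from
# the precontrast baseline up to and including the peak, wash-out = from the
# peak (included in both segments: the peak is the junction) to the end.
# Slopes/intercepts are ordinary least squares on each segment; areas are
# trapezoidal. No signal-to-concentration conversion is applied.

.ols_line <- function(t, s) {
  tb <- mean(t); sb <- mean(s)
  slope <- sum((t - tb) * (s - sb)) / sum((t - tb)^2)
  c(slope = slope, intercept = sb - slope * tb)
}

.trapz <- function(t, s) sum(diff(t) * (utils::head(s, -1) + utils::tail(s, -1)) / 2)

#' Dynamic features of a time-intensity curve
#'
#' TTP = time of the (earliest) signal maximum; MSD = peak minus baseline
#' signal; WIS/WII and WOS/WOI = slope and intercept of least-squares lines
#' through the wash-in and wash-out samples; AUGC, AUCWI, AUCWO = trapezoidal
#' areas under the whole curve and its two segments. When the peak is the
#' last sample the wash-out features are missing-coded (`NA`) and flagged;
#' when the peak is the baseline itself (flat or decaying curve) the wash-in
#' line is the degenerate zero-slope line through the baseline and AUCWI = 0.
#'
#' @param curve A [ti_curve()].
#' @return List of class `dyn_features` with fields `TTP`, `MSD`, `WIS`,
#'   `WII`, `WOS`, `WOI`, `AUGC`, `AUCWI`, `AUCWO` and a character vector
#'   `flags`.
#' @export
dynamic_features <- function(curve) {
  stopifnot(inherits(curve, "ti_curve"))
  t <- curve$times; s <- curve$signals
  n <- length(s)
  b <- curve$baseline_index
  peak <- which.max(s)  # which.max returns the earliest maximum
  flags <- character(0)

  ttp <- t[peak]
  msd <- s[peak] - s[b]

  # wash-in: [baseline .. peak]
  if (peak > b) {
    wi <- .ols_line(t[b:peak], s[b:peak])
    aucwi <- .trapz(t[b:peak], s[b:peak])
  } else {
    wi <- c(slope = 0, intercept = s[b])
    aucwi <- 0
    flags <- c(flags, "degenerate wash-in: peak at baseline")
  }

  # wash-out: [peak .. end]
  if (peak < n) {
    wo <- .ols_line(t[peak:n], s[peak:n])
    aucwo <- .trapz(t[peak:n], s[peak:n])
  } else {
    wo <- c(slope = NA_real_, intercept = NA_real_)
    aucwo <- NA_real_
    flags <- c(flags, "missing wash-out: peak at last sample")
  }

  structure(list(
    TTP = ttp, MSD = msd,
    WIS = unname(wi["slope"]), WII = unname(wi["intercept"]),
    WOS = unname(wo["slope"]), WOI = unname(wo["intercept"]),
    AUGC = .trapz(t, s), AUCWI = aucwi, AUCWO = aucwo,
    flags = flags
  ), class = "dyn_features")
}

#' Canonical dynamic feature names
#' @return Character vector of the 9 feature column names.
#' @export
dyn_feature_names <- function() {
  c("TTP", "MSD", "WIS", "WII", "WOS", "WOI", "AUGC", "AUCWI", "AUCWO")
}

#' Dynamic features for a set of curves
#'
#' @param curves Named list of [ti_curve()] objects (names = node ids), e.g.
#'   from [read_curves_csv()].
#' @return data.frame with `node_id` and the 9 feature columns, sorted by
#'   `node_id`; rows with missing wash-out are kept with `NA` fields.
#' @export
batch_dynamic <- function(curves) {
  ids <- names(curves)
  if (is.null(ids) || any(ids == "")) stop("curves must be a named list")
  if (anyDuplicated(ids)) {
    stop("duplicate node_id in curves: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  rows <- lapply(ids, function(id) {
    f <- dynamic_features(curves[[id]])
    data.frame(node_id = id, TTP = f$TTP, MSD = f$MSD, WIS = f$WIS,
               WII = f$WII, WOS = f$WOS, WOI = f$WOI, AUGC = f$AUGC,
               AUCWI = f$AUCWI, AUCWO = f$AUCWO, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$node_id), , drop = FALSE]
}
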