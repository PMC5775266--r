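#' Read a northern band-intensity table
#'
#' @param path TSV with header columns `feature_id`, `strain` (`wt` or
#'   `rnc`), `time_point_h`, `band_signal`, `control_signal` (the same
#'   lane's 5S rRNA signal). `#`-prefixed lines are skipped.
#' @return A validated data.frame with those columns, numeric where due.
#' @export
read_northern_table <- function(path) {
  d <- read_checked_tsv(path)
  needed <- c("feature_id", "strain", "time_point_h", "band_signal",
              "control_signal")
  missing <- setdiff(needed, names(d))
  if (length(missing)) {
    stop("northern table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  d$time_point_h <- vapply(seq_len(nrow(d)), function(i)
    parse_numeric_cell(d$time_point_h[i], path, i, "time_point_h"), 0)
  d$band_signal <- vapply(seq_len(nrow(d)), function(i)
    parse_numeric_cell(d$band_signal[i], path, i, "band_signal"), 0)
  d$control_signal <- vapply(seq_len(nrow(d)), function(i)
    parse_numeric_cell(d$control_signal[i], path, i, "control_signal"), 0)
  validate_measurements(d)
  d
}

validate_measurements <- function(d) {
  bad <- setdiff(unique(d$strain), c("wt", "rnc"))
  if (length(bad)) {
    stop("unknown strain label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(d$band_signal)) || any(d$band_signal < 0)) {
    stop("band_signal must be a nonnegative number", call. = FALSE)
  }
  zero <- which(is.na(d$control_signal) | d$control_signal <= 0)
  if (length(zero)) {
    i <- zero[1L]
    stop("zero or missing 5S control signal in lane (", d$feature_id[i],
         ", ", d$strain[i], ", ", d$time_point_h[i], " h)", call. = FALSE)
  }
  invisible(d)
}

#' Normalize band signals to the 5S loading control
#'
#' Each band signal is divided by the 5S rRNA signal of the same lane,
#' correcting lane-to-lane loading differences; the normalized value is
#' invariant to rescaling a whole lane.
#'
#' @param measurements Data.frame as returned by [read_northern_table()].
#' @return The same data.frame with a `normalized` column appended.
#' @export
normalize_measurements <- function(measurements) {
  validate_measurements(measurements)
  measurements$normalized <-
    measurements$band_signal / measurements$control_signal
  measurements
}

#' Classify one feature's response to RNase III deletion
#'
#' For each time point measured in both strains the ratio
#' `(rnc + floor) / (wt + floor)` of 5S-normalized intensities is formed
#' (the pseudo-floor keeps ratios finite for blank lanes); their geometric
#' mean G across shared time points summarizes the course. G at least
#' `ratio_threshold` is `increased_in_rnc`; G at most `1/ratio_threshold`
#' is `decreased_in_rnc`; if every normalized value in both strains is
#' below `detection_floor` the feature is `not_detected`; anything else is
#' `unchanged`.
#'
#' @param profile Data.frame for one feature with columns `strain`,
#'   `time_point_h`, `normalized` (from [normalize_measurements()]).
#' @param ratio_threshold Fold-ratio threshold (default 2).
#' @param detection_floor Pseudo-floor on normalized intensities
#'   (default 0.01).
#' @return List with `response` and `ratios` (named per-time-point
#'   rnc/wt ratios, so a single-time-point reading can be checked too).
#' @export
classify_rnc_response <- function(profile, ratio_threshold = 2,
                                  detection_floor = 0.01) {
  stopifnot(ratio_threshold > 0, detection_floor > 0)
  wt <- profile[profile$strain == "wt", , drop = FALSE]
  rnc <- profile[profile$strain == "rnc", , drop = FALSE]
  shared <- intersect(wt$time_point_h, rnc$time_point_h)
  if (length(shared) == 0L) {
    stop("insufficient data: no time point measured in both strains",
         call. = FALSE)
  }
  if (all(profile$normalized < detection_floor)) {
    return(list(response = "not_detected",
                ratios = stats::setNames(rep(NA_real_, length(shared)),
                                         shared)))
  }
  shared <- sort(shared)
  ratios <- vapply(shared, function(tp) {
    (rnc$normalized[match(tp, rnc$time_point_h)] + detection_floor) /
      (wt$normalized[match(tp, wt$time_point_h)] + detection_floor)
  }, 0)
  names(ratios) <- shared
  g <- exp(mean(log(ratios)))
  response <- if (g >= ratio_threshold) "increased_in_rnc"
              else if (g <= 1 / ratio_threshold) "decreased_in_rnc"
              else "unchanged"
  list(response = response, ratios = ratios, geometric_mean_ratio = g)
}

#' Build 5S-normalized profiles and response calls for all features
#'
#' @param measurements Data.frame as returned by [read_northern_table()]
#'   (or the same columns built in code).
#' @param ratio_threshold,detection_floor See [classify_rnc_response()].
#' @return Data.frame, one row per feature: `feature_id`, `response`,
#'   `geometric_mean_ratio`, and one `ratio_<t>h` column per shared time
#'   point.
#' @export
northern_profiles <- function(measurements, ratio_threshold = 2,
                              detection_floor = 0.01) {
  norm <- normalize_measurements(measurements)
  feats <- unique(norm$feature_id)
  rows <- lapply(feats, function(f) {
    r <- classify_rnc_response(norm[norm$feature_id == f, , drop = FALSE],
                               ratio_threshold, detection_floor)
    out <- data.frame(feature_id = f, response = r$response,
                      geometric_mean_ratio =
                        if (is.null(r$geometric_mean_ratio)) NA_real_
                        else r$geometric_mean_ratio,
                      stringsAsFactors = FALSE)
    for (tp in names(r$ratios)) {
      out[[paste0("ratio_", tp, "h")]] <- unname(r$ratios[tp])
    }
    out
  })
  ## pad to common columns before binding
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cc in setdiff(cols, names(r))) r[[cc]] <- NA_real_
    r[cols]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
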