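#' Quantify clotting-time-induced change per marker
#'
#' For each donor and marker, computes the relative change of the serum level
#' at the 4 h and 24 h clotting timepoints against that donor's 0.5 h
#' baseline, `(level_t - level_0.5) / level_0.5`, then summarizes per marker.
#' The default summary is the mean of per-donor relative changes (matching a
#' per-donor bar presentation); `method = "of_means"` instead reports the
#' relative change of the donor-mean levels.
#'
#' A direction-consistency flag records whether every donor moved the same
#' way at a timepoint (e.g. levels always lower after 24 h); it is reported
#' for context but does not by itself drive deselection.
#'
#' @param series Long-format clotting table with columns `donor`, `marker`,
#'   `time_h` (containing 0.5 and the later timepoints) and `level` (> 0).
#' @param method `"per_donor"` (default) or `"of_means"`.
#' @return An object of class `stability_report`: a `data.frame` with one row
#'   per marker (`marker`, `mean_rel_change_4h`, `mean_rel_change_24h`,
#'   `consistent_4h`, `consistent_24h`), with the per-donor changes attached
#'   as attribute `"per_donor"`.
#' @export
relative_change <- function(series, method = c("per_donor", "of_means")) {
  method <- match.arg(method)
  req <- c("donor", "marker", "time_h", "level")
  miss <- setdiff(req, names(series))
  if (length(miss)) stop("series lacks column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(series$level) | series$level <= 0)) {
    bad <- which(!is.finite(series$level) | series$level <= 0)[1]
    stop("nonpositive level for donor '", series$donor[bad], "', marker '",
         series$marker[bad], "' at ", series$time_h[bad], " h")
  }

  markers <- unique(series$marker)
  donors <- unique(series$donor)
  per_donor <- NULL
  rows <- lapply(markers, function(mk) {
    sub <- series[series$marker == mk, , drop = FALSE]
    chg <- lapply(c(4, 24), function(tt) {
      vapply(donors, function(d) {
        base <- sub$level[sub$donor == d & sub$time_h == 0.5]
        lev <- sub$level[sub$donor == d & sub$time_h == tt]
        if (length(base) != 1L)
          stop("missing 0.5 h baseline for donor '", d, "', marker '", mk, "'")
        if (length(lev) != 1L)
          stop("missing ", tt, " h level for donor '", d, "', marker '", mk, "'")
        (lev - base) / base
      }, numeric(1))
    })
    per_donor <<- rbind(
      per_donor,
      data.frame(marker = mk, donor = rep(donors, 2),
                 time_h = rep(c(4, 24), each = length(donors)),
                 rel_change = c(chg[[1]], chg[[2]]),
                 stringsAsFactors = FALSE))
    summarize <- function(tt, ch) {
      if (method == "per_donor") mean(ch) else {
        base <- vapply(donors, function(d)
          sub$level[sub$donor == d & sub$time_h == 0.5], numeric(1))
        lev <- vapply(donors, function(d)
          sub$level[sub$donor == d & sub$time_h == tt], numeric(1))
        (mean(lev) - mean(base)) / mean(base)
      }
    }
    consistent <- function(ch) all(ch > 0) || all(ch < 0)
    data.frame(marker = mk,
               mean_rel_change_4h = summarize(4, chg[[1]]),
               mean_rel_change_24h = summarize(24, chg[[2]]),
               consistent_4h = consistent(chg[[1]]),
               consistent_24h = consistent(chg[[2]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_donor") <- per_donor
  attr(out, "method") <- method
  class(out) <- c("stability_report", "data.frame")
  out
}

#' Deselect pre-analytically unstable markers
#'
#' A marker is removed when the magnitude of its mean relative change exceeds
#' `threshold` at either clotting timepoint; the retained list preserves the
#' report's marker order. Deselected markers are attached as an attribute and
#' flagged in the report.
#'
#' @param report A [relative_change()] report.
#' @param threshold Deselection cutoff on `|mean relative change|`
#'   (default 0.20, separating strong clotting drift from the minor
#'   fluctuations tolerated in stable markers).
#' @return Character vector of retained marker names (input order), with
#'   attribute `"deselected"`.
#' @export
deselect_markers <- function(report, threshold = 0.20) {
  stopifnot(inherits(report, "stability_report"), threshold >= 0)
  drop <- abs(report$mean_rel_change_4h) > threshold |
    abs(report$mean_rel_change_24h) > threshold
  retained <- report$marker[!drop]
  attr(retained, "deselected") <- report$marker[drop]
  retained
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %d markers (method: %s)\n",
              nrow(x), attr(x, "method")))
  df <- as.data.frame(x)
  df$mean_rel_change_4h <- sprintf("%+.1f%%", 100 * df$mean_rel_change_4h)
  df$mean_rel_change_24h <- sprintf("%+.1f%%", 100 * df$mean_rel_change_24h)
  print(df, row.names = FALSE)
  invisible(x)
}
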