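#' TcB band cutoffs
#'
#' The default bands are low = \[0, 0.25\], mid = \[0.375, 0.625\],
#' high = \[0.75, 1\]; samples falling in the gaps are excluded from
#' group-wise analysis. All intervals are closed at both ends, so the printed
#' endpoints belong to their named bands (0.25 is low, 0.375 is mid).
#'
#' @param low,mid,high Length-2 numeric vectors `c(lo, hi)` on `[0, 1]`.
#' @return A named list of the three intervals, validated to be ordered and
#'   non-overlapping.
#' @export
tcb_cutoffs <- function(low = c(0, 0.25), mid = c(0.375, 0.625),
                        high = c(0.75, 1)) {
  bands <- list(low = as.numeric(low), mid = as.numeric(mid),
                high = as.numeric(high))
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (length(b) != 2L || any(!is.finite(b)) || b[1L] > b[2L]) {
      stop(sprintf("invalid %s band: must be c(lo, hi) with lo <= hi", nm),
           call. = FALSE)
    }
  }
  if (bands$low[2L] > bands$mid[1L] || bands$mid[2L] > bands$high[1L]) {
    stop("TcB bands overlap or are out of order (need low <= mid <= high)",
         call. = FALSE)
  }
  structure(bands, class = "tcb_cutoffs")
}

#' Assign samples to TcB bands
#'
#' Each sample gets exactly one label in low < mid < high, or `excluded` when
#' its TcB falls between the bands. Interval membership is closed at both
#' ends; where two bands share an endpoint the lower band wins.
#'
#' @param tcb Data frame from [compute_tcb()] (columns `sample_id`, `tcb`),
#'   or any data frame with those columns.
#' @param cutoffs A [tcb_cutoffs()] object.
#' @return Data frame with `sample_id`, `tcb` and `group` (factor with levels
#'   low, mid, high, excluded). A `counts` attribute carries the per-group
#'   tally; counts sum to the number of samples.
#' @export
assign_tcb_groups <- function(tcb, cutoffs = tcb_cutoffs()) {
  if (!inherits(cutoffs, "tcb_cutoffs")) {
    cutoffs <- do.call(tcb_cutoffs, as.list(cutoffs))
  }
  x <- tcb$tcb
  group <- rep("excluded", length(x))
  for (nm in c("low", "mid", "high")) {
    b <- cutoffs[[nm]]
    hit <- group == "excluded" & x >= b[1L] & x <= b[2L]
    group[hit] <- nm
  }
  out <- data.frame(sample_id = tcb$sample_id, tcb = x,
                    group = factor(group,
                                   levels = c("low", "mid", "high", "excluded")),
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- table(out$group)
  attr(out, "cutoffs") <- cutoffs
  out
}

# internal: samples of one band, with minimum-size guard used by the DE layer
group_samples <- function(groups, name, min_size = 3L, warn = TRUE) {
  ids <- groups$sample_id[groups$group == name]
  if (length(ids) < min_size) {
    if (warn) warning(sprintf("group '%s' has %d sample(s), fewer than %d; skipped",
                              name, length(ids), min_size), call. = FALSE)
    return(NULL)
  }
  ids
}
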