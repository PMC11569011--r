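# Windowed comparison of IMU-derived angles against the optical reference:
# per-activity RMSE over 1-s windows and a mean-absolute-difference (MAD)
# histogram binned by reference angle rounded to the nearest whole degree.

# round half away from zero (the "nearest whole degree" rule)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Average an angle series over non-overlapping windows
#'
#' Windows are anchored at the first sample (or at \code{anchor}); each
#' output value is the mean of the unmasked samples in its window.  A window
#' whose samples are all masked yields a masked output.  A partial trailing
#' window is kept only if its unmasked samples amount to at least half of a
#' full window.
#'
#' @param series an \code{\link{angle_series}}.
#' @param window_s window length in seconds (default 1.0), at least one
#'   sample period.
#' @param anchor window anchor time in seconds (default first sample).
#' @return An \code{\link{angle_series}} with one sample per window, stamped
#'   at the window center.
#' @export
window_average <- function(series, window_s = 1.0, anchor = NULL) {
  stopifnot(inherits(series, "angle_series"))
  t <- series$time_s
  if (is.null(anchor)) anchor <- t[1]
  dt <- if (length(t) > 1) stats::median(diff(t)) else window_s
  if (window_s < dt - 1e-12)
    stop_fmt("window_average: window (%g s) below one sample period", window_s)
  full_n <- max(1, round(window_s / dt))
  idx <- floor((t - anchor) / window_s + 1e-9)
  keep <- idx >= 0
  out_t <- out_a <- numeric(0); out_v <- logical(0)
  for (w in sort(unique(idx[keep]))) {
    in_w <- keep & idx == w
    ok <- in_w & series$valid
    n_in <- sum(in_w)
    partial <- n_in < full_n
    if (partial && sum(ok) < 0.5 * full_n) next
    out_t <- c(out_t, anchor + (w + 0.5) * window_s)
    if (any(ok)) {
      out_a <- c(out_a, mean(series$angle[ok]))
      out_v <- c(out_v, TRUE)
    } else {
      out_a <- c(out_a, NA_real_)
      out_v <- c(out_v, FALSE)
    }
  }
  angle_series(out_t, out_a, out_v, label = attr(series, "label"))
}

#' Per-activity RMSE between an estimate and a reference
#'
#' For each activity segment, both series are restricted to the segment and
#' averaged over non-overlapping windows anchored at the segment start
#' (skipped when \code{sample_wise}); squared differences are pooled per
#' activity label and over the union of all labeled samples, so the overall
#' RMSE squared is the sample-count-weighted mean of the per-activity RMSE
#' squares.
#'
#' @param est,ref aligned \code{\link{angle_series}} (same time base).
#' @param segments an \code{\link{activity_segments}}.
#' @param window_s comparison window in seconds (default 1.0).
#' @param sample_wise compare raw samples instead of window averages.
#' @return Object of class \code{evaluation_report}: list with
#'   \code{by_activity} (data frame \code{label, n, rmse}), \code{overall}
#'   (one-row data frame), \code{settings}.
#' @export
rmse_by_activity <- function(est, ref, segments, window_s = 1.0,
                             sample_wise = FALSE) {
  stopifnot(inherits(est, "angle_series"), inherits(ref, "angle_series"),
            inherits(segments, "activity_segments"))
  if (nrow(est) != nrow(ref) || max(abs(est$time_s - ref$time_s)) > 1e-6)
    stop_fmt("rmse_by_activity: series are not aligned (n_est=%d, n_ref=%d, overlap [%g, %g] vs [%g, %g] s)",
             nrow(est), nrow(ref), min(est$time_s), max(est$time_s),
             min(ref$time_s), max(ref$time_s))
  labels <- unique(segments$label)
  ss <- setNames(numeric(length(labels)), labels)
  nn <- setNames(integer(length(labels)), labels)
  for (i in seq_len(nrow(segments))) {
    lab <- segments$label[i]
    in_seg <- est$time_s >= segments$t_start[i] &
      est$time_s < segments$t_end[i]
    if (!any(in_seg)) next
    e <- angle_series(est$time_s[in_seg], est$angle[in_seg],
                      est$valid[in_seg])
    r <- angle_series(ref$time_s[in_seg], ref$angle[in_seg],
                      ref$valid[in_seg])
    if (!sample_wise) {
      e <- window_average(e, window_s, anchor = segments$t_start[i])
      r <- window_average(r, window_s, anchor = segments$t_start[i])
      n <- min(nrow(e), nrow(r))
      ok <- e$valid[seq_len(n)] & r$valid[seq_len(n)]
      d <- e$angle[seq_len(n)][ok] - r$angle[seq_len(n)][ok]
    } else {
      ok <- e$valid & r$valid
      d <- e$angle[ok] - r$angle[ok]
    }
    ss[lab] <- ss[lab] + sum(d^2)
    nn[lab] <- nn[lab] + length(d)
  }
  by_act <- data.frame(label = labels, n = as.integer(nn),
                       rmse = ifelse(nn > 0, sqrt(ss / pmax(nn, 1)), NA_real_))
  overall <- data.frame(label = "all", n = sum(nn),
                        rmse = if (sum(nn) > 0) sqrt(sum(ss) / sum(nn))
                               else NA_real_)
  structure(list(by_activity = by_act, overall = overall,
                 settings = list(window_s = window_s,
                                 sample_wise = sample_wise)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s comparison\n",
              if (x$settings$sample_wise) "sample-wise"
              else sprintf("%.1f-s window", x$settings$window_s)))
  d <- rbind(x$by_activity, x$overall)
  for (i in seq_len(nrow(d)))
    cat(sprintf("  %-24s n=%5d  RMSE = %s\n", d$label[i], d$n[i],
                if (is.na(d$rmse[i])) "undefined (no samples)"
                else sprintf("%.3f deg", d$rmse[i])))
  invisible(x)
}

#' Mean-absolute-difference histogram by reference angle
#'
#' Each compared sample is assigned to the bin of its reference angle
#' rounded to the nearest whole degree (half away from zero); each bin
#' reports the mean absolute estimator-minus-reference difference and the
#' sample count.  Bin counts partition the compared samples.
#'
#' @param est,ref aligned \code{\link{angle_series}}.
#' @return Data frame with columns \code{ref_deg}, \code{mad}, \code{n},
#'   class \code{mad_histogram}.
#' @export
mad_histogram <- function(est, ref) {
  stopifnot(inherits(est, "angle_series"), inherits(ref, "angle_series"))
  if (nrow(est) != nrow(ref))
    stop_fmt("mad_histogram: series lengths differ")
  ok <- est$valid & ref$valid
  bin <- round_half_away(ref$angle[ok])
  ad <- abs(est$angle[ok] - ref$angle[ok])
  bins <- sort(unique(bin))
  structure(data.frame(
    ref_deg = as.integer(bins),
    mad = vapply(bins, function(b) mean(ad[bin == b]), numeric(1)),
    n = vapply(bins, function(b) sum(bin == b), integer(1))),
    class = c("mad_histogram", "data.frame"))
}

#' Write an evaluation report as TSV and readable text
#'
#' @param report an \code{\link{rmse_by_activity}} result.
#' @param path_tsv,path_txt output file paths (either may be NULL to skip).
#' @param mad optional \code{\link{mad_histogram}} appended to both outputs.
#' @return \code{invisible(NULL)}.
#' @export
write_evaluation_report <- function(report, path_tsv = NULL, path_txt = NULL,
                                    mad = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  d <- rbind(report$by_activity, report$overall)
  if (!is.null(path_tsv)) {
    write.table(d, path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(mad))
      suppressWarnings(write.table(mad, path_tsv, sep = "\t", quote = FALSE,
                                   row.names = FALSE, append = TRUE))
  }
  if (!is.null(path_txt)) {
    con <- file(path_txt, "w"); on.exit(close(con))
    sink(con); print(report); if (!is.null(mad)) print(mad); sink()
  }
  invisible(NULL)
}
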