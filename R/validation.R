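# Agreement analysis between detected and reference gait events.

#' Match detected events to reference events
#'
#' Greedy nearest-time matching within each label: the globally closest
#' detected/reference pair is matched first, each event is used at most
#' once, and pairs farther apart than `max_gap_ms` are never formed.
#'
#' @param detected,reference [gait_events()] data frames.
#' @param max_gap_ms maximum |time difference| for a valid pair (ms,
#'   default 100).
#' @return list with `pairs` (data frame: `label`, `time_detected`,
#'   `time_reference`, `diff` = detected - reference in seconds),
#'   `unmatched_detected` and `unmatched_reference`.
#' @export
match_events <- function(detected, reference, max_gap_ms = 100) {
  gap <- max_gap_ms / 1000
  pairs <- list()
  un_det <- list()
  un_ref <- list()
  for (lab in unique(c(detected$label, reference$label))) {
    d <- detected[detected$label == lab, , drop = FALSE]
    r <- reference[reference$label == lab, , drop = FALSE]
    if (nrow(d) && nrow(r)) {
      dm <- abs(outer(d$time, r$time, "-"))
      dm[dm > gap] <- Inf
      used_d <- logical(nrow(d))
      used_r <- logical(nrow(r))
      repeat {
        k <- which.min(dm)
        if (!length(k) || !is.finite(dm[k])) break
        i <- (k - 1L) %% nrow(d) + 1L
        j <- (k - 1L) %/% nrow(d) + 1L
        pairs[[length(pairs) + 1L]] <- data.frame(
          label = lab, time_detected = d$time[i],
          time_reference = r$time[j], diff = d$time[i] - r$time[j])
        used_d[i] <- TRUE
        used_r[j] <- TRUE
        dm[i, ] <- Inf
        dm[, j] <- Inf
      }
    } else {
      used_d <- logical(nrow(d))
      used_r <- logical(nrow(r))
    }
    if (any(!used_d)) un_det[[lab]] <- d[!used_d, , drop = FALSE]
    if (any(!used_r)) un_ref[[lab]] <- r[!used_r, , drop = FALSE]
  }
  pairs_df <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(label = character(), time_detected = numeric(),
               time_reference = numeric(), diff = numeric())
  pairs_df <- pairs_df[order(pairs_df$time_reference), , drop = FALSE]
  rownames(pairs_df) <- NULL
  list(pairs = pairs_df,
       unmatched_detected = if (length(un_det)) do.call(rbind, un_det) else NULL,
       unmatched_reference = if (length(un_ref)) do.call(rbind, un_ref) else NULL)
}

#' Bland-Altman agreement statistics
#'
#' Mean and SD (n-1 denominator) of the pairwise differences, 95 percent
#' limits of agreement at mean +/- 1.96 SD, and the count/fraction of pairs
#' falling outside the limits.
#'
#' @param diffs numeric vector of pairwise differences (s), `n >= 2`.
#' @return object of class `bland_altman` with fields `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`, `n`, `outside_count`,
#'   `outside_fraction`.
#' @export
bland_altman <- function(diffs) {
  n <- length(diffs)
  if (n < 2L) stop("Bland-Altman analysis needs at least 2 differences",
                   call. = FALSE)
  m <- mean(diffs)
  s <- stats::sd(diffs)
  lo <- m - 1.96 * s
  hi <- m + 1.96 * s
  outside <- sum(diffs < lo | diffs > hi)
  structure(list(mean_diff = m, sd_diff = s, loa_low = lo, loa_high = hi,
                 n = n, outside_count = outside,
                 outside_fraction = outside / n),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> n=%d mean=%.4g s sd=%.4g s LoA [%.4g, %.4g] s outside %d (%.1f%%)\n",
    x$n, x$mean_diff, x$sd_diff, x$loa_low, x$loa_high, x$outside_count,
    100 * x$outside_fraction))
  invisible(x)
}

#' Per-label timing-error summary
#'
#' @param pairs the `pairs` data frame from [match_events()].
#' @return data frame with one row per label: `n`, `mean_diff`, `sd_diff`,
#'   `median_diff`, `mae` (all in seconds).
#' @export
summarize_errors <- function(pairs) {
  labs <- intersect(c("HS", "TS", "HO", "TO"), unique(pairs$label))
  if (!length(labs)) {
    warning("no matched pairs to summarize")
    return(data.frame(label = character(), n = integer(),
                      mean_diff = numeric(), sd_diff = numeric(),
                      median_diff = numeric(), mae = numeric()))
  }
  do.call(rbind, lapply(labs, function(lab) {
    d <- pairs$diff[pairs$label == lab]
    data.frame(label = lab, n = length(d), mean_diff = mean(d),
               sd_diff = if (length(d) > 1) stats::sd(d) else 0,
               median_diff = stats::median(d), mae = mean(abs(d)))
  }))
}

#' Write a validation report as CSV
#'
#' One row per label with the error summary and Bland-Altman fields, plus an
#' `all` row pooling every matched pair.
#'
#' @param detected,reference [gait_events()] data frames.
#' @param path output CSV path.
#' @param max_gap_ms matching gap passed to [match_events()].
#' @return (invisibly) the report data frame.
#' @export
write_validation_report <- function(detected, reference, path,
                                    max_gap_ms = 100) {
  m <- match_events(detected, reference, max_gap_ms)
  summ <- summarize_errors(m$pairs)
  rows <- lapply(seq_len(nrow(summ)), function(i) {
    d <- m$pairs$diff[m$pairs$label == summ$label[i]]
    ba <- if (length(d) >= 2) bland_altman(d) else NULL
    cbind(summ[i, , drop = FALSE],
          loa_low = if (is.null(ba)) NA_real_ else ba$loa_low,
          loa_high = if (is.null(ba)) NA_real_ else ba$loa_high,
          outside_count = if (is.null(ba)) NA_integer_ else ba$outside_count,
          outside_fraction = if (is.null(ba)) NA_real_ else ba$outside_fraction)
  })
  if (nrow(m$pairs) >= 2) {
    ba <- bland_altman(m$pairs$diff)
    rows[[length(rows) + 1L]] <- data.frame(
      label = "all", n = ba$n, mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
      median_diff = stats::median(m$pairs$diff), mae = mean(abs(m$pairs$diff)),
      loa_low = ba$loa_low, loa_high = ba$loa_high,
      outside_count = ba$outside_count, outside_fraction = ba$outside_fraction)
  }
  report <- do.call(rbind, rows)
  utils::write.csv(report, path, row.names = FALSE)
  invisible(report)
}
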