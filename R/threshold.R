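# Family-specific allergenicity threshold on the mismatch-tolerant epitope
# count (#positive IEDB-2M): sequences with at least T mapped epitopes are
# called allergenic. The threshold scan maximizes balanced accuracy over a
# labelled panel; group separation is tested with Welch's unequal-variance
# t-test from summary statistics.

#' Classify a sequence by its epitope count
#'
#' @param count Integer epitope count(s) (e.g. `n_positive_2m`).
#' @param threshold Integer threshold `T`; the boundary is inclusive
#'   (`count >= T` is allergenic).
#' @return Character vector, `"allergenic"` or `"less_non_allergenic"`.
#' @export
classify_by_count <- function(count, threshold = 4L) {
  stopifnot(threshold >= 0L)
  ifelse(count >= threshold, "allergenic", "less_non_allergenic")
}

#' Scan for the count threshold that best separates the classes
#'
#' Tries every integer threshold from 0 to `max(count) + 1`, classifying
#' `count >= T` as allergenic, and returns the threshold maximizing balanced
#' accuracy (mean of sensitivity on the allergenic class and specificity on
#' the less/non-allergenic class). Ties are broken by the smallest
#' threshold, so results are deterministic.
#'
#' @param data A tibble with columns `count` (integer >= 0) and `label`
#'   (`"allergenic"` / `"less_non_allergenic"`); both labels must occur.
#' @return A list with `threshold`, `balanced_accuracy` and
#'   `per_class_accuracy` (named: sensitivity on allergenic, specificity on
#'   less/non-allergenic).
#' @export
scan_threshold <- function(data) {
  stopifnot(all(c("count", "label") %in% names(data)), all(data$count >= 0))
  is_pos <- data$label == "allergenic"
  is_neg <- data$label == "less_non_allergenic"
  if (!any(is_pos) || !any(is_neg)) {
    stop("both classes must be present to scan a threshold", call. = FALSE)
  }
  if (!all(is_pos | is_neg)) {
    stop("unknown label(s): ",
         paste(unique(data$label[!(is_pos | is_neg)]), collapse = ", "),
         call. = FALSE)
  }
  candidates <- 0:(max(data$count) + 1L)
  best <- NULL
  for (t in candidates) {
    sens <- mean(data$count[is_pos] >= t)
    spec <- mean(data$count[is_neg] < t)
    ba <- (sens + spec) / 2
    if (is.null(best) || ba > best$balanced_accuracy + 1e-12) {
      best <- list(threshold = t, balanced_accuracy = ba,
                   per_class_accuracy = c(allergenic = sens,
                                          less_non_allergenic = spec))
    }
  }
  best
}

#' Capture rate of a threshold over a set of counts
#'
#' What fraction of the sequences reach at least `threshold` mapped
#' epitopes — e.g. the share of compiled parvalbumins captured by the
#' family-specific threshold.
#'
#' @param counts Integer vector of epitope counts.
#' @param threshold Integer threshold.
#' @return A list with `n_captured`, `n_total` and `percent` (whole
#'   percent, rounded half-up).
#' @export
capture_rate <- function(counts, threshold = 4L) {
  if (length(counts) == 0L) stop("no counts supplied", call. = FALSE)
  n_cap <- sum(counts >= threshold)
  list(n_captured = n_cap, n_total = length(counts),
       percent = round_half_up(100 * n_cap / length(counts), 0L))
}

#' Welch's two-sample t-test from summary statistics
#'
#' Unequal-variance t-test computed from group means, SDs and sizes:
#' `t = (mean1 - mean2) / sqrt(sd1^2/n1 + sd2^2/n2)`, with
#' Welch-Satterthwaite degrees of freedom and a two-tailed p-value from the
#' t distribution.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return A list with `t`, `df` and `p_two_tailed`.
#' @export
welch_t_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2L || n2 < 2L) {
    stop("both groups need at least two observations", call. = FALSE)
  }
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0", call. = FALSE)
  if (sd1 == 0 && sd2 == 0) {
    stop("degenerate variances: both group SDs are zero", call. = FALSE)
  }
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  se <- sqrt(v1 + v2)
  t_stat <- (mean1 - mean2) / se
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t_stat), df = df)
  list(t = t_stat, df = df, p_two_tailed = p)
}

#' Threshold report for a labelled count panel
#'
#' Convenience wrapper combining the scan (or a fixed threshold), the
#' capture rate on the allergenic class, and Welch's t-test between the two
#' classes' counts.
#'
#' @param data A tibble with `sequence_id`, `count`, `label` (see
#'   [scan_threshold()]).
#' @param threshold `"scan"` (default) to optimize, or a fixed integer.
#' @return A list with `threshold`, `balanced_accuracy`,
#'   `per_class_accuracy`, `capture` (over allergenic counts) and `welch`.
#' @export
threshold_report <- function(data, threshold = "scan") {
  if (identical(threshold, "scan")) {
    scan <- scan_threshold(data)
  } else {
    t_fix <- as.integer(threshold)
    is_pos <- data$label == "allergenic"
    sens <- mean(data$count[is_pos] >= t_fix)
    spec <- mean(data$count[!is_pos] < t_fix)
    scan <- list(threshold = t_fix, balanced_accuracy = (sens + spec) / 2,
                 per_class_accuracy = c(allergenic = sens,
                                        less_non_allergenic = spec))
  }
  pos <- data$count[data$label == "allergenic"]
  neg <- data$count[data$label == "less_non_allergenic"]
  welch <- welch_t_test(mean(pos), stats::sd(pos), length(pos),
                        mean(neg), stats::sd(neg), length(neg))
  c(scan, list(capture = capture_rate(pos, scan$threshold), welch = welch))
}
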