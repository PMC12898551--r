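#' Side difference of a caliber proportion
#'
#' Signed difference (reconstructed minus contralateral) of one class
#' proportion for one case; lies in \[-1, 1\].
#'
#' @param proportions A [caliber_proportions()] data.frame holding both sides
#'   of one case.
#' @param class One of `"small"`, `"medium"`, `"large"`.
#' @return The signed difference.
#' @export
side_difference <- function(proportions, class = c("small", "medium", "large")) {
  class <- match.arg(class)
  r <- proportions[proportions$side == "reconstructed", class]
  c <- proportions[proportions$side == "contralateral", class]
  if (length(r) != 1 || length(c) != 1)
    stop("proportions must contain exactly one row per side")
  r - c
}

#' Fit an interval trend line
#'
#' Ordinary least-squares fit of a proportion difference against the
#' postoperative interval. The slope's sign is the scientifically meaningful
#' output (a remodeling tendency), not its magnitude.
#'
#' @param points A data.frame with columns `interval_months` and `difference`
#'   (one point per case).
#' @return An object of class `trend_result` with `slope` (difference per
#'   month), `intercept` and `n`.
#' @export
fit_trend <- function(points) {
  if (nrow(points) < 2) stop("at least 2 points are required for a trend")
  if (length(unique(points$interval_months)) < 2)
    stop("undefined slope: all intervals identical")
  fit <- lm(difference ~ interval_months, data = points)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 n = nrow(points)),
            class = "trend_result")
}

#' Descriptive summary of a numeric variable
#'
#' Reports either mean with sample standard deviation (n - 1 denominator) or
#' median (interpolated for even n) with range, the two conventions used for
#' cohort descriptors.
#'
#' @param values Numeric vector, n >= 1.
#' @param mode `"median_range"` or `"mean_sd"`.
#' @param label Optional variable label.
#' @return An object of class `summary_stats`.
#' @export
summarize_values <- function(values, mode = c("median_range", "mean_sd"),
                             label = "") {
  mode <- match.arg(mode)
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values to summarise")
  if (mode == "mean_sd") {
    structure(list(label = label, mode = mode, center = mean(values),
                   spread = sd(values), n = length(values)),
              class = "summary_stats")
  } else {
    structure(list(label = label, mode = mode, center = median(values),
                   min = min(values), max = max(values), n = length(values)),
              class = "summary_stats")
  }
}

#' @export
print.summary_stats <- function(x, ...) {
  if (x$mode == "mean_sd")
    cat(sprintf("%s: %.3g +/- %.3g (n = %d)\n", x$label, x$center, x$spread, x$n))
  else
    cat(sprintf("%s: median %.4g (range %.4g-%.4g, n = %d)\n",
                x$label, x$center, x$min, x$max, x$n))
  invisible(x)
}

#' Assemble the study-level report
#'
#' Aggregates per-case results into the study report: depth-profile pairs for
#' QC-passed cases, caliber proportions for every case with diameter data,
#' per-case side differences, one trend fit per caliber class (an undefined
#' trend is reported, not skipped), descriptive summaries, and the QC
#' exclusion list.
#'
#' @param cases List of case records, each a list with `case_id`,
#'   `interval_months`, optional `profiles` (a [side_profiles()] result or
#'   `NULL` when QC-excluded), `proportions` (a [caliber_proportions()]
#'   data.frame), and `qc` (per-side verdicts).
#' @return An object of class `study_report`: data.frames `profiles`,
#'   `proportions`, `differences`, `trends`, `summary`, `qc`.
#' @export
build_report <- function(cases) {
  if (!length(cases)) stop("at least one case is required")
  scheme <- depth_layers()

  profiles <- do.call(rbind, lapply(cases, function(cs) {
    if (is.null(cs$profiles)) return(NULL)
    do.call(rbind, lapply(c("reconstructed", "contralateral"), function(s) {
      p <- cs$profiles[[s]]
      data.frame(case = cs$case_id, side = s,
                 layer = scheme$layer, lo_mm = scheme$lo_mm, hi_mm = scheme$hi_mm,
                 density_pct = p$density_pct)
    }))
  }))

  proportions <- do.call(rbind, lapply(cases, function(cs) {
    if (is.null(cs$proportions)) return(NULL)
    cbind(cs$proportions, interval_months = cs$interval_months)
  }))

  differences <- do.call(rbind, lapply(cases, function(cs) {
    if (is.null(cs$proportions)) return(NULL)
    do.call(rbind, lapply(c("small", "medium", "large"), function(cl) {
      data.frame(case = cs$case_id, interval_months = cs$interval_months,
                 class = cl,
                 difference = side_difference(cs$proportions, cl))
    }))
  }))

  trends <- do.call(rbind, lapply(c("small", "medium", "large"), function(cl) {
    pts <- differences[differences$class == cl, , drop = FALSE]
    tr <- tryCatch(fit_trend(pts), error = function(e) NULL)
    if (is.null(tr))
      data.frame(class = cl, slope = NA_real_, intercept = NA_real_,
                 n = if (is.null(pts)) 0L else nrow(pts), status = "undefined")
    else
      data.frame(class = cl, slope = tr$slope, intercept = tr$intercept,
                 n = tr$n, status = "ok")
  }))

  intervals <- vapply(cases, function(cs) cs$interval_months, numeric(1))
  iv <- summarize_values(intervals, "median_range", "interval_months")
  summary <- data.frame(
    label = c("n_cases", "n_density_cases", "interval_median_months",
              "interval_min_months", "interval_max_months"),
    value = c(length(cases),
              sum(vapply(cases, function(cs) !is.null(cs$profiles), logical(1))),
              iv$center, iv$min, iv$max))

  qc <- do.call(rbind, lapply(cases, function(cs) {
    if (is.null(cs$qc)) return(NULL)
    do.call(rbind, lapply(names(cs$qc), function(s) {
      data.frame(case = cs$case_id, side = s,
                 contact_fraction = cs$qc[[s]]$contact_fraction,
                 verdict = cs$qc[[s]]$verdict)
    }))
  }))

  structure(list(profiles = profiles, proportions = proportions,
                 differences = differences, trends = trends,
                 summary = summary, qc = qc),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  %d case(s) with caliber data, %d with depth profiles\n",
              if (is.null(x$proportions)) 0L else length(unique(x$proportions$case)),
              if (is.null(x$profiles)) 0L else length(unique(x$profiles$case))))
  print(x$trends, row.names = FALSE)
  invisible(x)
}
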