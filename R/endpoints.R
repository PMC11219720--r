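#' Extract per-subject vitals at the five named timepoints
#'
#' The five analysis timepoints are the start of the experiment (0 min), the
#' end of controlled hemorrhage (60), the start of resuscitation phase 2
#' (120), the time at which the 1 MHz impedance recovers its initial value
#' (group-level, from \code{\link{recovery_time}}), and the end of fluid
#' infusion (180). Per subject and variable, the measurement nearest each
#' named minute is taken (ties resolved to the earlier reading); missing MAP
#' (undetectable waveform) propagates as missing.
#'
#' @param vitals Data frame with columns \code{subject_id}, \code{t_min},
#'   \code{pr}, \code{map}, \code{sv}, \code{svv}, covering [0, 180].
#' @param protocol A \code{bia_protocol} (for the vitals interval).
#' @param recovery_minute Recovery time in minutes, or \code{NA} if the
#'   impedance never recovered (the endpoint is then flagged absent).
#' @return Data frame of class \code{endpoint_set}: columns
#'   \code{subject_id}, \code{variable} (PR/MAP/SV/SVV), \code{timepoint},
#'   \code{t_min}, \code{value}; attribute \code{timepoint_minutes}.
#' @export
extract_endpoints <- function(vitals, protocol, recovery_minute = NA_real_) {
  validate_protocol(protocol)
  stopifnot(all(c("subject_id", "t_min", "pr", "map", "sv", "svv")
                %in% names(vitals)))
  tp <- c(start = 0, end_hemorrhage = 60, start_resus2 = 120,
          recovery_1M = recovery_minute, end_infusion = 180)
  vars <- c(PR = "pr", MAP = "map", SV = "sv", SVV = "svv")
  rows <- list()
  for (s in unique(vitals$subject_id)) {
    vs <- vitals[vitals$subject_id == s, ]
    for (nm in names(tp)) {
      if (is.na(tp[[nm]])) next
      d <- abs(vs$t_min - tp[[nm]])
      if (min(d) > protocol$vitals_interval) {
        abort(sprintf("no measurement within %g min of timepoint '%s'",
                      protocol$vitals_interval, nm), "hemobia_missing_timepoint")
      }
      i <- which(d == min(d))[1]  # ties -> earlier reading
      for (v in names(vars)) {
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = s, variable = v, timepoint = nm,
          t_min = vs$t_min[i], value = vs[[vars[[v]]]][i])
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "timepoint_minutes") <- tp
  class(out) <- c("endpoint_set", "data.frame")
  out
}

#' Jarque-Bera test of normality
#'
#' Computes \code{JB = n/6 (S^2 + (K - 3)^2 / 4)} from the sample skewness S
#' and kurtosis K (population-moment convention), with p-value from the
#' chi-square(2) reference distribution.
#'
#' @param values Numeric vector, n >= 4, non-constant.
#' @return List with \code{statistic}, \code{p_value}, \code{n}.
#' @export
jarque_bera <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 4) abort("need at least 4 values", "hemobia_bad_series")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 <= 0) abort("zero variance", "hemobia_zero_variance")
  s <- mean((values - m)^3) / m2^1.5
  k <- mean((values - m)^4) / m2^2
  jb <- n / 6 * (s^2 + (k - 3)^2 / 4)
  list(statistic = jb,
       p_value = stats::pchisq(jb, df = 2, lower.tail = FALSE),
       n = n)
}

#' Two-sample t-test
#'
#' Pooled-variance (Student) independent two-sample t-test by default, with
#' a Welch option.
#'
#' @param values_a,values_b Numeric vectors, each n >= 2 after removing
#'   missing values.
#' @param var_equal Pooled variance if TRUE (default), Welch otherwise.
#' @return List with \code{statistic}, \code{p_value}, \code{n1}, \code{n2}.
#' @export
ttest_two <- function(values_a, values_b, var_equal = TRUE) {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort("each sample needs at least 2 finite values", "hemobia_bad_series")
  }
  ht <- stats::t.test(values_a, values_b, var.equal = var_equal)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n1 = length(values_a), n2 = length(values_b))
}

#' Percent change between two values
#'
#' \code{(v_start - v_end) / v_start * 100}: positive for decreases,
#' matching the convention of reporting a fall from start to end as a
#' positive percentage.
#'
#' @param v_start Starting value (non-zero).
#' @param v_end Ending value.
#' @return Percent change (numeric).
#' @export
percent_change <- function(v_start, v_end) {
  if (any(v_start == 0)) abort("v_start must be non-zero", "hemobia_bad_series")
  (v_start - v_end) / v_start * 100
}

#' Stroke-volume fluid-responsiveness rule
#'
#' A fluid bolus is deemed effective (the subject "fluid responsive") when
#' stroke volume rises by at least 10\%.
#'
#' @param sv_before Stroke volume before the bolus (> 0).
#' @param sv_after Stroke volume after the bolus.
#' @return List with \code{delta_pct} (positive for increases) and
#'   \code{responsive} (TRUE iff delta_pct >= 10).
#' @export
delta_sv_responsiveness <- function(sv_before, sv_after) {
  if (sv_before <= 0) {
    abort("sv_before must be positive", "hemobia_bad_series")
  }
  delta <- (sv_after - sv_before) / sv_before * 100
  list(delta_pct = delta, responsive = delta >= 10)
}

#' Pointwise endpoint comparisons and restoration flags
#'
#' For each variable, compares adjacent named timepoints and start vs end of
#' infusion with \code{\link{ttest_two}}, reports the percent change of the
#' group means, and flags the variable "restored" when the start vs
#' end-of-infusion difference is non-significant at \code{alpha} -- i.e. the
#' infusion returned the variable to its pre-hemorrhage level.
#'
#' @param endpoints An \code{\link{extract_endpoints}} result.
#' @param alpha Significance level (default 0.05).
#' @param var_equal,paired Test options; the default follows the pointwise
#'   independent-test convention even though timepoints share subjects (a
#'   paired alternative is available).
#' @param adjust Multiple-testing adjustment passed to
#'   \code{\link[stats]{p.adjust}} ("none" by default).
#' @return List of class \code{endpoint_report}: \code{comparisons} (data
#'   frame with variable, pair, t, p, percent_change, significant) and
#'   \code{restored} (named logical per variable).
#' @export
endpoint_comparison_report <- function(endpoints, alpha = 0.05,
                                       var_equal = TRUE, paired = FALSE,
                                       adjust = "none") {
  stopifnot(inherits(endpoints, "endpoint_set"))
  tps <- intersect(c("start", "end_hemorrhage", "start_resus2",
                     "recovery_1M", "end_infusion"),
                   unique(endpoints$timepoint))
  pairs <- cbind(tps[-length(tps)], tps[-1])
  if (all(c("start", "end_infusion") %in% tps)) {
    pairs <- rbind(pairs, c("start", "end_infusion"))
  }
  vals <- function(v, tp) {
    d <- endpoints[endpoints$variable == v & endpoints$timepoint == tp, ]
    d <- d[order(d$subject_id), ]
    d$value
  }
  vars <- intersect(c("PR", "MAP", "SV", "SVV"), unique(endpoints$variable))
  rows <- list()
  for (v in vars) {
    for (r in seq_len(nrow(pairs))) {
      a <- vals(v, pairs[r, 1]); b2 <- vals(v, pairs[r, 2])
      if (paired) {
        ok <- is.finite(a) & is.finite(b2)
        a <- a[ok]; b2 <- b2[ok]
      }
      tt <- tryCatch({
        if (paired) {
          ht <- stats::t.test(a, b2, paired = TRUE)
          list(statistic = unname(ht$statistic), p_value = ht$p.value)
        } else {
          ttest_two(a, b2, var_equal = var_equal)
        }
      }, error = function(e) list(statistic = NA_real_, p_value = NA_real_))
      pc <- if (mean(a, na.rm = TRUE) != 0) {
        percent_change(mean(a, na.rm = TRUE), mean(b2, na.rm = TRUE))
      } else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, pair = paste(pairs[r, 1], pairs[r, 2], sep = "-"),
        t = tt$statistic, p = tt$p_value, percent_change = pc)
    }
  }
  cmp <- do.call(rbind, rows)
  cmp$p_adj <- stats::p.adjust(cmp$p, method = adjust)
  cmp$significant <- !is.na(cmp$p_adj) & cmp$p_adj < alpha
  restored <- vapply(vars, function(v) {
    row <- cmp[cmp$variable == v & cmp$pair == "start-end_infusion", ]
    nrow(row) == 1 && !is.na(row$p_adj) && row$p_adj >= alpha
  }, TRUE)
  structure(list(comparisons = cmp, restored = restored, alpha = alpha),
            class = "endpoint_report")
}

#' @export
print.endpoint_report <- function(x, ...) {
  cat("Endpoint comparisons (alpha =", x$alpha, ")\n")
  print(x$comparisons, row.names = FALSE, digits = 4)
  cat("Restored at end of infusion:\n")
  for (v in names(x$restored)) {
    cat(sprintf("  %-4s %s\n", v, if (x$restored[[v]]) "yes" else "no"))
  }
  invisible(x)
}
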