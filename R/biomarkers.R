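# Action-potential biomarkers and abnormality detection.

#' Compute action-potential biomarkers from a voltage trace
#'
#' Biomarkers follow standard cellular-electrophysiology conventions:
#' \itemize{
#'   \item \code{rest_v}: voltage at the start of the pace (pre-stimulus);
#'   \item \code{peak_v}: maximum voltage; \code{amplitude} = peak - rest;
#'   \item \code{dvdt_max}: maximum forward-difference upstroke velocity;
#'   \item \code{apd90}/\code{apd50}: time from the instant of maximum
#'     upstroke velocity to the first subsequent downward crossing of
#'     \eqn{V_{thresh}(p) = peak - (p/100) \cdot amplitude}, with linear
#'     interpolation between samples.  \code{NA} (absent, not zero) when the
#'     crossing never occurs within the trace.
#' }
#'
#' @param trace An \code{ap_trace} (or a list with \code{times} and
#'   \code{voltages}) with at least 3 samples.
#' @param percents Repolarisation levels to report; default \code{c(50, 90)}.
#' @return An object of class \code{ap_biomarkers}.
#' @export
#' @examples
#' t <- seq(0, 500, by = 0.1)
#' v <- ifelse(t < 10, -85, pmax(-85, 15 - (t - 10) * 0.5))
#' compute_biomarkers(list(times = t, voltages = v))
compute_biomarkers <- function(trace, percents = c(50, 90)) {
  tm <- trace$times
  v <- trace$voltages
  if (length(tm) < 3L || length(v) != length(tm))
    stop("trace must contain at least 3 samples", call. = FALSE)
  if (any(!is.finite(v)))
    stop("trace voltages must be finite", call. = FALSE)
  rest_v <- v[1]
  peak_v <- max(v)
  amplitude <- peak_v - rest_v
  dv <- diff(v) / diff(tm)
  i_up <- which.max(dv)
  dvdt_max <- dv[i_up]
  t_up <- tm[i_up]

  apd <- function(p) {
    thresh <- peak_v - (p / 100) * amplitude
    # first downward crossing at or after the upstroke
    idx <- seq(i_up, length(v) - 1L)
    down <- idx[v[idx] >= thresh & v[idx + 1L] < thresh]
    if (length(down) == 0L) return(NA_real_)
    i <- down[1]
    frac <- (v[i] - thresh) / (v[i] - v[i + 1L])
    t_cross <- tm[i] + frac * (tm[i + 1L] - tm[i])
    t_cross - t_up
  }
  apds <- vapply(sort(percents), apd, numeric(1))
  names(apds) <- paste0("apd", sort(percents))
  structure(c(as.list(apds),
              list(peak_v = peak_v, rest_v = rest_v, dvdt_max = dvdt_max,
                   amplitude = amplitude)),
            class = "ap_biomarkers")
}

#' @export
print.ap_biomarkers <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "absent" else sprintf("%.2f", v)
  cat(sprintf("APD90 %s ms, APD50 %s ms, peak %.1f mV, rest %.1f mV, max dV/dt %.1f mV/ms\n",
              fmt(x$apd90), fmt(x$apd50), x$peak_v, x$rest_v, x$dvdt_max))
  invisible(x)
}

#' Detect abnormal action-potential behaviour
#'
#' Flags the pathological behaviours a safety screen must surface:
#' \describe{
#'   \item{ALTERNANS}{the final two paces' APD90 differ by more than
#'     \code{alternans_tol} ms (beat-to-beat alternation);}
#'   \item{DEPOLARISATION_FAILURE}{the peak voltage never reaches
#'     \code{depol_threshold} (no action potential elicited);}
#'   \item{REPOLARISATION_FAILURE}{an action potential was elicited but the
#'     90\% repolarisation level is never reached within the pace.}
#' }
#'
#' @param last Biomarkers of the final pace ([compute_biomarkers()]).
#' @param previous Biomarkers of the preceding pace, or \code{NULL}.
#' @param last_trace The final pace's trace (quoted in message details).
#' @param alternans_tol APD90 difference threshold in ms (default 1).
#' @param depol_threshold Peak-voltage threshold in mV (default 0).
#' @return List of abnormality records (possibly empty), each with
#'   \code{code} and \code{detail}.
#' @export
detect_abnormalities <- function(last, previous = NULL, last_trace = NULL,
                                 alternans_tol = 1, depol_threshold = 0) {
  stopifnot(inherits(last, "ap_biomarkers"))
  msgs <- list()
  add <- function(code, detail)
    c(msgs, list(structure(list(code = code, detail = detail),
                           class = "ap_abnormality")))
  if (!is.null(previous) && !is.na(last$apd90) && !is.na(previous$apd90)) {
    d <- abs(last$apd90 - previous$apd90)
    if (d > alternans_tol)
      msgs <- add("ALTERNANS",
                  sprintf("APD90 alternates between %.2f and %.2f ms (|diff| %.2f > %g ms)",
                          previous$apd90, last$apd90, d, alternans_tol))
  }
  if (last$peak_v < depol_threshold) {
    msgs <- add("DEPOLARISATION_FAILURE",
                sprintf("peak voltage %.1f mV never reached %g mV",
                        last$peak_v, depol_threshold))
  } else if (is.na(last$apd90)) {
    msgs <- add("REPOLARISATION_FAILURE",
                sprintf("voltage never recovered to the 90%% repolarisation level (end of pace at %.1f mV)",
                        if (!is.null(last_trace))
                          last_trace$voltages[length(last_trace$voltages)]
                        else last$peak_v))
  } else if (!is.null(previous) && is.na(previous$apd90) &&
             previous$peak_v >= depol_threshold) {
    # 2:1-like rhythms repolarise only on alternate paces; the failing pace
    # is then the retained *previous* one and must not pass silently
    msgs <- add("REPOLARISATION_FAILURE",
                sprintf("the preceding pace never recovered to the 90%% repolarisation level (next pace started at %.1f mV)",
                        last$rest_v))
  }
  msgs
}

#' @export
print.ap_abnormality <- function(x, ...) {
  cat(x$code, "-", x$detail, "\n")
  invisible(x)
}

# render a list of abnormality records as a single CSV-safe string
format_abnormalities <- function(msgs) {
  if (length(msgs) == 0L) return("")
  paste(vapply(msgs, function(m) paste0(m$code, ": ", m$detail),
               character(1)), collapse = " | ")
}
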