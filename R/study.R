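# Study orchestration: control pace plus concentration sweep, percent-change
# summary, abnormality messages and CSV export.

#' Concentration range for a sweep
#'
#' @param low,high Range bounds in micromolar; \code{low > 0} (a control at
#'   0 uM is always added separately) and \code{high >= low}.
#' @param count Number of test concentrations (>= 1).
#' @param log_spaced Space concentrations evenly in log10 (default) or
#'   linearly.
#' @return An object of class \code{ap_conc_range}.
#' @export
#' @examples
#' concentration_grid(conc_range(0.1, 100, 4))   # 0, 0.1, 1, 10, 100
conc_range <- function(low, high, count, log_spaced = TRUE) {
  if (!is.numeric(low) || !is.numeric(high) || !is.finite(low) ||
      !is.finite(high))
    stop("low and high must be finite concentrations (uM)", call. = FALSE)
  if (log_spaced && low <= 0)
    stop("low must be > 0 for log spacing", call. = FALSE)
  if (!log_spaced && low < 0)
    stop("low must be >= 0", call. = FALSE)
  if (high < low) stop("high must be >= low", call. = FALSE)
  count <- as.integer(count)
  if (is.na(count) || count < 1L) stop("count must be >= 1", call. = FALSE)
  if (count >= 2L && high == low)
    stop("count >= 2 requires high > low", call. = FALSE)
  structure(list(low = low, high = high, count = count,
                 log_spaced = isTRUE(log_spaced)),
            class = "ap_conc_range")
}

#' Concentration grid
#'
#' Expands a [conc_range()] into the ordered vector of concentrations to
#' simulate: a 0 uM control first, then \code{count} values from \code{low}
#' to \code{high}, log10- or linearly spaced with exact endpoints.
#'
#' @param range A [conc_range()].
#' @return Numeric vector of concentrations in micromolar, starting with 0.
#' @export
concentration_grid <- function(range) {
  stopifnot(inherits(range, "ap_conc_range"))
  if (range$count == 1L) {
    grid <- range$low
  } else if (range$log_spaced) {
    grid <- 10^seq(log10(range$low), log10(range$high),
                   length.out = range$count)
  } else {
    grid <- seq(range$low, range$high, length.out = range$count)
  }
  grid[1] <- range$low
  grid[length(grid)] <- range$high
  c(0, grid)
}

.ap_log <- function(verbose, ...) {
  if (isTRUE(verbose))
    message(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), sprintf(...))
}

#' Run a concentration-sweep study
#'
#' The full safety-screen pipeline: pace the unblocked model to pseudo-steady
#' state (the 0 uM control), then for each test concentration compute the
#' per-channel block factors, scale the maximal conductances, re-pace to
#' steady state (warm-started from the control's converged state), compute
#' biomarkers on the final pace, and report the percent change in APD90
#' relative to the control together with any abnormality messages.
#'
#' @param model_name Registered model name (see [list_models()]).
#' @param compound A [compound_spec()].
#' @param range A [conc_range()].
#' @param protocol A [pacing_protocol()].
#' @param parameter_overrides Optional named vector overriding model
#'   parameters (applied before block, e.g. for sensitivity checks).
#' @param warm_start Start each drugged run from the control's converged
#'   state (default) instead of the model's resting state.
#' @param verbose Emit timestamped progress messages.
#' @return An object of class \code{ap_study}: a \code{table} data frame
#'   (one row per concentration, control first), per-row \code{traces}, the
#'   control steady-state object and run metadata.
#' @export
#' @examples
#' \donttest{
#' study <- run_study("sixcurrent_demo",
#'                    compound_spec("example", channel_block("hERG", pic50 = 6)),
#'                    conc_range(0.1, 10, 3),
#'                    pacing_protocol(frequency = 1))
#' summary(study)
#' }
run_study <- function(model_name, compound, range,
                      protocol = pacing_protocol(),
                      parameter_overrides = NULL, warm_start = TRUE,
                      verbose = FALSE) {
  stopifnot(inherits(compound, "ap_compound"),
            inherits(range, "ap_conc_range"),
            inherits(protocol, "ap_protocol"))
  model <- get_model(model_name)
  params <- model$default_parameters
  if (!is.null(parameter_overrides)) {
    bad <- setdiff(names(parameter_overrides), names(params))
    if (length(bad) > 0L)
      stop("unknown model parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    params[names(parameter_overrides)] <- parameter_overrides
  }
  concs <- concentration_grid(range)

  .ap_log(verbose, "control run: pacing '%s' at %g Hz", model_name,
          protocol$frequency)
  control <- pace_to_steady(model, params, protocol)
  .ap_log(verbose, "control: %d paces, converged = %s", control$paces_run,
          control$converged)
  ctrl_bio <- compute_biomarkers(control$final_trace)
  ctrl_prev_bio <- if (!is.null(control$previous_trace))
    compute_biomarkers(control$previous_trace) else NULL

  rows <- vector("list", length(concs))
  traces <- vector("list", length(concs))
  for (k in seq_along(concs)) {
    conc <- concs[k]
    factors <- block_factors(compound, conc)
    if (k == 1L) {
      ss <- control
      bio <- ctrl_bio
      prev_bio <- ctrl_prev_bio
      err <- NA_character_
    } else {
      pb <- apply_block(model, params, factors)
      start <- if (warm_start) control$end_state
               else model$default_initial_state
      .ap_log(verbose, "concentration %g uM", conc)
      ss <- NULL
      err <- NA_character_
      bio <- NULL
      prev_bio <- NULL
      ss <- tryCatch(pace_to_steady(model, pb, protocol,
                                    initial_state = start),
                     error = function(e) {
                       err <<- conditionMessage(e)
                       NULL
                     })
      if (!is.null(ss)) {
        bio <- compute_biomarkers(ss$final_trace)
        prev_bio <- if (!is.null(ss$previous_trace))
          compute_biomarkers(ss$previous_trace) else NULL
      }
    }
    if (is.null(ss)) {
      msgs <- list(structure(list(code = "SOLVER_FAILURE", detail = err),
                             class = "ap_abnormality"))
      rows[[k]] <- list(conc = conc, factors = factors, biomarkers = NULL,
                        delta_apd90_pct = NA_real_, messages = msgs,
                        converged = FALSE, paces_run = NA_integer_)
      traces[[k]] <- NULL
      next
    }
    msgs <- detect_abnormalities(bio, prev_bio, ss$final_trace)
    # a pace flagged for repolarisation failure has no meaningful APD90:
    # report it as absent and exclude the row from the percent change
    if (any(vapply(msgs, `[[`, character(1), "code") ==
            "REPOLARISATION_FAILURE"))
      bio$apd90 <- NA_real_
    delta <- if (k == 1L) {
      0
    } else if (!is.na(bio$apd90) && !is.na(ctrl_bio$apd90)) {
      100 * (bio$apd90 - ctrl_bio$apd90) / ctrl_bio$apd90
    } else {
      NA_real_
    }
    rows[[k]] <- list(conc = conc, factors = factors, biomarkers = bio,
                      delta_apd90_pct = delta, messages = msgs,
                      converged = isTRUE(ss$converged),
                      paces_run = ss$paces_run)
    traces[[k]] <- ss$final_trace
    if (length(msgs) > 0L)
      .ap_log(verbose, "  %g uM: %s", conc, format_abnormalities(msgs))
  }

  tab <- do.call(rbind, lapply(rows, function(r) {
    b <- r$biomarkers
    g <- function(x) if (is.null(b) || is.na(b[[x]])) NA_real_ else b[[x]]
    data.frame(conc_uM = r$conc,
               factor_IKr = r$factors[["IKr"]],
               factor_ICaL = r$factors[["ICaL"]],
               factor_INa = r$factors[["INa"]],
               factor_IKs = r$factors[["IKs"]],
               factor_IK1 = r$factors[["IK1"]],
               factor_Ito = r$factors[["Ito"]],
               apd90_ms = g("apd90"), apd50_ms = g("apd50"),
               peak_mV = g("peak_v"), rest_mV = g("rest_v"),
               dvdt_max = g("dvdt_max"),
               delta_apd90_pct = r$delta_apd90_pct,
               converged = r$converged, paces_run = r$paces_run,
               messages = format_abnormalities(r$messages),
               stringsAsFactors = FALSE)
  }))

  structure(list(
    table = tab, rows = rows, traces = traces, control = control,
    metadata = list(model = model_name, compound = compound,
                    protocol = protocol, range = range,
                    warm_start = warm_start,
                    version = as.character(utils::packageVersion("apsweep")),
                    timestamp = format(Sys.time(), tz = "UTC",
                                       "%Y-%m-%dT%H:%M:%SZ"))
  ), class = "ap_study")
}

#' @export
print.ap_study <- function(x, ...) {
  cat("Action-potential block study\n")
  cat("  model:   ", x$metadata$model, "\n")
  cat("  compound:", x$metadata$compound$name, "\n")
  cat(sprintf("  pacing:   %g Hz\n", x$metadata$protocol$frequency))
  cat(sprintf("  rows:     %d (control + %d concentrations)\n",
              nrow(x$table), nrow(x$table) - 1L))
  invisible(x)
}

#' @export
summary.ap_study <- function(object, ...) {
  cols <- c("conc_uM", "apd90_ms", "delta_apd90_pct", "converged",
            "paces_run", "messages")
  out <- object$table[, cols]
  class(out) <- c("summary.ap_study", "data.frame")
  out
}

#' @export
print.summary.ap_study <- function(x, ...) {
  df <- as.data.frame(x)
  df$apd90_ms <- round(df$apd90_ms, 2)
  df$delta_apd90_pct <- round(df$delta_apd90_pct, 2)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Plot a study summary
#'
#' Left panel: percent change in APD90 against concentration (log x-axis).
#' Right panel: the steady-state action potentials overlaid, down-sampled for
#' display.
#'
#' @param x An \code{ap_study}.
#' @param which \code{"summary"}, \code{"traces"} or \code{"both"}.
#' @param ... Passed to the underlying plot calls.
#' @return \code{x}, invisibly.
#' @export
plot.ap_study <- function(x, which = c("both", "summary", "traces"), ...) {
  which <- match.arg(which)
  if (which == "both") {
    old <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(old))
  }
  tab <- x$table
  if (which %in% c("both", "summary")) {
    sel <- tab$conc_uM > 0 & !is.na(tab$delta_apd90_pct)
    plot(tab$conc_uM[sel], tab$delta_apd90_pct[sel], log = "x", type = "b",
         pch = 19, xlab = "concentration (uM)",
         ylab = expression(Delta * "APD90 (%)"), ...)
    graphics::abline(h = 0, lty = 3)
  }
  if (which %in% c("both", "traces")) {
    keep <- !vapply(x$traces, is.null, logical(1))
    tr <- x$traces[keep]
    ds <- function(t) {
      i <- seq(1, length(t$times), by = max(1L, round(1 / (t$times[2] - t$times[1]))))
      list(times = t$times[i], voltages = t$voltages[i])
    }
    tr <- lapply(tr, ds)
    rng <- range(unlist(lapply(tr, `[[`, "voltages")))
    cols <- grDevices::hcl.colors(length(tr), "viridis")
    plot(NULL, xlim = c(0, max(tr[[1]]$times)), ylim = rng,
         xlab = "time (ms)", ylab = "V (mV)", ...)
    for (i in seq_along(tr))
      graphics::lines(tr[[i]]$times, tr[[i]]$voltages, col = cols[i])
  }
  invisible(x)
}

#' Export a study as CSV files
#'
#' Writes \code{summary.csv} (one row per concentration: block factors,
#' biomarkers, percent APD90 change, convergence and messages; absent values
#' are empty cells), one down-sampled voltage trace per concentration
#' (\code{trace_conc_<value>uM.csv}), and \code{metadata.csv} echoing all
#' inputs.  Output is deterministic given the study object.
#'
#' @param result An \code{ap_study}.
#' @param directory Output directory; created if missing.
#' @param trace_step Trace resampling interval in ms (default 1; use
#'   \code{NULL} for the full 0.1 ms grid).
#' @return Character vector of the files written, invisibly.
#' @export
export_csv <- function(result, directory, trace_step = 1) {
  stopifnot(inherits(result, "ap_study"))
  if (file.exists(directory) && !dir.exists(directory))
    stop("'", directory, "' exists and is not a directory", call. = FALSE)
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (file.access(directory, mode = 2) != 0)
    stop("directory '", directory, "' is not writable", call. = FALSE)

  files <- character(0)
  tab <- result$table
  out <- format_num_df(tab)
  out[out == "NA"] <- ""   # absent biomarkers are empty cells, not sentinels
  path <- file.path(directory, "summary.csv")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  files <- c(files, path)

  for (k in seq_len(nrow(tab))) {
    if (is.null(result$traces[[k]])) next
    p <- file.path(directory,
                   sprintf("trace_conc_%guM.csv", tab$conc_uM[k]))
    write_trace_csv(result$traces[[k]], p, step = trace_step)
    files <- c(files, p)
  }

  md <- result$metadata
  cmp <- md$compound
  block_lines <- vapply(cmp$blocks, function(b)
    sprintf("%s pIC50=%g Hill=%g", b$channel, b$pic50, b$hill), character(1))
  meta <- data.frame(
    key = c("model", "compound", "blocks", "frequency_Hz", "stim_amplitude",
            "stim_duration_ms", "stim_offset_ms", "abs_tol", "rel_tol",
            "output_step_ms", "max_paces", "steady_norm_tol", "conc_low_uM",
            "conc_high_uM", "conc_count", "log_spaced", "warm_start",
            "version", "timestamp_utc"),
    value = c(md$model, cmp$name,
              if (length(block_lines) > 0L)
                paste(block_lines, collapse = "; ") else "none",
              md$protocol$frequency,
              if (is.null(md$protocol$stim_amplitude)) "model-default"
              else md$protocol$stim_amplitude,
              md$protocol$stim_duration, md$protocol$stim_offset,
              md$protocol$abs_tol, md$protocol$rel_tol,
              md$protocol$output_step, md$protocol$max_paces,
              md$protocol$steady_norm_tol, md$range$low, md$range$high,
              md$range$count, md$range$log_spaced, md$warm_start,
              md$version, md$timestamp),
    stringsAsFactors = FALSE)
  mpath <- file.path(directory, "metadata.csv")
  utils::write.csv(meta, mpath, row.names = FALSE, quote = FALSE)
  files <- c(files, mpath)
  invisible(files)
}
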