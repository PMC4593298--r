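#' Fraction of current remaining under block
#'
#' The concentration--response curve used throughout the package: the fraction
#' of an ion current remaining at compound concentration \eqn{C} is
#' \deqn{f(C) = \frac{1}{1 + (C/\mathrm{IC}_{50})^{h}},}
#' where \eqn{h} is the Hill coefficient.  At \eqn{C = \mathrm{IC}_{50}}
#' exactly half the current remains, for any \eqn{h > 0}.
#'
#' @param conc Concentration(s), in the same units as \code{ic50}
#'   (conventionally micromolar). Must be \eqn{\ge 0}; vectorised.
#' @param ic50 Half-maximal inhibitory concentration, \eqn{> 0}.
#' @param hill Hill coefficient, \eqn{> 0}. Default 1 (one compound molecule
#'   blocks one channel).
#' @return Numeric vector in \eqn{(0, 1]}: 1 means no block.
#' @seealso [pic50_to_ic50()], [block_factors()]
#' @export
#' @examples
#' fraction_remaining(1, ic50 = 1)          # 0.5: half block at the IC50
#' fraction_remaining(c(0, 0.1, 1, 10), 1)  # monotone decreasing
fraction_remaining <- function(conc, ic50, hill = 1) {
  if (!is.numeric(conc) || anyNA(conc) || any(conc < 0))
    stop("conc must be non-negative and finite", call. = FALSE)
  if (!is.numeric(ic50) || length(ic50) != 1L || !is.finite(ic50) || ic50 <= 0)
    stop("ic50 must be a single positive number", call. = FALSE)
  if (!is.numeric(hill) || length(hill) != 1L || !is.finite(hill) || hill <= 0)
    stop("hill must be a single positive number", call. = FALSE)
  1 / (1 + (conc / ic50)^hill)
}

#' Convert between pIC50 and IC50
#'
#' The package stores potencies canonically as pIC50, defined as
#' \eqn{-\log_{10}} of the molar IC50, so an IC50 in micromolar converts as
#' \eqn{\mathrm{IC}_{50}[\mu M] = 10^{6 - \mathrm{pIC}_{50}}}
#' (pIC50 of 6 is 1 micromolar).
#'
#' @param pic50,ic50 Finite numeric vectors; \code{ic50} in micromolar,
#'   strictly positive.
#' @return \code{pic50_to_ic50}: IC50 in micromolar; \code{ic50_to_pic50}:
#'   the dimensionless pIC50.
#' @export
#' @examples
#' pic50_to_ic50(6)      # 1 uM
#' ic50_to_pic50(0.001)  # 9
pic50_to_ic50 <- function(pic50) {
  if (!is.numeric(pic50) || anyNA(pic50) || any(!is.finite(pic50)))
    stop("pic50 must be finite", call. = FALSE)
  10^(6 - pic50)
}

#' @rdname pic50_to_ic50
#' @export
ic50_to_pic50 <- function(ic50) {
  if (!is.numeric(ic50) || anyNA(ic50) || any(!is.finite(ic50)) ||
      any(ic50 <= 0))
    stop("ic50 must be positive and finite (omit a channel that was not ",
         "measured rather than coding it as 0)", call. = FALSE)
  6 - log10(ic50)
}

#' One channel's concentration--response curve
#'
#' Describes the potency of a compound against a single channel.  Supply
#' either \code{pic50} or \code{ic50} (micromolar); the value is stored
#' canonically as pIC50.
#'
#' @param channel Channel name, parsed by [parse_channel()].
#' @param pic50 pIC50 (\eqn{-\log_{10}} molar IC50); finite.
#' @param ic50 IC50 in micromolar, \eqn{> 0}; alternative to \code{pic50}.
#' @param hill Hill coefficient in \eqn{(0, 10]}; defaults to 1.
#' @return An object of class \code{ap_channel_block}.
#' @export
#' @examples
#' channel_block("hERG", pic50 = 6)
#' channel_block("ICaL", ic50 = 0.4, hill = 1.2)
channel_block <- function(channel, pic50 = NULL, ic50 = NULL, hill = 1) {
  channel <- parse_channel(channel)
  if (length(channel) != 1L)
    stop("channel_block describes a single channel", call. = FALSE)
  if (is.null(pic50) == is.null(ic50))
    stop("supply exactly one of pic50 or ic50", call. = FALSE)
  if (!is.null(ic50)) pic50 <- ic50_to_pic50(ic50)
  if (!is.numeric(pic50) || length(pic50) != 1L || !is.finite(pic50))
    stop("pic50 must be a single finite number", call. = FALSE)
  if (!is.numeric(hill) || length(hill) != 1L || !is.finite(hill) ||
      hill <= 0 || hill > 10)
    stop("hill must be in (0, 10]", call. = FALSE)
  structure(list(channel = channel, pic50 = pic50, hill = hill),
            class = "ap_channel_block")
}

#' @export
print.ap_channel_block <- function(x, ...) {
  cat(sprintf("%s: pIC50 %.4g (IC50 %.4g uM), Hill %.3g\n",
              x$channel, x$pic50, pic50_to_ic50(x$pic50), x$hill))
  invisible(x)
}

#' A compound's multi-channel block specification
#'
#' Collects per-channel concentration--response curves for one compound.  A
#' channel with no entry is treated as unblocked at every concentration.
#'
#' @param name Compound name (free text).
#' @param ... [channel_block()] objects, at most one per channel, or a single
#'   list of them.
#' @return An object of class \code{ap_compound}.
#' @export
#' @examples
#' compound_spec("example", channel_block("hERG", pic50 = 6))
#' compound_spec("inert")   # nothing measured: no block anywhere
compound_spec <- function(name = "compound", ...) {
  blocks <- list(...)
  if (length(blocks) == 1L && is.list(blocks[[1]]) &&
      !inherits(blocks[[1]], "ap_channel_block"))
    blocks <- blocks[[1]]
  ok <- vapply(blocks, inherits, logical(1), what = "ap_channel_block")
  if (!all(ok))
    stop("all block entries must be created with channel_block()",
         call. = FALSE)
  chans <- vapply(blocks, `[[`, character(1), "channel")
  if (anyDuplicated(chans))
    stop("duplicate channel(s): ",
         paste(unique(chans[duplicated(chans)]), collapse = ", "),
         call. = FALSE)
  names(blocks) <- chans
  structure(list(name = as.character(name)[1], blocks = blocks),
            class = "ap_compound")
}

#' @export
print.ap_compound <- function(x, ...) {
  cat("Compound:", x$name, "\n")
  if (length(x$blocks) == 0L) {
    cat("  (no measured channel block)\n")
  } else {
    for (b in x$blocks) {
      cat("  ")
      print(b)
    }
  }
  invisible(x)
}

#' Per-channel fraction of current remaining at one concentration
#'
#' Evaluates the compound's concentration--response curve for each of the six
#' channels.  Channels without a measured curve get exactly 1 (no block).
#'
#' @param compound An [compound_spec()] object.
#' @param conc Concentration in micromolar, \eqn{\ge 0}.
#' @return Named numeric vector over all six channels (class
#'   \code{ap_block_factors}), each value in \eqn{[0, 1]}.
#' @export
#' @examples
#' cmp <- compound_spec("example", channel_block("hERG", pic50 = 6))
#' block_factors(cmp, 1)   # IKr at 0.5, everything else exactly 1
block_factors <- function(compound, conc) {
  if (!inherits(compound, "ap_compound"))
    stop("compound must be created with compound_spec()", call. = FALSE)
  if (!is.numeric(conc) || length(conc) != 1L || !is.finite(conc) || conc < 0)
    stop("conc must be a single non-negative concentration (uM)",
         call. = FALSE)
  out <- rep(1, 6)
  names(out) <- channel_ids()
  for (b in compound$blocks) {
    out[b$channel] <- fraction_remaining(conc, pic50_to_ic50(b$pic50), b$hill)
  }
  structure(out, class = "ap_block_factors")
}

#' @export
print.ap_block_factors <- function(x, ...) {
  cat("Fraction of current remaining:\n")
  print(round(unclass(x), 6))
  invisible(x)
}
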