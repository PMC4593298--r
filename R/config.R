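# YAML config support for the CLI: a flat mapping whose keys mirror the CLI
# flags with underscores, e.g.
#
#   model: sixcurrent_demo
#   pacing_freq: 1
#   pic50_herg: 6
#   hill_herg: 1
#   plasma_conc_low: 0.1
#   plasma_conc_high: 100
#   plasma_conc_count: 7
#
# Explicit command-line flags win over config values.

.config_keys <- function() {
  c("model", "pacing_freq", "plasma_conc_low", "plasma_conc_high",
    "plasma_conc_count", "linear_spacing", "compound_name", "max_paces",
    "output", "trace_step",
    as.vector(outer(c("pic50_", "ic50_", "hill_"),
                    c("herg", "cal", "na", "iks", "ik1", "ito"), paste0)))
}

#' Read a study config file
#'
#' @param path Path to a YAML file with flat keys matching the CLI flags
#'   (underscored), e.g. \code{pic50_herg: 6}.
#' @return Named list of settings.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop("config file '", path, "' not found", call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg) || is.null(names(cfg)))
    stop("config must be a mapping of key: value pairs", call. = FALSE)
  bad <- setdiff(names(cfg), .config_keys())
  if (length(bad) > 0L)
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg
}

# merge config values into parsed options; flags the user actually passed
# keep priority because optparse has already placed them in `opt`, so only
# fill keys still at their documented defaults/NULL.
.merge_config <- function(opt, path) {
  cfg <- read_config(path)
  defaults <- list(model = "sixcurrent_demo", pacing_freq = 1,
                   plasma_conc_low = 0.1, plasma_conc_high = 100,
                   plasma_conc_count = 7L, linear_spacing = FALSE,
                   compound_name = "compound", max_paces = NA,
                   output = "apsweep_out", trace_step = 1)
  for (key in names(cfg)) {
    current <- opt[[key]]
    dflt <- defaults[[key]]
    untouched <- is.null(current) ||
      (!is.null(dflt) && length(current) == 1L && isTRUE(all.equal(current, dflt)))
    if (untouched) opt[[key]] <- cfg[[key]]
  }
  opt
}
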