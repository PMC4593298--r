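#' @title Ion-channel identifiers
#'
#' @description The six screenable cardiac currents handled by the package:
#' \code{IKr} (hERG/Kv11.1 rapid delayed rectifier), \code{ICaL} (Cav1.2
#' L-type calcium), \code{INa} (Nav1.5 fast sodium), \code{IKs} (Kv7.1 slow
#' delayed rectifier), \code{IK1} (Kir2.1 inward rectifier) and \code{Ito}
#' (Kv4.3 fast transient outward).
#'
#' @return Character vector of the six canonical channel identifiers.
#' @export
#' @examples
#' channel_ids()
channel_ids <- function() {
  c("IKr", "ICaL", "INa", "IKs", "IK1", "Ito")
}

# synonym table: lower-cased alias -> canonical id.  Gene, protein and current
# names from standard screening panels.
.channel_synonyms <- c(
  ikr = "IKr", herg = "IKr", kcnh2 = "IKr", "kv11.1" = "IKr",
  ical = "ICaL", cal = "ICaL", cacna1c = "ICaL", "cav1.2" = "ICaL",
  ina = "INa", na = "INa", scn5a = "INa", "nav1.5" = "INa",
  iks = "IKs", kcnq1 = "IKs", "kv7.1" = "IKs", mink = "IKs",
  ik1 = "IK1", k1 = "IK1", kcnj2 = "IK1", "kir2.1" = "IK1",
  ito = "Ito", itof = "Ito", "ito,fast" = "Ito", "ito.fast" = "Ito",
  kcnd3 = "Ito", "kv4.3" = "Ito"
)

#' Parse an ion-channel name
#'
#' Case-insensitive; accepts the canonical identifiers plus common gene,
#' protein and current synonyms (e.g. \code{"hERG"}, \code{"Nav1.5"},
#' \code{"CACNA1C"}).
#'
#' @param x Character vector of channel names.
#' @return Character vector of canonical identifiers (see [channel_ids()]).
#' @export
#' @examples
#' parse_channel(c("hERG", "nav1.5", "IKs"))
parse_channel <- function(x) {
  if (!is.character(x)) stop("channel name must be a character vector")
  key <- tolower(trimws(x))
  out <- unname(.channel_synonyms[key])
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown channel name(s): ", paste(sQuote(bad), collapse = ", "),
         "; valid channels: ", paste(channel_ids(), collapse = ", "),
         call. = FALSE)
  }
  out
}
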