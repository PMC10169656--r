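# Internal helpers shared across modules.

# Locale-independent lexicographic sort (radix = C locale), so writers are
# byte-deterministic regardless of the session's collation.
csort <- function(x) sort(x, method = "radix")

corder <- function(...) order(..., method = "radix")

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Derive a stage-specific seed from a root seed; stays inside 32-bit range.
stageSeed <- function(seed, stage) {
  offs <- c(simulate = 1L, diff = 2L, activity = 3L, model = 4L,
            enrich = 5L, report = 6L)
  k <- if (stage %in% names(offs)) offs[[stage]] else 99L
  (as.integer(seed) %% 2000000L) * 1000L + k * 7L
}

#' Parse and format phosphosite identifiers
#'
#' Phosphosites are written \code{"PROTEIN_T170"}: the host protein symbol,
#' an underscore, the residue letter (S, T or Y) and the 1-based sequence
#' position. \code{parsePhosphosite()} splits such strings (vectorised) and
#' fails, naming the offending entries, on anything that does not conform;
#' \code{phosphositeString()} is its inverse, so the two round-trip
#' losslessly.
#'
#' @param x character vector of phosphosite strings.
#' @param protein,residue,position components of a site: protein symbol,
#'   residue in \code{S}/\code{T}/\code{Y}, integer position \eqn{\ge} 1.
#' @return \code{parsePhosphosite}: data.frame with columns \code{site},
#'   \code{protein}, \code{residue}, \code{position}.
#'   \code{phosphositeString}: character vector.
#' @examples
#' parsePhosphosite("CDK7_T170")
#' phosphositeString("CDK7", "T", 170)
#' @export
parsePhosphosite <- function(x) {
  rx <- "^(.+)_([STY])([0-9]+)$"
  ok <- grepl(rx, x)
  pos <- suppressWarnings(as.integer(sub(rx, "\\3", x)))
  ok <- ok & !is.na(pos) & pos >= 1L
  if (!all(ok))
    stopf("unparseable phosphosite ID(s): %s",
          paste(unique(x[!ok]), collapse = ", "))
  data.frame(site = x,
             protein = sub(rx, "\\1", x),
             residue = sub(rx, "\\2", x),
             position = pos,
             stringsAsFactors = FALSE)
}

#' @rdname parsePhosphosite
#' @export
phosphositeString <- function(protein, residue, position) {
  if (!all(residue %in% c("S", "T", "Y")))
    stopf("residue must be S, T or Y")
  if (!all(position >= 1))
    stopf("position must be >= 1")
  paste0(protein, "_", residue, as.integer(position))
}

# Map the accepted sign vocabulary (numeric and SIGNOR-style verbs) to +1/-1;
# NA for anything unknown.
normalizeSign <- function(x) {
  x0 <- tolower(trimws(as.character(x)))
  out <- rep(NA_real_, length(x0))
  out[x0 %in% c("1", "+1", "activates", "activate", "activation") |
        startsWith(x0, "up-regulates")] <- 1
  out[x0 %in% c("-1", "inhibits", "inhibit", "inhibition") |
        startsWith(x0, "down-regulates")] <- -1
  out
}

edgeKey <- function(source, target, sign)
  paste(source, ifelse(sign > 0, "activates", "inhibits"), target, sep = "\t")
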