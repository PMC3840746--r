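#' Define a restriction enzyme
#'
#' An enzyme is a recognition pattern (IUPAC-aware) plus the cut offset: the
#' number of bases of the recognition site that lie 5' of the top-strand cut.
#' The packaged default is HaeIII (GG/CC): recognition `GGCC`, cut offset 2,
#' a blunt cutter, so both strands share the cut position.  For non-blunt
#' enzymes only the top-strand cut is modeled.
#'
#' @param name Enzyme name.
#' @param recognition IUPAC DNA recognition sequence, length >= 4.
#' @param cut_offset Integer in `[0, nchar(recognition)]`; the top strand is
#'   cut after this many bases of the site.
#' @return An object of class `ardra_enzyme`.
#' @examples
#' enzyme() # HaeIII
#' enzyme("EcoRI", "GAATTC", 1)
#' @export
enzyme <- function(name = "HaeIII", recognition = "GGCC", cut_offset = 2) {
  recognition <- normalize_residues(recognition)
  if (nchar(recognition) < 4L) {
    abort("recognition sequence must be at least 4 bases",
          class = "ardra_data_error")
  }
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(recognition)) {
    abort("cut_offset must lie in [0, nchar(recognition)]",
          class = "ardra_data_error")
  }
  structure(
    list(name = name, recognition = recognition, cut_offset = cut_offset),
    class = "ardra_enzyme"
  )
}

#' @export
print.ardra_enzyme <- function(x, ...) {
  site <- paste0(substr(x$recognition, 1, x$cut_offset), "/",
                 substr(x$recognition, x$cut_offset + 1, nchar(x$recognition)))
  cat(sprintf("<enzyme %s: %s>\n", x$name, site))
  invisible(x)
}

# "NAME:SITE:OFFSET" (CLI --enzyme-def convention)
parse_enzyme <- function(spec) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3L) {
    abort("enzyme definition must be NAME:SITE:OFFSET",
          class = "ardra_usage_error")
  }
  enzyme(parts[1], parts[2], suppressWarnings(as.integer(parts[3])))
}
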