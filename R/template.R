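#' Load a BLA section template
#'
#' Ships three hand-digitized synthetic section templates (anterior,
#' intermediate, posterior) qualitatively matching the BLA's coronal geometry:
#' an outline polygon split into LA (dorsal) and BA (ventral) nuclei by a
#' shared border polyline, six ordered registration landmarks on the outline
#' (dorsal tip, dorsolateral shoulder, lateral border end, ventral tip,
#' medioventral shoulder, medial border end), and the dorsal-most point as
#' origin. Coordinates are micrometres; y increases ventrally. The geometry
#' makes no claim of atlas fidelity.
#'
#' @param section \code{"anterior"}, \code{"intermediate"} or
#'   \code{"posterior"}.
#' @return a [RegionTemplate-class] object.
#' @examples
#' blaTemplate("intermediate")
#' @export
blaTemplate <- function(section = c("intermediate", "anterior", "posterior")) {
  section <- match.arg(section)
  file <- system.file("extdata", "bla_templates.json", package = "blamap",
                      mustWork = TRUE)
  readRegionTemplate(file, section)
}

#' Read a region template from a JSON polygon file
#'
#' The file holds, per section, coordinate arrays \code{outline}, \code{la},
#' \code{ba}, \code{border}, \code{landmarks} (all n x 2, um) and an optional
#' named \code{subregions} list of polygons.
#'
#' @param file path to the JSON template file.
#' @param section section name (a top-level key of the file).
#' @return a [RegionTemplate-class].
#' @export
readRegionTemplate <- function(file, section) {
  tpl <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (!section %in% names(tpl))
    stop("section '", section, "' not present in ", file)
  t <- tpl[[section]]
  asm <- function(x) {
    m <- as.matrix(x)
    dimnames(m) <- NULL
    storage.mode(m) <- "double"
    m
  }
  outline <- asm(t$outline)
  origin <- outline[which.min(outline[, 2]), ]
  subs <- t$subregions
  subs <- if (is.null(subs) || !length(subs)) list() else lapply(subs, asm)
  new("RegionTemplate", section = section, outline = outline,
      la = asm(t$la), ba = asm(t$ba), border = asm(t$border),
      subregions = subs, landmarks = asm(t$landmarks), origin = origin)
}
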