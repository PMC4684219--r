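#' Van der Waals radius lookup
#'
#' Radii come from a bundled, editable heavy-atom radius table
#' (`extdata/vdw_radii.tsv`). Aromatic-ring pseudo-atoms take the table's
#' carbon radius: they stand in for the ring's pi face, which is carbon.
#'
#' @param element character vector of element symbols (e.g. "C", "N", "O");
#'   the special symbol "PI" denotes a ring pseudo-atom.
#' @return numeric vector of radii in Angstrom.
#' @export
#' @examples
#' vdw_radius(c("C", "O"))
vdw_radius <- function(element) {
  tab <- vdw_table()
  element <- toupper(element)
  element[element == "PI"] <- "C"
  r <- tab[element]
  if (anyNA(r)) {
    stop("unknown element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  }
  unname(r)
}

vdw_table <- function() {
  if (is.null(.hotspot_env$vdw)) {
    df <- utils::read.delim(hotspot_extdata("vdw_radii.tsv"),
                            comment.char = "#", stringsAsFactors = FALSE)
    .hotspot_env$vdw <- stats::setNames(df$radius, toupper(df$element))
  }
  .hotspot_env$vdw
}
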