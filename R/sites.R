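# Site definitions: generic-number positions making up each named pocket.

#' Load site definitions
#'
#' Reads a two-column TSV (`site`, `position`) listing the generic residue
#' numbers that make up each named site. The packaged default covers the
#' known and orphan allosteric sites analysed in depth (OS5, OS6, OS9, KS2,
#' KS5, KS8) in Ballesteros-Weinstein numbering.
#'
#' @param path Path to a TSV; defaults to the packaged table.
#' @return Tibble with columns `site` and `position`, one row per
#'   (site, generic number); positions are unique within a site.
#' @examples
#' sites <- load_site_definitions()
#' dplyr::count(sites, site)
#' @export
load_site_definitions <- function(path = pocketome_extdata("site_definitions.tsv")) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(site = "c", position = "c"))
  if (nrow(tab) == 0) return(tibble(site = character(), position = character()))
  bad <- !gn_valid(tab$position)
  if (any(bad)) {
    abort(paste0("malformed generic number at line(s) ",
                 paste(which(bad) + 1L, collapse = ", "), " of ", path))
  }
  distinct(tab, .data$site, .data$position)
}

#' Positions of one named site
#' @param sites Site tibble as from [load_site_definitions()].
#' @param name Site name, e.g. `"OS5"`.
#' @return Character vector of generic numbers.
#' @export
site_positions <- function(sites, name) {
  out <- sites$position[sites$site == name]
  if (length(out) == 0) abort(paste0("unknown site '", name, "'"))
  out
}
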