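# State-specific contact importance from the clear-state PCA.

#' Normalised state-specific contact importance per site
#'
#' Takes the separating component of a clear-state PCA (the first, by
#' default), normalises its loadings to the largest absolute value so they
#' range over (0, 1], assigns each contact to the inactive (positive
#' loading, under the package sign convention) or active (negative) state,
#' drops contacts within a single helix, and keeps contacts at or above the
#' normalised-coefficient cutoff. When site definitions are given, contacts
#' are restricted to those touching at least one site residue and reported
#' per site with a flag for whether one or both residues belong to the
#' site.
#'
#' @param pca A `contact_pca`, typically from [recalculate_pca()].
#' @param sites Optional site tibble from [load_site_definitions()];
#'   `NULL` keeps all inter-helix contacts without site assignment.
#' @param cutoff Normalised-coefficient cutoff in (0, 1] (0.5 or 0.7 are
#'   typical reporting choices).
#' @param component Index of the separating component (default 1).
#' @return Tibble with columns `site`, `contact`, `pos_a`, `pos_b`,
#'   `state`, `coeff_norm`, `membership` (`"both"`/`"one"`), ordered by
#'   descending `coeff_norm`.
#' @export
contact_importance <- function(pca, sites = NULL, cutoff = 0.5,
                               component = 1) {
  col <- paste0("PC", component)
  if (!col %in% names(pca$loadings)) {
    abort(paste0("PCA has no component ", component))
  }
  load <- pca$loadings[[col]]
  if (max(abs(load)) < 1e-12) abort("all-zero loadings on the separating component")
  imp <- tibble(contact = pca$loadings$contact, loading = load) %>%
    mutate(coeff_norm = abs(.data$loading) / max(abs(.data$loading)),
           state = ifelse(.data$loading > 0, "inactive", "active")) %>%
    tidyr::separate_wider_delim("contact", "-", names = c("pos_a", "pos_b"),
                                cols_remove = FALSE) %>%
    filter(gn_helix(.data$pos_a) != gn_helix(.data$pos_b),
           .data$coeff_norm >= cutoff)
  if (is.null(sites)) {
    out <- imp %>%
      mutate(site = NA_character_, membership = NA_character_)
  } else {
    per_site <- sites %>%
      group_by(.data$site) %>%
      summarise(positions = list(.data$position), .groups = "drop")
    out <- tidyr::expand_grid(imp, site_row = seq_len(nrow(per_site))) %>%
      mutate(site = per_site$site[.data$site_row],
             n_in = purrr::map2_int(
               .data$pos_a, .data$site_row,
               function(pa, sr) sum(c(pa) %in% per_site$positions[[sr]])) +
               purrr::map2_int(
                 .data$pos_b, .data$site_row,
                 function(pb, sr) sum(c(pb) %in% per_site$positions[[sr]]))) %>%
      filter(.data$n_in >= 1) %>%
      mutate(membership = ifelse(.data$n_in == 2, "both", "one")) %>%
      select(-"site_row", -"n_in")
  }
  out %>%
    select("site", "contact", "pos_a", "pos_b", "state", "coeff_norm",
           "membership") %>%
    arrange(dplyr::desc(.data$coeff_norm), .data$contact)
}
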