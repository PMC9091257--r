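# Census of non-ligand components occupying known sites.

.component_categories <- c("surfactant", "steroid", "fatty_acid", "polymer",
                           "anion", "other")

#' Component category lookup
#'
#' Maps 3-letter chemical component codes to the five census categories
#' (surfactant, steroid, fatty acid, polymer, anion); anything absent from
#' the table is `other`. The packaged default covers the codes commonly
#' resolved in receptor structures (CLR/CHS steroids, OLA/OLC/PLM fatty
#' acids, PEG-family polymers, sulfate/phosphate/chloride anions,
#' maltoside/glucoside surfactants, ...).
#'
#' @param path TSV with columns `het_code`, `category`.
#' @return Named character vector keyed by het code.
#' @export
default_component_categories <- function(path = pocketome_extdata("het_categories.tsv")) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  bad <- setdiff(unique(tab$category), .component_categories)
  if (length(bad) > 0) {
    abort(paste0("unknown component category: ", paste(bad, collapse = ", ")))
  }
  setNames(tab$category, tab$het_code)
}

#' Classify a chemical component
#'
#' @param het_code Character vector of 3-letter component codes.
#' @param lookup Category lookup from [default_component_categories()].
#' @return Character vector of categories (`other` when unlisted).
#' @examples
#' classify_component(c("CLR", "SO4", "ZZZ"))
#' @export
classify_component <- function(het_code, lookup = default_component_categories()) {
  out <- unname(lookup[het_code])
  out[is.na(out)] <- "other"
  out
}

#' Components occupying a site in one structure
#'
#' A component occupies the site when at least one of its heavy atoms lies
#' within `contact_cutoff` of atoms of at least two distinct site residues
#' (a reproducible geometric proxy for visual pocket inspection).
#' Components whose het code appears in `exclude` (e.g. designed
#' orthosteric/allosteric ligands) are skipped.
#'
#' @param structure A `gpcr_structure` with hetero records.
#' @param site_positions Generic numbers defining the site; at least two
#'   must be mapped on the structure.
#' @param contact_cutoff Distance cutoff in Angstrom (default 4.5).
#' @param lookup Category lookup table.
#' @param exclude Het codes to ignore.
#' @return Tibble with one row per occupying component: `structure_id`,
#'   `het_code`, `het_id`, `category`, `n_site_residues` contacted.
#' @export
site_occupancy <- function(structure, site_positions, contact_cutoff = 4.5,
                           lookup = default_component_categories(),
                           exclude = character()) {
  site_at <- filter(structure$atoms,
                    .data$generic_number %in% site_positions)
  n_mapped <- dplyr::n_distinct(site_at$generic_number)
  if (n_mapped < 2) {
    abort(paste0("site has ", n_mapped,
                 " mapped residue(s) on ", structure$structure_id,
                 " (need >= 2)"))
  }
  het <- structure$hetero %>%
    filter(!.data$het_code %in% exclude, .data$element != "H")
  empty <- tibble(structure_id = character(), het_code = character(),
                  het_id = integer(), category = character(),
                  n_site_residues = integer())
  if (nrow(het) == 0) return(empty)
  sxyz <- cbind(site_at$x, site_at$y, site_at$z)
  res <- het %>%
    group_by(.data$het_code, .data$het_id) %>%
    summarise(n_site_residues = {
      hxyz <- cbind(.data$x, .data$y, .data$z)
      d2 <- outer(rowSums(hxyz^2), rowSums(sxyz^2), `+`) -
        2 * tcrossprod(hxyz, sxyz)
      hit <- colSums(d2 <= contact_cutoff^2) > 0
      dplyr::n_distinct(site_at$generic_number[hit])
    }, .groups = "drop") %>%
    filter(.data$n_site_residues >= 2)
  if (nrow(res) == 0) return(empty)
  tibble(structure_id = structure$structure_id,
         het_code = res$het_code, het_id = res$het_id,
         category = classify_component(res$het_code, lookup),
         n_site_residues = as.integer(res$n_site_residues))
}

#' Aggregate site occupancy across structures
#'
#' Counts, per site, the structures with at least one occupying component
#' and, per (site, category), the structures containing that category
#' (deduplicated within a structure). Two percentage denominators are
#' emitted: the site's occupied-structure count and the total number of
#' structures surveyed.
#'
#' @param records Tibble binding [site_occupancy()] outputs with an added
#'   `site` column (see [census_structures()]).
#' @param sites Character vector of site names to report (defaults to those
#'   present in `records`).
#' @param n_total Total number of structures surveyed (for the site-level
#'   percentage).
#' @return An `occupancy_table`: tibble with columns `site`, `category`,
#'   `n_structures`, `occupied_structures`, `pct_of_occupied`, plus
#'   attribute rows `category = "any"` giving the site-level census
#'   (`pct_of_total` against `n_total`).
#' @export
aggregate_occupancy <- function(records, sites = NULL, n_total = NULL) {
  sites <- sites %||% sort(unique(records$site))
  n_total <- n_total %||% dplyr::n_distinct(records$structure_id)
  per_site <- purrr::map(sites, function(s) {
    rec <- filter(records, .data$site == s)
    occ_ids <- unique(rec$structure_id)
    n_occ <- length(occ_ids)
    cat_counts <- rec %>%
      distinct(.data$structure_id, .data$category) %>%
      dplyr::count(.data$category, name = "n_structures")
    cat_rows <- tibble(site = s,
                       category = .component_categories) %>%
      left_join(cat_counts, by = "category") %>%
      mutate(n_structures = tidyr::replace_na(.data$n_structures, 0L),
             occupied_structures = n_occ,
             pct_of_occupied = if (n_occ > 0) {
               100 * .data$n_structures / n_occ
             } else 0,
             pct_of_total = 100 * .data$n_structures / n_total)
    any_row <- tibble(site = s, category = "any",
                      n_structures = n_occ, occupied_structures = n_occ,
                      pct_of_occupied = ifelse(n_occ > 0, 100, 0),
                      pct_of_total = 100 * n_occ / n_total)
    bind_rows(any_row, cat_rows)
  })
  out <- bind_rows(per_site)
  structure(out, n_total = n_total,
            class = c("occupancy_table", class(tibble())))
}

#' Run the occupancy census over many structures and sites
#'
#' @param structures List of `gpcr_structure` objects.
#' @param sites Site tibble from [load_site_definitions()].
#' @param contact_cutoff Distance cutoff in Angstrom.
#' @param lookup Category lookup table.
#' @param exclude Named list (by structure id) of het codes to exclude, or
#'   a character vector applied to all structures.
#' @return An `occupancy_table` over all (structure, site) combinations.
#' @export
census_structures <- function(structures, sites, contact_cutoff = 4.5,
                              lookup = default_component_categories(),
                              exclude = character()) {
  site_names <- unique(sites$site)
  recs <- purrr::map(structures, function(s) {
    excl <- if (is.list(exclude)) {
      exclude[[s$structure_id]] %||% character()
    } else exclude
    purrr::map(site_names, function(sn) {
      occ <- site_occupancy(s, site_positions(sites, sn),
                            contact_cutoff = contact_cutoff,
                            lookup = lookup, exclude = excl)
      if (nrow(occ) > 0) mutate(occ, site = sn) else NULL
    })
  })
  records <- bind_rows(purrr::flatten(recs))
  if (nrow(records) == 0) {
    records <- tibble(structure_id = character(), het_code = character(),
                      het_id = integer(), category = character(),
                      n_site_residues = integer(), site = character())
  }
  aggregate_occupancy(records, sites = site_names,
                      n_total = length(structures))
}

#' @describeIn aggregate_occupancy Bar chart of per-site category counts.
#' @param object An `occupancy_table`.
#' @param ... Unused.
#' @export
autoplot.occupancy_table <- function(object, ...) {
  df <- filter(as_tibble(object), .data$category != "any",
               .data$n_structures > 0)
  ggplot(df, aes(.data$category, .data$n_structures,
                 fill = .data$category)) +
    geom_col() +
    facet_wrap(~site) +
    labs(x = NULL, y = "structures with component") +
    theme_minimal()
}
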