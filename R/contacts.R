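# Residue contact maps under the van der Waals + buffer criterion.

#' Compute the residue contact map of a structure
#'
#' Two generically numbered residues are in contact when any atom pair
#' between them is closer than the sum of the atoms' van der Waals radii
#' plus a buffer distance. To suppress trivial local contacts, pairs less
#' than `min_seq_sep` positions apart in author numbering are ignored
#' whenever one of the two atoms involved is a backbone atom (side
#' chain-side chain proximity still counts). Only residues carrying a
#' generic number with helix index 1-7 (plus helix 8 when `include_h8`)
#' enter the map, restricting it to the transmembrane bundle.
#'
#' @param structure A `gpcr_structure` with radii assigned.
#' @param buffer Buffer distance in Angstrom (default 0.5).
#' @param min_seq_sep Minimum author-position separation below which
#'   backbone-involving atom pairs are excluded (default 4).
#' @param include_h8 Include helix 8 positions (default TRUE).
#' @param heavy_only Drop hydrogens before the distance check (default
#'   FALSE: all atoms present are used).
#' @return A `contact_map`: tibble with columns `structure_id`, `pos_a`,
#'   `pos_b` (generic numbers, `pos_a` before `pos_b` in (helix, position)
#'   order) and `contact` (the `"a-b"` label), with the parameters stored
#'   in the `params` attribute.
#' @examples
#' b <- make_bundle(bundle_spec(seed = 1))
#' nrow(compute_contacts(b$structure))
#' @export
compute_contacts <- function(structure, buffer = 0.5, min_seq_sep = 4,
                             include_h8 = TRUE, heavy_only = FALSE) {
  helices <- if (include_h8) 1:8 else 1:7
  at <- structure$atoms %>%
    filter(!is.na(.data$generic_number),
           gn_helix(.data$generic_number) %in% helices)
  if (heavy_only) at <- filter(at, .data$element != "H")
  params <- list(buffer = buffer, min_seq_sep = min_seq_sep,
                 include_h8 = include_h8, heavy_only = heavy_only,
                 radius_table = "bondi")
  if (nrow(at) == 0) {
    warn(paste0(structure$structure_id,
                ": no generically numbered residues; empty contact map"))
    return(new_contact_map(empty_contacts(structure$structure_id), params))
  }
  xyz <- cbind(at$x, at$y, at$z)
  # pairwise atom distances vs per-pair vdW threshold
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), `+`) - 2 * tcrossprod(xyz)
  thr <- outer(at$vdw_radius, at$vdw_radius, `+`) + buffer
  close <- d2 < thr^2
  pair <- which(close & upper.tri(close), arr.ind = TRUE)
  if (nrow(pair) == 0) {
    return(new_contact_map(empty_contacts(structure$structure_id), params))
  }
  a <- pair[, 1]
  b <- pair[, 2]
  same_res <- at$generic_number[a] == at$generic_number[b]
  seq_sep <- abs(at$author_pos[a] - at$author_pos[b])
  excluded <- seq_sep < min_seq_sep & (at$is_backbone[a] | at$is_backbone[b])
  keep <- !same_res & !excluded
  if (!any(keep)) {
    return(new_contact_map(empty_contacts(structure$structure_id), params))
  }
  res <- tibble(gn_a = at$generic_number[a][keep],
                gn_b = at$generic_number[b][keep]) %>%
    mutate(contact = contact_label(.data$gn_a, .data$gn_b)) %>%
    distinct(.data$contact, .keep_all = TRUE)
  swap <- gn_lt(res$gn_b, res$gn_a)
  cm <- tibble(
    structure_id = structure$structure_id,
    pos_a = ifelse(swap, res$gn_b, res$gn_a),
    pos_b = ifelse(swap, res$gn_a, res$gn_b),
    contact = res$contact)
  pa <- gn_parse(cm$pos_a)
  pb <- gn_parse(cm$pos_b)
  cm <- cm[order(pa$helix, pa$position, pb$helix, pb$position), ]
  new_contact_map(cm, params)
}

empty_contacts <- function(structure_id) {
  tibble(structure_id = character(), pos_a = character(),
         pos_b = character(), contact = character())
}

new_contact_map <- function(tbl, params) {
  structure(tbl, params = params,
            class = c("contact_map", class(tibble())))
}

#' Contact-map parameters
#' @param map A `contact_map`.
#' @return The parameter list recorded on the map.
#' @export
contact_params <- function(map) attr(map, "params")

#' Write / read contact maps as TSV
#'
#' The parameter set travels in `# key value` comment lines so that a map
#' round-trips together with the settings that produced it.
#'
#' @param map A `contact_map`.
#' @param path File path.
#' @return `write_contact_map()`: `path`, invisibly; `read_contact_map()`:
#'   a `contact_map`.
#' @export
write_contact_map <- function(map, path) {
  p <- contact_params(map)
  hdr <- sprintf("# %s %s", names(p), unlist(lapply(p, as.character)))
  writeLines(c(hdr, "structure_id\tpos_a\tpos_b",
               sprintf("%s\t%s\t%s", map$structure_id, map$pos_a, map$pos_b)),
             path)
  invisible(path)
}

#' @rdname write_contact_map
#' @export
read_contact_map <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- stringr::str_split_fixed(sub("^# ", "", hdr), " ", 2)
  params <- as.list(kv[, 2])
  names(params) <- kv[, 1]
  for (f in c("buffer", "min_seq_sep")) {
    if (!is.null(params[[f]])) params[[f]] <- as.numeric(params[[f]])
  }
  for (f in c("include_h8", "heavy_only")) {
    if (!is.null(params[[f]])) params[[f]] <- as.logical(params[[f]])
  }
  body <- lines[!grepl("^#", lines)]
  tbl <- readr::read_tsv(I(paste(body, collapse = "\n")),
                         show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  tbl <- mutate(as_tibble(tbl),
                contact = contact_label(.data$pos_a, .data$pos_b))
  new_contact_map(tbl, params)
}
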