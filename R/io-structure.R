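# Readers/writers for receptor structures, numbering tables and metadata.

#' Construct a receptor structure object
#'
#' A `gpcr_structure` bundles one protein chain (as a per-atom tibble) with
#' its metadata and any hetero components. Most users will obtain structures
#' from [read_structure()] or [make_bundle()] rather than building them by
#' hand.
#'
#' @param atoms Tibble with columns `chain`, `author_pos` (integer), `ins`
#'   (insertion-code suffix, `""` if none), `aa` (one-letter code), `generic_number`
#'   (label like `"3.50"` or `NA`), `atom` (atom name), `element`,
#'   `x`, `y`, `z` (Angstrom). Columns `is_backbone` and `vdw_radius` are
#'   derived if absent.
#' @param structure_id,receptor_id Labels.
#' @param gpcr_class One of `"A"`, `"B1"`, `"B2"`, `"C"`, `"D1"`, `"F"` or `NA`.
#' @param state One of `"active"`, `"intermediate"`, `"inactive"`, `"unknown"`.
#' @param hetero Tibble of hetero-component atoms with columns `het_code`,
#'   `het_id`, `element`, `x`, `y`, `z` (may be empty).
#' @return A `gpcr_structure` object.
#' @export
new_structure <- function(atoms, structure_id = "struct", receptor_id = "rec",
                          gpcr_class = NA_character_, state = "unknown",
                          hetero = empty_hetero()) {
  atoms <- as_tibble(atoms)
  if (nrow(atoms) == 0) abort("structure has no atoms (empty chain)")
  if (!"ins" %in% names(atoms)) atoms$ins <- ""
  if (!"is_backbone" %in% names(atoms)) {
    atoms$is_backbone <- is_backbone_name(atoms$atom)
  }
  if (!"vdw_radius" %in% names(atoms)) {
    atoms$vdw_radius <- vdw_radius(atoms$element)
  }
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    abort("non-finite atom coordinates")
  }
  bad <- gn_cols_invalid(atoms$generic_number)
  if (any(bad)) {
    abort(paste0("malformed generic number(s): ",
                 paste(unique(atoms$generic_number[bad]), collapse = ", ")))
  }
  structure(
    list(structure_id = structure_id, receptor_id = receptor_id,
         gpcr_class = gpcr_class, state = state,
         atoms = atoms, hetero = as_tibble(hetero)),
    class = "gpcr_structure"
  )
}

gn_cols_invalid <- function(gn) !is.na(gn) & !gn_valid(gn)

empty_hetero <- function() {
  tibble(het_code = character(), het_id = integer(),
         element = character(), x = double(), y = double(), z = double())
}

#' @export
print.gpcr_structure <- function(x, ...) {
  res <- residue_table(x)
  cat("<gpcr_structure> ", x$structure_id,
      " (receptor ", x$receptor_id,
      ", class ", x$gpcr_class %||% NA,
      ", state ", x$state, ")\n", sep = "")
  cat("  ", nrow(res), " residues, ", nrow(x$atoms), " atoms, ",
      sum(!is.na(res$generic_number)), " generically numbered, ",
      nrow(x$hetero), " hetero atoms\n", sep = "")
  invisible(x)
}

#' @describeIn new_structure Per-atom tibble view of a structure.
#' @param x A `gpcr_structure`.
#' @param ... Unused.
#' @export
as_tibble.gpcr_structure <- function(x, ...) x$atoms

#' One row per residue of a structure
#'
#' @param structure A `gpcr_structure`.
#' @return Tibble with columns `chain`, `author_pos`, `ins`, `aa`,
#'   `generic_number` and `n_atoms`.
#' @export
residue_table <- function(structure) {
  structure$atoms %>%
    group_by(.data$chain, .data$author_pos, .data$ins) %>%
    summarise(aa = .data$aa[1], generic_number = .data$generic_number[1],
              n_atoms = dplyr::n(), .groups = "drop")
}

#' Read a generic-residue-number table
#'
#' The TSV maps author residue positions to class-specific generic numbers
#' (Ballesteros-Weinstein and analogous schemes), with columns
#' `receptor_id`, `chain`, `author_pos`, `aa`, `generic_number`.
#'
#' @param path Path to a tab-separated file.
#' @return Tibble with those five columns; the mapping must be injective in
#'   both directions per receptor.
#' @export
read_numbering_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           receptor_id = "c", chain = "c", author_pos = "i",
                           aa = "c", generic_number = "c"))
  bad <- !gn_valid(tab$generic_number)
  if (any(bad)) {
    abort(paste0("malformed generic number at line(s) ",
                 paste(which(bad) + 1L, collapse = ", "), " of ", path))
  }
  dup <- tab %>%
    group_by(.data$receptor_id) %>%
    summarise(dup = anyDuplicated(paste(.data$chain, .data$author_pos)) > 0 ||
                anyDuplicated(.data$generic_number) > 0) %>%
    filter(.data$dup)
  if (nrow(dup) > 0) {
    abort(paste0("numbering not one-to-one for receptor(s): ",
                 paste(dup$receptor_id, collapse = ", ")))
  }
  tab
}

#' Read the per-structure metadata table
#'
#' @param path TSV with columns `structure_id`, `receptor_id`, `chain`,
#'   `gpcr_class`, `state`.
#' @return Tibble of metadata rows.
#' @export
read_structure_metadata <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
  needed <- c("structure_id", "receptor_id", "chain", "gpcr_class", "state")
  missing <- setdiff(needed, names(meta))
  if (length(missing) > 0) {
    abort(paste0("metadata lacks column(s): ", paste(missing, collapse = ", ")))
  }
  meta
}

#' Read a prepared receptor coordinate file
#'
#' Parses a PDB file (first model only), keeps one protein chain, applies
#' the first-conformation rule for alternate locations, attaches generic
#' residue numbers from a numbering table, and routes HETATM records to the
#' structure's hetero component table.
#'
#' @param path Path to a PDB file.
#' @param numbering Optional numbering tibble as from
#'   [read_numbering_table()] (rows for other receptors are ignored).
#' @param meta Optional single metadata row (tibble or list) with fields
#'   `structure_id`, `receptor_id`, `chain`, `gpcr_class`, `state`. Without
#'   it, the first chain in the file is used and ids default to the file
#'   name.
#' @return A [new_structure()] object.
#' @examples
#' b <- make_bundle(bundle_spec(seed = 1))
#' f <- tempfile(fileext = ".pdb")
#' write_structure(b$structure, f)
#' s <- read_structure(f)
#' s
#' @export
read_structure <- function(path, numbering = NULL, meta = NULL) {
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) abort(paste0("cannot parse PDB file ", path, ": ",
                                     conditionMessage(e))))
  at <- as_tibble(pdb$atom)
  if (nrow(at) == 0) abort(paste0("no atoms in ", path))
  meta <- as.list(meta %||% list())
  chain_sel <- meta$chain %||% at$chain[at$type == "ATOM"][1]
  if (is.na(chain_sel) || is.null(chain_sel)) chain_sel <- at$chain[1]
  at <- filter(at, .data$chain == chain_sel)
  if (nrow(filter(at, .data$type == "ATOM")) == 0) {
    abort(paste0("empty chain '", chain_sel, "' in ", path))
  }

  # altloc rule: keep the first listed conformation of each atom
  alt_key <- paste(at$type, at$resno, at$insert, at$elety)
  at <- at[!duplicated(alt_key), , drop = FALSE]

  prot <- filter(at, .data$type == "ATOM")
  het <- filter(at, .data$type == "HETATM")

  element <- ifelse(is.na(prot$elesy) | prot$elesy == "",
                    substr(trimws(prot$elety), 1, 1), prot$elesy)
  atoms <- tibble(
    chain = prot$chain,
    author_pos = as.integer(prot$resno),
    ins = ifelse(is.na(prot$insert), "", prot$insert),
    aa = unname(.aa3to1[prot$resid]) %>% tidyr::replace_na("X"),
    generic_number = NA_character_,
    atom = trimws(prot$elety),
    element = normalise_element(element),
    x = prot$x, y = prot$y, z = prot$z
  )

  receptor_id <- meta$receptor_id %||% sub("\\.pdb$", "", basename(path))
  if (!is.null(numbering)) {
    num <- filter(numbering, .data$receptor_id == .env$receptor_id,
                  .data$chain == .env$chain_sel)
    if (nrow(num) == 0 && dplyr::n_distinct(numbering$receptor_id) == 1) {
      # a single-receptor table applies regardless of the id on file
      num <- filter(numbering, .data$chain == .env$chain_sel)
    }
    idx <- match(paste(atoms$chain, atoms$author_pos),
                 paste(num$chain, num$author_pos))
    atoms$generic_number <- num$generic_number[idx]
    unmatched <- setdiff(num$author_pos, atoms$author_pos)
    if (length(unmatched) > 0) {
      warn(paste0("numbering entries for absent residue(s) skipped: ",
                  paste(unmatched, collapse = ", ")))
    }
  }

  hetero <- tibble(
    het_code = het$resid,
    het_id = as.integer(het$resno),
    element = normalise_element(
      ifelse(is.na(het$elesy) | het$elesy == "",
             substr(trimws(het$elety), 1, 1), het$elesy)),
    x = het$x, y = het$y, z = het$z
  )

  new_structure(
    atoms,
    structure_id = meta$structure_id %||% sub("\\.pdb$", "", basename(path)),
    receptor_id = receptor_id,
    gpcr_class = meta$gpcr_class %||% NA_character_,
    state = meta$state %||% "unknown",
    hetero = hetero
  )
}

#' Write a structure back to PDB
#'
#' Protein atoms are written as ATOM records and hetero components as
#' HETATM records; coordinates are kept to three decimals. Round-tripping
#' through [read_structure()] preserves atom counts, residue identities and
#' coordinates at that precision.
#'
#' @param structure A `gpcr_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  aa3 <- names(.aa3to1)[match(a$aa, .aa3to1)]
  aa3[is.na(aa3)] <- "UNK"
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)) %% 100000, pdb_atom_name(a$atom), aa3,
    substr(a$chain, 1, 1), a$author_pos %% 10000,
    ifelse(a$ins == "", " ", a$ins),
    a$x, a$y, a$z, 1, 0, toupper(a$element))
  h <- structure$hetero
  if (nrow(h) > 0) {
    h <- h %>%
      group_by(.data$het_id) %>%
      mutate(.atname = paste0(.data$element, row_number())) %>%
      ungroup()
    lines <- c(lines, sprintf(
      "HETATM%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      (nrow(a) + seq_len(nrow(h))) %% 100000, pdb_atom_name(h$.atname),
      substr(h$het_code, 1, 3), substr(a$chain[1], 1, 1), h$het_id %% 10000,
      h$x, h$y, h$z, 1, 0, toupper(h$element)))
  }
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

# PDB atom-name column convention: names up to 3 characters start in
# column 14, 4-character names in column 13.
pdb_atom_name <- function(name) {
  name <- trimws(name)
  ifelse(nchar(name) >= 4, substr(name, 1, 4), paste0(" ", sprintf("%-3s", name)))
}
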