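# Element data and generic-residue-number helpers shared across modules.

# Bondi-style van der Waals radii (Angstrom). Unknown elements fall back to
# the carbon radius with a warning at lookup time.
.vdw_table <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98, Se = 1.90, B = 1.92
)

.vdw_default <- 1.70

# Backbone atom names; hydrogens bonded to N/CA carry these PDB names.
.backbone_atoms <- c("N", "CA", "C", "O", "OXT", "H", "H1", "H2", "H3", "HA",
                     "HA2", "HA3")

.aa1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.aa3to1 <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F", GLY = "G",
  HIS = "H", ILE = "I", LYS = "K", LEU = "L", MET = "M", ASN = "N",
  PRO = "P", GLN = "Q", ARG = "R", SER = "S", THR = "T", VAL = "V",
  TRP = "W", TYR = "Y"
)

#' Look up van der Waals radii by element symbol
#'
#' Radii follow the Bondi convention (C 1.70, N 1.55, O 1.52, S 1.80,
#' H 1.20, P 1.80 Angstrom). Elements absent from the packaged table get the
#' carbon radius (1.70) with a warning.
#'
#' @param element Character vector of element symbols.
#' @return Numeric vector of radii in Angstrom.
#' @examples
#' vdw_radius(c("C", "N", "O"))
#' @export
vdw_radius <- function(element) {
  element <- normalise_element(element)
  r <- unname(.vdw_table[element])
  if (anyNA(r)) {
    unknown <- unique(element[is.na(r)])
    warn(paste0("unknown element(s) ", paste(unknown, collapse = ", "),
                "; using default radius ", .vdw_default, " A"))
    r[is.na(r)] <- .vdw_default
  }
  r
}

# "CL"/"cl" -> "Cl" etc.
normalise_element <- function(element) {
  element <- trimws(element)
  paste0(toupper(substr(element, 1, 1)), tolower(substr(element, 2, 3)))
}

is_backbone_name <- function(atom_name) {
  toupper(trimws(atom_name)) %in% .backbone_atoms
}

#' Parse generic residue numbers
#'
#' Generic numbers are opaque labels of the form `"helix.position"`
#' (e.g. `"3.50"`), with helix in 1..8. `gn_parse()` splits them,
#' `gn_helix()` returns the helix index, and `gn_valid()` checks syntax.
#'
#' @param gn Character vector of generic-number labels.
#' @return `gn_parse()`: a tibble with columns `gn`, `helix`, `position`;
#'   `gn_helix()`: integer vector; `gn_valid()`: logical vector.
#' @examples
#' gn_parse(c("3.50", "7.54"))
#' @export
gn_parse <- function(gn) {
  ok <- gn_valid(gn)
  helix <- position <- rep(NA_integer_, length(gn))
  parts <- stringr::str_split_fixed(gn[ok], stringr::fixed("."), 2)
  helix[ok] <- as.integer(parts[, 1])
  position[ok] <- as.integer(parts[, 2])
  tibble(gn = gn, helix = helix, position = position)
}

#' @rdname gn_parse
#' @export
gn_helix <- function(gn) gn_parse(gn)$helix

#' @rdname gn_parse
#' @export
gn_valid <- function(gn) {
  stringr::str_detect(gn %||% character(), "^[1-8]\\.[0-9]+$") & !is.na(gn)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Canonical order of generic numbers: by (helix, position).
gn_order <- function(gn) {
  p <- gn_parse(gn)
  order(p$helix, p$position)
}

# TRUE where a precedes b in (helix, position) order.
gn_lt <- function(a, b) {
  pa <- gn_parse(a)
  pb <- gn_parse(b)
  pa$helix < pb$helix | (pa$helix == pb$helix & pa$position < pb$position)
}

# Canonical "a-b" contact label with the lower generic number first.
contact_label <- function(pos_a, pos_b) {
  swap <- gn_lt(pos_b, pos_a)
  lo <- ifelse(swap, pos_b, pos_a)
  hi <- ifelse(swap, pos_a, pos_b)
  paste0(lo, "-", hi)
}
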