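# Multi-molecule TRIPOS MOL2 reading and writing for docked probe poses.
#
# Docking engines emit one MOLECULE block per pose; general-purpose MOL2
# readers in R handle single molecules only, so the multi-block splitting
# and the ATOM/BOND section parsing are done here directly.

#' Read docked probe poses from a multi-molecule MOL2 file
#'
#' Each `@<TRIPOS>MOLECULE` block becomes one pose. The pose id is the
#' molecule name (made unique when repeated); the probe id is the name with
#' a trailing `_<digits>` pose suffix stripped, so poses of the same probe
#' group together. Elements are derived from the SYBYL atom-type prefix
#' (`"C.ar"` to `"C"`); the per-atom charge column is read and rounded to
#' the formal charge.
#'
#' @param path Path to a MOL2 file. An empty file yields an empty pose set.
#' @return A `pose_set`: list with tibbles `atoms` (`pose_id`, `probe_id`,
#'   `atom`, `name`, `element`, `x`, `y`, `z`, `charge`) and `bonds`
#'   (`pose_id`, `a`, `b`, `order`).
#' @examples
#' cloud <- make_pose_cloud(centres = rbind(c(0, 0, 0)), n_per_centre = 2,
#'                          sigma = 0.5, seed = 1)
#' f <- tempfile(fileext = ".mol2")
#' write_poses(cloud$poses, f)
#' read_poses(f)
#' @export
read_poses <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (length(starts) == 0) return(new_pose_set())
  ends <- c(starts[-1] - 1L, length(lines))

  blocks <- purrr::map(seq_along(starts), function(i) {
    parse_mol2_block(lines[starts[i]:ends[i]], i)
  })
  # make repeated molecule names unique while preserving grouping by probe
  uid <- make.unique(purrr::map_chr(blocks, "pose_id"), sep = "#")
  atoms <- bind_rows(purrr::imap(blocks, function(bl, i) {
    bl$atoms$pose_id <- uid[i]
    bl$atoms
  }))
  bonds <- bind_rows(purrr::imap(blocks, function(bl, i) {
    if (nrow(bl$bonds) > 0) bl$bonds$pose_id <- uid[i]
    bl$bonds
  }))
  new_pose_set(atoms, bonds)
}

parse_mol2_block <- function(block, index) {
  fail <- function(what) {
    abort(paste0("corrupt MOLECULE block ", index, ": ", what))
  }
  if (length(block) < 3) fail("truncated header")
  name <- trimws(block[2])
  counts <- suppressWarnings(as.integer(strsplit(trimws(block[3]), "\\s+")[[1]]))
  n_atoms <- counts[1]
  n_bonds <- if (length(counts) >= 2) counts[2] else 0L
  if (is.na(n_atoms)) fail("unreadable atom count")

  atom_at <- grep("^@<TRIPOS>ATOM", block)[1]
  if (is.na(atom_at)) fail("missing ATOM section")
  if (atom_at + n_atoms > length(block)) fail("ATOM section shorter than declared")
  arec <- do.call(rbind, strsplit(trimws(block[atom_at + seq_len(n_atoms)]), "\\s+"))
  if (ncol(arec) < 6) fail("too few ATOM fields")
  xyz <- matrix(suppressWarnings(as.numeric(arec[, 3:5])), ncol = 3)
  if (anyNA(xyz)) fail("non-numeric coordinates")
  charge <- if (ncol(arec) >= 9) suppressWarnings(as.numeric(arec[, 9])) else 0
  charge[is.na(charge)] <- 0

  probe_id <- sub("_[0-9]+$", "", name)
  atoms <- tibble(
    pose_id = name, probe_id = probe_id,
    atom = seq_len(n_atoms), name = arec[, 2],
    element = normalise_element(sub("\\..*$", "", arec[, 6])),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], charge = charge
  )

  bond_at <- grep("^@<TRIPOS>BOND", block)[1]
  if (is.na(bond_at) && n_bonds > 0) {
    warn(paste0("MOLECULE block ", index, " (", name,
                "): missing BOND section, pose kept with no bonds"))
    n_bonds <- 0L
  }
  if (n_bonds > 0) {
    if (bond_at + n_bonds > length(block)) fail("BOND section shorter than declared")
    brec <- do.call(rbind, strsplit(trimws(block[bond_at + seq_len(n_bonds)]), "\\s+"))
    a <- suppressWarnings(as.integer(brec[, 2]))
    b <- suppressWarnings(as.integer(brec[, 3]))
    if (anyNA(a) || anyNA(b) || any(a < 1 | a > n_atoms | b < 1 | b > n_atoms)) {
      fail("bond indices out of range")
    }
    bonds <- tibble(pose_id = name, a = a, b = b, order = brec[, 4])
  } else {
    bonds <- empty_bonds()
  }
  list(pose_id = name, atoms = atoms, bonds = bonds)
}

new_pose_set <- function(atoms = empty_pose_atoms(), bonds = empty_bonds()) {
  structure(list(atoms = as_tibble(atoms), bonds = as_tibble(bonds)),
            class = "pose_set")
}

empty_pose_atoms <- function() {
  tibble(pose_id = character(), probe_id = character(), atom = integer(),
         name = character(), element = character(),
         x = double(), y = double(), z = double(), charge = double())
}

empty_bonds <- function() {
  tibble(pose_id = character(), a = integer(), b = integer(),
         order = character())
}

#' @export
print.pose_set <- function(x, ...) {
  cat("<pose_set> ", dplyr::n_distinct(x$atoms$pose_id), " poses, ",
      dplyr::n_distinct(x$atoms$probe_id), " probes, ",
      nrow(x$atoms), " atoms\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.pose_set <- function(x, ...) x$atoms

#' Number of poses in a pose set
#' @param poses A `pose_set`.
#' @return Integer count of distinct poses.
#' @export
n_poses <- function(poses) dplyr::n_distinct(poses$atoms$pose_id)

#' Concatenate pose sets
#' @param ... `pose_set` objects.
#' @return A single `pose_set` with poses in input order.
#' @export
bind_poses <- function(...) {
  sets <- list(...)
  new_pose_set(bind_rows(purrr::map(sets, "atoms")),
               bind_rows(purrr::map(sets, "bonds")))
}

#' Write a pose set as a multi-molecule MOL2 file
#'
#' @param poses A `pose_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_poses <- function(poses, path) {
  con <- file(path, "w")
  on.exit(close(con))
  ids <- unique(poses$atoms$pose_id)
  for (id in ids) {
    a <- filter(poses$atoms, .data$pose_id == id)
    b <- filter(poses$bonds, .data$pose_id == id)
    aromatic <- a$atom %in% c(b$a[b$order == "ar"], b$b[b$order == "ar"])
    sybyl <- ifelse(aromatic, paste0(a$element, ".ar"), a$element)
    writeLines(c(
      "@<TRIPOS>MOLECULE", id,
      sprintf("%d %d 1", nrow(a), nrow(b)),
      "SMALL", "USER_CHARGES", "@<TRIPOS>ATOM",
      sprintf("%d %s %.4f %.4f %.4f %s 1 LIG %.4f",
              a$atom, a$name, a$x, a$y, a$z, sybyl, a$charge)
    ), con)
    if (nrow(b) > 0) {
      writeLines(c("@<TRIPOS>BOND",
                   sprintf("%d %d %d %s", seq_len(nrow(b)), b$a, b$b, b$order)),
                 con)
    }
  }
  invisible(path)
}
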