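# Shared fixtures and independent oracles for the suite.

# --- tiny molecule fixtures (pose sets built in code) -----------------------

pose_from_atoms <- function(atoms, bonds, id = "mol") {
  atoms$pose_id <- id
  atoms$probe_id <- sub("_[0-9]+$", "", id)
  if (nrow(bonds) > 0) bonds$pose_id <- id else bonds <- pocketome:::empty_bonds()
  pocketome:::new_pose_set(atoms, bonds)
}

acetate_pose <- function(id = "acetate") {
  # CH3-C(=O)-O(-): heavy atoms only, formal charge on the terminal oxygen
  atoms <- tibble::tibble(
    atom = 1:4, name = c("C1", "C2", "O1", "O2"),
    element = c("C", "C", "O", "O"),
    x = c(-1.5, 0, 0.6, 0.6), y = c(0, 0, 1.1, -1.1), z = 0,
    charge = c(0, 0, 0, -1))
  bonds <- tibble::tibble(a = c(1L, 2L, 2L), b = c(2L, 3L, 4L),
                          order = c("1", "2", "1"))
  pose_from_atoms(atoms, bonds, id)
}

methane_pose <- function(id = "methane") {
  atoms <- tibble::tibble(atom = 1L, name = "C1", element = "C",
                          x = 0, y = 0, z = 0, charge = 0)
  pose_from_atoms(atoms, tibble::tibble(a = integer(), b = integer(),
                                        order = character()), id)
}

cyclohexane_pose <- function(id = "cyclohexane") {
  ang <- 2 * pi * (0:5) / 6
  atoms <- tibble::tibble(atom = 1:6, name = paste0("C", 1:6), element = "C",
                          x = 1.53 * cos(ang), y = 1.53 * sin(ang),
                          z = rep(c(0.25, -0.25), 3), charge = 0)
  bonds <- tibble::tibble(a = 1:6, b = c(2:6, 1L), order = "1")
  pose_from_atoms(atoms, bonds, id)
}

ethylamine_pose <- function(id = "ethylamine") {
  atoms <- tibble::tibble(atom = 1:3, name = c("C1", "C2", "N1"),
                          element = c("C", "C", "N"),
                          x = c(0, 1.5, 2.4), y = c(0, 0, 1.1), z = 0,
                          charge = 0)
  bonds <- tibble::tibble(a = c(1L, 2L), b = c(2L, 3L), order = "1")
  pose_from_atoms(atoms, bonds, id)
}

# --- minimal structures -----------------------------------------------------

# residue of one or more named atoms at given coordinates
residue_atoms <- function(author_pos, gn, atoms, elements, xyz,
                          chain = "A", aa = "A") {
  tibble::tibble(
    chain = chain, author_pos = as.integer(author_pos), ins = "",
    aa = aa, generic_number = gn, atom = atoms, element = elements,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

# two single-atom residues at a controlled distance
two_atom_structure <- function(distance, pos_a = 10L, pos_b = 80L,
                               gn_a = "1.50", gn_b = "2.50",
                               atom = "CB", element = "C") {
  atoms <- dplyr::bind_rows(
    residue_atoms(pos_a, gn_a, atom, element, cbind(0, 0, 0)),
    residue_atoms(pos_b, gn_b, atom, element, cbind(distance, 0, 0)))
  new_structure(atoms, structure_id = "pairfix")
}

# random small structure for the brute-force contact oracle: n residues on a
# loose chain, 1-4 atoms each, some backbone, all generically numbered
random_contact_fixture <- function(n_res = 30, seed = 1) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_res), function(i) {
      centre <- runif(3, 0, 12)
      n_at <- sample(1:4, 1)
      names_ <- c("N", "CA", "CB", "CG")[seq_len(n_at)]
      xyz <- sweep(matrix(rnorm(n_at * 3, 0, 0.8), n_at, 3), 2, centre, `+`)
      residue_atoms(i, paste0(sample(1:7, 1), ".", 30 + i), names_,
                    c("N", "C", "C", "C")[seq_len(n_at)], xyz)
    })
    new_structure(dplyr::bind_rows(rows),
                  structure_id = paste0("rand", seed))
  })
}

# hand-built site sequence table from named rows like c(a = "AVK", ...)
make_table <- function(rows) {
  structure(tibble::tibble(receptor_id = names(rows), row = unname(rows)),
            positions = seq_len(nchar(rows[1])),
            class = c("site_sequence_table", class(tibble::tibble())))
}

# --- independent oracles ----------------------------------------------------

# brute-force all-atom-pairs double loop over residues; mirrors the contact
# definition directly without any vectorisation shared with the package
brute_force_contacts <- function(structure, buffer = 0.5, min_seq_sep = 4,
                                 heavy_only = FALSE) {
  at <- structure$atoms
  at <- at[!is.na(at$generic_number), ]
  if (heavy_only) at <- at[at$element != "H", ]
  keys <- unique(at$generic_number)
  found <- character()
  for (i in seq_along(keys)) {
    for (j in seq_along(keys)) {
      if (j <= i) next
      ai <- at[at$generic_number == keys[i], ]
      aj <- at[at$generic_number == keys[j], ]
      hit <- FALSE
      for (p in seq_len(nrow(ai))) {
        for (q in seq_len(nrow(aj))) {
          d <- sqrt(sum((c(ai$x[p], ai$y[p], ai$z[p]) -
                           c(aj$x[q], aj$y[q], aj$z[q]))^2))
          if (d < ai$vdw_radius[p] + aj$vdw_radius[q] + buffer) {
            sep <- abs(ai$author_pos[p] - aj$author_pos[q])
            bb <- ai$is_backbone[p] || aj$is_backbone[q]
            if (!(sep < min_seq_sep && bb)) hit <- TRUE
          }
          if (hit) break
        }
        if (hit) break
      }
      if (hit) {
        found <- c(found, pocketome:::contact_label(keys[i], keys[j]))
      }
    }
  }
  sort(found)
}

# brute-force PCA oracle via eigen-decomposition of the covariance matrix
eigen_pca_oracle <- function(m) {
  mc <- scale(m, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(mc), symmetric = TRUE)
  list(values = ev$values, vectors = ev$vectors)
}

expect_ggplot <- function(p) testthat::expect_s3_class(p, "ggplot")
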