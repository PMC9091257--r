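# Seeded generators for synthetic inputs: idealised 7TM bundles, probe-pose
# clouds, fingerprint cohorts, site sequences and hetero-component
# placements. Every generator is a pure function of (spec, seed) and
# returns a ground-truth manifest alongside the data.

#' Specification of a synthetic 7TM bundle
#'
#' Parameters of an idealised seven-helix bundle (plus a short helix-8
#' stub): ideal alpha-helices (3.6 residues per turn, 1.5 Angstrom rise)
#' placed on a circle, with backbone N/CA/C/O and a CB pseudo-side-chain
#' per residue. In the active state, helix 6 is tilted about its
#' extracellular end so its intracellular half swings away from the bundle
#' axis, which breaks a set of helix-6 contacts present in the inactive
#' state.
#'
#' @param n_res Residues per transmembrane helix.
#' @param radius Bundle circle radius in Angstrom.
#' @param rise Helical rise per residue (Angstrom).
#' @param state `"inactive"` or `"active"`.
#' @param tilt_deg Helix-6 tilt applied in the active state (degrees).
#' @param noise_sd Coordinate noise (Angstrom, Gaussian, applied after
#'   geometry).
#' @param include_h8 Add the helix-8 stub (8 residues).
#' @param receptor_id,structure_id,gpcr_class Labels.
#' @param seed Integer seed.
#' @return A `bundle_spec` list.
#' @export
bundle_spec <- function(n_res = 24, radius = 9.2, rise = 1.5,
                        state = c("inactive", "active"), tilt_deg = 12,
                        noise_sd = 0, include_h8 = TRUE,
                        receptor_id = "SYNR", structure_id = NULL,
                        gpcr_class = "A", seed = 1) {
  state <- match.arg(state)
  structure(list(
    n_res = n_res, radius = radius, rise = rise, state = state,
    tilt_deg = tilt_deg, noise_sd = noise_sd, include_h8 = include_h8,
    receptor_id = receptor_id,
    structure_id = structure_id %||% paste0(receptor_id, "_", state),
    gpcr_class = gpcr_class, seed = seed), class = "bundle_spec")
}

#' Generate a synthetic 7TM bundle
#'
#' @param spec A [bundle_spec()].
#' @return List with `structure` (a `gpcr_structure`), `numbering`
#'   (tibble in [read_numbering_table()] layout), `fasta` (named sequence
#'   vector) and `manifest` (list with the residue pairs in contact range
#'   on the noiseless coordinates, computed by a direct per-pair distance
#'   scan).
#' @examples
#' b <- make_bundle(bundle_spec(seed = 7))
#' b$structure
#' @export
make_bundle <- function(spec) {
  withr::with_seed(spec$seed, make_bundle_impl(spec))
}

make_bundle_impl <- function(spec) {
  n <- spec$n_res
  mid <- ceiling(n / 2)
  helix_phi <- 2 * pi * (0:6) / 7
  a_helix <- 2.3                      # CA circle radius of an ideal helix
  twist <- 100 * pi / 180

  res_list <- list()
  for (h in 1:7) {
    dirz <- if (h %% 2 == 1) 1 else -1
    centre <- c(spec$radius * cos(helix_phi[h]),
                spec$radius * sin(helix_phi[h]), 0)
    for (j in 1:n) {
      theta <- j * twist + h         # per-helix phase offset
      zloc <- dirz * (j - mid) * spec$rise
      ca <- centre + c(a_helix * cos(theta), a_helix * sin(theta), zloc)
      res_list[[length(res_list) + 1]] <- tibble(
        helix = h, idx = j,
        author_pos = 40L * h + j,
        generic_number = paste0(h, ".", 50 - mid + j),
        theta = theta, ca_x = ca[1], ca_y = ca[2], ca_z = ca[3],
        ax_x = centre[1], ax_y = centre[2], dirz = dirz)
    }
  }
  if (spec$include_h8) {
    # short amphipathic stub running tangentially at the intracellular end
    start <- c(spec$radius * cos(-pi / 7), spec$radius * sin(-pi / 7),
               -(mid * spec$rise) - 2)
    tangent <- c(-sin(-pi / 7), cos(-pi / 7), 0)
    for (j in 1:8) {
      theta <- j * twist
      ca <- start + tangent * (j * 1.5) +
        c(0, 0, 0.5 * sin(theta))
      res_list[[length(res_list) + 1]] <- tibble(
        helix = 8, idx = j, author_pos = 400L + j,
        generic_number = paste0("8.", 46 + j),
        theta = theta, ca_x = ca[1], ca_y = ca[2], ca_z = ca[3],
        ax_x = start[1] + tangent[1] * j * 1.5,
        ax_y = start[2] + tangent[2] * j * 1.5, dirz = 1)
    }
  }
  res <- bind_rows(res_list)

  # helix-6 activation tilt: pivot at the extracellular (top) end of the
  # helix-6 axis, rotation about the tangential horizontal axis, swinging
  # the intracellular end radially outward
  if (spec$state == "active" && spec$tilt_deg != 0) {
    sel <- res$helix == 6
    phi6 <- helix_phi[6]
    pivot <- c(spec$radius * cos(phi6), spec$radius * sin(phi6),
               mid * spec$rise)
    axis <- c(-sin(phi6), cos(phi6), 0)
    ang <- spec$tilt_deg * pi / 180
    radial <- c(cos(phi6), sin(phi6), 0)
    # choose the sign that moves the helix bottom outward
    test_pt <- c(spec$radius * cos(phi6), spec$radius * sin(phi6),
                 -mid * spec$rise)
    move1 <- rotate_about(test_pt, pivot, axis, ang)
    sgn <- if (sum((move1 - test_pt) * radial) > 0) 1 else -1
    xyz <- rotate_about(cbind(res$ca_x[sel], res$ca_y[sel], res$ca_z[sel]),
                        pivot, axis, sgn * ang)
    res$ca_x[sel] <- xyz[, 1]
    res$ca_y[sel] <- xyz[, 2]
    res$ca_z[sel] <- xyz[, 3]
    ax <- rotate_about(cbind(res$ax_x[sel], res$ax_y[sel], res$ca_z[sel] * 0 +
                               res$ca_z[sel]), pivot, axis, sgn * ang)
    res$ax_x[sel] <- ax[, 1]
    res$ax_y[sel] <- ax[, 2]
  }

  aa_pool <- c("A", "V", "L", "I", "F", "M", "T", "S", "W", "Y", "G", "C")
  res$aa <- sample(aa_pool, nrow(res), replace = TRUE)

  atoms <- build_bundle_atoms(res, spec)
  if (spec$noise_sd > 0) {
    atoms$x <- atoms$x + rnorm(nrow(atoms), 0, spec$noise_sd)
    atoms$y <- atoms$y + rnorm(nrow(atoms), 0, spec$noise_sd)
    atoms$z <- atoms$z + rnorm(nrow(atoms), 0, spec$noise_sd)
  }

  str <- new_structure(atoms, structure_id = spec$structure_id,
                       receptor_id = spec$receptor_id,
                       gpcr_class = spec$gpcr_class, state = spec$state)
  numbering <- tibble(receptor_id = spec$receptor_id, chain = "A",
                      author_pos = res$author_pos, aa = res$aa,
                      generic_number = res$generic_number)
  seq_chars <- rep("G", max(res$author_pos))
  seq_chars[res$author_pos] <- res$aa
  fasta <- setNames(paste(seq_chars, collapse = ""), spec$receptor_id)

  noiseless <- if (spec$noise_sd > 0) {
    build_bundle_atoms(res, spec)
  } else atoms
  manifest <- list(
    spec = spec,
    contacts = bundle_contact_scan(noiseless),
    helix6_positions = res$generic_number[res$helix == 6])
  list(structure = str, numbering = numbering, fasta = fasta,
       manifest = manifest)
}

# N/CA/C/O/CB coordinates from the CA trace; backbone neighbours are
# interpolated along the trace, CB points radially away from the helix axis
build_bundle_atoms <- function(res, spec) {
  n_res <- nrow(res)
  ca <- cbind(res$ca_x, res$ca_y, res$ca_z)
  prev <- rbind(ca[1, ] - c(0, 0, 1.5), ca[-n_res, , drop = FALSE])
  nxt <- rbind(ca[-1, , drop = FALSE], ca[n_res, ] + c(0, 0, 1.5))
  same_prev <- c(FALSE, res$helix[-1] == res$helix[-n_res] &
                   res$idx[-1] == res$idx[-n_res] + 1)
  same_nxt <- c(res$helix[-n_res] == res$helix[-1] &
                  res$idx[-n_res] == res$idx[-1] - 1, FALSE)
  prev[!same_prev, ] <- ca[!same_prev, ] + matrix(c(0, 0, -1.5),
                                                  sum(!same_prev), 3, byrow = TRUE)
  nxt[!same_nxt, ] <- ca[!same_nxt, ] + matrix(c(0, 0, 1.5),
                                               sum(!same_nxt), 3, byrow = TRUE)
  n_at <- ca + 0.38 * (prev - ca)
  c_at <- ca + 0.40 * (nxt - ca)
  radial <- cbind(ca[, 1] - res$ax_x, ca[, 2] - res$ax_y, 0)
  rn <- sqrt(rowSums(radial^2))
  rn[rn == 0] <- 1
  cb <- ca + 1.53 * radial / rn
  o_at <- c_at + 1.23 * radial / rn

  per_res <- function(name, element, xyz, backbone) {
    tibble(chain = "A", author_pos = res$author_pos, ins = "",
           aa = res$aa, generic_number = res$generic_number,
           atom = name, element = element, is_backbone = backbone,
           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  atoms <- bind_rows(
    per_res("N", "N", n_at, TRUE),
    per_res("CA", "C", ca, TRUE),
    per_res("C", "C", c_at, TRUE),
    per_res("O", "O", o_at, TRUE),
    per_res("CB", "C", cb, FALSE))
  atoms %>%
    arrange(.data$author_pos,
            match(.data$atom, c("N", "CA", "C", "O", "CB"))) %>%
    mutate(vdw_radius = vdw_radius(.data$element))
}

rotate_about <- function(points, pivot, axis, angle) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  sweep(sweep(points, 2, pivot) %*% t(R), 2, pivot, `+`)
}

# direct per-residue-pair distance scan (independent of compute_contacts):
# returns the generically numbered inter-residue pairs within vdW + buffer,
# applying the backbone/sequence-separation exclusion
bundle_contact_scan <- function(atoms, buffer = 0.5, min_seq_sep = 4) {
  keys <- unique(atoms$author_pos)
  by_res <- split(atoms, atoms$author_pos)
  out <- list()
  for (i in seq_along(keys)) {
    ai <- by_res[[i]]
    for (j in seq_along(keys)) {
      if (j <= i) next
      aj <- by_res[[j]]
      # cheap CA prefilter
      cai <- ai[ai$atom == "CA", c("x", "y", "z")]
      caj <- aj[aj$atom == "CA", c("x", "y", "z")]
      if (sum((unlist(cai) - unlist(caj))^2) > 18^2) next
      found <- FALSE
      for (p in seq_len(nrow(ai))) {
        for (q in seq_len(nrow(aj))) {
          d <- sqrt((ai$x[p] - aj$x[q])^2 + (ai$y[p] - aj$y[q])^2 +
                      (ai$z[p] - aj$z[q])^2)
          if (d < ai$vdw_radius[p] + aj$vdw_radius[q] + buffer) {
            sep <- abs(ai$author_pos[p] - aj$author_pos[q])
            if (!(sep < min_seq_sep && (ai$is_backbone[p] || aj$is_backbone[q]))) {
              found <- TRUE
              break
            }
          }
        }
        if (found) break
      }
      if (found) {
        out[[length(out) + 1]] <- tibble(
          gn_a = ai$generic_number[1], gn_b = aj$generic_number[1])
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(pos_a = character(), pos_b = character(),
                  contact = character()))
  }
  res <- bind_rows(out)
  swap <- gn_lt(res$gn_b, res$gn_a)
  tibble(pos_a = ifelse(swap, res$gn_b, res$gn_a),
         pos_b = ifelse(swap, res$gn_a, res$gn_b)) %>%
    mutate(contact = paste0(.data$pos_a, "-", .data$pos_b))
}

#' Benzene probe template
#'
#' Six aromatic carbons on a regular hexagon of radius 1.39 Angstrom,
#' centred at the origin; the default probe for [make_pose_cloud()].
#'
#' @param name Probe label.
#' @return A single-pose `pose_set`.
#' @export
benzene_template <- function(name = "benzene") {
  ang <- 2 * pi * (0:5) / 6
  atoms <- tibble(pose_id = name, probe_id = name, atom = 1:6,
                  name = paste0("C", 1:6), element = "C",
                  x = 1.39 * cos(ang), y = 1.39 * sin(ang), z = 0,
                  charge = 0)
  bonds <- tibble(pose_id = name, a = 1:6, b = c(2:6, 1L), order = "ar")
  new_pose_set(atoms, bonds)
}

#' Generate a probe-pose cloud around planted cavity centres
#'
#' Rigid copies of the template probe are dropped with centroids drawn from
#' isotropic Gaussians at the given centres and uniformly random
#' orientations, emulating docking output concentrated in cavities.
#'
#' @param centres Matrix (k x 3) of cavity centres (Angstrom).
#' @param n_per_centre Poses per centre.
#' @param sigma Gaussian spread of pose centroids (Angstrom, > 0).
#' @param template Template `pose_set` (default [benzene_template()]).
#' @param seed Integer seed.
#' @param path Optional MOL2 output path.
#' @return List with `poses` (a `pose_set`), `manifest` (tibble of centre
#'   coordinates and counts) and `path`.
#' @export
make_pose_cloud <- function(centres, n_per_centre, sigma = 1,
                            template = benzene_template(), seed = 1,
                            path = NULL) {
  centres <- matrix(as.numeric(centres), ncol = 3)
  if (sigma <= 0) abort("sigma must be > 0")
  withr::with_seed(seed, {
    t_atoms <- template$atoms
    t_bonds <- template$bonds
    t_xyz <- cbind(t_atoms$x, t_atoms$y, t_atoms$z)
    t_xyz <- sweep(t_xyz, 2, colMeans(t_xyz))
    all_atoms <- list()
    all_bonds <- list()
    pose_no <- 0
    for (ci in seq_len(nrow(centres))) {
      for (k in seq_len(n_per_centre)) {
        pose_no <- pose_no + 1
        R <- random_rotation()
        centroid <- centres[ci, ] + rnorm(3, 0, sigma)
        xyz <- sweep(t_xyz %*% t(R), 2, centroid, `+`)
        id <- paste0(t_atoms$probe_id[1], "_", pose_no)
        a <- t_atoms
        a$pose_id <- id
        a$x <- xyz[, 1]
        a$y <- xyz[, 2]
        a$z <- xyz[, 3]
        all_atoms[[pose_no]] <- a
        if (nrow(t_bonds) > 0) {
          b <- t_bonds
          b$pose_id <- id
          all_bonds[[pose_no]] <- b
        }
      }
    }
    poses <- if (pose_no == 0) new_pose_set() else {
      new_pose_set(bind_rows(all_atoms), bind_rows(all_bonds))
    }
    if (!is.null(path)) write_poses(poses, path)
    list(poses = poses,
         manifest = tibble(centre = seq_len(nrow(centres)),
                           x = centres[, 1], y = centres[, 2],
                           z = centres[, 3], n = n_per_centre),
         path = path)
  })
}

# uniform random rotation from a normalised quaternion
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}

#' Specification of a synthetic fingerprint cohort
#'
#' @param n_active,n_inactive Structures per state.
#' @param planted_contacts Tibble with columns `contact` (label like
#'   `"3.43-5.54"`) and `state` (`"active"`/`"inactive"`): contacts present
#'   in that state and absent in the other. The default plants six
#'   inter-helix contacts, three per state.
#' @param n_background Background contacts present in every structure.
#' @param flip_noise Independent bit-flip probability (0 <= p < 0.5).
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_active = 20, n_inactive = 20,
                        planted_contacts = default_planted_contacts(),
                        n_background = 60, flip_noise = 0.05, seed = 1) {
  if (flip_noise < 0 || flip_noise >= 0.5) abort("flip_noise must be in [0, 0.5)")
  same_helix <- gn_helix(sub("-.*", "", planted_contacts$contact)) ==
    gn_helix(sub(".*-", "", planted_contacts$contact))
  if (any(same_helix)) abort("planted contacts must be inter-helix")
  structure(list(n_active = n_active, n_inactive = n_inactive,
                 planted_contacts = planted_contacts,
                 n_background = n_background,
                 flip_noise = flip_noise, seed = seed),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_planted_contacts <- function() {
  tibble(contact = c("3.50-5.58", "5.54-6.44", "5.61-6.33",
                     "3.43-5.54", "3.23-4.61", "3.30-4.60"),
         state = rep(c("active", "inactive"), each = 3))
}

#' Generate a synthetic contact-fingerprint cohort
#'
#' Active-planted contacts are present in active structures and absent in
#' inactive ones (and vice versa); background contacts are present
#' everywhere; every bit is then flipped independently with the spec's
#' noise probability.
#'
#' @param spec A [cohort_spec()].
#' @return List with `fingerprints` (a `fingerprint_matrix`) and `manifest`
#'   (the planted contact tibble).
#' @examples
#' coh <- make_fingerprint_cohort(cohort_spec(flip_noise = 0, seed = 2))
#' coh$fingerprints
#' @export
make_fingerprint_cohort <- function(spec) {
  withr::with_seed(spec$seed, {
    planted <- spec$planted_contacts
    pool <- background_contact_pool()
    pool <- setdiff(pool, planted$contact)
    bg <- sample(pool, min(spec$n_background, length(pool)))
    contacts <- c(planted$contact, bg)
    ids <- c(sprintf("ACT%03d", seq_len(spec$n_active)),
             sprintf("INA%03d", seq_len(spec$n_inactive)))
    states <- rep(c("active", "inactive"), c(spec$n_active, spec$n_inactive))
    m <- matrix(0L, length(ids), length(contacts),
                dimnames = list(ids, contacts))
    m[, bg] <- 1L
    for (r in seq_len(nrow(planted))) {
      m[states == planted$state[r], planted$contact[r]] <- 1L
    }
    if (spec$flip_noise > 0) {
      flips <- matrix(runif(length(m)) < spec$flip_noise, nrow(m))
      m[flips] <- 1L - m[flips]
    }
    fp <- new_fingerprint_matrix(m, "A", tibble(structure_id = ids,
                                                state = states))
    list(fingerprints = fp, manifest = planted)
  })
}

# inter-helix generic-number pairs used as background fingerprint columns
background_contact_pool <- function() {
  gns <- paste0(rep(1:7, each = 5), ".", rep(c(40, 44, 48, 52, 56), 7))
  pairs <- utils::combn(gns, 2)
  keep <- gn_helix(pairs[1, ]) != gn_helix(pairs[2, ])
  paste0(pairs[1, keep], "-", pairs[2, keep])
}

#' Generate synthetic site sequences with controlled conservation
#'
#' Per position, a consensus residue is drawn once; each receptor then
#' carries the consensus with probability `conservation` and a uniformly
#' random amino acid otherwise.
#'
#' @param n_receptors Number of receptors.
#' @param site_positions Generic numbers of the site.
#' @param conservation Scalar or per-position vector in `[0, 1]`; ignored
#'   when `profile` is given.
#' @param profile Optional explicit per-position residue profile: a list
#'   (recycled to the number of positions) of named probability vectors,
#'   e.g. `list(c(V = 1/3, I = 1/3, L = 1/3))`; probabilities must sum to
#'   1 per position.
#' @param seed Integer seed.
#' @param fasta_path,numbering_path Optional output paths.
#' @return List with `seqs` (named vector), `numbering` (tibble),
#'   `table` (a `site_sequence_table`) and `manifest` (consensus,
#'   conservation, and the expected pairwise class-match probability under
#'   the packaged class table).
#' @export
make_site_sequences <- function(n_receptors, site_positions,
                                conservation = 0.8, profile = NULL, seed = 1,
                                fasta_path = NULL, numbering_path = NULL) {
  np <- length(site_positions)
  cons <- rep(conservation, length.out = np)
  if (!is.null(profile)) {
    profile <- rep(profile, length.out = np)
    for (p in profile) {
      if (abs(sum(p) - 1) > 1e-8) abort("profile probabilities must sum to 1")
    }
  }
  withr::with_seed(seed, {
    consensus <- sample(.aa1, np, replace = TRUE)
    ids <- sprintf("REC%03d", seq_len(n_receptors))
    draw_row <- function() {
      if (is.null(profile)) {
        take <- runif(np) < cons
        ifelse(take, consensus, sample(.aa1, np, replace = TRUE))
      } else {
        vapply(profile, function(p) sample(names(p), 1, prob = p),
               character(1))
      }
    }
    rows <- vapply(ids, function(id) paste(draw_row(), collapse = ""),
                   character(1))
    seqs <- setNames(unname(rows), ids)
    numbering <- tidyr::expand_grid(receptor_id = ids,
                                    i = seq_len(np)) %>%
      mutate(chain = "A", author_pos = .data$i,
             aa = substring(seqs[.data$receptor_id], .data$i, .data$i),
             generic_number = site_positions[.data$i]) %>%
      select("receptor_id", "chain", "author_pos", "aa", "generic_number")
    if (!is.null(fasta_path)) write_receptor_fasta(seqs, fasta_path)
    if (!is.null(numbering_path)) readr::write_tsv(numbering, numbering_path)
    classes <- default_residue_classes()
    p_class <- vapply(seq_len(np), function(i) {
      if (is.null(profile)) {
        p <- rep((1 - cons[i]) / 20, 20)
        names(p) <- .aa1
        p[consensus[i]] <- p[consensus[i]] + cons[i]
      } else {
        p <- profile[[i]]
      }
      sum(vapply(split(p, classes[names(p)]), function(g) sum(g)^2, 0))
    }, 0)
    table <- extract_site_sequences(seqs, numbering, site_positions)
    list(seqs = seqs, numbering = numbering, table = table,
         manifest = list(consensus = consensus, conservation = cons,
                         expected_class_match = mean(p_class)))
  })
}

.category_codes <- c(surfactant = "BOG", steroid = "CLR", fatty_acid = "OLA",
                     polymer = "PEG", anion = "SO4", other = "UNL")

#' Place synthetic hetero components in or away from a site
#'
#' `"inside"` placements drop a small component next to the closest pair of
#' site residues so that the occupancy rule (one heavy atom within the
#' cutoff of two distinct site residues) holds by construction; `"far"`
#' placements put it 60 Angstrom away so it cannot.
#'
#' @param structure A `gpcr_structure`.
#' @param site_positions Generic numbers of the site (mapped on the
#'   structure).
#' @param category Component category; its representative het code is used
#'   (e.g. `fatty_acid` places OLA).
#' @param placement `"inside"` or `"far"`.
#' @param seed Integer seed.
#' @param het_id Identifier for the placed component.
#' @return The structure with the component appended to `hetero`.
#' @export
make_components <- function(structure, site_positions,
                            category = "fatty_acid",
                            placement = c("inside", "far"), seed = 1,
                            het_id = NULL) {
  placement <- match.arg(placement)
  code <- .category_codes[[category]] %||% "UNL"
  site_at <- filter(structure$atoms,
                    .data$generic_number %in% site_positions,
                    .data$atom %in% c("CA", "CB"))
  if (dplyr::n_distinct(site_at$generic_number) < 2) {
    abort("site has fewer than 2 mapped residues on this structure")
  }
  withr::with_seed(seed, {
    xyz <- cbind(site_at$x, site_at$y, site_at$z)
    d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), `+`) - 2 * tcrossprod(xyz)
    diff_res <- outer(site_at$generic_number, site_at$generic_number, `!=`)
    d2[!diff_res] <- Inf
    best <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
    anchor <- (xyz[best[1], ] + xyz[best[2], ]) / 2
    if (placement == "far") anchor <- anchor + c(60, 0, 0)
    n_at <- 4
    coords <- sweep(matrix(rnorm(n_at * 3, 0, 0.3), n_at, 3), 2, anchor, `+`)
    coords[1, ] <- anchor              # guarantee the contact atom
    hid <- het_id %||% (max(c(structure$hetero$het_id, 900L)) + 1L)
    structure$hetero <- bind_rows(
      structure$hetero,
      tibble(het_code = code, het_id = as.integer(hid),
             element = "C", x = coords[, 1], y = coords[, 2],
             z = coords[, 3]))
    structure
  })
}
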