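# Contact maps, fingerprints, PCA state separation and contact importance.

test_that("the vdW + buffer criterion separates 3.85 from 3.95 Angstrom", {
  # two carbons: r 1.70 + 1.70 + 0.5 buffer = 3.90
  close <- compute_contacts(two_atom_structure(3.85))
  expect_equal(nrow(close), 1)
  expect_equal(close$contact, "1.50-2.50")
  far <- compute_contacts(two_atom_structure(3.95))
  expect_equal(nrow(far), 0)
})

test_that("local backbone-involving pairs are excluded, side chains kept", {
  mk <- function(atom_b, elem_b) {
    atoms <- dplyr::bind_rows(
      residue_atoms(10, "3.50", "CB", "C", cbind(0, 0, 0)),
      residue_atoms(12, "3.52", atom_b, elem_b, cbind(3.0, 0, 0)))
    new_structure(atoms, structure_id = "seq-sep")
  }
  # only close pair involves a backbone N two positions away -> excluded
  expect_equal(nrow(compute_contacts(mk("N", "N"))), 0)
  # same geometry through a side-chain atom -> included
  expect_equal(nrow(compute_contacts(mk("CG", "C"))), 1)
  # and the same backbone pair at separation >= 4 counts again
  atoms <- dplyr::bind_rows(
    residue_atoms(10, "3.50", "CB", "C", cbind(0, 0, 0)),
    residue_atoms(20, "3.60", "N", "N", cbind(3.0, 0, 0)))
  expect_equal(nrow(compute_contacts(new_structure(atoms))), 1)
})

test_that("structures without generic numbers yield an empty map with warning", {
  atoms <- residue_atoms(1, NA_character_, "CA", "C", cbind(0, 0, 0))
  s <- new_structure(atoms)
  expect_warning(cm <- compute_contacts(s), "no generically numbered")
  expect_equal(nrow(cm), 0)
  expect_equal(contact_params(cm)$buffer, 0.5)
})

test_that("compute_contacts equals the brute-force all-pairs oracle", {
  for (seed in 1:6) {
    fix <- random_contact_fixture(n_res = 30, seed = seed)
    got <- sort(compute_contacts(fix)$contact)
    want <- brute_force_contacts(fix)
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("contact maps round-trip through their TSV report", {
  b <- make_bundle(bundle_spec(seed = 2))
  cm <- compute_contacts(b$structure, buffer = 0.4, min_seq_sep = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_contact_map(cm, f)
  cm2 <- read_contact_map(f)
  expect_equal(sort(cm2$contact), sort(cm$contact))
  expect_equal(contact_params(cm2)$buffer, 0.4)
  expect_equal(contact_params(cm2)$min_seq_sep, 5)
})

test_that("helix 8 positions participate only when included", {
  b <- make_bundle(bundle_spec(seed = 4))
  with_h8 <- compute_contacts(b$structure, include_h8 = TRUE)
  without <- compute_contacts(b$structure, include_h8 = FALSE)
  h8 <- grepl("^8\\.", with_h8$pos_a) | grepl("^8\\.", with_h8$pos_b)
  expect_equal(sort(without$contact), sort(with_h8$contact[!h8]))
})

# --- fingerprints -----------------------------------------------------------

map_of <- function(id, contacts) {
  parts <- strsplit(contacts, "-")
  tbl <- tibble::tibble(
    structure_id = id,
    pos_a = purrr::map_chr(parts, 1),
    pos_b = purrr::map_chr(parts, 2),
    contact = contacts)
  pocketome:::new_contact_map(tbl, list(buffer = 0.5, min_seq_sep = 4))
}

test_that("identical maps give an all-ones fingerprint matrix", {
  maps <- lapply(c("s1", "s2", "s3"), map_of,
                 contacts = c("1.50-2.50", "3.50-6.30"))
  fp <- build_fingerprints(maps, "A")
  expect_true(all(fp$matrix == 1))
  expect_equal(dim(fp$matrix), c(3L, 2L))
})

test_that("contacts at positions unresolved in one structure are dropped", {
  maps <- list(map_of("sA", c("3.50-6.30", "1.50-2.50")),
               map_of("sB", c("1.50-2.50")))
  resolved <- list(sA = c("3.50", "6.30", "1.50", "2.50"),
                   sB = c("1.50", "2.50"))    # sB lacks 6.30
  fp <- build_fingerprints(maps, "A", resolved = resolved)
  expect_equal(fp$contacts, "1.50-2.50")
  expect_error(
    build_fingerprints(maps, "A", resolved = list(sA = "1.50", sB = "2.50")),
    "resolved in every")
})

test_that("fingerprint dimensions match brute-force set arithmetic", {
  withr::with_seed(10, {
    pool <- pocketome:::background_contact_pool()
    positions <- unique(unlist(strsplit(pool, "-")))
    # each structure resolves a random subset of positions and forms
    # contacts only among them
    pos_sets <- lapply(1:10, function(i) sample(positions, 28))
    maps <- lapply(1:10, function(i) {
      ok <- vapply(strsplit(pool, "-"),
                   function(p) all(p %in% pos_sets[[i]]), TRUE)
      map_of(sprintf("s%02d", i), sample(pool[ok], sample(10:25, 1)))
    })
    names(pos_sets) <- sprintf("s%02d", 1:10)
    fp <- build_fingerprints(maps, "A", resolved = pos_sets)
    # oracle: union of contacts, both positions resolved in every structure
    all_contacts <- unique(unlist(lapply(maps, function(m) m$contact)))
    common <- Reduce(intersect, pos_sets)
    keep <- vapply(strsplit(all_contacts, "-"),
                   function(p) all(p %in% common), TRUE)
    expect_equal(ncol(fp$matrix), sum(keep))
    expect_equal(nrow(fp$matrix), 10)
    expect_setequal(fp$contacts, all_contacts[keep])
    # row content check against membership
    for (i in c(1, 5, 10)) {
      expect_equal(unname(fp$matrix[i, ]),
                   as.integer(fp$contacts %in% maps[[i]]$contact))
    }
  })
})

test_that("fingerprints round-trip through TSV", {
  coh <- make_fingerprint_cohort(cohort_spec(n_active = 4, n_inactive = 4,
                                             seed = 5))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_fingerprints(coh$fingerprints, f)
  fp2 <- read_fingerprints(f, class_label = "A")
  expect_equal(fp2$matrix, coh$fingerprints$matrix)
  expect_equal(fp2$structures, coh$fingerprints$structures)
})

# --- PCA --------------------------------------------------------------------

test_that("identical fingerprint rows give zero variance components", {
  m <- matrix(1L, 4, 3, dimnames = list(paste0("s", 1:4),
                                        c("1.50-2.50", "1.50-3.50", "2.50-3.50")))
  fp <- pocketome:::new_fingerprint_matrix(
    m, "A", tibble::tibble(structure_id = rownames(m), state = "unknown"))
  expect_warning(pca <- run_pca(fp), "zero-variance")
  expect_true(all(pca$explained_variance_ratio == 0))
})

test_that("a clean two-cluster cohort loads all variance on PC1", {
  coh <- make_fingerprint_cohort(cohort_spec(n_active = 5, n_inactive = 5,
                                             flip_noise = 0, seed = 6))
  pca <- run_pca(coh$fingerprints)
  expect_equal(pca$explained_variance_ratio[1], 1, tolerance = 1e-12)
  # scores form two point masses
  by_state <- split(pca$scores$PC1, pca$scores$state)
  expect_lt(diff(range(by_state$active)), 1e-9)
  expect_lt(diff(range(by_state$inactive)), 1e-9)
  expect_gt(min(by_state$inactive) - max(by_state$active), 1)
})

test_that("PCA matches a brute-force eigen-decomposition oracle", {
  coh <- make_fingerprint_cohort(cohort_spec(n_active = 8, n_inactive = 8,
                                             flip_noise = 0.1, seed = 7))
  pca <- run_pca(coh$fingerprints, n_components = 5)
  oracle <- eigen_pca_oracle(coh$fingerprints$matrix)
  evr_oracle <- oracle$values / sum(oracle$values)
  expect_equal(pca$explained_variance_ratio, evr_oracle[1:5],
               tolerance = 1e-9)
  # loadings agree up to sign with the eigenvectors
  for (j in 1:3) {
    got <- pca$loadings[[paste0("PC", j)]]
    want <- oracle$vectors[, j]
    expect_equal(abs(sum(got * want)), 1, tolerance = 1e-9)
  }
})

test_that("components are orthonormal and variance ratios non-increasing", {
  coh <- make_fingerprint_cohort(cohort_spec(flip_noise = 0.08, seed = 8))
  pca <- run_pca(coh$fingerprints)
  L <- as.matrix(pca$loadings[, -1])
  expect_equal(crossprod(L), diag(ncol(L)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(pca$explained_variance_ratio) <= 1e-12))
})

test_that("scores are reproduced under row permutation", {
  coh <- make_fingerprint_cohort(cohort_spec(flip_noise = 0.05, seed = 9))
  fp <- coh$fingerprints
  perm <- sample(nrow(fp$matrix))
  fp2 <- pocketome:::new_fingerprint_matrix(
    fp$matrix[perm, ], fp$gpcr_class, fp$structures[perm, ])
  s1 <- run_pca(fp)$scores
  s2 <- run_pca(fp2)$scores
  joined <- dplyr::left_join(s1, s2, by = "structure_id",
                             suffix = c("", ".perm"))
  expect_equal(joined$PC1, joined$PC1.perm, tolerance = 1e-9)
  expect_equal(joined$PC2, joined$PC2.perm, tolerance = 1e-9)
})

test_that("the sign convention puts inactive structures on the high side", {
  for (seed in 1:5) {
    coh <- make_fingerprint_cohort(cohort_spec(flip_noise = 0.05, seed = seed))
    sc <- run_pca(coh$fingerprints)$scores
    expect_gt(mean(sc$PC1[sc$state == "inactive"]),
              mean(sc$PC1[sc$state == "active"]))
  }
})

# --- clear-state selection --------------------------------------------------

fake_pca <- function(scores, states = NULL, loadings = NULL,
                     gpcr_class = "A") {
  n <- nrow(scores)
  structure(list(
    scores = tibble::tibble(
      structure_id = paste0("s", seq_len(n)),
      state = states %||% rep("unknown", n),
      PC1 = scores[, 1], PC2 = scores[, 2]),
    loadings = loadings,
    explained_variance_ratio = c(0.6, 0.3),
    sign_convention = "mean inactive score >= mean active score per component",
    gpcr_class = gpcr_class), class = "contact_pca")
}

test_that("class A thresholds assign the worked score examples", {
  pca <- fake_pca(rbind(c(8, 0), c(0, 8), c(1, 1)))
  sel <- select_clear_states(pca)
  expect_equal(nrow(sel), 2)
  expect_equal(sel$clear_state[sel$structure_id == "s1"], "inactive")
  expect_equal(sel$clear_state[sel$structure_id == "s2"], "active")
  expect_false("s3" %in% sel$structure_id)
})

test_that("infinitely low thresholds select every structure", {
  pca <- fake_pca(rbind(c(8, 0), c(0, 8), c(1, 1), c(-4, -9)))
  sel <- select_clear_states(pca, inactive_pc1 = -Inf, active_pc2 = -Inf)
  expect_equal(nrow(sel), 4)
})

test_that("raising a threshold never adds a structure", {
  withr::with_seed(12, {
    sc <- cbind(rnorm(40, 4, 3), rnorm(40, 4, 3))
    pca <- fake_pca(sc)
    prev <- select_clear_states(pca, inactive_pc1 = 0, active_pc2 = 0)
    for (thr in c(2, 4, 6)) {
      cur <- try(select_clear_states(pca, inactive_pc1 = thr,
                                     active_pc2 = thr), silent = TRUE)
      if (inherits(cur, "try-error")) break   # empty set -> error, fine
      expect_true(all(cur$structure_id %in% prev$structure_id))
      prev <- cur
    }
  })
})

test_that("wide planted separation recovers the generator's state labels", {
  coh <- make_fingerprint_cohort(cohort_spec(flip_noise = 0.02, seed = 13))
  pca <- run_pca(coh$fingerprints)
  # planted cohorts separate along PC1; select on it symmetrically
  mid <- 0
  sel <- pca$scores %>%
    dplyr::mutate(clear_state = ifelse(PC1 > mid, "inactive", "active"))
  expect_equal(sel$clear_state, sel$state)
})

test_that("class B1 selection drops high-PC1 structures and outliers", {
  pca <- fake_pca(rbind(c(9, 0), c(1, 2), c(0, -2), c(2, 1)),
                  states = c("active", "active", "inactive", "inactive"),
                  gpcr_class = "B1")
  sel <- select_clear_states(pca, outliers = "s4")
  expect_setequal(sel$structure_id, c("s2", "s3"))
  expect_equal(sel$clear_state, sel$state)
})

# --- contact importance -----------------------------------------------------

test_that("loadings normalise to the largest absolute coefficient", {
  loadings <- tibble::tibble(contact = c("1.50-2.50", "3.50-6.30"),
                             PC1 = c(0.2, -0.4))
  pca <- fake_pca(rbind(c(1, 0), c(-1, 0)), loadings = loadings)
  imp <- contact_importance(pca, cutoff = 0)
  expect_equal(imp$coeff_norm[imp$contact == "1.50-2.50"], 0.5)
  expect_equal(imp$coeff_norm[imp$contact == "3.50-6.30"], 1.0)
  expect_equal(imp$state[imp$contact == "1.50-2.50"], "inactive")
  expect_equal(imp$state[imp$contact == "3.50-6.30"], "active")
})

test_that("same-helix contacts are excluded regardless of loading", {
  loadings <- tibble::tibble(contact = c("5.54-5.58", "5.54-6.44"),
                             PC1 = c(1, 0.9))
  pca <- fake_pca(rbind(c(1, 0), c(-1, 0)), loadings = loadings)
  imp <- contact_importance(pca, cutoff = 0.5)
  expect_equal(imp$contact, "5.54-6.44")
})

test_that("site restriction reports contacts touching site residues", {
  sites <- load_site_definitions()
  loadings <- tibble::tibble(
    contact = c("5.54-6.44", "5.54-6.41", "3.43-5.54", "1.30-2.40"),
    PC1 = c(-1, -0.7, 0.8, 0.9))
  pca <- fake_pca(rbind(c(1, 0), c(-1, 0)), loadings = loadings)
  imp <- contact_importance(pca, sites = sites, cutoff = 0.5)
  os5 <- dplyr::filter(imp, site == "OS5")
  # 5.54-6.44 reported as an OS5 active-state contact (5.54 lies in OS5)
  expect_true("5.54-6.44" %in% os5$contact)
  expect_equal(os5$state[os5$contact == "5.54-6.44"], "active")
  expect_equal(os5$membership[os5$contact == "5.54-6.44"], "one")
  # 5.54-6.41 has both residues inside OS5
  expect_equal(os5$membership[os5$contact == "5.54-6.41"], "both")
  # 3.43-5.54 touches OS5 with one residue
  expect_equal(os5$membership[os5$contact == "3.43-5.54"], "one")
  # a contact outside every packaged site disappears
  expect_false("1.30-2.40" %in% imp$contact)
  expect_error(contact_importance(
    fake_pca(rbind(c(1, 0), c(-1, 0)),
             loadings = tibble::tibble(contact = "1.50-2.50", PC1 = 0)),
    cutoff = 0.5), "all-zero")
})

test_that("planted state contacts are recovered across the full pipeline", {
  # noiseless: the separating component's support is exactly the planted set
  coh0 <- make_fingerprint_cohort(cohort_spec(flip_noise = 0, seed = 3))
  pca0 <- run_pca(coh0$fingerprints)
  l1 <- pca0$loadings$PC1
  support <- pca0$loadings$contact[abs(l1) > 1e-9]
  expect_setequal(support, coh0$manifest$contact)
  # with flip noise, all planted contacts clear the 0.5 cutoff with the
  # correct state sign
  coh <- make_fingerprint_cohort(cohort_spec(flip_noise = 0.05, seed = 4))
  imp <- contact_importance(run_pca(coh$fingerprints), cutoff = 0.5)
  found <- dplyr::inner_join(coh$manifest, imp, by = "contact",
                             suffix = c(".true", ""))
  expect_equal(nrow(found), 6)
  expect_equal(found$state, found$state.true)
})
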