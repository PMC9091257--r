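# Recording kernel, deposition, grid combination and export.

test_that("a zero dampening factor keeps everything in the centre voxel", {
  k <- build_kernel(s_v = 0.5, t = 0)
  expect_equal(attr(k, "centre_weight"), 1)
  expect_equal(sum(k$weight[k$shell != "centre"]), 0)
})

test_that("the default kernel reproduces the 83.34/16.66 split", {
  k <- build_kernel(s_v = 0.5)
  shells <- kernel_shells(k)
  expect_equal(sum(k$weight), 1, tolerance = 1e-12)
  expect_equal(shells$total[shells$shell == "centre"], 0.1666,
               tolerance = 1e-12)
  expect_equal(sum(shells$total[shells$shell != "centre"]), 0.8334,
               tolerance = 1e-12)
  expect_equal(shells$n_voxels, c(1L, 6L, 12L, 8L))
})

test_that("per-shell totals follow v * t * (count / distance)", {
  s <- 0.5
  t <- 0.1309
  k <- build_kernel(s, t)
  v <- 1 / (1 + t * (6 / s + 12 / (sqrt(2) * s) + 8 / (sqrt(3) * s)))
  shells <- kernel_shells(k)
  expect_equal(shells$total[shells$shell == "face"], v * t * 6 / s,
               tolerance = 1e-12)
  expect_equal(shells$total[shells$shell == "edge"],
               v * t * 12 / (sqrt(2) * s), tolerance = 1e-12)
  expect_equal(shells$total[shells$shell == "corner"],
               v * t * 8 / (sqrt(3) * s), tolerance = 1e-12)
})

test_that("kernel weights decrease strictly from centre to corner", {
  # strict decrease centre > face needs t < d at the face distance, i.e.
  # a dampening factor below the spacing; true for the defaults
  withr::with_seed(4, {
    for (i in 1:20) {
      s <- runif(1, 0.1, 3)
      t <- runif(1, 0.05, 0.95) * s
      sh <- kernel_shells(build_kernel(s, t))
      w <- sh$weight[match(c("centre", "face", "edge", "corner"), sh$shell)]
      expect_true(all(diff(w) < 0))
    }
  })
  expect_error(build_kernel(-1, 0.1), "s_v")
  expect_error(build_kernel(0.5, -0.1), "t must")
})

test_that("one deposit adds unit mass with the documented shell pattern", {
  k <- build_kernel(0.5)
  g <- deposit(feature_grid(spacing = 0.5), c(0.25, 0.25, 0.25), k)
  expect_equal(grid_mass(g), 1, tolerance = 1e-12)
  expect_equal(g$n_recordings, 1)
  vals <- sort(unique(round(g$values[g$values > 0], 12)))
  shells <- kernel_shells(k)
  expect_equal(sum(g$values != 0), 27)
  expect_equal(vals, sort(round(shells$weight, 12)))
  expect_equal(sum(abs(g$values - shells$weight[shells$shell == "face"]) < 1e-12), 6)
  expect_equal(sum(abs(g$values - shells$weight[shells$shell == "edge"]) < 1e-12), 12)
  expect_equal(sum(abs(g$values - shells$weight[shells$shell == "corner"]) < 1e-12), 8)
  # centre voxel holds the centre weight
  expect_equal(max(g$values), attr(k, "centre_weight"), tolerance = 1e-12)
})

test_that("depositing twice at a point doubles every voxel", {
  k <- build_kernel(0.5)
  p <- c(1.3, -0.2, 2.6)
  g1 <- deposit(feature_grid(spacing = 0.5), p, k)
  g2 <- deposit(g1, p, k)
  expect_equal(g2$values, 2 * g1$values, tolerance = 1e-12)
  expect_equal(g2$n_recordings, 2)
})

test_that("grids grow on out-of-bounds deposits without losing mass", {
  k <- build_kernel(0.5)
  g <- deposit(feature_grid(spacing = 0.5), c(0, 0, 0), k)
  g <- deposit(g, c(30, -15, 8), k)
  expect_equal(grid_mass(g), 2, tolerance = 1e-9)
  expect_error(deposit(g, c(NA, 0, 0), k), "non-finite")
  expect_error(deposit(g, c(0, 0, 0), build_kernel(0.4)), "spacing")
})

test_that("grid_from_matches conserves match counts per class", {
  empty <- grid_from_matches(match_features(pocketome:::new_pose_set()))
  expect_length(empty, 8)
  expect_true(all(vapply(empty, grid_mass, 0) == 0))

  cloud <- make_pose_cloud(rbind(c(0, 0, 0)), 25, sigma = 1, seed = 5)
  m <- match_features(cloud$poses)
  grids <- grid_from_matches(m)
  expect_equal(grid_mass(grids$everything), 150, tolerance = 1e-9)
  expect_equal(grid_mass(grids$aromatic), 150, tolerance = 1e-9)
  expect_equal(grid_mass(grids$donor), 0)
})

test_that("a planted gaussian cloud peaks within one voxel diagonal", {
  withr::with_seed(11, {
    centre <- c(4.2, -1.3, 7.7)
    pts <- sweep(matrix(rnorm(500 * 3, 0, 1), 500, 3), 2, centre, `+`)
    matches <- tibble::tibble(
      pose_id = "p", probe_id = "p", feature_class = "everything",
      atoms = as.list(1:500), x = pts[, 1], y = pts[, 2], z = pts[, 3])
    g <- grid_from_matches(matches, s_v = 0.5)$everything
    top <- dplyr::slice_max(tibble::as_tibble(g), value, n = 1)
    dist <- sqrt(sum((c(top$x, top$y, top$z) - centre)^2))
    expect_lt(dist, sqrt(3) * 0.5)
  })
})

test_that("combining identically placed grids is elementwise addition", {
  k <- build_kernel(0.5)
  g1 <- deposit(feature_grid(origin = c(0, 0, 0), spacing = 0.5,
                             shape = c(8, 8, 8)), c(1.1, 1.1, 1.1), k)
  g2 <- deposit(feature_grid(origin = c(0, 0, 0), spacing = 0.5,
                             shape = c(8, 8, 8)), c(2.3, 1.7, 0.9), k)
  master <- combine_grids(list(g1, g2))
  inner <- master$values[seq_len(8), seq_len(8), seq_len(8)]
  expect_equal(inner, g1$values + g2$values, tolerance = 1e-12)
  expect_equal(grid_mass(master), 2, tolerance = 1e-12)
})

test_that("a half-voxel offset splits each voxel evenly eight ways", {
  g <- feature_grid(origin = c(0.25, 0.25, 0.25), spacing = 0.5,
                    shape = c(2, 2, 2))
  g$values[1, 1, 1] <- 1
  g$n_recordings <- 1
  anchor <- feature_grid(origin = c(0, 0, 0), spacing = 0.5,
                         shape = c(1, 1, 1))
  master <- combine_grids(list(anchor, g))
  nz <- master$values[master$values != 0]
  expect_length(nz, 8)
  expect_true(all(abs(nz - 0.125) < 1e-12))
  expect_equal(grid_mass(master), 1, tolerance = 1e-12)
})

test_that("mass is conserved when combining randomly offset grids", {
  withr::with_seed(3, {
    k <- build_kernel(0.5)
    grids <- lapply(1:10, function(i) {
      org <- runif(3, -2, 2)
      deposit(feature_grid(origin = org, spacing = 0.5, shape = c(4, 4, 4)),
              org + runif(3, 0.5, 1.5), k)
    })
    master <- combine_grids(grids)
    expect_equal(grid_mass(master), 10, tolerance = 1e-9)
  })
  bad <- feature_grid(spacing = 0.4)
  expect_error(combine_grids(list(feature_grid(spacing = 0.5), bad)),
               "spacings")
})

toy_grid <- function(vals) {
  g <- feature_grid(origin = c(0, 0, 0), spacing = 1, shape = c(length(vals), 1, 1))
  g$values[] <- vals
  g$n_recordings <- sum(vals)
  g
}

test_that("top_fraction_points selects the minimal covering prefix", {
  g <- toy_grid(c(4, 3, 2, 1))
  all_vox <- top_fraction_points(g, 100)
  expect_equal(nrow(all_vox), 4)
  sel <- top_fraction_points(g, 70)
  expect_equal(nrow(sel), 2)
  expect_equal(sel$value, c(4, 3))
})

test_that("ties at the cut break by ascending lattice index", {
  g <- toy_grid(c(2, 2, 2))
  sel <- top_fraction_points(g, 50)
  expect_equal(nrow(sel), 2)
  expect_equal(sel$ix, c(1, 2))
})

test_that("empty grids export an empty dummy-atom file with a warning", {
  f <- withr::local_tempfile(fileext = ".pdb")
  expect_warning(sel <- top_fraction_points(feature_grid(), 50, path = f),
                 "empty")
  expect_equal(nrow(sel), 0)
  expect_true(file.exists(f))
})

test_that("dummy-atom export writes voxel values into the B-factor", {
  g <- toy_grid(c(4, 3, 2, 1))
  f <- withr::local_tempfile(fileext = ".pdb")
  top_fraction_points(g, 70, path = f)
  lines <- grep("^HETATM", readLines(f), value = TRUE)
  expect_length(lines, 2)
  expect_true(all(grepl("DUM", lines)))
  expect_equal(as.numeric(substr(lines, 61, 66)), c(4, 3))
})

test_that("OpenDX export round-trips values, origin, spacing and shape", {
  withr::with_seed(5, {
    g <- feature_grid(origin = c(-1, 0.5, 2), spacing = 0.5,
                      shape = c(3, 4, 5), feature_class = "aromatic")
    g$values[] <- runif(60)
    g$n_recordings <- grid_mass(g)
    f <- withr::local_tempfile(fileext = ".dx")
    write_dx(g, f)
    g2 <- read_dx(f)
    expect_equal(g2$values, g$values, tolerance = 1e-6)
    expect_equal(g2$origin, g$origin, tolerance = 1e-6)
    expect_equal(g2$shape, g$shape)
    expect_equal(g2$spacing, g$spacing)
    expect_equal(g2$feature_class, "aromatic")
  })
})

test_that("an empty grid writes a valid all-zero field", {
  f <- withr::local_tempfile(fileext = ".dx")
  write_dx(feature_grid(shape = c(2, 2, 2)), f)
  g2 <- read_dx(f)
  expect_true(all(g2$values == 0))
})

test_that("the OpenDX body runs with the last axis fastest", {
  g <- feature_grid(origin = c(0, 0, 0), spacing = 1, shape = c(2, 2, 2))
  g$values[] <- 1:8          # R fills first axis fastest
  f <- withr::local_tempfile(fileext = ".dx")
  write_dx(g, f)
  lines <- readLines(f)
  start <- grep("data follows", lines) + 1
  body <- as.numeric(unlist(strsplit(trimws(lines[start:(start + 2)]), "\\s+")))
  # expected order: (1,1,1),(1,1,2),(1,2,1),(1,2,2),(2,1,1),...
  expect_equal(body, c(1, 5, 3, 7, 2, 6, 4, 8))
})

test_that("grids translate exactly with lattice translations of the matches", {
  withr::with_seed(8, {
    pts <- matrix(runif(30, 0, 4), 10, 3)
    mk <- function(p) {
      tibble::tibble(pose_id = "p", probe_id = "p",
                     feature_class = "everything", atoms = as.list(1:10),
                     x = p[, 1], y = p[, 2], z = p[, 3])
    }
    shift <- c(2, -1.5, 3)           # integer multiples of the spacing
    g1 <- grid_from_matches(mk(pts), s_v = 0.5,
                            classes = "everything")$everything
    g2 <- grid_from_matches(mk(sweep(pts, 2, shift, `+`)), s_v = 0.5,
                            classes = "everything")$everything
    expect_equal(g2$origin - g1$origin, shift)
    expect_equal(g2$values, g1$values, tolerance = 1e-12)
  })
})

test_that("planted cavity centres are recovered as separated local maxima", {
  centres <- rbind(c(0, 0, 0), c(12, 0, 0), c(0, 12, 0))
  cloud <- make_pose_cloud(centres, n_per_centre = 300, sigma = 1, seed = 2)
  m <- match_features(cloud$poses)
  master <- grid_from_matches(m, s_v = 0.5)$everything
  mx <- find_grid_maxima(master, k = 3, min_separation = 5)
  expect_equal(nrow(mx), 3)
  for (i in 1:3) {
    d <- sqrt(rowSums(sweep(as.matrix(mx[, c("x", "y", "z")]), 2,
                            centres[i, ])^2))
    expect_lt(min(d), sqrt(3) * 0.5)
  }
})
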