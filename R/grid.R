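# Voxel density grids: deposition, combination, export.
#
# A feature_grid is a tight axis-aligned box of cubic voxels. Voxel
# (i, j, k) (1-based) covers the half-open cube
# [origin + (i-1) s, origin + i s) x ... ; its centre is
# origin + (i - 1/2) s. Grid mass (the sum over voxels) always equals the
# number of recordings deposited, which every operation preserves.

#' Construct an empty feature grid
#'
#' @param origin Coordinates (Angstrom) of the lower corner of voxel (1,1,1).
#' @param spacing Voxel edge length in Angstrom.
#' @param shape Integer vector of three voxel counts.
#' @param feature_class Label of the feature the grid records.
#' @param provenance Character vector of source labels.
#' @return A `feature_grid` object.
#' @export
feature_grid <- function(origin = c(0, 0, 0), spacing = 0.5,
                         shape = c(1, 1, 1), feature_class = "everything",
                         provenance = character()) {
  structure(
    list(origin = as.numeric(origin), spacing = spacing,
         shape = as.integer(shape),
         values = array(0, dim = pmax(shape, 1L)),
         feature_class = feature_class,
         n_recordings = 0,
         provenance = provenance),
    class = "feature_grid")
}

#' @export
print.feature_grid <- function(x, ...) {
  cat("<feature_grid> ", x$feature_class, ", ",
      paste(x$shape, collapse = "x"), " voxels @ ", x$spacing, " A, mass ",
      format(grid_mass(x)), " (", x$n_recordings, " recordings)\n", sep = "")
  invisible(x)
}

#' Total grid mass
#' @param grid A `feature_grid`.
#' @return Sum over all voxel values.
#' @export
grid_mass <- function(grid) sum(grid$values)

#' Tibble view of the non-empty voxels of a grid
#'
#' @param x A `feature_grid`.
#' @param ... Unused.
#' @return Tibble with voxel indices (`ix`, `iy`, `iz`, 1-based), voxel
#'   centre coordinates (`x`, `y`, `z`) and `value`, restricted to nonzero
#'   voxels.
#' @export
as_tibble.feature_grid <- function(x, ...) {
  origin <- x$origin
  s <- x$spacing
  nz <- which(x$values != 0)
  idx <- arrayInd(nz, dim(x$values))
  vals <- x$values[nz]
  tibble(
    ix = idx[, 1], iy = idx[, 2], iz = idx[, 3],
    x = origin[1] + (idx[, 1] - 0.5) * s,
    y = origin[2] + (idx[, 2] - 0.5) * s,
    z = origin[3] + (idx[, 3] - 0.5) * s,
    value = vals)
}

# Accumulate unit recordings at the given points (n x 3 matrix) into the
# grid; assumes all 27-voxel stencils fit inside the current bounds.
accumulate_points <- function(grid, points, kernel) {
  n <- nrow(points)
  vi <- floor(sweep(points, 2, grid$origin) / grid$spacing) + 1L
  off <- as.matrix(kernel[, c("dx", "dy", "dz")])
  w <- rep(kernel$weight, times = n)
  pi_ <- rep(seq_len(n), each = 27L)
  oi <- rep(seq_len(27L), times = n)
  ix <- vi[pi_, 1] + off[oi, 1]
  iy <- vi[pi_, 2] + off[oi, 2]
  iz <- vi[pi_, 3] + off[oi, 3]
  d <- dim(grid$values)
  lin <- ix + (iy - 1L) * d[1] + (iz - 1L) * d[1] * d[2]
  agg <- rowsum(w, lin)
  at <- as.integer(rownames(agg))
  grid$values[at] <- grid$values[at] + agg[, 1]
  grid$n_recordings <- grid$n_recordings + n
  grid
}

#' Deposit recordings into a grid
#'
#' Applies the 27-voxel recording kernel at each point: the voxel containing
#' the point receives the centre weight and its lattice neighbours the
#' dampened fractions. Each point adds a total mass of exactly 1. The grid
#' grows (re-origins on the same lattice) whenever a stencil would fall
#' outside the current bounds.
#'
#' @param grid A `feature_grid` whose spacing equals the kernel's.
#' @param points A length-3 vector or an n x 3 matrix of coordinates (Angstrom).
#' @param kernel A `recording_kernel` from [build_kernel()].
#' @return The updated `feature_grid`.
#' @examples
#' k <- build_kernel()
#' g <- deposit(feature_grid(spacing = 0.5), c(0.25, 0.25, 0.25), k)
#' grid_mass(g)
#' @export
deposit <- function(grid, points, kernel) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  if (!all(is.finite(points))) abort("non-finite deposit location")
  if (abs(attr(kernel, "spacing") - grid$spacing) > 1e-12) {
    abort("kernel spacing does not match grid spacing")
  }
  s <- grid$spacing
  vmin <- floor(sweep(points, 2, grid$origin) / s) + 1L
  lo <- apply(vmin, 2, min) - 1L
  hi <- apply(vmin, 2, max) + 1L
  if (any(lo < 1L) || any(hi > grid$shape)) {
    new_lo <- pmin(lo, 1L)
    new_hi <- pmax(hi, grid$shape)
    shift <- 1L - new_lo                       # whole voxels prepended
    new_shape <- as.integer(new_hi - new_lo + 1L)
    values <- array(0, dim = new_shape)
    if (grid$n_recordings > 0 || any(grid$values != 0)) {
      values[shift[1] + seq_len(grid$shape[1]),
             shift[2] + seq_len(grid$shape[2]),
             shift[3] + seq_len(grid$shape[3])] <- grid$values
    }
    grid$origin <- grid$origin - shift * s
    grid$shape <- new_shape
    grid$values <- values
  }
  accumulate_points(grid, points, kernel)
}

#' Build per-class density grids from feature matches
#'
#' One grid per feature class in `classes` (all eight by default), each a
#' tight bounding box around that class's deposit locations. The mass of
#' each grid equals the number of matches of its class.
#'
#' @param matches Match tibble from [match_features()].
#' @param s_v Voxel spacing in Angstrom.
#' @param t Dampening factor; see [build_kernel()].
#' @param classes Feature classes to build grids for.
#' @param provenance Optional source label stored on each grid.
#' @return Named list of `feature_grid` objects.
#' @export
grid_from_matches <- function(matches, s_v = 0.5, t = default_dampening(),
                              classes = .feature_classes,
                              provenance = character()) {
  kernel <- build_kernel(s_v, t)
  out <- lapply(classes, function(cl) {
    m <- filter(matches, .data$feature_class == cl)
    if (nrow(m) == 0) {
      return(feature_grid(spacing = s_v, feature_class = cl,
                          provenance = provenance))
    }
    pts <- cbind(m$x, m$y, m$z)
    vmin <- floor(apply(pts, 2, min) / s_v) - 1
    vmax <- floor(apply(pts, 2, max) / s_v) + 1
    g <- feature_grid(origin = vmin * s_v, spacing = s_v,
                      shape = as.integer(vmax - vmin + 1),
                      feature_class = cl, provenance = provenance)
    accumulate_points(g, pts, kernel)
  })
  setNames(out, classes)
}

#' Combine grids into a master grid
#'
#' Builds a master grid encompassing all input grids (which must share
#' spacing and feature class) and redistributes every source voxel's value
#' over the at most eight master voxels it overlaps, weighting by the
#' product of per-axis fractional overlaps. Total mass is conserved.
#'
#' @param grids List of `feature_grid` objects.
#' @return A single master `feature_grid`.
#' @export
combine_grids <- function(grids) {
  if (length(grids) == 0) abort("no grids to combine")
  if (length(grids) == 1) return(grids[[1]])
  s <- grids[[1]]$spacing
  cl <- grids[[1]]$feature_class
  for (g in grids) {
    if (abs(g$spacing - s) > 1e-12) {
      abort("cannot combine grids with different spacings")
    }
    if (!identical(g$feature_class, cl)) {
      abort("cannot combine grids of different feature classes")
    }
  }
  origin <- do.call(pmin, lapply(grids, function(g) g$origin))
  # index extent needed on the master lattice
  hi <- do.call(pmax, lapply(grids, function(g) {
    f <- (g$origin - origin) / s
    floor(f + g$shape - 1) + 2   # +1 for fractional spill, 1-based
  }))
  master <- feature_grid(origin = origin, spacing = s,
                         shape = as.integer(hi),
                         feature_class = cl,
                         provenance = unlist(lapply(grids, function(g) g$provenance)))
  d <- dim(master$values)
  for (g in grids) {
    nz <- which(g$values != 0)
    if (length(nz) == 0) {
      master$n_recordings <- master$n_recordings + g$n_recordings
      next
    }
    idx <- arrayInd(nz, dim(g$values))
    f <- (g$origin - origin) / s                 # constant per-axis offset
    base <- sweep(idx - 1L, 2, floor(f), `+`) + 1L
    frac <- f - floor(f)
    vals <- g$values[nz]
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      wt <- (if (cx == 0) 1 - frac[1] else frac[1]) *
            (if (cy == 0) 1 - frac[2] else frac[2]) *
            (if (cz == 0) 1 - frac[3] else frac[3])
      if (wt == 0) next
      lin <- (base[, 1] + cx) + (base[, 2] + cy - 1L) * d[1] +
        (base[, 3] + cz - 1L) * d[1] * d[2]
      agg <- rowsum(vals * wt, lin)
      at <- as.integer(rownames(agg))
      master$values[at] <- master$values[at] + agg[, 1]
    }
    master$n_recordings <- master$n_recordings + g$n_recordings
  }
  master
}

#' Highest-density voxels containing a given fraction of the grid mass
#'
#' Voxels are ranked by value (ties broken by ascending lattice index) and
#' the minimal prefix whose cumulative mass reaches `p` percent of the total
#' is returned; optionally written as a dummy-atom PDB (HETATM records,
#' residue `DUM`, element `X`) with the voxel value in the B-factor column.
#'
#' @param grid A `feature_grid`.
#' @param p Percentage of total mass to cover (0 < p <= 100).
#' @param path Optional output PDB path.
#' @return Tibble of selected voxels (indices, centre coordinates, `value`,
#'   cumulative fraction `cum_fraction`), highest value first.
#' @export
top_fraction_points <- function(grid, p, path = NULL) {
  if (!is.finite(p) || p <= 0 || p > 100) abort("p must be in (0, 100]")
  vox <- as_tibble(grid)
  if (nrow(vox) == 0) {
    warn("empty grid: no voxels to export")
    if (!is.null(path)) writeLines(c("TER", "END"), path)
    return(mutate(vox, cum_fraction = double()))
  }
  lin <- vox$ix + (vox$iy - 1) * grid$shape[1] +
    (vox$iz - 1) * grid$shape[1] * grid$shape[2]
  vox <- vox[order(-vox$value, lin), ]
  total <- sum(vox$value)
  vox$cum_fraction <- cumsum(vox$value) / total
  keep <- seq_len(match(TRUE, vox$cum_fraction >= p / 100 - 1e-12))
  vox <- vox[keep, ]
  if (!is.null(path)) {
    lines <- sprintf(
      "HETATM%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(vox)) %% 100000, " X", "DUM", "X",
      seq_len(nrow(vox)) %% 10000, vox$x, vox$y, vox$z, 1,
      pmin(vox$value, 999.99), "X")
    writeLines(c(lines, "TER", "END"), path)
  }
  vox
}

#' Local density maxima of a grid
#'
#' A voxel is a local maximum if its value exceeds that of all 26
#' neighbours. Maxima are returned highest first after greedy suppression
#' of maxima closer than `min_separation` to an already accepted one.
#'
#' @param grid A `feature_grid`.
#' @param k Number of maxima to return (all if `Inf`).
#' @param min_separation Minimum distance between reported maxima (Angstrom).
#' @return Tibble with voxel centre coordinates and `value`.
#' @export
find_grid_maxima <- function(grid, k = Inf, min_separation = 3) {
  v <- grid$values
  d <- dim(v)
  if (any(d < 3)) abort("grid too small for local-maximum search")
  pad <- array(-Inf, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- v
  is_max <- array(TRUE, dim = d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    nb <- pad[(2:(d[1] + 1)) + dx, (2:(d[2] + 1)) + dy, (2:(d[3] + 1)) + dz]
    is_max <- is_max & (v > nb)
  }
  at <- which(is_max & v > 0)
  if (length(at) == 0) return(tibble(x = double(), y = double(),
                                     z = double(), value = double()))
  idx <- arrayInd(at, d)
  cand <- tibble(
    x = grid$origin[1] + (idx[, 1] - 0.5) * grid$spacing,
    y = grid$origin[2] + (idx[, 2] - 0.5) * grid$spacing,
    z = grid$origin[3] + (idx[, 3] - 0.5) * grid$spacing,
    value = v[at]) %>%
    arrange(dplyr::desc(.data$value))
  kept <- integer()
  for (i in seq_len(nrow(cand))) {
    if (length(kept) > 0) {
      dmin <- min(sqrt((cand$x[kept] - cand$x[i])^2 +
                         (cand$y[kept] - cand$y[i])^2 +
                         (cand$z[kept] - cand$z[i])^2))
      if (dmin < min_separation) next
    }
    kept <- c(kept, i)
    if (length(kept) >= k) break
  }
  cand[kept, ]
}

#' Write a grid as an OpenDX scalar field
#'
#' @param grid A `feature_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, path) {
  d <- pmax(grid$shape, 1L)
  centre0 <- grid$origin + grid$spacing / 2
  vals <- as.vector(aperm(grid$values, c(3, 2, 1)))   # z fastest
  n <- length(vals)
  pad_n <- ceiling(n / 3) * 3
  vals <- c(vals, rep(NA_real_, pad_n - n))
  rows <- matrix(vals, ncol = 3, byrow = TRUE)
  body <- apply(rows, 1, function(r) {
    paste(sprintf("%.10g", r[!is.na(r)]), collapse = " ")
  })
  header <- c(
    sprintf("# feature_class %s n_recordings %.10g", grid$feature_class,
            grid$n_recordings),
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f", centre0[1], centre0[2], centre0[3]),
    sprintf("delta %.6f 0 0", grid$spacing),
    sprintf("delta 0 %.6f 0", grid$spacing),
    sprintf("delta 0 0 %.6f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", n))
  footer <- c("attribute \"dep\" string \"positions\"",
              "object \"density\" class field",
              "component \"positions\" value 1",
              "component \"connections\" value 2",
              "component \"data\" value 3")
  writeLines(c(header, body, footer), path)
  invisible(path)
}

#' Read an OpenDX scalar field written by [write_dx()]
#'
#' @param path Path to a `.dx` file.
#' @return A `feature_grid`.
#' @export
read_dx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  counts_line <- grep("class gridpositions counts", lines, value = TRUE)[1]
  if (is.na(counts_line)) abort(paste0(path, " is not an OpenDX grid"))
  shape <- as.integer(strsplit(sub(".*counts ", "", counts_line), "\\s+")[[1]])
  origin_line <- grep("^origin", lines, value = TRUE)[1]
  centre0 <- as.numeric(strsplit(trimws(sub("^origin", "", origin_line)),
                                 "\\s+")[[1]])
  deltas <- grep("^delta", lines, value = TRUE)
  dvals <- lapply(deltas, function(l) {
    as.numeric(strsplit(trimws(sub("^delta", "", l)), "\\s+")[[1]])
  })
  spacing <- dvals[[1]][1]
  data_at <- grep("data follows", lines)[1]
  n <- prod(shape)
  vals <- numeric(0)
  i <- data_at + 1
  while (length(vals) < n && i <= length(lines)) {
    if (grepl("^(attribute|object|component)", lines[i])) break
    vals <- c(vals, as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    i <- i + 1
  }
  if (length(vals) != n) abort("OpenDX data block has wrong length")
  values <- aperm(array(vals, dim = rev(shape)), c(3, 2, 1))
  meta <- grep("^# feature_class", lines, value = TRUE)
  fc <- if (length(meta) > 0) strsplit(meta[1], "\\s+")[[1]][3] else "everything"
  nrec <- if (length(meta) > 0) {
    as.numeric(strsplit(meta[1], "\\s+")[[1]][5])
  } else sum(vals)
  g <- feature_grid(origin = centre0 - spacing / 2, spacing = spacing,
                    shape = shape, feature_class = fc)
  g$values <- values
  g$n_recordings <- nrec
  g
}

#' @describeIn feature_grid Maximum-intensity projection of a grid along z,
#'   drawn with `geom_raster`.
#' @param object A `feature_grid`.
#' @param ... Unused.
#' @export
autoplot.feature_grid <- function(object, ...) {
  proj <- apply(object$values, c(1, 2), max)
  df <- tidyr::expand_grid(
    ix = seq_len(nrow(proj)), iy = seq_len(ncol(proj))) %>%
    mutate(x = object$origin[1] + (.data$ix - 0.5) * object$spacing,
           y = object$origin[2] + (.data$iy - 0.5) * object$spacing,
           density = proj[cbind(.data$ix, .data$iy)])
  ggplot(df, aes(.data$x, .data$y, fill = .data$density)) +
    geom_raster() +
    scale_fill_viridis_c() +
    coord_equal() +
    labs(title = paste0(object$feature_class, " density (max projection)"),
         x = "x (Å)", y = "y (Å)") +
    theme_minimal()
}
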