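# Pharmacophore feature tagging of probe poses.
#
# Eight feature classes are perceived directly on the pose bond graph:
# hydrogen-bond donors and acceptors, aromatic atoms, halogen atoms, basic
# and acidic substructures, aliphatic ring atoms, and an `everything` class
# covering every atom. The packaged pattern table records the equivalent
# SMARTS for each class; matching itself uses the rule set below
# (implicit-hydrogen counts from standard valences, aromaticity from SYBYL
# `ar` bonds, ring membership from the non-bridge edges of the bond graph).

.feature_classes <- c("donor", "acceptor", "aromatic", "halogen", "basic",
                      "acidic", "aliphatic_ring", "everything")

#' Feature pattern table
#'
#' `default_feature_patterns()` returns the packaged eight-class table;
#' `read_feature_patterns()` reads a user table in the same two-column
#' format (`feature_class`, `smarts`). The `feature_class` column selects
#' which of the eight built-in perception rules apply; the `smarts` column
#' documents the intended substructure.
#'
#' @param path Path to a TSV pattern file.
#' @return Tibble with columns `feature_class` and `smarts`.
#' @examples
#' default_feature_patterns()
#' @export
default_feature_patterns <- function() {
  read_feature_patterns(pocketome_extdata("feature_patterns.tsv"))
}

#' @rdname default_feature_patterns
#' @export
read_feature_patterns <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  unknown <- setdiff(tab$feature_class, .feature_classes)
  if (length(unknown) > 0) {
    abort(paste0("unsupported feature class(es): ",
                 paste(unknown, collapse = ", ")))
  }
  if (anyDuplicated(tab$feature_class)) {
    abort("each feature class may appear at most once")
  }
  tab
}

#' Match pharmacophore features in probe poses
#'
#' Tags every pose with its feature-class substructure occurrences and a
#' deposit location per occurrence. Multi-atom substructures (acidic and
#' basic groups) are deposited at the unweighted centroid of the matched
#' atoms by default; `locations = "atom"` instead records one occurrence
#' per matched atom. Single-atom classes (aromatic, halogen, everything,
#' donor, acceptor, aliphatic ring) are identical under both settings.
#'
#' @param poses A `pose_set` from [read_poses()] or [make_pose_cloud()].
#' @param patterns Pattern tibble; defaults to the packaged eight classes.
#' @param locations `"centroid"` (default) or `"atom"`.
#' @return Tibble with columns `pose_id`, `probe_id`, `feature_class`,
#'   `atoms` (list-column of matched atom indices), `x`, `y`, `z`.
#' @examples
#' cloud <- make_pose_cloud(centres = rbind(c(0, 0, 0)), n_per_centre = 1,
#'                          sigma = 0.1, seed = 1)
#' dplyr::count(match_features(cloud$poses), feature_class)
#' @export
match_features <- function(poses, patterns = default_feature_patterns(),
                           locations = c("centroid", "atom")) {
  locations <- match.arg(locations)
  classes <- patterns$feature_class
  ids <- unique(poses$atoms$pose_id)
  atom_groups <- split(poses$atoms, factor(poses$atoms$pose_id, levels = ids))
  bond_groups <- split(poses$bonds, factor(poses$bonds$pose_id, levels = ids))

  out <- purrr::map2(atom_groups, bond_groups, function(a, b) {
    match_pose_features(a, b, classes)
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(pose_id = character(), probe_id = character(),
                  feature_class = character(), atoms = list(),
                  x = double(), y = double(), z = double()))
  }
  if (locations == "atom") {
    all_atoms <- unlist(out$atoms)
    out <- out[rep(seq_len(nrow(out)), lengths(out$atoms)), ]
    out$atoms <- as.list(all_atoms)
    out <- out %>%
      mutate(.atom = purrr::map_int(.data$atoms, 1)) %>%
      distinct(.data$pose_id, .data$feature_class, .data$.atom,
               .keep_all = TRUE) %>%
      select(-".atom")
  }
  coords <- purrr::map(seq_len(nrow(out)), function(i) {
    a <- out$pose_atoms[[i]]
    idx <- out$atoms[[i]]
    c(mean(a$x[idx]), mean(a$y[idx]), mean(a$z[idx]))
  })
  out$x <- purrr::map_dbl(coords, 1)
  out$y <- purrr::map_dbl(coords, 2)
  out$z <- purrr::map_dbl(coords, 3)
  select(out, "pose_id", "probe_id", "feature_class", "atoms",
         "x", "y", "z")
}

match_pose_features <- function(a, b, classes) {
  p <- perceive_pose(a, b)
  n <- nrow(a)
  sets <- list()
  add <- function(class, atom_sets) {
    if (length(atom_sets) == 0) return()
    sets[[length(sets) + 1]] <<- tibble(
      feature_class = class, atoms = atom_sets)
  }
  per_atom <- function(mask) as.list(which(mask))

  for (cl in classes) {
    switch(cl,
      everything = add("everything", per_atom(rep(TRUE, n))),
      aromatic = add("aromatic", per_atom(p$aromatic)),
      halogen = add("halogen", per_atom(p$element %in% c("F", "Cl", "Br", "I"))),
      donor = add("donor",
                  per_atom(p$element %in% c("N", "O") & p$total_h >= 1)),
      acceptor = add("acceptor",
                     per_atom(p$element %in% c("N", "O") &
                                p$valence %in% c(2, 3) & p$charge <= 0)),
      aliphatic_ring = add("aliphatic_ring",
                           per_atom(p$element == "C" & p$in_ring & !p$aromatic)),
      basic = add("basic", basic_matches(p)),
      acidic = add("acidic", acidic_matches(p))
    )
  }
  if (length(sets) == 0) return(NULL)
  res <- bind_rows(sets)
  res$pose_id <- a$pose_id[1]
  res$probe_id <- a$probe_id[1]
  res$pose_atoms <- list(a)
  res
}

# Derived per-atom chemistry used by the matching rules.
perceive_pose <- function(a, b) {
  n <- nrow(a)
  order_num <- c(`1` = 1, `2` = 2, `3` = 3, am = 1, ar = 1.5,
                 du = 1, un = 1, nc = 0)
  bo <- unname(order_num[b$order])
  bo[is.na(bo)] <- 1

  bond_sum <- explicit_h <- degree <- numeric(n)
  double_to <- vector("list", n)
  nb <- vector("list", n)
  for (k in seq_len(nrow(b))) {
    i <- b$a[k]; j <- b$b[k]
    bond_sum[i] <- bond_sum[i] + bo[k]
    bond_sum[j] <- bond_sum[j] + bo[k]
    degree[i] <- degree[i] + 1
    degree[j] <- degree[j] + 1
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
    if (b$order[k] == "2") {
      double_to[[i]] <- c(double_to[[i]], j)
      double_to[[j]] <- c(double_to[[j]], i)
    }
  }
  element <- a$element
  charge <- round(a$charge)
  explicit_h <- purrr::map_dbl(nb, ~ sum(element[.x] == "H"))

  default_val <- c(C = 4, N = 3, O = 2, S = 2, P = 3, B = 3, H = 1,
                   F = 1, Cl = 1, Br = 1, I = 1)
  dv <- unname(default_val[element])
  dv[is.na(dv)] <- 4
  implicit_h <- pmax(0, round(dv + charge - bond_sum))
  implicit_h[element == "H"] <- 0

  aromatic <- rep(FALSE, n)
  if (nrow(b) > 0) {
    ar_atoms <- unique(c(b$a[b$order == "ar"], b$b[b$order == "ar"]))
    aromatic[ar_atoms] <- TRUE
  }

  in_ring <- rep(FALSE, n)
  if (nrow(b) > 0) {
    g <- igraph::make_graph(rbind(b$a, b$b), n = n, directed = FALSE)
    bridge_ids <- igraph::bridges(g)
    cyclic <- setdiff(seq_len(nrow(b)), as.integer(bridge_ids))
    in_ring[unique(c(b$a[cyclic], b$b[cyclic]))] <- TRUE
  }

  list(element = element, charge = charge, degree = degree,
       neighbours = nb, double_to = double_to,
       explicit_h = explicit_h, implicit_h = implicit_h,
       total_h = explicit_h + implicit_h,
       valence = round(bond_sum + implicit_h),
       connections = degree + implicit_h,
       aromatic = aromatic, in_ring = in_ring)
}

# Basic substructures: sp3 amines bonded only to carbon/hydrogen (no amide,
# no N-heteroatom bond), plus amidine/guanidine groups matched as the
# central carbon with its nitrogen neighbours.
basic_matches <- function(p) {
  out <- list()
  amine <- which(
    p$element == "N" & !p$aromatic & p$connections == 3 &
      purrr::map_lgl(p$double_to, ~ length(.x) == 0) &
      purrr::map_lgl(p$neighbours, ~ all(p$element[.x] %in% c("C", "H"))))
  # drop amide-like N (neighbour carbon double-bonded to O)
  amine <- amine[!purrr::map_lgl(amine, function(i) {
    any(purrr::map_lgl(p$neighbours[[i]], function(j) {
      p$element[j] == "C" && any(p$element[p$double_to[[j]]] == "O")
    }))
  })]
  out <- c(out, as.list(amine))
  amidine_c <- which(
    p$element == "C" &
      purrr::map_lgl(p$double_to, ~ any(p$element[.x] == "N")) &
      purrr::map_lgl(p$neighbours, ~ sum(p$element[.x] == "N") >= 2))
  for (i in amidine_c) {
    out[[length(out) + 1]] <-
      sort(c(i, p$neighbours[[i]][p$element[p$neighbours[[i]]] == "N"]))
  }
  out
}

# Acidic substructures: carboxylic/carboxylate and their sulfur/phosphorus
# analogues, matched as {central atom, involved oxygens}.
acidic_matches <- function(p) {
  centres <- which(
    p$element %in% c("C", "S", "P") &
      purrr::map_lgl(p$double_to, ~ any(p$element[.x] == "O")))
  out <- list()
  for (i in centres) {
    nbs <- p$neighbours[[i]]
    o_dbl <- intersect(p$double_to[[i]], which(p$element == "O"))
    o_sgl <- setdiff(nbs[p$element[nbs] == "O"], o_dbl)
    o_acidic <- o_sgl[p$charge[o_sgl] < 0 | p$total_h[o_sgl] >= 1]
    if (length(o_dbl) >= 1 && length(o_acidic) >= 1) {
      out[[length(out) + 1]] <- sort(c(i, o_dbl, o_acidic))
    }
  }
  out
}
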