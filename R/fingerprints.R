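# Binary contact fingerprints over a class-wide contact union.

#' Build a class-specific fingerprint matrix from contact maps
#'
#' The column set is the union of contacts over all member maps, restricted
#' to contacts whose both positions are resolved in every member structure;
#' each structure's row is the bit vector of which of those contacts it
#' forms.
#'
#' @param maps List of `contact_map` objects (at least two).
#' @param class_label GPCR class label stored on the matrix.
#' @param states Optional named character vector mapping structure id to
#'   activation state (`"active"`, `"intermediate"`, `"inactive"`,
#'   `"unknown"`).
#' @param resolved Optional list (named by structure id, or in map order) of
#'   the generic positions resolved in each structure. By default the
#'   positions appearing in each structure's own contact map are used; pass
#'   the true resolved sets when structures have contact-free resolved
#'   positions.
#' @return A `fingerprint_matrix`: list with `gpcr_class`, `structures`
#'   (tibble of `structure_id`, `state`), `contacts` (column labels) and
#'   `matrix` (binary, structures x contacts).
#' @export
build_fingerprints <- function(maps, class_label = NA_character_,
                               states = NULL, resolved = NULL) {
  if (length(maps) < 2) abort("need at least two contact maps")
  ids <- purrr::map_chr(maps, ~ .x$structure_id[1] %||% NA_character_)
  ids[is.na(ids)] <- paste0("structure", seq_along(maps))[is.na(ids)]
  if (is.null(resolved)) {
    resolved <- purrr::map(maps, ~ unique(c(.x$pos_a, .x$pos_b)))
  } else if (!is.null(names(resolved))) {
    resolved <- resolved[ids]
  }
  common <- Reduce(intersect, resolved)
  if (length(common) == 0) {
    abort("no generic position is resolved in every structure")
  }
  all_contacts <- bind_rows(purrr::map(maps, ~ .x[, c("pos_a", "pos_b", "contact")])) %>%
    distinct(.data$contact, .keep_all = TRUE) %>%
    filter(.data$pos_a %in% common, .data$pos_b %in% common)
  pa <- gn_parse(all_contacts$pos_a)
  pb <- gn_parse(all_contacts$pos_b)
  all_contacts <- all_contacts[order(pa$helix, pa$position,
                                     pb$helix, pb$position), ]
  m <- matrix(0L, nrow = length(maps), ncol = nrow(all_contacts),
              dimnames = list(ids, all_contacts$contact))
  for (i in seq_along(maps)) {
    m[i, ] <- as.integer(all_contacts$contact %in% maps[[i]]$contact)
  }
  st <- if (is.null(states)) rep("unknown", length(ids)) else {
    unname(states[ids]) %>% tidyr::replace_na("unknown")
  }
  new_fingerprint_matrix(m, class_label, tibble(structure_id = ids, state = st))
}

new_fingerprint_matrix <- function(m, class_label, structures) {
  structure(list(gpcr_class = class_label, structures = structures,
                 contacts = colnames(m), matrix = m),
            class = "fingerprint_matrix")
}

#' @export
print.fingerprint_matrix <- function(x, ...) {
  cat("<fingerprint_matrix> class ", x$gpcr_class, ": ",
      nrow(x$matrix), " structures x ", ncol(x$matrix), " contacts\n",
      sep = "")
  invisible(x)
}

#' @export
as_tibble.fingerprint_matrix <- function(x, ...) {
  tidyr::expand_grid(structure_id = rownames(x$matrix),
                     contact = colnames(x$matrix)) %>%
    mutate(bit = as.integer(t(x$matrix))) %>%
    left_join(x$structures, by = "structure_id") %>%
    select("structure_id", "state", "contact", "bit")
}

#' Write / read a fingerprint matrix as TSV
#'
#' The header row carries the contact labels (`"3.50-6.30"`), the first two
#' columns the structure id and state.
#'
#' @param fp A `fingerprint_matrix`.
#' @param path File path.
#' @param class_label Class label to attach on read.
#' @return `write_fingerprints()`: `path` invisibly; `read_fingerprints()`:
#'   a `fingerprint_matrix`.
#' @export
write_fingerprints <- function(fp, path) {
  df <- data.frame(structure_id = fp$structures$structure_id,
                   state = fp$structures$state,
                   fp$matrix, check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path, class_label = NA_character_) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -(1:2)])
  storage.mode(m) <- "integer"
  rownames(m) <- df$structure_id
  new_fingerprint_matrix(m, class_label,
                         tibble(structure_id = df$structure_id,
                                state = df$state))
}
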