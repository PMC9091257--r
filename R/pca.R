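# Principal component analysis of contact fingerprints and the selection of
# clearly active / clearly inactive structures.

#' PCA of a contact fingerprint matrix
#'
#' Structures are samples, contacts are variables. The binary matrix is
#' mean-centred (no variance scaling) and decomposed by singular values;
#' components are ordered by explained variance. Signs are fixed
#' deterministically: each component is flipped so that the mean score of
#' inactive-labelled structures is at least that of active-labelled ones
#' (falling back, when a state group is absent, to making the
#' largest-magnitude loading positive). Under this convention a positive
#' loading marks a contact associated with the inactive state.
#'
#' @param fp A `fingerprint_matrix`.
#' @param n_components Number of components to keep (default 10, capped at
#'   the matrix rank bound).
#' @return A `contact_pca`: list with `scores` (tibble: `structure_id`,
#'   `state`, `PC1`, ...), `loadings` (tibble: `contact`, `PC1`, ...),
#'   `explained_variance_ratio`, `sign_convention` and `gpcr_class`.
#' @examples
#' coh <- make_fingerprint_cohort(cohort_spec(seed = 1))
#' pca <- run_pca(coh$fingerprints)
#' glance(pca)
#' @export
run_pca <- function(fp, n_components = 10) {
  m <- fp$matrix
  if (nrow(m) < 2 || ncol(m) < 2) abort("need >= 2 structures and >= 2 contacts")
  k <- min(n_components, nrow(m) - 1, ncol(m))
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  total_var <- sum(pc$sdev^2)
  if (total_var < 1e-24) {
    warn("zero-variance fingerprint matrix: all components are zero")
    evr <- rep(0, k)
  } else {
    evr <- (pc$sdev^2 / total_var)[seq_len(k)]
  }
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]

  st <- fp$structures$state
  has_both <- any(st == "inactive") && any(st == "active")
  for (j in seq_len(k)) {
    flip <- if (has_both) {
      mean(scores[st == "inactive", j]) < mean(scores[st == "active", j])
    } else {
      loadings[which.max(abs(loadings[, j])), j] < 0
    }
    if (flip) {
      scores[, j] <- -scores[, j]
      loadings[, j] <- -loadings[, j]
    }
  }
  structure(
    list(
      scores = bind_cols(fp$structures, as_tibble(scores)),
      loadings = bind_cols(tibble(contact = colnames(m)), as_tibble(loadings)),
      explained_variance_ratio = unname(evr),
      sign_convention = if (has_both) {
        "mean inactive score >= mean active score per component"
      } else "largest-magnitude loading positive",
      gpcr_class = fp$gpcr_class),
    class = "contact_pca")
}

#' @importFrom dplyr bind_cols
#' @export
print.contact_pca <- function(x, ...) {
  cat("<contact_pca> class ", x$gpcr_class, ": ", nrow(x$scores),
      " structures, ", nrow(x$loadings), " contacts, ",
      length(x$explained_variance_ratio), " components\n", sep = "")
  cat("  variance ratio: ",
      paste(sprintf("%.3f", head(x$explained_variance_ratio, 5)),
            collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @describeIn run_pca Loadings in long form (`contact`, `component`,
#'   `loading`, `coeff_norm` within component).
#' @param x A `contact_pca`.
#' @param ... Unused.
#' @export
tidy.contact_pca <- function(x, ...) {
  x$loadings %>%
    tidyr::pivot_longer(-"contact", names_to = "component",
                        values_to = "loading") %>%
    group_by(.data$component) %>%
    mutate(coeff_norm = abs(.data$loading) / max(abs(.data$loading))) %>%
    ungroup()
}

#' @describeIn run_pca One-row summary (structures, contacts, variance
#'   explained by PC1 and PC1+PC2).
#' @export
glance.contact_pca <- function(x, ...) {
  evr <- x$explained_variance_ratio
  tibble(n_structures = nrow(x$scores), n_contacts = nrow(x$loadings),
         var_pc1 = evr[1], var_pc12 = sum(evr[seq_len(min(2, length(evr)))]))
}

#' @describeIn run_pca Score plot of the first two components coloured by
#'   activation state.
#' @param object A `contact_pca`.
#' @export
autoplot.contact_pca <- function(object, ...) {
  evr <- object$explained_variance_ratio
  ggplot(object$scores,
         aes(.data$PC1, .data$PC2, colour = .data$state)) +
    geom_point(size = 2) +
    labs(x = sprintf("PC1 (%.1f%%)", 100 * evr[1]),
         y = sprintf("PC2 (%.1f%%)", 100 * evr[2]),
         colour = "state") +
    theme_minimal()
}

#' Select clearly active / clearly inactive structures
#'
#' For class A, structures with `PC1 > inactive_pc1` form the clear
#' inactive set and structures with `PC2 > active_pc2` the clear active set
#' (defaults 7 and 7.5). For class B1, structures with
#' `PC1 > b1_drop_pc1` (default 3) are discarded and the remaining
#' labelled active/inactive structures are kept. An explicit `outliers` id
#' list is always removed. The returned subset feeds a re-calculated PCA in
#' which the first component separates the states.
#'
#' @param pca A `contact_pca` computed on the full class.
#' @param gpcr_class `"A"` or `"B1"`; defaults to the class recorded on the
#'   PCA.
#' @param inactive_pc1,active_pc2 Class A score thresholds.
#' @param b1_drop_pc1 Class B1 PC1 drop threshold.
#' @param outliers Structure ids to remove unconditionally.
#' @return Tibble with `structure_id`, `state` (input label) and
#'   `clear_state` (`"active"` or `"inactive"`), one row per selected
#'   structure.
#' @export
select_clear_states <- function(pca, gpcr_class = NULL,
                                inactive_pc1 = 7, active_pc2 = 7.5,
                                b1_drop_pc1 = 3, outliers = character()) {
  gpcr_class <- gpcr_class %||% pca$gpcr_class
  if (is.na(gpcr_class)) gpcr_class <- "A"
  sc <- filter(pca$scores, !.data$structure_id %in% outliers)
  if (identical(gpcr_class, "B1")) {
    out <- sc %>%
      filter(.data$PC1 <= b1_drop_pc1,
             .data$state %in% c("active", "inactive")) %>%
      mutate(clear_state = .data$state)
  } else {
    inact <- sc$PC1 > inactive_pc1
    act <- sc$PC2 > active_pc2
    # a structure passing both thresholds goes with its larger score
    to_inactive <- inact & (!act | sc$PC1 >= sc$PC2)
    out <- sc %>%
      mutate(clear_state = dplyr::case_when(
        to_inactive ~ "inactive",
        act ~ "active",
        TRUE ~ NA_character_)) %>%
      filter(!is.na(.data$clear_state))
  }
  if (!any(out$clear_state == "active") || !any(out$clear_state == "inactive")) {
    abort("clear-state selection left an empty active or inactive set; review thresholds")
  }
  select(out, "structure_id", "state", "clear_state")
}

#' Re-run the fingerprint PCA on the clear-state subset
#'
#' Convenience wrapper: subsets the fingerprint matrix to the selected
#' structures (relabelled by their clear state) and recomputes [run_pca()].
#'
#' @param fp The full `fingerprint_matrix`.
#' @param clear Selection tibble from [select_clear_states()].
#' @param n_components Components to keep.
#' @return A `contact_pca` on the subset.
#' @export
recalculate_pca <- function(fp, clear, n_components = 10) {
  idx <- match(clear$structure_id, fp$structures$structure_id)
  sub <- new_fingerprint_matrix(
    fp$matrix[idx, , drop = FALSE], fp$gpcr_class,
    tibble(structure_id = clear$structure_id, state = clear$clear_state))
  run_pca(sub, n_components)
}
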