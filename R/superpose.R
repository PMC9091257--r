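# Rigid-body least-squares superposition on shared generically numbered CA.

#' Superpose one structure onto another
#'
#' Least-squares rigid-body fit (Kabsch algorithm) on the CA atoms of the
#' generic positions present in both structures. This is deliberately a
#' simple superposition for aligned/synthetic coordinates; it is not a
#' structure-alignment method.
#'
#' @param mobile,reference `gpcr_structure` objects sharing at least three
#'   generic positions with CA atoms.
#' @return A list of class `superposition`: `rotation` (3x3, applied to
#'   centred mobile coordinates), `translation` (length-3), `rmsd`
#'   (Angstrom, over the shared CA set), `positions` (the generic numbers
#'   used). The fitted mobile coordinate of a point p is
#'   `rotation %*% (p - mobile_centroid) + translation`.
#' @examples
#' b <- make_bundle(bundle_spec(seed = 3))
#' superpose(b$structure, b$structure)$rmsd
#' @export
superpose <- function(mobile, reference) {
  m_ca <- ca_by_gn(mobile)
  r_ca <- ca_by_gn(reference)
  shared <- intersect(m_ca$generic_number, r_ca$generic_number)
  if (length(shared) < 3) {
    abort(paste0("only ", length(shared),
                 " shared generically numbered CA positions (need >= 3)"))
  }
  M <- as.matrix(m_ca[match(shared, m_ca$generic_number), c("x", "y", "z")])
  R <- as.matrix(r_ca[match(shared, r_ca$generic_number), c("x", "y", "z")])
  cm <- colMeans(M)
  cr <- colMeans(R)
  Mc <- sweep(M, 2, cm)
  Rc <- sweep(R, 2, cr)
  s <- svd(crossprod(Mc, Rc))
  d <- sign(det(s$v %*% t(s$u)))
  U <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- Mc %*% t(U)
  rmsd <- sqrt(mean(rowSums((fitted - Rc)^2)))
  structure(list(rotation = U, translation = cr, rmsd = rmsd,
                 positions = shared),
            class = "superposition")
}

ca_by_gn <- function(structure) {
  structure$atoms %>%
    filter(.data$atom == "CA", !is.na(.data$generic_number)) %>%
    distinct(.data$generic_number, .keep_all = TRUE) %>%
    select("generic_number", "x", "y", "z")
}

#' @export
print.superposition <- function(x, ...) {
  cat("<superposition> ", length(x$positions), " shared CA positions, rmsd ",
      sprintf("%.4f", x$rmsd), " A\n", sep = "")
  invisible(x)
}
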