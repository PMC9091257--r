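# Receptorome-wide sequence identity, similarity and polarity of
# site-defining residues.

#' Residue physicochemical class table
#'
#' Five-way classification used for sequence similarity: polar, apolar,
#' positively charged, negatively charged, aromatic. The packaged default
#' places H with the positives, C with the apolars, and the aromatics
#' (F, W, Y) in their own class; alternatives are one TSV edit away.
#'
#' @param path TSV with columns `aa` and `class`.
#' @return Named character vector mapping one-letter code to class; all 20
#'   amino acids must be assigned exactly once.
#' @examples
#' table(default_residue_classes())
#' @export
default_residue_classes <- function(path = pocketome_extdata("residue_classes.tsv")) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  classes <- setNames(tab$class, tab$aa)
  if (!setequal(names(classes), .aa1) || anyDuplicated(names(classes))) {
    abort("residue class table must assign each of the 20 amino acids exactly once")
  }
  ok <- c("polar", "apolar", "positive", "negative", "aromatic")
  if (!all(classes %in% ok)) {
    abort(paste0("residue classes must be one of: ", paste(ok, collapse = ", ")))
  }
  classes
}

#' Extract per-receptor site sequences
#'
#' For each receptor, reads off the residue letter at every site position
#' via the numbering table (author position indexes the full sequence); a
#' gap (`"-"`) marks positions the receptor lacks. Receptors with all-gap
#' rows are excluded with a warning.
#'
#' @param seqs Named character vector of full receptor sequences (names are
#'   receptor ids), as from [read_receptor_fasta()].
#' @param numbering Numbering tibble from [read_numbering_table()].
#' @param site_positions Character vector of generic numbers defining the
#'   site (see [site_positions()]).
#' @return A `site_sequence_table`: tibble with `receptor_id` and one
#'   character column per site position, plus a `row` column with the
#'   concatenated symbols.
#' @export
extract_site_sequences <- function(seqs, numbering, site_positions) {
  ids <- names(seqs)
  rows <- purrr::map_chr(ids, function(rid) {
    num <- filter(numbering, .data$receptor_id == rid)
    at <- num$author_pos[match(site_positions, num$generic_number)]
    letters_ <- ifelse(is.na(at) | at > nchar(seqs[[rid]]), "-",
                       substring(seqs[[rid]], at, at))
    paste(letters_, collapse = "")
  })
  tab <- tibble(receptor_id = ids, row = rows)
  all_gap <- rows == strrep("-", length(site_positions))
  if (any(all_gap)) {
    warn(paste0("receptor(s) with no mapped site position excluded: ",
                paste(ids[all_gap], collapse = ", ")))
    tab <- tab[!all_gap, ]
  }
  structure(tab, positions = site_positions,
            class = c("site_sequence_table", class(tibble())))
}

#' Pairwise identity and similarity matrices for a site
#'
#' Identity is the percentage of compared positions with the same residue;
#' similarity the percentage falling in the same physicochemical class.
#' Positions gapped in either member of a pair are excluded from that
#' pair's denominator; a pair with no comparable positions is reported as
#' `NA`.
#'
#' @param table A `site_sequence_table`.
#' @param classes Residue class table from [default_residue_classes()].
#' @return A `pair_matrices` object: list of two symmetric percentage
#'   matrices (`identity`, `similarity`) with 100 on the diagonal.
#' @examples
#' ss <- make_site_sequences(4, paste0("5.", 51:55), conservation = 1, seed = 1)
#' pm <- pairwise_matrices(ss$table)
#' pm$identity
#' @export
pairwise_matrices <- function(table, classes = default_residue_classes()) {
  n <- nrow(table)
  if (n < 2) abort("need at least two receptors")
  chars <- do.call(rbind, strsplit(table$row, ""))
  cls <- matrix(classes[chars], nrow = n)
  ident <- simil <- matrix(NA_real_, n, n,
                           dimnames = list(table$receptor_id,
                                           table$receptor_id))
  diag(ident) <- diag(simil) <- 100
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- chars[i, ] != "-" & chars[j, ] != "-"
      if (!any(ok)) next
      ident[i, j] <- ident[j, i] <- 100 * mean(chars[i, ok] == chars[j, ok])
      simil[i, j] <- simil[j, i] <- 100 * mean(cls[i, ok] == cls[j, ok])
    }
  }
  structure(list(identity = ident, similarity = simil),
            class = "pair_matrices")
}

#' @export
print.pair_matrices <- function(x, ...) {
  off <- x$similarity[upper.tri(x$similarity)]
  cat("<pair_matrices> ", nrow(x$identity), " receptors; mean identity ",
      sprintf("%.1f", mean(x$identity[upper.tri(x$identity)], na.rm = TRUE)),
      "%, mean similarity ", sprintf("%.1f", mean(off, na.rm = TRUE)),
      "%\n", sep = "")
  invisible(x)
}

#' @describeIn pairwise_matrices Long-form tibble of the unordered pairs.
#' @param x A `pair_matrices` object.
#' @param ... Unused.
#' @export
tidy.pair_matrices <- function(x, ...) {
  ids <- rownames(x$identity)
  idx <- which(upper.tri(x$identity), arr.ind = TRUE)
  tibble(receptor_a = ids[idx[, 1]], receptor_b = ids[idx[, 2]],
         identity = x$identity[idx], similarity = x$similarity[idx])
}

#' @describeIn pairwise_matrices Heat map of the similarity matrix.
#' @param object A `pair_matrices` object.
#' @export
autoplot.pair_matrices <- function(object, ...) {
  tidy(object) %>%
    ggplot(aes(.data$receptor_a, .data$receptor_b,
               fill = .data$similarity)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, 100)) +
    labs(x = NULL, y = NULL, fill = "similarity (%)") +
    theme_minimal()
}

#' Site polarity
#'
#' Per receptor, the fraction of non-gap site positions whose residue class
#' is polar or charged (aromatic counts as apolar), and the average across
#' receptors.
#'
#' @param table A `site_sequence_table`.
#' @param classes Residue class table.
#' @return List with `per_receptor` (tibble of `receptor_id`,
#'   `polar_fraction`) and `average`.
#' @export
site_polarity <- function(table, classes = default_residue_classes()) {
  polar_classes <- c("polar", "positive", "negative")
  fr <- purrr::map_dbl(table$row, function(row) {
    ch <- strsplit(row, "")[[1]]
    ch <- ch[ch != "-"]
    if (length(ch) == 0) return(NA_real_)
    mean(classes[ch] %in% polar_classes)
  })
  list(per_receptor = tibble(receptor_id = table$receptor_id,
                             polar_fraction = fr),
       average = mean(fr, na.rm = TRUE))
}

#' Read receptor sequences from FASTA
#'
#' @param path FASTA file keyed by receptor id.
#' @return Named character vector of sequences.
#' @export
read_receptor_fasta <- function(path) {
  fa <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                           forceDNAtolower = FALSE)
  setNames(toupper(unlist(fa)), names(fa))
}

#' Write receptor sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_receptor_fasta <- function(seqs, path) {
  seqinr::write.fasta(as.list(unname(seqs)), names(seqs), path)
  invisible(path)
}
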