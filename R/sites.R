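#' Classify alignment columns by parsimony status on a tree
#'
#' Per column: the number of distinct non-gap states, whether the column is
#' parsimony-informative (at least two states each present in at least two
#' sequences, gaps excluded), the unconstrained minimum number of changes
#' (`distinct states - 1`), the Fitch step count on the supplied topology,
#' and the derived flags: *supporting* (informative and achieving the
#' minimum) and *homoplasic* (requiring parallel or reverse substitutions,
#' i.e. steps on the tree exceed the minimum). For coding regions with a
#' declared frame, a *synonymous* flag marks columns where every observed
#' gap-free codon variant encodes the same amino acid.
#'
#' @param x An [msa] object.
#' @param tree A `phylo` topology whose tips match the alignment labels.
#' @param coding Optional character vector of region names to treat as
#'   coding; by default every region with a non-`NA` frame. Naming a region
#'   without a frame is an error.
#' @return Tibble with one row per column: `site` (0-based), `region`,
#'   `codon_pos` (0/1/2 within codons, `NA` outside coding), `n_states`,
#'   `informative`, `min_steps`, `steps_on_tree`, `supporting`,
#'   `homoplasic`, `synonymous`.
#' @export
classify_sites <- function(x, tree, coding = NULL) {
  if (!setequal(tree$tip.label, x$labels)) {
    abort("tree leaves must equal alignment labels")
  }
  mat <- x$mat
  L <- ncol(mat)
  masks <- matrix(nt_bitmask(mat), nrow = nrow(mat),
                  dimnames = list(rownames(mat), NULL))
  steps <- fitch_count(tree, masks, full_mask = 15L)

  n_states <- integer(L); informative <- logical(L)
  for (s in seq_len(L)) {
    col <- mat[, s]
    col <- col[!is_gapish(col)]
    tab <- table(col)
    n_states[s] <- length(tab)
    informative[s] <- sum(tab >= 2L) >= 2L
  }
  min_steps <- pmax(n_states - 1L, 0L)

  region_of <- rep(NA_character_, L)
  codon_pos <- rep(NA_integer_, L)
  synonymous <- rep(NA, L)
  if (!is.null(x$regions)) {
    coding_regions <- resolve_coding_regions(x$regions, coding)
    for (k in seq_len(nrow(x$regions))) {
      r <- x$regions[k, ]
      idx <- (r$start + 1L):r$end
      region_of[idx] <- r$region
      if (r$region %in% coding_regions) {
        frame <- x$regions$frame[k]
        pos <- ((seq_along(idx) - 1L) + frame) %% 3L
        codon_pos[idx] <- pos
        synonymous[idx] <- synonymous_flags(mat[, idx, drop = FALSE], frame)
      }
    }
  }
  tibble(site = 0:(L - 1L), region = region_of, codon_pos = codon_pos,
         n_states = n_states, informative = informative,
         min_steps = min_steps, steps_on_tree = as.integer(steps),
         supporting = informative & steps == min_steps,
         homoplasic = steps > min_steps,
         synonymous = synonymous)
}

resolve_coding_regions <- function(regions, coding) {
  with_frame <- regions$region[!is.na(regions$frame)]
  if (is.null(coding)) return(with_frame)
  missing_frame <- setdiff(coding, with_frame)
  if (length(missing_frame)) {
    abort(sprintf("frame missing for coding region(s): %s",
                  paste(missing_frame, collapse = ", ")))
  }
  coding
}

# For each column of a coding block, TRUE when all observed complete codons
# (no gap/N in the codon) encode a single amino acid. Columns in incomplete
# trailing codons stay NA.
synonymous_flags <- function(block, frame) {
  L <- ncol(block)
  out <- rep(NA, L)
  # frame is the GFF-style phase: bases to skip before the first full codon
  starts <- seq(frame %% 3L + 1L, L - 2L, by = 3L)
  gc <- Biostrings::GENETIC_CODE
  for (s in starts) {
    codons <- paste0(block[, s], block[, s + 1L], block[, s + 2L])
    codons <- codons[!grepl("[-N]", codons)]
    if (!length(codons)) next
    aas <- gc[codons]
    same <- length(unique(aas)) == 1L && !any(is.na(aas))
    out[s:(s + 2L)] <- same
  }
  out
}

#' Pairwise codon degeneracy of third positions
#'
#' Classifies every complete-codon third position for a pair of sequences
#' following the pairwise two-fold-site procedure: a third position counts
#' as two-fold for the pair only when *both* sequences' codons make it
#' two-fold (exactly two nucleotides at the third position preserve the
#' encoded amino acid). Codons containing gaps or `N` are skipped; codons
#' translating to a stop trigger a warning and are excluded.
#'
#' @param x An [msa] object.
#' @param pair Character vector of two labels.
#' @param coding Optional coding-region names (default: regions with frame).
#' @return Tibble: `site` (0-based third-position column), `region`,
#'   `codon_a`, `codon_b`, `fold_a`, `fold_b` (degeneracy 0/2/3/4),
#'   `two_fold_pair`, `unchanged` (identical third-position base).
#' @export
degeneracy_pairwise <- function(x, pair, coding = NULL) {
  stopifnot(length(pair) == 2L, all(pair %in% x$labels))
  if (is.null(x$regions)) abort("msa has no region map")
  coding_regions <- resolve_coding_regions(x$regions, coding)
  if (!length(coding_regions)) abort("no coding regions declared")
  rows <- list()
  n_stop <- 0L
  for (k in which(x$regions$region %in% coding_regions)) {
    r <- x$regions[k, ]
    idx <- (r$start + 1L):r$end
    block <- x$mat[pair, idx, drop = FALSE]
    starts <- seq(r$frame %% 3L + 1L, length(idx) - 2L, by = 3L)
    for (s in starts) {
      ca <- paste0(block[1, s], block[1, s + 1L], block[1, s + 2L])
      cb <- paste0(block[2, s], block[2, s + 1L], block[2, s + 2L])
      if (grepl("[-N]", ca) || grepl("[-N]", cb)) next
      fa <- codon_fold(ca); fb <- codon_fold(cb)
      if (is.na(fa) || is.na(fb)) { n_stop <- n_stop + 1L; next }
      rows[[length(rows) + 1L]] <- tibble(
        site = r$start + s + 1L,  # 0-based column of the third position
        region = r$region, codon_a = ca, codon_b = cb,
        fold_a = fa, fold_b = fb,
        two_fold_pair = fa == 2L && fb == 2L,
        unchanged = substr(ca, 3, 3) == substr(cb, 3, 3))
    }
  }
  if (n_stop > 0L) warn(sprintf("%d codon(s) with internal stop excluded", n_stop))
  if (!length(rows)) {
    return(tibble(site = integer(), region = character(), codon_a = character(),
                  codon_b = character(), fold_a = integer(), fold_b = integer(),
                  two_fold_pair = logical(), unchanged = logical()))
  }
  bind_rows(rows)
}

# Third-position degeneracy of a codon under the standard genetic code:
# number of third-position nucleotides preserving the amino acid, reported
# in the conventional 0/2/3/4-fold labels (1 synonymous option -> 0-fold).
# NA for stop codons.
codon_fold <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[[codon]]
  if (is.null(aa) || aa == "*") return(NA_integer_)
  stem <- substr(codon, 1, 2)
  alts <- gc[paste0(stem, NT_LEVELS)]
  n_syn <- sum(alts == aa, na.rm = TRUE)
  c(0L, 2L, 3L, 4L)[n_syn]
}
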