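#' Construct an aligned, region-annotated sequence set
#'
#' The `msa` object is the universal substrate of the package: a set of
#' aligned sequences over the alphabet `{A, C, G, T, -, N}`, an optional
#' ordered region map (e.g. introns and exons) in 0-based half-open
#' alignment coordinates, and a species tag for every sequence.
#'
#' @param seqs Named character vector of aligned sequences (equal lengths),
#'   or a character matrix with one row per sequence.
#' @param species Named character vector mapping labels to species tags.
#'   When `NULL`, the tag is taken as the part of each label before the
#'   first underscore (e.g. `"Mac_ADH1.1"` is species `"Mac"`).
#' @param regions Optional tibble/data frame with columns `region`, `start`,
#'   `end` and optionally `frame` (0, 1 or 2 for coding regions, `NA`
#'   otherwise). Regions must tile `[0, width)` without overlap.
#' @param ambiguous How to treat IUPAC ambiguity codes other than `N`:
#'   `"error"` (default) or `"to_n"` (silently mapped to `N`).
#'
#' @return An object of class `msa`: a list with elements `mat` (character
#'   matrix, rows = sequences), `labels`, `species`, and `regions`.
#' @export
msa <- function(seqs, species = NULL, regions = NULL, ambiguous = c("error", "to_n")) {
  ambiguous <- match.arg(ambiguous)
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    if (is.null(names(seqs))) abort("sequences must be named")
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      abort(sprintf(
        "ragged alignment: sequence lengths differ (%s)",
        paste(unique(lens), collapse = ", ")))
    }
    mat <- do.call(rbind, strsplit(toupper(unname(seqs)), "", fixed = TRUE))
    rownames(mat) <- names(seqs)
  }
  mat[] <- toupper(mat)
  labels <- rownames(mat)
  if (is.null(labels)) abort("sequences must be named")
  if (anyDuplicated(labels)) {
    abort(sprintf("duplicate labels: %s",
                  paste(unique(labels[duplicated(labels)]), collapse = ", ")))
  }
  bad <- !(mat %in% c(NT_LEVELS, "-", "N"))
  if (any(bad)) {
    if (ambiguous == "to_n") {
      mat[bad] <- "N"
    } else {
      abort(sprintf("unsupported characters in alignment: %s (use ambiguous = \"to_n\")",
                    paste(unique(mat[bad]), collapse = ", ")))
    }
  }
  if (is.null(species)) {
    species <- setNames(sub("_.*$", "", labels), labels)
  } else {
    species <- species[labels]
    if (any(is.na(species))) abort("every label needs a species tag")
  }
  regions <- validate_regions(regions, ncol(mat))
  structure(
    list(mat = mat, labels = labels, species = setNames(as.character(species), labels),
         regions = regions),
    class = "msa")
}

validate_regions <- function(regions, width) {
  if (is.null(regions)) return(NULL)
  regions <- as_tibble(regions)
  if (!all(c("region", "start", "end") %in% names(regions))) {
    abort("region map needs columns `region`, `start`, `end`")
  }
  if (!"frame" %in% names(regions)) regions$frame <- NA_integer_
  regions <- regions[order(regions$start), , drop = FALSE]
  if (any(regions$start < 0) || any(regions$end > width) ||
      any(regions$end <= regions$start)) {
    abort("regions must satisfy 0 <= start < end <= alignment width")
  }
  if (nrow(regions) > 1L &&
      any(regions$start[-1L] < regions$end[-nrow(regions)])) {
    abort("region overlap: regions must not overlap")
  }
  regions$frame <- as.integer(regions$frame)
  regions
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns\n", nrow(x$mat), ncol(x$mat)))
  cat("  species:", paste(unique(x$species), collapse = ", "), "\n")
  if (!is.null(x$regions)) {
    cat(sprintf("  regions: %d (%s)\n", nrow(x$regions),
                paste(utils::head(x$regions$region, 5), collapse = ", ")))
  }
  invisible(x)
}

#' @export
dim.msa <- function(x) dim(x$mat)

#' Alignment width (number of columns)
#' @param x An [msa] object.
#' @return Integer number of alignment columns.
#' @export
msa_width <- function(x) ncol(x$mat)

#' Read an alignment from FASTA, optionally with a region map
#'
#' Sequences are uppercased on input. Ambiguity codes other than `N` are
#' rejected unless `ambiguous = "to_n"`. The optional region map is a
#' 4-column TSV (`region`, `start`, `end`, `frame`) with 0-based half-open
#' coordinates; `frame` is `NA` for non-coding regions.
#'
#' @param path Path to an aligned FASTA file.
#' @param region_map Optional path to a region-map TSV.
#' @inheritParams msa
#' @return An [msa] object.
#' @export
read_msa <- function(path, region_map = NULL, species = NULL,
                     ambiguous = c("error", "to_n")) {
  set <- Biostrings::readBStringSet(path)
  seqs <- setNames(as.character(set), names(set))
  regions <- if (!is.null(region_map)) read_region_map(region_map) else NULL
  msa(seqs, species = species, regions = regions, ambiguous = ambiguous)
}

#' Read a region map TSV
#'
#' @param path Path to a TSV with columns `region`, `start`, `end`, `frame`.
#' @return A tibble (not yet validated against an alignment width).
#' @export
read_region_map <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    region = readr::col_character(),
    start = readr::col_integer(),
    end = readr::col_integer(),
    frame = readr::col_integer()), comment = "#")
}

#' Write an alignment to canonical FASTA (and optional region map)
#'
#' Canonical form: one header line per sequence, sequence on a single line;
#' `read_msa()` of the output reproduces the input byte-for-byte on re-write.
#'
#' @param x An [msa] object.
#' @param path Output FASTA path.
#' @param region_map Optional output path for the region-map TSV.
#' @return `x`, invisibly.
#' @export
write_msa <- function(x, path, region_map = NULL) {
  seqs <- apply(x$mat, 1L, paste, collapse = "")
  writeLines(paste0(">", x$labels, "\n", seqs[x$labels]), path, sep = "\n")
  if (!is.null(region_map)) {
    if (is.null(x$regions)) abort("msa has no region map to write")
    readr::write_tsv(x$regions, region_map)
  }
  invisible(x)
}

#' Extract a column range or region as a new alignment
#'
#' @param x An [msa] object.
#' @param start,end 0-based half-open column range.
#' @return An [msa] restricted to the requested columns (region map dropped).
#' @export
msa_slice <- function(x, start, end) {
  if (start < 0 || end > ncol(x$mat) || end <= start) {
    abort("slice must satisfy 0 <= start < end <= width")
  }
  msa(x$mat[, (start + 1L):end, drop = FALSE], species = x$species)
}

#' Extract one named region as a new alignment
#'
#' @param x An [msa] object with a region map.
#' @param region Region name.
#' @return An [msa] of that region's columns; its region map carries the
#'   single region (re-based to 0) with its frame.
#' @export
msa_region <- function(x, region) {
  if (is.null(x$regions)) abort("msa has no region map")
  r <- x$regions[x$regions$region == region, ]
  if (nrow(r) != 1L) abort(sprintf("unknown region: %s", region))
  out <- msa_slice(x, r$start, r$end)
  out$regions <- tibble(region = r$region, start = 0L,
                        end = r$end - r$start, frame = r$frame)
  out
}

#' Concatenate alignments over an identical label set
#'
#' Rows are joined in input order and the per-input regions recorded with
#' cumulative offsets, as when per-intron alignments are concatenated into
#' one combined intronic alignment.
#'
#' @param msas List of [msa] objects with identical label sets.
#' @param names Optional character vector of region names, one per input,
#'   used for inputs that carry no region map of their own.
#' @return A single [msa]; `regions` tiles the full concatenated width.
#' @export
concatenate_msa <- function(msas, names = NULL) {
  if (length(msas) == 0L) abort("no alignments to concatenate")
  labels <- msas[[1L]]$labels
  for (i in seq_along(msas)) {
    diffs <- union(setdiff(labels, msas[[i]]$labels),
                   setdiff(msas[[i]]$labels, labels))
    if (length(diffs)) {
      abort(sprintf("label-set mismatch at input %d: %s", i,
                    paste(diffs, collapse = ", ")))
    }
  }
  if (is.null(names)) names <- paste0("region", seq_along(msas))
  mats <- lapply(msas, function(m) m$mat[labels, , drop = FALSE])
  mat <- do.call(cbind, mats)
  offs <- cumsum(c(0L, vapply(mats, ncol, integer(1))))
  regions <- purrr::imap(msas, function(m, i) {
    if (!is.null(m$regions)) {
      dplyr::mutate(m$regions, start = .data$start + offs[i],
                    end = .data$end + offs[i])
    } else {
      tibble(region = names[[i]], start = offs[i], end = offs[i + 1L],
             frame = NA_integer_)
    }
  })
  out <- msa(mat, species = msas[[1L]]$species)
  out$regions <- validate_regions(bind_rows(regions), ncol(mat))
  out
}
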