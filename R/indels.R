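#' Extract micro-indels and code them as binary characters
#'
#' Collects maximal gap runs per sequence; runs with identical start and
#' length in two or more sequences become shared presence/absence
#' characters. A sequence whose own gap strictly engulfs a character's span
#' is scored missing (`.`) for that character, since presence or absence of
#' the smaller indel is unobservable there. Singleton indels are retained
#' but flagged uninformative; runs longer than `max_len` (the "micro"
#' cutoff) are excluded.
#'
#' @param x An [msa] object.
#' @param max_len Maximum indel length retained (default 100 nt).
#' @return An `indel_matrix` object: list with `chars` (tibble: `char_id`,
#'   `start` 0-based, `length`, `n_present`, `n_absent`, `shared`,
#'   `informative`) and `states` (labels x characters character matrix over
#'   `{"0","1","."}`).
#' @export
extract_indels <- function(x, max_len = 100) {
  labels <- x$labels
  runs_by_label <- purrr::map(labels, function(lab) {
    r <- rle(x$mat[lab, ] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths  # 0-based starts
    keep <- r$values
    tibble(start = starts[keep], length = r$lengths[keep])
  })
  names(runs_by_label) <- labels
  all_runs <- bind_rows(runs_by_label, .id = "label")
  all_runs <- all_runs[all_runs$length <= max_len, , drop = FALSE]
  if (!nrow(all_runs)) {
    return(new_indel_matrix(
      tibble(char_id = character(), start = integer(), length = integer(),
             n_present = integer(), n_absent = integer(),
             shared = logical(), informative = logical()),
      matrix(character(), nrow = length(labels), ncol = 0,
             dimnames = list(labels, NULL))))
  }
  chars <- all_runs |>
    group_by(.data$start, .data$length) |>
    summarise(n_present = n(), .groups = "drop") |>
    arrange(.data$start, .data$length) |>
    mutate(char_id = sprintf("ind_%05d_%d", .data$start, .data$length))
  states <- matrix("0", nrow = length(labels), ncol = nrow(chars),
                   dimnames = list(labels, chars$char_id))
  for (lab in labels) {
    runs <- runs_by_label[[lab]]
    if (!nrow(runs)) next
    # exact matches -> present
    hit <- match(paste(chars$start, chars$length),
                 paste(runs$start, runs$length))
    states[lab, !is.na(hit)] <- "1"
    # engulfing larger gaps (any run, including > max_len) -> missing
    full <- rle(x$mat[lab, ] == "-")
    ends <- cumsum(full$lengths); starts <- ends - full$lengths
    gs <- starts[full$values]; ge <- ends[full$values]
    for (ci in which(is.na(hit))) {
      cs <- chars$start[ci]; ce <- cs + chars$length[ci]
      engulf <- any(gs <= cs & ge >= ce & !(gs == cs & ge == ce))
      if (engulf) states[lab, ci] <- "."
    }
  }
  chars$n_absent <- colSums(states == "0")
  chars$shared <- chars$n_present >= 2L
  chars$informative <- chars$n_present >= 2L & chars$n_absent >= 2L
  chars <- chars[, c("char_id", "start", "length", "n_present", "n_absent",
                     "shared", "informative")]
  new_indel_matrix(chars, states)
}

new_indel_matrix <- function(chars, states) {
  structure(list(chars = chars, states = states), class = "indel_matrix")
}

#' @export
print.indel_matrix <- function(x, ...) {
  cat(sprintf("<indel_matrix> %d characters (%d shared, %d informative) x %d sequences\n",
              nrow(x$chars), sum(x$chars$shared), sum(x$chars$informative),
              nrow(x$states)))
  invisible(x)
}

#' @rdname extract_indels
#' @param x An `indel_matrix`.
#' @param ... Unused.
#' @method tidy indel_matrix
#' @export
tidy.indel_matrix <- function(x, ...) {
  if (ncol(x$states) == 0L) {
    return(tibble(label = character(), char_id = character(),
                  state = character()) |>
             left_join(x$chars, by = "char_id"))
  }
  as_tibble(x$states, rownames = "label") |>
    tidyr::pivot_longer(-"label", names_to = "char_id", values_to = "state") |>
    left_join(x$chars, by = "char_id")
}

#' Keep only shared (or informative) characters
#' @param mim An `indel_matrix`.
#' @param informative_only Keep only parsimony-informative characters.
#' @return A filtered `indel_matrix`.
#' @export
shared_indels <- function(mim, informative_only = FALSE) {
  keep <- if (informative_only) mim$chars$informative else mim$chars$shared
  new_indel_matrix(mim$chars[keep, , drop = FALSE],
                   mim$states[, keep, drop = FALSE])
}

#' Fitch parsimony of binary indel characters on a topology
#'
#' Per character, the Fitch small-parsimony count with missing states free
#' (a missing leaf never forces a change). A character with fewer than two
#' non-missing state classes costs 0 steps and is flagged degenerate. An
#' informative character needing more than one step is homoplasic on the
#' supplied topology.
#'
#' @param mim An `indel_matrix` (its labels must be a subset of the tree
#'   leaves).
#' @param tree A `phylo` topology.
#' @param topology_id Optional name recorded in the report.
#' @return A `parsimony_report`: tibble per character (`char_id`, `steps`,
#'   `min_steps`, `homoplasic`, `degenerate`) with attributes
#'   `total_steps` and `topology_id`; see [glance()].
#' @export
fitch_steps <- function(mim, tree, topology_id = NULL) {
  if (!all(rownames(mim$states) %in% tree$tip.label)) {
    abort(sprintf("tree lacks leaves: %s",
                  paste(setdiff(rownames(mim$states), tree$tip.label),
                        collapse = ", ")))
  }
  if (nrow(mim$chars) == 0L) {
    rep <- tibble(char_id = character(), steps = integer(),
                  min_steps = integer(), homoplasic = logical(),
                  degenerate = logical())
  } else {
    masks <- matrix(bin_bitmask(mim$states), nrow = nrow(mim$states),
                    dimnames = dimnames(mim$states))
    steps <- fitch_count(tree, masks, full_mask = 3L)
    n1 <- colSums(mim$states == "1")
    n0 <- colSums(mim$states == "0")
    min_steps <- as.integer(n1 >= 1L & n0 >= 1L)
    degenerate <- (n1 + n0) < 2L | n1 == 0L | n0 == 0L
    rep <- tibble(char_id = mim$chars$char_id, steps = as.integer(steps),
                  min_steps = min_steps,
                  homoplasic = mim$chars$informative & steps > 1L,
                  degenerate = degenerate)
  }
  attr(rep, "total_steps") <- sum(rep$steps)
  attr(rep, "topology_id") <- topology_id %||% "tree"
  class(rep) <- c("parsimony_report", class(rep))
  rep
}

#' @rdname fitch_steps
#' @param x A `parsimony_report`.
#' @param ... Unused.
#' @method glance parsimony_report
#' @export
glance.parsimony_report <- function(x, ...) {
  tibble(topology = attr(x, "topology_id"),
         total_steps = attr(x, "total_steps"),
         n_characters = nrow(x),
         n_homoplasic = sum(x$homoplasic))
}

#' Rank alternative topologies by indel parsimony
#'
#' Scores each candidate topology by the total Fitch step count over the
#' binary indel characters and ranks ascending (fewest extra events first),
#' the comparison used to discriminate alternative gene-family phylogenies.
#'
#' @param mim An `indel_matrix`.
#' @param trees Named list of `phylo` topologies over the same leaves.
#' @return Tibble: `topology`, `total_steps`, `delta` (to best),
#'   `n_homoplasic`; attribute `reports` holds the per-character reports.
#' @export
compare_topologies <- function(mim, trees) {
  if (length(trees) < 2L) abort("need >= 2 topologies")
  if (is.null(names(trees))) names(trees) <- paste0("tree", seq_along(trees))
  leaf_sets <- purrr::map(trees, ~sort(.x$tip.label))
  if (length(unique(leaf_sets)) != 1L) abort("topologies must share one leaf set")
  reports <- purrr::imap(trees, ~fitch_steps(mim, .x, topology_id = .y))
  out <- purrr::map(reports, glance) |> bind_rows() |>
    arrange(.data$total_steps) |>
    mutate(delta = .data$total_steps - .data$total_steps[1L])
  attr(out, "reports") <- reports
  out
}

#' Co-localise homoplasic indels with candidate conversion regions
#'
#' Annotates each homoplasic character with any overlapping candidate
#' region and with the carrier set (labels sharing the gap), whose joint
#' state implies the conversion partner. A region corroborates a character
#' when they overlap and both members of the region's pair carry the gap.
#'
#' @param mim An `indel_matrix`.
#' @param tree The reference topology (homoplasy is tree-relative).
#' @param regions Candidate regions from [candidate_regions()].
#' @return Tibble, one row per homoplasic character x overlapping region
#'   (orphan characters keep one row with `NA` region): `char_id`, `start`,
#'   `length`, `carriers`, `region_start`, `region_end`, `region_pair`,
#'   `corroborating`.
#' @export
colocalize_indels <- function(mim, tree, regions) {
  rep <- fitch_steps(mim, tree)
  homop <- rep$char_id[rep$homoplasic]
  if (!length(homop)) {
    return(tibble(char_id = character(), start = integer(), length = integer(),
                  carriers = character(), region_start = integer(),
                  region_end = integer(), region_pair = character(),
                  corroborating = logical()))
  }
  chars <- mim$chars[mim$chars$char_id %in% homop, ]
  purrr::pmap(chars[, c("char_id", "start", "length")],
              function(char_id, start, length) {
    carriers <- rownames(mim$states)[mim$states[, char_id] == "1"]
    cs <- start; ce <- start + length
    if (!is.null(regions) && nrow(regions)) {
      ov <- regions[regions$start < ce & regions$end > cs, , drop = FALSE]
    } else {
      ov <- NULL
    }
    if (is.null(ov) || !nrow(ov)) {
      return(tibble(char_id = char_id, start = start, length = length,
                    carriers = paste(carriers, collapse = ","),
                    region_start = NA_integer_, region_end = NA_integer_,
                    region_pair = NA_character_, corroborating = FALSE))
    }
    corr <- ov$label_a %in% carriers & ov$label_b %in% carriers
    tibble(char_id = char_id, start = start, length = length,
           carriers = paste(carriers, collapse = ","),
           region_start = ov$start, region_end = ov$end,
           region_pair = pair_key(ov$label_a, ov$label_b),
           corroborating = corr)
  }) |> bind_rows()
}

#' Export an indel matrix as TSV or NEXUS
#'
#' @param mim An `indel_matrix`.
#' @param path Output path.
#' @param format `"tsv"` (labels x characters) or `"nexus"` (for
#'   cross-checking in standard parsimony programs).
#' @return `mim`, invisibly.
#' @export
write_indel_matrix <- function(mim, path, format = c("tsv", "nexus")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- as_tibble(mim$states, rownames = "label")
    readr::write_tsv(df, path)
  } else {
    lab <- rownames(mim$states)
    rows <- paste(format(lab, width = max(nchar(lab)) + 2L),
                  apply(mim$states, 1L, paste, collapse = ""))
    writeLines(c("#NEXUS", "BEGIN DATA;",
                 sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(mim$states),
                         ncol(mim$states)),
                 "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=.;",
                 "  MATRIX", rows, "  ;", "END;"), path)
  }
  invisible(mim)
}
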