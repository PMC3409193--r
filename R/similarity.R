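#' Sliding-window similarity scan parameters
#'
#' Defaults follow the intronic analysis conventions: 250-nt windows
#' (150 nt is conventional for exonic data), single-nucleotide step,
#' windows with more than 20% gapped sites unscored, and a 0.96 candidate
#' threshold. The threshold sits above the ~0.938 +/- 0.018 background
#' similarity of orthologous introns that diverged at the human/macaque
#' split, so that super-threshold windows flag recent conversion.
#'
#' @param window Window width in alignment columns.
#' @param step Window start increment (default 1).
#' @param max_gap_fraction Maximum tolerated fraction of gapped sites in a
#'   window; above it no score is reported.
#' @param threshold Similarity above which windows become candidates.
#' @return A `scan_params` list.
#' @export
scan_params <- function(window = 250, step = 1, max_gap_fraction = 0.20,
                        threshold = 0.96) {
  assert_scalar_number(window, "window", min = 1)
  assert_scalar_number(step, "step", min = 1, max = window)
  assert_scalar_number(max_gap_fraction, "max_gap_fraction", min = 0, max = 1 - 1e-12)
  assert_scalar_number(threshold, "threshold", min = 0, max = 1)
  structure(list(window = as.integer(window), step = as.integer(step),
                 max_gap_fraction = max_gap_fraction, threshold = threshold),
            class = "scan_params")
}

#' Windowed pairwise similarity track
#'
#' For each window position, identities score 1 and mismatches 0; sites
#' where either sequence has a gap (or `N`) are skipped, and if gapped
#' sites exceed `max_gap_fraction` of the window no score is reported.
#' The score is `identities / (window - skipped sites)`. A final partial
#' window is not scored (fixed-denominator semantics).
#'
#' @param x An [msa] object.
#' @param pair Character vector of two labels.
#' @param params A [scan_params()] object.
#' @return A `similarity_track` tibble: `label_a`, `label_b`, `start`
#'   (0-based window start), `center`, `n_used`, `n_gap`, `score` (`NA`
#'   where unscored).
#' @export
windowed_similarity <- function(x, pair, params = scan_params()) {
  stopifnot(length(pair) == 2L, all(pair %in% x$labels))
  L <- msa_width(x)
  w <- params$window
  if (w > L) abort("window larger than alignment")
  a <- x$mat[pair[1], ]; b <- x$mat[pair[2], ]
  gap <- is_gapish(a) | is_gapish(b)
  ident <- !gap & a == b
  csg <- cumsum(c(0L, gap))
  csi <- cumsum(c(0L, ident))
  starts <- seq(0L, L - w, by = params$step)
  n_gap <- csg[starts + w + 1L] - csg[starts + 1L]
  n_id <- csi[starts + w + 1L] - csi[starts + 1L]
  n_used <- w - n_gap
  score <- ifelse(n_gap > params$max_gap_fraction * w, NA_real_, n_id / n_used)
  out <- tibble(label_a = pair[1], label_b = pair[2],
                start = starts, center = starts + w / 2,
                n_used = n_used, n_gap = n_gap, score = score)
  attr(out, "params") <- params
  class(out) <- c("similarity_track", class(out))
  out
}

#' Similarity tracks for many pairs
#'
#' @param x An [msa] object.
#' @param pairs Two-column matrix/data frame of label pairs; by default all
#'   within-species pairs (the comparisons relevant for gene conversion).
#' @param params A [scan_params()] object.
#' @return A `similarity_track` tibble over all requested pairs.
#' @export
similarity_scan <- function(x, pairs = NULL, params = scan_params()) {
  if (is.null(pairs)) {
    labs <- x$labels
    cmb <- utils::combn(labs, 2)
    same <- x$species[cmb[1, ]] == x$species[cmb[2, ]]
    pairs <- t(cmb[, same, drop = FALSE])
  }
  pairs <- as.matrix(pairs)
  out <- purrr::map(seq_len(nrow(pairs)), function(i) {
    windowed_similarity(x, pairs[i, ], params)
  }) |> bind_rows()
  attr(out, "params") <- params
  class(out) <- c("similarity_track", class(out))
  out
}

#' Candidate conversion regions from similarity tracks
#'
#' Maximal runs of consecutive scored windows with score strictly above the
#' threshold, merged per pair and mapped back to alignment coordinates
#' (region end = last window start + window).
#'
#' @param tracks A `similarity_track` tibble (one or many pairs).
#' @param params A [scan_params()]; defaults to the params the track was
#'   computed with.
#' @return Tibble: `label_a`, `label_b`, `start`, `end`, `peak_score`,
#'   `n_windows`. Zero rows when nothing exceeds the threshold.
#' @export
candidate_regions <- function(tracks, params = NULL) {
  params <- params %||% attr(tracks, "params")
  if (is.null(params)) abort("supply `params` (track carries none)")
  w <- params$window; step <- params$step; thr <- params$threshold
  tracks |>
    group_by(.data$label_a, .data$label_b) |>
    group_modify(function(df, key) {
      df <- arrange(df, .data$start)
      hit <- !is.na(df$score) & df$score > thr
      if (!any(hit)) {
        return(tibble(start = integer(), end = integer(),
                      peak_score = double(), n_windows = integer()))
      }
      # runs of consecutive hits (consecutive = start advances by `step`)
      hs <- df$start[hit]; sc <- df$score[hit]
      brk <- c(TRUE, diff(hs) != step)
      run <- cumsum(brk)
      tibble(start = tapply(hs, run, min)[unique(run)] |> as.integer(),
             end = as.integer(tapply(hs, run, max)[unique(run)] + w),
             peak_score = as.numeric(tapply(sc, run, max)[unique(run)]),
             n_windows = as.integer(tapply(hs, run, length)[unique(run)]))
    }) |>
    ungroup()
}

#' @importFrom dplyr group_modify
#' @method autoplot similarity_track
#' @export
autoplot.similarity_track <- function(object, ...) {
  params <- attr(object, "params")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$center, y = .data$score,
                                            colour = paste(.data$label_a, .data$label_b, sep = " vs "))) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "alignment position", y = "windowed similarity",
                  colour = "pair") +
    ggplot2::theme_minimal()
  if (!is.null(params)) {
    p <- p + ggplot2::geom_hline(yintercept = params$threshold,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}
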