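#' Parameters for the Sawyer fragment statistic
#'
#' Defaults preserve the published run configuration: `g_scale = 1`,
#' minimum aligned fragment length 1 nt, minimum polymorphisms in a
#' fragment 2, minimum pairwise fragment score 2, at most 1 overlapping
#' fragment, alpha 0.05. The mismatch penalty within fragments follows
#' Sawyer's formulation where the penalty grows with the group polymorphism
#' count: `penalty = 1 + n_poly / g_scale` (infinite at `g_scale = 0`, i.e.
#' no mismatch tolerated); it can be overridden via `mismatch_penalty`.
#'
#' @param g_scale Mismatch penalty scale (0 = no mismatches allowed).
#' @param min_frag_len Minimum fragment span in nucleotides.
#' @param min_polymorphisms Minimum polymorphic sites within a fragment.
#' @param min_frag_score Minimum fragment score.
#' @param max_overlap_frags Maximum overlapping fragments retained.
#' @param n_permutations Permutation replicates for p-values (>= 1000
#'   recommended).
#' @param seed Optional seed applied locally during permutation.
#' @param alpha Significance level after Bonferroni correction.
#' @param mismatch_penalty Optional explicit penalty overriding the
#'   `g_scale` rule.
#' @return A `sawyer_params` list.
#' @export
sawyer_params <- function(g_scale = 1, min_frag_len = 1, min_polymorphisms = 2,
                          min_frag_score = 2, max_overlap_frags = 1,
                          n_permutations = 1000, seed = NULL, alpha = 0.05,
                          mismatch_penalty = NULL) {
  assert_scalar_number(g_scale, "g_scale", min = 0)
  assert_scalar_number(n_permutations, "n_permutations", min = 0)
  structure(list(g_scale = g_scale, min_frag_len = min_frag_len,
                 min_polymorphisms = min_polymorphisms,
                 min_frag_score = min_frag_score,
                 max_overlap_frags = max_overlap_frags,
                 n_permutations = as.integer(n_permutations), seed = seed,
                 alpha = alpha, mismatch_penalty = mismatch_penalty),
            class = "sawyer_params")
}

#' Polymorphic sites within a same-species group
#'
#' Columns with at least two distinct non-gap states among the group;
#' monomorphic and all-gap columns are dropped. Groups of two are allowed
#' (pairwise-only mode) with a warning.
#'
#' @param x An [msa] object.
#' @param group Character vector of labels (>= 2; >= 3 recommended).
#' @return Integer vector of 0-based column indices.
#' @export
polymorphic_sites <- function(x, group) {
  stopifnot(all(group %in% x$labels))
  if (length(group) < 2L) abort("group needs >= 2 sequences")
  if (length(group) == 2L) warn("pairwise-only mode: group has just 2 sequences")
  sub <- x$mat[group, , drop = FALSE]
  n_states <- apply(sub, 2L, function(col) {
    length(unique(col[!is_gapish(col)]))
  })
  which(n_states >= 2L) - 1L
}

# Penalty per mismatching polymorphic site.
sawyer_penalty <- function(params, n_poly) {
  if (!is.null(params$mismatch_penalty)) return(params$mismatch_penalty)
  if (params$g_scale == 0) return(Inf)
  1 + n_poly / params$g_scale
}

# Match vector for a pair over the polymorphic sites: +1 at matches,
# -penalty at mismatches; sites where either member is gapped are dropped.
# Returns list(score = numeric vector, site = 0-based columns kept).
pair_match_vector <- function(x, pair, sites, penalty) {
  a <- x$mat[pair[1], sites + 1L]
  b <- x$mat[pair[2], sites + 1L]
  ok <- !(is_gapish(a) | is_gapish(b))
  sc <- ifelse(a[ok] == b[ok], 1, -penalty)
  list(score = sc, site = sites[ok])
}

# All maximal scoring subsequences (Ruzzo-Tompa); returns tibble of
# disjoint fragments with 1-based indices into the score vector.
maximal_scoring_segments <- function(score) {
  n <- length(score)
  if (!n) return(tibble(from = integer(), to = integer(), score = double()))
  # stack of candidate segments: cumulative left (L) and right (R) scores
  I <- list()
  cum <- 0
  for (k in seq_len(n)) {
    s <- score[k]
    if (s <= 0) { cum <- cum + s; next }
    seg <- list(from = k, to = k, L = cum, R = cum + s)
    cum <- cum + s
    repeat {
      # find rightmost j with L_j < seg$L
      j <- length(I)
      while (j >= 1L && I[[j]]$L >= seg$L) j <- j - 1L
      if (j >= 1L && I[[j]]$R < seg$R) {
        seg <- list(from = I[[j]]$from, to = seg$to, L = I[[j]]$L, R = seg$R)
        I <- I[seq_len(j - 1L)]
      } else {
        I[[length(I) + 1L]] <- seg
        break
      }
    }
  }
  if (!length(I)) return(tibble(from = integer(), to = integer(), score = double()))
  tibble(from = purrr::map_int(I, ~as.integer(.x$from)),
         to = purrr::map_int(I, ~as.integer(.x$to)),
         score = purrr::map_dbl(I, ~.x$R - .x$L))
}

# Best (maximum) fragment score only — Kadane, vector-fast for permutations.
best_fragment_score <- function(score) {
  if (!length(score)) return(0)
  cs <- cumsum(score)
  max(0, max(cs - cummin(c(0, cs[-length(cs)]))))
}

#' Sawyer fragments for one pair
#'
#' Within the polymorphic-site subsequence of the pair, a fragment accrues
#' +1 per matching site and -penalty per mismatching site; all maximal
#' nonnegative-score runs are retained, then filtered by the minimum span,
#' polymorphism count, and score thresholds.
#'
#' @param x An [msa] object.
#' @param pair Two labels.
#' @param sites Output of [polymorphic_sites()] for the pair's group.
#' @param params A [sawyer_params()] object.
#' @return Tibble: `label_a`, `label_b`, `start`, `end` (0-based half-open
#'   alignment coordinates), `n_sites`, `n_match`, `n_mismatch`, `score`.
#' @export
sawyer_fragments <- function(x, pair, sites, params = sawyer_params()) {
  if (!length(sites)) {
    return(tibble(label_a = character(), label_b = character(),
                  start = integer(), end = integer(), n_sites = integer(),
                  n_match = integer(), n_mismatch = integer(), score = double()))
  }
  pen <- sawyer_penalty(params, length(sites))
  mv <- pair_match_vector(x, pair, sites, pen)
  segs <- maximal_scoring_segments(mv$score)
  if (nrow(segs)) {
    segs <- segs |>
      mutate(start = mv$site[.data$from],
             end = mv$site[.data$to] + 1L,
             n_sites = .data$to - .data$from + 1L,
             n_match = purrr::map2_int(.data$from, .data$to,
                                       ~sum(mv$score[.x:.y] > 0)),
             n_mismatch = .data$n_sites - .data$n_match) |>
      filter(.data$end - .data$start >= params$min_frag_len,
             .data$n_sites >= params$min_polymorphisms,
             .data$score >= params$min_frag_score)
  }
  if (!nrow(segs) || is.null(segs$start)) {
    return(tibble(label_a = character(), label_b = character(),
                  start = integer(), end = integer(), n_sites = integer(),
                  n_match = integer(), n_mismatch = integer(), score = double()))
  }
  tibble(label_a = pair[1], label_b = pair[2],
         start = as.integer(segs$start), end = as.integer(segs$end),
         n_sites = as.integer(segs$n_sites),
         n_match = as.integer(segs$n_match),
         n_mismatch = as.integer(segs$n_mismatch),
         score = as.numeric(segs$score))
}

#' Permutation test for conversion fragments within a species group
#'
#' For every pair in the group, the observed best fragment score is
#' compared with a null built by permuting the order of the group's
#' polymorphic-site columns (destroying linear clustering while preserving
#' per-site frequencies): `p = (1 + #null >= observed) / (1 + B)`,
#' Bonferroni-corrected across the pairs of the group. Permutations and
#' correction are within-species, matching grouping by genus.
#'
#' @param x An [msa] object.
#' @param group Same-species labels (>= 2).
#' @param params A [sawyer_params()] with `n_permutations >= 1`.
#' @return A `sawyer_test` tibble: `label_a`, `label_b`, `observed`,
#'   `start`, `end` (best fragment), `p`, `p_corrected`, `significant`.
#' @export
sawyer_test <- function(x, group, params = sawyer_params()) {
  if (params$n_permutations < 1L) abort("n_permutations must be >= 1")
  sites <- polymorphic_sites(x, group)
  pairs <- utils::combn(group, 2)
  n_pairs <- ncol(pairs)
  run <- function() {
    pen <- sawyer_penalty(params, length(sites))
    mvs <- purrr::map(seq_len(n_pairs), function(i) {
      pair_match_vector(x, pairs[, i], sites, pen)
    })
    obs <- purrr::map_dbl(mvs, ~best_fragment_score(.x$score))
    exceed <- integer(n_pairs)
    B <- params$n_permutations
    keep_idx <- purrr::map(mvs, ~match(.x$site, sites))
    for (b in seq_len(B)) {
      perm <- sample.int(length(sites))
      for (i in seq_len(n_pairs)) {
        # permuting group columns permutes each pair's usable sites
        sc <- mvs[[i]]$score[order(perm[keep_idx[[i]]])]
        if (best_fragment_score(sc) >= obs[i]) exceed[i] <- exceed[i] + 1L
      }
    }
    p <- (1 + exceed) / (1 + B)
    best <- purrr::map(seq_len(n_pairs), function(i) {
      fr <- sawyer_fragments(x, pairs[, i], sites, params)
      if (nrow(fr)) fr[which.max(fr$score), c("start", "end")] else
        tibble(start = NA_integer_, end = NA_integer_)
    }) |> bind_rows()
    tibble(label_a = pairs[1, ], label_b = pairs[2, ], observed = obs,
           start = best$start, end = best$end, p = p,
           p_corrected = pmin(1, p * n_pairs),
           significant = pmin(1, p * n_pairs) < params$alpha)
  }
  out <- if (!is.null(params$seed)) withr::with_seed(params$seed, run()) else run()
  if (all(out$observed == 0)) {
    warn("degenerate statistic: all observed best scores are 0; p set to 1")
    out$p <- 1; out$p_corrected <- 1; out$significant <- FALSE
  }
  attr(out, "params") <- params
  attr(out, "n_sites") <- length(sites)
  class(out) <- c("sawyer_test", class(out))
  out
}

#' Import external conversion-region annotations
#'
#' Reads region tables from external detectors (e.g. phylogenetic-
#' incompatibility or bootscan methods) as additional evidence flags.
#' Format: TSV with columns `label_a`, `label_b`, `start`, `end`, `method`,
#' `p`.
#'
#' @param path TSV path.
#' @return Tibble of annotations.
#' @export
read_conversion_annotations <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    label_a = readr::col_character(), label_b = readr::col_character(),
    start = readr::col_integer(), end = readr::col_integer(),
    method = readr::col_character(), p = readr::col_double()),
    comment = "#")
}

#' Integrate evidence lines into conversion calls
#'
#' Implements the two-tier calling rule. A *recent* call is a
#' super-threshold similarity region (score > 0.96 by default) with at
#' least one corroborating indicator in that region for the same pair: a
#' co-localised homoplasic micro-indel, a significant fragment statistic,
#' or an imported external annotation. A significant fragment with only
#' background similarity becomes an *ancient* call (statistic only).
#' Super-threshold regions without corroboration are reported as
#' uncorroborated candidates, not calls. Overlapping calls for one pair
#' are merged with union extent and combined evidence.
#'
#' @param candidates Output of [candidate_regions()].
#' @param coloc Output of [colocalize_indels()] (may be `NULL`).
#' @param sawyer A `sawyer_test` result or row-bound results (may be `NULL`).
#' @param external Imported annotations (may be `NULL`).
#' @return Tibble of `conversion_call`s: `label_a`, `label_b`, `start`,
#'   `end`, `tier` (`"recent"`, `"ancient"`, `"uncorroborated"`),
#'   `ev_similarity`, `ev_microindel`, `ev_sawyer`, `ev_external`,
#'   `p_sawyer`, `called`.
#' @export
integrate_calls <- function(candidates, coloc = NULL, sawyer = NULL,
                            external = NULL) {
  sig <- NULL
  if (!is.null(sawyer) && nrow(sawyer)) {
    sig <- sawyer[sawyer$significant & !is.na(sawyer$start), , drop = FALSE]
  }
  calls <- list()
  overlap <- function(s1, e1, s2, e2) !is.na(s2) & s1 < e2 & e1 > s2
  if (!is.null(candidates) && nrow(candidates)) {
    for (i in seq_len(nrow(candidates))) {
      cand <- candidates[i, ]
      key <- pair_key(cand$label_a, cand$label_b)
      ev_ind <- FALSE
      if (!is.null(coloc) && nrow(coloc)) {
        ev_ind <- any(coloc$corroborating & coloc$region_pair == key &
                        overlap(cand$start, cand$end, coloc$region_start,
                                coloc$region_end), na.rm = TRUE)
      }
      ev_saw <- FALSE; p_saw <- NA_real_
      if (!is.null(sig) && nrow(sig)) {
        hit <- pair_key(sig$label_a, sig$label_b) == key &
          overlap(cand$start, cand$end, sig$start, sig$end)
        ev_saw <- any(hit)
        if (ev_saw) p_saw <- min(sig$p_corrected[hit])
      }
      ev_ext <- FALSE
      if (!is.null(external) && nrow(external)) {
        ev_ext <- any(pair_key(external$label_a, external$label_b) == key &
                        overlap(cand$start, cand$end, external$start, external$end))
      }
      corroborated <- ev_ind || ev_saw || ev_ext
      calls[[length(calls) + 1L]] <- tibble(
        label_a = cand$label_a, label_b = cand$label_b,
        start = cand$start, end = cand$end,
        tier = if (corroborated) "recent" else "uncorroborated",
        ev_similarity = TRUE, ev_microindel = ev_ind, ev_sawyer = ev_saw,
        ev_external = ev_ext, p_sawyer = p_saw, called = corroborated)
    }
  }
  # ancient tier: significant fragments with no super-threshold region
  if (!is.null(sig) && nrow(sig)) {
    for (i in seq_len(nrow(sig))) {
      fr <- sig[i, ]
      key <- pair_key(fr$label_a, fr$label_b)
      has_cand <- !is.null(candidates) && nrow(candidates) &&
        any(pair_key(candidates$label_a, candidates$label_b) == key &
              overlap(fr$start, fr$end, candidates$start, candidates$end))
      if (!has_cand) {
        calls[[length(calls) + 1L]] <- tibble(
          label_a = fr$label_a, label_b = fr$label_b,
          start = fr$start, end = fr$end, tier = "ancient",
          ev_similarity = FALSE, ev_microindel = FALSE, ev_sawyer = TRUE,
          ev_external = FALSE, p_sawyer = fr$p_corrected, called = TRUE)
      }
    }
  }
  if (!length(calls)) {
    return(tibble(label_a = character(), label_b = character(),
                  start = integer(), end = integer(), tier = character(),
                  ev_similarity = logical(), ev_microindel = logical(),
                  ev_sawyer = logical(), ev_external = logical(),
                  p_sawyer = double(), called = logical()))
  }
  merge_pair_calls(bind_rows(calls))
}

# Merge overlapping same-pair same-tier calls: union extent, OR evidence.
merge_pair_calls <- function(calls) {
  calls |>
    mutate(key = pair_key(.data$label_a, .data$label_b)) |>
    arrange(.data$key, .data$tier, .data$start) |>
    group_by(.data$key, .data$tier) |>
    group_modify(function(df, k) {
      grp <- cumsum(c(TRUE, df$start[-1L] > cummax(df$end[-nrow(df)])))
      df$grp <- grp
      df |>
        group_by(.data$grp) |>
        summarise(label_a = .data$label_a[1L], label_b = .data$label_b[1L],
                  start = min(.data$start), end = max(.data$end),
                  ev_similarity = any(.data$ev_similarity),
                  ev_microindel = any(.data$ev_microindel),
                  ev_sawyer = any(.data$ev_sawyer),
                  ev_external = any(.data$ev_external),
                  p_sawyer = suppressWarnings(min(.data$p_sawyer, na.rm = TRUE)),
                  called = any(.data$called), .groups = "drop") |>
        select(-"grp")
    }) |>
    ungroup() |>
    mutate(p_sawyer = ifelse(is.infinite(.data$p_sawyer), NA_real_, .data$p_sawyer)) |>
    select("label_a", "label_b", "start", "end", "tier", "ev_similarity",
           "ev_microindel", "ev_sawyer", "ev_external", "p_sawyer", "called")
}
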