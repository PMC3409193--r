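#' Pairwise evolutionary distances with pairwise gap deletion
#'
#' Computes all pairwise distances among alignment members. A column is used
#' for a pair iff neither member has a gap or `N` there (pairwise deletion,
#' the "ignored gapped sites shared by the pair" rule). Available models:
#'
#' * `"p"` — proportion of differing sites.
#' * `"jc"` — Jukes-Cantor correction.
#' * `"k2p"` — Kimura two-parameter.
#' * `"tn93cl"` (default) — TN93 with composite parameter sharing: base
#'   frequencies and the two transition/transversion rate ratios are
#'   estimated once from the whole alignment, then each pair's divergence is
#'   the TN93 distance solving the pair's observed difference proportion
#'   under those shared parameters. This mirrors the defining feature of
#'   maximum-composite-likelihood distances (parameters shared across
#'   pairs) with a tractable moment estimator.
#'
#' Variances come from the delta method on the per-pair compared-site
#' counts. Pairs with zero comparable sites, or saturated pairs (correction
#' logarithm undefined), get `NA` with a warning.
#'
#' @param x An [msa] object.
#' @param model One of `"tn93cl"`, `"p"`, `"jc"`, `"k2p"`.
#' @return A `paralog_dist` object: list with `labels`, matrices `d`, `var`,
#'   `n_sites`, the `model` name, and (for `"tn93cl"`) the shared
#'   parameter estimates. Use [tidy()] for a long tibble.
#' @export
pairwise_distance <- function(x, model = c("tn93cl", "p", "jc", "k2p")) {
  model <- match.arg(model)
  labels <- x$labels
  if (length(labels) < 2L) abort("need at least 2 sequences")
  enc <- encode_nt(x$mat)
  n <- length(labels)
  d <- v <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  ns <- matrix(0L, n, n, dimnames = list(labels, labels))
  diag(d) <- 0; diag(v) <- 0
  counts <- pair_site_counts(enc)
  shared <- NULL
  if (model == "tn93cl") {
    shared <- tn93_shared_parameters(enc, counts)
  }
  saturated <- character(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ct <- counts[[i]][[j]]
      ns[i, j] <- ns[j, i] <- ct["n"]
      if (ct["n"] == 0L) next
      est <- switch(model,
        p = {
          p <- ct["mm"] / ct["n"]
          c(d = unname(p), var = unname(p * (1 - p) / ct["n"]))
        },
        jc = jc_distance(ct["mm"] / ct["n"], ct["n"]),
        k2p = k2p_distance((ct["ts1"] + ct["ts2"]) / ct["n"],
                           ct["tv"] / ct["n"], ct["n"]),
        tn93cl = tn93cl_pair(shared$fit, ct))
      if (is.na(est["d"]) && model != "p") {
        saturated <- c(saturated, paste(labels[i], labels[j], sep = "-"))
      }
      d[i, j] <- d[j, i] <- est[["d"]]
      v[i, j] <- v[j, i] <- est[["var"]]
    }
  }
  if (length(saturated)) {
    warn(sprintf("distance undefined (saturated) for: %s",
                 paste(saturated, collapse = ", ")))
  }
  structure(list(labels = labels, d = d, var = v, n_sites = ns,
                 model = model, species = x$species, shared = shared),
            class = "paralog_dist")
}

# Per-pair site counts: comparable sites n, mismatches mm, A<->G transitions
# ts1, C<->T transitions ts2, transversions tv.
pair_site_counts <- function(enc) {
  n <- nrow(enc)
  out <- vector("list", n)
  for (i in seq_len(n)) out[[i]] <- vector("list", n)
  for (i in seq_len(max(n - 1L, 0L))) {
    a <- enc[i, ]
    for (j in (i + 1L):n) {
      b <- enc[j, ]
      ok <- !is.na(a) & !is.na(b)
      aa <- a[ok]; bb <- b[ok]
      idx <- (aa - 1L) * 4L + bb
      tab <- tabulate(idx, nbins = 16L)
      m <- matrix(tab, 4, 4, byrow = TRUE)  # rows = state in i
      mm <- sum(m) - sum(diag(m))
      ts1 <- m[1, 3] + m[3, 1]
      ts2 <- m[2, 4] + m[4, 2]
      out[[i]][[j]] <- c(n = sum(m), mm = mm, ts1 = ts1, ts2 = ts2,
                         tv = mm - ts1 - ts2)
    }
  }
  out
}

# Shared TN93 parameters from the whole alignment: empirical base
# frequencies plus rate ratios k1, k2 from pooled pair counts via the
# standard TN93 component estimators.
tn93_shared_parameters <- function(enc, counts) {
  tab <- tabulate(enc[!is.na(enc)], nbins = 4L)
  pi <- tab / sum(tab)
  pooled <- c(n = 0, mm = 0, ts1 = 0, ts2 = 0, tv = 0)
  for (i in seq_along(counts)) {
    for (j in seq_along(counts[[i]])) {
      if (!is.null(counts[[i]][[j]])) pooled <- pooled + counts[[i]][[j]]
    }
  }
  P1 <- pooled["ts1"] / pooled["n"]; P2 <- pooled["ts2"] / pooled["n"]
  Q <- pooled["tv"] / pooled["n"]
  pR <- pi[1] + pi[3]; pY <- pi[2] + pi[4]
  w1 <- 1 - pR * P1 / (2 * pi[1] * pi[3]) - Q / (2 * pR)
  w2 <- 1 - pY * P2 / (2 * pi[2] * pi[4]) - Q / (2 * pY)
  w3 <- 1 - Q / (2 * pR * pY)
  a1 <- if (w1 > 0) -log(w1) else NA_real_
  a2 <- if (w2 > 0) -log(w2) else NA_real_
  b <- if (w3 > 0) -log(w3) else NA_real_
  # rate ratios relative to transversions; fall back to 1 when inestimable
  k1 <- if (!is.na(a1) && !is.na(b) && b > 0) max((a1 - pY * b) / b, 1e-3) else 1
  k2 <- if (!is.na(a2) && !is.na(b) && b > 0) max((a2 - pR * b) / b, 1e-3) else 1
  fit <- tn93_model(pi, k1 = unname(k1), k2 = unname(k2))
  list(pi = pi, k1 = unname(k1), k2 = unname(k2), fit = fit)
}

# Per-pair distance under the shared TN93 model: solve the observed
# difference proportion; delta-method variance via the slope of p(d).
tn93cl_pair <- function(fit, ct) {
  p_obs <- unname(ct["mm"] / ct["n"])
  d <- tn93_invert_p(fit, p_obs)
  if (is.na(d)) return(c(d = NA_real_, var = NA_real_))
  eps <- 1e-6
  slope <- (fit$pdiff(d + eps) - fit$pdiff(max(d - eps, 0))) /
    (eps + min(d, eps))
  v <- p_obs * (1 - p_obs) / (unname(ct["n"]) * slope^2)
  c(d = d, var = v)
}

#' Build a `paralog_dist` from a labelled distance matrix
#'
#' Used to analyse published distance tables with the downstream operations
#' (group averages, ortholog assignment, neighbor-joining).
#'
#' @param d Symmetric numeric matrix with dimnames (NA allowed off-diagonal).
#' @param species Named character vector label -> species; parsed from the
#'   label prefix before `"_"` when `NULL`.
#' @param var Optional symmetric matrix of variance estimates.
#' @param n_sites Optional matrix of compared-site counts.
#' @return A `paralog_dist` object.
#' @export
as_paralog_dist <- function(d, species = NULL, var = NULL, n_sites = NULL) {
  labels <- rownames(d)
  if (is.null(labels) || !identical(labels, colnames(d))) {
    abort("`d` must have matching dimnames")
  }
  if (max(abs(d - t(d)), na.rm = TRUE) > 1e-12) abort("`d` must be symmetric")
  diag(d) <- 0
  if (is.null(species)) species <- setNames(sub("_.*$", "", labels), labels)
  structure(list(labels = labels, d = d,
                 var = var %||% matrix(NA_real_, nrow(d), ncol(d), dimnames = dimnames(d)),
                 n_sites = n_sites %||% matrix(NA_integer_, nrow(d), ncol(d), dimnames = dimnames(d)),
                 model = "supplied", species = species[labels], shared = NULL),
            class = "paralog_dist")
}

#' @export
print.paralog_dist <- function(x, ...) {
  cat(sprintf("<paralog_dist> %d labels, model = %s\n", length(x$labels), x$model))
  print(round(x$d, 4))
  invisible(x)
}

#' @export
as.matrix.paralog_dist <- function(x, ...) x$d

#' @rdname pairwise_distance
#' @param x A `paralog_dist` object.
#' @param ... Unused.
#' @method tidy paralog_dist
#' @export
tidy.paralog_dist <- function(x, ...) {
  labels <- x$labels
  idx <- which(upper.tri(x$d), arr.ind = TRUE)
  tibble(
    label_a = labels[idx[, 1]], label_b = labels[idx[, 2]],
    species_a = unname(x$species[labels[idx[, 1]]]),
    species_b = unname(x$species[labels[idx[, 2]]]),
    distance = x$d[idx], variance = x$var[idx],
    n_sites = x$n_sites[idx])
}

#' @rdname pairwise_distance
#' @method glance paralog_dist
#' @export
glance.paralog_dist <- function(x, ...) {
  td <- tidy(x)
  tibble(model = x$model, n_labels = length(x$labels),
         n_pairs = nrow(td), n_na = sum(is.na(td$distance)),
         mean_distance = mean(td$distance, na.rm = TRUE))
}

#' Group-wise averages of pairwise distances
#'
#' Summarises entries of a distance matrix over contrasts between (or
#' within) groups of labels, e.g. "all within-species paralog pairs" or
#' "human paralogs", reporting the unweighted mean and sample sd.
#'
#' @param dm A `paralog_dist`.
#' @param groups Named character vector mapping every label to a group.
#' @param contrasts Tibble with columns `contrast`, `group_a`, `group_b`.
#'   `group_a == group_b` means all unordered pairs within that group; a row
#'   with both `NA` pools all within-group pairs across groups.
#' @return Tibble: `contrast`, `mean`, `sd`, `n_pairs`, `n_na`. Single-pair
#'   contrasts have `sd = NA`; empty contrasts have `NA` mean with
#'   `n_pairs = 0`.
#' @export
group_averages <- function(dm, groups, contrasts) {
  if (!all(dm$labels %in% names(groups))) {
    abort(sprintf("unmapped labels: %s",
                  paste(setdiff(dm$labels, names(groups)), collapse = ", ")))
  }
  td <- tidy(dm)
  td$ga <- unname(groups[td$label_a])
  td$gb <- unname(groups[td$label_b])
  one <- function(contrast, group_a, group_b) {
    rows <- if (is.na(group_a) && is.na(group_b)) {
      td[td$ga == td$gb, ]
    } else if (group_a == group_b) {
      td[td$ga == group_a & td$gb == group_a, ]
    } else {
      td[(td$ga == group_a & td$gb == group_b) |
           (td$ga == group_b & td$gb == group_a), ]
    }
    vals <- rows$distance
    tibble(contrast = contrast,
           mean = if (sum(!is.na(vals))) mean(vals, na.rm = TRUE) else NA_real_,
           sd = if (sum(!is.na(vals)) > 1) sd(vals, na.rm = TRUE) else NA_real_,
           n_pairs = sum(!is.na(vals)), n_na = sum(is.na(vals)))
  }
  purrr::pmap(as_tibble(contrasts)[c("contrast", "group_a", "group_b")], one) |>
    bind_rows()
}

#' Smallest-distance ortholog assignment
#'
#' For each label and each foreign species, finds the minimum-distance
#' partner, its margin over the second-best candidate, and whether the
#' assignment is reciprocal (each member is the other's best partner in the
#' counterpart species). Ties at the minimum (within `tol`) are flagged
#' ambiguous and both candidates reported; conflicts (two labels of one
#' species claiming the same partner) are reported, never silently
#' resolved.
#'
#' @param dm A `paralog_dist` with species tags.
#' @param tol Tie tolerance on distances.
#' @return Tibble with one row per (label, foreign species, candidate):
#'   `label`, `species`, `partner_species`, `partner`, `distance`, `margin`,
#'   `ambiguous`, `reciprocal`, `conflict`.
#' @export
assign_orthologs <- function(dm, tol = 1e-9) {
  species <- dm$species
  if (length(unique(species)) < 2L) abort("need at least 2 species")
  rows <- list()
  for (lab in dm$labels) {
    for (sp in setdiff(unique(species), species[lab])) {
      cand <- dm$labels[species == sp]
      dv <- dm$d[lab, cand]
      if (all(is.na(dv))) next
      best <- min(dv, na.rm = TRUE)
      hits <- cand[!is.na(dv) & dv <= best + tol]
      rest <- sort(dv[!cand %in% hits])
      margin <- if (length(rest)) unname(rest[1] - best) else NA_real_
      rows[[length(rows) + 1L]] <- tibble(
        label = lab, species = unname(species[lab]), partner_species = sp,
        partner = hits, distance = unname(dm$d[lab, hits]),
        margin = margin, ambiguous = length(hits) > 1L)
    }
  }
  out <- bind_rows(rows)
  # reciprocity: partner's best in `label`'s species is `label`
  best_of <- function(lab, sp) {
    sub <- out[out$label == lab & out$partner_species == sp, ]
    sub$partner
  }
  out$reciprocal <- purrr::pmap_lgl(out, function(label, species, partner_species,
                                                  partner, ...) {
    label %in% best_of(partner, species)
  })
  out <- out |>
    group_by(.data$species, .data$partner_species, .data$partner) |>
    mutate(conflict = dplyr::n_distinct(.data$label) > 1L) |>
    ungroup()
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ; for an additive matrix the returned tree realises the input
#' distances exactly. Three taxa get the closed-form star resolution.
#'
#' @param dm A `paralog_dist` (complete: no `NA` off-diagonal entries).
#' @return An unrooted `phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(dm) {
  d <- dm$d
  bad <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf("NA distances for pairs: %s",
                  paste(paste(dm$labels[bad[, 1]], dm$labels[bad[, 2]], sep = "-"),
                        collapse = ", ")))
  }
  if (length(dm$labels) < 3L) abort("need at least 3 labels")
  if (length(dm$labels) == 3L) {
    l <- dm$labels
    bl <- c((d[1, 2] + d[1, 3] - d[2, 3]) / 2,
            (d[1, 2] + d[2, 3] - d[1, 3]) / 2,
            (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
    txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", l[1], bl[1], l[2], bl[2], l[3], bl[3])
    return(ape::read.tree(text = txt))
  }
  ape::nj(stats::as.dist(d))
}

#' Per-region nearest paralog and chimera diagnostics
#'
#' Recomputes pairwise distances within each region of the alignment and,
#' for each focal sequence, reports the minimum-distance same-species
#' paralog in that region. A paralog created by a chimeric duplication (5'
#' and 3' portions descending from different parents) shows a switch of
#' nearest parent between the 5' and 3' blocks of regions.
#'
#' @param x An [msa] with at least 2 regions.
#' @param model Distance model, as in [pairwise_distance()].
#' @param min_sites Regions shorter than this are flagged low-confidence
#'   (default 100 sites).
#' @return Tibble: `region`, `start`, `end`, `label`, `nearest`, `distance`,
#'   `low_confidence`.
#' @export
per_region_nearest <- function(x, model = "tn93cl", min_sites = 100) {
  if (is.null(x$regions) || nrow(x$regions) < 2L) abort("need >= 2 regions")
  out <- purrr::pmap(x$regions, function(region, start, end, frame) {
    sub <- msa_slice(x, start, end)
    dm <- suppressWarnings(pairwise_distance(sub, model = model))
    rows <- purrr::map(dm$labels, function(lab) {
      cand <- dm$labels[dm$species == dm$species[lab] & dm$labels != lab]
      if (!length(cand)) return(NULL)
      dv <- dm$d[lab, cand]
      if (all(is.na(dv))) return(NULL)
      best <- cand[which.min(dv)]
      tibble(region = region, start = start, end = end, label = lab,
             nearest = best, distance = unname(min(dv, na.rm = TRUE)),
             low_confidence = (end - start) < min_sites)
    })
    bind_rows(rows)
  })
  bind_rows(out)
}

#' Chimera signal from per-region nearest-paralog calls
#'
#' Flags a label when its confident regions split into a 5' block and a 3'
#' block with different nearest parents, each block consistent across at
#' least two contiguous regions.
#'
#' @param prn Output of [per_region_nearest()].
#' @return Tibble: `label`, `flagged`, `parent_5p`, `parent_3p`,
#'   `breakpoint` (alignment coordinate between the blocks, `NA` if not
#'   flagged).
#' @export
chimera_signals <- function(prn) {
  prn |>
    filter(!.data$low_confidence) |>
    arrange(.data$label, .data$start) |>
    group_by(.data$label) |>
    summarise(sig = list(chimera_one(.data$nearest, .data$start, .data$end)),
              .groups = "drop") |>
    tidyr::unnest_wider("sig")
}

chimera_one <- function(nearest, start, end) {
  m <- length(nearest)
  for (k in seq_len(max(m - 2L, 0L))[-1L]) {  # k in 2..(m-2)
    left <- nearest[1:k]; right <- nearest[(k + 1L):m]
    if (length(unique(left)) == 1L && length(unique(right)) == 1L &&
        left[1] != right[1] && length(left) >= 2L && length(right) >= 2L) {
      return(list(flagged = TRUE, parent_5p = left[1], parent_3p = right[1],
                  breakpoint = end[k]))
    }
  }
  list(flagged = FALSE, parent_5p = NA_character_, parent_3p = NA_character_,
       breakpoint = NA_real_)
}

#' Write a square labelled distance matrix as TSV
#' @param dm A `paralog_dist`.
#' @param path Output path.
#' @return `dm`, invisibly.
#' @export
write_distance_tsv <- function(dm, path) {
  df <- as.data.frame(dm$d)
  df <- cbind(label = rownames(df), df)
  readr::write_tsv(as_tibble(df), path)
  invisible(dm)
}
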