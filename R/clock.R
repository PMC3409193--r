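#' Molecular-clock parameters for two-fold degenerate sites
#'
#' The dating statistic is the fraction of two-fold degenerate third
#' positions left unchanged in a pair (f2). It decays from 1 towards the
#' equilibrium identity `q = p1^2 + p2^2` of the silent two-state
#' (AT-type/GC-type) nucleotide bias. Defaults: a rate constant of
#' 3.1e-9 silent substitutions/site/year and an equilibrium silent
#' nucleotide site bias of 0.52/0.48, giving `q ~ 0.5008`.
#'
#' @param rate Silent substitution rate constant, substitutions/site/year.
#' @param bias Length-2 equilibrium bias of the two silent states
#'   (sums to 1).
#' @return A `clock_params` list with `rate`, `bias`, and derived `q`.
#' @export
clock_params <- function(rate = 3.1e-9, bias = c(0.52, 0.48)) {
  assert_scalar_number(rate, "rate", min = 1e-15)
  if (length(bias) != 2L || abs(sum(bias) - 1) > 1e-8) {
    abort("`bias` must be two proportions summing to 1")
  }
  q <- silent_equilibrium_identity(bias)
  if (q <= 0.5 || q >= 1) abort("equilibrium identity must lie in (0.5, 1)")
  structure(list(rate = rate, bias = bias, q = q), class = "clock_params")
}

#' f2 statistic: fraction of two-fold degenerate sites unchanged
#'
#' Counts, over a coding pair, the third positions that are two-fold
#' degenerate in both sequences' codons and reports the fraction left
#' unchanged.
#'
#' @param x An [msa] with coding regions (non-`NA` frame).
#' @param pair Two labels.
#' @param coding Optional coding region names.
#' @return Tibble: `label_a`, `label_b`, `f2`, `n` (two-fold sites
#'   compared), `n_unchanged`. `f2` is `NA` (flagged) when `n = 0`.
#' @export
f2_statistic <- function(x, pair, coding = NULL) {
  deg <- degeneracy_pairwise(x, pair, coding = coding)
  two <- deg[deg$two_fold_pair, , drop = FALSE]
  n <- nrow(two)
  tibble(label_a = pair[1], label_b = pair[2],
         f2 = if (n) mean(two$unchanged) else NA_real_,
         n = n, n_unchanged = sum(two$unchanged))
}

#' Date a divergence from f2 by inverting the exponential-decay clock
#'
#' Inverts `f2(T) = q + (1 - q) * exp(-2 * rate * T / (1 - q))`, where `T`
#' is the time in years since the pair's common ancestor. The calibration
#' constant `1/(1 - q)` in the exponent fixes the *initial* decay rate of
#' f2 at `2 * rate` per year (two lineages each accumulating silent
#' substitutions at `rate`), so the quoted rate constant keeps its units.
#' The confidence interval propagates the binomial error of f2 through the
#' (monotone) inversion. `f2 <= q` means the statistic has reached its
#' saturation plateau and the date is undefined.
#'
#' @param f2 Observed fraction unchanged (scalar or vector).
#' @param n Number of two-fold sites compared.
#' @param params A [clock_params()] object.
#' @param time_scale `"divergence"` (default; years since the common
#'   ancestor) or `"total"` (summed branch time, twice the former).
#' @param conf_level Confidence level for the binomial CI.
#' @return Tibble: `f2`, `n`, `t_years`, `t_lower`, `t_upper`, `saturated`.
#' @export
trex_date <- function(f2, n, params = clock_params(),
                      time_scale = c("divergence", "total"),
                      conf_level = 0.95) {
  time_scale <- match.arg(time_scale)
  q <- params$q
  scale <- if (time_scale == "total") 2 else 1
  invert <- function(f) {
    if (is.na(f) || f <= q) return(NA_real_)
    f <- min(f, 1)
    scale * -(1 - q) / (2 * params$rate) * log((f - q) / (1 - q))
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(pmax(f2 * (1 - f2), 0) / n)
  tibble(
    f2 = f2, n = n,
    t_years = purrr::map_dbl(f2, invert),
    t_lower = purrr::map_dbl(pmin(f2 + z * se, 1), invert),
    t_upper = purrr::map_dbl(f2 - z * se, invert),
    saturated = !is.na(f2) & f2 <= q)
}

#' Filter reference introns for clock suitability
#'
#' A reference intron qualifies as a neutral clock only when it avoids the
#' features known to distort intron divergence rates: long conserved
#' noncoding sequence (LCNS/ultraconserved regions), proximity to a
#' telomere (< 15 Mbp), and high GC content. Presence in an mRNA database
#' is retained by default (shown not to imply functional constraint).
#' Records with missing metadata are excluded with reason `"incomplete"`.
#'
#' @param refs Tibble with columns `gene`, `gc_pct`, `telomere_mbp`,
#'   `lcns`, and optionally `in_mrna`.
#' @param gc_max Maximum GC% of the surrounding region (default 45).
#' @param telomere_min_mbp Minimum distance to the telomere (default 15).
#' @param drop_lcns Exclude introns overlapping LCNS (default TRUE).
#' @param drop_mrna Exclude introns present in mRNA databases (default
#'   FALSE).
#' @return The input tibble with `kept` (logical) and `reasons`
#'   (`;`-separated exclusion reasons, `""` when kept).
#' @export
filter_reference_introns <- function(refs, gc_max = 45, telomere_min_mbp = 15,
                                     drop_lcns = TRUE, drop_mrna = FALSE) {
  refs <- as_tibble(refs)
  need <- c("gene", "gc_pct", "telomere_mbp", "lcns")
  if (!all(need %in% names(refs))) {
    abort(sprintf("refs needs columns: %s", paste(need, collapse = ", ")))
  }
  reasons <- purrr::pmap_chr(
    list(refs$gc_pct, refs$telomere_mbp, refs$lcns,
         refs$in_mrna %||% rep(FALSE, nrow(refs))),
    function(gc, tel, lcns, mrna) {
      if (any(is.na(c(gc, tel, lcns)))) return("incomplete")
      r <- character()
      if (gc > gc_max) r <- c(r, "high_gc")
      if (tel < telomere_min_mbp) r <- c(r, "telomeric")
      if (drop_lcns && isTRUE(lcns)) r <- c(r, "lcns")
      if (drop_mrna && isTRUE(mrna)) r <- c(r, "in_mrna")
      paste(r, collapse = ";")
    })
  refs$kept <- reasons == ""
  refs$reasons <- reasons
  refs
}

#' Place gene duplications relative to speciation splits
#'
#' Compares the mean pairwise distance among paralogs with the ortholog
#' distance distribution of each speciation split: a duplication predates a
#' split when the paralogs are more diverged than the split's orthologs,
#' postdates it when less diverged, and is unresolved when the difference
#' is within one pooled standard deviation (a Welch-style comparison is
#' also reported for reference).
#'
#' @param paralog_summary One-row tibble/list with `mean`, `sd`, `n`.
#' @param ortholog_summaries Tibble with columns `split`, `mean`, `sd`, `n`
#'   (one row per speciation split; pre-averaged across reference genes).
#' @return Tibble: `split`, `paralog_mean`, `ortholog_mean`, `delta`,
#'   `pooled_sd`, `welch_t`, `verdict` in `{"before", "after",
#'   "unresolved"}`.
#' @export
place_duplications <- function(paralog_summary, ortholog_summaries) {
  ps <- as.list(paralog_summary)
  purrr::pmap(as_tibble(ortholog_summaries)[c("split", "mean", "sd", "n")],
              function(split, mean, sd, n) {
    if (is.na(mean)) {
      return(tibble(split = split, paralog_mean = ps$mean,
                    ortholog_mean = NA_real_, delta = NA_real_,
                    pooled_sd = NA_real_, welch_t = NA_real_,
                    verdict = "unresolved"))
    }
    delta <- ps$mean - mean
    pooled <- sqrt(((ps$n - 1) * ps$sd^2 + (n - 1) * sd^2) / (ps$n + n - 2))
    welch <- delta / sqrt(ps$sd^2 / ps$n + sd^2 / n)
    verdict <- if (is.na(pooled) || abs(delta) < pooled) "unresolved"
               else if (delta > 0) "before" else "after"
    tibble(split = split, paralog_mean = ps$mean, ortholog_mean = mean,
           delta = delta, pooled_sd = pooled, welch_t = welch,
           verdict = verdict)
  }) |> bind_rows()
}

#' Dot-and-verdict plot of duplication placement
#' @param object Output of [place_duplications()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_placement <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(y = .data$split)) +
    ggplot2::geom_point(ggplot2::aes(x = .data$ortholog_mean, colour = "orthologs"),
                        size = 3, na.rm = TRUE) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$paralog_mean[1]),
                        linetype = "dashed") +
    ggplot2::geom_text(ggplot2::aes(x = .data$ortholog_mean, label = .data$verdict),
                       vjust = -1, size = 3, na.rm = TRUE) +
    ggplot2::labs(x = "mean pairwise distance (subs/site)", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}
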