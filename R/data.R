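#' Bundled worked example: primate ADH1 intron distance matrix
#'
#' Published pairwise distance estimates (maximum composite likelihood,
#' pairwise gap deletion) among the concatenated intron alignments of 12
#' primate class-I alcohol-dehydrogenase (ADH1) paralogs: three human
#' (`Hum_`), five rhesus macaque (`Mac_`, including the `ADH1.0`
#' pseudogene) and four common marmoset (`Cal_`) genes. `Mac_ADH1.2`, a
#' chimeric/converted gene, is largely absent from the published matrix
#' (its entries are `NA`).
#'
#' @param drop_incomplete Drop labels with any `NA` distance
#'   (`Mac_ADH1.2`), giving a complete matrix as used for tree building
#'   (default `FALSE`).
#' @return A `paralog_dist` object; see [pairwise_distance()].
#' @export
adh1_distance_example <- function(drop_incomplete = FALSE) {
  path <- system.file("extdata", "adh1_intron_distances.tsv",
                      package = "paralogr")
  tab <- readr::read_tsv(path, comment = "#", col_types = "ccdd")
  labels <- unique(c(tab$label_a, tab$label_b))
  d <- v <- matrix(NA_real_, length(labels), length(labels),
                   dimnames = list(labels, labels))
  diag(d) <- 0; diag(v) <- 0
  for (i in seq_len(nrow(tab))) {
    a <- tab$label_a[i]; b <- tab$label_b[i]
    d[a, b] <- d[b, a] <- tab$distance[i]
    v[a, b] <- v[b, a] <- tab$variance[i]
  }
  if (drop_incomplete) {
    repeat {
      na_count <- rowSums(is.na(d))
      if (!any(na_count > 0L)) break
      worst <- which.max(na_count)
      d <- d[-worst, -worst]; v <- v[-worst, -worst]
    }
  }
  as_paralog_dist(d, var = v)
}

#' Bundled worked example: reference intron divergence summaries
#'
#' Mean and sd of pairwise distances among orthologous intronic regions of
#' the screened non-ADH1 reference genes (plus ADH4 introns 6-8), per
#' speciation split: New World monkeys vs catarrhines, Old World monkeys
#' vs hominoids, strepsirhines vs haplorhines.
#'
#' @return Tibble with one row per reference intron.
#' @export
adh1_reference_introns <- function() {
  path <- system.file("extdata", "adh1_reference_introns.tsv",
                      package = "paralogr")
  readr::read_tsv(path, comment = "#", col_types = "cdddddddd")
}

#' Bundled worked example: reference-intron screening metadata
#'
#' Candidate clock-reference introns with the metadata used by
#' [filter_reference_introns()]. GC and telomere values for the excluded
#' loci are the published ones; unpublished fields carry synthetic
#' mid-arm placeholders (see the file header).
#'
#' @return Tibble: `gene`, `gc_pct`, `telomere_mbp`, `lcns`, `in_mrna`.
#' @export
reference_intron_screen <- function() {
  path <- system.file("extdata", "reference_intron_screen_synthetic.tsv",
                      package = "paralogr")
  readr::read_tsv(path, comment = "#", col_types = "cddll")
}

#' Ortholog split summaries for duplication placement
#'
#' Convenience summariser of [adh1_reference_introns()]: pools the
#' per-gene means into one `mean`, `sd`, `n` row per speciation split,
#' shaped for [place_duplications()].
#'
#' @return Tibble: `split`, `mean`, `sd`, `n`.
#' @export
reference_split_summaries <- function() {
  refs <- adh1_reference_introns()
  one <- function(split, m) {
    tibble(split = split, mean = mean(m), sd = sd(m), n = length(m))
  }
  bind_rows(
    one("platyrrhine_catarrhine", refs$nwm_catarrhine_mean),
    one("owm_hominoid", refs$owm_hominoid_mean),
    one("strepsirhine_haplorhine", refs$strep_haplorhine_mean))
}
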