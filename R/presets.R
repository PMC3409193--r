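#' Ready-made simulated gene families
#'
#' Deterministic (given `seed`) presets that emulate the study regime of a
#' primate-like multi-paralog family: two or three species, four paralogs
#' created in rapid succession on the ancestral branch before the deepest
#' speciation, one lineage-specific loss, a ~12.5 kb "intronic" alignment
#' in 8 regions, and optional chimeric duplication or recent conversion
#' tracts.
#'
#' Presets:
#' * `"fourparalog_oneloss"` — 4 ancestral paralogs (`P1`-`P4`), the first
#'   lost on the `Hum` branch; micro-indel process on.
#' * `"chimeric_dup"` — adds a chimeric duplicate (`PX`, 5' from `P2`, 3'
#'   from `P3`) on the `Mac` branch.
#' * `"conversion_recent"` — adds one recent 800-nt conversion tract
#'   between `Mac` paralogs `P2` -> `P3`.
#' * `"no_conversion"` — the base family with indels off (null model for
#'   false-positive-rate studies).
#' * `"small_family"` — a 3 kb, 2-species, 4-paralog family without indels
#'   (fast replicate unit for permutation-test calibration), optionally
#'   with a planted conversion via `conversion_len`.
#'
#' @param preset Preset name.
#' @param seed Integer seed (mandatory; presets are deterministic given
#'   `preset` + `seed`).
#' @param conversion_len For `"small_family"`: plant one conversion tract
#'   of this fixed length (`NULL` = none).
#' @return As [simulate_family()]: list with `msa` and `truth`.
#' @export
make_family <- function(preset = c("fourparalog_oneloss", "chimeric_dup",
                                   "conversion_recent", "no_conversion",
                                   "small_family"),
                        seed, conversion_len = NULL) {
  preset <- match.arg(preset)
  if (missing(seed)) abort("`seed` is mandatory")
  base_tree <- "((Hum:30e6,Mac:30e6)cat:13e6,Cal:43e6)anc:5e6;"
  intron_lengths <- c(1500, 1600, 1550, 1500, 1600, 1550, 1600, 1600)
  regions <- tibble(
    region = paste0("intron", seq_along(intron_lengths)),
    start = cumsum(c(0L, intron_lengths[-8L])),
    end = cumsum(intron_lengths), frame = NA_integer_)
  dups <- tibble(species = "anc", time = c(1e6, 2e6, 3e6),
                 gene = c("P1", "P1", "P2"),
                 new_name = c("P2", "P3", "P4"))
  losses <- tibble(species = "Hum", time = 25e6, gene = "P1")
  subst <- list(rate = 1.4e-9, pi = c(0.3, 0.2, 0.2, 0.3), k1 = 2, k2 = 2)
  indel_on <- list(rate = 2e-11, mean_len = 4, max_len = 100)
  indel_off <- list(rate = 0, mean_len = 4, max_len = 100)

  cfg <- switch(preset,
    fourparalog_oneloss = sim_config(
      base_tree, root_length = sum(intron_lengths), regions = regions,
      subst = subst, indel = indel_on, duplications = dups, losses = losses,
      seed = seed),
    no_conversion = sim_config(
      base_tree, root_length = sum(intron_lengths), regions = regions,
      subst = subst, indel = indel_off, duplications = dups, losses = losses,
      seed = seed),
    chimeric_dup = sim_config(
      base_tree, root_length = sum(intron_lengths), regions = regions,
      subst = subst, indel = indel_off,
      duplications = bind_rows(
        dups,
        tibble(species = "Mac", time = 28e6, gene = "P2", new_name = "PX",
               chimeric_with = "P3", breakpoint = 6250L)),
      losses = losses, seed = seed),
    conversion_recent = sim_config(
      base_tree, root_length = sum(intron_lengths), regions = regions,
      subst = subst, indel = indel_on, duplications = dups, losses = losses,
      conversions = tibble(species = "Mac", time = 43e6, donor = "P2",
                           recipient = "P3", start = NA_integer_,
                           mean_len = 800, fixed = TRUE),
      seed = seed),
    small_family = {
      conv <- if (!is.null(conversion_len)) {
        tibble(species = "A", time = 43e6, donor = "P2", recipient = "P3",
               start = NA_integer_, mean_len = conversion_len, fixed = TRUE)
      } else NULL
      sim_config(
        "(A:40e6,B:40e6)anc:5e6;", root_length = 3000,
        subst = subst, indel = indel_off,
        duplications = tibble(species = "anc", time = c(1e6, 2e6, 3e6),
                              gene = c("P1", "P1", "P2"),
                              new_name = c("P2", "P3", "P4")),
        conversions = conv, seed = seed)
    })
  simulate_family(cfg)
}
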