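# Independent oracles and fixture builders used across the suite.

# Brute-force small parsimony: minimum number of changes over all possible
# ancestral state assignments (exhaustive enumeration). `tip_states` is a
# named vector of state labels; NA = missing (free). Works for any states.
brute_force_parsimony <- function(tree, tip_states, state_space = NULL) {
  tr <- ape::multi2di(if (ape::is.rooted(tree)) tree else
    ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE))
  states <- state_space %||% sort(unique(stats::na.omit(tip_states)))
  n_tip <- length(tr$tip.label)
  n_int <- tr$Nnode
  edge <- tr$edge
  tips <- tip_states[tr$tip.label]
  grid <- as.matrix(expand.grid(rep(list(states), n_int),
                                stringsAsFactors = FALSE))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    assign <- c(tips, grid[g, ])
    cost <- 0
    for (e in seq_len(nrow(edge))) {
      a <- assign[edge[e, 1]]
      b <- assign[edge[e, 2]]
      if (!is.na(a) && !is.na(b) && a != b) cost <- cost + 1
    }
    best <- min(best, cost)
  }
  best
}

# Random binary (rooted) tree over n tips labelled t1..tn.
random_tree <- function(n, labels = paste0("t", seq_len(n))) {
  ape::rtree(n, tip.label = sample(labels))
}

# Quick msa construction from a character vector of strings.
toy_msa <- function(seqs, species = NULL, regions = NULL) {
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs), "_x")
  msa(seqs, species = species, regions = regions)
}

# An indel_matrix built directly from a states matrix (labels x chars).
toy_indel_matrix <- function(states, starts = NULL, lengths = NULL) {
  n_char <- ncol(states)
  chars <- tibble::tibble(
    char_id = colnames(states) %||% paste0("c", seq_len(n_char)),
    start = starts %||% seq(0L, by = 10L, length.out = n_char),
    length = lengths %||% rep(3L, n_char),
    n_present = colSums(states == "1"),
    n_absent = colSums(states == "0"))
  chars$shared <- chars$n_present >= 2L
  chars$informative <- chars$n_present >= 2L & chars$n_absent >= 2L
  colnames(states) <- chars$char_id
  paralogr:::new_indel_matrix(chars, states)
}

# Path-length (additive) distance matrix of a phylo tree.
tree_distance_matrix <- function(tree) {
  m <- ape::cophenetic.phylo(tree)
  m[tree$tip.label, tree$tip.label]
}

# Standard groups / contrasts for the bundled worked example.
example_groups <- function(dm) {
  stats::setNames(sub("_.*", "", dm$labels), dm$labels)
}
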