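# Fitch small parsimony on bitmask-encoded character states.
#
# States are encoded as integer bitmasks so that the Fitch set operations are
# plain bitwAnd/bitwOr, vectorised across all characters at once. A tip with
# missing data carries the full mask and therefore never forces a change.

# Vectorised Fitch count: `tip_states` is a tips x characters integer matrix
# of bitmasks (0 is not allowed; use full_mask for missing). Returns an
# integer vector of step counts per character.
fitch_count <- function(tree, tip_states, full_mask) {
  tr <- root_for_parsimony(tree)
  if (is.null(rownames(tip_states))) abort("tip_states needs rownames")
  missing_tips <- setdiff(tr$tip.label, rownames(tip_states))
  n_tip <- length(tr$tip.label)
  n_char <- ncol(tip_states)
  states <- matrix(full_mask, nrow = n_tip + tr$Nnode, ncol = n_char)
  present <- intersect(tr$tip.label, rownames(tip_states))
  states[match(present, tr$tip.label), ] <- tip_states[present, , drop = FALSE]
  steps <- integer(n_char)
  edge <- ape::reorder.phylo(tr, "postorder")$edge
  seen <- logical(n_tip + tr$Nnode)
  for (k in seq_len(nrow(edge))) {
    parent <- edge[k, 1L]
    child <- edge[k, 2L]
    if (!seen[parent]) {
      states[parent, ] <- states[child, ]
      seen[parent] <- TRUE
    } else {
      inter <- bitwAnd(states[parent, ], states[child, ])
      empty <- inter == 0L
      steps <- steps + empty
      states[parent, ] <- ifelse(empty,
                                 bitwOr(states[parent, ], states[child, ]),
                                 inter)
    }
  }
  steps
}

# Encode nucleotide columns (characters of an alignment) as bitmasks:
# A=1, C=2, G=4, T=8, gap/N = 15 (uninformative, "excluded").
nt_bitmask <- function(chars) {
  m <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  out <- unname(m[chars])
  out[is.na(out)] <- 15L
  out
}

# Binary presence/absence characters: "0" = 1, "1" = 2, "." (missing) = 3.
bin_bitmask <- function(chars) {
  out <- integer(length(chars))
  out[chars == "0"] <- 1L
  out[chars == "1"] <- 2L
  out[chars == "."] <- 3L
  if (any(out == 0L)) abort("binary states must be '0', '1' or '.'")
  out
}
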