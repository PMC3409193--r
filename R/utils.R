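# Internal helpers shared across modules.

NT_LEVELS <- c("A", "C", "G", "T")

# Encode a character matrix over {A,C,G,T,-,N} as integers:
# A=1, C=2, G=3, T=4; gap and N become NA (both are "not comparable").
encode_nt <- function(mat) {
  out <- match(mat, NT_LEVELS)
  dim(out) <- dim(mat)
  dimnames(out) <- dimnames(mat)
  out
}

is_gapish <- function(x) x == "-" | x == "N"

# Unordered label pair in canonical order (for joins across evidence tables).
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

`%||%` <- rlang::`%||%`

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name,
                  format(min), format(max)))
  }
  invisible(x)
}

# Root an input topology (possibly unrooted) into a binary rooted tree on
# which Fitch counting is exact; the parsimony score of a binary unrooted
# tree is invariant to the rooting position.
root_for_parsimony <- function(tree) {
  if (!inherits(tree, "phylo")) abort("`tree` must be an ape 'phylo' object")
  tr <- tree
  if (!ape::is.rooted(tr)) {
    tr <- ape::root(tr, outgroup = tr$tip.label[1L], resolve.root = TRUE)
  }
  if (!ape::is.binary(tr)) tr <- ape::multi2di(tr)
  tr
}
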