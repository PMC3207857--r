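# shared generators and independent oracles

rand_seq <- function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                              collapse = "")

# random ungapped alignment: n sequences mutated from one ancestor
rand_alignment <- function(n, L, p_mut = 0.05, species = NULL) {
  anc <- strsplit(rand_seq(L), "")[[1L]]
  seqs <- vapply(seq_len(n), function(i) {
    s <- anc
    hit <- which(runif(L) < p_mut)
    s[hit] <- vapply(s[hit], function(b) sample(setdiff(c("A","C","G","T"), b), 1L), "")
    paste(s, collapse = "")
  }, "")
  if (is.null(species)) species <- rep("sp", n)
  haplotype_alignment(seqs, paste0(species, "_h", seq_len(n)), species)
}

# brute-force pairwise-difference oracle over gap/N-free columns
pi_oracle <- function(aln, species = NULL) {
  mat <- aln$mat
  if (!is.null(species)) mat <- mat[aln$species %in% species, , drop = FALSE]
  ok <- apply(mat, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  mat <- mat[, ok, drop = FALSE]
  n <- nrow(mat)
  d <- utils::combn(n, 2L, function(ij) sum(mat[ij[1L], ] != mat[ij[2L], ]))
  mean(d) / ncol(mat)
}

fisher_oracle <- function(m) stats::fisher.test(m)$p.value

# exhaustive parsimony oracle: minimum changes over all internal labelings.
# tree given as an edge matrix (parent, child) over node numbers, leaves
# first; leaf_states is a character vector of bases.
parsimony_oracle <- function(edges, leaf_states, states = c("A","C","G","T")) {
  nodes <- sort(unique(as.vector(edges)))
  ntip <- length(leaf_states)
  internal <- setdiff(nodes, seq_len(ntip))
  grid <- do.call(expand.grid, c(rep(list(states), length(internal)),
                                 stringsAsFactors = FALSE))
  lab <- matrix("", nrow = nrow(grid), ncol = max(nodes))
  for (i in seq_len(ntip)) lab[, i] <- leaf_states[i]
  for (k in seq_along(internal)) lab[, internal[k]] <- grid[[k]]
  changes <- rowSums(vapply(seq_len(nrow(edges)), function(e)
    lab[, edges[e, 1L]] != lab[, edges[e, 2L]], logical(nrow(grid))))
  min(changes)
}

toy_lib <- toy_motif_library()

extdata <- function(f) system.file("extdata", f, package = "crekit")
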