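# In-code fixtures shared across the suite.

# A random fingerprint dataset over a full residues x types layout.
random_dataset <- function(n_residues = 3L, n_ligands = 6L, density = 0.3,
                           types = INTERACTION_TYPES, name = "rand") {
  lay <- bit_layout(sprintf("RES%d", seq_len(n_residues)), types)
  p <- n_residues * length(types)
  bits <- matrix(rbinom(n_ligands * p, 1L, density), n_ligands, p,
                 dimnames = list(sprintf("lig%d", seq_len(n_ligands)),
                                 layout_names(lay)))
  act <- rep_len(c(TRUE, FALSE), n_ligands)
  fp_dataset(bits, active = act, name = name, layout = lay)
}

# Independent brute-force confusion count (loop, no vectorised tricks).
brute_counts <- function(x, y) {
  a <- b <- cc <- d <- 0L
  for (i in seq_along(x)) {
    if (x[i] == 1 && y[i] == 1) a <- a + 1L
    else if (x[i] == 1) b <- b + 1L
    else if (y[i] == 1) cc <- cc + 1L
    else d <- d + 1L
  }
  list(a = a, b = b, c = cc, d = d, p = length(x))
}

# Independent SRD oracle: explicit loop over objects.
brute_srd <- function(r1, r2) {
  s <- 0
  for (i in seq_along(r1)) s <- s + abs(r1[i] - r2[i])
  s
}

# All permutations of 1..n via recursive construction (independent of the
# package's iterative builder).
perms_recursive <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms_recursive(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(first) {
    rest <- sub + (sub >= first)
    cbind(first, rest)
  }))
}

# Brute-force pairwise AUC: count active > inactive pairs, ties half.
brute_auc <- function(scores, labels) {
  act <- scores[labels]; inact <- scores[!labels]
  tot <- 0
  for (x in act) for (y in inact) {
    tot <- tot + (x > y) + 0.5 * (x == y)
  }
  tot / (length(act) * length(inact))
}
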