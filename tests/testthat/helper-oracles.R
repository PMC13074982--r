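# Independent brute-force oracles used across the test files. These
# deliberately avoid the package's own code paths (and igraph): distances
# come from a hand-rolled per-source BFS, autocorrelations from a double
# loop over all atom pairs.

# all-pairs shortest paths by BFS from every source
bfs_distances <- function(g) {
  n <- nrow(g$atoms)
  adj <- vector("list", n)
  for (b in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[b]; j <- g$bonds$j[b]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  d <- matrix(NA_integer_, n, n)
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n); dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L; queue <- c(queue, w)
      }
    }
    d[s, ] <- dist
  }
  d
}

# plain double-loop autocorrelation over unordered pairs, using BFS distances
brute_autocorr <- function(g, lag, scheme, centered = FALSE, averaged = FALSE) {
  w <- atom_weights(g, scheme)
  if (centered) w <- w - mean(w)
  d <- bfs_distances(g)
  n <- length(w)
  s <- 0; count <- 0L
  if (lag == 0) {
    s <- sum(w * w); count <- n
  } else {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (d[i, j] == lag) { s <- s + w[i] * w[j]; count <- count + 1L }
    }
  }
  if (!averaged) return(s)
  if (count == 0L) 0 else s / count
}

brute_moran <- function(g, lag, scheme) {
  w <- atom_weights(g, scheme)
  v <- mean((w - mean(w))^2)
  if (v <= 0) return(0)
  num <- brute_autocorr(g, lag, scheme, centered = TRUE, averaged = TRUE)
  num / v
}

# hat-matrix diagonal the long way round
brute_hat_diag <- function(x) {
  xm <- cbind(1, as.matrix(x))
  diag(xm %*% solve(crossprod(xm)) %*% t(xm))
}

# molecule with all-equal weights and no hydrogens: a bare carbon ring
bare_carbon_ring <- function(n = 6) {
  new_molecule_graph(data.frame(element = rep("C", n)),
                     data.frame(i = seq_len(n), j = c(seq_len(n)[-1], 1),
                                order = 1))
}

# two bonded heavy atoms, no hydrogens
bare_pair <- function(e1 = "C", e2 = "Cl") {
  new_molecule_graph(data.frame(element = c(e1, e2)),
                     data.frame(i = 1, j = 2, order = 1))
}

# H-explicit molecular formulas for the 54 packaged compounds, frozen from
# an independent cheminformatics toolkit parsing the same SMILES
table1_formulas <- c(
  "C6H4N2O4", "C8H10", "C7H5N", "C7H8O", "C9H12", "C8H10", "C7H8O",
  "C8H10O", "C7H14", "C7H8", "C6H6O", "C6H12", "C6H3Br3O", "C14H10",
  "C7H6N2O4", "C8H8O2", "C8H10O", "C12H27O4P", "C16H10", "C3H4O4",
  "C12H3Br7O", "C19H17O4P", "C8H12Br4", "C6H5FO", "C12H7Br3O", "CH2O",
  "C3H9O4P", "C9H21O4P", "C6H4N2O4", "C8H9Br", "C8H10O", "C8H10O",
  "C6H7N", "CH2O2", "CHCl3", "C6H6", "C2H4O", "C6H15O4P", "C5H8",
  "C18H15OP", "C2H7O4P", "C14H10", "C13H10", "C6Br6", "C11H10", "C10H8",
  "C9H21O3P", "C12H10", "C8H8O2", "C9H10O2", "C8H8O", "C6H5NO2",
  "C6H4N2O4", "C7H7NO2")

# render a molecule_graph's formula in Hill order (C, H, then alphabetical)
hill_formula <- function(g) {
  cnt <- molecular_formula(g)
  els <- names(cnt)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(ord, ifelse(cnt[ord] > 1, cnt[ord], ""), collapse = "")
}
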