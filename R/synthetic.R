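# Synthetic test inputs: random molecular graphs for the descriptor oracles
# and linear-model datasets with known coefficients for the fitting and
# validation machinery. All generators are pure functions of their seed.

#' Generate random hydrogen-saturated molecular graphs
#'
#' Draws connected random graphs over a heavy-atom skeleton (a random
#' spanning tree, optionally with extra ring-closing edges and double bonds
#' where valence allows) and saturates every remaining valence with explicit
#' hydrogens. Used as descriptor-oracle inputs, not as chemically meaningful
#' structures.
#'
#' @param n_graphs Number of graphs.
#' @param n_atoms Length-2 range for the heavy-atom count.
#' @param elements Probability weights over heavy elements (named numeric).
#' @param p_ring Probability of attempting one extra ring-closing edge.
#' @param p_double Probability of upgrading an eligible bond to a double
#'   bond.
#' @param seed Integer seed.
#' @return List of `molecule_graph` objects.
#' @export
gen_graphs <- function(n_graphs, n_atoms = c(2, 8),
                       elements = c(C = 0.6, N = 0.15, O = 0.15, Cl = 0.1),
                       p_ring = 0.3, p_double = 0.2, seed = 1) {
  stopifnot(n_graphs >= 1, length(n_atoms) == 2L, n_atoms[1] >= 1,
            n_atoms[2] >= n_atoms[1], !is.null(names(elements)),
            all(names(elements) %in% supported_elements()))
  val <- vapply(names(elements), function(el)
    max(.default_valence[[el]]), numeric(1))
  with_seed(seed, lapply(seq_len(n_graphs), function(gi) {
    nh <- if (n_atoms[1] == n_atoms[2]) n_atoms[1]
          else sample(seq(n_atoms[1], n_atoms[2]), 1L)
    elem <- sample(names(elements), nh, replace = TRUE, prob = elements)
    bonds <- data.frame(i = integer(), j = integer(), order = numeric())
    if (nh > 1) {
      # random spanning tree: attach atom a to a uniformly chosen earlier atom
      parent <- vapply(2:nh, function(a) sample.int(a - 1L, 1L), integer(1))
      bonds <- data.frame(i = parent, j = 2:nh, order = 1)
    }
    used <- tabulate(c(bonds$i, bonds$j), nbins = nh)
    spare <- function(a) val[elem[a]] - used[a]
    if (nh > 2 && stats::runif(1) < p_ring) {
      free <- which(vapply(seq_len(nh), spare, numeric(1)) >= 1)
      key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
      if (length(free) >= 2) {
        pick <- sample(free, 2L)
        if (!paste(min(pick), max(pick)) %in% key) {
          bonds <- rbind(bonds, data.frame(i = pick[1], j = pick[2], order = 1))
          used[pick] <- used[pick] + 1L
        }
      }
    }
    for (b in seq_len(nrow(bonds))) {
      if (stats::runif(1) < p_double &&
          spare(bonds$i[b]) >= 1 && spare(bonds$j[b]) >= 1) {
        bonds$order[b] <- 2
        used[c(bonds$i[b], bonds$j[b])] <- used[c(bonds$i[b], bonds$j[b])] + 1L
      }
    }
    # hydrogen saturation
    atoms <- data.frame(element = elem, stringsAsFactors = FALSE)
    for (a in seq_len(nh)) {
      nfree <- spare(a)
      if (nfree > 0) for (h in seq_len(nfree)) {
        atoms <- rbind(atoms, data.frame(element = "H"))
        bonds <- rbind(bonds, data.frame(i = a, j = nrow(atoms), order = 1))
      }
    }
    new_molecule_graph(atoms, bonds)
  }))
}

#' Generate a linear-model dataset with known truth
#'
#' Samples a descriptor matrix with independent Gaussian columns and a
#' response `y = beta0 + X beta + N(0, sigma^2)`, the statistical structure
#' an MLR QSAR model assumes. The generating parameters are returned for
#' recovery scoring.
#'
#' @param n Number of rows; must exceed `length(beta) + 2`.
#' @param beta Numeric vector of true coefficients (its length sets `k`).
#' @param beta0 True intercept (default 0).
#' @param sigma Noise standard deviation (`>= 0`).
#' @param x_mean,x_sd Mean and standard deviation of the predictor columns
#'   (recycled over columns).
#' @param seed Integer seed.
#' @return List with `x` (data frame `x1..xk`), `y`, and the truth
#'   (`beta0`, `beta`, `sigma`, `seed`).
#' @export
gen_linear <- function(n, beta, beta0 = 0, sigma = 1,
                       x_mean = 0, x_sd = 1, seed = 1) {
  k <- length(beta)
  stopifnot(n > k + 2, sigma >= 0, k >= 1)
  x_mean <- rep_len(x_mean, k); x_sd <- rep_len(x_sd, k)
  with_seed(seed, {
    x <- vapply(seq_len(k), function(jc)
      stats::rnorm(n, x_mean[jc], x_sd[jc]), numeric(n))
    colnames(x) <- paste0("x", seq_len(k))
    y <- beta0 + drop(x %*% beta) + stats::rnorm(n, 0, sigma)
    list(x = as.data.frame(x), y = y, beta0 = beta0, beta = beta,
         sigma = sigma, seed = seed)
  })
}

#' Generate a dataset shaped like the adsorption-energy table
#'
#' A chemistry-free stand-in for the packaged dataset, for end-to-end
#' pipeline tests: 54 synthetic compounds whose response reproduces the
#' table's bimodal structure -- a conventional-pollutant cluster of 40
#' values around -9 kcal/mol and a flame-retardant cluster of 14 values
#' below -40 kcal/mol -- with four correlated pseudo-descriptors whose
#' pairwise correlations stay moderate (VIF < 10).
#'
#' @param seed Integer seed.
#' @param n_weak,n_strong Cluster sizes (defaults 40 and 14).
#' @return Data frame with `id`, `cluster`, pseudo-descriptors `x1..x4`, and
#'   the synthetic response `ead`.
#' @export
gen_paperlike <- function(seed = 1, n_weak = 40, n_strong = 14) {
  n <- n_weak + n_strong
  with_seed(seed, {
    ead <- c(pmin(stats::rnorm(n_weak, -9, 3.5), -0.3),
             stats::rnorm(n_strong, -48, 5))
    s <- stats::sd(ead)
    slopes <- c(0.8, -0.6, 0.7, -0.9)
    x <- vapply(slopes, function(a)
      a * ead + stats::rnorm(n, 0, s), numeric(n))
    colnames(x) <- paste0("x", seq_along(slopes))
    cbind(data.frame(id = sprintf("syn_%02d", seq_len(n)),
                     cluster = rep(c("conventional", "flame_retardant"),
                                   c(n_weak, n_strong)),
                     stringsAsFactors = FALSE),
          as.data.frame(x), ead = ead)
  })
}
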