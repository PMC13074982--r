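# 2D autocorrelation and Burden-matrix (BCUT) descriptors.
#
# All autocorrelations run over the hydrogen-explicit graph. Pairs are
# unordered (each {i,j} counted once) and lag 0 is the self-term sum(w^2)
# (or the centered / averaged variants thereof). A lag with no contributing
# atom pair yields 0, carrying an `undefined` attribute instead of NaN so
# descriptor tables stay finite.

.autocorr <- function(g, lag, scheme, centered, averaged) {
  stopifnot(inherits(g, "molecule_graph"), length(lag) == 1L, lag >= 0)
  w <- atom_weights(g, scheme)
  if (centered) w <- w - mean(w)
  if (lag == 0) {
    s <- sum(w^2)
    delta <- length(w)
  } else {
    idx <- which(g$dist == lag & upper.tri(g$dist))
    if (!length(idx)) {
      out <- 0
      attr(out, "undefined") <- TRUE
      return(out)
    }
    i <- (idx - 1L) %% nrow(g$dist) + 1L
    j <- (idx - 1L) %/% nrow(g$dist) + 1L
    s <- sum(w[i] * w[j])
    delta <- length(idx)
  }
  if (averaged) s / delta else s
}

#' Broto-Moreau autocorrelation descriptors
#'
#' Autocorrelation of an atomic property over the molecular graph: the sum of
#' weight products over unordered atom pairs separated by `lag` bonds, with
#' the lag-0 term defined as the sum of squared weights.
#'
#' * `ats()` - plain (uncentered) autocorrelation.
#' * `aats()` - averaged by the number of contributing terms (atom count at
#'   lag 0, pair count otherwise).
#' * `atsc()` - centered: weights are replaced by deviations from the mean
#'   weight over all atoms.
#' * `aatsc()` - centered and averaged; at lag 0 this is the population
#'   variance of the weights.
#'
#' @param g A `molecule_graph`.
#' @param lag Topological distance (bond count), a non-negative integer.
#' @param scheme Weighting scheme passed to [atom_weights()].
#' @return A single numeric value. When no atom pair exists at the requested
#'   lag the value is 0 and carries attribute `undefined = TRUE`.
#' @seealso [mats()] for the Moran variant, [bcut_w1h()].
#' @examples
#' benzene <- parse_smiles("c1ccccc1")
#' ats(benzene, 1, "m")
#' aatsc(benzene, 0, "v")   # population variance of volume weights
#' @export
ats <- function(g, lag, scheme = c("m", "v", "p"))
  .autocorr(g, lag, match.arg(scheme), centered = FALSE, averaged = FALSE)

#' @rdname ats
#' @export
aats <- function(g, lag, scheme = c("m", "v", "p"))
  .autocorr(g, lag, match.arg(scheme), centered = FALSE, averaged = TRUE)

#' @rdname ats
#' @export
atsc <- function(g, lag, scheme = c("m", "v", "p"))
  .autocorr(g, lag, match.arg(scheme), centered = TRUE, averaged = FALSE)

#' @rdname ats
#' @export
aatsc <- function(g, lag, scheme = c("m", "v", "p"))
  .autocorr(g, lag, match.arg(scheme), centered = TRUE, averaged = TRUE)

#' Moran autocorrelation descriptor
#'
#' Spatial-autocorrelation index of an atomic property over the molecular
#' graph: the averaged centered autocorrelation at the given lag divided by
#' the population variance of the weights. Values lie in \[-1, 1\] up to
#' floating tolerance. A graph with homogeneous weights (zero variance)
#' returns 0 by convention, as does a lag with no contributing pair.
#'
#' @inheritParams ats
#' @param lag Positive integer lag.
#' @return A single numeric value.
#' @export
mats <- function(g, lag, scheme = c("m", "v", "p")) {
  stopifnot(lag >= 1)
  scheme <- match.arg(scheme)
  w <- atom_weights(g, scheme)
  v <- mean((w - mean(w))^2)
  num <- .autocorr(g, lag, scheme, centered = TRUE, averaged = TRUE)
  if (v <= 0 || isTRUE(attr(num, "undefined"))) {
    out <- 0
    attr(out, "undefined") <- isTRUE(attr(num, "undefined"))
    return(out)
  }
  as.numeric(num) / v
}

# Burden connectivity matrix: exact atomic masses on the diagonal; bonded
# pairs get bond-order-scaled off-diagonals (order x 0.05, aromatic 1.5 x
# 0.05 = 0.075, +0.01 when either atom is terminal); all non-bonded pairs
# 0.001. The off-diagonal convention is calibrated against published
# BCUTw-1h reference values (benzene 12.15, aniline 14.00, nitrobenzene
# 16.00).
burden_matrix <- function(g) {
  n <- nrow(g$atoms)
  M <- matrix(0.001, n, n)
  diag(M) <- atom_weights(g, "m")
  if (nrow(g$bonds)) {
    term <- g$atoms$is_terminal
    for (b in seq_len(nrow(g$bonds))) {
      i <- g$bonds$i[b]; j <- g$bonds$j[b]
      x <- g$bonds$order[b] * 0.05
      if (term[i] || term[j]) x <- x + 0.01
      M[i, j] <- x; M[j, i] <- x
    }
  }
  M
}

#' Highest mass-weighted Burden eigenvalue (BCUTw-1h)
#'
#' The largest eigenvalue of the Burden connectivity matrix with exact atomic
#' masses on the diagonal. Electron-rich heteroatoms (N, O, halogens) raise
#' this descriptor because the top eigenvalue tracks the heaviest atoms and
#' their bonding environment.
#'
#' @param g A `molecule_graph` (must be connected; guaranteed by the parser).
#' @return A single numeric value.
#' @examples
#' round(bcut_w1h(parse_smiles("c1ccccc1")), 2)   # 12.15
#' @export
bcut_w1h <- function(g) {
  stopifnot(inherits(g, "molecule_graph"))
  max(eigen(burden_matrix(g), symmetric = TRUE, only.values = TRUE)$values)
}

# ---- descriptor tables ------------------------------------------------------

#' Names of the eight descriptors used by the adsorption-energy models
#'
#' @return Character vector of descriptor names.
#' @export
model_descriptor_names <- function()
  c("ATSC1m", "AATSC0v", "MATS1m", "BCUTw-1h",
    "AATS1m", "AATS7p", "ATSC0p", "AATSC1p")

#' All descriptor names implemented by the engine
#'
#' The Broto-Moreau families (ATS, AATS, ATSC, AATSC) at lags 0-7 and the
#' Moran family (MATS) at lags 1-7, each under the three weighting schemes,
#' plus `BCUTw-1h`.
#'
#' @return Character vector of descriptor names.
#' @export
descriptor_names <- function() {
  schemes <- c("m", "v", "p")
  nm <- c(
    outer(outer(c("ATS", "AATS", "ATSC", "AATSC"), 0:7, paste0), schemes, paste0),
    outer(outer("MATS", 1:7, paste0), schemes, paste0)
  )
  c(sort(as.character(nm)), "BCUTw-1h")
}

# Evaluate one named descriptor on one graph.
.descriptor_value <- function(g, name) {
  if (name == "BCUTw-1h") return(bcut_w1h(g))
  m <- regmatches(name, regexec("^(AATSC|AATS|ATSC|ATS|MATS)([0-7])([mvp])$", name))[[1]]
  if (!length(m))
    stop(sprintf("unknown descriptor '%s'; supported: %s", name,
                 paste(descriptor_names(), collapse = ", ")))
  fun <- switch(m[2], ATS = ats, AATS = aats, ATSC = atsc, AATSC = aatsc,
                MATS = mats)
  as.numeric(fun(g, as.integer(m[3]), m[4]))
}

#' Compute a descriptor table for a set of molecules
#'
#' @param molecules A character vector of SMILES, a list of `molecule_graph`
#'   objects, or a single `molecule_graph`.
#' @param names Descriptor names to compute; defaults to the eight
#'   descriptors used by the adsorption-energy models
#'   ([model_descriptor_names()]). See [descriptor_names()] for the full set.
#' @param id Optional identifiers for the rows; defaults to SMILES (or the
#'   list names, or a running index).
#' @return A data frame with an `id` column followed by one numeric column
#'   per descriptor, rows in input order. Writable with [utils::write.csv()].
#' @examples
#' molecular_descriptors(c("c1ccccc1", "Nc1ccccc1"), c("BCUTw-1h", "AATSC0v"))
#' @export
molecular_descriptors <- function(molecules, names = model_descriptor_names(),
                                  id = NULL) {
  if (inherits(molecules, "molecule_graph")) molecules <- list(molecules)
  if (is.character(molecules)) {
    if (is.null(id)) id <- molecules
    molecules <- lapply(molecules, parse_smiles)
  } else if (is.list(molecules)) {
    if (is.null(id))
      id <- if (!is.null(base::names(molecules))) base::names(molecules)
            else as.character(seq_along(molecules))
  } else stop("'molecules' must be SMILES strings or molecule_graph objects")
  stopifnot(all(vapply(molecules, inherits, logical(1), "molecule_graph")),
            length(id) == length(molecules))
  for (nm in names) .check_descriptor_name(nm)
  vals <- matrix(NA_real_, length(molecules), length(names),
                 dimnames = list(NULL, names))
  for (r in seq_along(molecules))
    for (nm in names)
      vals[r, nm] <- .descriptor_value(molecules[[r]], nm)
  out <- data.frame(id = id, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(vals, check.names = FALSE))
  rownames(out) <- NULL
  out
}

.check_descriptor_name <- function(name) {
  if (!name %in% descriptor_names())
    stop(sprintf("unknown descriptor '%s'; supported: %s", name,
                 paste(descriptor_names(), collapse = ", ")))
  invisible(name)
}

#' Drop all-zero (and optionally constant) descriptor columns
#'
#' Screening step applied to a descriptor table before model development:
#' descriptors that are zero for every compound carry no information and are
#' removed; setting `drop_constant = TRUE` also removes columns with zero
#' variance.
#'
#' @param table A data frame as returned by [molecular_descriptors()];
#'   non-numeric columns (such as `id`) are kept untouched.
#' @param drop_constant Also drop constant non-zero columns (default `FALSE`).
#' @param tol Numerical tolerance for "zero".
#' @return The reduced data frame, with attribute `dropped` listing the
#'   removed descriptor names.
#' @export
drop_constant_descriptors <- function(table, drop_constant = FALSE,
                                      tol = 1e-12) {
  stopifnot(is.data.frame(table), nrow(table) > 0)
  num <- vapply(table, is.numeric, logical(1))
  kill <- vapply(seq_along(table), function(jc) {
    if (!num[jc]) return(FALSE)
    x <- table[[jc]]
    all(abs(x) < tol) || (drop_constant && max(x) - min(x) < tol)
  }, logical(1))
  out <- table[, !kill, drop = FALSE]
  attr(out, "dropped") <- names(table)[kill]
  out
}
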