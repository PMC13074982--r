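# Hydrogen-explicit molecular graphs from SMILES.
#
# The parser covers the SMILES subset needed for small organic pollutants:
# the organic subset (C, N, O, P, F, Cl, Br and their aromatic lowercase
# forms), bracket atoms with charge and explicit hydrogen counts, branches,
# ring closures (including %nn) and the bond symbols - = # : / \.
# Aromaticity is taken from the SMILES annotation itself (lowercase atoms /
# ':' bonds); Kekule input is accepted but its ring bonds keep their written
# orders. Stereo markers are read and ignored. Disconnected inputs ('.')
# are rejected: descriptors are only defined for connected graphs.

.parse_error <- function(msg, smiles, pos = NULL) {
  loc <- if (!is.null(pos)) sprintf(" at position %d", pos) else ""
  stop(errorCondition(
    sprintf("cannot parse SMILES '%s': %s%s", smiles, msg, loc),
    class = c("mpqsar_parse_error", "error", "condition")))
}

.unsupported_element <- function(el, smiles) {
  stop(errorCondition(
    sprintf("unsupported element '%s' in SMILES '%s' (supported: %s)",
            el, smiles, paste(supported_elements(), collapse = ", ")),
    class = c("mpqsar_unsupported_element", "error", "condition")))
}

# default valences used for implicit hydrogen counts
.default_valence <- list(C = 4, N = 3, O = 2, F = 1, Cl = 1, Br = 1, P = c(3, 5))

#' Parse a SMILES string into a hydrogen-explicit molecular graph
#'
#' Builds an atom/bond graph from a SMILES string, adds implicit hydrogens as
#' explicit atoms, and computes the topological (bond-count) distance matrix.
#' Only the elements in [supported_elements()] are accepted.
#'
#' @param smiles A single SMILES string.
#' @param hydrogens Add implicit hydrogens as explicit atoms (default `TRUE`;
#'   all descriptor routines assume hydrogen-explicit graphs).
#' @return An object of class `molecule_graph`: a list with components
#'   `atoms` (data frame: `element`, `aromatic`, `charge`, `is_terminal`),
#'   `bonds` (data frame: `i`, `j`, `order` with aromatic bonds coded 1.5),
#'   `dist` (integer matrix of shortest-path bond counts) and `smiles`.
#' @examples
#' g <- parse_smiles("c1ccccc1")   # benzene: 6 C + 6 H
#' nrow(g$atoms)
#' @export
parse_smiles <- function(smiles, hydrogens = TRUE) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles))
    stop("'smiles' must be a single non-empty string")

  ch <- strsplit(smiles, "")[[1]]
  n <- length(ch)

  element <- character(); aromatic <- logical(); charge <- integer()
  hcount <- integer()  # NA = implicit (organic subset), >=0 = fixed (bracket)
  bi <- integer(); bj <- integer(); border <- numeric(); bdefault <- logical()

  prev <- NA_integer_
  stack <- integer()
  pending <- NA_real_   # NA = unspecified bond
  ring <- list()        # ring-closure bookkeeping: number -> list(atom, bond)

  add_bond <- function(a, b, order, default) {
    if (a == b) .parse_error("self-bond", smiles)
    bi <<- c(bi, a); bj <<- c(bj, b)
    border <<- c(border, order); bdefault <<- c(bdefault, default)
  }

  add_atom <- function(el, arom, chg, hc) {
    element <<- c(element, el); aromatic <<- c(aromatic, arom)
    charge <<- c(charge, chg); hcount <<- c(hcount, hc)
    idx <- length(element)
    if (!is.na(prev)) {
      add_bond(prev, idx, if (is.na(pending)) 1 else pending, is.na(pending))
      pending <<- NA_real_
    }
    prev <<- idx
    idx
  }

  close_ring <- function(num, pos) {
    if (is.na(prev)) .parse_error("ring bond before any atom", smiles, pos)
    key <- as.character(num)
    if (is.null(ring[[key]])) {
      ring[[key]] <<- list(atom = prev, bond = pending)
      pending <<- NA_real_
    } else {
      open <- ring[[key]]
      b <- pending
      if (is.na(b)) b <- open$bond
      else if (!is.na(open$bond) && open$bond != b)
        .parse_error(sprintf("conflicting ring-closure bond orders for ring %s", key),
                     smiles, pos)
      add_bond(open$atom, prev, if (is.na(b)) 1 else b, is.na(b))
      ring[[key]] <<- NULL
      pending <<- NA_real_
    }
  }

  i <- 1L
  while (i <= n) {
    c1 <- ch[i]
    c2 <- if (i < n) paste0(c1, ch[i + 1L]) else ""
    if (c1 == "(") {
      if (is.na(prev)) .parse_error("branch before any atom", smiles, i)
      stack <- c(stack, prev); i <- i + 1L
    } else if (c1 == ")") {
      if (!length(stack)) .parse_error("unmatched ')'", smiles, i)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (c1 %in% c("-", "/", "\\")) {
      pending <- 1; i <- i + 1L
    } else if (c1 == "=") {
      pending <- 2; i <- i + 1L
    } else if (c1 == "#") {
      pending <- 3; i <- i + 1L
    } else if (c1 == ":") {
      pending <- 1.5; i <- i + 1L
    } else if (c1 == ".") {
      .parse_error("disconnected structures ('.') are not supported", smiles, i)
    } else if (c1 == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste0(ch[i + 1L], ch[i + 2L])))
        .parse_error("'%' must be followed by two digits", smiles, i)
      close_ring(as.integer(paste0(ch[i + 1L], ch[i + 2L])), i)
      i <- i + 3L
    } else if (grepl("^[0-9]$", c1)) {
      close_ring(as.integer(c1), i)
      i <- i + 1L
    } else if (c1 == "[") {
      j <- i
      while (j <= n && ch[j] != "]") j <- j + 1L
      if (j > n) .parse_error("unterminated bracket atom", smiles, i)
      body <- paste(ch[(i + 1L):(j - 1L)], collapse = "")
      m <- regexec("^([0-9]*)([A-Z][a-z]?|[a-z])(@{0,2})(H[0-9]*)?([+-][0-9]*|\\+{2,}|-{2,})?$",
                   body)[[1]]
      if (m[1] == -1) .parse_error(sprintf("malformed bracket atom '[%s]'", body),
                                   smiles, i)
      parts <- regmatches(body, list(m))[[1]]
      el <- parts[3]
      arom <- el == tolower(el)
      el_std <- if (arom) paste0(toupper(substr(el, 1, 1)), substring(el, 2)) else el
      if (!el_std %in% supported_elements()) .unsupported_element(el_std, smiles)
      hs <- parts[5]
      hc <- if (hs == "") 0L else if (hs == "H") 1L else as.integer(substring(hs, 2))
      cs <- parts[6]
      chg <- if (cs == "") 0L
        else if (grepl("^\\++$", cs)) nchar(cs)
        else if (grepl("^-+$", cs)) -nchar(cs)
        else if (nchar(cs) == 1L) ifelse(cs == "+", 1L, -1L)
        else as.integer(paste0(substr(cs, 1, 1), substring(cs, 2))) *
             ifelse(substr(cs, 1, 1) == "+", 1L, 1L)
      if (cs %in% c("+", "-")) chg <- ifelse(cs == "+", 1L, -1L)
      add_atom(el_std, arom, as.integer(chg), hc)
      i <- j + 1L
    } else if (c2 %in% c("Cl", "Br")) {
      add_atom(c2, FALSE, 0L, NA_integer_); i <- i + 2L
    } else if (c1 %in% c("C", "N", "O", "P", "F")) {
      add_atom(c1, FALSE, 0L, NA_integer_); i <- i + 1L
    } else if (c1 %in% c("c", "n", "o", "p")) {
      add_atom(toupper(c1), TRUE, 0L, NA_integer_); i <- i + 1L
    } else if (c1 %in% c("B", "S", "I", "b", "s") ||
               grepl("^[A-Za-z]$", c1)) {
      .unsupported_element(c1, smiles)
    } else {
      .parse_error(sprintf("unexpected token '%s'", c1), smiles, i)
    }
  }
  if (length(stack)) .parse_error("unmatched '('", smiles)
  if (length(ring)) .parse_error(
    sprintf("unclosed ring bond(s): %s", paste(names(ring), collapse = ", ")), smiles)
  if (!is.na(pending)) .parse_error("dangling bond symbol", smiles)
  if (!length(element)) .parse_error("no atoms", smiles)

  # Resolve unspecified bonds between two aromatic atoms: aromatic (order 1.5)
  # when the bond lies on a cycle, plain single otherwise (e.g. biphenyl link).
  for (b in which(bdefault & aromatic[bi] & aromatic[bj])) {
    if (.in_cycle(length(element), bi, bj, b)) border[b] <- 1.5
  }

  # implicit hydrogen counts for organic-subset atoms
  bsum <- numeric(length(element))
  for (b in seq_along(bi)) {
    bsum[bi[b]] <- bsum[bi[b]] + border[b]
    bsum[bj[b]] <- bsum[bj[b]] + border[b]
  }
  nh <- hcount
  for (a in which(is.na(hcount))) {
    val <- .default_valence[[element[a]]]
    need <- ceiling(bsum[a] - 1e-9)
    val <- val[val >= need][1]
    nh[a] <- if (is.na(val)) 0L else as.integer(val - need)
  }

  atoms <- data.frame(element = element, aromatic = aromatic, charge = charge,
                      stringsAsFactors = FALSE)
  bonds <- data.frame(i = bi, j = bj, order = border)
  if (hydrogens && any(nh > 0L)) {
    for (a in seq_along(nh)) {
      if (nh[a] > 0L) for (k in seq_len(nh[a])) {
        atoms <- rbind(atoms, data.frame(element = "H", aromatic = FALSE,
                                         charge = 0L))
        bonds <- rbind(bonds, data.frame(i = a, j = nrow(atoms), order = 1))
      }
    }
  }
  new_molecule_graph(atoms, bonds, smiles = smiles)
}

# is bond b (endpoints bi[b], bj[b]) on a cycle? i.e. endpoints still
# connected when the bond is removed
.in_cycle <- function(n_atoms, bi, bj, b) {
  keep <- setdiff(seq_along(bi), b)
  adj <- vector("list", n_atoms)
  for (e in keep) {
    adj[[bi[e]]] <- c(adj[[bi[e]]], bj[e])
    adj[[bj[e]]] <- c(adj[[bj[e]]], bi[e])
  }
  seen <- logical(n_atoms)
  queue <- bi[b]; seen[queue] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  seen[bj[b]]
}

#' Construct a molecule graph from atom and bond tables
#'
#' Low-level constructor used by [parse_smiles()] and by the synthetic graph
#' generator. Validates connectivity, checks elements against the property
#' table, flags terminal atoms and computes the topological distance matrix.
#'
#' @param atoms Data frame with at least an `element` column; optional
#'   `aromatic` and `charge` columns default to `FALSE` / `0`.
#' @param bonds Data frame with columns `i`, `j` and `order` (1, 2, 3, or
#'   1.5 for aromatic). A single-atom molecule may have zero bonds.
#' @param smiles Optional SMILES string to carry along as provenance.
#' @return A `molecule_graph` object; see [parse_smiles()].
#' @export
new_molecule_graph <- function(atoms, bonds, smiles = NA_character_) {
  stopifnot(is.data.frame(atoms), "element" %in% names(atoms),
            is.data.frame(bonds))
  if (is.null(atoms$aromatic)) atoms$aromatic <- FALSE
  if (is.null(atoms$charge)) atoms$charge <- 0L
  bad <- setdiff(unique(atoms$element), supported_elements())
  if (length(bad)) .unsupported_element(bad[1], smiles)
  na <- nrow(atoms)
  if (nrow(bonds)) {
    stopifnot(all(c("i", "j", "order") %in% names(bonds)),
              all(bonds$i >= 1), all(bonds$j >= 1),
              all(bonds$i <= na), all(bonds$j <= na),
              all(bonds$i != bonds$j),
              all(bonds$order %in% c(1, 1.5, 2, 3)))
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) stop("duplicate bonds between the same atom pair")
  }
  g <- structure(list(atoms = atoms, bonds = bonds, smiles = smiles),
                 class = "molecule_graph")
  g$dist <- topological_distances(g)
  deg <- tabulate(c(bonds$i, bonds$j), nbins = na)
  g$atoms$is_terminal <- deg == 1L
  rownames(g$atoms) <- NULL
  rownames(g$bonds) <- NULL
  g
}

#' Topological distance matrix of a molecular graph
#'
#' All-pairs shortest path lengths counted in bonds, the "lag" underlying the
#' autocorrelation descriptors.
#'
#' @param g A `molecule_graph`.
#' @return A symmetric integer matrix with zero diagonal.
#' @export
topological_distances <- function(g) {
  stopifnot(inherits(g, "molecule_graph"))
  na <- nrow(g$atoms)
  if (na == 1L) return(matrix(0L, 1L, 1L))
  ig <- igraph::make_empty_graph(n = na, directed = FALSE)
  ig <- igraph::add_edges(ig, rbind(g$bonds$i, g$bonds$j))
  d <- igraph::distances(ig)
  if (any(is.infinite(d)))
    stop(errorCondition("molecular graph is disconnected",
                        class = c("mpqsar_disconnected", "error", "condition")))
  storage.mode(d) <- "integer"
  dimnames(d) <- NULL
  d
}

#' Atomic weight vector for a weighting scheme
#'
#' @param g A `molecule_graph`.
#' @param scheme `"m"` (exact atomic mass), `"v"` (van der Waals volume) or
#'   `"p"` (atomic polarizability); see [atom_property_table()].
#' @return Numeric vector, one weight per atom, in atom order.
#' @export
atom_weights <- function(g, scheme = c("m", "v", "p")) {
  stopifnot(inherits(g, "molecule_graph"))
  scheme <- match.arg(scheme)
  column <- c(m = "mass", v = "vdw_volume", p = "polarizability")[[scheme]]
  .atom_property(g$atoms$element, column)
}

#' @export
print.molecule_graph <- function(x, ...) {
  counts <- table(x$atoms$element)
  formula <- paste0(names(counts), ifelse(counts > 1, counts, ""), collapse = "")
  cat(sprintf("<molecule_graph> %s  (%d atoms, %d bonds)\n",
              formula, nrow(x$atoms), nrow(x$bonds)))
  if (!is.na(x$smiles)) cat("  smiles:", x$smiles, "\n")
  invisible(x)
}

#' Molecular formula counts of a graph
#'
#' @param g A `molecule_graph`.
#' @return Named integer vector of element counts, alphabetical by symbol.
#' @export
molecular_formula <- function(g) {
  stopifnot(inherits(g, "molecule_graph"))
  counts <- table(g$atoms$element)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out[order(names(out))]
}
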