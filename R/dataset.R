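# The packaged 54-compound adsorption-energy dataset and its bookkeeping.

# column sums used as an integrity checksum for the packaged table
.table1_checksums <- c(ead_pe = -1144.67, ead_pom = -853.45, ead_pva = -974.70)

#' The 54-compound aqueous adsorption-energy dataset
#'
#' DFT-derived adsorption energies (kcal/mol) of 54 organic compounds --
#' 40 conventional aliphatic/aromatic pollutants, six brominated and eight
#' phosphorus-based flame retardants -- on polyethylene (PE),
#' polyoxymethylene (POM) and polyvinyl alcohol (PVA) microplastics in
#' implicit water, together with curated SMILES. More negative values mean
#' stronger adsorption.
#'
#' @return A data frame with columns `index`, `cas`, `name`, `smiles`,
#'   `ead_pe`, `ead_pom`, `ead_pva` (54 rows). The load is checksum-verified
#'   against totals embedded in the package.
#' @examples
#' d <- mp_adsorption_data()
#' range(d$ead_pe)
#' @export
mp_adsorption_data <- function() {
  if (is.null(.mpqsar_env$table1)) {
    path <- system.file("extdata", "table1.csv", package = "mpqsar",
                        mustWork = TRUE)
    # '#' appears inside SMILES (triple bonds), so strip comment lines by hand
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "#")]
    tab <- utils::read.csv(text = paste(ln, collapse = "\n"),
                           stringsAsFactors = FALSE)
    sums <- round(c(ead_pe = sum(tab$ead_pe), ead_pom = sum(tab$ead_pom),
                    ead_pva = sum(tab$ead_pva)), 2)
    if (nrow(tab) != 54L || anyNA(tab) || any(tab[, 5:7] >= 0) ||
        !isTRUE(all.equal(sums, .table1_checksums)))
      stop(errorCondition("packaged adsorption dataset failed integrity check",
                          class = c("mpqsar_integrity", "error", "condition")))
    .mpqsar_env$table1 <- tab
  }
  .mpqsar_env$table1
}

#' Adsorption energy from total energies
#'
#' Bookkeeping for user-supplied electronic-structure totals: the adsorption
#' energy is the energy of the polymer--compound complex minus the energies
#' of the isolated polymer and the isolated compound, all in consistent
#' units.
#'
#' @param e_complex Total energy of the microplastic + compound complex.
#' @param e_mps Total energy of the microplastic alone.
#' @param e_com Total energy of the compound alone.
#' @return `e_complex - e_mps - e_com` (vectorized).
#' @examples
#' adsorption_energy(-100, -60, -35)   # -5
#' @export
adsorption_energy <- function(e_complex, e_mps, e_com) {
  stopifnot(is.numeric(e_complex), is.numeric(e_mps), is.numeric(e_com),
            all(is.finite(e_complex)), all(is.finite(e_mps)),
            all(is.finite(e_com)))
  e_complex - e_mps - e_com
}

#' Seeded training/validation split
#'
#' Randomly splits `n` compounds into training and validation sets at the
#' given ratio (default 4:1, i.e. 43/11 for the 54-compound dataset). The
#' split is a pure function of `seed`.
#'
#' @param n Number of compounds, or a data frame whose rows are compounds.
#' @param ratio Two integers, training : validation (default `c(4, 1)`).
#' @param seed Integer seed controlling the split.
#' @return An object of class `split_spec`: list with integer vectors
#'   `train` and `validation` (sorted, disjoint, covering `1:n`), plus
#'   `n_train`, `n_validation`, `ratio` and `seed`.
#' @examples
#' sp <- split_dataset(54, seed = 1)
#' c(sp$n_train, sp$n_validation)   # 43 11
#' @export
split_dataset <- function(n, ratio = c(4, 1), seed) {
  if (is.data.frame(n)) n <- nrow(n)
  stopifnot(length(n) == 1L, n >= 2, length(ratio) == 2L, all(ratio > 0))
  n_val <- round(n * ratio[2] / sum(ratio))
  if (n_val < 1 || n_val >= n)
    stop("invalid ratio: validation set would be empty or exhaust the data")
  val <- sort(with_seed(seed, sample.int(n, n_val)))
  structure(list(train = setdiff(seq_len(n), val), validation = val,
                 n_train = n - n_val, n_validation = n_val,
                 ratio = ratio, seed = seed),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec> %d train / %d validation (ratio %d:%d, seed %s)\n",
              x$n_train, x$n_validation, x$ratio[1], x$ratio[2],
              format(x$seed)))
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state; all randomized routines in the package funnel through this.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
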