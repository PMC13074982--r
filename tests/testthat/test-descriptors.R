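# Autocorrelation and BCUT descriptor machinery against brute-force oracles.

test_that("autocorrelation base cases follow the definitions", {
  lone <- new_molecule_graph(data.frame(element = "Cl"),
                             data.frame(i = integer(), j = integer(),
                                        order = numeric()))
  w <- atom_weights(lone, "m")
  expect_equal(ats(lone, 0, "m"), w^2)
  expect_equal(as.numeric(aats(lone, 0, "m")), w^2)

  pair <- bare_pair("C", "Cl")
  wp <- atom_weights(pair, "m")
  expect_equal(ats(pair, 1, "m"), wp[1] * wp[2])
  # homonuclear pair: one contributing pair, so AATS1 = w^2
  cc <- bare_pair("C", "C")
  expect_equal(as.numeric(aats(cc, 1, "m")),
               atom_property_table()["C", "mass"]^2)

  benzene <- parse_smiles("c1ccccc1")
  wb <- atom_weights(benzene, "m")
  expect_equal(as.numeric(aats(benzene, 0, "m")), mean(wb^2))
})

test_that("all autocorrelation families match the pair-enumeration oracle", {
  graphs <- gen_graphs(50, n_atoms = c(2, 10), seed = 101)
  for (g in graphs) for (lag in 0:7) for (scheme in c("m", "v", "p")) {
    expect_equal(as.numeric(ats(g, lag, scheme)),
                 brute_autocorr(g, lag, scheme), tolerance = 1e-9)
    expect_equal(as.numeric(aats(g, lag, scheme)),
                 brute_autocorr(g, lag, scheme, averaged = TRUE),
                 tolerance = 1e-9)
    expect_equal(as.numeric(atsc(g, lag, scheme)),
                 brute_autocorr(g, lag, scheme, centered = TRUE),
                 tolerance = 1e-9)
    expect_equal(as.numeric(aatsc(g, lag, scheme)),
                 brute_autocorr(g, lag, scheme, centered = TRUE,
                                averaged = TRUE), tolerance = 1e-9)
    if (lag >= 1)
      expect_equal(as.numeric(mats(g, lag, scheme)),
                   brute_moran(g, lag, scheme), tolerance = 1e-9)
  }
})

test_that("centering annihilates homogeneous weights and bounds hold", {
  ring <- bare_carbon_ring(6)
  for (lag in 0:3) expect_equal(as.numeric(atsc(ring, lag, "m")), 0)
  expect_equal(as.numeric(mats(ring, 1, "m")), 0)   # 0/0 convention

  graphs <- gen_graphs(100, n_atoms = c(3, 10), seed = 7)
  for (g in graphs) {
    expect_gte(as.numeric(atsc(g, 0, "m")), 0)
    w <- atom_weights(g, "v")
    expect_equal(as.numeric(aatsc(g, 0, "v")), mean((w - mean(w))^2),
                 tolerance = 1e-12)
  }

  # two-level weight patterns reach the Moran extreme of -1 exactly:
  # a heteronuclear pair, and a perfect star (methane) at lag 1
  expect_equal(as.numeric(mats(bare_pair("C", "O"), 1, "m")), -1)
  expect_equal(as.numeric(mats(parse_smiles("C"), 1, "m")), -1)
})

test_that("lags with no atom pair return zero with an undefined flag", {
  ethane <- parse_smiles("CC")   # max distance 3
  v <- ats(ethane, 7, "m")
  expect_equal(as.numeric(v), 0)
  expect_true(attr(v, "undefined"))
  expect_true(attr(aats(ethane, 7, "p"), "undefined"))
  expect_true(attr(mats(ethane, 7, "m"), "undefined"))
})

test_that("descriptors are invariant under atom relabeling", {
  g <- parse_smiles("CC(=O)Oc1ccccc1")
  n <- nrow(g$atoms)
  perm <- c(seq(2, n, by = 2), seq(1, n, by = 2))  # deterministic shuffle
  inv <- order(perm)
  g2 <- new_molecule_graph(g$atoms[perm, c("element", "aromatic", "charge")],
                           data.frame(i = inv[g$bonds$i], j = inv[g$bonds$j],
                                      order = g$bonds$order))
  for (nm in model_descriptor_names())
    expect_equal(mpqsar:::.descriptor_value(g2, nm),
                 mpqsar:::.descriptor_value(g, nm), tolerance = 1e-9)
})

test_that("descriptor tables are total, deterministic and validated", {
  d <- mp_adsorption_data()
  tab <- molecular_descriptors(d$smiles, model_descriptor_names(), id = d$name)
  expect_equal(dim(tab), c(54, 9))
  expect_true(all(is.finite(as.matrix(tab[, -1]))))

  empty <- molecular_descriptors(character(0), c("ATS1m", "BCUTw-1h"))
  expect_equal(nrow(empty), 0)
  expect_equal(colnames(empty), c("id", "ATS1m", "BCUTw-1h"))

  rep2 <- molecular_descriptors(c("Cc1ccccc1", "Cc1ccccc1"))
  expect_equal(rep2[1, -1], rep2[2, -1], ignore_attr = TRUE)

  expect_error(molecular_descriptors("CC", "ATS9m"), regexp = "supported")
  expect_error(molecular_descriptors("CC", "XLogP"), regexp = "supported")
})

test_that("all-zero descriptor columns are screened out", {
  tab <- data.frame(id = letters[1:5], a = rnorm(5), z = rep(0, 5),
                    c = rep(2, 5))
  red <- drop_constant_descriptors(tab)
  expect_equal(colnames(red), c("id", "a", "c"))
  expect_equal(attr(red, "dropped"), "z")

  red2 <- drop_constant_descriptors(tab, drop_constant = TRUE)
  expect_equal(colnames(red2), c("id", "a"))

  clean <- data.frame(a = rnorm(5), b = rnorm(5))
  expect_equal(drop_constant_descriptors(clean), clean, ignore_attr = TRUE)

  wide <- as.data.frame(matrix(rnorm(50 * 6), 6))
  wide[, 1:10] <- 0
  expect_equal(ncol(drop_constant_descriptors(wide)), 40)
})
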