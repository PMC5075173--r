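# Charge model: ionizable-group counting, net charge, bisection pI,
# molecular weight, composition. Oracle comparisons use the independent
# grid-scan oracle from helper-oracles.R.

test_that("count_ionizable tallies the seven charged residues", {
  c1 <- count_ionizable("DECK")
  expect_equal(c1$counts[c("D", "E", "C", "K")], c(D = 1L, E = 1L, C = 1L, K = 1L))
  expect_equal(sum(c1$counts), 4L)

  c2 <- count_ionizable("ggGG")
  expect_equal(sum(c2$counts), 0L)
  expect_true(c2$has_nterm && c2$has_cterm)

  c3 <- count_ionizable("KKKKDDDD")
  expect_equal(c3$counts[["K"]], 4L)
  expect_equal(c3$counts[["D"]], 4L)
})

test_that("counting is case-insensitive, whitespace-tolerant, reproducible", {
  a <- count_ionizable("dEcK\n r")
  b <- count_ionizable("DECKR")
  expect_identical(a$counts, b$counts)
  expect_identical(a, count_ionizable("dEcK\n r"))
})

test_that("non-standard letters warn and are skipped; U is not cysteine", {
  expect_warning(c1 <- count_ionizable("DXECK"), "non-standard")
  expect_equal(sum(c1$counts), 4L)
  expect_equal(c1$length, 4L)
  expect_warning(c2 <- count_ionizable("UGG"), "non-standard")
  expect_equal(c2$counts[["C"]], 0L)
  expect_error(count_ionizable(""), "empty")
  expect_error(count_ionizable("  \n "), "empty")
})

test_that("net charge is zero at the termini midpoint of a glycine run", {
  mid <- (9.564 + 2.383) / 2
  expect_equal(net_charge("GGGG", mid, "IPC_peptide"), 0, tolerance = 1e-12)
})

test_that("a single ionizable group carries charge 0.5 at its own pKa", {
  pk <- get_pka_set("EMBOSS")
  asp <- count_ionizable("D", nterm = FALSE, cterm = FALSE)
  expect_equal(net_charge(asp, pk$values[["D"]], pk), -0.5)
  lys <- count_ionizable("K", nterm = FALSE, cterm = FALSE)
  expect_equal(net_charge(lys, pk$values[["K"]], pk), 0.5)
})

test_that("net charge matches the independent per-group summation", {
  pk <- get_pka_set("EMBOSS")
  for (ph in c(2, 7, 11.5)) {
    expect_equal(net_charge("DEKRHCY", ph, pk),
                 oracle_charge("DEKRHCY", ph, pk$values),
                 tolerance = 1e-12)
  }
  set.seed(42)
  for (i in 1:20) {
    s <- random_aa_sequence(sample(5:60, 1))
    nm <- sample(list_pka_sets(), 1)
    ph <- runif(1, 0, 14)
    expect_equal(net_charge(s, ph, nm),
                 oracle_charge(s, ph, get_pka_set(nm)$values),
                 tolerance = 1e-12, info = paste(nm, s))
  }
})

test_that("net charge is strictly decreasing in pH (property)", {
  set.seed(7)
  for (i in 1:50) {
    s <- random_aa_sequence(sample(5:80, 1))
    nm <- sample(list_pka_sets(), 1)
    ph <- sort(runif(2, 0, 14))
    expect_gt(net_charge(s, ph[1], nm), net_charge(s, ph[2], nm))
  }
})

test_that("charge limits equal the group counts at extreme pH", {
  set.seed(8)
  for (i in 1:10) {
    s <- random_aa_sequence(sample(5:50, 1))
    cn <- count_ionizable(s)
    n_pos <- 1 + cn$counts[["H"]] + cn$counts[["K"]] + cn$counts[["R"]]
    n_neg <- 1 + cn$counts[["C"]] + cn$counts[["D"]] + cn$counts[["E"]] +
      cn$counts[["Y"]]
    expect_equal(net_charge(s, -20, "EMBOSS"), n_pos, tolerance = 1e-6)
    expect_equal(net_charge(s, 34, "EMBOSS"), -n_neg, tolerance = 1e-6)
  }
})

test_that("pI of a no-side-chain sequence is the termini pKa midpoint, all sets", {
  for (nm in list_pka_sets()) {
    v <- get_pka_set(nm)$values
    expect_equal(isoelectric_point("GGGG", nm)$pi,
                 (v[["NTERM"]] + v[["CTERM"]]) / 2,
                 tolerance = 0.001, info = nm)
  }
  expect_equal(isoelectric_point("GGGG", "IPC_peptide")$pi, 5.9735,
               tolerance = 0.001)
  expect_equal(isoelectric_point("GGGG", "Lehninger")$pi, 6.015,
               tolerance = 0.001)
})

test_that("bisection agrees with the grid-scan oracle on random sequences", {
  set.seed(101)
  sets <- c("EMBOSS", "IPC_protein", "Patrickios")
  for (i in 1:40) {
    s <- random_aa_sequence(sample(5:200, 1))
    for (nm in sets) {
      got <- isoelectric_point(s, nm)$pi
      want <- oracle_grid_pi(s, get_pka_set(nm)$values)
      expect_lt(abs(got - want), 0.001 + 1e-4, label = paste(nm, s))
    }
  }
})

test_that("the hierarchical grid oracle equals the flat exhaustive scan", {
  v <- get_pka_set("EMBOSS")$values
  for (s in c("KRKRDEDE", "MVHLGPKKPQARKGSMADC")) {
    expect_equal(oracle_grid_pi(s, v), oracle_grid_pi_flat(s, v),
                 tolerance = 1e-12)
  }
})

test_that("convergence takes at most ceil(log2(14/precision)) iterations", {
  for (prec in c(0.01, 0.001)) {
    p <- isoelectric_point("KRKRDEDE", "EMBOSS", precision = prec)
    expect_lte(p$iterations, ceiling(log2(14 / prec)))
    expect_equal(p$precision, prec)
  }
  # ~ a dozen iterations at the default 0.001 precision (warm start halves
  # the 14-unit bracket first)
  expect_lte(isoelectric_point("KRKRDEDE", "EMBOSS")$iterations, 14L)
})

test_that("appending acids never raises pI; appending bases never lowers it", {
  set.seed(55)
  for (i in 1:30) {
    s <- random_aa_sequence(sample(5:60, 1))
    nm <- sample(list_pka_sets(), 1)
    base <- isoelectric_point(s, nm)$pi
    acid <- sample(c("D", "E"), 1)
    base_dn <- isoelectric_point(paste0(s, acid), nm)$pi
    expect_lte(base_dn, base + 0.002, label = paste(nm, s, acid))
    alk <- sample(c("K", "R"), 1)
    base_up <- isoelectric_point(paste0(s, alk), nm)$pi
    expect_gte(base_up, base - 0.002, label = paste(nm, s, alk))
  }
})

test_that("degenerate inputs raise the documented errors", {
  # no ionizable group at all: glycines with both termini blocked
  cn <- count_ionizable("GGGG", nterm = FALSE, cterm = FALSE)
  expect_error(isoelectric_point(cn, "EMBOSS"), "no ionizable groups")
  # no root in [0, 14]: only basic groups, C-terminus blocked
  lys <- count_ionizable("KKK", cterm = FALSE)
  expect_error(isoelectric_point(lys, "EMBOSS"), "constant sign")
})

test_that("molecular weight uses average masses plus one water", {
  expect_equal(molecular_weight("G"), 75.07, tolerance = 0.01)
  expect_equal(molecular_weight("GG"), 132.12, tolerance = 0.01)
  expect_error(molecular_weight(""), "empty")
  # independent check: sum of table masses
  s <- "ACDEFGHIKLMNPQRSTVWY"
  expect_equal(molecular_weight(s),
               sum(c(71.0788, 103.1388, 115.0886, 129.1155, 147.1766,
                     57.0519, 137.1411, 113.1594, 128.1741, 113.1594,
                     131.1926, 114.1038, 97.1167, 128.1307, 156.1875,
                     87.0782, 101.1051, 99.1326, 186.2132, 163.1760)) +
                 18.01524,
               tolerance = 1e-6)
})

test_that("aa_composition returns fractions that sum to one", {
  expect_equal(aa_composition("AAAA"), c(A = 1.0))
  expect_equal(aa_composition("ACAC"), c(A = 0.5, C = 0.5))
  expect_equal(unname(aa_composition("DEKR")), rep(0.25, 4))
  set.seed(9)
  s <- random_aa_sequence(200)
  expect_equal(sum(aa_composition(s)), 1, tolerance = 1e-9)
})
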