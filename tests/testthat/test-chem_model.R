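test_that("formula parsing handles Hill notation and rejects junk", {
  expect_equal(parse_formula("C10H11N3O3S"),
               c(C = 10L, H = 11L, N = 3L, O = 3L, S = 1L))
  expect_equal(parse_formula("C6H6N"), c(C = 6L, H = 6L, N = 1L))
  expect_error(parse_formula("C6H6N!"), "cannot parse")
})

test_that("monoisotopic m/z reproduces the six monitored masses", {
  printed <- c("F92" = 92.0493, "F92 15N" = 93.0465, "F92 13C" = 93.0532,
               "F99" = 99.0552, "F99 15N" = 100.0525, "F99 13C" = 100.0587)
  cat <- smx_catalog()
  for (lab in names(printed)) {
    expect_lt(abs(monoisotopic_mz(cat[[lab]]) - printed[[lab]]), 0.001)
  }
})

test_that("iso_spec validates substitutions and charge", {
  expect_error(iso_spec("X", "C6H6N", charge = 0), "charge")
  expect_error(iso_spec("X", "C6H6N", list(N = c(15, 2))), "exceeds")
  # unknown nuclide surfaces with its name at m/z time
  sp <- iso_spec("X", "C6H6N", list(C = c(14, 1)))
  expect_error(monoisotopic_mz(sp), "14C")
})

test_that("match_peak assigns, distinguishes isobars, and flags ambiguity", {
  cat <- smx_catalog()
  expect_identical(match_peak(92.0493, cat)$label, "F92")
  # 15N vs 13C species 0.0067 u apart at m/z 93: 20 ppm resolves them
  expect_identical(match_peak(93.0465, cat)$label, "F92 15N")
  expect_identical(match_peak(93.0532, cat)$label, "F92 13C")
  expect_null(match_peak(500.0, cat))
  expect_error(match_peak(93.05, cat, tolerance_ppm = 500), "ambiguous")
  expect_error(match_peak(92.0493, cat, tolerance_ppm = 0), "tolerance_ppm")
})

test_that("stochastic isotopologue ratio is linear in atom count", {
  expect_equal(stochastic_isotopologue_ratio("C6H6N", "C", 0.01), 0.06)
  expect_equal(stochastic_isotopologue_ratio("C4H7N2O", "N", 0.003),
               0.006)
  expect_equal(stochastic_isotopologue_ratio("C6H6N", "N", 0.003678),
               0.003678)
  set.seed(42)
  for (i in 1:20) {
    n <- sample(1:30, 1)
    r <- runif(1, 1e-4, 0.05)
    f <- c(C = n, H = 1L)
    expect_equal(stochastic_isotopologue_ratio(f, "C", r), n * r)
  }
  expect_error(stochastic_isotopologue_ratio("C6H6N", "S", 0.01), "absent")
})

test_that("mixing enrichment matches direct evaluation and is monotone", {
  # equal fractions: 0 permil (and the depletion-boundary warning fires)
  expect_warning(
    expect_equal(position_enrichment_from_mixing(0.001, 1, 0.0107, 0.0107),
                 0),
    "depletion")
  # 1 mg of 99 atom % label into 1 g natural: order ~100 permil
  e <- position_enrichment_from_mixing(0.001, 1, 0.99, 0.0107)
  expect_gt(e, 85); expect_lt(e, 105)
  # first-order linearity in the spike at small spike fraction
  e2 <- position_enrichment_from_mixing(0.002, 1, 0.99, 0.0107)
  expect_lt(abs(e2 / e - 2), 0.01 * 2)
  # strictly increasing in labeled amount and in label fraction
  amounts <- seq(5e-4, 5e-3, length.out = 8)
  vals <- vapply(amounts, position_enrichment_from_mixing, numeric(1),
                 unlabeled_moles = 1, label_atom_fraction = 0.99)
  expect_true(all(diff(vals) > 0))
  fracs <- seq(0.2, 0.99, length.out = 8)
  vals <- vapply(fracs, function(x)
    position_enrichment_from_mixing(0.001, 1, x), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_warning(position_enrichment_from_mixing(0.001, 1, 0.001, 0.0107),
                 "depletion")
})

test_that("bulk <-> fragment mass balance uses atom-count weighting", {
  smx <- smx_molecule()
  expect_equal(fragment_calc_from_bulk(12, smx, "F99", "N"), 18)
  expect_equal(fragment_calc_from_bulk(2.5, smx, "F99", "C"), 6.25)
  expect_equal(fragment_calc_from_bulk(0, smx, "F92", "C"), 0)
  expect_error(fragment_calc_from_bulk(5, smx, "F92", "O"), "no O")

  expect_equal(bulk_from_fragments(c(F92 = 30, F99 = 0), smx, "N"), 10)
  expect_equal(bulk_from_fragments(c(F92 = 0, F99 = 25), smx, "C"), 10)
  expect_equal(bulk_from_fragments(c(F92 = 7, F99 = 7), smx, "C"), 7)
  expect_error(bulk_from_fragments(c(F92 = 30), smx, "N"), "incomplete")
})

test_that("fragment_calc_from_bulk round-trips through bulk_from_fragments", {
  smx <- smx_molecule()
  set.seed(7)
  for (i in 1:20) {
    shift <- runif(1, -50, 250)
    frag <- sample(c("F92", "F99"), 1)
    el <- sample(c("C", "N"), 1)
    fc <- fragment_calc_from_bulk(shift, smx, frag, el)
    other <- setdiff(c("F92", "F99"), frag)
    d <- stats::setNames(c(fc, 0), c(frag, other))
    expect_equal(bulk_from_fragments(d, smx, el), shift)
  }
})

test_that("delta-linear mass balance tracks the exact ratio-space oracle", {
  smx <- smx_molecule()
  r13 <- natural_isotope_ratio("C")
  set.seed(11)
  for (i in 1:10) {
    d <- c(F92 = runif(1, -30, 100), F99 = runif(1, -30, 100))
    lin <- bulk_from_fragments(d, smx, "C")
    exact <- fragiso:::bulk_from_fragments_exact(d, smx, "C", r13)
    expect_lt(abs(lin - exact), 0.1)  # second-order terms only
  }
})

test_that("nuclide table is internally consistent", {
  tab <- isotope_table()
  sums <- tapply(tab$isotopes$abundance, tab$isotopes$element, sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_equal(natural_isotope_ratio("C"), 0.0107 / 0.9893)
  expect_equal(natural_isotope_ratio("N"), 0.003663 / 0.996337)
})
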