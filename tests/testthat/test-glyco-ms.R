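blocks <- default_building_blocks()

# independent full Cartesian-product enumeration used as completeness oracle
oracle_decompose <- function(mass, pep_mass, tol_ppm = 5) {
  grid <- expand.grid(Hex = 0:9, HexNAc = 0:7, dHex = 0:2, NeuAc = 0:4,
                      P = 0:2)
  theo <- pep_mass + as.matrix(grid) %*% blocks$mass
  ppm <- 1e6 * (mass - theo) / theo
  hits <- grid[abs(ppm) <= tol_ppm, , drop = FALSE]
  hits[do.call(order, hits), , drop = FALSE]
}

test_that("neutral mass follows the protonated-species convention", {
  expect_equal(neutral_mass(101.0072765, 1), 100, tolerance = 1e-9)
  m <- 2345.678
  expect_equal(neutral_mass((m + 2 * 1.0072765) / 2, 2),
               neutral_mass((m + 3 * 1.0072765) / 3, 3), tolerance = 1e-9)
  expect_error(neutral_mass(500, 0), "charge")
})

test_that("peptide masses are additive sums of residues plus water", {
  expect_equal(peptide_mass("KVANKT"), 659.39661, tolerance = 1e-4)
  expect_equal(peptide_mass(""), 18.010565, tolerance = 1e-9)
  expect_equal(peptide_mass("ACD") + peptide_mass("EFG") - 18.010565,
               peptide_mass("ACDEFG"), tolerance = 1e-9)
  expect_error(peptide_mass("ABZ"), "unknown residue")
})

test_that("composition strings parse and render consistently", {
  cts <- parse_composition("Hex5HexNAc2dHex1")
  expect_equal(unname(cts[c("Hex", "HexNAc", "dHex")]), c(5L, 2L, 1L))
  expect_equal(glycoform_label(cts), "Man5-GlcNAc2-Fuc")
  expect_equal(parse_composition("NeuAc2P1Hex3"),
               c(Hex = 3L, HexNAc = 0L, dHex = 0L, NeuAc = 2L, P = 1L))
  expect_error(parse_composition("Foo3"), "unknown")
})

test_that("the G0 glycopeptide mass decomposes uniquely", {
  pep <- data.frame(peptide_id = "KVANKT", mass = peptide_mass("KVANKT"))
  hits <- decompose_mass(1957.87255, pep, tolerance_ppm = 5)
  expect_equal(nrow(hits), 1)
  expect_equal(unname(unlist(hits[1, c("Hex", "HexNAc", "dHex", "NeuAc", "P")])),
               c(3, 4, 0, 0, 0))
  expect_lt(abs(hits$ppm_error), 0.01)
})

test_that("a bare peptide mass yields the empty composition", {
  pep <- data.frame(peptide_id = "p", mass = 1000)
  hits <- decompose_mass(1000, pep)
  expect_equal(nrow(hits), 1)
  expect_equal(sum(hits[1, blocks$block]), 0)
  expect_equal(hits$glycoform[1], "")
  # and no candidates means an empty result, not an error
  expect_equal(nrow(decompose_mass(1000, data.frame(peptide_id = character(0),
                                                    mass = numeric(0)))), 0)
})

test_that("branch-and-bound enumeration agrees with the Cartesian oracle", {
  set.seed(21)
  pep_mass <- peptide_mass("KVANKT")
  masses <- c(
    # masses planted on valid compositions (with slight ppm offsets)
    vapply(1:20, function(i) {
      cts <- c(sample(0:9, 1), sample(0:7, 1), sample(0:2, 1),
               sample(0:4, 1), sample(0:2, 1))
      (pep_mass + sum(cts * blocks$mass)) * (1 + runif(1, -4e-6, 4e-6))
    }, numeric(1)),
    # and masses drawn uniformly (mostly empty hit sets)
    runif(20, pep_mass, pep_mass + 3000))
  pep <- data.frame(peptide_id = "KVANKT", mass = pep_mass)
  for (m in masses) {
    mine <- decompose_mass(m, pep)
    orc <- oracle_decompose(m, pep_mass)
    expect_equal(nrow(mine), nrow(orc))
    if (nrow(mine) > 0) {
      a <- mine[, blocks$block, drop = FALSE]
      a <- a[do.call(order, a), , drop = FALSE]
      expect_equal(unname(as.matrix(a)), unname(as.matrix(orc)))
      # soundness: every reported candidate is inside tolerance
      expect_true(all(abs(mine$ppm_error) <= 5))
    }
  }
})

test_that("candidate ordering is deterministic: |ppm| then lexicographic", {
  pep <- data.frame(peptide_id = "p", mass = 1000)
  wide <- decompose_mass(1000 + 2 * 162.05282, pep, tolerance_ppm = 5)
  expect_equal(wide$ppm_error, wide$ppm_error[order(abs(wide$ppm_error))])
})

test_that("a tiny node budget raises the bounds advice", {
  pep <- data.frame(peptide_id = "p", mass = 1000)
  expect_error(decompose_mass(3000, pep, max_nodes = 10), "tighten")
})

test_that("assignment is invariant to charge state", {
  cfg <- scenario_config(1, noise_cv = 0)
  pepm <- peptide_mass("KVANKT")
  ft <- gen_glycopeptide_features(
    list(N65 = c(Hex5HexNAc2dHex1 = 0.7, Hex5HexNAc2 = 0.3)),
    c(N65 = pepm), ppm_error_sd = 0, charge_states = c(2, 3), config = cfg)
  peps <- data.frame(peptide_id = "pep", mass = pepm, glycosite = "N65")
  asn <- assign_glycopeptides(ft, peps)
  expect_equal(nrow(asn), nrow(ft))
  expect_true(all(abs(asn$ppm_error) < 1e-6))
  expect_equal(sort(asn$glycoform[asn$charge == 2]),
               sort(asn$glycoform[asn$charge == 3]))
})

test_that("deamidation-yield comparison flags true glycosites", {
  expect_equal(deamidation_delta(), 0.98402)
  before <- data.frame(peptide_id = c("a", "a", "b", "c", "d"),
                       deamidated = c(TRUE, FALSE, TRUE, TRUE, TRUE),
                       abundance = c(1, 50, 2, 3, 5))
  after <- data.frame(peptide_id = c("a", "b", "c", "d"),
                      deamidated = TRUE,
                      abundance = c(10, 40, 30, 5))
  res <- detect_glycosite_peptides(before, after, fold_threshold = 2)
  expect_equal(res$peptide_id[res$glycosite_evidence], c("a", "b", "c"))
  expect_false(res$glycosite_evidence[res$peptide_id == "d"])  # equal yields

  after2 <- after[after$peptide_id != "d", ]
  expect_warning(detect_glycosite_peptides(before, after2), "skipped")
})

test_that("site reports reproduce constructed glycoform fractions", {
  cfg <- scenario_config(1, noise_cv = 0)
  pepm <- peptide_mass("KVANKT")
  ft <- gen_glycopeptide_features(
    list(N65 = c(Hex5HexNAc2dHex1 = 0.9, Hex5HexNAc2 = 0.1)),
    c(N65 = pepm), ppm_error_sd = 0, config = cfg)
  peps <- data.frame(peptide_id = "pep", mass = pepm, glycosite = "N65")
  rep65 <- site_report(assign_glycopeptides(ft, peps), "N65")
  fr <- setNames(rep65$table$fraction, rep65$table$glycoform)
  expect_equal(unname(fr["Hex5HexNAc2dHex1"]), 0.9, tolerance = 1e-9)
  expect_equal(unname(fr["Hex5HexNAc2"]), 0.1, tolerance = 1e-9)
  expect_equal(rep65$fucosylated_fraction, 0.9, tolerance = 1e-9)
  expect_error(site_report(assign_glycopeptides(ft, peps), "N99"), "no assignments")
})

test_that("fractions sum to one across random synthetic sites", {
  pepm <- peptide_mass("KVANKT")
  peps <- data.frame(peptide_id = "pep", mass = pepm, glycosite = "S")
  forms <- c("Hex5HexNAc2", "Hex5HexNAc2dHex1", "Hex3HexNAc4",
             "Hex3HexNAc4dHex1")
  for (s in 1:15) {
    set.seed(s)
    fr <- as.numeric(rmultinom(1, 100, rep(1, 4))) / 100
    keep <- fr > 0
    cfg <- scenario_config(s, noise_cv = 0.2)
    ft <- gen_glycopeptide_features(list(S = setNames(fr[keep], forms[keep])),
                                    c(S = pepm), ppm_error_sd = 1,
                                    config = cfg)
    r <- site_report(assign_glycopeptides(ft, peps), "S")
    expect_equal(sum(r$table$fraction), 1, tolerance = 1e-9)
    expect_true(all(r$table$fraction >= 0 & r$table$fraction <= 1))
    fuc_share <- sum(r$table$fraction[r$table$fucosylated])
    expect_equal(r$fucosylated_fraction, fuc_share, tolerance = 1e-9)
  }
})

test_that("all-fucosylated sites report fraction one", {
  cfg <- scenario_config(1, noise_cv = 0)
  pepm <- peptide_mass("KVANKT")
  ft <- gen_glycopeptide_features(
    list(S = c(Hex5HexNAc2dHex1 = 0.6, Hex3HexNAc4dHex2 = 0.4)),
    c(S = pepm), ppm_error_sd = 0, config = cfg)
  peps <- data.frame(peptide_id = "pep", mass = pepm, glycosite = "S")
  r <- site_report(assign_glycopeptides(ft, peps), "S")
  expect_equal(r$fucosylated_fraction, 1, tolerance = 1e-9)
})
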