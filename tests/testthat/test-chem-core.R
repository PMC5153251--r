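test_that("nominal mass arithmetic matches known hydrocarbon masses", {
  expect_identical(nominal_mass(parse_formula("C23H48")), 324L)
  expect_identical(nominal_mass(parse_formula("CH4")), 16L)
  expect_identical(nominal_mass(parse_formula("C37H76")), 520L)
  expect_identical(nominal_mass(molecular_formula(C = 16, H = 32, O = 2)),
                   256L)
  expect_error(nominal_mass(molecular_formula(Xx = 2)), "Xx")
})

test_that("formula parsing and formatting round-trip", {
  for (f in c("C30H62", "C18H34O2", "C27H46O", "CH4")) {
    expect_identical(format(parse_formula(f)), f)
  }
  expect_error(parse_formula("notaformula!"), "parse")
})

test_that("structure to formula follows C = L + k, H = 2C + 2 - 2d", {
  expect_identical(format(formula_of(hydrocarbon(29, 9))), "C30H62")
  expect_identical(format(formula_of(hydrocarbon(15))), "C15H32")
  expect_identical(format(formula_of(hydrocarbon(23, n_double_bonds = 1))),
                   "C23H46")
  oleic <- hydrocarbon(1, other_class = "Oleic acid")
  expect_error(formula_of(oleic), "other_class")
  expect_error(diagnostic_ions(oleic), "alkanes")
})

test_that("diagnostic ions invert branch locants to the expected pairs", {
  expect_identical(diagnostic_ions(hydrocarbon(29, 9)), c(141L, 309L))
  expect_identical(diagnostic_ions(hydrocarbon(29, 15)), 225L)
  expect_identical(diagnostic_ions(hydrocarbon(29, 7)), c(113L, 337L))
  expect_identical(diagnostic_ions(hydrocarbon(26)), integer())
  expect_error(diagnostic_ions(hydrocarbon(23, 9, n_double_bonds = 1)),
               "unsaturated")
})

test_that("monomethyl diagnostic pairs sum to parent mass + 28", {
  for (L in 20:40) {
    for (b in 2:(L - 1)) {
      s <- hydrocarbon(L, b)
      ions <- diagnostic_ions(s)
      m <- nominal_mass(formula_of(s))
      if (length(ions) == 1L) {
        expect_identical(2L * ions, m + 28L)
      } else {
        expect_identical(sum(ions), m + 28L)
      }
    }
  }
})

test_that("diagnostic ions are invariant under end-renumbering", {
  for (L in c(21, 28, 35)) {
    for (b in 2:(L - 1)) {
      expect_identical(diagnostic_ions(hydrocarbon(L, b)),
                       diagnostic_ions(hydrocarbon(L, L + 1L - b)))
    }
  }
})

test_that("branch locants canonicalize to the lowest-locant numbering", {
  expect_identical(hydrocarbon(29, 21)$branch_positions, 9L)
  expect_identical(hydrocarbon(28, c(27, 19))$branch_positions, c(2L, 10L))
  expect_identical(hydrocarbon(29, 15)$branch_positions, 15L)
  expect_error(hydrocarbon(29, 1), "1 < b")
  expect_error(hydrocarbon(29, 29), "1 < b")
})

test_that("systematic names parse and format both ways", {
  cases <- list(
    list(name = "9-methylnonacosane", L = 29L, b = 9L, db = 0L),
    list(name = "5,9-dimethylhentriacontane", L = 31L, b = c(5L, 9L),
         db = 0L),
    list(name = "Pentadecane", L = 15L, b = integer(), db = 0L),
    list(name = "2,10-dimethyloctacosane", L = 28L, b = c(2L, 10L), db = 0L))
  for (cs in cases) {
    s <- parse_hydrocarbon_name(cs$name)
    expect_identical(s$backbone_length, cs$L)
    expect_identical(s$branch_positions, cs$b)
    expect_identical(s$n_double_bonds, cs$db)
    expect_identical(format(s), cs$name)
  }
  amb <- parse_hydrocarbon_name("*-pentacosene")
  expect_identical(amb$backbone_length, 25L)
  expect_identical(amb$n_double_bonds, 1L)
  expect_true(amb$ambiguous)
  expect_identical(format(amb), "*-pentacosene")
  tri <- parse_hydrocarbon_name("*-trimethyloctadecane")
  expect_identical(tri$backbone_length, 18L)
  expect_identical(length(tri$branch_positions), 3L)
  expect_true(all(is.na(tri$branch_positions)))
  # qualifiers in parentheses are ignored
  lik <- parse_hydrocarbon_name("*-methyltriacontane (likely 4-)")
  expect_identical(lik$backbone_length, 30L)
  # non-hydrocarbons become annotated records
  chol <- parse_hydrocarbon_name("Cholesterol-like")
  expect_false(is.null(chol$other_class))
})

test_that("formula arithmetic reproduces the compound table masses", {
  tab <- tf_compound_table()
  ok <- tab$mw_computed == tab$mw_printed
  expect_identical(sum(!ok), 1L)
  expect_identical(tab$formula[!ok], "C21H44")
  expect_identical(tab$mw_printed[!ok], 295L)
  expect_identical(tab$mw_computed[!ok], 296L)
  expect_true(all(tab$mw_discrepant == !ok))
})
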