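popc <- reagent("POPC", 760.1, 10, "stabilizer")
chol <- reagent("cholesterol", 386.7, 10, "helper")
peg  <- reagent("DSPE-PEG", 2810, 10, "adhesion")
man  <- reagent("DSPE-PEG-MAN", 3000, 10, "targeting")
dchol <- reagent("DChol", 537.3, 18, "cationic_lipid")

shell_recipe <- list(
  recipe_line(popc, mass_ug = 520),
  recipe_line(chol, mass_ug = 130),
  recipe_line(peg, mass_ug = 40),
  recipe_line(man, mass_ug = 310)
)

test_that("mass and volume lines convert to the printed mole amounts", {
  expect_equal(moles_from_line(recipe_line(popc, mass_ug = 520)), 684,
               tolerance = 0.001)
  # 90 uL of an 18 mg/mL stock of the cationic lipid is ~3.0 umol
  expect_equal(moles_from_line(recipe_line(dchol, volume_uL = 90)) / 1e3,
               3.0, tolerance = 0.01)
  expect_equal(moles_from_line(recipe_line(popc, mass_ug = 0)), 0)
  expect_error(recipe_line(reagent("x", 100), volume_uL = 5),
               "stock_concentration")
  # moles are additive across split lines of one reagent
  split <- moles_from_line(recipe_line(popc, mass_ug = 200)) +
    moles_from_line(recipe_line(popc, mass_ug = 320))
  expect_equal(split, moles_from_line(recipe_line(popc, mass_ug = 520)))
})

test_that("shell-lipid mole composition reports 60/30/1/9", {
  tab <- mole_percentages(shell_recipe)
  expect_equal(tab$mole_percent, c(60.1, 29.5, 1.3, 9.1), tolerance = 0.005)
  expect_equal(tab$mole_percent_report, c(60, 30, 1, 9))
  expect_equal(sum(tab$mole_percent), 100, tolerance = 1e-9)
  expect_equal(mole_percentages(list(recipe_line(popc, mass_ug = 1)))
               $mole_percent, 100)
  two <- list(recipe_line(popc, mass_ug = 760.1),
              recipe_line(chol, mass_ug = 386.7))
  expect_equal(mole_percentages(two)$mole_percent, c(50, 50))
  expect_error(mole_percentages(list()), "at least one")
})

test_that("counterion excess and dose concentration are simple ratios", {
  expect_equal(counterion_excess(1.3, 3.0, 2), 3.0 / 2.6)
  expect_equal(counterion_excess(1.3, 2.6, 2), 1.0)
  expect_equal(counterion_excess(1.0, 2.0, 2), 1.0)
  # homogeneous of degree 0 in the batch scale
  for (s in c(0.1, 2, 17)) {
    expect_equal(counterion_excess(1.3 * s, 3.0 * s, 2),
                 counterion_excess(1.3, 3.0, 2))
  }
  expect_error(counterion_excess(0, 3), "positive")
  expect_equal(dose_concentration(40, 250), 0.16)
  expect_equal(dose_concentration(0, 250), 0)
  expect_equal(dose_concentration(40, 400), 0.10)
  expect_error(dose_concentration(40, 0), "positive")
})

test_that("recipe report aggregates and warns appropriately", {
  rep1 <- recipe_report(shell_recipe, payload_monomer_umol = 1.3,
                        counterion_umol = 3.0, payload_nmol = 40,
                        final_volume_uL = 250,
                        target_mole_percent = c(POPC = 60,
                                                cholesterol = 30,
                                                `DSPE-PEG` = 1,
                                                `DSPE-PEG-MAN` = 9))
  expect_length(rep1$warnings, 0)
  expect_equal(rep1$table$mole_percent_report, c(60, 30, 1, 9))
  expect_equal(rep1$counterion_excess, 3.0 / 2.6)
  expect_equal(rep1$dose_concentration, 0.16)
  # halving the counterion triggers a shortfall warning
  rep2 <- recipe_report(shell_recipe, payload_monomer_umol = 1.3,
                        counterion_umol = 1.5)
  expect_match(rep2$warnings, "shortfall", all = FALSE)
  expect_error(recipe_report(list()), "at least one")
})

test_that("the recipe fixture round-trips and reproduces the report", {
  path <- withr::local_tempfile(fileext = ".yaml")
  make_recipe_fixture(path)
  rec <- read_recipe_yaml(path)
  tab <- mole_percentages(rec$lines)
  expect_equal(tab$mole_percent_report, c(60, 30, 1, 9))
  # round trip unchanged
  expect_identical(yaml::read_yaml(path), make_recipe_fixture())
  # stable content across writes
  path2 <- withr::local_tempfile(fileext = ".yaml")
  make_recipe_fixture(path2)
  expect_identical(readLines(path), readLines(path2))
})
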