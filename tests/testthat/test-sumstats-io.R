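test_that("read/write round-trips a validated table and drops invalid rows", {
  tbl <- dplyr::bind_rows(
    make_assoc("rs1", pos = 100, beta = 0.12345678912, se = 0.02),
    make_assoc("rs2", pos = 200, eaf = 0.45, beta = -0.05, se = 0.01),
    make_assoc("rs3", pos = 300, effect_allele = "T", other_allele = "C")
  )
  x <- as_sumstats(tbl, trait_id = "expr")
  expect_equal(nrow(x), 3)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(x, path)
  y <- read_sumstats(path, trait_id = "expr")
  expect_equal(as.data.frame(y), as.data.frame(x), tolerance = 1e-9)

  # a second write/read is the identity on the already-round-tripped table
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(y, path2)
  expect_identical(readLines(path), readLines(path2))

  bad <- dplyr::bind_rows(tbl, make_assoc("rs4", se = 0))
  expect_message(z <- as_sumstats(bad), class = "targetmr_validation")
  expect_equal(nrow(z), 3)
  expect_equal(unname(validation_log(z)["n_dropped"]), 1)
  expect_equal(unname(validation_log(z)["nonpositive_se"]), 1)
})

test_that("column mapping renames fields and missing columns are fatal", {
  raw <- make_assoc("rs1")
  names(raw)[names(raw) == "variant_id"] <- "SNP"
  names(raw)[names(raw) == "beta"] <- "b"
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(raw, path, sep = "\t", quote = FALSE, row.names = FALSE)
  x <- read_sumstats(path, column_map = c(variant_id = "SNP", beta = "b"))
  expect_equal(x$variant_id, "rs1")
  expect_equal(x$beta, 0.1)
  expect_error(read_sumstats(path), class = "targetmr_config_error")
  expect_error(
    read_sumstats(path, column_map = c(variant_id = "nope")),
    class = "targetmr_config_error"
  )
})

test_that("binary traits require case/control counts", {
  expect_error(as_sumstats(make_assoc(), trait_type = "binary"),
               class = "targetmr_config_error")
  x <- as_sumstats(make_assoc(), trait_id = "t2d", trait_type = "binary",
                   n_cases = 100, n_controls = 900)
  expect_equal(trait_type(x), "binary")
  expect_equal(attr(x, "n_cases"), 100)
})

test_that("harmonization aligns swapped and strand-flipped alleles", {
  exp <- make_assoc("rs1", effect_allele = "A", other_allele = "G", beta = 0.1)

  same <- harmonize_pair(exp, make_assoc("rs1", effect_allele = "A",
                                         other_allele = "G", beta = 0.05))
  expect_equal(same$action, "kept")
  expect_equal(same$outcome$beta, 0.05)

  swap <- harmonize_pair(exp, make_assoc("rs1", effect_allele = "G",
                                         other_allele = "A", beta = 0.05,
                                         eaf = 0.3))
  expect_equal(swap$action, "flipped")
  expect_equal(swap$outcome$beta, -0.05)
  expect_equal(swap$outcome$eaf, 0.7)

  comp <- harmonize_pair(exp, make_assoc("rs1", effect_allele = "T",
                                         other_allele = "C", beta = 0.05,
                                         eaf = 0.3))
  expect_equal(comp$action, "complemented")
  expect_equal(comp$outcome$beta, 0.05)
  expect_equal(comp$outcome$effect_allele, "A")

  comp_swap <- harmonize_pair(exp, make_assoc("rs1", effect_allele = "C",
                                              other_allele = "T", beta = 0.05,
                                              eaf = 0.3))
  expect_equal(comp_swap$action, "flipped")
  expect_equal(comp_swap$outcome$beta, -0.05)

  bad <- harmonize_pair(exp, make_assoc("rs1", effect_allele = "A",
                                        other_allele = "C"))
  expect_true(bad$rejected)
  expect_equal(bad$action, "rejected:allele-mismatch")
})

test_that("palindromic variants follow the ambiguity band rule", {
  pal_mid <- harmonize_pair(
    make_assoc("rs1", effect_allele = "A", other_allele = "T", eaf = 0.50),
    make_assoc("rs1", effect_allele = "A", other_allele = "T", eaf = 0.50),
    palindrome_eaf_band = c(0.42, 0.58)
  )
  expect_equal(pal_mid$action, "rejected:palindromic-ambiguous")

  # outside the band: aligned by frequency
  pal_keep <- harmonize_pair(
    make_assoc("rs1", effect_allele = "A", other_allele = "T", eaf = 0.2),
    make_assoc("rs1", effect_allele = "A", other_allele = "T", eaf = 0.25,
               beta = 0.04)
  )
  expect_equal(pal_keep$action, "kept")
  pal_flip <- harmonize_pair(
    make_assoc("rs1", effect_allele = "A", other_allele = "T", eaf = 0.2),
    make_assoc("rs1", effect_allele = "T", other_allele = "A", eaf = 0.8,
               beta = 0.04)
  )
  expect_equal(pal_flip$action, "flipped")
  expect_equal(pal_flip$outcome$beta, -0.04)
  expect_equal(pal_flip$outcome$eaf, 0.2, tolerance = 1e-12)

  # palindromic with missing outcome frequency cannot be resolved
  out_na <- make_assoc("rs1", effect_allele = "A", other_allele = "T")
  out_na$eaf <- NA_real_
  pal_na <- harmonize_pair(
    make_assoc("rs1", effect_allele = "A", other_allele = "T", eaf = 0.2),
    out_na
  )
  expect_equal(pal_na$action, "rejected:palindromic-missing-eaf")

  # non-palindromic with missing outcome frequency proceeds
  out_na2 <- make_assoc("rs1", effect_allele = "G", other_allele = "A",
                        beta = 0.05)
  out_na2$eaf <- NA_real_
  ok_na <- harmonize_pair(make_assoc("rs1"), out_na2)
  expect_equal(ok_na$action, "flipped")
  expect_equal(ok_na$outcome$beta, -0.05)
})

test_that("harmonization is idempotent and the double swap is an involution", {
  exp <- make_assoc("rs1", effect_allele = "A", other_allele = "G")
  out <- make_assoc("rs1", effect_allele = "G", other_allele = "A",
                    beta = 0.07, eaf = 0.25)
  once <- harmonize_pair(exp, out)
  twice <- harmonize_pair(exp, once$outcome)
  expect_equal(twice$action, "kept")
  expect_equal(twice$outcome, once$outcome)

  # swapping the already-harmonized outcome's alleles back and
  # re-harmonizing restores the original beta and eaf
  reswapped <- once$outcome
  reswapped$effect_allele <- "G"
  reswapped$other_allele <- "A"
  reswapped$beta <- -reswapped$beta
  reswapped$eaf <- 1 - reswapped$eaf
  expect_equal(reswapped$beta, out$beta)
  expect_equal(reswapped$eaf, out$eaf)
})

test_that("table-level harmonization joins, filters and reports actions", {
  exposure <- dplyr::bind_rows(
    make_assoc("rs1", pos = 100),
    make_assoc("rs2", pos = 200, effect_allele = "C", other_allele = "T"),
    make_assoc("rs3", pos = 300, effect_allele = "A", other_allele = "T",
               eaf = 0.5),
    make_assoc("rs4", pos = 400)
  )
  outcome <- dplyr::bind_rows(
    make_assoc("rs1", beta = 0.02),
    make_assoc("rs2", effect_allele = "T", other_allele = "C", beta = 0.03),
    make_assoc("rs3", effect_allele = "A", other_allele = "T", eaf = 0.5),
    make_assoc("rs9")
  )
  h <- harmonize_sumstats(exposure, outcome)
  expect_equal(h$variant_id, c("rs1", "rs2"))
  expect_equal(h$beta_out, c(0.02, -0.03))
  rep <- harmonization_report(h)
  expect_equal(nrow(rep), 3)  # rs4/rs9 never join
  expect_equal(rep$action[rep$variant_id == "rs3"],
               "rejected:palindromic-ambiguous")
})
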