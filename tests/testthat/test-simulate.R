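design <- design_presets()$simple
mid <- strrep("GATCA", 2)
unit <- list(system = "simple", enzyme = "TestEnz",
             pcr_condition = "standard", individual = "ind1")

test_that("simulation is byte-identical for a fixed seed", {
  alleles <- c(hap1 = random_insert(170, seed = 40))
  prof <- enzyme_error_profile("e", substitution_rate = 0.01,
                               homopolymer_indel_rate = 0.05)
  a <- simulate_unit(design, alleles, prof, 50, mid, seed = 8, unit = unit)
  b <- simulate_unit(design, alleles, prof, 50, mid, seed = 8, unit = unit)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_unit(design, alleles, prof, 50, mid, seed = 9, unit = unit)
  expect_false(identical(a$reads$sequence, c_$reads$sequence))
})

test_that("with all error knobs at zero every read is correct end to end", {
  alleles <- c(hap1 = random_insert(170, seed = 41))
  prof <- enzyme_error_profile("clean")
  sim <- simulate_unit(design, alleles, prof, 100, mid, seed = 5, unit = unit)
  expect_true(all(sim$truth$is_correct))
  expect_true(all(sim$truth$source_allele == "hap1"))

  sheet <- simple_sheet(mid = mid, enzyme = "TestEnz")
  panel <- reference_panel(data.frame(
    individual = "ind1", locus = "mito_cr", allele_id = "hap1",
    sequence = unname(alleles), stringsAsFactors = FALSE
  ))
  dx <- demultiplex(sim$reads, design, sheet)
  expect_equal(unname(dx$summary[["none"]]), 100L)
  st <- classify_reads(dx, panel, "mito_cr")
  expect_equal(st$p_hat, 1)
})

test_that("classified correctness reproduces the generator's truth per read", {
  alleles <- c(hap1 = random_insert(170, seed = 42))
  prof <- enzyme_error_profile("noisy", substitution_rate = 0.004)
  sim <- simulate_unit(design, alleles, prof, 400, mid, seed = 6, unit = unit)
  sheet <- simple_sheet(mid = mid, enzyme = "TestEnz")
  panel <- reference_panel(data.frame(
    individual = "ind1", locus = "mito_cr", allele_id = "hap1",
    sequence = unname(alleles), stringsAsFactors = FALSE
  ))
  dx <- demultiplex(sim$reads, design, sheet)
  rec <- dx$records[dx$records$reject_reason == "none", ]
  truth <- sim$truth[match(rec$read_id, sim$truth$read_id), ]
  classified_correct <- rec$trimmed_insert == unname(alleles)
  expect_equal(classified_correct, truth$is_correct)
  st <- classify_reads(dx, panel, "mito_cr")
  expect_equal(st$n_correct, sum(sim$truth$is_correct))
})

test_that("an all-chimera unit with end-discriminating alleles has no correct read", {
  base <- random_insert(168, seed = 43)
  # alleles differ at the first and last base, so any single crossover mixes
  # the two discriminating positions
  a1 <- paste0("A", base, "C")
  a2 <- paste0("C", base, "G")
  prof <- enzyme_error_profile("chim", chimera_fraction = 1)
  sim <- simulate_unit(design, c(x = a1, y = a2), prof, 120, mid, seed = 7)
  expect_true(all(sim$truth$source_allele == "chimera"))
  expect_false(any(sim$truth$is_correct))
})

test_that("chimeras require two distinct template alleles", {
  prof <- enzyme_error_profile("chim", chimera_fraction = 0.3)
  expect_error(simulate_unit(design, c(a = random_insert(170, seed = 44)),
                             prof, 10, mid, seed = 1),
               "two distinct")
})

test_that("calibration hits closed-form substitution rates", {
  allele100 <- random_insert(100, seed = 45)
  pr <- calibrate_profile(enzyme_error_profile("e", target_p_correct = 0.5),
                          allele100)
  expect_equal(pr$substitution_rate, 1 - 0.5^(1 / 100), tolerance = 1e-12)

  pr1 <- calibrate_profile(enzyme_error_profile("e", target_p_correct = 1),
                           allele100)
  expect_equal(pr1$substitution_rate, 0)

  # with a fixed chimera fraction the substitution survival carries the rest
  two <- c(paste0("A", random_insert(98, seed = 46), "C"),
           paste0("C", random_insert(98, seed = 47), "G"))
  prc <- calibrate_profile(
    enzyme_error_profile("e", target_p_correct = 0.9,
                         chimera_fraction = 0.05),
    two
  )
  expect_equal((1 - prc$substitution_rate)^100, 0.9 / 0.95,
               tolerance = 1e-9)

  expect_error(
    calibrate_profile(enzyme_error_profile("e", target_p_correct = 0.98,
                                           chimera_fraction = 0.05), two),
    "infeasible"
  )
  expect_error(calibrate_profile(enzyme_error_profile("e"), allele100),
               "not set")
})

test_that("a calibrated profile reproduces its target proportion", {
  panel <- synthetic_reference_panel("ind1", seed = 3)
  alleles <- panel$sequence[panel$locus == "mito_cr"]
  names(alleles) <- "hap1"
  prof <- calibrate_profile(
    enzyme_error_profile("e", target_p_correct = 0.75), alleles
  )
  sim <- simulate_unit(design, alleles, prof, 4000, mid, seed = 10,
                       unit = unit)
  p_hat <- mean(sim$truth$is_correct)
  ci <- 2.576 * sqrt(0.75 * 0.25 / 4000)
  expect_lt(abs(p_hat - 0.75), ci)
})

test_that("simulate_experiment wires units, sheet and panel together", {
  profs <- list(enzyme_error_profile("good", target_p_correct = 0.9),
                enzyme_error_profile("bad", target_p_correct = 0.4))
  ex <- simulate_experiment(profs, systems = c("simple", "two_allele"),
                            conditions = "standard",
                            individuals = c("ind1", "ind2"),
                            n_reads = 30, seed = 12)
  # 2 systems x 2 individuals x 2 profiles
  expect_equal(nrow(ex$sheet), 8L)
  expect_equal(nrow(ex$reads), 8L * 30L)
  expect_equal(anyDuplicated(ex$sheet$mid), 0L)
  # demultiplex one locus and check reads land in their generating unit
  dx <- demultiplex(ex$reads, ex$designs$simple, ex$sheet)
  rec <- dx$records[dx$records$reject_reason == "none", ]
  truth <- ex$truth[match(rec$read_id, ex$truth$read_id), ]
  expect_equal(rec$enzyme, truth$enzyme)
  expect_equal(rec$individual, truth$individual)
})
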