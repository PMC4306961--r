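# hand-built per-unit statistics
stats_row <- function(system, enzyme, n, x, condition = "standard",
                      individual = "ind1") {
  out <- data.frame(system = system, enzyme = enzyme,
                    pcr_condition = condition, individual = individual,
                    n_reads = n, n_correct = x, p_hat = ifelse(n > 0, x / n, NA),
                    included = n > 10, stringsAsFactors = FALSE)
  out$per_allele_counts <- list(c(A = x))
  out
}

bind_stats <- function(...) {
  out <- do.call(rbind, list(...))
  class(out) <- c("correct_read_stats", "data.frame")
  out
}

test_that("coverage table reproduces the haplotype column from pooled p", {
  st <- bind_stats(
    stats_row("simple", "Phusion", 50, 44),    # pooled p = 0.88
    stats_row("simple", "Biotaq", 100, 53)     # pooled p = 0.53
  )
  tab <- build_coverage_table(st)
  expect_equal(tab$hap_coverage[tab$enzyme == "Phusion"], 7L)
  expect_equal(tab$hap_coverage[tab$enzyme == "Biotaq"], 16L)
  expect_equal(tab$hap_status, c("ok", "ok"))
  expect_true(all(is.na(tab$ta_coverage_equal)))
  expect_equal(unique(tab$ta_status), "n.a.")
})

test_that("two-allele columns pool both conditions and satisfy equal <= unequal", {
  st <- bind_stats(
    stats_row("two_allele", "Gold", 200, 150, condition = "standard"),
    stats_row("two_allele", "Gold", 100, 90, condition = "modified")
  )
  tab <- build_coverage_table(st)
  expect_equal(tab$ta_p, 240 / 300)
  expect_equal(tab$ta_n_reads, 300L)
  expect_true(tab$ta_coverage_equal <= tab$ta_coverage_unequal)
  # pooled p, not the mean of the two unit proportions
  expect_equal(tab$ta_coverage_equal,
               min_coverage(allele_profile(0.8, c(1, 1)))$n_min)
})

test_that("no-amplification and insufficient-data flags follow the legend", {
  st <- bind_stats(
    stats_row("simple", "Vent", 0, 0),          # amplified nothing
    stats_row("simple", "OneTaq", 9, 5),        # <= 10 reads: no included unit
    stats_row("simple", "Gold", 50, 0)          # reads but zero correct
  )
  tab <- build_coverage_table(st)
  expect_equal(tab$hap_status[tab$enzyme == "Vent"], "n.a.")
  expect_equal(tab$hap_status[tab$enzyme == "OneTaq"], "i.d.")
  expect_equal(tab$hap_status[tab$enzyme == "Gold"], "i.d.")
  expect_true(all(is.na(tab$hap_coverage)))
  expect_equal(nrow(build_coverage_table(st[0, ])), 0L)
})

test_that("coverage table writes n.a./i.d. flags in place of numbers", {
  st <- bind_stats(
    stats_row("simple", "Phusion", 50, 44),
    stats_row("simple", "Vent", 0, 0)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_coverage_table(build_coverage_table(st), path)
  txt <- utils::read.delim(path, colClasses = "character")
  expect_equal(txt$haplotype[txt$enzyme == "Phusion"], "7")
  expect_equal(txt$haplotype[txt$enzyme == "Vent"], "n.a.")
})

test_that("comparing a collection with itself gives no difference", {
  st <- bind_stats(
    stats_row("two_allele", "Gold", 500, 300, individual = "ind1"),
    stats_row("two_allele", "Gold", 400, 220, individual = "ind2")
  )
  res <- compare_conditions(st, st, reps = 500, seed = 2)
  expect_equal(res$difference, 0)
  expect_gt(res$p_value, 0.99)
  expect_equal(res$n_strata, 2L)
})

test_that("strata present in only one condition are dropped with a message", {
  a <- bind_stats(stats_row("two_allele", "Gold", 100, 60,
                            individual = "ind1"),
                  stats_row("two_allele", "Gold", 100, 55,
                            individual = "ind2"))
  b <- bind_stats(stats_row("two_allele", "Gold", 100, 70,
                            condition = "modified", individual = "ind1"))
  expect_message(res <- compare_conditions(a, b, reps = 200, seed = 3),
                 "dropped")
  expect_equal(res$n_strata, 1L)
})

test_that("a large known effect is detected", {
  set.seed(77)
  # ten one-vs-one strata: 2^10 label configurations, so p-values below 0.01
  # are attainable
  mk <- function(p, condition) {
    rows <- lapply(1:10, function(s) {
      stats_row("two_allele", paste0("E", s), 2000,
                rbinom(1, 2000, p), condition = condition)
    })
    do.call(bind_stats, rows)
  }
  res <- compare_conditions(mk(0.5, "standard"), mk(0.65, "modified"),
                            reps = 500, seed = 4)
  expect_lt(res$p_value, 0.01)
  expect_lt(abs(res$difference - 0.15), 0.05)
})

test_that("probability curves are tabulated per profile and monotone", {
  profs <- list(best = allele_profile(0.88),
                equal = allele_profile(0.84, c(1, 1)),
                biased = allele_profile(0.84, c(2, 1)))
  tab <- probability_curves(profs, k = 3, n_max = 60)
  expect_equal(sort(unique(tab$label)), sort(names(profs)))
  expect_true(all(tab$probability >= 0 & tab$probability <= 1))
  for (lab in names(profs)) {
    expect_true(all(diff(tab$probability[tab$label == lab]) >= -1e-12))
  }
  # the best-enzyme haplotype curve crosses 99.9% exactly at 7 reads
  best <- tab[tab$label == "best", ]
  expect_gte(best$probability[best$n == 7], 0.999)
  expect_lt(best$probability[best$n == 6], 0.999)
  expect_error(probability_curves(profs, k = 3, n_max = 2), "n_max")
})
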