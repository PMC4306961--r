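# Enzyme-level aggregation: coverage tables, condition comparison and
# probability curves.

#' Build a per-enzyme coverage table
#'
#' For every enzyme, pools the included units (more than 10 reads) of the
#' simple system to give the haplotype column, and of the biallelic system
#' (both PCR conditions combined) to give the two-allele columns, then
#' computes the minimum coverage under amplification weights 1 (haplotype),
#' (1, 1) (equal) and (2, 1) (one allele amplifying half as well as the
#' other). Enzymes with no units at all for a system are flagged \code{n.a.}
#' (did not amplify); enzymes whose data do not support a coverage estimate
#' (no included unit, or no correct reads) are flagged \code{i.d.}.
#'
#' @param stats A \code{correct_read_stats} data.frame carrying the unit key
#'   columns.
#' @param target A \code{\link{recovery_target}}.
#' @return A data.frame of class \code{enzyme_summary}, one row per enzyme:
#'   \code{enzyme}, \code{hap_status}, \code{hap_p}, \code{hap_n_reads},
#'   \code{hap_coverage}, \code{ta_status}, \code{ta_p}, \code{ta_n_reads},
#'   \code{ta_coverage_equal}, \code{ta_coverage_unequal}.
#' @export
build_coverage_table <- function(stats, target = recovery_target()) {
  if (!nrow(stats)) {
    out <- data.frame(enzyme = character(0), hap_status = character(0),
                      hap_p = numeric(0), hap_n_reads = integer(0),
                      hap_coverage = integer(0), ta_status = character(0),
                      ta_p = numeric(0), ta_n_reads = integer(0),
                      ta_coverage_equal = integer(0),
                      ta_coverage_unequal = integer(0))
    class(out) <- c("enzyme_summary", "data.frame")
    return(out)
  }
  enzymes <- sort(unique(stats$enzyme))

  summarise_system <- function(enz, system) {
    sys_stats <- stats[stats$enzyme == enz & stats$system == system, ,
                       drop = FALSE]
    if (!nrow(sys_stats) || sum(sys_stats$n_reads) == 0) {
      return(list(status = "n.a.", p = NA_real_, n = 0L))
    }
    inc <- sys_stats[sys_stats$included, , drop = FALSE]
    if (!nrow(inc)) {
      return(list(status = "i.d.", p = NA_real_,
                  n = sum(sys_stats$n_reads)))
    }
    n <- sum(inc$n_reads)
    p <- sum(inc$n_correct) / n
    if (p == 0) return(list(status = "i.d.", p = p, n = n))
    list(status = "ok", p = p, n = n)
  }

  rows <- lapply(enzymes, function(enz) {
    hap <- summarise_system(enz, "simple")
    ta <- summarise_system(enz, "two_allele")
    hap_cov <- if (hap$status == "ok") {
      min_coverage(allele_profile(hap$p), target)$n_min
    } else NA_integer_
    ta_eq <- if (ta$status == "ok") {
      min_coverage(allele_profile(ta$p, c(1, 1)), target)$n_min
    } else NA_integer_
    ta_un <- if (ta$status == "ok") {
      min_coverage(allele_profile(ta$p, c(2, 1)), target)$n_min
    } else NA_integer_
    data.frame(
      enzyme = enz,
      hap_status = hap$status, hap_p = hap$p, hap_n_reads = hap$n,
      hap_coverage = hap_cov,
      ta_status = ta$status, ta_p = ta$p, ta_n_reads = ta$n,
      ta_coverage_equal = ta_eq, ta_coverage_unequal = ta_un,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("enzyme_summary", "data.frame")
  out
}

#' Compare two PCR conditions by stratified permutation
#'
#' Read-weighted comparison of the correct-read proportion between two sets
#' of experimental units (for example standard versus modified cycling),
#' stratified by enzyme and individual. Within each stratum the per-condition
#' proportions are computed from pooled counts, their difference is weighted
#' by the stratum's total reads, and significance is assessed by randomly
#' reassigning the condition labels of the stratum's units. Strata present in
#' only one condition are dropped with a message.
#'
#' @param stats_a,stats_b \code{correct_read_stats} for the two conditions.
#' @param reps Number of label permutations (at least 100).
#' @param seed Integer seed.
#' @return List with \code{difference} (mean proportion in b minus a),
#'   \code{p_value} (two-sided), \code{n_strata} and \code{reps}.
#' @export
compare_conditions <- function(stats_a, stats_b, reps = 1000L, seed = 1L) {
  if (!nrow(stats_a) || !nrow(stats_b)) {
    stop("both condition collections must be non-empty")
  }
  reps <- as.integer(reps)
  if (reps < 100L) stop("reps must be at least 100")

  key_a <- paste(stats_a$enzyme, stats_a$individual, sep = "\r")
  key_b <- paste(stats_b$enzyme, stats_b$individual, sep = "\r")
  strata <- intersect(unique(key_a), unique(key_b))
  dropped <- setdiff(union(unique(key_a), unique(key_b)), strata)
  if (length(dropped)) {
    message(length(dropped),
            " stratum/strata present in only one condition dropped")
  }
  if (!length(strata)) stop("no stratum is present in both conditions")

  # per-stratum unit counts: rows are units, label 0 = a, 1 = b
  per_stratum <- lapply(strata, function(s) {
    a <- stats_a[key_a == s, c("n_reads", "n_correct"), drop = FALSE]
    b <- stats_b[key_b == s, c("n_reads", "n_correct"), drop = FALSE]
    list(n = c(a$n_reads, b$n_reads),
         x = c(a$n_correct, b$n_correct),
         lab = rep(c(0L, 1L), c(nrow(a), nrow(b))))
  })

  stat_fun <- function(labs) {
    d <- w <- numeric(length(per_stratum))
    for (s in seq_along(per_stratum)) {
      ps <- per_stratum[[s]]
      lab <- labs[[s]]
      na <- sum(ps$n[lab == 0L]); nb <- sum(ps$n[lab == 1L])
      if (na == 0 || nb == 0) { d[s] <- 0; w[s] <- 0; next }
      d[s] <- sum(ps$x[lab == 1L]) / nb - sum(ps$x[lab == 0L]) / na
      w[s] <- na + nb
    }
    if (sum(w) == 0) 0 else sum(w * d) / sum(w)
  }

  obs_labs <- lapply(per_stratum, `[[`, "lab")
  observed <- stat_fun(obs_labs)

  perm_stats <- with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      stat_fun(lapply(obs_labs, function(lab) sample(lab)))
    }, numeric(1))
  })
  p_value <- (1 + sum(abs(perm_stats) >= abs(observed) - 1e-12)) / (reps + 1)

  list(difference = observed, p_value = p_value,
       n_strata = length(strata), reps = reps)
}

#' Tabulate recovery-probability curves
#'
#' Recovery probability as a function of total reads for a set of allele
#' profiles, suitable for plotting one panel per profile shape (haplotype,
#' equal biallelic, 2:1 biased biallelic).
#'
#' @param profiles Named list of \code{\link{allele_profile}} objects.
#' @param k Minimum copies per allele.
#' @param n_max Largest read number tabulated.
#' @return data.frame with columns \code{label}, \code{n},
#'   \code{probability}, for n from k to \code{n_max}.
#' @export
probability_curves <- function(profiles, k = 3L, n_max = 50L) {
  k <- as.integer(k)
  if (n_max < k) stop("n_max must be at least k")
  if (is.null(names(profiles)) || any(!nzchar(names(profiles)))) {
    names(profiles) <- paste0("profile", seq_along(profiles))
  }
  ns <- k:n_max
  rows <- lapply(names(profiles), function(lab) {
    data.frame(label = lab, n = ns,
               probability = recovery_probability(ns, profiles[[lab]], k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an enzyme coverage table as tab-separated text
#'
#' Columns mirror a coverage report: enzyme, haplotype coverage, two-allele
#' coverage under equal and under 2:1 amplification, with \code{n.a.} /
#' \code{i.d.} flags in place of unavailable values.
#'
#' @param table An \code{enzyme_summary} from
#'   \code{\link{build_coverage_table}}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_coverage_table <- function(table, path) {
  fmt <- function(value, status) {
    ifelse(status == "ok", as.character(value), status)
  }
  out <- data.frame(
    enzyme = table$enzyme,
    haplotype = fmt(table$hap_coverage, table$hap_status),
    two_allele_equal = fmt(table$ta_coverage_equal, table$ta_status),
    two_allele_unequal = fmt(table$ta_coverage_unequal, table$ta_status),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
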