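# Synthetic tailed-amplicon read generator.
#
# Emulates reads with the two-round tailed architecture (adaptor, MID, M13
# tail, locus primer, insert, mirrored reverse structure) and a controllable
# error structure: per-base substitutions, homopolymer-site indels (runs of
# three or more identical bases), and single-crossover chimeras formed when a
# partially extended strand primes on a different allele. Correctness of each
# emitted read is judged post hoc on the emitted insert, so a back-mutation
# that regenerates a reference sequence counts as correct.

#' Per-enzyme error profile
#'
#' @param label Enzyme label.
#' @param target_p_correct Desired expected proportion of correct reads, used
#'   by \code{\link{calibrate_profile}}; \code{NA} to specify mechanistic
#'   rates directly.
#' @param substitution_rate Per-base substitution probability.
#' @param homopolymer_indel_rate Per-homopolymer-site (run of >= 3 identical
#'   bases) probability of a one-base insertion or deletion.
#' @param chimera_fraction Probability that a read is a two-template chimera;
#'   must be 0 when only one template allele exists.
#' @param allele_weights Positive amplification weights over the template
#'   alleles (recycled to the number of alleles at simulation time).
#' @return An object of class \code{enzyme_error_profile}.
#' @export
enzyme_error_profile <- function(label,
                                 target_p_correct = NA_real_,
                                 substitution_rate = 0,
                                 homopolymer_indel_rate = 0,
                                 chimera_fraction = 0,
                                 allele_weights = 1) {
  probs <- c(substitution_rate = substitution_rate,
             homopolymer_indel_rate = homopolymer_indel_rate,
             chimera_fraction = chimera_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("error rates must be probabilities in [0, 1]")
  }
  if (!is.na(target_p_correct) &&
      (target_p_correct < 0 || target_p_correct > 1)) {
    stop("target_p_correct must be in [0, 1]")
  }
  if (any(allele_weights <= 0)) stop("allele_weights must be positive")
  structure(
    list(label = label, target_p_correct = target_p_correct,
         substitution_rate = substitution_rate,
         homopolymer_indel_rate = homopolymer_indel_rate,
         chimera_fraction = chimera_fraction,
         allele_weights = allele_weights),
    class = "enzyme_error_profile"
  )
}

homopolymer_sites <- function(seq) {
  m <- gregexpr("([ACGT])\\1{2,}", seq, perl = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

#' Calibrate mechanistic rates to a target correct-read proportion
#'
#' Solves for the substitution rate at which the analytic probability that a
#' read survives unaltered equals \code{target_p_correct}, keeping the
#' profile's chimera fraction and homopolymer indel rate fixed. Survival
#' factorises over independent events: a read of allele i survives with
#' probability \code{(1 - chimera_fraction) * (1 - substitution_rate)^L_i *
#' (1 - homopolymer_indel_rate)^H_i}, where \code{L_i} is the allele length
#' and \code{H_i} its number of homopolymer sites; the expectation is taken
#' over the allele weights.
#'
#' @param profile An \code{\link{enzyme_error_profile}} with
#'   \code{target_p_correct} set.
#' @param alleles Character vector of template allele sequences.
#' @return The profile with \code{substitution_rate} replaced by the
#'   calibrated value.
#' @examples
#' pr <- enzyme_error_profile("e", target_p_correct = 0.5)
#' calibrate_profile(pr, paste(rep("ACGT", 25), collapse = ""))
#' @export
calibrate_profile <- function(profile, alleles) {
  stopifnot(inherits(profile, "enzyme_error_profile"))
  target <- profile$target_p_correct
  if (is.na(target)) stop("target_p_correct is not set")
  alleles <- toupper(alleles)
  L <- nchar(alleles)
  H <- vapply(alleles, homopolymer_sites, integer(1))
  w <- rep_len(profile$allele_weights, length(alleles))
  w <- w / sum(w)
  cf <- profile$chimera_fraction
  ir <- profile$homopolymer_indel_rate

  survival <- function(sr) {
    sum(w * (1 - cf) * (1 - sr)^L * (1 - ir)^H)
  }
  if (target > survival(0) + 1e-12) {
    stop("infeasible target: chimera/indel rates alone cap the correct-read ",
         "proportion at ", format(survival(0), digits = 4))
  }
  if (target == 1) {
    profile$substitution_rate <- 0
    return(profile)
  }
  sr <- if (target == 0) {
    1
  } else if (length(unique(L)) == 1L && length(unique(H)) == 1L) {
    1 - (target / ((1 - cf) * (1 - ir)^H[1]))^(1 / L[1])
  } else {
    stats::uniroot(function(s) survival(s) - target,
                   interval = c(0, 1), tol = 1e-12)$root
  }
  profile$substitution_rate <- min(max(sr, 0), 1)
  profile
}

mutate_substitutions <- function(inserts, rate) {
  if (rate <= 0) return(inserts)
  bases <- c("A", "C", "G", "T")
  lens <- nchar(inserts)
  n_mut <- stats::rbinom(length(inserts), lens, rate)
  for (i in which(n_mut > 0)) {
    pos <- sample.int(lens[i], n_mut[i])
    chars <- strsplit(inserts[i], "")[[1]]
    for (p in pos) {
      chars[p] <- sample(setdiff(bases, chars[p]), 1)
    }
    inserts[i] <- paste(chars, collapse = "")
  }
  inserts
}

mutate_homopolymers <- function(inserts, rate) {
  if (rate <= 0) return(inserts)
  for (i in seq_along(inserts)) {
    m <- gregexpr("([ACGT])\\1{2,}", inserts[i], perl = TRUE)[[1]]
    if (m[1] == -1L) next
    hit <- which(stats::runif(length(m)) < rate)
    if (!length(hit)) next
    chars <- strsplit(inserts[i], "")[[1]]
    # apply right-to-left so earlier positions stay valid
    for (j in rev(hit)) {
      pos <- m[j]
      if (stats::runif(1) < 0.5) {
        chars <- append(chars, chars[pos], after = pos)   # one-base insertion
      } else {
        chars <- chars[-pos]                              # one-base deletion
      }
    }
    inserts[i] <- paste(chars, collapse = "")
  }
  inserts
}

#' Simulate reads for one experimental unit
#'
#' Each read picks a template allele in proportion to the profile's allele
#' weights; with probability \code{chimera_fraction} the insert is replaced
#' by a single-crossover chimera of two distinct alleles at a uniformly
#' chosen internal breakpoint; substitutions and homopolymer indels are then
#' applied; finally the insert is wrapped in the full tailed-read structure
#' (degenerate primer positions realised per read) and emitted in a random
#' orientation. Deterministic for a fixed seed.
#'
#' @param design An \code{\link{amplicon_design}}.
#' @param alleles Named character vector of reference allele sequences for
#'   the unit's individual (names are allele ids).
#' @param profile An \code{\link{enzyme_error_profile}}.
#' @param n_reads Number of reads to emit.
#' @param mid MID barcode for the unit (length \code{design$mid_length}).
#' @param seed Integer seed.
#' @param unit Optional list/row with \code{system}, \code{enzyme},
#'   \code{pcr_condition}, \code{individual} copied into the truth table.
#' @param read_prefix Prefix for generated read ids.
#' @return List with \code{reads} (data.frame \code{read_id}, \code{sequence})
#'   and \code{truth} (data.frame \code{read_id}, \code{source_allele}
#'   (allele id, \code{"chimera"}, or \code{"error"}), \code{is_correct},
#'   plus the unit columns when \code{unit} is given). \code{is_correct} is
#'   true iff the emitted insert is character-identical to a reference
#'   allele.
#' @export
simulate_unit <- function(design, alleles, profile, n_reads, mid,
                          seed = 1L, unit = NULL, read_prefix = "read") {
  stopifnot(inherits(design, "amplicon_design"),
            inherits(profile, "enzyme_error_profile"))
  alleles <- toupper(alleles)
  if (!length(alleles)) stop("at least one template allele is required")
  if (is.null(names(alleles))) {
    names(alleles) <- paste0("allele", seq_along(alleles))
  }
  if (nchar(mid) != design$mid_length) {
    stop("mid must have length ", design$mid_length)
  }
  m <- length(unique(alleles))
  if (profile$chimera_fraction > 0 && m < 2L) {
    stop("chimeras require at least two distinct template alleles")
  }
  w <- rep_len(profile$allele_weights, length(alleles))

  with_seed(seed, {
    idx <- sample.int(length(alleles), n_reads, replace = TRUE, prob = w)
    inserts <- unname(alleles[idx])
    source <- names(alleles)[idx]

    is_chim <- stats::runif(n_reads) < profile$chimera_fraction
    for (i in which(is_chim)) {
      others <- which(alleles != alleles[idx[i]])
      j <- if (length(others) == 1L) others else sample(others, 1)
      a1 <- alleles[[idx[i]]]
      a2 <- alleles[[j]]
      # crossover strictly inside the first template
      b <- sample.int(nchar(a1) - 1L, 1)
      inserts[i] <- paste0(substr(a1, 1, b),
                           substr(a2, b + 1L, nchar(a2)))
      source[i] <- "chimera"
    }

    inserts <- mutate_substitutions(inserts, profile$substitution_rate)
    inserts <- mutate_homopolymers(inserts, profile$homopolymer_indel_rate)

    is_correct <- inserts %in% alleles
    altered <- !is_correct & source != "chimera"
    source[altered] <- "error"

    fwd_primers <- realize_iupac_many(design$forward_primer, n_reads)
    rev_primers <- realize_iupac_many(design$reverse_primer, n_reads)
    rc_rev_primers <- if (n_reads) reverse_complement(rev_primers)
                      else character(0)
    full <- paste0(design$adaptor_forward, mid, design$forward_tail,
                   fwd_primers, inserts, rc_rev_primers,
                   reverse_complement(design$reverse_tail),
                   reverse_complement(mid),
                   reverse_complement(design$adaptor_reverse))
    full <- as.character(full)

    flip <- stats::runif(n_reads) < 0.5
    if (any(flip)) full[flip] <- reverse_complement(full[flip])

    ids <- sprintf("%s_%05d", read_prefix, seq_len(n_reads))
    truth <- data.frame(read_id = ids, source_allele = source,
                        is_correct = is_correct, stringsAsFactors = FALSE)
    if (!is.null(unit)) {
      truth$system <- unit$system
      truth$enzyme <- unit$enzyme
      truth$pcr_condition <- unit$pcr_condition
      truth$individual <- unit$individual
    }
    list(
      reads = data.frame(read_id = ids, sequence = full,
                         stringsAsFactors = FALSE),
      truth = truth
    )
  })
}

#' Synthetic reference allele panel for the three marker systems
#'
#' Random reference alleles matching the bundled designs: one haplotype of
#' 168-172 bp per individual for the simple (mitochondrial) system, two
#' distinct 257 bp alleles for the biallelic nuclear system, and three
#' distinct 184 bp alleles for the multigene system. Homopolymer runs are
#' capped at five bases. The panel is synthetic: it stands in for the
#' Sanger-derived haplotypes and MHC genotypes that anchor a real experiment.
#'
#' @param individuals Character vector of individual labels.
#' @param seed Integer seed.
#' @return A \code{\link{reference_panel}}.
#' @export
synthetic_reference_panel <- function(individuals = c("ind1", "ind2", "ind3"),
                                      seed = 1L) {
  with_seed(seed, {
    draw <- function(len) {
      repeat {
        s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = "")
        # reject draws with homopolymers longer than 5 bp
        if (!grepl("([ACGT])\\1{5}", s, perl = TRUE)) return(s)
      }
    }
    rows <- list()
    for (ind in individuals) {
      rows[[length(rows) + 1L]] <- data.frame(
        individual = ind, locus = "mito_cr", allele_id = "hap1",
        sequence = draw(sample(168:172, 1)), stringsAsFactors = FALSE
      )
      for (a in 1:2) {
        rows[[length(rows) + 1L]] <- data.frame(
          individual = ind, locus = "mhc2_ex2",
          allele_id = paste0("DRB_", a),
          sequence = draw(257), stringsAsFactors = FALSE
        )
      }
      for (a in 1:3) {
        rows[[length(rows) + 1L]] <- data.frame(
          individual = ind, locus = "mhc1_ex3",
          allele_id = paste0("MHC1_", a),
          sequence = draw(184), stringsAsFactors = FALSE
        )
      }
    }
    reference_panel(do.call(rbind, rows))
  })
}

#' Simulate a miniature multi-enzyme amplicon experiment
#'
#' Builds a small, fully synthetic version of the study design: the three
#' marker systems, several enzyme error profiles, both PCR conditions and a
#' panel of individuals, each combination forming one experimental unit with
#' its own MID. Returns everything the downstream pipeline needs, so
#' demultiplexing, classification and reporting can be exercised end to end.
#'
#' @param profiles List of \code{\link{enzyme_error_profile}} objects; their
#'   \code{target_p_correct} values are honoured via
#'   \code{\link{calibrate_profile}} when set.
#' @param systems Which of the bundled marker systems to include.
#' @param conditions PCR condition labels to include.
#' @param individuals Individual labels.
#' @param n_reads Reads per experimental unit.
#' @param seed Integer seed; drives the panel, the MID set and every unit
#'   simulation.
#' @return List with \code{reads}, \code{truth}, \code{sheet}
#'   (a \code{\link{sample_sheet}}), \code{panel}, and \code{designs}.
#' @export
simulate_experiment <- function(profiles,
                                systems = c("simple", "two_allele",
                                            "multigene"),
                                conditions = c("standard", "modified"),
                                individuals = c("ind1", "ind2", "ind3"),
                                n_reads = 200L,
                                seed = 1L) {
  designs <- design_presets()[systems]
  panel <- synthetic_reference_panel(individuals, seed = seed)
  combos <- expand.grid(system = systems, condition = conditions,
                        individual = individuals,
                        profile = seq_along(profiles),
                        stringsAsFactors = FALSE)
  mids <- generate_mids(nrow(combos), seed = seed + 1L)

  sheet_rows <- list()
  reads <- list()
  truth <- list()
  for (i in seq_len(nrow(combos))) {
    co <- combos[i, ]
    prof <- profiles[[co$profile]]
    design <- designs[[co$system]]
    alleles <- panel$sequence[panel$individual == co$individual &
                                panel$locus == design$locus_name]
    names(alleles) <- panel$allele_id[panel$individual == co$individual &
                                        panel$locus == design$locus_name]
    if (!is.na(prof$target_p_correct)) {
      prof <- calibrate_profile(prof, alleles)
    }
    if (length(unique(alleles)) < 2L) prof$chimera_fraction <- 0
    unit <- list(system = co$system, enzyme = prof$label,
                 pcr_condition = co$condition, individual = co$individual)
    sim <- simulate_unit(design, alleles, prof, n_reads, mids[i],
                         seed = seed + 1000L + i, unit = unit,
                         read_prefix = sprintf("u%03d", i))
    sheet_rows[[i]] <- data.frame(
      mid = mids[i], locus = design$locus_name,
      system = co$system, enzyme = prof$label,
      pcr_condition = co$condition, individual = co$individual,
      stringsAsFactors = FALSE
    )
    reads[[i]] <- sim$reads
    truth[[i]] <- sim$truth
  }
  list(
    reads = do.call(rbind, reads),
    truth = do.call(rbind, truth),
    sheet = sample_sheet(do.call(rbind, sheet_rows)),
    panel = panel,
    designs = designs
  )
}
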