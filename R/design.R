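# Amplicon designs and sample sheets.
#
# A design describes the two-round tailed-primer read architecture of one
# locus: reads carry, in order, a sequencing adaptor (its last `key_length`
# bases are the platform key), a sample-specific MID barcode, a universal M13
# tail, the locus-specific primer, the insert, and the reverse-complemented
# mirror of that structure at the other end.

SYSTEMS <- c("simple", "two_allele", "multigene")
CONDITIONS <- c("standard", "modified")

#' Describe a tailed-amplicon design
#'
#' @param locus_name Label for the locus.
#' @param forward_primer,reverse_primer Locus-specific primers, 5'-3' on their
#'   own strand; IUPAC degeneracy codes allowed.
#' @param forward_tail,reverse_tail Universal tails appended 5' of each locus
#'   primer in the first PCR round (M13 tails).
#' @param adaptor_forward,adaptor_reverse Sequencing adaptors added in the
#'   second round, 5' of the MID.
#' @param mid_length Length of the sample-specific MID barcode (bases).
#' @param key_length Length of the platform key at the 3' end of each adaptor.
#' @param insert_length_range Inclusive \code{c(min, max)} length, in bases, of
#'   the insert excluding primers, tails, MIDs and adaptors.
#' @return An object of class \code{amplicon_design}.
#' @examples
#' design_presets()$simple
#' @export
amplicon_design <- function(locus_name, forward_primer, reverse_primer,
                            forward_tail, reverse_tail,
                            adaptor_forward, adaptor_reverse,
                            mid_length = 10L, key_length = 4L,
                            insert_length_range) {
  stopifnot(is.character(locus_name), nzchar(locus_name))
  parts <- c(forward_primer = forward_primer, reverse_primer = reverse_primer,
             forward_tail = forward_tail, reverse_tail = reverse_tail,
             adaptor_forward = adaptor_forward,
             adaptor_reverse = adaptor_reverse)
  parts <- toupper(parts)
  if (any(!nzchar(parts))) stop("primers, tails and adaptors must be non-empty")
  ok <- is_iupac(parts)
  if (!all(ok)) {
    stop("non-IUPAC characters in design field '", names(parts)[!ok][1], "'")
  }
  mid_length <- as.integer(mid_length)
  key_length <- as.integer(key_length)
  if (mid_length <= 0) stop("mid_length must be positive")
  if (key_length < 0) stop("key_length must be non-negative")
  insert_length_range <- as.integer(insert_length_range)
  if (length(insert_length_range) != 2 ||
      insert_length_range[1] > insert_length_range[2]) {
    stop("insert_length_range must be c(min, max) with min <= max")
  }
  structure(
    c(list(locus_name = locus_name), as.list(parts),
      list(mid_length = mid_length, key_length = key_length,
           insert_length_range = insert_length_range)),
    class = "amplicon_design"
  )
}

#' @export
print.amplicon_design <- function(x, ...) {
  cat("Tailed-amplicon design for locus '", x$locus_name, "'\n", sep = "")
  cat("  forward: ", x$adaptor_forward, " [MID:", x$mid_length, "] ",
      tolower(x$forward_tail), " ", x$forward_primer, "\n", sep = "")
  cat("  reverse: ", x$adaptor_reverse, " [MID:", x$mid_length, "] ",
      tolower(x$reverse_tail), " ", x$reverse_primer, "\n", sep = "")
  cat("  insert length: ", x$insert_length_range[1], "-",
      x$insert_length_range[2], " bp\n", sep = "")
  invisible(x)
}

#' Bundled amplicon designs for the three marker systems
#'
#' Three designs of increasing genetic complexity: a mitochondrial control
#' region fragment (one haplotype per individual), an MHC class II exon 2
#' fragment (one or two alleles), and an MHC class I exon 3 fragment
#' (multigene family, several alleles per individual). All three share the
#' universal M13 tails and Lib-A adaptors of the two-round tailed design.
#'
#' @return Named list of \code{amplicon_design} objects with elements
#'   \code{simple}, \code{two_allele} and \code{multigene}.
#' @export
design_presets <- function() {
  tails <- list(ft = "GTTTTCCCAGTCACGAC", rt = "AACAGCTATGACCATG")
  adA <- "CGTATCGCCTCCCTCGCGCCATCAG"
  adB <- "CTATGCGCCTTGCCAGCCCGCTCAG"
  list(
    simple = amplicon_design(
      "mito_cr", "GAATTCCCCGGTCTTGTAAACC", "CATTAATGCACGACGTACATAGG",
      tails$ft, tails$rt, adA, adB,
      insert_length_range = c(168, 172)
    ),
    two_allele = amplicon_design(
      "mhc2_ex2", "GGGTCTCACACCYKCCAG", "GMGCWGCAGSGTCTCYTT",
      tails$ft, tails$rt, adA, adB,
      insert_length_range = c(252, 262)
    ),
    multigene = amplicon_design(
      "mhc1_ex3", "GCTTCTCATCCTAGTTCCCTT", "GCCTAGGAGTGCAGCAGA",
      tails$ft, tails$rt, adA, adB,
      insert_length_range = c(179, 189)
    )
  )
}

#' Build a validated sample sheet
#'
#' A sample sheet maps MID barcodes (optionally per locus) to experimental
#' units. The unit key is the tuple (system, enzyme, pcr_condition,
#' individual).
#'
#' @param df A data.frame with columns \code{mid}, \code{locus},
#'   \code{system}, \code{enzyme}, \code{pcr_condition}, \code{individual}.
#' @param mid_length Expected MID length; every MID must have exactly this
#'   length.
#' @return The validated data.frame, with class \code{sample_sheet} prepended.
#' @export
sample_sheet <- function(df, mid_length = 10L) {
  req <- c("mid", "locus", "system", "enzyme", "pcr_condition", "individual")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("sample sheet is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df$mid <- toupper(df$mid)
  if (any(nchar(df$mid) != mid_length)) {
    stop("all MIDs must have length ", mid_length)
  }
  if (!all(df$system %in% SYSTEMS)) {
    stop("system must be one of: ", paste(SYSTEMS, collapse = ", "))
  }
  if (!all(df$pcr_condition %in% CONDITIONS)) {
    stop("pcr_condition must be one of: ", paste(CONDITIONS, collapse = ", "))
  }
  key <- paste(df$mid, df$locus, sep = "\r")
  if (anyDuplicated(key)) {
    stop("a MID maps to two experimental units for the same locus")
  }
  if (any(!nzchar(df$enzyme)) || any(!nzchar(df$individual))) {
    stop("enzyme and individual labels must be non-empty")
  }
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Read a sample sheet from delimited text
#'
#' @param path Tab-separated file with the columns documented in
#'   \code{\link{sample_sheet}}.
#' @param mid_length Expected MID length.
#' @return A \code{sample_sheet}.
#' @export
read_sample_sheet <- function(path, mid_length = 10L) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  sample_sheet(df, mid_length = mid_length)
}

#' Generate a set of MID barcodes
#'
#' Draws random barcodes of the given length with a minimum pairwise Hamming
#' distance, so that single errors cannot convert one MID into another.
#'
#' @param n Number of barcodes.
#' @param length Barcode length in bases.
#' @param min_dist Minimum pairwise Hamming distance.
#' @param seed Integer seed.
#' @return Character vector of \code{n} barcodes.
#' @export
generate_mids <- function(n, length = 10L, min_dist = 3L, seed = 1L) {
  with_seed(seed, {
    mids <- character(0)
    tries <- 0L
    while (length(mids) < n) {
      cand <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                    collapse = "")
      if (all(vapply(mids, hamming, integer(1), cand) >= min_dist)) {
        mids <- c(mids, cand)
      }
      tries <- tries + 1L
      if (tries > 10000L * n) stop("cannot place ", n, " MIDs at distance ",
                                   min_dist)
    }
    mids
  })
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random number stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
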