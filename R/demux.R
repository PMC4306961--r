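# MID demultiplexing with the completeness and size filters.
#
# A read is assigned iff, in either orientation, it contains in order a
# complete MID from the sample sheet, the complete forward tail and the
# complete forward locus primer, then the insert, then the reverse complement
# of the reverse primer, reverse tail and the same MID. Matching is exact and
# mismatch-free; IUPAC degeneracy is honoured in the locus primers only.

REJECT_REASONS <- c("none", "no_mid", "incomplete_primer",
                    "length_out_of_range", "ambiguous_mid")

#' Demultiplex amplicon reads to experimental units
#'
#' Applies the completeness filter (complete MID, tail and locus primer at
#' both ends, same MID at both ends, either read orientation accepted) and the
#' size filter (trimmed insert length within the design's
#' \code{insert_length_range}). Matching is exact: no mismatches are tolerated
#' in MIDs, tails or primers; degenerate IUPAC codes in the locus primers
#' match any base of their set. Rejected reads are data, not errors: every
#' input read yields exactly one record with a \code{reject_reason}.
#'
#' @param reads data.frame with columns \code{read_id} and \code{sequence}
#'   (as returned by \code{\link{read_sequences}}).
#' @param design An \code{\link{amplicon_design}}.
#' @param sheet A \code{\link{sample_sheet}}; only rows whose \code{locus}
#'   equals \code{design$locus_name} are used.
#' @return An object of class \code{demux_result}: a list with
#'   \describe{
#'     \item{records}{data.frame with one row per input read: \code{read_id},
#'       the unit key columns (\code{system}, \code{enzyme},
#'       \code{pcr_condition}, \code{individual}; \code{NA} when unassigned),
#'       \code{orientation} (\code{forward}/\code{reverse}/\code{unassigned}),
#'       \code{trimmed_insert} (\code{NA} when unassigned) and
#'       \code{reject_reason}.}
#'     \item{summary}{named integer vector of counts per reject reason
#'       (\code{none} = assigned).}
#'   }
#' @export
demultiplex <- function(reads, design, sheet) {
  stopifnot(inherits(design, "amplicon_design"))
  sheet <- as.data.frame(sheet, stringsAsFactors = FALSE)
  sheet <- sheet[sheet$locus == design$locus_name, , drop = FALSE]
  if (any(nchar(sheet$mid) != design$mid_length)) {
    stop("sample sheet MIDs inconsistent with design mid_length")
  }

  n <- nrow(reads)
  seqs <- toupper(reads$sequence)
  rc_seqs <- if (n) reverse_complement(seqs) else character(0)

  pat <- paste0(
    "([ACGT]{", design$mid_length, "})",
    design$forward_tail,
    iupac_regex(design$forward_primer),
    "([A-Z]*?)",
    iupac_regex(reverse_complement(design$reverse_primer)),
    reverse_complement(design$reverse_tail),
    "([ACGT]{", design$mid_length, "})"
  )

  fwd <- match_structure(pat, seqs)
  rev <- match_structure(pat, rc_seqs)

  # a candidate is a structural match whose two MIDs agree and are in the sheet
  validate <- function(m) {
    row <- rep(NA_integer_, n)
    idx <- which(m$matched)
    if (length(idx)) {
      mid2 <- reverse_complement(m$mid2rc[idx])
      agree <- m$mid1[idx] == mid2
      row[idx[agree]] <- match(m$mid1[idx[agree]], sheet$mid)
    }
    row
  }
  row_f <- validate(fwd)
  row_r <- validate(rev)

  lo <- design$insert_length_range[1]
  hi <- design$insert_length_range[2]

  ambiguous <- !is.na(row_f) & !is.na(row_r) & row_f != row_r
  use_f <- !is.na(row_f) & !ambiguous
  use_r <- is.na(row_f) & !is.na(row_r) & !ambiguous

  row <- ifelse(use_f, row_f, ifelse(use_r, row_r, NA_integer_))
  insert <- ifelse(use_f, fwd$insert, ifelse(use_r, rev$insert, NA_character_))
  orientation <- ifelse(use_f, "forward",
                        ifelse(use_r, "reverse", "unassigned"))

  len_ok <- !is.na(insert) & nchar(insert) >= lo & nchar(insert) <= hi
  assigned <- !is.na(row) & len_ok

  reason <- rep("no_mid", n)
  reason[ambiguous] <- "ambiguous_mid"
  reason[!is.na(row) & !len_ok] <- "length_out_of_range"
  reason[assigned] <- "none"

  # structural failures: distinguish "barcode absent" from "primer incomplete"
  unresolved <- which(reason == "no_mid")
  for (i in unresolved) {
    if (has_mid_tail(seqs[i], rc_seqs[i], sheet$mid, design)) {
      reason[i] <- "incomplete_primer"
    }
  }

  unit_cols <- c("system", "enzyme", "pcr_condition", "individual")
  out <- data.frame(
    read_id = reads$read_id,
    system = NA_character_, enzyme = NA_character_,
    pcr_condition = NA_character_, individual = NA_character_,
    orientation = "unassigned",
    trimmed_insert = NA_character_,
    reject_reason = reason,
    stringsAsFactors = FALSE
  )
  if (any(assigned)) {
    out[assigned, unit_cols] <- sheet[row[assigned], unit_cols]
    out$orientation[assigned] <- orientation[assigned]
    out$trimmed_insert[assigned] <- insert[assigned]
  }

  summary <- table(factor(out$reject_reason, levels = REJECT_REASONS))
  structure(list(records = out, summary = c(summary)), class = "demux_result")
}

# vectorised structural match; returns the three capture groups
match_structure <- function(pattern, x) {
  if (!length(x)) {
    return(list(matched = logical(0), mid1 = character(0),
                insert = character(0), mid2rc = character(0)))
  }
  m <- regexpr(pattern, x, perl = TRUE)
  matched <- m != -1L
  cs <- attr(m, "capture.start")
  cl <- attr(m, "capture.length")
  grab <- function(j) {
    out <- rep(NA_character_, length(x))
    idx <- which(matched)
    out[idx] <- substring(x[idx], cs[idx, j], cs[idx, j] + cl[idx, j] - 1L)
    out
  }
  list(matched = matched, mid1 = grab(1L), insert = grab(2L),
       mid2rc = grab(3L))
}

# does the read carry any sheet MID immediately followed by the forward tail,
# in either orientation?
has_mid_tail <- function(seq, rc_seq, mids, design) {
  probes <- paste0(mids, design$forward_tail)
  any(vapply(probes, function(p) {
    grepl(p, seq, fixed = TRUE) || grepl(p, rc_seq, fixed = TRUE)
  }, logical(1)))
}

#' @export
print.demux_result <- function(x, ...) {
  n <- nrow(x$records)
  cat("Demultiplexing of", n, "reads\n")
  for (r in names(x$summary)) {
    lab <- if (r == "none") "assigned" else r
    cat(sprintf("  %-20s %d\n", lab, x$summary[[r]]))
  }
  invisible(x)
}

#' Write assigned reads to per-unit FASTA files
#'
#' @param demux A \code{demux_result}.
#' @param dir Output directory (created if needed). One FASTA per experimental
#'   unit, named \code{system_enzyme_condition_individual.fasta}.
#' @return Character vector of the files written, invisibly.
#' @export
write_assigned_fasta <- function(demux, dir) {
  rec <- demux$records
  rec <- rec[rec$reject_reason == "none", , drop = FALSE]
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  key <- paste(rec$system, rec$enzyme, rec$pcr_condition, rec$individual,
               sep = "_")
  files <- character(0)
  for (k in unique(key)) {
    sel <- key == k
    f <- file.path(dir, paste0(k, ".fasta"))
    write_fasta(rec$read_id[sel], rec$trimmed_insert[sel], f)
    files <- c(files, f)
  }
  invisible(files)
}
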