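# Identity-based read classification against known reference alleles.
#
# The scoring rule is pure identity: a read is correct iff its trimmed insert
# is character-identical to a reference allele of its individual (either
# strand). Indels, substitutions and chimeras all make a read incorrect;
# there is no clustering or variant calling.

#' Build a reference allele panel
#'
#' @param df data.frame with columns \code{individual}, \code{locus},
#'   \code{allele_id}, \code{sequence}. Alleles within one
#'   (individual, locus) entry must be pairwise distinct.
#' @return The validated data.frame with class \code{reference_panel}.
#' @export
reference_panel <- function(df) {
  req <- c("individual", "locus", "allele_id", "sequence")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("reference panel is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df$sequence <- toupper(df$sequence)
  if (any(!nzchar(df$sequence))) stop("reference alleles must be non-empty")
  key <- paste(df$individual, df$locus, df$sequence, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate allele sequence within one (individual, locus) entry")
  }
  class(df) <- c("reference_panel", "data.frame")
  df
}

#' Read a reference panel from FASTA
#'
#' Headers must have the structured form \code{individual|locus|allele_id}.
#'
#' @param path FASTA file path.
#' @return A \code{\link{reference_panel}}.
#' @export
read_reference_panel <- function(path) {
  seqs <- read_sequences(path, "fasta")
  parts <- strsplit(seqs$read_id, "|", fixed = TRUE)
  if (any(lengths(parts) != 3)) {
    stop("reference FASTA headers must be 'individual|locus|allele_id'")
  }
  m <- do.call(rbind, parts)
  reference_panel(data.frame(
    individual = m[, 1], locus = m[, 2], allele_id = m[, 3],
    sequence = seqs$sequence, stringsAsFactors = FALSE
  ))
}

#' Classify assigned reads as correct or incorrect
#'
#' A read is correct iff its trimmed insert is character-identical to any
#' reference allele of its individual at the locus, on either strand. Correct
#' reads are attributed to the matching allele (ties broken by allele_id sort
#' order). Per unit, the proportion of correct reads \code{p_hat} is
#' \code{n_correct / n_reads}, and the unit is \code{included} in downstream
#' statistics iff it has more than 10 reads.
#'
#' @param records Assigned demultiplexing records: a \code{demux_result} or
#'   its \code{records} data.frame (unassigned rows are dropped).
#' @param panel A \code{\link{reference_panel}}.
#' @param locus Locus name to look up in the panel.
#' @return A data.frame of class \code{correct_read_stats}, one row per
#'   experimental unit: the unit key columns, \code{n_reads},
#'   \code{n_correct}, \code{p_hat}, \code{included}, and a list-column
#'   \code{per_allele_counts} of named counts summing to \code{n_correct}.
#' @export
classify_reads <- function(records, panel, locus) {
  if (inherits(records, "demux_result")) records <- records$records
  rec <- records[records$reject_reason == "none", , drop = FALSE]
  pan <- panel[panel$locus == locus, , drop = FALSE]

  unit_cols <- c("system", "enzyme", "pcr_condition", "individual")
  missing_ind <- setdiff(unique(rec$individual), unique(pan$individual))
  if (length(missing_ind)) {
    bad <- rec[match(missing_ind[1], rec$individual), unit_cols]
    stop("individual '", missing_ind[1], "' (unit ",
         paste(unlist(bad), collapse = "/"),
         ") has no reference alleles for locus '", locus, "'")
  }

  if (!nrow(rec)) {
    res <- data.frame(system = character(0), enzyme = character(0),
                      pcr_condition = character(0), individual = character(0),
                      n_reads = integer(0), n_correct = integer(0),
                      p_hat = numeric(0), included = logical(0))
    res$per_allele_counts <- list()
    class(res) <- c("correct_read_stats", "data.frame")
    return(res)
  }

  key <- interaction(rec[unit_cols], drop = TRUE, sep = "\r", lex.order = TRUE)
  groups <- split(seq_len(nrow(rec)), key)

  rows <- lapply(groups, function(idx) {
    ind <- rec$individual[idx[1]]
    alleles <- pan[pan$individual == ind, , drop = FALSE]
    alleles <- alleles[order(alleles$allele_id), , drop = FALSE]
    # identity on either strand; attribution to the first matching allele
    hit <- match(rec$trimmed_insert[idx], alleles$sequence)
    rc_hit <- match(reverse_complement(rec$trimmed_insert[idx]),
                    alleles$sequence)
    hit[is.na(hit)] <- rc_hit[is.na(hit)]
    counts <- table(factor(alleles$allele_id[hit],
                           levels = alleles$allele_id))
    n_reads <- length(idx)
    n_correct <- sum(!is.na(hit))
    out <- rec[idx[1], unit_cols]
    out$n_reads <- n_reads
    out$n_correct <- n_correct
    out$p_hat <- if (n_reads > 0) n_correct / n_reads else NA_real_
    out$included <- n_reads > 10L
    out$per_allele_counts <- list(c(counts))
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("correct_read_stats", "data.frame")
  res
}

#' Pool per-unit statistics over a grouping key
#'
#' Read and correct-read counts (and per-allele counts) are summed within each
#' group; \code{p_hat} and the \code{included} flag (pooled reads > 10) are
#' recomputed from the pooled counts.
#'
#' @param stats A \code{correct_read_stats} data.frame.
#' @param by Character vector naming the key columns to keep, a subset of
#'   \code{c("system", "enzyme", "pcr_condition", "individual")}.
#' @return A pooled \code{correct_read_stats} data.frame with the \code{by}
#'   columns.
#' @export
pool_stats <- function(stats, by) {
  unit_cols <- c("system", "enzyme", "pcr_condition", "individual")
  if (!all(by %in% unit_cols)) {
    stop("'by' must be a subset of: ", paste(unit_cols, collapse = ", "))
  }
  if (!nrow(stats)) {
    out <- stats[, c(by, "n_reads", "n_correct", "p_hat", "included"),
                 drop = FALSE]
    out$per_allele_counts <- list()
    return(out)
  }
  key <- interaction(stats[by], drop = TRUE, sep = "\r", lex.order = TRUE)
  groups <- split(seq_len(nrow(stats)), key)
  rows <- lapply(groups, function(idx) {
    out <- stats[idx[1], by, drop = FALSE]
    out$n_reads <- sum(stats$n_reads[idx])
    out$n_correct <- sum(stats$n_correct[idx])
    out$p_hat <- if (out$n_reads > 0) out$n_correct / out$n_reads else NA_real_
    out$included <- out$n_reads > 10L
    all_counts <- unlist(stats$per_allele_counts[idx])
    merged <- if (length(all_counts)) {
      tapply(all_counts, names(all_counts), sum)
    } else {
      numeric(0)
    }
    out$per_allele_counts <- list(merged[order(names(merged))])
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("correct_read_stats", "data.frame")
  res
}

#' Write per-unit statistics as tab-separated text
#'
#' @param stats A \code{correct_read_stats} data.frame.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_stats_tsv <- function(stats, path) {
  flat <- as.data.frame(stats)
  flat$per_allele_counts <- vapply(
    stats$per_allele_counts,
    function(x) paste(sprintf("%s=%d", names(x), as.integer(x)),
                      collapse = ";"),
    character(1)
  )
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
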