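# Chronological sequence-frequency tables: per-isotype full joins over
# weeks, maximum-frequency column, S#/L# sequence IDs, and the stacked
# two-isotype table used by all downstream stages.
#
# Column layout: sequence_id, isotype, sequence, freq_w<week>...,
# max_freq. The integer week vector is kept in attribute "weeks".

freq_cols <- function(weeks) paste0("freq_w", weeks)

#' Weeks covered by a chronological table
#' @param ct Chronological data.frame.
#' @return Integer vector of weeks.
#' @export
chrono_weeks <- function(ct) attr(ct, "weeks")

#' Frequency matrix of a chronological table
#' @param ct Chronological data.frame.
#' @return Integer matrix, rows as in `ct`, one column per week.
#' @export
freq_matrix <- function(ct) {
  as.matrix(ct[, freq_cols(chrono_weeks(ct)), drop = FALSE])
}

#' Full-join per-week tables of one isotype
#'
#' One row per unique sequence observed in any week; a sequence absent
#' from a week gets frequency 0 there.
#'
#' @param tables Named list of sequence-frequency data.frames; names
#'   are the integer weeks.
#' @return Chronological data.frame (IDs unset) with `max_freq`.
#' @export
full_join_weeks <- function(tables) {
  weeks <- as.integer(names(tables))
  if (anyNA(weeks)) stop("tables must be named by integer week")
  if (anyDuplicated(weeks)) stop("duplicate week")
  ord <- order(weeks)
  weeks <- weeks[ord]
  tables <- tables[ord]
  seqs <- unique(unlist(lapply(tables, `[[`, "sequence"), use.names = FALSE))
  mat <- matrix(0L, nrow = length(seqs), ncol = length(weeks),
                dimnames = list(NULL, freq_cols(weeks)))
  for (k in seq_along(weeks)) {
    t <- tables[[k]]
    mat[match(t$sequence, seqs), k] <- as.integer(t$frequency)
  }
  ct <- data.frame(sequence = seqs, stringsAsFactors = FALSE)
  ct <- cbind(ct, as.data.frame(mat))
  ct$max_freq <- if (length(seqs)) apply(mat, 1L, max) else integer(0)
  attr(ct, "weeks") <- weeks
  ct
}

#' Assign S#/L# sequence IDs within one isotype
#'
#' Rows are sorted by descending maximum frequency and numbered
#' `S1, S2, ...` (IgG2, short hinge) or `L1, L2, ...` (IgG3, long
#' hinge). Ties are broken by earlier first-appearance week, then by
#' lexicographic sequence, so the assignment is invariant to input row
#' order.
#'
#' @param ct Output of [full_join_weeks()].
#' @param isotype `"IgG2"` or `"IgG3"`.
#' @return Chronological data.frame with `sequence_id` and `isotype`.
#' @export
assign_sequence_ids <- function(ct, isotype) {
  isotype <- match.arg(isotype, c("IgG2", "IgG3"))
  prefix <- if (isotype == "IgG2") "S" else "L"
  weeks <- chrono_weeks(ct)
  fm <- freq_matrix(ct)
  first_week <- apply(fm > 0L, 1L, function(x) weeks[which(x)[1]])
  ord <- order(-ct$max_freq, first_week, ct$sequence)
  ct <- ct[ord, , drop = FALSE]
  out <- data.frame(sequence_id = paste0(prefix, seq_len(nrow(ct)),
                                         recycle0 = TRUE),
                    isotype = rep(isotype, nrow(ct)),
                    stringsAsFactors = FALSE)
  out <- cbind(out, ct)
  rownames(out) <- NULL
  attr(out, "weeks") <- weeks
  out
}

#' Stack the IgG2 and IgG3 chronological tables
#'
#' @param igg2,igg3 ID-assigned chronological data.frames sharing one
#'   week set. The same nucleotide sequence may appear once per
#'   isotype.
#' @return Combined chronological data.frame.
#' @export
stack_isotypes <- function(igg2, igg3) {
  w2 <- chrono_weeks(igg2)
  w3 <- chrono_weeks(igg3)
  if (!identical(w2, w3)) stop("week sets differ between isotypes")
  out <- rbind(igg2, igg3)
  rownames(out) <- NULL
  attr(out, "weeks") <- w2
  out
}

#' Build the stacked chronological table from per-sample tables
#'
#' Convenience wrapper: full-join each isotype's weekly tables, assign
#' S#/L# IDs, and stack.
#'
#' @param igg2_tables,igg3_tables Named lists (week -> table) for each
#'   isotype; either may be an empty list.
#' @return Chronological data.frame.
#' @export
build_chronology <- function(igg2_tables, igg3_tables) {
  weeks <- sort(unique(c(as.integer(names(igg2_tables)),
                         as.integer(names(igg3_tables)))))
  pad <- function(tabs) {
    empty <- data.frame(sequence = character(0), frequency = integer(0),
                        stringsAsFactors = FALSE)
    full <- setNames(rep(list(empty), length(weeks)), as.character(weeks))
    full[names(tabs)] <- tabs
    full
  }
  ig2 <- assign_sequence_ids(full_join_weeks(pad(igg2_tables)), "IgG2")
  ig3 <- assign_sequence_ids(full_join_weeks(pad(igg3_tables)), "IgG3")
  stack_isotypes(ig2, ig3)
}

#' Write / read a chronological table as TSV
#' @param ct Chronological data.frame.
#' @param path Output path.
#' @export
write_chronology <- function(ct, path) {
  write.table(ct, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chronology
#' @export
read_chronology <- function(path) {
  ct <- read.delim(path, stringsAsFactors = FALSE)
  wcols <- grep("^freq_w", names(ct), value = TRUE)
  attr(ct, "weeks") <- as.integer(sub("^freq_w", "", wcols))
  ct
}
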