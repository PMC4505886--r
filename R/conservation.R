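## Sequence conservation at the CoR-adjacent framework position.
##
## The residue pair flanking the center of rotation corresponds to position
## 44 of the IMGT unique numbering in both chains. Conservation is tabulated
## from a user-supplied multiple sequence alignment of V-segment sequences
## (the aligner is external; a column-to-IMGT-position map ties alignment
## columns to numbering positions).

#' Read an aligned FASTA file
#'
#' @param path Path to an aligned FASTA (equal-length rows, `-` gaps).
#' @return Object of class `msa_alignment`: character matrix (rows =
#'   sequences, named; columns = alignment positions), upper case.
#' @export
read_aligned_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- seqinr::read.fasta(path, seqtype = "AA", set.attributes = FALSE,
                             forceDNAtolower = FALSE)
  if (length(seqs) == 0) stop("format error: no sequences in ", path)
  ids <- names(seqs)
  if (anyDuplicated(ids))
    stop("format error: duplicate sequence ids in ", path)
  widths <- lengths(seqs)
  if (length(unique(widths)) != 1)
    stop("format error: ragged alignment (sequence lengths ",
         paste(sort(unique(widths)), collapse = ", "), ")")
  ali <- toupper(do.call(rbind, seqs))
  rownames(ali) <- ids
  structure(ali, class = c("msa_alignment", "matrix"))
}

#' Write an alignment back to FASTA
#'
#' @param alignment An `msa_alignment` (or character matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(alignment, path) {
  ids <- rownames(alignment)
  seqs <- apply(alignment, 1, paste, collapse = "")
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  invisible(path)
}

#' Amino-acid frequencies at one alignment column
#'
#' Counts each residue type at the column; gaps (`-`, `.`) and fully
#' undetermined letters (`X`) are reported separately as incomplete rows
#' rather than silently dropped. Fractions are relative to the number of
#' sequences with a residue at the column, so they sum to 1 when gaps are
#' absent and to at most 1 always (relative to all sequences).
#'
#' @param alignment An `msa_alignment`.
#' @param column 1-based alignment column.
#' @param position_label Label for the reported position (e.g.
#'   `"IMGT 44"`); defaults to the column number.
#' @return Object of class `position_frequency`: data.frame `aa`, `count`,
#'   `fraction` sorted by count, with attributes `n_sequences`, `n_gap`,
#'   `n_counted`, `position_label`, `incomplete_ids`.
#' @export
frequency_at_position <- function(alignment, column, position_label = NULL) {
  stopifnot(is.matrix(alignment))
  if (!is.numeric(column) || length(column) != 1 ||
      column < 1 || column > ncol(alignment))
    stop("column ", column, " outside alignment width ", ncol(alignment))
  if (is.null(position_label)) position_label <- as.character(column)
  col <- toupper(alignment[, column])
  is_gap <- col %in% c("-", ".", "X")
  counted <- col[!is_gap]
  tab <- sort(table(counted), decreasing = TRUE)
  out <- data.frame(aa = names(tab), count = as.integer(tab),
                    fraction = as.numeric(tab) / length(counted),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("position_frequency", "data.frame"),
            n_sequences = nrow(alignment),
            n_gap = sum(is_gap),
            n_counted = length(counted),
            position_label = position_label,
            incomplete_ids = rownames(alignment)[is_gap])
}

#' @export
print.position_frequency <- function(x, ...) {
  cat("Residue frequencies at position ", attr(x, "position_label"), " (",
      attr(x, "n_counted"), " of ", attr(x, "n_sequences"),
      " sequences counted, ", attr(x, "n_gap"), " gap/incomplete)\n",
      sep = "")
  df <- as.data.frame(unclass(x))[seq_len(nrow(x)), c("aa", "count",
                                                      "fraction")]
  df$fraction <- round(df$fraction, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
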