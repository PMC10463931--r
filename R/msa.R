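# Aligned-FASTA parsing, residue <-> column maps, and traceback of
# residue-specific descriptor features to Ballesteros-Weinstein generic
# positions / receptor regions.

new_msa <- function(ids, rows) {
  if (anyDuplicated(ids)) stop("duplicate ids in MSA")
  L <- unique(nchar(rows))
  if (length(L) != 1) stop("ragged rows: all aligned rows must have equal length")
  maps <- lapply(rows, function(r) {
    ch <- strsplit(r, "")[[1]]
    which(!(ch %in% c("-", ".")))
  })
  names(maps) <- ids
  structure(list(ids = ids, rows = stats::setNames(rows, ids), L = L,
                 maps = maps), class = "ddpd_msa")
}

#' Parse an aligned FASTA file
#'
#' Both `-` and `.` are treated as gap characters. Residue-to-column maps
#' (strictly increasing, one entry per ungapped residue) are precomputed
#' for every record.
#'
#' @param path Aligned FASTA file.
#' @return A `ddpd_msa`: list with `ids`, `rows` (named aligned strings),
#'   `L` (column count) and `maps` (1-based residue -> column).
#' @export
parse_msa <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) < 1) stop("no records in alignment")
  ids <- sub("\\s.*$", "", names(seqs))
  new_msa(ids, as.character(seqs))
}

#' Write an MSA as aligned FASTA
#'
#' @param msa A `ddpd_msa`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path) {
  x <- Biostrings::BStringSet(msa$rows)
  names(x) <- msa$ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @export
print.ddpd_msa <- function(x, ...) {
  cat("ddpd_msa:", length(x$ids), "sequences x", x$L, "columns\n")
  invisible(x)
}

msa_map_of <- function(msa, target_id) {
  if (!target_id %in% msa$ids) stop("target ", target_id, " absent from MSA")
  msa$maps[[target_id]]
}

#' Map an alignment column to a residue of one target
#'
#' Inverse of the residue -> column map.
#'
#' @param msa A `ddpd_msa`.
#' @param target_id Target identifier.
#' @param column 1-based alignment column.
#' @return 1-based residue index, or `NA` when the target has a gap at that
#'   column.
#' @export
column_to_residue <- function(msa, target_id, column) {
  if (column < 1 || column > msa$L) stop("column out of range 1..", msa$L)
  map <- msa_map_of(msa, target_id)
  hit <- match(column, map)
  if (is.na(hit)) NA_integer_ else hit
}

#' Read a generic-position (Ballesteros-Weinstein) annotation table
#'
#' Two or three column CSV: `column` (1-based MSA column), `bw` (generic
#' label such as "3.32", may be empty), and optionally `region` (N-term,
#' TM1-7, ICL1-3, ECL1-3, H8, C-term).
#'
#' @param path CSV file path.
#' @param L Optional alignment length for range validation.
#' @return data.frame with columns `column`, `bw`, `region`.
#' @export
read_bw_table <- function(path, L = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"column" %in% names(tab)) stop("BW table needs a 'column' column")
  if (!"bw" %in% names(tab)) tab$bw <- NA_character_
  if (!"region" %in% names(tab)) tab$region <- NA_character_
  tab$bw[tab$bw == ""] <- NA_character_
  tab$region[tab$region == ""] <- NA_character_
  if (!is.null(L) && any(tab$column < 1 | tab$column > L)) {
    stop("BW table column outside 1..", L)
  }
  tab[, c("column", "bw", "region")]
}

#' Trace a residue-specific descriptor feature to its generic position
#'
#' Parses a feature label of the form `AA{column}_PC{c}` and reports the
#' alignment column, the principal-component index, the
#' Ballesteros-Weinstein label of that column when one exists (else the
#' region label, else "unannotated"), and optionally the concrete residue
#' of a target at that column.
#'
#' @param feature_name Feature label, e.g. `"AA223_PC3"`.
#' @param bw Annotation table from [read_bw_table()], or `NULL`.
#' @param msa A `ddpd_msa`, or `NULL`.
#' @param target_id Optional target for residue lookup.
#' @return A list with `column`, `pc`, `label`, `residue` (1-based residue
#'   index in the target, or `NA`).
#' @export
trace_feature <- function(feature_name, bw = NULL, msa = NULL,
                          target_id = NULL) {
  m <- regmatches(feature_name,
                  regexec("^AA([0-9]+)_PC([0-9]+)$", feature_name))[[1]]
  if (length(m) != 3) stop("malformed feature name: ", feature_name)
  column <- as.integer(m[2]); pc <- as.integer(m[3])
  if (!is.null(msa) && (column < 1 || column > msa$L)) {
    stop("column out of range 1..", msa$L)
  }
  label <- "unannotated"
  if (!is.null(bw)) {
    row <- bw[bw$column == column, , drop = FALSE]
    if (nrow(row)) {
      label <- if (!is.na(row$bw[1])) row$bw[1]
               else if (!is.na(row$region[1])) row$region[1]
               else "unannotated"
    }
  }
  residue <- NA_integer_
  if (!is.null(msa) && !is.null(target_id)) {
    residue <- column_to_residue(msa, target_id, column)
  }
  list(column = column, pc = pc, label = label, residue = residue)
}
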