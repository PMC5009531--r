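#' Read a PSI-BLAST ASCII PSSM profile
#'
#' Parses the `-out_ascii_pssm` dialect: header lines, then one row per
#' residue starting with the residue index and letter, followed by 20
#' integer log-odds columns (the first block; the second block of 20
#' weighted-percentage columns and the trailing information columns are
#' ignored). Columns follow the PSI-BLAST amino-acid order
#' `A R N D C Q E G H I L K M F P S T W Y V`.
#'
#' @param path Path to an ASCII PSSM file.
#' @param sequence Optional amino-acid string; if supplied, residue letters
#'   in the file are checked against it and a mismatch is an error.
#' @return A tibble with `position`, `aa`, and one integer column per
#'   amino acid in PSI-BLAST column order. Zero rows for a header-only file.
#' @export
read_pssm <- function(path, sequence = NULL) {
  if (!file.exists(path)) abort(paste0("PSSM file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  # residue rows: index, letter, then numbers
  is_row <- grepl("^\\s*\\d+\\s+[A-Za-z]\\s+-?\\d", lines)
  rows <- lines[is_row]
  if (length(rows) == 0L) return(.empty_pssm_tbl())

  parsed <- purrr::map(seq_along(rows), function(j) {
    tok <- strsplit(trimws(rows[j]), "\\s+")[[1]]
    vals <- suppressWarnings(as.integer(tok[-(1:2)]))
    vals <- vals[!is.na(vals)]
    if (length(vals) < 20L) {
      abort(sprintf(
        "PSSM row %d has %d numeric log-odds values; 20 required",
        j, length(vals)))
    }
    list(position = as.integer(tok[1]), aa = toupper(tok[2]),
         scores = vals[1:20])
  })
  aa <- purrr::map_chr(parsed, "aa")
  if (!is.null(sequence)) {
    seq_chars <- if (length(sequence) == 1L) {
      strsplit(sequence, "")[[1]]
    } else {
      sequence
    }
    if (length(seq_chars) != length(aa) || any(toupper(seq_chars) != aa)) {
      abort("PSSM residue letters do not match the supplied sequence")
    }
  }
  m <- do.call(rbind, purrr::map(parsed, "scores"))
  colnames(m) <- PSSM_AA_ORDER
  dplyr::bind_cols(
    tibble(position = purrr::map_int(parsed, "position"), aa = aa),
    tibble::as_tibble(m)
  )
}

.empty_pssm_tbl <- function() {
  m <- matrix(integer(), nrow = 0, ncol = 20,
              dimnames = list(NULL, PSSM_AA_ORDER))
  dplyr::bind_cols(tibble(position = integer(), aa = character()),
                   tibble::as_tibble(m))
}

#' Write a profile in PSI-BLAST ASCII PSSM layout
#'
#' Emits the header, the double amino-acid column ruler, one row per
#' residue with the 20 log-odds integers followed by a zeroed
#' weighted-percentage block, and the trailing blank lines, so that the
#' file is re-readable by [read_pssm()] with exact value round-trip.
#'
#' @param profile Tibble as returned by [read_pssm()]: `position`, `aa`,
#'   plus the 20 score columns in PSI-BLAST order.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pssm <- function(profile, path) {
  .check_cols(profile, c("position", "aa", PSSM_AA_ORDER), "profile")
  header <- c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("           ",
           paste(sprintf("%4s", PSSM_AA_ORDER), collapse = ""),
           "  ",
           paste(sprintf("%4s", PSSM_AA_ORDER), collapse = ""))
  )
  m <- as.matrix(profile[, PSSM_AA_ORDER])
  rows <- vapply(seq_len(nrow(profile)), function(i) {
    paste0(sprintf("%5d %s ", profile$position[i], profile$aa[i]),
           paste(sprintf("%4d", m[i, ]), collapse = ""),
           "  ",
           paste(sprintf("%4d", rep(0L, 20)), collapse = ""),
           sprintf("  %4.2f %8.2f", 0, 0))
  }, character(1))
  writeLines(c(header, rows, "", ""), path)
  invisible(path)
}
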