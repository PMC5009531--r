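#' Read and write chain sequences as FASTA
#'
#' Thin wrappers around Biostrings' FASTA support. Sequences are exchanged
#' as a tibble of `chain_id` and `sequence`.
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: tibble with `chain_id`, `sequence`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  tibble(chain_id = names(ss), sequence = unname(as.character(ss)))
}

#' @rdname read_fasta
#' @param seqs Tibble with `chain_id`, `sequence`.
#' @export
write_fasta <- function(seqs, path) {
  .check_cols(seqs, c("chain_id", "sequence"), "seqs")
  ss <- Biostrings::AAStringSet(setNames(seqs$sequence, seqs$chain_id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read and write per-residue assignment tables
#'
#' Assignment TSVs carry either hard labels (`ss` in `{H, E, C}`, `sa` in
#' `{B, E}`) or predictor probabilities (`ss_H`, `ss_E`, `ss_C` summing to 1;
#' `sa_E`, `sa_B` summing to 1), keyed by `chain_id` and `position`.
#'
#' @param path TSV path.
#' @return A tibble with the file's columns.
#' @export
read_assignments <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_assignments
#' @param df Assignment tibble.
#' @export
write_assignments <- function(df, path) {
  .check_cols(df, c("chain_id", "position"), "df")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read and write flexibility label tables
#'
#' Label TSVs record the normalized B-value and discrete flexibility state
#' per residue: columns `chain_id`, `position`, `aa`, `b_norm`, `state`.
#'
#' @param path TSV path.
#' @return A label tibble.
#' @export
read_labels <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    chain_id = readr::col_character(),
                    position = readr::col_integer(),
                    aa = readr::col_character(),
                    b_norm = readr::col_double(),
                    state = readr::col_character()
                  ))
}

#' @rdname read_labels
#' @param labels Label tibble with columns `chain_id`, `position`, `aa`,
#'   `b_norm`, `state`.
#' @export
write_labels <- function(labels, path) {
  .check_cols(labels, c("chain_id", "position", "aa", "b_norm", "state"),
              "labels")
  readr::write_tsv(labels, path, progress = FALSE)
  invisible(path)
}

#' Write per-residue flexibility predictions
#'
#' Emits a TSV with columns `chain_id`, `position`, `aa`, `p_R`, `p_I`,
#' `p_F`, `state`; probabilities are written with six decimal places so a
#' read-back reproduces them exactly at that precision. An empty prediction
#' set yields a header-only file.
#'
#' @param pred Tibble with the columns above (`state` optional; recomputed
#'   as the probability argmax if absent, ties toward R then I).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_predictions <- function(pred, path) {
  .check_cols(pred, c("chain_id", "position", "aa", "p_R", "p_I", "p_F"),
              "pred")
  if (!"state" %in% names(pred)) {
    probs <- as.matrix(pred[, c("p_R", "p_I", "p_F")])
    pred$state <- if (nrow(pred) == 0L) character() else
      FLEX_STATES[max.col(probs, ties.method = "first")]
  }
  out <- pred |>
    dplyr::mutate(dplyr::across(c("p_R", "p_I", "p_F"),
                                ~ sprintf("%.6f", .x))) |>
    dplyr::select(dplyr::all_of(
      c("chain_id", "position", "aa", "p_R", "p_I", "p_F", "state")))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    chain_id = readr::col_character(),
                    position = readr::col_integer(),
                    aa = readr::col_character(),
                    p_R = readr::col_double(),
                    p_I = readr::col_double(),
                    p_F = readr::col_double(),
                    state = readr::col_character()
                  ))
}
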