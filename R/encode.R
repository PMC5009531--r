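# Names of the 34 per-residue feature slots, in encoding order.
.feature_names <- function() {
  c(paste0("pssm_", PSSM_AA_ORDER),
    paste0("scrs_", FLEX_STATES),
    c("ss_H", "ss_E", "ss_C"),
    c("sa_E", "sa_B"),
    paste0("aap_", colnames(.aap_raw)),
    "terminal")
}

#' Logistic scaling of PSSM log-odds
#'
#' Maps integer log-odds to (0, 1) with the standard logistic transform
#' `1 / (1 + exp(-x))`, bounding PSSM inputs like every other feature.
#'
#' @param log_odds Numeric vector or matrix.
#' @return Same shape, values in (0, 1).
#' @examples
#' scale_pssm(c(-2, 0, 2))
#' @export
scale_pssm <- function(log_odds) {
  if (any(!is.finite(log_odds))) abort("PSSM log-odds must be finite")
  1 / (1 + exp(-log_odds))
}

#' Assemble the 34 feature values of one residue
#'
#' Concatenates, in fixed order: 20 logistically scaled PSSM values, 3
#' context scores (SCRS), 3 secondary-structure probabilities (H, E, C),
#' 2 solvent-accessibility probabilities (exposed, buried), 5 normalized
#' amino-acid properties, and 1 terminal-overlap indicator. A padding
#' position (a window slot beyond either chain end) is all zeros with the
#' terminal indicator set to 1.
#'
#' @param aa One-letter residue code (used for the property lookup; `"X"`
#'   or unknown codes get the column-mean property row).
#' @param pssm_row 20 log-odds values (raw; scaled internally).
#' @param scrs 3 context scores.
#' @param ss_probs 3 secondary-structure probabilities.
#' @param sa_probs 2 solvent-accessibility probabilities.
#' @param is_padding If `TRUE` all other arguments are ignored.
#' @return Named numeric vector of length 34.
#' @export
residue_features <- function(aa = NULL, pssm_row = NULL, scrs = NULL,
                             ss_probs = NULL, sa_probs = NULL,
                             is_padding = FALSE) {
  nm <- .feature_names()
  if (is_padding) {
    return(setNames(c(rep(0, 33), 1), nm))
  }
  if (length(pssm_row) != 20L) abort("pssm_row must have 20 values")
  if (length(scrs) != 3L) abort("scrs must have 3 values")
  if (length(ss_probs) != 3L) abort("ss_probs must have 3 values")
  if (length(sa_probs) != 2L) abort("sa_probs must have 2 values")
  if (any(c(ss_probs, sa_probs) < 0)) abort("probabilities must be >= 0")
  aap <- .aap_matrix()
  row <- if (!is.null(aa) && aa %in% rownames(aap)) aap[aa, ] else aap["X", ]
  setNames(c(scale_pssm(as.numeric(pssm_row)), as.numeric(scrs),
             as.numeric(ss_probs), as.numeric(sa_probs),
             as.numeric(row), 0), nm)
}

#' Sliding-window encoding of one residue
#'
#' Concatenates the per-residue feature rows of the `window` positions
#' centred on `center` (offsets -7..+7 for the default window of 15).
#' Offsets that fall outside the chain become padding slots (zeros with the
#' terminal indicator 1), so the encoding always has
#' `window * 34 = 510` values at the default width.
#'
#' @param features Numeric matrix (chain length x 34), e.g. rows built by
#'   [residue_features()].
#' @param center 1-based centre position.
#' @param window Odd window length (default 15).
#' @return Numeric vector of length `window * 34`.
#' @export
encode_window <- function(features, center, window = 15L) {
  if (!is.matrix(features) || ncol(features) != 34L) {
    abort("features must be a numeric matrix with 34 columns")
  }
  L <- nrow(features)
  if (center < 1L || center > L) abort("center out of range")
  half <- (window - 1L) %/% 2L
  pad <- c(rep(0, 33), 1)
  idx <- center + seq(-half, half)
  out <- lapply(idx, function(i) {
    if (i < 1L || i > L) pad else features[i, ]
  })
  v <- unlist(out, use.names = FALSE)
  names(v) <- paste0("w", sprintf("%02d", seq_len(window)), "_",
                     rep(.feature_names(), times = window))
  v
}

# Resolve per-residue SS / SA probability columns for a corpus tibble:
# probability columns win if present, otherwise one-hot from hard labels.
.resolve_ss_sa <- function(corpus) {
  has_ss_probs <- all(c("ss_H", "ss_E", "ss_C") %in% names(corpus))
  has_sa_probs <- all(c("sa_E", "sa_B") %in% names(corpus))
  if (!has_ss_probs) {
    .check_cols(corpus, "ss", "corpus (no ss probability columns)")
    corpus$ss_H <- as.numeric(corpus$ss == "H")
    corpus$ss_E <- as.numeric(corpus$ss == "E")
    corpus$ss_C <- as.numeric(corpus$ss == "C")
  }
  if (!has_sa_probs) {
    .check_cols(corpus, "sa", "corpus (no sa probability columns)")
    corpus$sa_E <- as.numeric(corpus$sa == "E")
    corpus$sa_B <- as.numeric(corpus$sa == "B")
  }
  corpus
}

#' Encode a labeled corpus into network inputs
#'
#' Builds, per chain, the 34-column per-residue feature matrix (scaled
#' PSSM, SCRS from the potential table, SS/SA probabilities, amino-acid
#' properties, terminal flag) and expands it into one sliding-window row
#' per residue. Feature columns not supplied can be dropped for ablation
#' studies via `features`.
#'
#' @param corpus Residue tibble with `chain_id`, `position`, `aa`, optional
#'   `state`, and either probability columns (`ss_H`, `ss_E`, `ss_C`,
#'   `sa_E`, `sa_B`) or hard `ss`/`sa` labels.
#' @param pssm PSSM tibble with `chain_id`, `position` and the 20 log-odds
#'   columns in PSI-BLAST order, covering every corpus residue.
#' @param potentials A `flex_potentials` object (may be `NULL` when
#'   `"scrs"` is not among `features`).
#' @param window Odd window length (default 15; 510 inputs).
#' @param features Character subset of
#'   `c("pssm", "scrs", "ss", "sa", "aap")` to include; excluded groups are
#'   encoded as zeros so the input width is unchanged. Default all.
#' @return An object of class `flex_encoding`: list with `x` (numeric
#'   matrix, residues x `window * 34`), `label` (state per row, `NA` when
#'   the corpus is unlabeled), `meta` (tibble `chain_id`, `position`),
#'   `window`, `features`.
#' @export
encode_corpus <- function(corpus, pssm, potentials = NULL, window = 15L,
                          features = c("pssm", "scrs", "ss", "sa", "aap")) {
  .check_cols(corpus, c("chain_id", "position", "aa"), "corpus")
  features <- match.arg(features, several.ok = TRUE)
  use <- function(f) f %in% features
  if (use("scrs") && is.null(potentials)) {
    abort("potentials required when the scrs feature group is enabled")
  }
  if (use("ss") || use("sa")) corpus <- .resolve_ss_sa(corpus)
  if (use("pssm")) {
    .check_cols(pssm, c("chain_id", "position", PSSM_AA_ORDER), "pssm")
    corpus <- dplyr::left_join(
      corpus,
      dplyr::select(pssm, dplyr::all_of(c("chain_id", "position",
                                          PSSM_AA_ORDER))),
      by = c("chain_id", "position"))
    if (anyNA(corpus[[PSSM_AA_ORDER[1]]])) {
      abort("pssm profile missing for some corpus residues")
    }
  }
  aap <- .aap_matrix()
  nm <- .feature_names()
  half <- (window - 1L) %/% 2L

  chains <- split(corpus, corpus$chain_id)
  blocks <- purrr::map(chains, function(ch) {
    L <- nrow(ch)
    f <- matrix(0, nrow = L, ncol = 34L, dimnames = list(NULL, nm))
    if (use("pssm")) {
      f[, 1:20] <- scale_pssm(as.matrix(ch[, PSSM_AA_ORDER]))
    }
    if (use("scrs")) {
      sc <- scrs_scores(potentials, ch$aa)
      f[, 21:23] <- as.matrix(sc[, c("scrs_R", "scrs_I", "scrs_F")])
    }
    if (use("ss")) f[, 24:26] <- as.matrix(ch[, c("ss_H", "ss_E", "ss_C")])
    if (use("sa")) f[, 27:28] <- as.matrix(ch[, c("sa_E", "sa_B")])
    if (use("aap")) {
      ridx <- match(ch$aa, rownames(aap))
      ridx[is.na(ridx)] <- which(rownames(aap) == "X")
      f[, 29:33] <- aap[ridx, , drop = FALSE]
    }
    # expand to sliding windows: pad row index L + 1
    fpad <- rbind(f, c(rep(0, 33), 1))
    idx <- outer(seq_len(L), seq(-half, half), "+")
    idx[idx < 1L | idx > L] <- L + 1L
    do.call(cbind, lapply(seq_len(window), function(j) {
      fpad[idx[, j], , drop = FALSE]
    }))
  })
  x <- do.call(rbind, blocks)
  colnames(x) <- paste0("w", sprintf("%02d", rep(seq_len(window), each = 34)),
                        "_", rep(nm, times = window))
  meta <- dplyr::bind_rows(purrr::map(chains, function(ch) {
    ch[, c("chain_id", "position", "aa")]
  }))
  attr(meta, "flex_filter") <- NULL
  label <- if ("state" %in% names(corpus)) {
    unlist(purrr::map(chains, "state"), use.names = FALSE)
  } else {
    rep(NA_character_, nrow(x))
  }
  structure(list(x = x, label = label, meta = meta, window = window,
                 features = features),
            class = "flex_encoding")
}

#' @export
print.flex_encoding <- function(x, ...) {
  cat("<flex_encoding>", nrow(x$x), "residues x", ncol(x$x), "inputs",
      sprintf("(window %d, features: %s)\n", x$window,
              paste(x$features, collapse = ", ")))
  invisible(x)
}

#' Write and read an encoded dataset
#'
#' Persists a `flex_encoding` as a TSV: metadata columns `chain_id`,
#' `position`, `label`, then one column per input value with the feature
#' layout recorded in the header names.
#'
#' @param encoding A `flex_encoding`.
#' @param path TSV path.
#' @return Invisibly, `path`.
#' @export
write_encoding <- function(encoding, path) {
  stopifnot(inherits(encoding, "flex_encoding"))
  df <- dplyr::bind_cols(
    encoding$meta,
    tibble(label = encoding$label),
    tibble::as_tibble(encoding$x)
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_encoding
#' @export
read_encoding <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  meta <- df[, c("chain_id", "position", "aa")]
  label <- df$label
  x <- as.matrix(df[, setdiff(names(df),
                              c("chain_id", "position", "aa", "label"))])
  window <- ncol(x) %/% 34L
  structure(list(x = x, label = as.character(label), meta = meta,
                 window = window,
                 features = c("pssm", "scrs", "ss", "sa", "aap")),
            class = "flex_encoding")
}
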