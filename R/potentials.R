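# Offset bookkeeping for a context window of half-width w: the 2w nonzero
# offsets and the ordered offset pairs (k1 < k2).
.context_offsets <- function(window_half) {
  k <- setdiff(seq(-window_half, window_half), 0L)
  pairs <- t(utils::combn(k, 2L))
  colnames(pairs) <- c("k1", "k2")
  list(k = k, pairs = pairs)
}

#' Count singlet/doublet/triplet residue-state contexts
#'
#' Tallies, over a labeled corpus, how often each residue type (singlet),
#' ordered residue pair at sequence offset k (doublet), and ordered residue
#' triple at offset pair k1 < k2 (triplet) is observed with the center
#' residue in each flexibility state, within a window of `2 * window_half + 1`
#' residues (default 7: offsets in -3..3 excluding 0). Contexts that extend
#' past either chain end are skipped -- no padding, no wraparound. Residues
#' of unknown type (`"X"`) contribute no counts; any context containing one
#' is skipped.
#'
#' @param corpus Labeled residue tibble with `chain_id`, `aa`, `state`
#'   (rows in sequence order within each chain). Every row must have a
#'   defined state; filter first.
#' @param window_half Context half-width (default 3).
#' @return An object of class `flex_counts`: dense count arrays `singlet`
#'   (state x residue), `doublet` (state x offset x residue x residue),
#'   `triplet` (state x offset-pair x residue x residue x residue), plus
#'   `state_totals`, `grand_total`, and the offset bookkeeping.
#' @export
count_contexts <- function(corpus, window_half = 3L) {
  .check_cols(corpus, c("chain_id", "aa", "state"), "corpus")
  if (any(is.na(corpus$state))) {
    abort("corpus contains residues with undefined state; filter first")
  }
  off <- .context_offsets(window_half)
  nk <- length(off$k)
  np <- nrow(off$pairs)

  singlet <- array(0L, dim = c(3L, 20L),
                   dimnames = list(FLEX_STATES, AA20))
  li_d <- vector("list", 0L)
  li_t <- vector("list", 0L)

  chains <- split(corpus[, c("aa", "state")], corpus$chain_id)
  for (ch in chains) {
    r <- match(ch$aa, AA20)          # NA for X / non-standard
    s <- match(ch$state, FLEX_STATES)
    if (any(is.na(s))) abort("corpus contains states outside {R, I, F}")
    L <- length(r)
    ok <- !is.na(r)
    if (any(ok)) {
      tab <- tabulate(s[ok] + 3L * (r[ok] - 1L), nbins = 60L)
      singlet <- singlet + array(tab, dim = c(3L, 20L))
    }
    for (ki in seq_len(nk)) {
      k <- off$k[ki]
      lo <- max(1L, 1L - k); hi <- min(L, L - k)
      if (lo > hi) next
      i <- lo:hi
      j <- i + k
      v <- ok[i] & ok[j]
      if (!any(v)) next
      li_d[[length(li_d) + 1L]] <-
        s[i][v] + 3L * ((ki - 1L) + nk * ((r[i][v] - 1L) +
                                          20L * (r[j][v] - 1L)))
    }
    for (pi in seq_len(np)) {
      k1 <- off$pairs[pi, 1L]; k2 <- off$pairs[pi, 2L]
      lo <- max(1L, 1L - k1); hi <- min(L, L - k2)
      if (lo > hi) next
      i <- lo:hi
      j1 <- i + k1; j2 <- i + k2
      v <- ok[i] & ok[j1] & ok[j2]
      if (!any(v)) next
      li_t[[length(li_t) + 1L]] <-
        s[i][v] + 3L * ((pi - 1L) + np * ((r[i][v] - 1L) +
                        20L * ((r[j1][v] - 1L) + 20L * (r[j2][v] - 1L))))
    }
  }
  li_d <- if (length(li_d)) unlist(li_d) else integer(0)
  li_t <- if (length(li_t)) unlist(li_t) else integer(0)
  doublet <- array(tabulate(li_d, nbins = 3L * nk * 400L),
                   dim = c(3L, nk, 20L, 20L),
                   dimnames = list(FLEX_STATES, as.character(off$k),
                                   AA20, AA20))
  triplet <- array(tabulate(li_t, nbins = 3L * np * 8000L),
                   dim = c(3L, np, 20L, 20L, 20L),
                   dimnames = list(FLEX_STATES, NULL, AA20, AA20, AA20))
  state_totals <- rowSums(singlet)
  structure(list(
    window_half = as.integer(window_half),
    offsets = off$k,
    offset_pairs = off$pairs,
    singlet = singlet,
    doublet = doublet,
    triplet = triplet,
    state_totals = state_totals,
    grand_total = sum(state_totals)
  ), class = "flex_counts")
}

#' @export
print.flex_counts <- function(x, ...) {
  cat("<flex_counts> window half-width", x$window_half, "\n")
  cat("  residues counted:", x$grand_total, "\n")
  cat("  state totals:",
      paste(names(x$state_totals), x$state_totals, sep = "=",
            collapse = "  "), "\n")
  invisible(x)
}

# -ln(f_hat / f) for one count array with state as the first dimension.
.potential_from_counts <- function(counts, f, w) {
  d <- dim(counts)
  m3 <- matrix(counts, nrow = 3L)
  m <- colSums(m3)
  denom <- m + w
  f_hat <- (m3 + w * f) / rep(denom, each = 3L)
  # unsmoothed empty cells (w = 0, m = 0): potential defined as 0
  f_hat[, denom == 0] <- f
  u <- -log(f_hat / f)
  array(u, dim = d, dimnames = dimnames(counts))
}

#' Derive mean-force pseudo-potentials from context counts
#'
#' Converts context counts into inverse-Boltzmann potentials
#' \eqn{U(C, x) = -\ln(\hat f(C \mid x) / f(C))}, where \eqn{f(C)} is the
#' corpus-wide state frequency and \eqn{\hat f} is the observed conditional
#' state frequency in context `x`, shrunk toward the prior with
#' `blend_weight` pseudo-observations:
#' \eqn{\hat f = (m f_{obs} + w f) / (m + w)} with `m` the context's total
#' count. A never-observed context therefore has \eqn{U = 0}; large
#' `blend_weight` drives all potentials toward 0, and `blend_weight = 0`
#' recovers the raw log-ratio wherever `m > 0`. Negative `U` marks a state
#' enriched in that context (favourable), positive `U` a depleted one.
#'
#' @param counts A `flex_counts` object from [count_contexts()].
#' @param blend_weight Pseudo-observation mass `w >= 0` (default 10).
#' @return An object of class `flex_potentials` holding the three potential
#'   arrays (same shapes as the counts), the state prior `prior`, and the
#'   smoothing weight.
#' @export
derive_potentials <- function(counts, blend_weight = 10) {
  stopifnot(inherits(counts, "flex_counts"))
  if (counts$grand_total == 0L) abort("empty corpus: no counted residues")
  if (!is.numeric(blend_weight) || blend_weight < 0) {
    abort("blend_weight must be a non-negative number")
  }
  f <- counts$state_totals / counts$grand_total
  if (any(f == 0)) {
    abort(paste0("state(s) never observed in the corpus: ",
                 paste(names(f)[f == 0], collapse = ", ")))
  }
  structure(list(
    window_half = counts$window_half,
    offsets = counts$offsets,
    offset_pairs = counts$offset_pairs,
    blend_weight = blend_weight,
    prior = f,
    singlet = .potential_from_counts(counts$singlet, f, blend_weight),
    doublet = .potential_from_counts(counts$doublet, f, blend_weight),
    triplet = .potential_from_counts(counts$triplet, f, blend_weight)
  ), class = "flex_potentials")
}

#' @export
print.flex_potentials <- function(x, ...) {
  cat("<flex_potentials> window half-width", x$window_half,
      " blend weight", x$blend_weight, "\n")
  cat("  state prior:",
      paste(names(x$prior), sprintf("%.3f", x$prior), sep = "=",
            collapse = "  "), "\n")
  cat("  non-zero cells: singlet", sum(x$singlet != 0),
      " doublet", sum(x$doublet != 0),
      " triplet", sum(x$triplet != 0), "\n")
  invisible(x)
}

# Total context potential for every position and state of one chain:
# returns an L x 3 matrix (columns R, I, F). Terms whose context leaves the
# chain, or involves an unknown residue, contribute 0.
.chain_potentials <- function(pot, seq_letters) {
  r <- match(seq_letters, AA20)
  L <- length(r)
  nk <- length(pot$offsets)
  np <- nrow(pot$offset_pairs)
  U <- matrix(0, nrow = L, ncol = 3L,
              dimnames = list(NULL, FLEX_STATES))
  ok <- !is.na(r)
  for (s in 1:3) {
    U[ok, s] <- pot$singlet[s, r[ok]]
    for (ki in seq_len(nk)) {
      k <- pot$offsets[ki]
      lo <- max(1L, 1L - k); hi <- min(L, L - k)
      if (lo > hi) next
      i <- lo:hi
      j <- i + k
      v <- ok[i] & ok[j]
      if (!any(v)) next
      iv <- i[v]
      U[iv, s] <- U[iv, s] +
        pot$doublet[cbind(s, ki, r[iv], r[j[v]])]
    }
    for (pi in seq_len(np)) {
      k1 <- pot$offset_pairs[pi, 1L]; k2 <- pot$offset_pairs[pi, 2L]
      lo <- max(1L, 1L - k1); hi <- min(L, L - k2)
      if (lo > hi) next
      i <- lo:hi
      j1 <- i + k1; j2 <- i + k2
      v <- ok[i] & ok[j1] & ok[j2]
      if (!any(v)) next
      iv <- i[v]
      U[iv, s] <- U[iv, s] +
        pot$triplet[cbind(s, pi, r[iv], r[j1[v]], r[j2[v]])]
    }
  }
  U
}

#' Combined context pseudo-potential of one residue
#'
#' Sums the singlet, doublet and triplet potentials of residue `i` in state
#' `state` over all in-range context offsets: for an interior residue of a
#' chain of length >= 7 with the default window this is 1 + 6 + 15 = 22
#' terms; at a chain end, out-of-range terms are simply omitted.
#'
#' @param pot A `flex_potentials` object.
#' @param sequence Amino-acid string (or character vector) of the chain.
#' @param i 1-based residue position.
#' @param state One of `"R"`, `"I"`, `"F"`.
#' @return A single numeric pseudo-potential value.
#' @export
combined_pseudo_potential <- function(pot, sequence, i, state) {
  stopifnot(inherits(pot, "flex_potentials"))
  letters <- if (length(sequence) == 1L) strsplit(sequence, "")[[1]] else sequence
  if (i < 1L || i > length(letters)) abort("position i out of range")
  s <- match(state, FLEX_STATES)
  if (is.na(s)) abort("state must be one of R, I, F")
  unname(.chain_potentials(pot, letters)[i, s])
}

#' Context-based state scores (SCRS)
#'
#' Converts the combined pseudo-potentials of a residue in the three
#' flexibility states into normalized preferences
#' \eqn{\exp(-U(C)) / \sum_{C'} \exp(-U(C'))}: a point on the 3-simplex,
#' each component in (0, 1), suitable as bounded network inputs.
#'
#' @param pot A `flex_potentials` object.
#' @param sequence Amino-acid string or character vector.
#' @param i Optional 1-based position; if `NULL` (default) all positions
#'   are scored.
#' @return A tibble with columns `position`, `scrs_R`, `scrs_I`, `scrs_F`.
#' @export
scrs_scores <- function(pot, sequence, i = NULL) {
  stopifnot(inherits(pot, "flex_potentials"))
  letters <- if (length(sequence) == 1L) strsplit(sequence, "")[[1]] else sequence
  U <- .chain_potentials(pot, letters)
  if (!is.null(i)) {
    if (any(i < 1L | i > length(letters))) abort("position i out of range")
    U <- U[i, , drop = FALSE]
  } else {
    i <- seq_along(letters)
  }
  e <- exp(-U)
  p <- e / rowSums(e)
  dimnames(p) <- NULL
  tibble(position = as.integer(i),
         scrs_R = p[, 1], scrs_I = p[, 2], scrs_F = p[, 3])
}

#' Serialize and restore a potential table
#'
#' The potential table is written as a single structured JSON document
#' holding the window half-width, the smoothing weight, the state prior,
#' and the three potential tables as explicit (state, offsets, residues,
#' value) records; cells with zero potential (in particular all
#' never-observed contexts) are omitted and restored as zero.
#'
#' @param pot A `flex_potentials` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_potentials <- function(pot, path) {
  stopifnot(inherits(pot, "flex_potentials"))
  nk <- length(pot$offsets)
  np <- nrow(pot$offset_pairs)

  s_idx <- which(pot$singlet != 0, arr.ind = TRUE)
  singlet <- tibble(
    state = FLEX_STATES[s_idx[, 1]],
    res = AA20[s_idx[, 2]],
    u = pot$singlet[s_idx]
  )
  d_idx <- which(pot$doublet != 0, arr.ind = TRUE)
  doublet <- tibble(
    state = FLEX_STATES[d_idx[, 1]],
    k = pot$offsets[d_idx[, 2]],
    res_i = AA20[d_idx[, 3]],
    res_j = AA20[d_idx[, 4]],
    u = pot$doublet[d_idx]
  )
  t_idx <- which(pot$triplet != 0, arr.ind = TRUE)
  triplet <- tibble(
    state = FLEX_STATES[t_idx[, 1]],
    k1 = pot$offset_pairs[t_idx[, 2], 1L],
    k2 = pot$offset_pairs[t_idx[, 2], 2L],
    res_i = AA20[t_idx[, 3]],
    res_j = AA20[t_idx[, 4]],
    res_k = AA20[t_idx[, 5]],
    u = pot$triplet[t_idx]
  )
  doc <- list(
    format = "flexseq_potentials",
    version = 1L,
    window_half = pot$window_half,
    blend_weight = pot$blend_weight,
    prior = as.list(pot$prior),
    singlet = singlet,
    doublet = doublet,
    triplet = triplet
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_potentials
#' @export
read_potentials <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$format) || doc$format != "flexseq_potentials") {
    abort("not a flexseq potential table")
  }
  off <- .context_offsets(doc$window_half)
  nk <- length(off$k)
  np <- nrow(off$pairs)
  prior <- unlist(doc$prior)[FLEX_STATES]
  singlet <- array(0, dim = c(3L, 20L), dimnames = list(FLEX_STATES, AA20))
  s <- doc$singlet
  if (length(s) > 0 && length(s$u) > 0) {
    singlet[cbind(match(s$state, FLEX_STATES), match(s$res, AA20))] <- s$u
  }
  doublet <- array(0, dim = c(3L, nk, 20L, 20L),
                   dimnames = list(FLEX_STATES, as.character(off$k),
                                   AA20, AA20))
  d <- doc$doublet
  if (length(d) > 0 && length(d$u) > 0) {
    doublet[cbind(match(d$state, FLEX_STATES), match(d$k, off$k),
                  match(d$res_i, AA20), match(d$res_j, AA20))] <- d$u
  }
  triplet <- array(0, dim = c(3L, np, 20L, 20L, 20L),
                   dimnames = list(FLEX_STATES, NULL, AA20, AA20, AA20))
  tr <- doc$triplet
  if (length(tr) > 0 && length(tr$u) > 0) {
    pair_id <- match(paste(tr$k1, tr$k2),
                     paste(off$pairs[, 1], off$pairs[, 2]))
    triplet[cbind(match(tr$state, FLEX_STATES), pair_id,
                  match(tr$res_i, AA20), match(tr$res_j, AA20),
                  match(tr$res_k, AA20))] <- tr$u
  }
  structure(list(
    window_half = as.integer(doc$window_half),
    offsets = off$k,
    offset_pairs = off$pairs,
    blend_weight = doc$blend_weight,
    prior = prior,
    singlet = singlet,
    doublet = doublet,
    triplet = triplet
  ), class = "flex_potentials")
}
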