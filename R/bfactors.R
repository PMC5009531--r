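#' Convert mean-squares displacement to a B-factor
#'
#' The crystallographic temperature factor of an atom with mean-squares
#' displacement \eqn{U^2} (Angstrom^2) is \eqn{B = 8 \pi^2 U^2}.
#'
#' @param msd Mean-squares displacement in Angstrom^2 (vectorized,
#'   non-negative).
#' @return B-factor(s) in Angstrom^2.
#' @examples
#' msd_to_bfactor(1)     # 8 * pi^2
#' msd_to_bfactor(0.25)
#' @export
msd_to_bfactor <- function(msd) {
  if (any(is.na(msd)) || any(msd < 0)) {
    abort("msd must be non-negative and non-missing")
  }
  8 * pi^2 * msd
}

#' Per-chain z-normalization of raw B-factors
#'
#' B-factors from different refinements sit on different scales, so each
#' chain is normalized independently: `b_norm = (raw - mu) / sigma` with
#' `mu` and `sigma` (population standard deviation, denominator `N`)
#' computed over that chain's residues that have a defined raw B-factor.
#' Residues with a missing raw value get a missing `b_norm`.
#'
#' @param chains Residue tibble with `chain_id` and `raw_bfactor` columns.
#' @param on_degenerate What to do with a chain whose defined B-factors are
#'   constant (`sigma == 0`) or number fewer than two: `"error"` (default)
#'   or `"drop"` the chain with a warning.
#' @return The input tibble with a `b_norm` column added; per-chain `mu`
#'   and `sigma` are available via [chain_bstats()].
#' @examples
#' df <- tibble::tibble(chain_id = "A", position = 1:3,
#'                      raw_bfactor = c(10, 20, 30))
#' normalize_bfactors(df)$b_norm
#' @export
normalize_bfactors <- function(chains, on_degenerate = c("error", "drop")) {
  .check_cols(chains, c("chain_id", "raw_bfactor"), "chains")
  on_degenerate <- match.arg(on_degenerate)
  stats <- chain_bstats(chains)
  bad <- stats$chain_id[stats$n_defined < 2L | stats$sigma == 0]
  if (length(bad) > 0L) {
    if (on_degenerate == "error") {
      abort(paste0(
        "degenerate chain(s) (constant or <2 defined B-factors): ",
        paste(bad, collapse = ", ")))
    }
    warn(paste0("dropping ", length(bad), " degenerate chain(s)"))
    chains <- dplyr::filter(chains, !.data$chain_id %in% bad)
    stats <- dplyr::filter(stats, !.data$chain_id %in% bad)
  }
  chains |>
    dplyr::left_join(dplyr::select(stats, dplyr::all_of(
      c("chain_id", "mu", "sigma"))), by = "chain_id") |>
    dplyr::mutate(b_norm = (.data$raw_bfactor - .data$mu) / .data$sigma) |>
    dplyr::select(-dplyr::all_of(c("mu", "sigma")))
}

#' @rdname normalize_bfactors
#' @return `chain_bstats()`: tibble with `chain_id`, `mu`, `sigma`
#'   (population), `n_defined`.
#' @export
chain_bstats <- function(chains) {
  .check_cols(chains, c("chain_id", "raw_bfactor"), "chains")
  chains |>
    dplyr::group_by(.data$chain_id) |>
    dplyr::summarise(
      n_defined = sum(is.finite(.data$raw_bfactor)),
      mu = mean(.data$raw_bfactor[is.finite(.data$raw_bfactor)]),
      sigma = {
        x <- .data$raw_bfactor[is.finite(.data$raw_bfactor)]
        if (length(x) == 0L) NA_real_ else sqrt(mean((x - mean(x))^2))
      },
      .groups = "drop"
    )
}

#' Flexibility state scheme
#'
#' Defines the discretization of normalized B-values into flexibility
#' states. The three-state scheme uses two thresholds: `b < t_low` is rigid
#' (R), `b > t_high` is flexible (F), anything else -- including exact
#' equality at either threshold -- is intermediate (I). The two-state
#' scheme uses one threshold: `b > t_two` is `"flexible"`, else `"rigid"`;
#' `t_two = 0.03` is the strict convention and `-0.3` the non-strict one.
#'
#' @param mode `"three_state"` (default) or `"two_state"`.
#' @param t_low,t_high Three-state thresholds (defaults -1.1 and 2.2).
#' @param t_two Two-state threshold (default 0.03, the strict convention).
#' @return An object of class `flex_scheme`.
#' @export
flex_scheme <- function(mode = c("three_state", "two_state"),
                        t_low = -1.1, t_high = 2.2, t_two = 0.03) {
  mode <- match.arg(mode)
  if (!is.numeric(t_low) || !is.numeric(t_high) || t_low >= t_high) {
    abort("flex_scheme requires numeric thresholds with t_low < t_high")
  }
  structure(list(mode = mode, t_low = t_low, t_high = t_high, t_two = t_two),
            class = "flex_scheme")
}

#' @export
print.flex_scheme <- function(x, ...) {
  if (x$mode == "three_state") {
    cat(sprintf("<flex_scheme> three-state: R < %g <= I <= %g < F\n",
                x$t_low, x$t_high))
  } else {
    cat(sprintf("<flex_scheme> two-state: flexible if b_norm > %g\n", x$t_two))
  }
  invisible(x)
}

#' Discretize normalized B-values into flexibility states
#'
#' @param b_norm Numeric vector of normalized B-values (`NA` allowed).
#' @param scheme A [flex_scheme()].
#' @return `flex_state()`: character vector of states (`"R"`, `"I"`, `"F"`
#'   or `"rigid"`/`"flexible"`), `NA` where `b_norm` is missing.
#' @examples
#' flex_state(c(-2, 0, 2.2, 3), flex_scheme())
#' @export
flex_state <- function(b_norm, scheme = flex_scheme()) {
  stopifnot(inherits(scheme, "flex_scheme"))
  if (scheme$mode == "three_state") {
    out <- rep(NA_character_, length(b_norm))
    ok <- !is.na(b_norm)
    out[ok] <- "I"
    out[ok & b_norm < scheme$t_low] <- "R"
    out[ok & b_norm > scheme$t_high] <- "F"
    out
  } else {
    dplyr::if_else(is.na(b_norm), NA_character_,
                   dplyr::if_else(b_norm > scheme$t_two,
                                  "flexible", "rigid"))
  }
}

#' @rdname flex_state
#' @param chains Residue tibble with a `b_norm` column.
#' @return `assign_flex_states()`: the input tibble with a `state` column.
#' @export
assign_flex_states <- function(chains, scheme = flex_scheme()) {
  .check_cols(chains, "b_norm", "chains")
  dplyr::mutate(chains, state = flex_state(.data$b_norm, scheme))
}

#' Apply the corpus filtering rules
#'
#' Chains shorter than `min_length` residues are removed (profile searches
#' are unreliable for very short sequences); residues with an undetermined
#' flexibility state (`NA` state: missing CA, missing B-factor, or
#' non-standard residue) are then eliminated, and chains that fall below
#' `min_length` after elimination are removed too.
#'
#' @param chains Labeled residue tibble with `chain_id` and `state`.
#' @param min_length Minimum surviving chain length (default 40).
#' @return The filtered tibble. Counts of removed chains/residues are
#'   attached as the `"flex_filter"` attribute (a one-row tibble with
#'   `chains_removed_short`, `residues_removed_undetermined`,
#'   `chains_removed_after`).
#' @export
filter_dataset <- function(chains, min_length = 40L) {
  .check_cols(chains, c("chain_id", "state"), "chains")
  len0 <- dplyr::count(chains, .data$chain_id, name = "len")
  short0 <- len0$chain_id[len0$len < min_length]
  step1 <- dplyr::filter(chains, !.data$chain_id %in% short0)
  n_undet <- sum(is.na(step1$state))
  step2 <- dplyr::filter(step1, !is.na(.data$state))
  len2 <- dplyr::count(step2, .data$chain_id, name = "len")
  short2 <- len2$chain_id[len2$len < min_length]
  out <- dplyr::filter(step2, !.data$chain_id %in% short2)
  attr(out, "flex_filter") <- tibble(
    chains_removed_short = length(short0),
    residues_removed_undetermined = n_undet,
    chains_removed_after = length(short2)
  )
  out
}

#' Label a raw corpus end to end
#'
#' Convenience pipeline: per-chain normalization, three-state assignment,
#' and corpus filtering in one call.
#'
#' @param chains Residue tibble with `chain_id`, `position`, `aa`,
#'   `raw_bfactor`.
#' @param scheme A [flex_scheme()].
#' @param min_length Passed to [filter_dataset()].
#' @return Filtered labeled tibble with `b_norm` and `state` columns.
#' @export
label_corpus <- function(chains, scheme = flex_scheme(), min_length = 40L) {
  chains |>
    normalize_bfactors(on_degenerate = "drop") |>
    assign_flex_states(scheme) |>
    filter_dataset(min_length = min_length)
}
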