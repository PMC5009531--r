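# Residue propensity classes used to couple sequence to secondary structure.
.helix_formers  <- c("A", "E", "L", "M", "Q", "K", "R", "H")
.strand_formers <- c("V", "I", "Y", "F", "W", "T", "C")
.coil_formers   <- c("G", "P", "N", "S", "D")

#' Synthetic corpus configuration
#'
#' Parameters of the generative model used for end-to-end testing. Chains
#' alternate coil and regular (helix/strand) secondary-structure segments;
#' solvent exposure is drawn per residue conditioned on segment type; the
#' raw Calpha B-factor of a residue is a group baseline (by SS x SA, coil
#' and exposed shifted upward) plus AR(1)-correlated Gaussian noise plus an
#' occasional lognormal spike that produces the right-skewed tail seen in
#' real normalized B-value distributions. Sequences are drawn with
#' SS-conditioned residue propensities, PSSM rows carry a log-odds boost on
#' the true residue, and "predicted" SS/SA probabilities are the true
#' one-hot assignment mixed with uniform simplex noise at a configurable
#' reliability, standing in for an external predictor.
#'
#' `effect_scale` scales every flexibility-related effect (group baseline
#' separation, spike-probability differences, sequence propensity bias);
#' at 0 the B-factor distribution is identical across SS/SA groups and no
#' feature carries information about the flexibility state.
#'
#' @param n_chains Number of chains (default 200).
#' @param length_range Chain length range, inclusive (default 40..120 so
#'   the corpus length filter passes).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @param p_helix Probability that a regular segment is a helix (0.6).
#' @param seg_len_coil,seg_len_helix,seg_len_strand Segment length
#'   distributions `c(min, geometric mean extra)`.
#' @param p_exposed Named probabilities of exposure given segment class,
#'   `c(coil = , regular = )`.
#' @param b_mu,b_sd Named baseline mean / within-group SD of the raw
#'   B-factor (Angstrom^2) for the four SS x SA groups `rb` (regular
#'   buried), `re` (regular exposed), `cb` (coil buried), `ce` (coil
#'   exposed).
#' @param p_spike Named per-group probability of a lognormal B-factor
#'   spike.
#' @param spike_meanlog,spike_sdlog Spike magnitude (lognormal
#'   parameters).
#' @param rho Neighbor AR(1) weight of the Gaussian noise component, in
#'   `[0, 1)`.
#' @param seq_ss_bias Multiplicative propensity boost of class-matched
#'   residues (1 = no coupling).
#' @param pssm_signal Mean log-odds boost of the true residue in its PSSM
#'   row.
#' @param pssm_noise_sd SD of the integer log-odds noise.
#' @param reliability Named mixing weights of truth vs uniform noise for
#'   the "predicted" SS and SA probabilities, `c(ss = , sa = )`.
#' @param effect_scale Global effect-size multiplier (see above).
#' @return A list of class `flex_sim_config`.
#' @export
simulate_config <- function(n_chains = 200L,
                            length_range = c(40L, 120L),
                            seed = 1L,
                            p_helix = 0.6,
                            seg_len_coil = c(2L, 3),
                            seg_len_helix = c(5L, 4),
                            seg_len_strand = c(3L, 3),
                            p_exposed = c(coil = 0.50, regular = 0.50),
                            b_mu = c(rb = 5, re = 20, cb = 21.5, ce = 23),
                            b_sd = c(rb = 1.2, re = 2.5, cb = 3, ce = 3.5),
                            p_spike = c(rb = 0, re = 0.01,
                                        cb = 0.06, ce = 0.55),
                            spike_meanlog = 2.8,
                            spike_sdlog = 0.3,
                            rho = 0.35,
                            seq_ss_bias = 3,
                            pssm_signal = 7,
                            pssm_noise_sd = 2,
                            reliability = c(ss = 0.85, sa = 0.85),
                            effect_scale = 1) {
  stopifnot(length(length_range) == 2L, length_range[1] >= 1L,
            length_range[1] <= length_range[2],
            rho >= 0, rho < 1,
            all(p_exposed >= 0 & p_exposed <= 1),
            all(p_spike >= 0 & p_spike <= 1),
            effect_scale >= 0)
  structure(as.list(environment()), class = "flex_sim_config")
}

# Effective group parameters after applying the global effect multiplier:
# at effect_scale = 0 every group collapses onto the residue-weighted
# average baseline and spike probability.
.effective_groups <- function(config) {
  w <- c(rb = 0.30, re = 0.30, cb = 0.20, ce = 0.20) # nominal group weights
  mu0 <- sum(w * config$b_mu[names(w)])
  ps0 <- sum(w * config$p_spike[names(w)])
  es <- config$effect_scale
  list(
    mu = mu0 + es * (config$b_mu[names(w)] - mu0),
    sd = config$b_sd[names(w)],
    p_spike = pmin(pmax(ps0 + es * (config$p_spike[names(w)] - ps0), 0), 1)
  )
}

.sample_segments <- function(L, config) {
  ss <- character(0)
  coil_turn <- TRUE
  while (length(ss) < L) {
    if (coil_turn) {
      n <- config$seg_len_coil[1] + stats::rgeom(1, 1 / (1 + config$seg_len_coil[2]))
      ss <- c(ss, rep("C", n))
    } else {
      if (runif(1) < config$p_helix) {
        n <- config$seg_len_helix[1] + stats::rgeom(1, 1 / (1 + config$seg_len_helix[2]))
        ss <- c(ss, rep("H", n))
      } else {
        n <- config$seg_len_strand[1] + stats::rgeom(1, 1 / (1 + config$seg_len_strand[2]))
        ss <- c(ss, rep("E", n))
      }
    }
    coil_turn <- !coil_turn
  }
  ss[seq_len(L)]
}

.sample_sequence <- function(ss, config) {
  bias <- 1 + config$effect_scale * (config$seq_ss_bias - 1)
  w_base <- setNames(rep(1, 20), AA20)
  pick <- function(boost_set) {
    w <- w_base
    w[boost_set] <- bias
    w / sum(w)
  }
  w_by_ss <- list(H = pick(.helix_formers), E = pick(.strand_formers),
                  C = pick(.coil_formers))
  vapply(ss, function(s) sample(AA20, 1L, prob = w_by_ss[[s]]),
         character(1), USE.NAMES = FALSE)
}

# mix one-hot truth with a uniform Dirichlet draw at given reliability
.noisy_probs <- function(onehot, reliability) {
  noise <- matrix(stats::rexp(length(onehot)), nrow = nrow(onehot))
  noise <- noise / rowSums(noise)
  reliability * onehot + (1 - reliability) * noise
}

#' Generate a synthetic flexibility corpus
#'
#' Draws chains, secondary structure, solvent accessibility, raw Calpha
#' B-factors, sequences, PSSM profiles and predictor-style SS/SA
#' probabilities from the generative model described in
#' [simulate_config()]. Deterministic given the config seed; raw
#' B-factors are rounded to two decimals (the PDB fixed-column precision)
#' so that file round-trips are exact.
#'
#' @param config A [simulate_config()].
#' @return A list of class `flex_corpus` with `residues` (tibble:
#'   `chain_id`, `position`, `aa`, `ss`, `sa`, `raw_bfactor`, `ss_H`,
#'   `ss_E`, `ss_C`, `sa_E`, `sa_B`) and `pssm` (tibble: `chain_id`,
#'   `position`, `aa`, 20 log-odds columns in PSI-BLAST order).
#' @export
generate_dataset <- function(config = simulate_config()) {
  stopifnot(inherits(config, "flex_sim_config"))
  grp <- .effective_groups(config)
  .with_seed(config$seed, {
    ids <- sprintf("S%03d", seq_len(config$n_chains))
    res_list <- vector("list", config$n_chains)
    pssm_list <- vector("list", config$n_chains)
    for (ci in seq_along(ids)) {
      L <- config$length_range[1] +
        sample.int(config$length_range[2] - config$length_range[1] + 1L,
                   1L) - 1L
      ss <- .sample_segments(L, config)
      p_exp <- ifelse(ss == "C", config$p_exposed["coil"],
                      config$p_exposed["regular"])
      sa <- ifelse(runif(L) < p_exp, "E", "B")
      g <- paste0(ifelse(ss == "C", "c", "r"), ifelse(sa == "E", "e", "b"))
      # AR(1) Gaussian component plus occasional lognormal spike
      e <- rnorm(L)
      noise <- numeric(L)
      noise[1] <- e[1]
      if (L > 1) {
        for (i in 2:L) {
          noise[i] <- config$rho * noise[i - 1] +
            sqrt(1 - config$rho^2) * e[i]
        }
      }
      spike <- (runif(L) < unname(grp$p_spike[g])) *
        rlnorm(L, config$spike_meanlog, config$spike_sdlog)
      b <- unname(pmax(grp$mu[g] + grp$sd[g] * noise + spike, 1))
      aa <- .sample_sequence(ss, config)

      ss_onehot <- cbind(H = as.numeric(ss == "H"),
                         E = as.numeric(ss == "E"),
                         C = as.numeric(ss == "C"))
      sa_onehot <- cbind(E = as.numeric(sa == "E"),
                         B = as.numeric(sa == "B"))
      ssp <- .noisy_probs(ss_onehot, config$reliability["ss"])
      sap <- .noisy_probs(sa_onehot, config$reliability["sa"])

      res_list[[ci]] <- tibble(
        chain_id = ids[ci], position = seq_len(L), aa = aa,
        ss = ss, sa = sa, raw_bfactor = round(b, 2),
        ss_H = ssp[, 1], ss_E = ssp[, 2], ss_C = ssp[, 3],
        sa_E = sap[, 1], sa_B = sap[, 2])

      m <- matrix(round(rnorm(L * 20, 0, config$pssm_noise_sd)),
                  nrow = L, ncol = 20,
                  dimnames = list(NULL, PSSM_AA_ORDER))
      m[cbind(seq_len(L), match(aa, PSSM_AA_ORDER))] <-
        m[cbind(seq_len(L), match(aa, PSSM_AA_ORDER))] + config$pssm_signal
      pssm_list[[ci]] <- dplyr::bind_cols(
        tibble(chain_id = ids[ci], position = seq_len(L), aa = aa),
        tibble::as_tibble(m))
    }
    structure(list(residues = dplyr::bind_rows(res_list),
                   pssm = dplyr::bind_rows(pssm_list),
                   config = config),
              class = "flex_corpus")
  })
}

#' @export
print.flex_corpus <- function(x, ...) {
  cat("<flex_corpus>", length(unique(x$residues$chain_id)), "chains,",
      nrow(x$residues), "residues\n")
  invisible(x)
}

#' Write a synthetic corpus to files in every supported format
#'
#' Emits CA-only PDB files (one per chain, under `pdb/`), a FASTA of all
#' sequences, ASCII PSSM profiles (under `pssm/`), predicted-probability
#' SS and SA TSVs, a true-assignment TSV, and a flexibility label TSV
#' computed with the default three-state scheme. All files are
#' re-readable by the package's readers with exact value round-trip.
#'
#' @param corpus A `flex_corpus` from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @param scheme Scheme used for the label TSV.
#' @param min_length Length filter applied before labeling.
#' @return Invisibly, a named list of the paths written.
#' @export
write_corpus_files <- function(corpus, dir, scheme = flex_scheme(),
                               min_length = 40L) {
  stopifnot(inherits(corpus, "flex_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- corpus$residues

  write_pdb_ca(res, file.path(dir, "pdb"))

  seqs <- res |>
    dplyr::group_by(.data$chain_id) |>
    dplyr::summarise(sequence = paste(.data$aa, collapse = ""),
                     .groups = "drop")
  write_fasta(seqs, file.path(dir, "sequences.fasta"))

  pssm_dir <- file.path(dir, "pssm")
  dir.create(pssm_dir, showWarnings = FALSE)
  for (id in unique(corpus$pssm$chain_id)) {
    prof <- dplyr::filter(corpus$pssm, .data$chain_id == id)
    write_pssm(prof, file.path(pssm_dir, paste0(id, ".pssm")))
  }

  write_assignments(
    dplyr::select(res, dplyr::all_of(
      c("chain_id", "position", "aa", "ss_H", "ss_E", "ss_C"))),
    file.path(dir, "ss.tsv"))
  write_assignments(
    dplyr::select(res, dplyr::all_of(
      c("chain_id", "position", "aa", "sa_E", "sa_B"))),
    file.path(dir, "sa.tsv"))
  write_assignments(
    dplyr::select(res, dplyr::all_of(
      c("chain_id", "position", "aa", "ss", "sa"))),
    file.path(dir, "assignments.tsv"))

  labeled <- label_corpus(res, scheme = scheme, min_length = min_length)
  write_labels(
    dplyr::select(labeled, dplyr::all_of(
      c("chain_id", "position", "aa", "b_norm", "state"))),
    file.path(dir, "labels.tsv"))

  invisible(list(
    pdb = file.path(dir, "pdb"),
    fasta = file.path(dir, "sequences.fasta"),
    pssm = pssm_dir,
    ss = file.path(dir, "ss.tsv"),
    sa = file.path(dir, "sa.tsv"),
    assignments = file.path(dir, "assignments.tsv"),
    labels = file.path(dir, "labels.tsv")
  ))
}

#' Conditional-mode oracle rate of the generative model
#'
#' Estimates how well the flexibility state can be predicted from the true
#' secondary-structure and exposure assignment alone, by tabulating the
#' most likely state per (SS, SA) group on one generated sample and
#' scoring it on an independent one. Because the generative model drives
#' the B-factor baseline through (SS, SA), this conditional mode is an
#' achievable reference rate for any classifier whose inputs include the
#' structural features; residual AR noise and spikes bound it away from 1.
#'
#' @param config A [simulate_config()].
#' @param n_chains Chains per sample (default 300).
#' @param seed Seed for the two samples (derived internally from it).
#' @param scheme Labeling scheme.
#' @return A list: `rate` (the held-out accuracy), `rule` (tibble mapping
#'   (ss, sa) to the modal state), `class_freq` (observed state
#'   frequencies on the held-out sample).
#' @export
oracle_bayes_rate <- function(config = simulate_config(), n_chains = 300L,
                              seed = 42L, scheme = flex_scheme()) {
  cfg1 <- config; cfg1$n_chains <- as.integer(n_chains); cfg1$seed <- seed
  cfg2 <- cfg1; cfg2$seed <- seed + 1000L
  lab <- function(cfg) {
    generate_dataset(cfg)$residues |>
      label_corpus(scheme = scheme)
  }
  train <- lab(cfg1)
  test <- lab(cfg2)
  rule <- train |>
    dplyr::count(.data$ss, .data$sa, .data$state) |>
    dplyr::group_by(.data$ss, .data$sa) |>
    dplyr::slice_max(.data$n, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(c("ss", "sa", "state")))
  scored <- test |>
    dplyr::left_join(rule, by = c("ss", "sa"), suffix = c("", "_pred"))
  list(
    rate = mean(scored$state == scored$state_pred),
    rule = rule,
    class_freq = prop.table(table(test$state)),
    n = nrow(test)
  )
}

#' Generate a labeled corpus with planted context preferences
#'
#' A direct residue/state sampler used to validate potential recovery:
#' states are drawn per residue from a base distribution whose odds can be
#' tilted by residue type (singlet plant) and/or by a specific flanking
#' residue pair at offsets (k1, k2) around the centre (triplet plant).
#' Amino acids are drawn uniformly and independently, so any structure in
#' the derived potentials comes from the planted tilts alone.
#'
#' @param n_chains,chain_length,seed Corpus shape and seed.
#' @param base_probs Base state distribution (default uniform over R, I,
#'   F).
#' @param singlet_tilt Optional named list: residue letter -> length-3
#'   multiplicative odds tilt over (R, I, F).
#' @param triplet_plant Optional list with `k1`, `k2`, `res_j`, `res_k`,
#'   `tilt` (length-3 odds multiplier applied when the residues at offsets
#'   k1 and k2 match).
#' @param alphabet Residue letters to draw from (default all 20; a reduced
#'   alphabet concentrates observations on fewer context cells).
#' @return A labeled residue tibble (`chain_id`, `position`, `aa`,
#'   `state`).
#' @export
simulate_labeled_corpus <- function(n_chains = 50L, chain_length = 100L,
                                    seed = 1L,
                                    base_probs = c(R = 1, I = 1, F = 1) / 3,
                                    singlet_tilt = NULL,
                                    triplet_plant = NULL,
                                    alphabet = AA20) {
  stopifnot(all(alphabet %in% AA20))
  .with_seed(seed, {
    out <- vector("list", n_chains)
    for (ci in seq_len(n_chains)) {
      aa <- sample(alphabet, chain_length, replace = TRUE)
      p <- matrix(rep(base_probs, each = chain_length),
                  nrow = chain_length)
      if (!is.null(singlet_tilt)) {
        for (res in names(singlet_tilt)) {
          hit <- aa == res
          p[hit, ] <- sweep(p[hit, , drop = FALSE], 2,
                            singlet_tilt[[res]], "*")
        }
      }
      if (!is.null(triplet_plant)) {
        tp <- triplet_plant
        i <- seq_len(chain_length)
        i <- i[i + tp$k1 >= 1 & i + tp$k2 <= chain_length]
        hit <- i[aa[i + tp$k1] == tp$res_j & aa[i + tp$k2] == tp$res_k]
        p[hit, ] <- sweep(p[hit, , drop = FALSE], 2, tp$tilt, "*")
      }
      p <- p / rowSums(p)
      u <- runif(chain_length)
      cp <- t(apply(p, 1, cumsum))
      state <- FLEX_STATES[1L + (u > cp[, 1]) + (u > cp[, 2])]
      out[[ci]] <- tibble(chain_id = sprintf("P%03d", ci),
                          position = seq_len(chain_length),
                          aa = aa, state = state)
    }
    dplyr::bind_rows(out)
  })
}
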