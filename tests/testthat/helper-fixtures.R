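# Shared fixtures and independent oracles for the test suite.

AA20_T <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
STATES_T <- c("R", "I", "F")

# Build one fixed-column PDB ATOM record (wwPDB layout).
make_pdb_line <- function(serial, resname3, chain, pos, b,
                          occ = 1.0, altloc = " ", atom = " CA ") {
  paste0("ATOM  ", formatC(serial, width = 5), " ", atom, altloc,
         formatC(resname3, width = 3), " ", chain,
         formatC(pos, width = 4), "    ",
         sprintf("%8.3f%8.3f%8.3f%6.2f%6.2f", 1, 2, 3, occ, b))
}

# Random small labeled corpus (standard residues only unless with_x).
random_small_corpus <- function(n_chains, max_len, seed, with_x = FALSE) {
  set.seed(seed)
  alphabet <- if (with_x) c(AA20_T, "X") else AA20_T
  dplyr::bind_rows(lapply(seq_len(n_chains), function(ci) {
    L <- sample(1:max_len, 1)
    tibble::tibble(
      chain_id = sprintf("T%02d", ci),
      position = seq_len(L),
      aa = sample(alphabet, L, replace = TRUE),
      state = sample(STATES_T, L, replace = TRUE))
  }))
}

# Independent brute-force context counter: plain loops and a named-list
# accumulator, no shared code with count_contexts().
brute_force_counts <- function(corpus, window_half = 3) {
  ks <- setdiff(-window_half:window_half, 0)
  env <- new.env()
  bump <- function(key) {
    env[[key]] <- (if (is.null(env[[key]])) 0 else env[[key]]) + 1
  }
  for (id in unique(corpus$chain_id)) {
    ch <- corpus[corpus$chain_id == id, ]
    L <- nrow(ch)
    for (i in seq_len(L)) {
      if (!ch$aa[i] %in% AA20_T) next
      bump(paste("S", ch$state[i], ch$aa[i]))
      for (k in ks) {
        j <- i + k
        if (j < 1 || j > L) next
        if (!ch$aa[j] %in% AA20_T) next
        bump(paste("D", ch$state[i], k, ch$aa[i], ch$aa[j]))
      }
      for (a in seq_along(ks)) {
        for (b in seq_along(ks)) {
          if (b <= a) next
          j1 <- i + ks[a]; j2 <- i + ks[b]
          if (j1 < 1 || j2 < 1 || j1 > L || j2 > L) next
          if (!ch$aa[j1] %in% AA20_T || !ch$aa[j2] %in% AA20_T) next
          bump(paste("T", ch$state[i], ks[a], ks[b],
                     ch$aa[i], ch$aa[j1], ch$aa[j2]))
        }
      }
    }
  }
  as.list(env)
}

# Compare a flex_counts object cell-by-cell against the brute-force map.
expect_counts_match <- function(counts, brute) {
  ks <- counts$offsets
  got <- list()
  idx <- which(counts$singlet > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    got[[paste("S", STATES_T[idx[r, 1]], AA20_T[idx[r, 2]])]] <-
      counts$singlet[idx[r, 1], idx[r, 2]]
  }
  idx <- which(counts$doublet > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    got[[paste("D", STATES_T[idx[r, 1]], ks[idx[r, 2]],
               AA20_T[idx[r, 3]], AA20_T[idx[r, 4]])]] <-
      counts$doublet[idx[r, 1], idx[r, 2], idx[r, 3], idx[r, 4]]
  }
  idx <- which(counts$triplet > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    pr <- counts$offset_pairs[idx[r, 2], ]
    got[[paste("T", STATES_T[idx[r, 1]], pr[1], pr[2],
               AA20_T[idx[r, 3]], AA20_T[idx[r, 4]], AA20_T[idx[r, 5]])]] <-
      counts$triplet[idx[r, 1], idx[r, 2], idx[r, 3], idx[r, 4], idx[r, 5]]
  }
  expect_setequal(names(got), names(brute))
  for (key in names(brute)) {
    expect_equal(unname(got[[key]]), unname(brute[[key]]),
                 info = paste("cell", key))
  }
}

# A potential table with constant values a / b / c in every singlet /
# doublet / triplet cell (window half-width 3), uniform prior.
uniform_potentials <- function(a = 0, b = 0, c = 0) {
  ks <- setdiff(-3:3, 0)
  pairs <- t(utils::combn(ks, 2))
  colnames(pairs) <- c("k1", "k2")
  structure(list(
    window_half = 3L, offsets = ks, offset_pairs = pairs,
    blend_weight = 10, prior = stats::setNames(rep(1 / 3, 3), STATES_T),
    singlet = array(a, c(3, 20), dimnames = list(STATES_T, AA20_T)),
    doublet = array(b, c(3, 6, 20, 20),
                    dimnames = list(STATES_T, as.character(ks),
                                    AA20_T, AA20_T)),
    triplet = array(c, c(3, 15, 20, 20, 20),
                    dimnames = list(STATES_T, NULL, AA20_T, AA20_T, AA20_T))
  ), class = "flex_potentials")
}

# Small multivariate-blob classification set with well-separated classes.
make_blobs <- function(n_per_class, n_in = 12, sep = 4, seed = 1,
                       states = STATES_T) {
  set.seed(seed)
  k <- length(states)
  centers <- matrix(0, k, n_in)
  for (i in seq_len(k)) centers[i, ((i - 1) %% n_in) + 1] <- sep
  x <- do.call(rbind, lapply(seq_len(k), function(i) {
    matrix(stats::rnorm(n_per_class * n_in), n_per_class, n_in) +
      matrix(centers[i, ], n_per_class, n_in, byrow = TRUE)
  }))
  y <- rep(states, each = n_per_class)
  ord <- sample(nrow(x))
  list(x = x[ord, , drop = FALSE], y = y[ord])
}
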