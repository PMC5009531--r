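test_that("context counts on a 3-residue chain match hand enumeration", {
  corpus <- tibble::tibble(chain_id = "A", position = 1:3,
                           aa = c("A", "C", "D"),
                           state = c("R", "I", "F"))
  cc <- count_contexts(corpus)
  expect_equal(cc$grand_total, 3)
  expect_equal(cc$singlet["R", "A"], 1)
  expect_equal(cc$singlet["I", "C"], 1)
  expect_equal(cc$singlet["F", "D"], 1)
  expect_equal(sum(cc$singlet), 3)
  k <- as.character(cc$offsets)
  expect_equal(cc$doublet["I", which(cc$offsets == -1), "C", "A"], 1)
  expect_equal(cc$doublet["I", which(cc$offsets == 1), "C", "D"], 1)
  pid <- function(k1, k2) {
    which(cc$offset_pairs[, 1] == k1 & cc$offset_pairs[, 2] == k2)
  }
  # all three in-range triplet contexts of the 3-residue chain
  expect_equal(cc$triplet["I", pid(-1, 1), "C", "A", "D"], 1)
  expect_equal(cc$triplet["R", pid(1, 2), "A", "C", "D"], 1)
  expect_equal(cc$triplet["F", pid(-2, -1), "D", "A", "C"], 1)
  expect_equal(sum(cc$triplet), 3)
})

test_that("counting matches the brute-force oracle on random small corpora", {
  for (seed in 1:4) {
    corpus <- random_small_corpus(n_chains = sample(1:5, 1), max_len = 10,
                                  seed = 100 + seed, with_x = seed %% 2 == 0)
    cc <- count_contexts(corpus)
    expect_counts_match(cc, brute_force_counts(corpus))
  }
})

test_that("empty and single-residue corpora count correctly", {
  empty <- tibble::tibble(chain_id = character(), aa = character(),
                          state = character())
  cc <- count_contexts(empty)
  expect_equal(cc$grand_total, 0)
  expect_error(derive_potentials(cc), "empty")

  one <- tibble::tibble(chain_id = "A", position = 1L, aa = "W",
                        state = "I")
  cc1 <- count_contexts(one)
  expect_equal(sum(cc1$singlet), 1)
  expect_equal(sum(cc1$doublet), 0)
  expect_equal(sum(cc1$triplet), 0)
  undef <- tibble::tibble(chain_id = "A", position = 1L, aa = "W",
                          state = NA_character_)
  expect_error(count_contexts(undef), "filter")
})

test_that("mean-force potentials reproduce hand-computed log-ratios", {
  # singlet cell A observed (R, I, F) = (8, 1, 1); padding chains of C and D
  # balance the totals so that the state prior is exactly uniform
  corpus <- dplyr::bind_rows(
    tibble::tibble(chain_id = sprintf("a%02d", 1:10), position = 1L,
                   aa = "A", state = c(rep("R", 8), "I", "F")),
    tibble::tibble(chain_id = sprintf("c%02d", 1:10), position = 1L,
                   aa = "C", state = c(rep("I", 9), "R")),
    tibble::tibble(chain_id = sprintf("d%02d", 1:10), position = 1L,
                   aa = "D", state = c(rep("F", 9), "R")))
  cc <- count_contexts(corpus)
  expect_equal(unname(cc$state_totals), c(10, 10, 10))

  pot0 <- derive_potentials(cc, blend_weight = 0)
  expect_equal(pot0$singlet["R", "A"], -log(0.8 / (1 / 3)),
               tolerance = 1e-12)                       # -0.8755
  pot3 <- derive_potentials(cc, blend_weight = 3)
  expect_equal(pot3$singlet["R", "A"], -log((8 + 1) / (10 + 3) / (1 / 3)),
               tolerance = 1e-12)                       # -0.7309
})

test_that("a corpus with uniform context-conditional frequencies gives U = 0", {
  corpus <- dplyr::bind_rows(lapply(seq_along(STATES_T), function(i) {
    tibble::tibble(chain_id = paste0("u", i), position = 1:3, aa = "A",
                   state = STATES_T[i])
  }))
  pot <- derive_potentials(count_contexts(corpus), blend_weight = 10)
  expect_equal(max(abs(pot$singlet)), 0)
  expect_equal(max(abs(pot$doublet)), 0)
  expect_equal(max(abs(pot$triplet)), 0)
})

test_that("never-observed cells have zero potential under smoothing", {
  corpus <- simulate_labeled_corpus(n_chains = 3, chain_length = 10,
                                    seed = 7,
                                    alphabet = c("A", "C", "D", "E"))
  pot <- derive_potentials(count_contexts(corpus), blend_weight = 10)
  unseen <- setdiff(AA20_T, corpus$aa)  # e.g. W never occurs
  expect_equal(max(abs(pot$singlet[, unseen])), 0)
  expect_equal(max(abs(pot$triplet[, , unseen, , ])), 0)
})

test_that("a missing state in the corpus is an error", {
  corpus <- tibble::tibble(chain_id = "A", position = 1:50,
                           aa = rep("A", 50), state = rep("I", 50))
  expect_error(derive_potentials(count_contexts(corpus)), "never observed")
})

test_that("enriching a state in a context strictly decreases its potential", {
  # two corpora with identical state totals (same prior); only the A cell
  # is more R-enriched in the second
  mk <- function(a_counts, b_counts) {
    dplyr::bind_rows(
      tibble::tibble(chain_id = sprintf("a%02d", seq_len(sum(a_counts))),
                     position = 1L, aa = "A",
                     state = rep(STATES_T, a_counts)),
      tibble::tibble(chain_id = sprintf("b%02d", seq_len(sum(b_counts))),
                     position = 1L, aa = "G",
                     state = rep(STATES_T, b_counts)))
  }
  c1 <- count_contexts(mk(c(2, 2, 2), c(6, 2, 2)))
  c2 <- count_contexts(mk(c(6, 2, 2), c(2, 2, 2)))
  expect_equal(c1$state_totals, c2$state_totals)
  for (w in c(0, 5, 20)) {
    p1 <- derive_potentials(c1, w)
    p2 <- derive_potentials(c2, w)
    expect_lt(p2$singlet["R", "A"], p1$singlet["R", "A"])
  }
})

test_that("blend weight interpolates between raw log-ratio and zero", {
  corpus <- random_small_corpus(5, 10, seed = 11)
  cc <- count_contexts(corpus)
  p_raw <- derive_potentials(cc, blend_weight = 1e-9)
  p_mid <- derive_potentials(cc, blend_weight = 10)
  p_inf <- derive_potentials(cc, blend_weight = 1e9)
  expect_lt(max(abs(p_inf$singlet)), 1e-6)
  expect_lt(max(abs(p_inf$triplet)), 1e-6)
  m <- colSums(matrix(cc$singlet, nrow = 3))
  obs <- which(cc$singlet > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(obs))) {
    s <- obs[r, 1]; a <- obs[r, 2]
    raw <- -log((cc$singlet[s, a] / m[a]) / (cc$state_totals[s] / cc$grand_total))
    expect_equal(unname(p_raw$singlet[s, a]), unname(raw), tolerance = 1e-6)
    # smoothing pulls toward zero
    expect_lte(abs(p_mid$singlet[s, a]), abs(raw) + 1e-9)
  }
})

test_that("combined potential sums the offset-enumerated terms", {
  pot <- uniform_potentials(a = 0.5, b = 0.25, c = -0.1)
  seqs <- paste(rep("A", 20), collapse = "")
  # interior residue: 1 singlet + 6 doublets + 15 triplets
  expect_equal(combined_pseudo_potential(pot, seqs, 10, "R"),
               0.5 + 6 * 0.25 + 15 * (-0.1), tolerance = 1e-12)
  # position 1: only positive offsets -> 1 + 3 + 3 terms
  expect_equal(combined_pseudo_potential(pot, seqs, 1, "I"),
               0.5 + 3 * 0.25 + 3 * (-0.1), tolerance = 1e-12)
  # zero table -> zero everywhere
  zero <- uniform_potentials()
  expect_equal(combined_pseudo_potential(zero, seqs, 5, "F"), 0)
  expect_error(combined_pseudo_potential(pot, seqs, 21, "R"), "range")
})

test_that("SCRS scores are a softmax of negated potentials on the 3-simplex", {
  zero <- uniform_potentials()
  sc <- scrs_scores(zero, "ACDEFG")
  expect_true(all(abs(rowSums(as.matrix(sc[, -1])) - 1) < 1e-9))
  expect_true(all(as.matrix(sc[, -1]) == 1 / 3))

  # U = (0, ln 2, ln 2) -> (0.5, 0.25, 0.25)
  pot <- uniform_potentials()
  pot$singlet["I", "A"] <- log(2)
  pot$singlet["F", "A"] <- log(2)
  sc1 <- scrs_scores(pot, "A", i = 1)
  expect_equal(c(sc1$scrs_R, sc1$scrs_I, sc1$scrs_F), c(0.5, 0.25, 0.25),
               tolerance = 1e-12)

  corpus <- random_small_corpus(4, 10, seed = 13)
  p <- derive_potentials(count_contexts(corpus), 10)
  sc2 <- scrs_scores(p, paste(corpus$aa[corpus$chain_id == "T01"],
                              collapse = ""))
  m <- as.matrix(sc2[, -1])
  expect_true(all(m > 0))
  expect_true(all(abs(rowSums(m) - 1) < 1e-9))
})

test_that("planted singlet preferences are recovered in sign", {
  tilt <- list(A = c(4, 1, 0.25), W = c(0.25, 1, 4), M = c(1, 4, 1))
  corpus <- simulate_labeled_corpus(n_chains = 60, chain_length = 100,
                                    seed = 15, singlet_tilt = tilt)
  cc <- count_contexts(corpus)
  expect_true(all(rowSums(cc$singlet)[STATES_T] > 0))
  # every tilted residue type has well over 100 observations
  expect_true(all(colSums(cc$singlet)[names(tilt)] >= 100))
  pot <- derive_potentials(cc, 10)
  expect_lt(pot$singlet["R", "A"], 0)  # favoured -> negative energy
  expect_gt(pot$singlet["F", "A"], 0)
  expect_gt(pot$singlet["R", "W"], 0)
  expect_lt(pot$singlet["F", "W"], 0)
  expect_lt(pot$singlet["I", "M"], 0)
})

test_that("potential tables round-trip through the JSON serialization", {
  corpus <- random_small_corpus(4, 10, seed = 17)
  pot <- derive_potentials(count_contexts(corpus), 10)
  p <- withr::local_tempfile(fileext = ".json")
  write_potentials(pot, p)
  back <- read_potentials(p)
  expect_equal(back$prior, pot$prior)
  expect_equal(back$blend_weight, pot$blend_weight)
  expect_equal(back$singlet, pot$singlet)
  expect_equal(back$doublet, pot$doublet)
  expect_equal(back$triplet, pot$triplet)
})
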