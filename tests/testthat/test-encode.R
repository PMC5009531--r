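test_that("logistic PSSM scaling hits the standard values and symmetry", {
  expect_equal(scale_pssm(0), 0.5)
  expect_equal(scale_pssm(1), 1 / (1 + exp(-1)), tolerance = 1e-12) # 0.7311
  v <- c(-7, -2, 0, 3, 11)
  expect_equal(scale_pssm(-v), 1 - scale_pssm(v), tolerance = 1e-12)
  expect_true(all(scale_pssm(c(-30, 30)) > 0 & scale_pssm(c(-30, 30)) < 1))
})

test_that("residue feature vectors have the 34-slot layout", {
  pad <- residue_features(is_padding = TRUE)
  expect_length(pad, 34)
  expect_equal(unname(pad), c(rep(0, 33), 1))

  rf <- residue_features("A", pssm_row = rep(0, 20), scrs = rep(1 / 3, 3),
                         ss_probs = c(1, 0, 0), sa_probs = c(0.5, 0.5))
  expect_length(rf, 34)
  expect_equal(unname(rf[34]), 0)
  aap <- aa_property_table()
  expect_equal(unname(rf[29:33]),
               as.numeric(aap[aap$aa == "A", -1]))
  expect_error(residue_features("A", rep(0, 19), rep(1 / 3, 3),
                                c(1, 0, 0), c(1, 0)), "20")
})

test_that("amino-acid properties are min-max normalized over the 20 residues", {
  aap <- aa_property_table()
  m <- as.matrix(aap[, -1])
  expect_true(all(m >= 0 & m <= 1))
  for (j in seq_len(ncol(m))) {
    # min and max are attained (polarizability shares its minimum between
    # two residues in the source property set)
    expect_gte(sum(m[, j] == 0), 1)
    expect_equal(sum(m[, j] == 1), 1)
  }
})

test_that("window encodings have 510 values with terminal padding", {
  L <- 30
  f <- matrix(stats::runif(L * 34), L, 34)
  f[, 34] <- 0
  w <- encode_window(f, 10)
  expect_length(w, 510)

  w1 <- encode_window(f, 1)
  # first 7 slots padded: terminal flag 1, all other values 0
  for (slot in 1:7) {
    block <- w1[((slot - 1) * 34 + 1):(slot * 34)]
    expect_equal(unname(block), c(rep(0, 33), 1))
  }
  expect_equal(unname(w1[7 * 34 + seq_len(34)]), unname(f[1, ]))

  single <- encode_window(f[1, , drop = FALSE], 1)
  expect_equal(sum(single[seq(34, 510, by = 34)]), 14) # 14 padded slots
  expect_error(encode_window(f, 31), "range")
})

test_that("corpus encodings are translation-consistent and bounded", {
  corpus <- generate_dataset(simulate_config(n_chains = 8, seed = 19))
  lab <- label_corpus(corpus$residues)
  pot <- derive_potentials(count_contexts(lab), 10)
  enc <- encode_corpus(lab, corpus$pssm, pot)
  expect_equal(ncol(enc$x), 510)
  expect_equal(nrow(enc$x), nrow(lab))
  expect_true(all(enc$x >= 0 & enc$x <= 1))
  expect_false(anyNA(enc$label))

  # overlapping-window identity within one chain: slot j at centre i equals
  # slot j-1 at centre i+1
  id <- enc$meta$chain_id[1]
  rows <- which(enc$meta$chain_id == id)
  for (i in head(rows, 20)) {
    for (slot in 2:15) {
      expect_equal(
        unname(enc$x[i, ((slot - 1) * 34 + 1):(slot * 34)]),
        unname(enc$x[i + 1, ((slot - 2) * 34 + 1):((slot - 1) * 34)]))
    }
  }
})

test_that("feature-group ablation zeroes exactly the excluded slots", {
  corpus <- generate_dataset(simulate_config(n_chains = 7, seed = 23))
  lab <- label_corpus(corpus$residues)
  pot <- derive_potentials(count_contexts(lab), 10)
  enc <- encode_corpus(lab, corpus$pssm, pot, features = "pssm")
  # scrs/ss/sa/aap blocks are zero in every window slot
  zero_cols <- as.vector(vapply(0:14, function(s) s * 34 + 21:33,
                                numeric(13)))
  expect_equal(max(abs(enc$x[, zero_cols])), 0)
  expect_gt(max(enc$x[, as.vector(vapply(0:14, function(s) s * 34 + 1:20,
                                         numeric(20)))]), 0)
})

test_that("encodings survive a file round-trip", {
  corpus <- generate_dataset(simulate_config(n_chains = 7,
                                             length_range = c(40L, 45L),
                                             seed = 29))
  lab <- label_corpus(corpus$residues)
  pot <- derive_potentials(count_contexts(lab), 10)
  enc <- encode_corpus(lab, corpus$pssm, pot)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_encoding(enc, p)
  back <- read_encoding(p)
  expect_equal(back$label, enc$label)
  expect_equal(unname(back$x), unname(enc$x), tolerance = 1e-12)
  expect_equal(as.data.frame(back$meta), as.data.frame(enc$meta))
})
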