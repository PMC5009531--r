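test_that("generation is deterministic given the seed, files included", {
  cfg <- simulate_config(n_chains = 5, seed = 101)
  c1 <- generate_dataset(cfg)
  c2 <- generate_dataset(cfg)
  expect_identical(c1$residues, c2$residues)
  expect_identical(c1$pssm, c2$pssm)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_corpus_files(c1, d1)
  write_corpus_files(c2, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  c3 <- generate_dataset(simulate_config(n_chains = 5, seed = 102))
  expect_false(identical(c1$residues$raw_bfactor, c3$residues$raw_bfactor))
})

test_that("the synthetic corpus echoes the empirical B-factor structure", {
  corpus <- generate_dataset(simulate_config(n_chains = 100, seed = 103))
  res <- corpus$residues
  expect_gt(nrow(res), 5000)
  # coil residues run hotter than helix/strand, exposed hotter than buried
  expect_gt(mean(res$raw_bfactor[res$ss == "C"]),
            mean(res$raw_bfactor[res$ss %in% c("H", "E")]))
  expect_gt(mean(res$raw_bfactor[res$sa == "E"]),
            mean(res$raw_bfactor[res$sa == "B"]))
  # right-skewed normalized distribution, most residues intermediate
  lab <- label_corpus(res)
  b <- lab$b_norm
  skew <- mean((b - mean(b))^3) / sd(b)^3
  expect_gt(skew, 0)
  tab <- prop.table(table(factor(lab$state, STATES_T)))
  expect_gt(tab["I"], tab["R"])
  expect_gt(tab["I"], tab["F"])
  expect_gt(tab["R"], 0)
  expect_gt(tab["F"], 0)
})

test_that("predicted SS/SA probabilities are simplex points centred on truth", {
  corpus <- generate_dataset(simulate_config(n_chains = 10, seed = 104))
  res <- corpus$residues
  expect_true(all(abs(res$ss_H + res$ss_E + res$ss_C - 1) < 1e-9))
  expect_true(all(abs(res$sa_E + res$sa_B - 1) < 1e-9))
  # the argmax of the noisy probabilities usually recovers the truth
  ss_hat <- c("H", "E", "C")[max.col(as.matrix(res[, c("ss_H", "ss_E",
                                                       "ss_C")]))]
  expect_gt(mean(ss_hat == res$ss), 0.9)
})

test_that("fixture files round-trip through every package reader", {
  cfg <- simulate_config(n_chains = 8, length_range = c(40L, 60L),
                         seed = 105)
  corpus <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  paths <- write_corpus_files(corpus, dir)

  back_pdb <- read_pdb_dir(paths$pdb)
  orig <- corpus$residues[order(corpus$residues$chain_id,
                                corpus$residues$position), ]
  expect_equal(back_pdb$raw_bfactor, orig$raw_bfactor)
  expect_equal(back_pdb$aa, orig$aa)

  seqs <- read_fasta(paths$fasta)
  expect_equal(nrow(seqs), 8)
  expect_equal(nchar(seqs$sequence[1]),
               sum(corpus$residues$chain_id == seqs$chain_id[1]))

  pf <- list.files(paths$pssm, full.names = TRUE)[1]
  prof <- read_pssm(pf)
  id <- sub("\\.pssm$", "", basename(pf))
  expect_equal(unname(as.matrix(prof[, flexseq:::PSSM_AA_ORDER])),
               unname(as.matrix(
                 corpus$pssm[corpus$pssm$chain_id == id,
                             flexseq:::PSSM_AA_ORDER])))

  labels <- read_labels(paths$labels)
  relab <- label_corpus(corpus$residues)
  expect_equal(labels$state, relab$state)
  expect_equal(labels$b_norm, relab$b_norm, tolerance = 1e-6)
})

test_that("the PDB B column is formatted to two decimals in columns 61-66", {
  chains <- tibble::tibble(chain_id = "A", position = 1L, aa = "M",
                           raw_bfactor = 12.3456)
  dir <- withr::local_tempdir()
  p <- write_pdb_ca(chains, dir)[1]
  line <- readLines(p)[1]
  expect_equal(substr(line, 61, 66), " 12.35")
  chains40 <- generate_dataset(simulate_config(
    n_chains = 1, length_range = c(40L, 40L), seed = 106))$residues
  p40 <- write_pdb_ca(chains40, dir)[1]
  expect_equal(sum(startsWith(readLines(p40), "ATOM")), 40)
})

test_that("planted triplet preferences are recovered by the potentials", {
  plant <- list(k1 = -1, k2 = 1, res_j = "A", res_k = "C",
                tilt = c(0.2, 0.6, 4))
  corpus <- simulate_labeled_corpus(
    n_chains = 130, chain_length = 120, seed = 107,
    alphabet = c("A", "C", "D", "E"), triplet_plant = plant)
  cc <- count_contexts(corpus)
  pair_id <- which(cc$offset_pairs[, 1] == -1 & cc$offset_pairs[, 2] == 1)
  for (center in c("A", "C", "D", "E")) {
    cell <- cc$triplet[, pair_id, match(center, AA20_T),
                       match("A", AA20_T), match("C", AA20_T)]
    expect_gte(sum(cell), 200)  # enough observations per planted cell
  }
  pot <- derive_potentials(cc, 10)
  for (center in c("A", "C", "D", "E")) {
    uF <- pot$triplet["F", pair_id, match(center, AA20_T),
                      match("A", AA20_T), match("C", AA20_T)]
    uR <- pot$triplet["R", pair_id, match(center, AA20_T),
                      match("A", AA20_T), match("C", AA20_T)]
    expect_lt(uF, 0)  # planted flexible preference -> favourable energy
    expect_gt(uR, 0)
  }
})

test_that("zero effect sizes leave the classifier at the no-information rate", {
  cfg <- simulate_config(n_chains = 40, length_range = c(40L, 60L),
                         seed = 108, effect_scale = 0)
  corpus <- generate_dataset(cfg)
  lab <- label_corpus(corpus$residues)
  pot <- derive_potentials(count_contexts(lab), 10)
  enc <- encode_corpus(lab, corpus$pssm, pot)
  ids <- unique(enc$meta$chain_id)
  test_ids <- ids[1:10]; val_ids <- ids[11:16]
  ti <- enc$meta$chain_id %in% test_ids
  vi <- enc$meta$chain_id %in% val_ids
  net <- train_network(enc$x[!(ti | vi), ], enc$label[!(ti | vi)],
                       enc$x[vi, ], enc$label[vi],
                       flex_net_config(n_hidden = 16, epochs = 15,
                                       patience = 4, seed = 109))
  q3 <- mean(predict(net, enc$x[ti, ])$state == enc$label[ti])
  # no feature carries information: accuracy can't beat the majority rate
  majority <- max(prop.table(table(enc$label[ti])))
  se <- sqrt(majority * (1 - majority) / sum(ti))
  expect_lt(q3, majority + 3 * se + 0.02)
})
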