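test_that("make_genome is deterministic and plants exactly", {
  g1 <- make_genome(length = 6000, seed = 81,
                    plants = list(plant_spec("TTTAATGT", 6)))
  g2 <- make_genome(length = 6000, seed = 81,
                    plants = list(plant_spec("TTTAATGT", 6)))
  expect_identical(g1$record$sequence, g2$record$sequence)
  expect_identical(g1$truth, g2$truth)

  tr <- find_repeats(g1$record)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$start, g1$truth$start)
  expect_equal(tr$end, g1$truth$end)
  expect_equal(tr$copy_number, 6)

  # clean background: no plants, nothing reported at the threshold
  g0 <- make_genome(length = 6000, seed = 82)
  expect_equal(nrow(find_repeats(g0$record)), 0L)

  # variant copies are planted verbatim
  gv <- make_genome(length = 6000, seed = 83, plants = list(
    plant_spec("TTTAATGT", 6,
               variant_positions = c("3" = "TGTAATGT"))))
  tract <- substr(gv$record$sequence, gv$truth$start, gv$truth$end)
  al <- flounder_tr3_alphabet()
  expect_equal(decompose(tract, al)$symbols,
               c("R", "R", "v1", "R", "R", "R"))
})

test_that("plants that do not fit their site class are refused", {
  expect_error(
    make_genome(length = 6000, seed = 84,
                plants = list(plant_spec("ACGTACGTAC", 40, "tRNA"))),
    "capacity")
  expect_error(plant_spec("TTTAATGT", 1), "copies")
  expect_error(plant_spec("TTTAATGT", 5,
                          variant_positions = c("9" = "TGTAATGT")),
               "copies")
  expect_error(plant_spec("TTTAATGT", 5,
                          variant_positions = c("2" = "TGTAAT")),
               "length")
})

test_that("clone sets carry their planted indels and controls", {
  al <- flounder_tr3_alphabet()
  base <- rep("R", 26)
  base[17] <- "v2"
  cs <- make_clone_set(base, indel_specs = list(
    list(kind = "deletion", symbols = rep("R", 6), position = 3),
    list(kind = "deletion", symbols = "v2", position = 17),
    list(kind = "insertion", symbols = c("v1", "R"), position = 10)),
    alphabet = al, n_clones = 5)
  expect_equal(nrow(cs$clones), 5L)
  expect_equal(cs$truth$kind,
               c("deletion", "deletion", "insertion", "none", "none"))
  # clone 1: 26 - 6 = 20 copies, tract 160 bp
  expect_length(cs$encodings[[1]]$symbols, 20L)
  tract1 <- substr(cs$clones$sequence[1], cs$clones$tract_start[1],
                   cs$clones$tract_end[1])
  e1 <- decompose(tract1, al, clone_id = "clone_01")
  expect_equal(length(e1$symbols) * 8L, 160L)
  # controls decode back to the base organisation
  tract4 <- substr(cs$clones$sequence[4], cs$clones$tract_start[4],
                   cs$clones$tract_end[4])
  e4 <- decompose(tract4, al)
  expect_equal(e4$symbols, base)
  # diffing control vs the v2 deletion pins the planted copy index
  call <- diff_encodings(cs$encodings[[4]], cs$encodings[[2]])
  expect_equal(call$kind, "deletion")
  expect_true(call$ambiguity_start <= 17 && 17 <= call$ambiguity_end)
  # zero specs: all clones identical
  cs0 <- make_clone_set(base, alphabet = al, n_clones = 3)
  expect_equal(unique(cs0$clones$sequence),
               cs0$clones$sequence[1])
  # inapplicable indel
  expect_error(make_clone_set(base, indel_specs = list(
    list(kind = "deletion", symbols = rep("R", 3), position = 16)),
    alphabet = al, n_clones = 2), "does not match")
})

test_that("the synthetic flounder CR reproduces the published cluster", {
  m <- flounder_motifs()
  qd <- make_pcornutus_cr("QD-07", seed = 85)
  blocks <- qd$blocks
  mtr <- substr(qd$sequence,
                blocks$start[blocks$block == "mtr_region"],
                blocks$end[blocks$block == "mtr_region"])
  sig <- detect_birth(mtr)
  expect_equal(sig$unit_len, 48L)
  expect_equal(sig$copies, 4L)
  expect_equal(sig$prefix_overlap, 6L)

  ds <- make_pcornutus_cr("DS-03", seed = 85)
  mtr2 <- substr(ds$sequence,
                 ds$blocks$start[ds$blocks$block == "mtr_region"],
                 ds$blocks$end[ds$blocks$block == "mtr_region"])
  sig2 <- detect_birth(mtr2)
  expect_equal(sig2$unit_len, 58L)
  expect_equal(sig2$copies, 2L)

  # the typical individual carries no M-TR duplication
  ty <- make_pcornutus_cr("typical", seed = 85)
  mtr3 <- substr(ty$sequence,
                 ty$blocks$start[ty$blocks$block == "mtr_region"],
                 ty$blocks$end[ty$blocks$block == "mtr_region"])
  expect_equal(nrow(detect_birth(mtr3)), 0L)

  # the QD-07 3'-TR tract: 51 copies, 408 bp
  tr3 <- blocks[blocks$block == "tr3_tract", ]
  expect_equal(tr3$end - tr3$start + 1L, 408L)
  al <- flounder_tr3_alphabet()
  e <- decompose(substr(qd$sequence, tr3$start, tr3$end), al)
  expect_length(e$symbols, 51L)

  # variant substitutions land at the requested copies
  v <- make_pcornutus_cr("typical", tr3_copies = 30,
                         tr3_variants = list("5" = "v1", "12" = "v2"),
                         seed = 86)
  tb <- v$blocks[v$blocks$block == "tr3_tract", ]
  ev <- decompose(substr(v$sequence, tb$start, tb$end), al)
  expect_equal(which(ev$symbols == "v1"), 5L)
  expect_equal(which(ev$symbols == "v2"), 12L)
})
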