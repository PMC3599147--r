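test_that("motif alphabets validate their variants", {
  al <- flounder_tr3_alphabet()
  expect_s3_class(al, "MotifAlphabet")
  expect_equal(al$motif_len, 8L)
  expect_error(motif_alphabet("TTTAATGT", c(v1 = "TTTAAT")), "length")
  expect_error(motif_alphabet("TTTAATGT", c(v1 = "TGAAATGT")),
               "max_hamming")
  expect_error(motif_alphabet("TTTAATGT", c("TGTAATGT")), "named")
  # two-mismatch variants allowed when max_hamming permits
  al2 <- motif_alphabet("TTTAATGT", c(vx = "TGAAATGT"), max_hamming = 2)
  expect_length(al2$motifs, 2L)
})

test_that("decompose segments variant-bearing tracts and keeps residuals", {
  m <- flounder_motifs()
  al <- flounder_tr3_alphabet()
  e <- decompose(paste0(m$tr3, m$tr3_v1, m$tr3), al)
  expect_equal(e$symbols, c("R", "v1", "R"))
  # the 51-copy tract of the longest observed clone: 408 bases
  e51 <- decompose(strrep(m$tr3, 51), al)
  expect_equal(length(e51$symbols), 51L)
  expect_equal(nchar(decode_encoding(e51)), 408L)
  # too short for one motif: everything is residual
  e0 <- decompose("ACGT", al)
  expect_equal(e0$symbols, character(0))
  expect_equal(e0$residual_suffix, "ACGT")
  # an unassignable window stops the tract (no chimeric encodings)
  e_stop <- decompose(paste0(m$tr3, "AAAAAAAA", m$tr3), al)
  expect_equal(e_stop$symbols, "R")
  expect_equal(nchar(e_stop$residual_suffix), 16L)
})

test_that("decode after decompose reproduces the input exactly", {
  set.seed(41)
  al <- flounder_tr3_alphabet()
  mot <- al$motifs
  for (i in 1:30) {
    syms <- sample(names(mot), sample(1:20, 1), replace = TRUE)
    pre <- substr(rand_dna(8), 1, sample(0:7, 1))
    suf <- substr(rand_dna(8), 1, sample(0:7, 1))
    s <- paste0(pre, paste(mot[syms], collapse = ""), suf)
    e <- decompose(s, al)
    expect_equal(decode_encoding(e), s)
    expect_gte(length(e$symbols), length(syms))  # frame may consume flanks
  }
})

test_that("single-indel diffs match the brute-force enumerator", {
  al <- motif_alphabet("TTTAATGT",
                       c(v1 = "TGTAATGT", v2 = "TATAATGT"))
  syms3 <- c("R", "v1", "v2")
  set.seed(43)
  for (rep in 1:40) {
    n <- sample(2:12, 1)
    base <- sample(syms3, n, replace = TRUE,
                   prob = c(0.6, 0.2, 0.2))
    k <- sample(1:min(3, n - 1), 1)
    at <- sample(n - k + 1, 1)
    # deletion case
    del <- base[-(at:(at + k - 1))]
    a <- make_encoding(base, al)
    b <- make_encoding(del, al)
    got <- diff_encodings(a, b)
    want <- enumerate_single_indels(base, del)
    expect_equal(as.data.frame(got[order(got$symbols),
                                   names(want)]),
                 want[order(want$symbols), ],
                 ignore_attr = TRUE)
    expect_true(all(got$kind == "deletion"))
    # the reverse comparison is the mirrored insertion
    rev <- diff_encodings(b, a)
    expect_true(all(rev$kind == "insertion"))
    expect_equal(sort(rev$symbols), sort(got$symbols))
  }
})

test_that("ambiguity intervals are maximal placement bands", {
  al <- flounder_tr3_alphabet()
  # deletion inside a run of identical symbols spans the run
  got <- diff_encodings(make_encoding("RRRRR", al),
                        make_encoding("RRRR", al))
  expect_equal(got[c("kind", "motif_count", "symbols")],
               tibble::tibble(kind = "deletion", motif_count = 1L,
                              symbols = "R"))
  expect_equal(c(got$ambiguity_start, got$ambiguity_end), c(1L, 5L))
  # unique variant pins the site
  got2 <- diff_encodings(make_encoding(c("R", "R", "v1", "R"), al),
                         make_encoding(c("R", "R", "R"), al))
  expect_equal(got2$symbols, "v1")
  expect_equal(c(got2$ambiguity_start, got2$ambiguity_end), c(3L, 3L))
  # six copies deleted from a run of ten: the band covers all ten
  got3 <- diff_encodings(make_encoding(strrep("R", 10), al),
                         make_encoding(strrep("R", 4), al))
  expect_equal(got3$motif_count, 6L)
  expect_equal(c(got3$ambiguity_start, got3$ambiguity_end), c(1L, 10L))
  # maximality: every placement inside the band works, the flanks fail
  base <- strsplit("RRvRR", "")[[1]]
  base[base == "v"] <- "v1"
  a <- make_encoding(base, al)
  call <- diff_encodings(a, make_encoding(c("R", "v1", "R", "R"), al))
  k <- call$motif_count
  run <- strsplit(call$symbols, ".", fixed = TRUE)[[1]]
  for (p in call$ambiguity_start:(call$ambiguity_end - k + 1L)) {
    expect_equal(base[-(p:(p + k - 1L))],
                 c("R", "v1", "R", "R"))
  }
  out <- c(call$ambiguity_start - 1L, call$ambiguity_end - k + 2L)
  for (p in out[out >= 1L & out + k - 1L <= length(base)]) {
    expect_false(identical(base[-(p:(p + k - 1L))],
                           c("R", "v1", "R", "R")))
  }
})

test_that("identical, complex and multi-event comparisons are reported", {
  al <- flounder_tr3_alphabet()
  a <- make_encoding(c("R", "v1", "R"), al)
  expect_equal(nrow(diff_encodings(a, a)), 0L)
  # same length, one substitution: no single indel explains it
  b <- make_encoding(c("R", "v2", "R"), al)
  got <- diff_encodings(a, b)
  expect_equal(got$kind, "complex")
  expect_equal(got$edit_distance, 1L)  # one symbol substituted
  # two separated deletions surface with max_events = 2
  long <- make_encoding(c("R", "v1", "R", "R", "v2", "R"), al)
  short <- make_encoding(c("R", "R", "R", "R"), al)
  two <- diff_encodings(long, short, max_events = 2L)
  expect_equal(nrow(two), 2L)
  expect_true(all(two$kind == "deletion"))
  expect_equal(sort(two$symbols), c("v1", "v2"))
  # different alphabets are refused
  other <- motif_alphabet("ATATTACA")
  expect_error(diff_encodings(a, make_encoding("R", other)), "alphabet")
})

test_that("detect_birth finds the flounder M-TR duplications exactly", {
  m <- flounder_motifs()
  ds <- paste0(strrep(m$ds03_unit, 2), m$ds03_flank)
  got <- detect_birth(ds)
  expect_equal(nrow(got), 1L)
  expect_equal(got$unit_len, 58L)
  expect_equal(got$copies, 2L)
  expect_equal(got$prefix_overlap, 5L)
  expect_equal(got$overlap_seq, "TTTAA")

  qd <- paste0(m$qd07_prefix, strrep(m$qd07_unit, 4), m$qd07_flank)
  got2 <- detect_birth(qd)
  expect_equal(nrow(got2), 1L)
  expect_equal(got2$unit_len, 48L)
  expect_equal(got2$copies, 4L)
  expect_equal(got2$prefix_overlap, 6L)
  expect_equal(got2$overlap_seq, "AACACT")

  # the unrepeated section of the other 18 individuals has no duplication
  expect_equal(nrow(detect_birth(m$mtr_section)), 0L)
  set.seed(47)
  expect_equal(nrow(detect_birth(rand_dna(150))), 0L)
  # min_copies gates reporting
  tri <- paste0(strrep("ACGTTGCAAT", 3), "CCGG")
  expect_equal(detect_birth(tri, min_unit = 8)$copies, 3L)
  expect_equal(nrow(detect_birth(tri, min_unit = 8, min_copies = 4)), 0L)
})

test_that("copy-number statistics reproduce the observed length range", {
  m <- flounder_motifs()
  al <- flounder_tr3_alphabet()
  encs <- list(decompose(strrep(m$tr3, 4), al, clone_id = "DS-04"),
               decompose(strrep(m$tr3, 51), al, clone_id = "QD-07"))
  st <- copy_number_stats(encs)
  expect_equal(st$min_copies, 4L)
  expect_equal(st$max_copies, 51L)
  expect_equal(st$table$tract_len, c(32L, 408L))
  # single clone: min == max
  one <- copy_number_stats(encs[1])
  expect_equal(one$min_copies, one$max_copies)
  # empty encodings drop with a warning
  encs2 <- c(encs, list(decompose("ACG", al, clone_id = "bad")))
  expect_warning(st2 <- copy_number_stats(encs2), "excluded")
  expect_equal(nrow(st2$table), 2L)
})
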