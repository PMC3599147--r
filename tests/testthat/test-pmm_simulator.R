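test_that("fold classes follow the unpaired-length thresholds", {
  expect_equal(classify_fold(5), "bulge")
  expect_equal(classify_fold(7), "loop")
  expect_equal(classify_fold(9), "hairpin")
  expect_equal(classify_fold(c(0, 1, 6, 8, 20)),
               c("none", "bulge", "loop", "loop", "hairpin"))
  expect_error(classify_fold(-1), "nonnegative")
})

test_that("find_mispair_site returns the nearest slipped register", {
  m <- "TTTAATGT"
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s),
                                       "")[[1]]), collapse = "")
  # tail = one motif against a two-copy template: slips one period
  expect_equal(find_mispair_site(m, rc(strrep(m, 2)), 1.0), 8L)
  # three copies: the nearest register still wins
  expect_equal(find_mispair_site(m, rc(strrep(m, 3)), 1.0), 8L)
  # no repeated sequence at full identity: nothing qualifies
  set.seed(61)
  expect_true(is.na(find_mispair_site("ACGTTGCA", rc("GGATCCTTAAGGCCAT"),
                                      1.0)))
  # exact complement at the correct register only: excluded
  expect_true(is.na(find_mispair_site("ACGTTGCA", rc("ACGTTGCA"), 1.0)))
  # window shorter than the tail
  expect_true(is.na(find_mispair_site("ACGTACGTACGT", rc("ACGT"), 0.5)))
})

test_that("switched-off pauses never mutate the genome", {
  g <- make_genome(length = 5000, seed = 71,
                   plants = list(plant_spec("TTTAATGT", 5)))
  p0 <- pmm_params(pause_profile = c(CR_5prime = 0, CR_3prime = 0,
                                     CDS = 0, other = 0))
  r <- evolve_lineages(g$record, n_lineages = 2, n_replications = 5000,
                       params = p0, seed = 1)
  expect_equal(nrow(r$events), 0L)
  expect_true(all(r$sequences == g$record$sequence))
})

test_that("protrusion side forces the outcome", {
  g <- make_genome(length = 5000, seed = 71,
                   plants = list(plant_spec("TTTAATGT", 12)))
  pN <- pmm_params(pause_profile = c(CR_5prime = 1, CR_3prime = 1,
                                     CDS = 0.2, other = 0.1),
                   protrusion_side_prob_N = 1.0)
  r <- evolve_lineages(g$record, n_lineages = 2, n_replications = 1500,
                       params = pN, seed = 2)
  applied <- r$events[r$events$outcome %in% c("insertion", "deletion"), ]
  expect_gt(nrow(applied), 0L)
  expect_true(all(applied$outcome == "insertion"))
})

test_that("event bookkeeping conserves sequence length", {
  g <- make_genome(length = 6000, seed = 72,
                   plants = list(plant_spec("TTTAATGT", 10),
                                 plant_spec("ATATTACA", 10, "CR_5prime")))
  r <- evolve_lineages(g$record, n_lineages = 4, n_replications = 800,
                       seed = 3)
  ap <- r$events[r$events$outcome %in% c("insertion", "deletion"), ]
  # every change is +/- motif_count * motif length
  expect_true(all(abs(ap$delta) ==
                    ap$motif_count * nchar(ap$motif)))
  # final length = founder length + sum of signed changes, per lineage
  for (ln in seq_len(4)) {
    expect_equal(unname(r$summary$final_lengths[ln]),
                 g$record$length + sum(ap$delta[ap$lineage == ln]))
  }
})

test_that("zero replications and fixed seeds are exactly reproducible", {
  g <- make_genome(length = 5000, seed = 73,
                   plants = list(plant_spec("TTTAATGT", 8)))
  r0 <- evolve_lineages(g$record, n_lineages = 3, n_replications = 0,
                        seed = 4)
  expect_true(all(r0$sequences == g$record$sequence))
  expect_equal(nrow(r0$events), 0L)

  ra <- evolve_lineages(g$record, n_lineages = 3, n_replications = 300,
                        seed = 5)
  rb <- evolve_lineages(g$record, n_lineages = 3, n_replications = 300,
                        seed = 5)
  expect_identical(ra$sequences, rb$sequences)
  expect_identical(ra$events, rb$events)
})

test_that("within a perfect tract, slips respect the motif period", {
  g <- make_genome(seed = 3, plants = list(plant_spec("TTTAATGT", 5)))
  x <- mttr:::.chars(g$record$sequence)
  cls <- position_classes(g$record)
  tru <- g$truth
  set.seed(11)
  n_in <- 0L
  for (i in 1:20000) {
    r <- mttr:::.pmm_step(x, cls, pmm_params(), i)
    ev <- r$event
    if (!is.null(ev) && ev$outcome %in% c("insertion", "deletion") &&
        ev$position - ev$unpaired_len + 1L >= tru$start &&
        ev$position <= tru$end) {
      n_in <- n_in + 1L
      expect_equal(ev$unpaired_len %% 8L, 0L)
    }
  }
  expect_gte(n_in, 1L)  # the tract does gain/lose whole copies
})

test_that("position classes split the CR and shift with indels", {
  g <- make_genome(length = 6000, seed = 74)
  cls <- position_classes(g$record)
  # the table tiles the genome
  expect_equal(sum(cls$end - cls$start + 1L), g$record$length)
  expect_setequal(unique(cls$class),
                  c("CR_5prime", "CR_3prime", "CDS", "other"))
  ori <- orient_control_region(g$record)
  # 5' half of the CR is labelled CR_5prime
  probe5 <- ori$cr_start + 10L
  expect_equal(mttr:::.class_at(cls, probe5), "CR_5prime")
  probe3 <- ori$cr_end - 10L
  expect_equal(mttr:::.class_at(cls, probe3), "CR_3prime")
  # an insertion before a class interval shifts it right
  shifted <- mttr:::.shift_classes(cls, probe5, 16L)
  expect_equal(mttr:::.class_at(shifted, probe3 + 16L), "CR_3prime")
})
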