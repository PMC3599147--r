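# Shared fixture builders (everything is generated in code; seeds are set
# by the calling test).

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# k random substitutions into a DNA string
perturb <- function(s, k) {
  if (k == 0L) return(s)
  x <- strsplit(s, "")[[1]]
  i <- sample(length(x), k)
  x[i] <- vapply(x[i], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, "")
  paste(x, collapse = "")
}

# TractEncoding straight from a symbol vector (or 1-char-symbol string)
make_encoding <- function(symbols, alphabet, id = "x") {
  if (length(symbols) == 1L && nchar(symbols) > 1L &&
      !symbols %in% names(alphabet$motifs)) {
    symbols <- strsplit(symbols, "")[[1]]
  }
  structure(list(clone_id = id, symbols = symbols, residual_prefix = "",
                 residual_suffix = "", alphabet = alphabet),
            class = "TractEncoding")
}

# the vertebrate survey per-class counts shipped with the package
survey_counts <- function() {
  path <- system.file("extdata", "vertebrate_mttr_counts.tsv",
                      package = "mttr")
  tibble::as_tibble(utils::read.delim(path, sep = "\t"))
}

# a small annotated linear-ish test genome with the standard gene order
# around the control region; much faster than make_genome for locator tests
mini_genome <- function(seq_len = 3000L, cr = c(1800L, 2700L),
                        wrap_cr = FALSE) {
  ft <- rbind(
    mt_feature("rRNA", "12S ribosomal RNA", 2851L %% seq_len, 3000L),
    mt_feature("CDS", "CytB", 200L, 1300L),
    mt_feature("CDS", "ND1", 1350L, 1600L),
    mt_feature("tRNA", "tRNA-Thr", 1610L, 1680L),
    mt_feature("tRNA", "tRNA-Pro", 1700L, 1790L),
    mt_feature("control_region", "control region", cr[1L], cr[2L]),
    mt_feature("tRNA", "tRNA-Phe", 2710L, 2780L))
  mt_genome_record("mini", rand_dna(seq_len), circular = TRUE,
                   features = ft, taxon_class = "Pisces")
}

expect_tibble_equal <- function(a, b) {
  testthat::expect_equal(as.data.frame(a), as.data.frame(b))
}
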