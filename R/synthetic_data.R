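# Synthetic fixtures: annotated circular mt genomes with planted repeats,
# flounder-style clone sets with planted indels, and clean random negatives.
# Every generator is seeded and deterministic, and returns a truth table so
# downstream detections can be checked exactly.

#' Specify a repeat tract to plant
#'
#' @param motif DNA motif.
#' @param copies integer number of copies (at least 2).
#' @param site_class where to plant: CR_3prime, CR_5prime, CDS, tRNA, rRNA
#'   or intergenic.
#' @param variant_positions named list/vector mapping copy index (1-based)
#'   to a variant motif of the same length, e.g. `c("3" = "TGTAATGT")`.
#' @return object of class `PlantSpec`.
#' @export
plant_spec <- function(motif, copies, site_class = "CR_3prime",
                       variant_positions = NULL) {
  motif <- toupper(motif)
  site_class <- match.arg(site_class, c("CR_3prime", "CR_5prime", "CDS",
                                        "tRNA", "rRNA", "intergenic"))
  stopifnot(nzchar(motif), copies >= 2L)
  if (length(variant_positions)) {
    idx <- as.integer(names(variant_positions))
    if (any(is.na(idx)) || any(idx < 1L | idx > copies)) {
      stop("variant copy indices must lie in [1, copies]")
    }
    if (any(nchar(unlist(variant_positions)) != nchar(motif))) {
      stop("variant motifs must have the same length as the motif")
    }
  }
  structure(list(motif = motif, copies = as.integer(copies),
                 site_class = site_class,
                 variant_positions = variant_positions),
            class = "PlantSpec")
}

.plant_sequence <- function(spec) {
  units <- rep(spec$motif, spec$copies)
  if (length(spec$variant_positions)) {
    idx <- as.integer(names(spec$variant_positions))
    units[idx] <- toupper(unlist(spec$variant_positions))
  }
  paste(units, collapse = "")
}

.random_dna <- function(n, gc = 0.45) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  .collapse(sample(names(p), n, replace = TRUE, prob = p))
}

# minimal but gene-order-faithful layout: 12S ... CytB, tRNA-Thr, tRNA-Pro,
# control region, tRNA-Phe, (pad) -> wraps to 12S; fractions of a 16.5 kb
# reference genome
.mt_layout <- function(len) {
  ref <- list(
    c("rRNA", "12S ribosomal RNA", 1, 950),
    c("rRNA", "16S ribosomal RNA", 1001, 2600),
    c("CDS", "ND1", 2651, 3550),
    c("CDS", "ND2", 3601, 4600),
    c("CDS", "COX1", 4701, 6200),
    c("CDS", "COX2", 6301, 6980),
    c("CDS", "ATP6", 7101, 7780),
    c("CDS", "COX3", 7801, 8580),
    c("CDS", "ND3", 8651, 9000),
    c("CDS", "ND4", 9251, 10550),
    c("CDS", "ND5", 10601, 12300),
    c("CDS", "ND6", 12351, 12850),
    c("CDS", "CytB", 12901, 14040),
    c("tRNA", "tRNA-Thr", 14051, 14120),
    c("tRNA", "tRNA-Pro", 14131, 14200),
    c("control_region", "control region", 14201, 16420),
    c("tRNA", "tRNA-Phe", 16421, 16490))
  sc <- len / 16500
  ft <- do.call(rbind, lapply(ref, function(r) {
    mt_feature(r[1L], r[2L], max(1L, round(as.integer(r[3L]) * sc)),
               min(len, round(as.integer(r[4L]) * sc)))
  }))
  ft$strand[ft$name %in% c("tRNA-Pro", "ND6")] <- "-"
  ft
}

# anchor position ranges for each plantable class, given a feature table
.plant_sites <- function(ft, len) {
  cr <- ft[ft$kind == "control_region", ][1L, ]
  cds <- ft[ft$name == "COX1", ][1L, ]
  trna <- ft[ft$name == "tRNA-Thr", ][1L, ]
  rrna <- ft[ft$name == "16S ribosomal RNA", ][1L, ]
  nd3 <- ft[ft$name == "ND3", ][1L, ]
  nd4 <- ft[ft$name == "ND4", ][1L, ]
  list(
    # 3' CR end abuts tRNA-Phe: park tracts ending 30 bp before cr$end
    CR_3prime = c(lo = cr$start + (cr$end - cr$start) %/% 2L + 60L,
                  hi = cr$end - 30L),
    CR_5prime = c(lo = cr$start + 30L,
                  hi = cr$start + (cr$end - cr$start) %/% 2L - 60L),
    CDS = c(lo = cds$start + 10L, hi = cds$end - 10L),
    tRNA = c(lo = trna$start, hi = trna$end),
    rRNA = c(lo = rrna$start + 10L, hi = rrna$end - 10L),
    intergenic = c(lo = nd3$end + 5L, hi = nd4$start - 5L))
}

#' Generate an annotated genome with planted repeats
#'
#' Builds a circular genome with the standard gene order (12S/16S, the
#' protein-coding genes through CytB, tRNA-Thr, tRNA-Pro, control region,
#' tRNA-Phe), a random background rejection-sampled so that no unintended
#' tandem scores above `min_score`, and the requested tracts planted by
#' substitution at their site classes. The truth table gives exact
#' coordinates.
#'
#' @param length genome size in bases, default 16500.
#' @param plants list of [plant_spec()]s.
#' @param gc background GC fraction, default 0.45.
#' @param seed optional integer seed (same seed, identical genome).
#' @param min_score cleanliness threshold for the background, default 50.
#' @param id record identifier.
#' @param taxon_class taxon class stamped on the record.
#' @return list with `record` (an `MtGenomeRecord`) and `truth` (tibble:
#'   `motif`, `motif_len`, `copies`, `site_class`, `start`, `end`,
#'   `tract_len`).
#' @export
make_genome <- function(length = 16500L, plants = list(), gc = 0.45,
                        seed = NULL, min_score = 50L, id = "synthetic_mt",
                        taxon_class = "Pisces") {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(plants, "PlantSpec")) plants <- list(plants)
  stopifnot(length >= 2000L)
  ft <- .mt_layout(length)

  seq <- .random_dna(length, gc)
  rec <- mt_genome_record(id, seq, circular = TRUE, features = ft,
                          taxon_class = taxon_class)
  for (iter in seq_len(25L)) {
    hits <- find_repeats(rec, min_score = min_score)
    if (!nrow(hits)) break
    x <- .chars(rec$sequence)
    for (i in seq_len(nrow(hits))) {
      iv <- .circ_expand(hits$start[i], hits$end[i], length)
      for (r in seq_len(nrow(iv))) {
        n <- iv[r, 2L] - iv[r, 1L] + 1L
        x[iv[r, 1L]:iv[r, 2L]] <- .chars(.random_dna(n, gc))
      }
    }
    rec <- mt_genome_record(id, .collapse(x), circular = TRUE,
                            features = ft, taxon_class = taxon_class)
  }
  if (nrow(find_repeats(rec, min_score = min_score))) {
    stop("could not build a clean background in 25 rounds; try another seed")
  }

  sites <- .plant_sites(ft, length)
  cursor <- stats::setNames(rep(NA_integer_, length(sites)), names(sites))
  x <- .chars(rec$sequence)
  truth <- list()
  for (spec in plants) {
    stopifnot(inherits(spec, "PlantSpec"))
    tr <- .plant_sequence(spec)
    tl <- nchar(tr)
    rng <- sites[[spec$site_class]]
    # stack multiple plants of one class from the high end downward
    hi <- if (is.na(cursor[[spec$site_class]])) rng[["hi"]] else
      cursor[[spec$site_class]]
    start <- hi - tl + 1L
    if (start < rng[["lo"]]) {
      stop("plant of ", tl, " bp exceeds capacity of class ",
           spec$site_class)
    }
    x[start:(start + tl - 1L)] <- .chars(tr)
    # harden the flanks: the three bases on either side must not continue
    # the cyclic motif, so detection recovers the truth coordinates exactly
    mchars <- .chars(spec$motif)
    p <- length(mchars)
    for (k in 1:3) {
      right <- start + tl - 1L + k
      if (right <= length(x)) {
        cont <- mchars[((tl + k - 1L) %% p) + 1L]
        if (x[right] == cont) x[right] <- sample(setdiff(c("A", "C", "G",
                                                           "T"), cont), 1L)
      }
      left <- start - k
      if (left >= 1L) {
        cont <- mchars[((-k) %% p) + 1L]
        if (x[left] == cont) x[left] <- sample(setdiff(c("A", "C", "G",
                                                         "T"), cont), 1L)
      }
    }
    cursor[[spec$site_class]] <- start - 25L
    truth[[length(truth) + 1L]] <- tibble::tibble(
      motif = spec$motif, motif_len = nchar(spec$motif),
      copies = spec$copies, site_class = spec$site_class,
      start = start, end = start + tl - 1L, tract_len = tl)
  }
  rec <- mt_genome_record(id, .collapse(x), circular = TRUE, features = ft,
                          taxon_class = taxon_class)
  truth <- if (length(truth)) do.call(rbind, truth) else
    tibble::tibble(motif = character(), motif_len = integer(),
                   copies = integer(), site_class = character(),
                   start = integer(), end = integer(),
                   tract_len = integer())
  list(record = rec, truth = truth)
}

.CLONE_FLANK5 <- "CCTAACCCCTAAAGGACTAATGAGC"
.CLONE_FLANK3 <- "GACCTTAACCGGCATAAGCCTTAGC"

#' Generate a clone set with planted motif indels
#'
#' Emulates a panel of cloned control-region fragments from one individual:
#' every clone decodes the base encoding with fixed flanks, and clone *i*
#' carries indel spec *i* (remaining clones are unmodified controls).
#'
#' @param base_encoding character vector of alphabet symbols (the founder
#'   tract organisation), or a single string of one-letter symbols.
#' @param indel_specs list of specs, each a list with `kind`
#'   (`"deletion"`/`"insertion"`), `symbols` (character vector of the run)
#'   and `position` (1-based copy index where the run is removed from /
#'   inserted before).
#' @param alphabet a [motif_alphabet()].
#' @param n_clones total clones (must be at least `length(indel_specs)`),
#'   default `length(indel_specs) + 2`.
#' @param seed unused randomness hook kept for interface symmetry; the clone
#'   set is fully determined by its arguments.
#' @return list with `clones` (tibble `id`, `sequence`, `tract_start`,
#'   `tract_end` — the flank-free tract coordinates), `encodings` (list of
#'   `TractEncoding`s), and `truth` (tibble `clone_id`, `kind`, `symbols`,
#'   `position`; control clones have kind `"none"`).
#' @export
make_clone_set <- function(base_encoding, indel_specs = list(), alphabet,
                           n_clones = length(indel_specs) + 2L,
                           seed = NULL) {
  stopifnot(inherits(alphabet, "MotifAlphabet"))
  if (!is.null(seed)) set.seed(seed)
  if (length(base_encoding) == 1L && nchar(base_encoding) > 1L &&
      !base_encoding %in% names(alphabet$motifs)) {
    base_encoding <- .chars(base_encoding)
  }
  if (!all(base_encoding %in% names(alphabet$motifs))) {
    stop("base encoding uses symbols outside the alphabet")
  }
  if (n_clones < length(indel_specs)) {
    stop("need at least one clone per indel spec")
  }
  clones <- list()
  truth <- list()
  encs <- list()
  for (i in seq_len(n_clones)) {
    id <- sprintf("clone_%02d", i)
    syms <- base_encoding
    if (i <= length(indel_specs)) {
      sp <- indel_specs[[i]]
      k <- length(sp$symbols)
      if (sp$kind == "deletion") {
        if (sp$position + k - 1L > length(syms) ||
            !identical(syms[sp$position:(sp$position + k - 1L)],
                       sp$symbols)) {
          stop("deletion spec ", i, " does not match the base encoding")
        }
        syms <- syms[-(sp$position:(sp$position + k - 1L))]
      } else if (sp$kind == "insertion") {
        if (sp$position > length(syms) + 1L) {
          stop("insertion spec ", i, " position out of range")
        }
        syms <- append(syms, sp$symbols, after = sp$position - 1L)
      } else {
        stop("unknown indel kind: ", sp$kind)
      }
      truth[[i]] <- tibble::tibble(clone_id = id, kind = sp$kind,
                                   symbols = paste(sp$symbols,
                                                   collapse = "."),
                                   position = sp$position)
    } else {
      truth[[i]] <- tibble::tibble(clone_id = id, kind = "none",
                                   symbols = "", position = NA_integer_)
    }
    seq <- paste0(.CLONE_FLANK5,
                  paste(alphabet$motifs[syms], collapse = ""),
                  .CLONE_FLANK3)
    clones[[i]] <- tibble::tibble(
      id = id, sequence = seq,
      tract_start = nchar(.CLONE_FLANK5) + 1L,
      tract_end = nchar(.CLONE_FLANK5) +
        length(syms) * alphabet$motif_len)
    encs[[i]] <- structure(list(clone_id = id, symbols = syms,
                                residual_prefix = "", residual_suffix = "",
                                alphabet = alphabet),
                           class = "TractEncoding")
  }
  list(clones = do.call(rbind, clones), encodings = encs,
       truth = do.call(rbind, truth))
}

#' Synthesise a flounder-style control region
#'
#' Builds a control region emulating the repeat cluster at the 3' end of the
#' *P. cornutus* CR: a CSB3 block, a 5'-TR tract (ATATTACA), the M-TR
#' section (unrepeated 65-base section in `"typical"` mode, the tandemly
#' duplicated 58-mer in `"DS-03"` mode, or the 48-mer array in `"QD-07"`
#' mode), and a 3'-TR tract (TTTAATGT) with optional single-base variant
#' copies. Flanking sequence is invented and neutral.
#'
#' @param mode `"QD-07"`, `"DS-03"` or `"typical"`.
#' @param m_copies copies of the M-TR unit (default 4 for QD-07, 2 for
#'   DS-03; ignored for typical).
#' @param tr3_copies copies in the 3'-TR tract (default 51 for QD-07, 26
#'   otherwise).
#' @param tr5_copies copies in the 5'-TR tract, default 4.
#' @param tr3_variants named list/vector mapping 3'-TR copy index to
#'   `"v1"` or `"v2"`.
#' @param seed optional seed for the random flanks.
#' @return list with `sequence` and `blocks` (tibble `block`, `start`,
#'   `end`).
#' @export
make_pcornutus_cr <- function(mode = c("QD-07", "DS-03", "typical"),
                              m_copies = NULL, tr3_copies = NULL,
                              tr5_copies = 4L, tr3_variants = NULL,
                              seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  m <- flounder_motifs()
  if (is.null(m_copies)) m_copies <- switch(mode, "QD-07" = 4L,
                                            "DS-03" = 2L, 1L)
  if (is.null(tr3_copies)) tr3_copies <- switch(mode, "QD-07" = 51L, 26L)
  mtr <- switch(mode,
    "typical" = m$mtr_section,
    "DS-03" = paste0(strrep(m$ds03_unit, m_copies), m$ds03_flank),
    "QD-07" = paste0(m$qd07_prefix, strrep(m$qd07_unit, m_copies),
                     m$qd07_flank))
  tr3_units <- rep(m$tr3, tr3_copies)
  if (length(tr3_variants)) {
    idx <- as.integer(names(tr3_variants))
    stopifnot(all(idx >= 1L & idx <= tr3_copies),
              all(unlist(tr3_variants) %in% c("v1", "v2")))
    tr3_units[idx] <- unlist(m[paste0("tr3_", unlist(tr3_variants))])
  }
  parts <- list(
    flank_5 = .random_dna(120L),
    CSB3 = "AAACCCCCCTTCCCCCCC",  # invented placeholder block
    tr5_tract = strrep(m$tr5, tr5_copies),
    spacer = .random_dna(20L),
    mtr_region = mtr,
    tr3_tract = paste(tr3_units, collapse = ""),
    flank_3 = .random_dna(40L))
  lens <- vapply(parts, nchar, 0L)
  ends <- unname(cumsum(lens))
  blocks <- tibble::tibble(block = names(parts),
                           start = ends - unname(lens) + 1L, end = ends)
  list(sequence = paste(unlist(parts), collapse = ""), blocks = blocks)
}
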