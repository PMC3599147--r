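# Forward simulation of Pause-Melting Misalignment (PMM): a replication
# pause lets the displaced parental heavy strand (D) compete with the
# nascent heavy strand (N) for the template light strand (T); the N-strand
# 3' tail melts, may re-anneal out of register at a near-complementary
# site, the unpaired span folds (bulge/loop/hairpin by length), and the
# next replication round fixes an insertion or deletion of the span.

.PMM_CLASSES <- c("CR_5prime", "CR_3prime", "CDS", "other")

#' PMM simulator parameters
#'
#' All rates are model configuration, not fitted values; defaults encode the
#' qualitative contrasts the mechanism predicts. Pauses are frequent at both
#' control-region ends (heavy-strand arrest at TAS; initiation/closure
#' traffic at the 3' end) and rare but nonzero elsewhere. The D-strand is
#' largely displaced by the time the fork reaches the CR 3' end, so its
#' competition there is weak and the melted tail shorter — hence
#' `competition_strength` scales `melt_length_mean`, and a slip can reach
#' at most as far as the melt.
#'
#' @param pause_profile named pause probability per replication for each
#'   position class (CR_5prime, CR_3prime, CDS, other).
#' @param competition_strength named D-strand competitiveness in `[0,1]` per
#'   class; lower at the CR 3' end.
#' @param melt_length_mean named mean melted-tail length (bases) per class;
#'   the effective mean is `melt_length_mean * competition_strength`.
#' @param mispair_min_identity identity fraction required for out-of-register
#'   re-annealing, default 0.9.
#' @param bulge_release_prob probability that a bulge (< 6 unpaired bases)
#'   slips off the strand end and the event aborts, default 0.7.
#' @param protrusion_side_prob_N probability the protrusion forms on the
#'   nascent strand (giving an insertion) rather than the template (giving
#'   a deletion), default 0.5.
#' @param max_search_window furthest slip offset considered (bases),
#'   default 200.
#' @param min_anchor shortest 3' anchor that can re-anneal at all (bases),
#'   default 4; a one- or two-base pairing is too unstable to anchor a
#'   mispair.
#' @param anchor_length_mean mean length of the re-annealing 3' anchor
#'   (bases), default 8; the anchor is geometric above `min_anchor` and
#'   never longer than the melt.
#' @return object of class `PMMParams`.
#' @export
pmm_params <- function(pause_profile = c(CR_5prime = 0.3, CR_3prime = 0.3,
                                         CDS = 0.05, other = 0.01),
                       competition_strength = c(CR_5prime = 1.0,
                                                CR_3prime = 0.5,
                                                CDS = 1.0, other = 1.0),
                       melt_length_mean = c(CR_5prime = 40, CR_3prime = 20,
                                            CDS = 20, other = 20),
                       mispair_min_identity = 0.9,
                       bulge_release_prob = 0.7,
                       protrusion_side_prob_N = 0.5,
                       max_search_window = 200L,
                       min_anchor = 4L,
                       anchor_length_mean = 8) {
  for (nm in c("pause_profile", "competition_strength", "melt_length_mean")) {
    v <- get(nm)
    if (!all(.PMM_CLASSES %in% names(v))) {
      stop(nm, " must name all of: ", paste(.PMM_CLASSES, collapse = ", "))
    }
  }
  stopifnot(all(pause_profile >= 0 & pause_profile <= 1),
            all(competition_strength >= 0 & competition_strength <= 1),
            all(melt_length_mean > 0),
            mispair_min_identity > 0, mispair_min_identity <= 1,
            bulge_release_prob >= 0, bulge_release_prob <= 1,
            protrusion_side_prob_N >= 0, protrusion_side_prob_N <= 1,
            max_search_window >= 1, min_anchor >= 1,
            anchor_length_mean > min_anchor)
  structure(list(pause_profile = pause_profile[.PMM_CLASSES],
                 competition_strength = competition_strength[.PMM_CLASSES],
                 melt_length_mean = melt_length_mean[.PMM_CLASSES],
                 mispair_min_identity = mispair_min_identity,
                 bulge_release_prob = bulge_release_prob,
                 protrusion_side_prob_N = protrusion_side_prob_N,
                 max_search_window = as.integer(max_search_window),
                 min_anchor = as.integer(min_anchor),
                 anchor_length_mean = anchor_length_mean),
            class = "PMMParams")
}

#' Classify an unpaired span by fold type
#'
#' The unpaired bases of a mispaired re-anneal are forced into a hairpin,
#' loop, or bulge when they number more than 8, 6 to 8, or fewer than 6,
#' respectively. Bulges are labile (they can slip along the strand and be
#' released); hairpins and loops hold the protrusion in place.
#'
#' @param unpaired_len number of unpaired bases (vectorised, `>= 0`).
#' @return character vector: `"none"` (0), `"bulge"` (< 6), `"loop"` (6-8)
#'   or `"hairpin"` (> 8).
#' @export
classify_fold <- function(unpaired_len) {
  if (any(unpaired_len < 0)) stop("unpaired_len must be nonnegative")
  ifelse(unpaired_len == 0, "none",
         ifelse(unpaired_len < 6, "bulge",
                ifelse(unpaired_len <= 8, "loop", "hairpin")))
}

#' Find the nearest out-of-register annealing site
#'
#' Deterministic primitive of the misalignment step: the 3' tail of the
#' nascent strand is slid back along the template and the nearest offset
#' (excluding the correct register) at which it anneals with identity at
#' least `min_identity` is returned. The template window is given 5'-3' in
#' template sense, positioned so that the correct register anneals the tail
#' at the window's end.
#'
#' @param nascent_3prime_tail DNA string (nonempty), 5'-3' nascent sense.
#' @param template_window DNA string, 5'-3' template sense.
#' @param min_identity required annealing identity in `(0, 1]`.
#' @return integer slip offset (bases), or `NA` when no site qualifies or
#'   the window is shorter than the tail.
#' @export
find_mispair_site <- function(nascent_3prime_tail, template_window,
                              min_identity) {
  stopifnot(nzchar(nascent_3prime_tail))
  tail_chars <- .chars(toupper(nascent_3prime_tail))
  win <- .chars(.revcomp(toupper(template_window)))  # nascent sense
  L <- length(tail_chars)
  W <- length(win)
  if (W < L) return(NA_integer_)
  for (d in seq_len(W - L)) {
    seg <- win[(W - L + 1L - d):(W - d)]
    ident <- mean(tail_chars == seg & tail_chars != "N")
    if (ident >= min_identity) return(d)
  }
  NA_integer_
}

# all qualifying slip offsets 1..d_max for a tail ending at `pos` of chars x
.mispair_candidates <- function(x, pos, tail_len, d_max, min_identity) {
  tail <- x[(pos - tail_len + 1L):pos]
  ds <- integer(0L)
  idents <- numeric(0L)
  for (d in seq_len(d_max)) {
    lo <- pos - tail_len + 1L - d
    if (lo < 1L) break
    seg <- x[lo:(pos - d)]
    ident <- mean(tail == seg & tail != "N")
    if (ident >= min_identity) {
      ds <- c(ds, d)
      idents <- c(idents, ident)
    }
  }
  list(ds = ds, idents = idents)
}

# position -> class lookup table from an annotated record: the CR is split
# at its midpoint into 5'/3' halves, CDS features are CDS, all else other
#' Position-class intervals for the PMM simulator
#'
#' @param record annotated `MtGenomeRecord` with an orientable control
#'   region.
#' @return tibble of non-wrapping intervals (`class`, `start`, `end`)
#'   covering the genome.
#' @export
position_classes <- function(record) {
  L <- record$length
  ori <- orient_control_region(record)
  cls <- rep("other", L)
  for (i in which(record$features$kind == "CDS")) {
    f <- record$features[i, ]
    for (r in seq_len(nrow(.circ_expand(f$start, f$end, L)))) {
      iv <- .circ_expand(f$start, f$end, L)[r, ]
      cls[iv[1L]:iv[2L]] <- "CDS"
    }
  }
  half <- ori$cr_length %/% 2L
  cr_pos <- (.circ_dist_fwd(1L, ori$cr_start, L) + seq_len(ori$cr_length) -
               1L) %% L + 1L
  off5 <- vapply(cr_pos, .cr_offset5, 0L, ori = ori, L = L)
  cls[cr_pos[off5 <= half]] <- "CR_5prime"
  cls[cr_pos[off5 > half]] <- "CR_3prime"
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  tibble::tibble(class = r$values,
                 start = ends - r$lengths + 1L,
                 end = ends)
}

.class_at <- function(classes, pos) {
  i <- which(classes$start <= pos & classes$end >= pos)
  if (length(i)) classes$class[i[1L]] else "other"
}

# shift class intervals after an indel of `delta` bases ending at `pos`
.shift_classes <- function(classes, pos, delta) {
  grow <- classes$end >= pos & classes$start <= pos
  after <- classes$start > pos
  classes$end[grow | after] <- classes$end[grow | after] + delta
  classes$start[after] <- classes$start[after] + delta
  classes[classes$end >= classes$start, , drop = FALSE]
}

.no_event <- function() NULL

.pmm_event_row <- function(replication_index, position, class, fold_class,
                           unpaired_len, outcome, motif, motif_count, birth,
                           identity, tail_len, delta) {
  tibble::tibble(replication_index = replication_index, position = position,
                 class = class, fold_class = fold_class,
                 unpaired_len = unpaired_len, outcome = outcome,
                 motif = motif, motif_count = motif_count, birth = birth,
                 identity = identity, tail_len = tail_len, delta = delta)
}

# single replication pass on a char vector; returns list(x, event)
.pmm_step <- function(x, classes, params, replication_index) {
  L <- length(x)
  pos <- sample.int(L, 1L)
  cls <- .class_at(classes, pos)
  if (stats::runif(1L) >= params$pause_profile[[cls]]) {
    return(list(x = x, event = NULL))
  }
  mmean <- params$melt_length_mean[[cls]] * params$competition_strength[[cls]]
  melt <- if (mmean <= 1) 1L else
    min(1L + stats::rgeom(1L, 1 / mmean), 2L * params$max_search_window)
  # the melted span holds both the re-annealing 3' anchor and the
  # looped-out bases, so a slip can reach at most melt - anchor back
  anchor <- min(melt, pos - 1L,
                params$min_anchor +
                  stats::rgeom(1L, 1 / (params$anchor_length_mean -
                                          params$min_anchor + 1)))
  abort <- .pmm_event_row(replication_index, pos, cls, "none", 0L,
                          "aborted_no_mispair", "", 0L, FALSE, NA_real_,
                          anchor, 0L)
  if (anchor < params$min_anchor) return(list(x = x, event = abort))
  d_max <- min(melt - anchor, params$max_search_window, pos - anchor)
  if (d_max < 1L) return(list(x = x, event = abort))
  cand <- .mispair_candidates(x, pos, anchor, d_max,
                              params$mispair_min_identity)
  if (!length(cand$ds)) return(list(x = x, event = abort))
  # the melted tail re-anneals at any qualifying register (uniform choice;
  # nearest-only annealing could never slip a full period twice)
  pick <- if (length(cand$ds) == 1L) 1L else
    sample.int(length(cand$ds), 1L)
  d <- cand$ds[pick]
  identity <- cand$idents[pick]
  fold <- classify_fold(d)
  if (fold == "bulge" && stats::runif(1L) < params$bulge_release_prob) {
    ev <- .pmm_event_row(replication_index, pos, cls, fold, d,
                         "aborted_release", "", 0L, FALSE, identity,
                         anchor, 0L)
    return(list(x = x, event = ev))
  }
  span <- x[(pos - d + 1L):pos]
  span_s <- .collapse(span)
  q <- .primitive_period(span_s)
  motif <- substr(span_s, 1L, q)
  count <- d %/% q
  insertion <- stats::runif(1L) < params$protrusion_side_prob_N
  if (insertion) {
    prev_copy <- if (pos - 2L * d >= 0L) x[(pos - 2L * d + 1L):(pos - d)]
                 else NULL
    birth <- is.null(prev_copy) || !identical(prev_copy, span)
    x2 <- append(x, span, after = pos)
    ev <- .pmm_event_row(replication_index, pos, cls, fold, d, "insertion",
                         motif, count, birth, identity, anchor, d)
  } else {
    birth <- FALSE
    x2 <- x[-((pos - d + 1L):pos)]
    ev <- .pmm_event_row(replication_index, pos, cls, fold, d, "deletion",
                         motif, count, birth, identity, anchor, -d)
  }
  list(x = x2, event = ev)
}

#' Simulate one replication pass
#'
#' One pass of the PMM mechanism: a candidate pause position is drawn
#' uniformly; a pause fires with its position class's probability; the
#' melted tail length is geometric with mean
#' `melt_length_mean * competition_strength` for that class; the tail
#' re-anneals at a qualifying out-of-register site no farther back than the
#' melt; the unpaired span folds per [classify_fold()], bulges abort with
#' `bulge_release_prob`; surviving events insert (protrusion on the nascent
#' strand) or delete (protrusion on the template) the slipped span.
#'
#' Randomness goes through R's RNG: call `set.seed()` (or use
#' [evolve_lineages()]) for reproducible runs.
#'
#' @param genome_seq DNA string.
#' @param annotations an annotated `MtGenomeRecord` or a
#'   [position_classes()] table.
#' @param params a [pmm_params()].
#' @param replication_index index recorded in the event row.
#' @return list with `seq` (possibly modified DNA string) and `event`
#'   (one-row tibble, or `NULL` when no pause fired).
#' @export
replicate_once <- function(genome_seq, annotations, params = pmm_params(),
                           replication_index = 1L) {
  stopifnot(nzchar(genome_seq), inherits(params, "PMMParams"))
  classes <- if (inherits(annotations, "MtGenomeRecord")) {
    position_classes(annotations)
  } else {
    annotations
  }
  res <- .pmm_step(.chars(toupper(genome_seq)), classes, params,
                   replication_index)
  list(seq = .collapse(res$x), event = res$event)
}

#' Evolve lineages under the PMM model
#'
#' Independently evolves `n_lineages` copies of an annotated founder genome
#' for `n_replications` passes each, returning final sequences, the full
#' event log, and summary statistics. Feature and class coordinates are
#' shifted along with every indel so position classes stay aligned with the
#' evolving sequence.
#'
#' @param founder annotated `MtGenomeRecord` (must have an orientable
#'   control region).
#' @param n_lineages number of independent lineages, default 50.
#' @param n_replications replication passes per lineage, default 500.
#' @param params a [pmm_params()].
#' @param seed optional integer seed; identical seeds give byte-identical
#'   output.
#' @param detect_final run [find_repeats()] on each final sequence and
#'   include copy-number/motif-length summaries of surviving repeats
#'   (slower), default `FALSE`.
#' @return list with `sequences` (named character vector), `events`
#'   (tibble, one row per pause event, with a `lineage` column), and
#'   `summary` (final lengths, per-class and per-outcome event counts,
#'   event motif-length table; plus detection summaries when
#'   `detect_final`).
#' @export
evolve_lineages <- function(founder, n_lineages = 50L, n_replications = 500L,
                            params = pmm_params(), seed = NULL,
                            detect_final = FALSE) {
  stopifnot(inherits(founder, "MtGenomeRecord"))
  if (!is.null(seed)) set.seed(seed)
  classes0 <- position_classes(founder)
  x0 <- .chars(founder$sequence)
  seqs <- character(n_lineages)
  logs <- list()
  for (ln in seq_len(n_lineages)) {
    x <- x0
    classes <- classes0
    for (r in seq_len(n_replications)) {
      res <- .pmm_step(x, classes, params, r)
      if (!is.null(res$event)) {
        ev <- res$event
        ev$lineage <- ln
        logs[[length(logs) + 1L]] <- ev
        if (ev$delta != 0L) {
          classes <- .shift_classes(classes, ev$position, ev$delta)
          x <- res$x
        }
      }
    }
    seqs[ln] <- .collapse(x)
  }
  names(seqs) <- sprintf("lineage_%03d", seq_len(n_lineages))
  events <- if (length(logs)) do.call(rbind, logs) else
    cbind(.pmm_event_row(integer(0L), integer(0L), character(0L),
                         character(0L), integer(0L), character(0L),
                         character(0L), integer(0L), logical(0L),
                         numeric(0L), integer(0L), integer(0L)),
          tibble::tibble(lineage = integer(0L)))
  applied <- events[events$outcome %in% c("insertion", "deletion"), ,
                    drop = FALSE]
  summary <- list(
    founder_length = founder$length,
    final_lengths = stats::setNames(nchar(seqs), names(seqs)),
    n_events = nrow(applied),
    events_by_class = table(applied$class),
    events_by_outcome = table(events$outcome),
    event_motif_lengths = table(nchar(applied$motif)))
  if (detect_final) {
    dets <- lapply(seqs, function(s) find_repeats(
      mt_genome_record(founder$id, s, circular = founder$circular)))
    all_det <- do.call(rbind, dets)
    summary$final_repeats <- all_det
    summary$copy_number_distribution <- table(all_det$copy_number)
    summary$final_motif_lengths <- table(all_det$motif_len)
  }
  list(sequences = seqs, events = tibble::as_tibble(events),
       summary = summary)
}
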