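# Tandem repeat detection with the survey's scoring scheme.
#
# Candidate periods come from exhaustive lag matching (every period up to
# max_period), extension is greedy with an x-drop, and the reported score is
# always the exact wraparound-DP score of the final tract against its
# consensus motif. This is a scoring-compatible detector, not a bit-exact
# clone of probabilistic k-tuple finders: determinism makes planted-truth
# and oracle tests exact.

#' Score a tract against the cyclic repetition of a motif
#'
#' Maximum global alignment score of `tract_seq` against the infinite cyclic
#' repetition of `motif` (wraparound dynamic programming). Every tract base
#' is aligned; the motif phase is free at both ends, so a perfect tract of
#' length L scores `match * L`. N mismatches everything.
#'
#' @param tract_seq DNA string (nonempty).
#' @param motif DNA string (nonempty).
#' @param match,mismatch,indel alignment weights; defaults are the survey's
#'   +2/-7/-7.
#' @return integer alignment score.
#' @examples
#' score_tract(strrep("TTTAATGT", 4), "TTTAATGT")  # 64
#' @export
score_tract <- function(tract_seq, motif, match = 2L, mismatch = -7L,
                        indel = -7L) {
  if (!nzchar(motif)) stop("motif must be nonempty")
  if (!nzchar(tract_seq)) stop("tract must be nonempty")
  .wdp_score(toupper(tract_seq), toupper(motif),
             as.integer(match), as.integer(mismatch), as.integer(indel))
}

#' Lexicographically smallest rotation of a motif
#'
#' Used as a deduplication key so that the same tandem array reported in two
#' phases compares equal; not used for display.
#'
#' @param motif DNA string (nonempty).
#' @return the canonical rotation.
#' @export
motif_canonical <- function(motif) {
  if (!nzchar(motif)) stop("motif must be nonempty")
  n <- nchar(motif)
  d <- paste0(motif, motif)
  rots <- substring(d, seq_len(n), seq_len(n) + n - 1L)
  min(rots)
}

# column-majority consensus over full copies of period p, phase anchored at
# `anchor` (1-based index into chars); returns motif in the frame of `from`
.consensus_motif <- function(x, from, to, p, anchor) {
  idx <- from:to
  col <- ((idx - anchor) %% p) + 1L
  cons <- character(p)
  for (j in seq_len(p)) {
    b <- x[idx[col == j]]
    b <- b[b != "N"]
    cons[j] <- if (length(b)) names(which.max(table(b))) else "N"
  }
  # rotate so the consensus reads in the frame of the tract start
  off <- ((from - anchor) %% p)
  .collapse(cons[((seq_len(p) - 1L + off) %% p) + 1L])
}

# greedy x-drop extension: walk from `pos` in direction `dir`, comparing to
# the cyclic motif (phase anchored at `anchor`), return furthest position
# with maximal cumulative score (match +2 / mismatch -7), or NA if none > 0
.extend <- function(x, pos, dir, motif_chars, p, anchor, n, xdrop = 21L) {
  best <- 0L; best_pos <- NA_integer_; cum <- 0L
  t <- pos
  while (t >= 1L && t <= n) {
    mc <- motif_chars[((t - anchor) %% p) + 1L]
    cum <- cum + if (x[t] == mc && x[t] != "N") 2L else -7L
    if (cum > best) { best <- cum; best_pos <- t }
    if (cum < best - xdrop) break
    t <- t + dir
  }
  best_pos
}

#' Detect tandem repeats on a (circular) genome
#'
#' Candidate periods are proposed by exact lag matching at every period up to
#' `max_period`; runs of matching positions (merged across gaps of up to 3,
#' i.e. across substitutions) seed a greedy extension against the anchor
#' motif, and the final tract is rescored exactly with [score_tract()]
#' against its column-majority consensus. On circular genomes the doubled
#' sequence is scanned and calls are deduplicated back to genome coordinates;
#' origin-wrapping tracts are reported with `start > end`. Overlapping calls
#' of the same (or harmonically related) period keep the highest-scoring
#' extension, ties breaking toward smaller period, then smaller start.
#'
#' @param record an `MtGenomeRecord`, or a plain DNA string (treated as a
#'   linear sequence).
#' @param min_score report threshold; strictly exceeded (`score > min_score`),
#'   default 50.
#' @param max_period largest motif length considered, default 500.
#' @return tibble with columns `genome_id`, `start`, `end`, `motif`,
#'   `motif_len`, `copy_number` (1 decimal), `score`, `percent_match`;
#'   zero rows when nothing qualifies. Every reported tract has
#'   `copy_number >= 2`.
#' @export
find_repeats <- function(record, min_score = 50L, max_period = 500L) {
  if (is.character(record)) {
    record <- mt_genome_record("seq", record, circular = FALSE)
  }
  empty <- tibble::tibble(genome_id = character(), start = integer(),
                          end = integer(), motif = character(),
                          motif_len = integer(), copy_number = numeric(),
                          score = integer(), percent_match = numeric())
  L <- record$length
  if (L < 4L) return(empty)
  S <- if (record$circular) paste0(record$sequence, record$sequence)
       else record$sequence
  x <- .chars(S)
  n <- length(x)
  maxp <- min(max_period, L %/% 2L)

  cand <- list()
  for (p in seq_len(maxp)) {
    if (n - p < 2L) break
    eq <- x[seq_len(n - p)] == x[(p + 1L):n] & x[seq_len(n - p)] != "N"
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    if (!length(keep)) next
    # merge TRUE runs across gaps <= 3 (a substitution breaks the lag match
    # at two single positions)
    rs <- starts[keep]; re <- ends[keep]
    merged_s <- rs[1L]; merged_e <- re[1L]; M <- re[1L] - rs[1L] + 1L
    best_run_s <- rs[1L]; best_run_len <- M
    regions <- list()
    flush <- function(s0, e0, m0, bs) {
      if (e0 - s0 + 1L >= p - 2L && 2L * (m0 + p) > min_score) {
        regions[[length(regions) + 1L]] <<- c(s0, e0, bs)
      }
    }
    if (length(keep) > 1L) {
      for (i in 2L:length(keep)) {
        if (rs[i] - merged_e - 1L <= 3L) {
          merged_e <- re[i]
          M <- M + re[i] - rs[i] + 1L
          if (re[i] - rs[i] + 1L > best_run_len) {
            best_run_len <- re[i] - rs[i] + 1L
            best_run_s <- rs[i]
          }
        } else {
          flush(merged_s, merged_e, M, best_run_s)
          merged_s <- rs[i]; merged_e <- re[i]
          M <- re[i] - rs[i] + 1L
          best_run_s <- rs[i]; best_run_len <- M
        }
      }
    }
    flush(merged_s, merged_e, M, best_run_s)
    for (rg in regions) {
      anchor <- rg[3L]
      if (anchor + p - 1L > n) next
      motif_chars <- x[anchor:(anchor + p - 1L)]
      ts <- .extend(x, anchor - 1L, -1L, motif_chars, p, anchor, n)
      te <- .extend(x, anchor + p, +1L, motif_chars, p, anchor, n)
      ts <- if (is.na(ts)) anchor else ts
      te <- if (is.na(te)) anchor + p - 1L else te
      span <- te - ts + 1L
      if (span < 2L * p || span > L) next
      cons <- .consensus_motif(x, ts, te, p, anchor)
      q <- .primitive_period(cons)
      motif <- substr(cons, 1L, q)
      sc <- .wdp_score(.collapse(x[ts:te]), motif, 2L, -7L, -7L)
      if (sc <= min_score) next
      mc2 <- .chars(motif)
      matches <- sum(x[ts:te] == mc2[((ts:te - ts) %% q) + 1L])
      cand[[length(cand) + 1L]] <- list(
        start = ts, end = te, p = q, motif = motif, score = sc,
        pm = round(100 * matches / span, 1))
    }
  }
  if (!length(cand)) return(empty)

  df <- do.call(rbind, lapply(cand, function(cc) {
    data.frame(start = cc$start, end = cc$end, p = cc$p, motif = cc$motif,
               score = cc$score, pm = cc$pm, stringsAsFactors = FALSE)
  }))
  # map to genome coordinates and drop doubled-sequence duplicates
  if (record$circular) {
    df <- df[df$start <= L, , drop = FALSE]
    df$gstart <- df$start
    df$gend <- ifelse(df$end > L, df$end - L, df$end)
  } else {
    df$gstart <- df$start
    df$gend <- df$end
  }
  if (!nrow(df)) return(empty)
  df$span <- mapply(.circ_len, df$gstart, df$gend, MoreArgs = list(len = L))
  df$key <- vapply(df$motif, motif_canonical, "")
  df <- df[order(-df$score, df$p, df$gstart), , drop = FALSE]

  acc <- df[0L, , drop = FALSE]
  for (i in seq_len(nrow(df))) {
    ci <- df[i, ]
    dup <- FALSE
    if (nrow(acc)) {
      for (j in seq_len(nrow(acc))) {
        aj <- acc[j, ]
        ov <- .circ_overlap(ci$gstart, ci$gend, aj$gstart, aj$gend, L)
        harmonic <- (ci$p %% aj$p == 0L) || (aj$p %% ci$p == 0L)
        if (ov >= 0.5 * ci$span && (harmonic || ci$key == aj$key)) {
          dup <- TRUE
          break
        }
      }
    }
    if (!dup) acc <- rbind(acc, ci)
  }
  acc <- acc[order(acc$gstart, acc$p), , drop = FALSE]
  tibble::tibble(
    genome_id = record$id,
    start = as.integer(acc$gstart),
    end = as.integer(acc$gend),
    motif = acc$motif,
    motif_len = as.integer(acc$p),
    copy_number = round(acc$span / acc$p, 1),
    score = as.integer(acc$score),
    percent_match = acc$pm)
}
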