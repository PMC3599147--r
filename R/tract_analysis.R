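# Motif-level tract encoding, clone diffing with ambiguity intervals, and
# the birth signature of newly generated repeats.

#' Define a motif alphabet
#'
#' A canonical motif plus named single-base (or up to `max_hamming`-base)
#' variants, e.g. the flounder 3'-TR alphabet TTTAATGT with variants
#' v1 = TGTAATGT and v2 = TATAATGT.
#'
#' @param canonical DNA motif.
#' @param variants named character vector of variant motifs, each the same
#'   length as `canonical` and within `max_hamming` of it.
#' @param max_hamming maximum Hamming distance for a window to be assigned a
#'   symbol; default 1 (the "varied by a single base" convention).
#' @param canonical_symbol symbol used for the canonical motif, default "R".
#' @return object of class `MotifAlphabet`: list with `motifs` (named,
#'   canonical first), `canonical`, `motif_len`, `max_hamming`.
#' @export
motif_alphabet <- function(canonical, variants = character(),
                           max_hamming = 1L, canonical_symbol = "R") {
  canonical <- toupper(canonical)
  stopifnot(nzchar(canonical))
  if (length(variants)) {
    if (is.null(names(variants)) || any(!nzchar(names(variants)))) {
      stop("variants must be named")
    }
    variants <- vapply(variants, toupper, "")
    if (any(nchar(variants) != nchar(canonical))) {
      stop("all motifs must have equal length")
    }
    dists <- vapply(variants, .hamming, 0, b = canonical)
    if (any(dists > max_hamming)) {
      stop("variant(s) beyond max_hamming of canonical: ",
           paste(names(variants)[dists > max_hamming], collapse = ", "))
    }
  }
  motifs <- c(stats::setNames(canonical, canonical_symbol), variants)
  if (anyDuplicated(names(motifs))) stop("symbols must be unique")
  structure(list(motifs = motifs, canonical = canonical_symbol,
                 motif_len = nchar(canonical),
                 max_hamming = as.integer(max_hamming)),
            class = "MotifAlphabet")
}

#' Decompose a tract into motif symbols
#'
#' Greedy left-to-right segmentation into motif-length windows; each window
#' takes the alphabet symbol of minimum Hamming distance if that distance is
#' within `max_hamming`, and the first unassignable window terminates the
#' tract (the rest becomes `residual_suffix` — no chimeric encodings). The
#' reading frame is chosen over all `motif_len` offsets to maximise the
#' number of assigned symbols, ties to the smallest offset.
#'
#' @param seq DNA string.
#' @param alphabet a [motif_alphabet()].
#' @param clone_id identifier carried on the encoding.
#' @return object of class `TractEncoding`: list with `clone_id`, `symbols`
#'   (character vector), `residual_prefix`, `residual_suffix`, `alphabet`.
#'   Decoding reproduces the input exactly (see [decode_encoding()]).
#' @export
decompose <- function(seq, alphabet, clone_id = NA_character_) {
  stopifnot(inherits(alphabet, "MotifAlphabet"))
  seq <- toupper(seq)
  p <- alphabet$motif_len
  n <- nchar(seq)
  mot_chars <- lapply(alphabet$motifs, .chars)
  best <- NULL
  if (n >= p) {
    x <- .chars(seq)
    for (f in 0:(p - 1L)) {
      pos <- f + 1L
      syms <- character(0L)
      while (pos + p - 1L <= n) {
        w <- x[pos:(pos + p - 1L)]
        d <- vapply(mot_chars, function(m) sum(m != w), 0)
        if (min(d) <= alphabet$max_hamming) {
          syms <- c(syms, names(alphabet$motifs)[which.min(d)])
          pos <- pos + p
        } else break
      }
      enc <- list(clone_id = clone_id, symbols = syms,
                  residual_prefix = substr(seq, 1L, f),
                  residual_suffix = substr(seq, pos, n),
                  alphabet = alphabet)
      if (is.null(best) || length(syms) > length(best$symbols)) best <- enc
    }
  } else {
    best <- list(clone_id = clone_id, symbols = character(0L),
                 residual_prefix = "", residual_suffix = seq,
                 alphabet = alphabet)
  }
  structure(best, class = "TractEncoding")
}

#' Reassemble the DNA of a tract encoding
#'
#' @param encoding a `TractEncoding`.
#' @return DNA string: `residual_prefix` + the symbols' motifs +
#'   `residual_suffix`.
#' @export
decode_encoding <- function(encoding) {
  a <- encoding$alphabet
  paste0(encoding$residual_prefix,
         paste(a$motifs[encoding$symbols], collapse = ""),
         encoding$residual_suffix)
}

#' @export
print.TractEncoding <- function(x, ...) {
  cat(sprintf("TractEncoding %s: %d copies [%s]%s%s\n",
              x$clone_id, length(x$symbols),
              paste(x$symbols, collapse = "."),
              if (nzchar(x$residual_prefix)) " +prefix" else "",
              if (nzchar(x$residual_suffix)) " +suffix" else ""))
  invisible(x)
}

.same_alphabet <- function(a, b) {
  identical(a$alphabet$motifs, b$alphabet$motifs)
}

.indel_call_cols <- function() {
  tibble::tibble(kind = character(), motif_count = integer(),
                 symbols = character(), ambiguity_start = integer(),
                 ambiguity_end = integer(), edit_distance = integer())
}

# symbol-level Levenshtein distance via utils::adist on a 1-char remapping
.symbol_edit_distance <- function(sa, sb) {
  syms <- unique(c(sa, sb))
  letters_pool <- c(letters, LETTERS, as.character(0:9))
  stopifnot(length(syms) <= length(letters_pool))
  map <- stats::setNames(letters_pool[seq_along(syms)], syms)
  as.integer(utils::adist(paste(map[sa], collapse = ""),
                          paste(map[sb], collapse = "")))
}

#' Diff two tract encodings
#'
#' Finds the single contiguous motif-indel events (runs of one or more
#' symbols) that convert encoding `a` into encoding `b`. The ambiguity
#' interval of a call is the maximal range of copy positions (1-based, in
#' the longer encoding) at which the same symbol run can be removed or
#' inserted with identical result: every placement of the run inside the
#' interval yields the same outcome, and no wider interval has that
#' property. For a one-symbol indel inside a run of identical symbols the
#' interval spans the whole run, mirroring the "any site from the 5th to
#' the 29th copy" style of reasoning about clone comparisons. Identical encodings give zero rows. When no single-event
#' explanation exists and `max_events > 1`, a minimal multi-event
#' (indel-only alignment) explanation is reported with point intervals;
#' otherwise a single `kind = "complex"` row carries the symbol-level edit
#' distance.
#'
#' @param a,b `TractEncoding`s over the same alphabet.
#' @param max_events maximum number of contiguous events considered
#'   (default 1).
#' @return tibble with columns `kind` (insertion/deletion/complex),
#'   `motif_count`, `symbols` (the run, dot-separated), `ambiguity_start`,
#'   `ambiguity_end`, `edit_distance` (`NA` except for complex rows).
#' @export
diff_encodings <- function(a, b, max_events = 1L) {
  stopifnot(inherits(a, "TractEncoding"), inherits(b, "TractEncoding"))
  if (!.same_alphabet(a, b)) stop("encodings use different alphabets")
  sa <- a$symbols
  sb <- b$symbols
  if (identical(sa, sb)) return(.indel_call_cols())

  d <- length(sa) - length(sb)
  if (d != 0L) {
    longer <- if (d > 0L) sa else sb
    shorter <- if (d > 0L) sb else sa
    k <- abs(d)
    nl <- length(longer)
    valid <- list()
    for (i in seq_len(nl - k + 1L)) {
      if (identical(longer[-(i:(i + k - 1L))], shorter)) {
        valid[[length(valid) + 1L]] <-
          list(pos = i, content = paste(longer[i:(i + k - 1L)],
                                        collapse = "."))
      }
    }
    if (length(valid)) {
      contents <- vapply(valid, `[[`, "", "content")
      poss <- vapply(valid, `[[`, 0L, "pos")
      kind <- if (d > 0L) "deletion" else "insertion"
      rows <- lapply(unique(contents), function(ct) {
        p <- poss[contents == ct]
        # the interval covers every copy the run could have touched: any
        # placement of the k-symbol run inside it gives the same result
        tibble::tibble(kind = kind, motif_count = k, symbols = ct,
                       ambiguity_start = min(p),
                       ambiguity_end = max(p) + k - 1L,
                       edit_distance = NA_integer_)
      })
      return(do.call(rbind, rows))
    }
  }

  if (max_events > 1L) {
    ev <- .indel_alignment_events(sa, sb)
    if (!is.null(ev) && nrow(ev) <= max_events) {
      ev$edit_distance <- NA_integer_
      return(ev)
    }
  }
  tibble::tibble(kind = "complex", motif_count = NA_integer_,
                 symbols = NA_character_, ambiguity_start = NA_integer_,
                 ambiguity_end = NA_integer_,
                 edit_distance = .symbol_edit_distance(sa, sb))
}

# indel-only alignment (LCS); returns one row per contiguous gap run, or
# NULL when the symbols cannot be aligned by indels alone
.indel_alignment_events <- function(sa, sb) {
  na <- length(sa); nb <- length(sb)
  # LCS dynamic programme
  D <- matrix(0L, na + 1L, nb + 1L)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      D[i + 1L, j + 1L] <- if (sa[i] == sb[j]) D[i, j] + 1L
                           else max(D[i, j + 1L], D[i + 1L, j])
    }
  }
  # traceback into runs of deletions (from a) and insertions (from b);
  # an LCS alignment is indel-only by construction
  i <- na; j <- nb
  ops <- list()
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L && sa[i] == sb[j] && D[i + 1L, j + 1L] == D[i, j] + 1L) {
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && D[i + 1L, j + 1L] == D[i, j + 1L]) {
      ops[[length(ops) + 1L]] <- list(kind = "deletion", sym = sa[i], pos = i)
      i <- i - 1L
    } else {
      ops[[length(ops) + 1L]] <- list(kind = "insertion", sym = sb[j], pos = j)
      j <- j - 1L
    }
  }
  if (!length(ops)) return(NULL)
  ops <- rev(ops)
  rows <- list()
  cur <- NULL
  for (op in ops) {
    if (!is.null(cur) && op$kind == cur$kind && op$pos == cur$last + 1L) {
      cur$syms <- c(cur$syms, op$sym)
      cur$last <- op$pos
    } else {
      if (!is.null(cur)) rows[[length(rows) + 1L]] <- cur
      cur <- list(kind = op$kind, syms = op$sym, first = op$pos,
                  last = op$pos)
    }
  }
  rows[[length(rows) + 1L]] <- cur
  do.call(rbind, lapply(rows, function(r) {
    tibble::tibble(kind = r$kind, motif_count = length(r$syms),
                   symbols = paste(r$syms, collapse = "."),
                   ambiguity_start = r$first, ambiguity_end = r$last,
                   edit_distance = NA_integer_)
  }))
}

#' Detect the birth signature of a new repeat
#'
#' Finds maximal exact tandem duplications (unit length at least `min_unit`,
#' at least `min_copies` exact copies) and reports, for each, the
#' `prefix_overlap`: the number of leading unit bases that also appear
#' immediately after the last full copy. A newly born repeat carries this
#' hallmark — the first bases of its unit equal the bases following the
#' tract — because the duplication arises from a mispaired re-anneal
#' anchored on a short sequence present at both ends of the copied span.
#'
#' @param region DNA string (nonempty).
#' @param min_unit minimal duplicated-unit length, default 8.
#' @param min_copies minimal number of exact copies, default 2.
#' @return tibble with `start`, `unit`, `unit_len`, `copies`,
#'   `prefix_overlap`, `overlap_seq`; zero rows when no duplication exists.
#' @export
detect_birth <- function(region, min_unit = 8L, min_copies = 2L) {
  region <- toupper(region)
  if (!nzchar(region)) stop("region must be nonempty")
  x <- .chars(region)
  n <- length(x)
  out <- list()
  if (n >= 2L * min_unit) {
    for (u in min_unit:(n %/% min_copies)) {
      eq <- x[seq_len(n - u)] == x[(u + 1L):n] & x[seq_len(n - u)] != "N"
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (i in which(r$values & r$lengths >= u * (min_copies - 1L))) {
        run_len <- r$lengths[i]
        copies <- run_len %/% u + 1L
        start <- starts[i]
        unit <- .collapse(x[start:(start + u - 1L)])
        if (.primitive_period(unit) < u) next  # harmonic of a smaller unit
        overlap <- run_len - (copies - 1L) * u
        out[[length(out) + 1L]] <- tibble::tibble(
          start = start, unit = unit, unit_len = u, copies = copies,
          prefix_overlap = overlap,
          overlap_seq = substr(unit, 1L, overlap))
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(start = integer(), unit = character(),
                          unit_len = integer(), copies = integer(),
                          prefix_overlap = integer(),
                          overlap_seq = character()))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$unit_len), ]
}

#' Copy-number statistics over clone encodings
#'
#' @param encodings list of `TractEncoding`s; encodings with zero symbols
#'   are excluded with a warning.
#' @return list with `min_copies`, `max_copies` and `table` (tibble
#'   `clone_id`, `copies`, `tract_len` where `tract_len = copies *
#'   motif_len`).
#' @export
copy_number_stats <- function(encodings) {
  stopifnot(length(encodings) > 0L)
  nsym <- vapply(encodings, function(e) length(e$symbols), 0L)
  if (any(nsym == 0L)) {
    warning(sum(nsym == 0L), " empty encoding(s) excluded")
    encodings <- encodings[nsym > 0L]
  }
  if (!length(encodings)) stop("no nonempty encodings")
  tab <- do.call(rbind, lapply(encodings, function(e) {
    tibble::tibble(clone_id = e$clone_id, copies = length(e$symbols),
                   tract_len = length(e$symbols) * e$alphabet$motif_len)
  }))
  list(min_copies = min(tab$copies), max_copies = max(tab$copies),
       table = tab)
}
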