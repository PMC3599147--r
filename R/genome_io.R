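# Reading/writing annotated mitochondrial genomes and circular coordinates.

.FEATURE_KINDS <- c("CDS", "tRNA", "rRNA", "control_region",
                    "TAS_block", "CSB_block", "other")
.TAXON_CLASSES <- c("Pisces", "Amphibia", "Reptilia", "Aves", "Mammalia",
                    "unknown")

#' Construct an annotated mitochondrial genome record
#'
#' The central container of the pipeline: an (optionally circular) DNA
#' sequence plus an ordered feature table. Coordinates are 1-based inclusive
#' throughout (GenBank convention); a feature stored with `start > end` wraps
#' the replication origin, which is only legal on a circular genome.
#'
#' @param id text identifier.
#' @param sequence DNA string; uppercased on input, alphabet A/C/G/T/N.
#' @param circular logical; circular topology.
#' @param features a data frame as built by [mt_feature()] (columns `kind`,
#'   `name`, `start`, `end`, `strand`); may be empty.
#' @param taxon_class one of Pisces, Amphibia, Reptilia, Aves, Mammalia,
#'   unknown.
#' @return an object of class `MtGenomeRecord`: a list with fields `id`,
#'   `sequence`, `length`, `circular`, `features`, `taxon_class`.
#' @examples
#' g <- mt_genome_record("x", "ACGTACGTAC",
#'                       features = mt_feature("CDS", "ND1", 2, 7))
#' g$length
#' @export
mt_genome_record <- function(id, sequence, circular = TRUE,
                             features = NULL, taxon_class = "unknown") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  if (!nzchar(sequence)) stop("sequence must be nonempty")
  bad <- setdiff(unique(.chars(sequence)), c("A", "C", "G", "T", "N"))
  if (length(bad)) {
    stop("non-ACGTN characters in sequence: ", paste(bad, collapse = ", "))
  }
  taxon_class <- match.arg(taxon_class, .TAXON_CLASSES)
  len <- nchar(sequence)
  if (is.null(features)) features <- mt_feature()[0L, ]
  features <- tibble::as_tibble(features)
  if (nrow(features)) {
    stopifnot(all(c("kind", "name", "start", "end", "strand") %in%
                    names(features)))
    if (!all(features$kind %in% .FEATURE_KINDS)) {
      stop("unknown feature kind(s): ",
           paste(setdiff(features$kind, .FEATURE_KINDS), collapse = ", "))
    }
    if (any(!nzchar(features$name))) stop("feature names must be nonempty")
    if (any(features$start < 1L | features$start > len |
            features$end < 1L | features$end > len)) {
      stop("feature coordinates outside [1, ", len, "]")
    }
    if (!circular && any(features$start > features$end)) {
      stop("origin-wrapping feature on a linear record")
    }
  }
  structure(
    list(id = id, sequence = sequence, length = len,
         circular = isTRUE(circular), features = features,
         taxon_class = taxon_class),
    class = "MtGenomeRecord"
  )
}

#' @export
print.MtGenomeRecord <- function(x, ...) {
  cat(sprintf("MtGenomeRecord %s: %d bp, %s, %d feature(s), class %s\n",
              x$id, x$length, if (x$circular) "circular" else "linear",
              nrow(x$features), x$taxon_class))
  invisible(x)
}

#' Build a feature table row
#'
#' @param kind one of CDS, tRNA, rRNA, control_region, TAS_block, CSB_block,
#'   other.
#' @param name feature name, e.g. `"tRNA-Phe"` or `"CSB3"`.
#' @param start,end 1-based inclusive coordinates; `start > end` marks an
#'   origin-wrapping feature on a circular genome.
#' @param strand `"+"` or `"-"` (heavy-strand sense is `"+"`).
#' @return a one-row tibble (or an empty prototype when called without
#'   arguments); rows from multiple calls can be combined with `rbind()`.
#' @export
mt_feature <- function(kind = character(), name = character(),
                       start = integer(), end = integer(), strand = "+") {
  if (length(kind)) {
    stopifnot(kind %in% .FEATURE_KINDS, nzchar(name))
    strand <- rep_len(strand, length(kind))
  } else {
    strand <- character()
  }
  tibble::tibble(kind = as.character(kind), name = as.character(name),
                 start = as.integer(start), end = as.integer(end),
                 strand = strand)
}

# control-region synonyms seen across GenBank annotations
.is_cr_name <- function(txt) {
  grepl("d-?loop|control[ _-]?region|\\bCR\\b|\\bcontrol\\b", txt,
        ignore.case = TRUE)
}

.qualifier <- function(lines, name) {
  rx <- paste0("^/", name, "=")
  hit <- grep(rx, lines, value = TRUE)
  if (!length(hit)) return(NA_character_)
  gsub('^"|"$', "", sub(rx, "", hit[1L]))
}

# "123..456", "complement(...)", "join(a..b,c..d)" (origin wrap), "<1..>99"
.parse_location <- function(loc) {
  strand <- if (grepl("complement", loc)) "-" else "+"
  inner <- gsub("complement\\(|join\\(|order\\(|\\)", "", loc)
  inner <- gsub("[<>]", "", inner)
  parts <- strsplit(inner, ",", fixed = TRUE)[[1L]]
  rng <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^([0-9]+)\\.\\.([0-9]+)$", p))[[1L]]
    if (length(m) == 3L) {
      as.integer(m[2:3])
    } else if (grepl("^[0-9]+$", p)) {
      rep(as.integer(p), 2L)
    } else {
      NULL
    }
  })
  if (any(vapply(rng, is.null, logical(1L)))) return(NULL)
  start <- rng[[1L]][1L]
  end <- rng[[length(rng)]][2L]
  list(start = start, end = end, strand = strand,
       wraps = length(rng) > 1L && end < start)
}

.feature_from_gb <- function(key, loc, quals) {
  name <- .qualifier(quals, "product")
  if (is.na(name)) name <- .qualifier(quals, "gene")
  note <- .qualifier(quals, "note")
  if (is.na(name)) name <- note
  kind <- switch(key,
    "CDS" = "CDS",
    "tRNA" = "tRNA",
    "rRNA" = "rRNA",
    "D-loop" = "control_region",
    NULL)
  if (is.null(kind)) {
    kind <- if (!is.na(note) && .is_cr_name(note)) "control_region"
            else if (!is.na(name) && .is_cr_name(name)) "control_region"
            else if (!is.na(note) && grepl("TAS", note)) "TAS_block"
            else if (!is.na(note) && grepl("CSB", note)) "CSB_block"
            else "other"
  }
  if (kind == "control_region" && (is.na(name) || !nzchar(name))) {
    name <- "control region"
  }
  if (is.na(name) || !nzchar(name)) name <- key
  mt_feature(kind, name, loc$start, loc$end, loc$strand)
}

#' Read GenBank flat files
#'
#' Minimal reader for the GenBank flat-file records the survey consumes:
#' LOCUS topology, the feature table (CDS/tRNA/rRNA/D-loop plus
#' control-region synonyms on misc_features), and the ORIGIN sequence.
#' Origin-spanning `join(x..L,1..y)` locations are stored with
#' `start = x, end = y` (the wrap convention of [mt_genome_record()]).
#'
#' @param path path to a GenBank flat file (one or more records).
#' @return list of [mt_genome_record()] objects; empty list for an empty
#'   file.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (!length(lines) || !any(nzchar(lines))) return(list())
  starts <- grep("^LOCUS", lines)
  if (!length(starts)) stop("no LOCUS line found in ", path)
  if (any(nzchar(trimws(lines[seq_len(starts[1L] - 1L)])))) {
    stop("malformed GenBank file ", path, ": text before first LOCUS")
  }
  ends <- c(starts[-1L] - 1L, length(lines))
  lapply(seq_along(starts), function(k) {
    .parse_gb_record(lines[starts[k]:ends[k]], path, k)
  })
}

.parse_gb_record <- function(rl, path, k) {
  locus <- rl[1L]
  toks <- strsplit(trimws(locus), "[[:space:]]+")[[1L]]
  if (length(toks) < 2L) stop("malformed LOCUS line in record ", k,
                              " of ", path)
  id <- toks[2L]
  circular <- grepl("circular", locus, ignore.case = TRUE)

  taxon <- "unknown"
  cls <- grep("taxon_class:", rl, value = TRUE)
  if (length(cls)) {
    m <- sub(".*taxon_class:([A-Za-z]+).*", "\\1", cls[1L])
    if (m %in% .TAXON_CLASSES) taxon <- m
  }

  # sequence
  oi <- grep("^ORIGIN", rl)
  if (!length(oi)) stop("record ", id, " in ", path, " has no ORIGIN section")
  seq_lines <- rl[(oi[1L] + 1L):length(rl)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("record ", id, " in ", path,
                              " has no sequence")

  # feature table
  features <- mt_feature()
  fi <- grep("^FEATURES", rl)
  if (length(fi)) {
    ft <- rl[(fi[1L] + 1L):(oi[1L] - 1L)]
    ft <- ft[nzchar(trimws(ft))]
    is_key <- grepl("^ {5}\\S", ft)
    idx <- cumsum(is_key)
    for (g in split(ft, idx)) {
      if (!grepl("^ {5}\\S", g[1L])) next
      head_toks <- strsplit(trimws(g[1L]), "[[:space:]]+")[[1L]]
      key <- head_toks[1L]
      if (key == "source") next
      loc_txt <- paste0(head_toks[-1L], collapse = "")
      rest <- trimws(g[-1L])
      qual_start <- grep("^/", rest)
      if (length(qual_start)) {
        # continuation lines of the location precede the first qualifier
        if (qual_start[1L] > 1L) {
          loc_txt <- paste0(loc_txt,
                            paste0(rest[seq_len(qual_start[1L] - 1L)],
                                   collapse = ""))
        }
        quals <- rest[qual_start[1L]:length(rest)]
      } else {
        loc_txt <- paste0(loc_txt, paste0(rest, collapse = ""))
        quals <- character()
      }
      loc <- .parse_location(loc_txt)
      if (is.null(loc)) {
        stop("record ", id, " in ", path,
             ": cannot parse feature location '", loc_txt, "'")
      }
      if (loc$start > loc$end && !circular && !loc$wraps) {
        stop("record ", id, " in ", path, ": start > end on linear record")
      }
      features <- rbind(features, .feature_from_gb(key, loc, quals))
    }
  }
  mt_genome_record(id, sequence, circular = circular, features = features,
                   taxon_class = taxon)
}

#' Write GenBank flat files
#'
#' Inverse of [read_genbank()] for synthetic fixtures; a written record reads
#' back with identical sequence, features and topology.
#'
#' @param records a single `MtGenomeRecord` or a list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(records, path) {
  if (inherits(records, "MtGenomeRecord")) records <- list(records)
  out <- unlist(lapply(records, .format_gb_record))
  writeLines(out, path)
  invisible(path)
}

.format_gb_record <- function(rec) {
  topo <- if (rec$circular) "circular" else "linear"
  kind_key <- c(CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                control_region = "D-loop", TAS_block = "misc_feature",
                CSB_block = "misc_feature", other = "misc_feature")
  out <- c(
    sprintf("LOCUS       %s %d bp    DNA     %s SYN", rec$id, rec$length,
            topo),
    sprintf("DEFINITION  %s synthetic mitochondrial genome.", rec$id),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", rec$length),
    sprintf("                     /note=\"taxon_class:%s\"", rec$taxon_class)
  )
  if (nrow(rec$features)) {
    for (i in seq_len(nrow(rec$features))) {
      f <- rec$features[i, ]
      loc <- if (f$start <= f$end) {
        sprintf("%d..%d", f$start, f$end)
      } else {
        sprintf("join(%d..%d,1..%d)", f$start, rec$length, f$end)
      }
      if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
      out <- c(out, sprintf("     %-15s %s", kind_key[[f$kind]], loc),
               sprintf("                     /product=\"%s\"", f$name))
      if (f$kind %in% c("TAS_block", "CSB_block")) {
        out <- c(out, sprintf("                     /note=\"%s\"",
                              sub("_block$", "", f$kind)))
      }
    }
  }
  out <- c(out, "ORIGIN")
  s <- tolower(rec$sequence)
  pos <- seq(1L, nchar(s), by = 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59L, nchar(s)))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", p, paste(groups, collapse = " ")))
  }
  c(out, "//")
}

#' Read a FASTA file
#'
#' @param path path to FASTA text.
#' @return tibble with columns `id` (first whitespace token of the header)
#'   and `sequence` (uppercased). Non-IUPAC characters raise an error listing
#'   the offending symbols.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(gsub("[[:space:]]", "", as.character(ss)))
  iupac <- .chars("ACGTNRYSWKMBDHV")
  bad <- setdiff(unique(unlist(strsplit(seqs, ""))), iupac)
  if (length(bad)) {
    stop("non-IUPAC characters in ", path, ": ", paste(bad, collapse = ", "))
  }
  ids <- vapply(strsplit(names(ss), "[[:space:]]+"), `[`, "", 1L)
  tibble::tibble(id = ids, sequence = unname(seqs))
}

#' Write a FASTA file
#'
#' @param x tibble with `id` and `sequence` columns, or a named character
#'   vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.data.frame(x)) {
    seqs <- stats::setNames(x$sequence, x$id)
  } else {
    seqs <- x
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Extract a subsequence with circular coordinates
#'
#' @param record an `MtGenomeRecord` (or plain DNA string, treated as
#'   circular).
#' @param start,end 1-based inclusive; `start > end` wraps the origin and is
#'   only legal on a circular record.
#' @return DNA string of length `(end - start + 1) mod length` (full length
#'   when `start == end + 1` would be ambiguous is not special-cased:
#'   `start = 1, end = length` returns the whole sequence).
#' @examples
#' g <- mt_genome_record("x", "ACGTAC")
#' circular_slice(g, 5, 2)  # "ACAC"
#' @export
circular_slice <- function(record, start, end) {
  if (is.character(record)) record <- mt_genome_record("seq", record)
  s <- record$sequence
  len <- record$length
  stopifnot(start >= 1L, start <= len, end >= 1L, end <= len)
  if (start <= end) {
    substr(s, start, end)
  } else {
    if (!record$circular) stop("start > end on a linear record")
    paste0(substr(s, start, len), substr(s, 1L, end))
  }
}
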