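# Classify detected tracts by genomic context, following the survey's
# location taxonomy: control-region 3'/5' ends, CDS, tRNA, rRNA, intergenic.

.CATEGORIES <- c("CR_3prime", "CR_5prime", "CR_unresolved", "CDS", "tRNA",
                 "rRNA", "intergenic")

#' Orient a control region
#'
#' The control region sits between tRNA-Pro and tRNA-Phe in the standard
#' vertebrate gene order: the end adjacent to tRNA-Pro (or, absent that, the
#' end nearer an annotated TAS block, where nascent heavy-strand elongation
#' arrests) is the 5' end in heavy-strand sense; the end adjacent to
#' tRNA-Phe is the 3' end.
#'
#' @param record an `MtGenomeRecord` with a `control_region` feature.
#' @return list with `cr_start`, `cr_end` (genome coordinates of the CR),
#'   `cr_length`, `five_prime` (`"start"` or `"end"`: which CR boundary is
#'   the 5' end) and `orientation` (`"known"` or `"unknown"`).
#' @export
orient_control_region <- function(record) {
  ft <- record$features
  crs <- ft[ft$kind == "control_region", , drop = FALSE]
  if (!nrow(crs)) stop("no control region annotated on ", record$id)
  cr <- crs[which.max(mapply(.circ_len, crs$start, crs$end,
                             MoreArgs = list(len = record$length))), ]
  L <- record$length
  res <- list(cr_start = cr$start, cr_end = cr$end,
              cr_length = .circ_len(cr$start, cr$end, L),
              five_prime = NA_character_, orientation = "unknown")

  trna <- ft[ft$kind == "tRNA", , drop = FALSE]
  pro <- trna[grepl("Pro", trna$name), , drop = FALSE]
  phe <- trna[grepl("Phe", trna$name), , drop = FALSE]
  if (nrow(pro)) {
    # gap walking outward from each CR boundary to the Pro gene
    gap_at_start <- .circ_dist_fwd(pro$end[1L], cr$start, L)
    gap_at_end <- .circ_dist_fwd(cr$end, pro$start[1L], L)
    res$five_prime <- if (gap_at_start <= gap_at_end) "start" else "end"
    res$orientation <- "known"
  } else if (nrow(phe)) {
    gap_at_end <- .circ_dist_fwd(cr$end, phe$start[1L], L)
    gap_at_start <- .circ_dist_fwd(phe$end[1L], cr$start, L)
    res$five_prime <- if (gap_at_end <= gap_at_start) "start" else "end"
    res$orientation <- "known"
  } else {
    tas <- ft[ft$kind == "TAS_block", , drop = FALSE]
    if (nrow(tas)) {
      # TAS lies inside the CR near its 5' end
      d_start <- .circ_dist_fwd(cr$start, tas$start[1L], L)
      d_end <- .circ_dist_fwd(tas$end[1L], cr$end, L)
      res$five_prime <- if (d_start <= d_end) "start" else "end"
      res$orientation <- "known"
    }
  }
  res
}

# 1-based offset of genome position `pos` from the CR 5' boundary (1..crlen)
.cr_offset5 <- function(pos, ori, L) {
  i <- .circ_dist_fwd(ori$cr_start, pos, L) + 1L
  if (identical(ori$five_prime, "start")) i else ori$cr_length - i + 1L
}

#' Classify one tract by genomic context
#'
#' A tract lying wholly inside the control region is assigned `CR_5prime`
#' when its midpoint falls in the 5'-most `end_fraction` of the CR,
#' `CR_3prime` when in the 3'-most `end_fraction`, and `CR_unresolved`
#' otherwise (the survey's "no clear location" tracts). Outside the CR the
#' feature kind with the largest base overlap wins (`partial = TRUE` when
#' the overlap is less than the tract length; ties break CDS > rRNA > tRNA),
#' and `intergenic` when no CDS/rRNA/tRNA overlaps.
#'
#' @param tract one row of a [find_repeats()] table (or a list with `start`,
#'   `end`).
#' @param record the annotated `MtGenomeRecord` the tract was called on.
#' @param end_fraction fraction of the CR length counted as each terminal
#'   band; default 0.5 (only an exact-midpoint tie is unresolved).
#' @return tibble row with `category`, `partial`, `feature_name`.
#' @export
classify_tract <- function(tract, record, end_fraction = 0.5) {
  L <- record$length
  ts <- as.integer(tract$start)
  te <- as.integer(tract$end)
  if (ts < 1L || ts > L || te < 1L || te > L) {
    stop("tract outside record bounds")
  }
  span <- .circ_len(ts, te, L)
  ft <- record$features
  crs <- ft[ft$kind == "control_region", , drop = FALSE]

  if (nrow(crs)) {
    ori <- orient_control_region(record)
    if (.circ_contains(ori$cr_start, ori$cr_end, ts, te, L)) {
      if (ori$orientation == "unknown") {
        return(tibble::tibble(category = "CR_unresolved", partial = FALSE,
                              feature_name = "control region"))
      }
      mid <- .circ_step(ts, (span - 1L) %/% 2L, L)
      d5 <- .cr_offset5(mid, ori, L)
      d3 <- ori$cr_length - d5 + 1L
      band <- end_fraction * ori$cr_length
      category <- if (d5 == d3) {
        "CR_unresolved"
      } else if (d5 < d3 && d5 <= band) {
        "CR_5prime"
      } else if (d3 < d5 && d3 <= band) {
        "CR_3prime"
      } else {
        "CR_unresolved"
      }
      return(tibble::tibble(category = category, partial = FALSE,
                            feature_name = "control region"))
    }
  }

  prec <- c(CDS = 1L, rRNA = 2L, tRNA = 3L)
  genic <- ft[ft$kind %in% names(prec), , drop = FALSE]
  if (nrow(genic)) {
    ov <- mapply(function(s, e) .circ_overlap(ts, te, s, e, L),
                 genic$start, genic$end)
    if (any(ov > 0L)) {
      best <- order(-ov, prec[genic$kind])[1L]
      return(tibble::tibble(
        category = genic$kind[best],
        partial = ov[best] < span,
        feature_name = genic$name[best]))
    }
  }
  tibble::tibble(category = "intergenic", partial = FALSE,
                 feature_name = "")
}

#' Locate every tract of a detection table
#'
#' Vectorised wrapper around [classify_tract()]: appends `category`,
#' `partial`, `feature_name` and the record's `taxon_class` to a
#' [find_repeats()] table.
#'
#' @param tracts tibble from [find_repeats()].
#' @param record the annotated `MtGenomeRecord`.
#' @param end_fraction see [classify_tract()].
#' @return the input tibble with location columns appended.
#' @export
locate_tracts <- function(tracts, record, end_fraction = 0.5) {
  if (!nrow(tracts)) {
    return(cbind(tracts,
                 tibble::tibble(category = character(), partial = logical(),
                                feature_name = character(),
                                taxon_class = character())))
  }
  loc <- do.call(rbind, lapply(seq_len(nrow(tracts)), function(i) {
    classify_tract(tracts[i, ], record, end_fraction)
  }))
  out <- cbind(tracts, loc)
  out$taxon_class <- record$taxon_class
  tibble::as_tibble(out)
}
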