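# Aggregate located tracts into the survey's summary statistics.

.CLASS_ORDER <- c("Pisces", "Amphibia", "Reptilia", "Aves", "Mammalia")

#' Survey table from per-class counts
#'
#' Builds the survey summary (one row per taxon class plus a Total row) from
#' raw counts, computing the percentage columns: `pct_cr` = 100 * n_cr /
#' n_trs and `pct_3_of_cr` = 100 * n_3prime / (n_3prime + n_5prime), both
#' rounded half-up to 2 decimals. The 3'/CR denominator is the *resolved*
#' CR tracts only: n_3prime + n_5prime can fall short of n_cr by the tracts
#' whose CR end could not be determined.
#'
#' @param counts data frame with columns `category` (taxon class),
#'   `n_species`, `n_species_with_trs`, `n_trs`, `n_cr`, `n_3prime`,
#'   `n_5prime`; one row per class, no Total row.
#' @return tibble with the input columns plus `pct_cr` and `pct_3_of_cr`,
#'   rows ordered Pisces, Amphibia, Reptilia, Aves, Mammalia (present
#'   classes only) then Total. Percentages are `NA` when a denominator is
#'   zero, never 0/0.
#' @export
survey_table <- function(counts) {
  counts <- tibble::as_tibble(counts)
  need <- c("category", "n_species", "n_species_with_trs", "n_trs", "n_cr",
            "n_3prime", "n_5prime")
  stopifnot(all(need %in% names(counts)))
  if (any(counts$n_cr > counts$n_trs)) stop("n_cr cannot exceed n_trs")
  if (any(counts$n_3prime + counts$n_5prime > counts$n_cr)) {
    stop("n_3prime + n_5prime cannot exceed n_cr")
  }
  ord <- order(match(counts$category, .CLASS_ORDER, nomatch = 99L))
  counts <- counts[ord, ]
  num <- setdiff(need, "category")
  tot <- counts[1L, ]
  tot$category <- "Total"
  for (cn in num) tot[[cn]] <- sum(counts[[cn]])
  if (!nrow(counts)) {
    tot <- tibble::tibble(category = "Total", n_species = 0L,
                          n_species_with_trs = 0L, n_trs = 0L, n_cr = 0L,
                          n_3prime = 0L, n_5prime = 0L)
  }
  out <- rbind(counts, tot)
  denom3 <- out$n_3prime + out$n_5prime
  out$pct_cr <- ifelse(out$n_trs > 0L,
                       round_half_up(100 * out$n_cr / out$n_trs, 2L), NA)
  out$pct_3_of_cr <- ifelse(denom3 > 0L,
                            round_half_up(100 * out$n_3prime / denom3, 2L),
                            NA)
  out
}

#' Summarise located tracts into the survey table
#'
#' Counts tracts per taxon class from a [locate_tracts()] table and hands
#' the counts to [survey_table()]. `n_species` (genomes surveyed, with or
#' without repeats) is not derivable from tracts alone; supply
#' `species_totals` when known, otherwise the genomes-with-TRs count is used.
#'
#' @param located tibble with at least `genome_id`, `taxon_class` and
#'   `category` columns.
#' @param species_totals optional data frame with `category` (taxon class)
#'   and `n_species`.
#' @return see [survey_table()].
#' @export
summarize_survey <- function(located, species_totals = NULL) {
  located <- tibble::as_tibble(located)
  if (!nrow(located)) {
    return(survey_table(tibble::tibble(
      category = character(), n_species = integer(),
      n_species_with_trs = integer(), n_trs = integer(), n_cr = integer(),
      n_3prime = integer(), n_5prime = integer())))
  }
  stopifnot(all(located$category %in% .CATEGORIES))
  classes <- unique(located$taxon_class)
  rows <- lapply(classes, function(cl) {
    d <- located[located$taxon_class == cl, ]
    with_trs <- length(unique(d$genome_id))
    n_sp <- with_trs
    if (!is.null(species_totals)) {
      hit <- species_totals$n_species[species_totals$category == cl]
      if (length(hit)) n_sp <- hit[1L]
    }
    tibble::tibble(
      category = cl, n_species = as.integer(n_sp),
      n_species_with_trs = as.integer(with_trs),
      n_trs = nrow(d),
      n_cr = sum(d$category %in% c("CR_3prime", "CR_5prime",
                                   "CR_unresolved")),
      n_3prime = sum(d$category == "CR_3prime"),
      n_5prime = sum(d$category == "CR_5prime"))
  })
  survey_table(do.call(rbind, rows))
}

#' Fraction of tracts outside the control region
#'
#' @param rows a [survey_table()] result containing a Total row.
#' @return percent, 1 decimal: `100 * (n_trs - n_cr) / n_trs`.
#' @export
outside_cr_fraction <- function(rows) {
  tot <- rows[rows$category == "Total", ]
  if (!nrow(tot)) stop("Total row required")
  if (tot$n_trs == 0L) return(NA_real_)
  round_half_up(100 * (tot$n_trs - tot$n_cr) / tot$n_trs, 1L)
}

#' Motif-length histogram by genomic context
#'
#' @param located a [locate_tracts()]-style tibble with `motif_len` and
#'   `category` columns.
#' @param context `"all"`, `"CR_3prime"`, `"CR_5prime"` or `"CDS"`.
#' @return tibble with `motif_len` and `count` (class
#'   `MotifLengthHistogram`, attribute `context`); empty context gives zero
#'   rows.
#' @export
motif_length_histogram <- function(located,
                                   context = c("all", "CR_3prime",
                                               "CR_5prime", "CDS")) {
  context <- match.arg(context)
  d <- if (context == "all") located else
    located[located$category == context, , drop = FALSE]
  tab <- table(factor(d$motif_len))
  out <- tibble::tibble(motif_len = as.integer(names(tab)),
                        count = as.integer(tab))
  attr(out, "context") <- context
  class(out) <- c("MotifLengthHistogram", class(out))
  out
}

#' Even- versus odd-length motif totals
#'
#' Short motifs in the survey skew toward even lengths; this tallies counts
#' at even and odd motif lengths up to `max_len`.
#'
#' @param hist a [motif_length_histogram()] result.
#' @param max_len largest motif length included (default 11, covering the
#'   2-11 bp band the comparison is about).
#' @return named integer vector `c(even = ..., odd = ...)`.
#' @export
even_odd_excess <- function(hist, max_len = 11L) {
  stopifnot(max_len >= 2L)
  d <- hist[hist$motif_len <= max_len, , drop = FALSE]
  c(even = sum(d$count[d$motif_len %% 2L == 0L]),
    odd = sum(d$count[d$motif_len %% 2L == 1L]))
}
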