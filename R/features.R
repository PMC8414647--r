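#' V/D/J gene usage
#'
#' Gene usage is the number of clones assigned to a gene divided by the total
#' number of clones carrying that segment (clone-count based, not
#' read-weighted). Genes absent from the repertoire are absent from the map.
#'
#' @param repertoire a `repertoire`.
#' @param segment_type `"V"`, `"D"` or `"J"`.
#' @return named numeric vector of fractions summing to 1 (empty, with a
#'   warning, when no clone carries the segment).
#' @export
gene_usage <- function(repertoire, segment_type = c("V", "D", "J")) {
  segment_type <- match.arg(segment_type)
  assert_that(nrow(repertoire$clones) > 0L, "repertoire is empty")
  col <- c(V = "v_gene", D = "d_gene", J = "j_gene")[[segment_type]]
  genes <- repertoire$clones[[col]]
  genes <- genes[!is.na(genes)]
  if (length(genes) == 0L) {
    warning("no clone has a ", segment_type, " assignment")
    return(setNames(numeric(), character()))
  }
  tab <- table(genes)
  setNames(as.numeric(tab) / length(genes), names(tab))
}

#' CDR3 length distribution
#'
#' Fraction of clones at each CDR3 length, in nucleotides or amino acids
#' (clone-count based). In `"aa"` mode only clones with an amino-acid CDR3
#' (in-frame junction) contribute.
#'
#' @param repertoire a `repertoire`.
#' @param unit `"nt"` or `"aa"`.
#' @return named numeric vector (names are lengths) summing to 1.
#' @export
cdr3_length_distribution <- function(repertoire, unit = c("nt", "aa")) {
  unit <- match.arg(unit)
  assert_that(nrow(repertoire$clones) > 0L, "repertoire is empty")
  lens <- if (unit == "nt") {
    nchar(repertoire$clones$cdr3_nt)
  } else {
    nchar(repertoire$clones$cdr3_aa[!is.na(repertoire$clones$cdr3_aa)])
  }
  if (length(lens) == 0L) {
    warning("no clone has a CDR3 in unit ", unit)
    return(setNames(numeric(), character()))
  }
  tab <- table(lens)
  setNames(as.numeric(tab) / length(lens), names(tab))
}

#' Junction insertion/deletion profile
#'
#' Length distributions of exonucleolytic deletions (sites V3, D5, D3, J5)
#' and non-templated insertions (junctions VD, DJ) over all clones with V, D
#' and J assignments and complete junction fields. Insertions and deletions
#' at the same junction are treated as mutually exclusive: a clone with a
#' positive insertion contributes length 0 to that junction's deletion
#' tallies, and a clone with a positive deletion contributes length 0 to
#' that junction's insertion tally.
#'
#' @param repertoire a `repertoire`.
#' @param exclusivity `"per_junction"` (default) applies the rule to the V-D
#'   and D-J junctions independently; `"global"` zeroes all deletion sites
#'   when any insertion is present anywhere in the clone, and vice versa.
#' @return object of class `junction_profile`: list with `deletion_freq`
#'   (named list V3/D5/D3/J5 of length->fraction vectors), `insertion_freq`
#'   (VD/DJ), and `n_clones_used`.
#' @export
junction_profile <- function(repertoire,
                             exclusivity = c("per_junction", "global")) {
  exclusivity <- match.arg(exclusivity)
  cl <- repertoire$clones
  complete <- !is.na(cl$v_gene) & !is.na(cl$d_gene) & !is.na(cl$j_gene) &
    !is.na(cl$v_del3) & !is.na(cl$d_del5) & !is.na(cl$d_del3) &
    !is.na(cl$j_del5) & !is.na(cl$ins_vd) & !is.na(cl$ins_dj)
  cl <- cl[complete, , drop = FALSE]
  if (nrow(cl) == 0L) {
    warning("no clone with complete V/D/J junction information")
    return(structure(list(deletion_freq = list(), insertion_freq = list(),
                          n_clones_used = 0L), class = "junction_profile"))
  }
  ins_vd_present <- cl$ins_vd > 0L
  ins_dj_present <- cl$ins_dj > 0L
  del_vd_present <- cl$v_del3 > 0L | cl$d_del5 > 0L
  del_dj_present <- cl$d_del3 > 0L | cl$j_del5 > 0L
  if (exclusivity == "global") {
    ins_present <- ins_vd_present | ins_dj_present
    del_present <- del_vd_present | del_dj_present
    ins_vd_present <- ins_dj_present <- ins_present
    del_vd_present <- del_dj_present <- del_present
  }
  tally <- function(x, zero) {
    x[zero] <- 0L
    tab <- table(x)
    setNames(as.numeric(tab) / length(x), names(tab))
  }
  structure(list(
    deletion_freq = list(
      V3 = tally(cl$v_del3, ins_vd_present),
      D5 = tally(cl$d_del5, ins_vd_present),
      D3 = tally(cl$d_del3, ins_dj_present),
      J5 = tally(cl$j_del5, ins_dj_present)
    ),
    insertion_freq = list(
      VD = tally(cl$ins_vd, del_vd_present),
      DJ = tally(cl$ins_dj, del_dj_present)
    ),
    n_clones_used = nrow(cl)
  ), class = "junction_profile")
}

#' @export
print.junction_profile <- function(x, ...) {
  cat(sprintf("<junction_profile> %d clone(s) with V/D/J assignments\n",
              x$n_clones_used))
  invisible(x)
}

#' Shannon diversity index
#'
#' \eqn{H = -\sum_i p_i \ln p_i} over clone frequencies, in nats, with
#' \eqn{0 \ln 0 = 0}.
#'
#' @param freqs clone frequency vector (non-negative, summing to 1).
#' @return non-negative scalar, at most \eqn{\ln R} for `R` clones.
#' @export
shannon_index <- function(freqs) {
  check_freqs(freqs)
  p <- freqs[freqs > 0]
  -sum(p * log(p))
}

#' Simpson diversity index
#'
#' \eqn{\sum_i p_i^2} over clone frequencies; 1 for a monoclonal repertoire,
#' \eqn{1/R} for a uniform one.
#'
#' @inheritParams shannon_index
#' @return scalar in (0, 1].
#' @export
simpson_index <- function(freqs) {
  check_freqs(freqs)
  sum(freqs^2)
}

#' D50 clonality index
#'
#' The percentage of distinct clones (ranked by abundance) whose cumulative
#' frequency first reaches 50% of the reads. 100 means perfectly even at the
#' half-way point granularity; low values indicate clonal expansion.
#'
#' @inheritParams shannon_index
#' @return percentage in (0, 100].
#' @export
d50 <- function(freqs) {
  check_freqs(freqs)
  p <- sort(freqs, decreasing = TRUE)
  m <- unname(which(cumsum(p) >= 0.5 - 1e-12)[1L])
  100 * m / length(freqs)
}

#' Fraction of reads in the top N clones
#'
#' Sum of the `top_n` largest read-weighted clone frequencies (1.0 when the
#' repertoire has at most `top_n` clones). Ties at the boundary break by
#' clone key for determinism.
#'
#' @param repertoire a `repertoire`.
#' @param top_n number of top clones (default 100).
#' @return fraction in (0, 1].
#' @export
top_clone_fraction <- function(repertoire, top_n = 100L) {
  assert_that(top_n >= 1L, "top_n must be >= 1")
  freqs <- clone_frequencies(repertoire)
  ord <- order(-freqs, names(freqs))
  sum(freqs[ord][seq_len(min(top_n, length(freqs)))])
}

#' All four diversity statistics of a repertoire
#'
#' Shannon, Simpson, D50 and top-100 fraction computed on read-weighted clone
#' frequencies.
#'
#' @param repertoire a `repertoire`.
#' @param top_n passed to [top_clone_fraction()].
#' @return named numeric vector `shannon, simpson, d50, top_fraction`.
#' @export
diversity_indices <- function(repertoire, top_n = 100L) {
  freqs <- clone_frequencies(repertoire)
  c(shannon = shannon_index(freqs), simpson = simpson_index(freqs),
    d50 = d50(freqs), top_fraction = top_clone_fraction(repertoire, top_n))
}
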