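#' @importFrom stats quantile rpois runif setNames phyper p.adjust dgeom
#' @importFrom utils read.delim write.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")
AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
ISOTYPE_LEVELS <- c("IGHM", "IGHD", "IGHG", "IGHA", "IGHE", "NA")

#' Translate nucleotide sequences with the standard genetic code
#'
#' Vectorised translation of in-frame nucleotide strings. Stop codons
#' translate to `"*"`. Sequences whose length is not a multiple of 3 (or that
#' are empty / NA) yield `NA`.
#'
#' @param nt character vector of nucleotide sequences over A/C/G/T.
#' @return character vector of amino-acid sequences.
#' @export
translate_nt <- function(nt) {
  out <- rep(NA_character_, length(nt))
  ok <- !is.na(nt) & nchar(nt) > 0L & nchar(nt) %% 3L == 0L &
    !grepl("[^ACGT]", nt)
  if (any(ok)) {
    out[ok] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(nt[ok]), no.init.codon = TRUE
    ))
  }
  out
}

gene_from_allele <- function(allele) {
  ifelse(is.na(allele) | allele == "", NA_character_, sub("\\*.*$", "", allele))
}

#' Parse a mutation-event string
#'
#' Mutation events are serialised as a comma-separated list of
#' `"pos:from>to"` items, with `pos` a 0-based germline-V coordinate.
#'
#' @param x single mutation string (may be `""` or `NA` for no events).
#' @return data.frame with integer `pos` and character `from`, `to`.
#' @export
parse_mutations <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(data.frame(pos = integer(), from = character(), to = character(),
                      stringsAsFactors = FALSE))
  }
  items <- strsplit(x, ",", fixed = TRUE)[[1]]
  m <- regmatches(items, regexec("^([0-9]+):([ACGT])>([ACGT])$", items))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed mutation item(s): ", paste(items[bad], collapse = ", "))
  }
  df <- data.frame(
    pos = as.integer(vapply(m, `[`, "", 2L)),
    from = vapply(m, `[`, "", 3L),
    to = vapply(m, `[`, "", 4L),
    stringsAsFactors = FALSE
  )
  if (any(df$from == df$to)) stop("mutation event with from == to")
  df
}

#' @rdname parse_mutations
#' @param events data.frame as returned by [parse_mutations()].
#' @export
format_mutations <- function(events) {
  if (is.null(events) || nrow(events) == 0L) return("")
  paste(sprintf("%d:%s>%s", events$pos, events$from, events$to), collapse = ",")
}

# Truncated geometric over 0..max with success probability prob.
rtgeom <- function(n, prob, max) {
  if (n == 0L) return(integer())
  w <- dgeom(0:max, prob)
  sample.int(max + 1L, n, replace = TRUE, prob = w) - 1L
}

tgeom_mean <- function(prob, max) {
  w <- dgeom(0:max, prob)
  sum((0:max) * w) / sum(w)
}

tgeom_var <- function(prob, max) {
  w <- dgeom(0:max, prob) / sum(dgeom(0:max, prob))
  m <- sum((0:max) * w)
  sum(((0:max) - m)^2 * w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

check_freqs <- function(freqs, tol = 1e-9) {
  assert_that(is.numeric(freqs) && length(freqs) > 0L,
              "frequency vector must be non-empty numeric")
  assert_that(all(freqs >= 0), "frequencies must be non-negative")
  assert_that(abs(sum(freqs) - 1) <= tol,
              sprintf("frequencies must sum to 1 (got %.12f)", sum(freqs)))
  invisible(freqs)
}
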