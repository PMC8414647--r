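#' Sequence query against an indexed subject set
#'
#' Amino-acid mode reports exact full-string matches on the scoped sequence.
#' Nucleotide mode reports near-exact matches: the best local alignment
#' (after a shared k-mer prefilter) must reach identity >= 0.90, with
#' identity defined as matching columns divided by alignment columns
#' (gap columns included), and the alignment must cover at least 90% of the
#' query. Hits are sorted by identity (descending), then subject id.
#'
#' @param query query sequence (nucleotide or amino acid per `mode`).
#' @param subjects data.frame with an `id` column and sequence columns named
#'   `cdr3_nt`, `cdr3_aa`, `vregion_nt`, `vregion_aa` as available.
#' @param mode `"nt"` or `"aa"`.
#' @param scope `"cdr3"` or `"vregion"`.
#' @param min_identity nucleotide identity threshold (default 0.9).
#' @param min_coverage minimum fraction of the query covered by the
#'   alignment (default 0.9).
#' @return data.frame with `query_id, subject_id, scope, mode, identity`.
#' @export
sequence_query <- function(query, subjects, mode = c("nt", "aa"),
                           scope = c("cdr3", "vregion"),
                           min_identity = 0.9, min_coverage = 0.9) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  assert_that(is.character(query) && length(query) == 1L && nzchar(query),
              "query must be a non-empty string")
  query <- toupper(query)
  if (mode == "nt") {
    assert_that(!grepl("[^ACGT]", query),
                "nt query must be over A/C/G/T")
  } else {
    assert_that(!grepl(sprintf("[^%s]", paste(AA_STANDARD, collapse = "")),
                       query), "aa query must use standard amino acids")
  }
  col <- paste0(if (scope == "cdr3") "cdr3" else "vregion", "_", mode)
  assert_that(col %in% names(subjects),
              sprintf("subjects lack column '%s'", col))
  subj_seq <- toupper(subjects[[col]])
  ok <- !is.na(subj_seq) & nzchar(subj_seq)
  hits <- if (mode == "aa") {
    idx <- which(ok & subj_seq == query)
    data.frame(subject_id = subjects$id[idx],
               identity = rep(1.0, length(idx)), stringsAsFactors = FALSE)
  } else {
    nt_query_hits(query, subjects$id[ok], subj_seq[ok], min_identity,
                  min_coverage)
  }
  out <- data.frame(query_id = rep("query", nrow(hits)),
                    subject_id = hits$subject_id,
                    scope = rep(scope, nrow(hits)),
                    mode = rep(mode, nrow(hits)),
                    identity = hits$identity, stringsAsFactors = FALSE)
  out <- out[order(-out$identity, out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# k-mer prefilter: with <= floor((1 - min_identity) * L) mismatches over a
# query of length L, pigeonhole guarantees an exact run of length
# >= floor((L - d) / (d + 1)); any subject without a shared k-mer of that
# length cannot reach the identity threshold without gaps dominating.
prefilter_k <- function(query_len, min_identity) {
  d <- floor((1 - min_identity) * query_len)
  max(4L, min(12L, floor((query_len - d) / (d + 1))))
}

kmer_set <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character())
  unique(substring(x, 1:(n - k + 1L), k:n))
}

nt_query_hits <- function(query, ids, seqs, min_identity, min_coverage) {
  k <- prefilter_k(nchar(query), min_identity)
  qk <- kmer_set(query, k)
  candidate <- vapply(seqs, function(s) {
    any(kmer_set(s, k) %in% qk)
  }, TRUE, USE.NAMES = FALSE)
  ids <- ids[candidate]; seqs <- seqs[candidate]
  if (length(ids) == 0L) {
    return(data.frame(subject_id = character(), identity = numeric(),
                      stringsAsFactors = FALSE))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = rep(query, length(seqs)), subject = Biostrings::DNAStringSet(seqs),
    type = "local", substitutionMatrix = mat,
    gapOpening = 2, gapExtension = 1
  )
  pat_aln <- as.character(Biostrings::alignedPattern(aln))
  sub_aln <- as.character(Biostrings::alignedSubject(aln))
  columns <- nchar(pat_aln)
  matches <- vapply(seq_along(pat_aln), function(i) {
    p <- strsplit(pat_aln[i], "")[[1]]
    s <- strsplit(sub_aln[i], "")[[1]]
    sum(p == s & p != "-")
  }, 0L)
  identity <- ifelse(columns > 0L, matches / columns, 0)
  cov_len <- vapply(seq_along(pat_aln), function(i) {
    sum(strsplit(pat_aln[i], "")[[1]] != "-")
  }, 0L)
  coverage <- cov_len / nchar(query)
  keep <- identity >= min_identity & coverage >= min_coverage
  data.frame(subject_id = ids[keep], identity = identity[keep],
             stringsAsFactors = FALSE)
}
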