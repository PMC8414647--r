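#' Assign an isotype from C-gene hits
#'
#' Maps the best-scoring constant-gene hit to one of the six isotype
#' categories IGHM, IGHD, IGHG, IGHA, IGHE or `"NA"` (no C gene detected).
#' Subclasses collapse to their class prefix (IGHG1 -> IGHG and so on).
#'
#' @param c_calls character vector of C hits, either bare allele names or
#'   MiXCR-style scored hits (`"IGHG1(500)"`); an empty vector, `NA` or an
#'   empty string means no C gene was found.
#' @return one of `"IGHM"`, `"IGHD"`, `"IGHG"`, `"IGHA"`, `"IGHE"`, `"NA"`.
#' @export
assign_isotype <- function(c_calls) {
  c_calls <- c_calls[!is.na(c_calls) & nzchar(c_calls)]
  if (length(c_calls) == 0L) return("NA")
  scored <- grepl("\\(", c_calls)
  best <- if (any(scored)) {
    best_hit(paste(c_calls, collapse = ","))
  } else {
    sort(c_calls)[1L]
  }
  if (is.na(best)) return("NA")
  m <- regmatches(best, regexec("^(IGH[MDGAE])", best))[[1]]
  if (length(m) < 2L) {
    warning("C call '", best, "' does not match an IGH isotype prefix")
    return("NA")
  }
  m[2L]
}

clone_key <- function(v_gene, j_gene, c_gene, cdr3_nt, use_c_gene = TRUE) {
  cg <- if (use_c_gene) ifelse(is.na(c_gene), "", c_gene) else ""
  paste(v_gene, j_gene, cg, cdr3_nt, sep = "|")
}

#' Cluster aligned records into clones
#'
#' Records sharing the same V gene, J gene, optionally C gene, and CDR3
#' nucleotide sequence are clustered into one clone. Gene identity is at the
#' gene level (allele names truncated at `"*"`). Clone read counts are the
#' sum of the supporting records' duplicate counts; the clone's CDR3
#' amino-acid sequence and junction fields come from the supporting record
#' with the highest duplicate count (ties broken by record id). Output order
#' is deterministic: descending read count, then clone key.
#'
#' @param records data.frame of aligned records (native layout, see
#'   [read_clone_table()]). Every record must have a V call, J call and CDR3.
#' @param sample_id sample identifier stored on the repertoire.
#' @param use_c_gene include the C gene in the clone key (default `TRUE`,
#'   the operative clone definition); `FALSE` clusters on V/J/CDR3nt only.
#' @param metadata named list of sample metadata.
#' @return a `repertoire` object: `list(sample_id, metadata, clones)` where
#'   `clones` is a data.frame with columns `clone_key, v_gene, d_gene,
#'   j_gene, c_gene, isotype, cdr3_nt, cdr3_aa, read_count, n_reads`,
#'   junction fields, and a `read_mutations` list-column holding one
#'   mutation string per supporting read.
#' @export
cluster_clones <- function(records, sample_id = "sample",
                           use_c_gene = TRUE, metadata = list()) {
  if (nrow(records) == 0L) {
    warning("no records to cluster; returning empty repertoire")
    return(new_repertoire(sample_id, metadata, empty_clones()))
  }
  assert_that(!any(is.na(records$v_call)) && !any(is.na(records$j_call)) &&
                !any(is.na(records$cdr3_nt)),
              "all records must carry v_call, j_call and cdr3_nt")
  v_gene <- gene_from_allele(records$v_call)
  d_gene <- gene_from_allele(records$d_call)
  j_gene <- gene_from_allele(records$j_call)
  c_gene <- gene_from_allele(records$c_call)
  key <- clone_key(v_gene, j_gene, c_gene, records$cdr3_nt, use_c_gene)
  fk <- factor(key)
  # representative record per clone: highest duplicate count, then record id
  ord <- order(fk, -records$duplicate_count, records$record_id)
  rep_i <- ord[!duplicated(fk[ord])]
  read_count <- rowsum(records$duplicate_count, fk)[, 1L]
  n_reads <- tabulate(fk, nbins = nlevels(fk))
  c_call_rep <- records$c_call[rep_i]
  iso_map <- vapply(unique(c_call_rep), function(cc) {
    assign_isotype(if (is.na(cc)) character() else cc)
  }, "")
  iso <- unname(iso_map[match(c_call_rep, names(iso_map))])
  iso[is.na(c_call_rep)] <- "NA"
  clones <- data.frame(
    clone_key = levels(fk),
    v_gene = v_gene[rep_i], d_gene = d_gene[rep_i],
    j_gene = j_gene[rep_i], c_gene = c_gene[rep_i],
    isotype = iso,
    cdr3_nt = records$cdr3_nt[rep_i], cdr3_aa = records$cdr3_aa[rep_i],
    read_count = unname(read_count), n_reads = n_reads,
    v_del3 = records$v_del3[rep_i], d_del5 = records$d_del5[rep_i],
    d_del3 = records$d_del3[rep_i], j_del5 = records$j_del5[rep_i],
    ins_vd = records$ins_vd[rep_i], ins_dj = records$ins_dj[rep_i],
    stringsAsFactors = FALSE
  )
  clones$read_mutations <- split(records$mutations, fk)
  out_ord <- order(-clones$read_count, clones$clone_key)
  clones <- clones[out_ord, , drop = FALSE]
  rownames(clones) <- NULL
  new_repertoire(sample_id, metadata, clones)
}

empty_clones <- function() {
  df <- data.frame(clone_key = character(), v_gene = character(),
                   d_gene = character(), j_gene = character(),
                   c_gene = character(), isotype = character(),
                   cdr3_nt = character(), cdr3_aa = character(),
                   read_count = integer(), n_reads = integer(),
                   v_del3 = integer(), d_del5 = integer(),
                   d_del3 = integer(), j_del5 = integer(),
                   ins_vd = integer(), ins_dj = integer(),
                   stringsAsFactors = FALSE)
  df$read_mutations <- list()
  df
}

new_repertoire <- function(sample_id, metadata, clones) {
  structure(list(sample_id = sample_id, metadata = metadata, clones = clones),
            class = "repertoire")
}

#' @export
print.repertoire <- function(x, ...) {
  cat(sprintf("<repertoire> %s: %d clone(s), %d read(s)\n", x$sample_id,
              nrow(x$clones), sum(x$clones$read_count)))
  if (length(x$metadata) > 0L) {
    cat("  metadata:", paste(names(x$metadata),
                             unlist(x$metadata, use.names = FALSE),
                             sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read-weighted clone frequencies of a repertoire
#'
#' @param repertoire a `repertoire`.
#' @return numeric vector (named by clone key) summing to 1.
#' @export
clone_frequencies <- function(repertoire) {
  counts <- repertoire$clones$read_count
  setNames(counts / sum(counts), repertoire$clones$clone_key)
}

#' Flatten a repertoire back to aligned records
#'
#' Each clone yields one record per supporting read; the clone's read count
#' is preserved by assigning the residual duplicate count to the first read.
#' Clustering the result reproduces the repertoire (idempotence).
#'
#' @param repertoire a `repertoire`.
#' @return data.frame of aligned records in native layout.
#' @export
repertoire_to_records <- function(repertoire) {
  cl <- repertoire$clones
  if (nrow(cl) == 0L) return(empty_records())
  recs <- lapply(seq_len(nrow(cl)), function(i) {
    muts <- cl$read_mutations[[i]]
    n_reads <- length(muts)
    dup <- c(cl$read_count[i] - (n_reads - 1L), rep(1L, n_reads - 1L))
    df <- empty_records()[seq_len(n_reads), , drop = FALSE]
    df$record_id <- sprintf("%s_r%d", formatC(i, width = 6, flag = "0"),
                            seq_len(n_reads))
    df$v_call <- cl$v_gene[i]; df$d_call <- cl$d_gene[i]
    df$j_call <- cl$j_gene[i]; df$c_call <- cl$c_gene[i]
    df$cdr3_nt <- cl$cdr3_nt[i]; df$cdr3_aa <- cl$cdr3_aa[i]
    df$duplicate_count <- dup
    df$v_del3 <- cl$v_del3[i]; df$d_del5 <- cl$d_del5[i]
    df$d_del3 <- cl$d_del3[i]; df$j_del5 <- cl$j_del5[i]
    df$ins_vd <- cl$ins_vd[i]; df$ins_dj <- cl$ins_dj[i]
    df$mutations <- muts
    df
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}
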