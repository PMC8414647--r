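write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

collapse_list_col <- function(x) {
  vapply(x, paste, "", collapse = ",")
}

#' Write per-sample repertoire feature tables
#'
#' Emits `usage_V.tsv`, `usage_D.tsv`, `usage_J.tsv`, `cdr3_length_nt.tsv`,
#' `cdr3_length_aa.tsv`, `junction_deletions.tsv`, `junction_insertions.tsv`
#' and `diversity.tsv` into `outdir`, in long format with a `sample_id`
#' column.
#'
#' @param repertoires list of `repertoire` objects.
#' @param outdir output directory (created if needed).
#' @return named character vector of written paths.
#' @export
write_feature_tables <- function(repertoires, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(repertoires, `[[`, "", "sample_id")
  gather <- function(fun) {
    rows <- lapply(seq_along(repertoires), function(i) {
      v <- fun(repertoires[[i]])
      if (length(v) == 0L) return(NULL)
      data.frame(sample_id = ids[i], category = names(v),
                 fraction = unname(v), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  paths <- c()
  for (st in c("V", "D", "J")) {
    df <- gather(function(r) suppressWarnings(gene_usage(r, st)))
    names(df)[2] <- "gene"
    p <- file.path(outdir, sprintf("usage_%s.tsv", st))
    write_tsv(df, p); paths[sprintf("usage_%s", st)] <- p
  }
  for (un in c("nt", "aa")) {
    df <- gather(function(r) suppressWarnings(cdr3_length_distribution(r, un)))
    names(df)[2] <- "length"
    p <- file.path(outdir, sprintf("cdr3_length_%s.tsv", un))
    write_tsv(df, p); paths[sprintf("cdr3_length_%s", un)] <- p
  }
  del_rows <- list(); ins_rows <- list()
  for (i in seq_along(repertoires)) {
    prof <- suppressWarnings(junction_profile(repertoires[[i]]))
    for (site in names(prof$deletion_freq)) {
      f <- prof$deletion_freq[[site]]
      del_rows[[paste(i, site)]] <- data.frame(
        sample_id = ids[i], site = site, length = as.integer(names(f)),
        fraction = unname(f), stringsAsFactors = FALSE)
    }
    for (jn in names(prof$insertion_freq)) {
      f <- prof$insertion_freq[[jn]]
      ins_rows[[paste(i, jn)]] <- data.frame(
        sample_id = ids[i], junction = jn, length = as.integer(names(f)),
        fraction = unname(f), stringsAsFactors = FALSE)
    }
  }
  p <- file.path(outdir, "junction_deletions.tsv")
  write_tsv(do.call(rbind, del_rows) %||%
              data.frame(sample_id = character(), site = character(),
                         length = integer(), fraction = numeric()), p)
  paths["junction_deletions"] <- p
  p <- file.path(outdir, "junction_insertions.tsv")
  write_tsv(do.call(rbind, ins_rows) %||%
              data.frame(sample_id = character(), junction = character(),
                         length = integer(), fraction = numeric()), p)
  paths["junction_insertions"] <- p
  div <- do.call(rbind, lapply(seq_along(repertoires), function(i) {
    d <- diversity_indices(repertoires[[i]])
    data.frame(sample_id = ids[i], shannon = d[["shannon"]],
               simpson = d[["simpson"]], d50 = d[["d50"]],
               top_fraction = d[["top_fraction"]], stringsAsFactors = FALSE)
  }))
  p <- file.path(outdir, "diversity.tsv")
  write_tsv(div, p); paths["diversity"] <- p
  paths
}

#' Write SHM profile tables
#'
#' Emits `shm_positions.tsv`, `shm_regions.tsv`, `shm_transitions.tsv` and
#' `shm_motifs.tsv` rows for one sample x isotype profile, appending to
#' per-run data frames handled by the caller; here one file set per call.
#'
#' @param profiles list of `shm_profile` objects (possibly several isotypes
#'   and samples), each with a `sample_id` attribute set by the caller.
#' @param outdir output directory.
#' @return named character vector of written paths.
#' @export
write_shm_tables <- function(profiles, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pos <- list(); reg <- list(); tra <- list(); mot <- list()
  for (pr in profiles) {
    if (pr$n_clones == 0L) next
    sid <- attr(pr, "sample_id") %||% "sample"
    pos[[length(pos) + 1L]] <- cbind(
      data.frame(sample_id = sid, isotype = pr$isotype,
                 stringsAsFactors = FALSE), pr$position_freq)
    reg[[length(reg) + 1L]] <- data.frame(
      sample_id = sid, isotype = pr$isotype, region = names(pr$region_rate),
      rate = unname(pr$region_rate), stringsAsFactors = FALSE)
    tr <- as.data.frame(as.table(pr$transition), stringsAsFactors = FALSE)
    names(tr) <- c("from", "to", "freq")
    tra[[length(tra) + 1L]] <- cbind(
      data.frame(sample_id = sid, isotype = pr$isotype,
                 stringsAsFactors = FALSE), tr)
    mot[[length(mot) + 1L]] <- cbind(
      data.frame(sample_id = sid, isotype = pr$isotype,
                 stringsAsFactors = FALSE), pr$motif_rate)
  }
  paths <- c()
  for (nm in c("positions", "regions", "transitions", "motifs")) {
    df <- switch(nm, positions = pos, regions = reg, transitions = tra,
                 motifs = mot)
    p <- file.path(outdir, sprintf("shm_%s.tsv", nm))
    if (length(df) > 0L) write_tsv(do.call(rbind, df), p) else next
    paths[sprintf("shm_%s", nm)] <- p
  }
  paths
}

#' Write a feature comparison table
#'
#' One row per category: reference five-number summary plus one column per
#' experimental sample.
#'
#' @param comparison a `feature_comparison`.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_comparison <- function(comparison, path) {
  df <- comparison$reference_summary
  ep <- comparison$experimental_points
  for (sid in colnames(ep)) df[[sid]] <- ep[df$category, sid]
  write_tsv(df, path)
}

#' Write public clone records
#'
#' @param public data.frame from [detect_public_clones()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_public_clones <- function(public, path) {
  out <- public
  out$exp_samples <- collapse_list_col(out$exp_samples)
  out$ref_samples <- collapse_list_col(out$ref_samples)
  write_tsv(out, path)
}

#' Write clone annotations
#'
#' @param annotations data.frame from [match_clones_to_db()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_annotations <- function(annotations, path) {
  out <- annotations
  out$matched_ids <- collapse_list_col(out$matched_ids)
  out$diseases <- collapse_list_col(out$diseases)
  write_tsv(out, path)
}

#' Write the full enrichment table
#'
#' @param enrichment data.frame from [disease_enrichment()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_enrichment <- function(enrichment, path) {
  write_tsv(enrichment, path)
}

#' Write query hits
#'
#' @param hits data.frame from [sequence_query()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_query_hits <- function(hits, path) {
  write_tsv(hits, path)
}
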