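NATIVE_COLUMNS <- c("record_id", "v_call", "d_call", "j_call", "c_call",
                    "cdr3_nt", "cdr3_aa", "duplicate_count", "v_del3",
                    "d_del5", "d_del3", "j_del5", "ins_vd", "ins_dj",
                    "mutations")

empty_records <- function() {
  df <- data.frame(record_id = character(), v_call = character(),
                   d_call = character(), j_call = character(),
                   c_call = character(), cdr3_nt = character(),
                   cdr3_aa = character(), duplicate_count = integer(),
                   v_del3 = integer(), d_del5 = integer(), d_del3 = integer(),
                   j_del5 = integer(), ins_vd = integer(), ins_dj = integer(),
                   mutations = character(), stringsAsFactors = FALSE)
  df
}

blank_to_na <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & !nzchar(trimws(x))] <- NA_character_
  x
}

#' Read a clone/read table
#'
#' Reads aligned-record tables in one of three dialects and returns a
#' normalised record data.frame (the "native" column set). Rows lacking a V
#' call, a J call or a CDR3 nucleotide sequence are skipped; the number of
#' skipped rows is attached as attribute `n_skipped` and reported via a
#' message.
#'
#' Dialects:
#' \describe{
#'   \item{airr}{AIRR Rearrangement TSV; mandatory columns `sequence_id`,
#'     `v_call`, `j_call`, `junction`, `duplicate_count`; `d_call`, `c_call`
#'     and `junction_aa` honoured when present. The junction (conserved Cys
#'     to conserved Trp) is taken as the CDR3 nucleotide sequence.}
#'   \item{mixcr}{MiXCR clone export subset; mandatory columns `cloneCount`,
#'     `allVHitsWithScore`, `allJHitsWithScore`, `nSeqCDR3`, `refPoints`.
#'     The best-scoring allele is retained from each multi-hit column;
#'     junction fields are derived from `refPoints` via [parse_refpoints()].}
#'   \item{native}{this package's TSV dialect with columns
#'     `record_id, v_call, d_call, j_call, c_call, cdr3_nt, cdr3_aa,
#'     duplicate_count, v_del3, d_del5, d_del3, j_del5, ins_vd, ins_dj,
#'     mutations` (mutations as a comma list of `pos:from>to`).}
#' }
#'
#' @param path TSV file path.
#' @param dialect `"airr"`, `"mixcr"` or `"native"`.
#' @param germline optional `germline_set`, used by the mixcr dialect to
#'   derive deletion lengths from germline alignment extents.
#' @return data.frame of aligned records in native column order.
#' @export
read_clone_table <- function(path, dialect = c("native", "airr", "mixcr"),
                             germline = NULL) {
  dialect <- tryCatch(match.arg(dialect),
                      error = function(e) stop("unknown dialect", call. = FALSE))
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE, colClasses = "character")
  rec <- switch(dialect,
                native = parse_native(df),
                airr = parse_airr(df),
                mixcr = parse_mixcr(df, germline))
  keep <- !is.na(rec$v_call) & !is.na(rec$j_call) &
    !is.na(rec$cdr3_nt) & nzchar(rec$cdr3_nt)
  n_skipped <- sum(!keep)
  if (n_skipped > 0L) {
    message(n_skipped, " record(s) without V call, J call or CDR3 skipped")
  }
  rec <- rec[keep, , drop = FALSE]
  rownames(rec) <- NULL
  # fill cdr3_aa by translation where absent and in-frame
  miss_aa <- is.na(rec$cdr3_aa)
  if (any(miss_aa)) rec$cdr3_aa[miss_aa] <- translate_nt(rec$cdr3_nt[miss_aa])
  structure(rec, n_skipped = n_skipped)
}

require_columns <- function(df, cols, dialect) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(dialect, " table is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

parse_native <- function(df) {
  require_columns(df, NATIVE_COLUMNS, "native")
  out <- df[NATIVE_COLUMNS]
  for (col in c("record_id", "v_call", "d_call", "j_call", "c_call",
                "cdr3_nt", "cdr3_aa", "mutations")) {
    out[[col]] <- blank_to_na(out[[col]])
  }
  out$mutations[is.na(out$mutations)] <- ""
  out$duplicate_count <- as.integer(out$duplicate_count)
  for (col in c("v_del3", "d_del5", "d_del3", "j_del5", "ins_vd", "ins_dj")) {
    out[[col]] <- suppressWarnings(as.integer(out[[col]]))
  }
  out
}

parse_airr <- function(df) {
  require_columns(df, c("sequence_id", "v_call", "j_call", "junction",
                        "duplicate_count"), "airr")
  out <- empty_records()[seq_len(nrow(df)), , drop = FALSE]
  out$record_id <- blank_to_na(df$sequence_id)
  out$v_call <- blank_to_na(df$v_call)
  out$j_call <- blank_to_na(df$j_call)
  out$d_call <- if ("d_call" %in% names(df)) blank_to_na(df$d_call) else NA_character_
  out$c_call <- if ("c_call" %in% names(df)) blank_to_na(df$c_call) else NA_character_
  out$cdr3_nt <- blank_to_na(df$junction)
  out$cdr3_aa <- if ("junction_aa" %in% names(df)) blank_to_na(df$junction_aa) else NA_character_
  out$duplicate_count <- as.integer(df$duplicate_count)
  out$mutations <- ""
  rownames(out) <- NULL
  out
}

#' Pick the best-scoring hit from a MiXCR multi-hit field
#'
#' Fields look like `"IGHV1-2*01(900),IGHV1-3*01(500)"`. The allele with the
#' highest printed score wins; ties break lexicographically by allele name.
#'
#' @param x character vector of multi-hit fields (may be `NA`/empty).
#' @return character vector of best allele names (`NA` where no hit).
#' @export
best_hit <- function(x) {
  vapply(x, function(field) {
    if (is.na(field) || !nzchar(field)) return(NA_character_)
    items <- strsplit(field, ",", fixed = TRUE)[[1]]
    m <- regmatches(items, regexec("^\\s*([^()]+?)\\s*\\(([-0-9.eE+]+)\\)\\s*$",
                                   items))
    ok <- vapply(m, length, 1L) == 3L
    if (!any(ok)) return(NA_character_)
    names_ <- vapply(m[ok], `[`, "", 2L)
    scores <- as.numeric(vapply(m[ok], `[`, "", 3L))
    best <- which(scores == max(scores))
    sort(names_[best])[1L]
  }, "", USE.NAMES = FALSE)
}

parse_mixcr <- function(df, germline = NULL) {
  require_columns(df, c("cloneCount", "allVHitsWithScore",
                        "allJHitsWithScore", "nSeqCDR3", "refPoints"),
                  "mixcr")
  n <- nrow(df)
  out <- empty_records()[seq_len(n), , drop = FALSE]
  out$record_id <- if ("cloneId" %in% names(df)) {
    blank_to_na(df$cloneId)
  } else {
    as.character(seq_len(n))
  }
  out$v_call <- best_hit(blank_to_na(df$allVHitsWithScore))
  out$j_call <- best_hit(blank_to_na(df$allJHitsWithScore))
  out$d_call <- if ("allDHitsWithScore" %in% names(df)) {
    best_hit(blank_to_na(df$allDHitsWithScore))
  } else NA_character_
  out$c_call <- if ("allCHitsWithScore" %in% names(df)) {
    best_hit(blank_to_na(df$allCHitsWithScore))
  } else NA_character_
  out$cdr3_nt <- blank_to_na(df$nSeqCDR3)
  out$cdr3_aa <- if ("aaSeqCDR3" %in% names(df)) blank_to_na(df$aaSeqCDR3) else NA_character_
  out$duplicate_count <- as.integer(round(as.numeric(df$cloneCount)))
  out$mutations <- ""
  rp <- blank_to_na(df$refPoints)
  for (i in seq_len(n)) {
    if (is.na(rp[i])) next
    jf <- parse_refpoints(rp[i], germline = germline, v_call = out$v_call[i],
                          d_call = out$d_call[i], j_call = out$j_call[i])
    out$v_del3[i] <- jf$v_del3; out$d_del5[i] <- jf$d_del5
    out$d_del3[i] <- jf$d_del3; out$j_del5[i] <- jf$j_del5
    out$ins_vd[i] <- jf$ins_vd; out$ins_dj[i] <- jf$ins_dj
  }
  rownames(out) <- NULL
  out
}

#' Parse a MiXCR-style refPoints string into junction fields
#'
#' The refPoints column is a colon-separated string of 21 slots of anchor
#' coordinates; absent anchors are empty slots. The slots consumed here
#' (1-based positions in the string) are read-coordinate anchors
#' 10 (CDR3 begin), 11 (V end, trimmed), 12 (D begin), 13 (D end),
#' 14 (J begin), 15 (CDR3 end), and germline-coordinate alignment extents
#' 16 (V alignment end), 17 (D alignment begin), 18 (D alignment end),
#' 19 (J alignment begin). All coordinates are 0-based half-open.
#'
#' Insertions are differences of read anchors, clamped at zero:
#' `ins_vd = max(0, Dbegin - Vend)`, `ins_dj = max(0, Jbegin - Dend)`.
#' Deletions are germline length minus aligned extent on the junction side:
#' `v_del3 = len(V) - VAlignEnd`, `d_del5 = DAlignBegin`,
#' `d_del3 = len(D) - DAlignEnd`, `j_del5 = JAlignBegin`; they require the
#' corresponding allele to be present in `germline` and are `NA` otherwise.
#' When the D anchors are empty all D-dependent fields (`ins_vd`, `ins_dj`,
#' `d_del5`, `d_del3`) are `NA`.
#'
#' @param refpoints one refPoints string.
#' @param germline optional `germline_set` for deletion math.
#' @param v_call,d_call,j_call allele names for the record.
#' @return list with integer (or `NA`) `v_del3, d_del5, d_del3, j_del5,
#'   ins_vd, ins_dj`.
#' @export
parse_refpoints <- function(refpoints, germline = NULL, v_call = NA,
                            d_call = NA, j_call = NA) {
  slots <- strsplit(refpoints, ":", fixed = TRUE)[[1]]
  # trailing empty slots are dropped by strsplit; pad back out
  if (length(slots) < 21L) {
    n_colon <- lengths(regmatches(refpoints, gregexpr(":", refpoints,
                                                      fixed = TRUE)))
    if (n_colon < 20L) {
      stop("refPoints string has ", n_colon + 1L,
           " slots; 21 required", call. = FALSE)
    }
    slots <- c(slots, rep("", 21L - length(slots)))
  }
  num <- suppressWarnings(as.integer(slots))
  v_end <- num[11L]; d_begin <- num[12L]; d_end <- num[13L]
  j_begin <- num[14L]
  v_aln_end <- num[16L]; d_aln_begin <- num[17L]; d_aln_end <- num[18L]
  j_aln_begin <- num[19L]
  has_d <- !is.na(d_begin) && !is.na(d_end)
  ins_vd <- if (has_d && !is.na(v_end)) max(0L, d_begin - v_end) else NA_integer_
  ins_dj <- if (has_d && !is.na(j_begin)) max(0L, j_begin - d_end) else NA_integer_
  seg_len <- function(call) {
    if (is.null(germline) || is.na(call) || !call %in% names(germline)) {
      return(NA_integer_)
    }
    nchar(germline[[call]]$sequence)
  }
  v_len <- seg_len(v_call); d_len <- seg_len(d_call); j_len <- seg_len(j_call)
  v_del3 <- if (!is.na(v_len) && !is.na(v_aln_end)) v_len - v_aln_end else NA_integer_
  d_del5 <- if (has_d && !is.na(d_aln_begin)) d_aln_begin else NA_integer_
  d_del3 <- if (has_d && !is.na(d_len) && !is.na(d_aln_end)) d_len - d_aln_end else NA_integer_
  j_del5 <- if (!is.na(j_aln_begin)) j_aln_begin else NA_integer_
  if (!has_d) d_del5 <- d_del3 <- NA_integer_
  vals <- c(v_del3 = v_del3, d_del5 = d_del5, d_del3 = d_del3,
            j_del5 = j_del5, ins_vd = ins_vd, ins_dj = ins_dj)
  if (any(!is.na(vals) & vals < 0L)) {
    stop("inconsistent refPoints coordinates: negative derived ",
         paste(names(vals)[!is.na(vals) & vals < 0L], collapse = ", "),
         call. = FALSE)
  }
  as.list(vals)
}

#' Compose a refPoints string from junction fields
#'
#' Inverse of [parse_refpoints()] (up to the arbitrary read offset of the V
#' end anchor). Used for round-trip validation and by tests.
#'
#' @param fields list with `v_del3, d_del5, d_del3, j_del5, ins_vd, ins_dj`.
#' @param germline `germline_set` providing segment lengths.
#' @param v_call,d_call,j_call allele names.
#' @param v_end read coordinate of the V end anchor.
#' @return a 21-slot refPoints string.
#' @export
compose_refpoints <- function(fields, germline, v_call, d_call = NA,
                              j_call = NA, v_end = 100L) {
  slots <- rep("", 21L)
  slots[11L] <- as.character(v_end)
  has_d <- !is.na(d_call) && !is.null(fields$ins_vd) && !is.na(fields$ins_vd)
  if (has_d) {
    d_len <- nchar(germline[[d_call]]$sequence)
    d_begin <- v_end + fields$ins_vd
    d_extent <- d_len - fields$d_del5 - fields$d_del3
    d_end <- d_begin + d_extent
    slots[12L] <- as.character(d_begin)
    slots[13L] <- as.character(d_end)
    slots[14L] <- as.character(d_end + fields$ins_dj)
    slots[17L] <- as.character(fields$d_del5)
    slots[18L] <- as.character(d_len - fields$d_del3)
  }
  if (!is.na(v_call)) {
    slots[16L] <- as.character(nchar(germline[[v_call]]$sequence) -
                                 fields$v_del3)
  }
  if (!is.null(fields$j_del5) && !is.na(fields$j_del5)) {
    slots[19L] <- as.character(fields$j_del5)
  }
  paste(slots, collapse = ":")
}

#' Write aligned records as native TSV
#'
#' @param records data.frame in native column layout.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_clone_table <- function(records, path) {
  out <- records[NATIVE_COLUMNS]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read an antibody database
#'
#' The database is a TSV with columns `id, source, cdr3_aa, v_call, j_call,
#' c_call, diseases, description`; `diseases` is a semicolon-separated list.
#' Records whose `cdr3_aa` is empty or contains a non-standard amino-acid
#' letter are rejected (reasons retained in the `rejected` attribute).
#' Duplicate ids are an error, as is a database with zero valid records.
#'
#' @param path TSV path.
#' @return data.frame with a `diseases` list-column of character vectors.
#' @export
read_antibody_db <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character")
  require_columns(df, c("id", "source", "cdr3_aa", "v_call", "j_call",
                        "c_call", "diseases", "description"), "antibody db")
  df$cdr3_aa <- toupper(blank_to_na(df$cdr3_aa))
  aa_ok <- !is.na(df$cdr3_aa) &
    !grepl(sprintf("[^%s]", paste(AA_STANDARD, collapse = "")), df$cdr3_aa)
  rejected <- data.frame(
    id = df$id[!aa_ok],
    reason = ifelse(is.na(df$cdr3_aa[!aa_ok]), "empty cdr3_aa",
                    "non-standard amino-acid letter"),
    stringsAsFactors = FALSE
  )
  df <- df[aa_ok, , drop = FALSE]
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup) > 0L) {
    stop("duplicate antibody id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("antibody database has zero valid records",
                           call. = FALSE)
  diseases <- lapply(df$diseases, function(d) {
    if (is.na(d) || !nzchar(trimws(d))) return(character())
    tags <- trimws(strsplit(d, ";", fixed = TRUE)[[1]])
    tags[nzchar(tags)]
  })
  out <- data.frame(id = df$id, source = df$source, cdr3_aa = df$cdr3_aa,
                    v_call = blank_to_na(df$v_call),
                    j_call = blank_to_na(df$j_call),
                    c_call = blank_to_na(df$c_call),
                    description = df$description, stringsAsFactors = FALSE)
  out$diseases <- diseases
  rownames(out) <- NULL
  if (nrow(rejected) > 0L) {
    message(nrow(rejected), " antibody record(s) rejected")
  }
  structure(out, rejected = rejected)
}
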