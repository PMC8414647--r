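get_gencode <- function() Biostrings::GENETIC_CODE

fr_span <- function(segment) {
  assert_that(all(c("FR1", "FR3") %in% names(segment$regions)),
              sprintf("segment %s lacks FR1/FR3 boundaries", segment$name))
  c(segment$regions$FR1[1L], segment$regions$FR3[2L])
}

#' Classify germline V positions as silent, replacement or composite loci
#'
#' For every position in a complete codon inside the FR1-FR3 span, the three
#' possible substitutions are enumerated against the standard genetic code.
#' If all three are synonymous the locus is *silent*; if none is, it is
#' *replacement*; otherwise *composite*. A substitution creating a stop
#' codon counts as non-synonymous.
#'
#' @param segment a V `germline_segment` with FR1-FR3 regions and reading
#'   frame set.
#' @return data.frame with `position` (0-based) and
#'   `class` in `silent`/`replacement`/`composite`; positions inside the
#'   span but not in a complete in-span codon are excluded and their number
#'   attached as attribute `n_excluded`.
#' @export
classify_loci <- function(segment) {
  assert_that(segment$segment_type == "V", "locus classification needs a V segment")
  span <- fr_span(segment)
  frame <- segment$reading_frame_offset
  seq_chars <- strsplit(segment$sequence, "")[[1]]
  positions <- span[1L]:(span[2L] - 1L)
  codon_start <- positions - ((positions - frame) %% 3L)
  in_codon <- codon_start >= span[1L] & codon_start + 3L <= span[2L] &
    codon_start >= 0L
  n_excluded <- sum(!in_codon)
  positions <- positions[in_codon]
  codon_start <- codon_start[in_codon]
  cls <- vapply(seq_along(positions), function(i) {
    codon <- seq_chars[codon_start[i] + 1:3]
    classify_position(codon, positions[i] - codon_start[i] + 1L)
  }, "")
  structure(data.frame(position = positions, class = cls,
                       stringsAsFactors = FALSE),
            n_excluded = n_excluded)
}

# codon: character(3); offset: 1..3 within codon
classify_position <- function(codon, offset) {
  code <- get_gencode()
  aa0 <- code[[paste(codon, collapse = "")]]
  alts <- setdiff(DNA_BASES, codon[offset])
  syn <- vapply(alts, function(b) {
    alt <- codon
    alt[offset] <- b
    aa <- code[[paste(alt, collapse = "")]]
    aa == aa0 && aa != "*"
  }, TRUE)
  if (all(syn)) "silent" else if (!any(syn)) "replacement" else "composite"
}

MOTIF_DEFS <- list(
  list(tag = "hotspot_WRCY_RGYW", pattern = "(?=[AT][AG]C[CT])", offset = 2L),
  list(tag = "hotspot_WRCY_RGYW", pattern = "(?=[AG]G[CT][AT])", offset = 1L),
  list(tag = "hotspot_WA_TW", pattern = "(?=[AT]A)", offset = 1L),
  list(tag = "hotspot_WA_TW", pattern = "(?=T[AT])", offset = 0L),
  list(tag = "coldspot_SYC_GRS", pattern = "(?=[CG][CT]C)", offset = 2L),
  list(tag = "coldspot_SYC_GRS", pattern = "(?=G[AG][CG])", offset = 0L)
)

#' Annotate hypermutation hotspot/coldspot motif positions
#'
#' Scans a germline segment for the canonical hotspot motifs WRCY/RGYW
#' (tagging the mutable C and G respectively) and WA/TW (tagging the A and
#' T), and the coldspot motifs SYC/GRS (tagging the C and G). IUPAC classes:
#' W = A/T, R = A/G, Y = C/T, S = C/G. Overlapping matches are all recorded;
#' a position may carry several tags.
#'
#' @param segment a `germline_segment`.
#' @return data.frame with `position` (0-based) and `tag`; unique rows.
#' @export
annotate_motifs <- function(segment) {
  seqs <- segment$sequence
  rows <- lapply(MOTIF_DEFS, function(def) {
    starts <- gregexpr(def$pattern, seqs, perl = TRUE)[[1]]
    if (starts[1L] == -1L) return(NULL)
    data.frame(position = as.integer(starts) - 1L + def$offset,
               tag = def$tag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(position = integer(), tag = character(),
                      stringsAsFactors = FALSE))
  }
  out <- unique(out)
  out <- out[order(out$position, out$tag), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-position mutation frequencies of one clone
#'
#' The clone is the unit: for every germline V position inside FR1-FR3, the
#' mutation frequency is the fraction of the clone's (non-redundant) reads
#' that carry a mutation event there, summed over the (at most 3) event
#' types. Per-event frequencies are returned alongside.
#'
#' @param clone one row of a repertoire's `clones` data.frame (or any list
#'   with a `read_mutations` character vector, one mutation string per read).
#' @param segment the V `germline_segment` the mutation coordinates refer to.
#' @return list with `freq` (named numeric, dense over the FR1-FR3 span,
#'   names are 0-based positions), `events` (data.frame `pos, from, to,
#'   freq`) and `n_reads`.
#' @export
clone_position_frequencies <- function(clone, segment) {
  span <- fr_span(segment)
  muts <- if (is.data.frame(clone)) clone$read_mutations[[1L]] else clone$read_mutations
  n_reads <- length(muts)
  assert_that(n_reads > 0L, "clone has no supporting reads")
  positions <- span[1L]:(span[2L] - 1L)
  freq <- setNames(numeric(length(positions)), positions)
  events <- lapply(muts, parse_mutations)
  ev <- do.call(rbind, events)
  seg_len <- nchar(segment$sequence)
  if (nrow(ev) > 0L && any(ev$pos >= seg_len)) {
    stop("mutation event position beyond segment ", segment$name,
         " length ", seg_len, call. = FALSE)
  }
  ev <- ev[ev$pos >= span[1L] & ev$pos < span[2L], , drop = FALSE]
  if (nrow(ev) > 0L) {
    ev_key <- paste(ev$pos, ev$from, ev$to)
    tab <- table(ev_key)
    ev_unique <- ev[!duplicated(ev_key), , drop = FALSE]
    ev_unique$freq <- as.numeric(tab[paste(ev_unique$pos, ev_unique$from,
                                           ev_unique$to)]) / n_reads
    pos_tab <- tapply(ev_unique$freq, ev_unique$pos, sum)
    freq[names(pos_tab)] <- as.numeric(pos_tab)
    ev_unique <- ev_unique[order(ev_unique$pos, ev_unique$to), , drop = FALSE]
    rownames(ev_unique) <- NULL
  } else {
    ev_unique <- data.frame(pos = integer(), from = character(),
                            to = character(), freq = numeric(),
                            stringsAsFactors = FALSE)
  }
  list(freq = freq, events = ev_unique, n_reads = n_reads)
}

find_v_segment <- function(germline, gene) {
  vs <- germline_of_type(germline, "V")
  hit <- which(gene_from_allele(names(vs)) == gene)
  if (length(hit) == 0L) return(NULL)
  vs[[hit[1L]]]
}

#' Repertoire-level somatic hypermutation profile
#'
#' Restricts to clones of one isotype (the SHM pattern is computed per
#' isotype) whose V gene has a germline segment with FR boundaries, and
#' aggregates clone-level position frequencies with equal weight per clone:
#'
#' * `position_freq`: per (V gene, position) mean mutation frequency over
#'   the clones using that gene, dense over each gene's FR1-FR3 span;
#' * `region_rate`: arithmetic mean of `position_freq` over each region's
#'   positions (pooled across genes);
#' * `transition`: 4x4 germline-base x observed-base matrix; entry (b, c)
#'   is the mean, over positions with germline base b, of the clone-averaged
#'   b->c event frequency, so each row sums to the mean mutation frequency
#'   of that base's positions;
#' * `motif_rate`: mean `position_freq` stratified by locus class
#'   (silent/replacement/composite, see [classify_loci()]) crossed with
#'   motif tag (see [annotate_motifs()]; `none` = untagged), with `all`
#'   marginals.
#'
#' @param repertoire a `repertoire` whose clones carry per-read mutations.
#' @param germline a `germline_set` with V boundaries.
#' @param isotype one of IGHM, IGHD, IGHG, IGHA, IGHE, `"NA"`.
#' @return an `shm_profile` object; empty (with warning) when no clone of
#'   the isotype is usable.
#' @export
repertoire_shm_profile <- function(repertoire, germline, isotype) {
  assert_that(isotype %in% ISOTYPE_LEVELS,
              "isotype must be one of the six categories")
  cl <- repertoire$clones
  cl <- cl[cl$isotype == isotype & !is.na(cl$v_gene), , drop = FALSE]
  usable <- vapply(cl$v_gene, function(g) {
    seg <- find_v_segment(germline, g)
    !is.null(seg) && all(c("FR1", "FR3") %in% names(seg$regions))
  }, TRUE)
  cl <- cl[usable, , drop = FALSE]
  if (nrow(cl) == 0L) {
    warning("no usable clone of isotype ", isotype)
    return(structure(list(isotype = isotype, position_freq = NULL,
                          region_rate = NULL, transition = NULL,
                          motif_rate = NULL, n_clones = 0L),
                     class = "shm_profile"))
  }

  genes <- unique(cl$v_gene)
  pos_rows <- list(); ev_acc <- list()
  for (g in genes) {
    seg <- find_v_segment(germline, g)
    sub <- cl[cl$v_gene == g, , drop = FALSE]
    span <- fr_span(seg)
    seg_len <- nchar(seg$sequence)
    positions <- span[1L]:(span[2L] - 1L)
    n_g <- nrow(sub)
    # one event row per (read, position); each contributes 1/n_reads to its
    # clone's frequency, and clones carry equal weight 1/n_g
    n_reads <- lengths(sub$read_mutations)
    read_str <- unlist(sub$read_mutations, use.names = FALSE)
    clone_of_read <- rep.int(seq_len(n_g), n_reads)
    keep <- !is.na(read_str) & nzchar(read_str)
    ev <- NULL
    if (any(keep)) {
      items <- strsplit(read_str[keep], ",", fixed = TRUE)
      it <- unlist(items, use.names = FALSE)
      bad <- !grepl("^[0-9]+:[ACGT]>[ACGT]$", it)
      if (any(bad)) stop("malformed mutation item(s): ",
                         paste(unique(it[bad]), collapse = ", "))
      ev <- data.frame(
        clone = rep.int(clone_of_read[keep], lengths(items)),
        pos = as.integer(sub(":.*$", "", it)),
        from = sub("^[0-9]+:([ACGT])>.*$", "\\1", it),
        to = sub("^.*>", "", it), stringsAsFactors = FALSE
      )
      if (any(ev$pos >= seg_len)) {
        stop("mutation event position beyond segment ", seg$name,
             " length ", seg_len, call. = FALSE)
      }
      ev <- ev[ev$pos >= span[1L] & ev$pos < span[2L], , drop = FALSE]
    }
    freq <- setNames(numeric(length(positions)), positions)
    if (!is.null(ev) && nrow(ev) > 0L) {
      w <- 1 / n_reads[ev$clone]
      pos_sum <- rowsum(w, ev$pos)
      freq[rownames(pos_sum)] <- pos_sum[, 1L] / n_g
      ev_key <- paste(ev$pos, ev$from, ev$to)
      ev_sum <- rowsum(w, ev_key)
      parts <- strsplit(rownames(ev_sum), " ", fixed = TRUE)
      ev_acc[[g]] <- data.frame(
        v_gene = g,
        pos = as.integer(vapply(parts, `[`, "", 1L)),
        from = vapply(parts, `[`, "", 2L),
        to = vapply(parts, `[`, "", 3L),
        freq = ev_sum[, 1L] / n_g, stringsAsFactors = FALSE
      )
    }
    base <- strsplit(seg$sequence, "")[[1]][positions + 1L]
    pos_rows[[g]] <- data.frame(v_gene = g, position = positions,
                                germline_base = base,
                                freq = unname(freq),
                                n_clones = n_g, stringsAsFactors = FALSE)
  }
  position_freq <- do.call(rbind, pos_rows)
  rownames(position_freq) <- NULL

  # region rates: mean of position_freq over each region's positions
  region_rate <- setNames(numeric(5L),
                          c("FR1", "CDR1", "FR2", "CDR2", "FR3"))
  for (rn in names(region_rate)) {
    vals <- numeric()
    for (g in genes) {
      seg <- find_v_segment(germline, g)
      if (!rn %in% names(seg$regions)) next
      iv <- seg$regions[[rn]]
      sel <- position_freq$v_gene == g & position_freq$position >= iv[1L] &
        position_freq$position < iv[2L]
      vals <- c(vals, position_freq$freq[sel])
    }
    region_rate[rn] <- if (length(vals) > 0L) mean(vals) else NA_real_
  }

  # transition matrix: mean event frequency per germline-base cell
  transition <- matrix(0, 4L, 4L, dimnames = list(DNA_BASES, DNA_BASES))
  n_cells_per_base <- table(factor(position_freq$germline_base,
                                   levels = DNA_BASES))
  ev_all <- if (length(ev_acc) > 0L) do.call(rbind, ev_acc) else NULL
  if (!is.null(ev_all)) {
    agg <- tapply(ev_all$freq, list(ev_all$from, ev_all$to), sum)
    for (b in DNA_BASES) for (cc in DNA_BASES) {
      if (b == cc || n_cells_per_base[[b]] == 0L) next
      v <- if (b %in% rownames(agg) && cc %in% colnames(agg)) agg[b, cc] else NA
      transition[b, cc] <- if (is.na(v)) 0 else v / n_cells_per_base[[b]]
    }
  }

  motif_rate <- motif_rate_table(position_freq, germline, genes)

  structure(list(isotype = isotype, position_freq = position_freq,
                 region_rate = region_rate, transition = transition,
                 motif_rate = motif_rate, n_clones = nrow(cl)),
            class = "shm_profile")
}

motif_rate_table <- function(position_freq, germline, genes) {
  ann <- lapply(genes, function(g) {
    seg <- find_v_segment(germline, g)
    loci <- classify_loci(seg)
    motifs <- annotate_motifs(seg)
    sel <- position_freq[position_freq$v_gene == g, , drop = FALSE]
    sel <- merge(sel, loci, by = "position")  # drops unclassified positions
    tags <- split(motifs$tag, motifs$position)
    sel_tags <- tags[as.character(sel$position)]
    sel_tags[vapply(sel_tags, is.null, TRUE)] <- list("none")
    data.frame(
      class = rep(sel$class, lengths(sel_tags)),
      tag = unlist(sel_tags, use.names = FALSE),
      freq = rep(sel$freq, lengths(sel_tags)),
      stringsAsFactors = FALSE
    )
  })
  ann <- do.call(rbind, ann)
  classes <- c("silent", "replacement", "composite", "all")
  tags <- c(vapply(MOTIF_DEFS, `[[`, "", "tag")[!duplicated(
    vapply(MOTIF_DEFS, `[[`, "", "tag"))], "none", "all")
  rows <- list()
  for (cls in classes) for (tg in tags) {
    sel <- (cls == "all" | ann$class == cls) & (tg == "all" | ann$tag == tg)
    rows[[paste(cls, tg)]] <- data.frame(
      locus_class = cls, motif_tag = tg,
      rate = if (any(sel)) mean(ann$freq[sel]) else NA_real_,
      n_positions = sum(sel), stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ratio of hotspot-tagged to untagged mutation frequency
#'
#' Pools an SHM profile's positional mutation frequencies across V genes and
#' contrasts hotspot-tagged positions (WRCY/RGYW, WA/TW; positions also
#' carrying a coldspot tag excluded) against positions carrying no motif tag
#' at all. Values above 1 indicate motif-focused hypermutation.
#'
#' @param profile an `shm_profile`.
#' @param germline the `germline_set` used to build the profile.
#' @return scalar ratio (NaN when a stratum has zero mean frequency).
#' @export
hotspot_to_untagged_ratio <- function(profile, germline) {
  pf <- profile$position_freq
  assert_that(!is.null(pf) && nrow(pf) > 0L, "profile has no positions")
  hot_vals <- numeric(); untagged_vals <- numeric()
  for (g in unique(pf$v_gene)) {
    seg <- find_v_segment(germline, g)
    m <- annotate_motifs(seg)
    hot <- setdiff(m$position[m$tag != "coldspot_SYC_GRS"],
                   m$position[m$tag == "coldspot_SYC_GRS"])
    tagged <- unique(m$position)
    sel <- pf[pf$v_gene == g, , drop = FALSE]
    hot_vals <- c(hot_vals, sel$freq[sel$position %in% hot])
    untagged_vals <- c(untagged_vals,
                       sel$freq[!sel$position %in% tagged])
  }
  mean(hot_vals) / mean(untagged_vals)
}

#' @export
print.shm_profile <- function(x, ...) {
  cat(sprintf("<shm_profile> isotype %s, %d clone(s)\n", x$isotype,
              x$n_clones))
  if (x$n_clones > 0L) {
    cat("  region rates:",
        paste(names(x$region_rate),
              sprintf("%.4g", x$region_rate), sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}
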