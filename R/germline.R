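#' Construct a germline segment
#'
#' A `germline_segment` holds one named V/D/J/C germline nucleotide sequence,
#' optional framework/CDR region boundaries (0-based half-open intervals) and
#' a reading-frame offset. Region boundaries are required downstream only for
#' V segments (hypermutation profiling, CDR3 anchoring in the simulator).
#'
#' The CDR3 anchor convention: the conserved Cys codon starts at the V
#' segment's `FR3` end, and the conserved Trp codon ends at the J segment's
#' `FR4` start, so the CDR3 printed by this package includes both conserved
#' residues (e.g. `CARGYGMDVW`).
#'
#' @param name allele name, e.g. `"IGHV1-2*01"`.
#' @param sequence nucleotide string over A/C/G/T (uppercased).
#' @param segment_type `"V"`, `"D"`, `"J"` or `"C"`; inferred from `name`
#'   when `NULL` (`IGHV...` -> V, `IGHJ...` -> J, `IGHD<digit>...` -> D,
#'   other `IGH[MDGAE]...` -> C).
#' @param regions named list of `c(start, end)` 0-based half-open intervals
#'   (subset of FR1, CDR1, FR2, CDR2, FR3 for V; FR4 allowed for J).
#' @param reading_frame_offset integer in 0..2.
#' @return an object of class `germline_segment`.
#' @export
germline_segment <- function(name, sequence, segment_type = NULL,
                             regions = list(), reading_frame_offset = 0L) {
  sequence <- toupper(sequence)
  assert_that(nzchar(sequence), sprintf("segment %s: empty sequence", name))
  assert_that(!grepl("[^ACGT]", sequence),
              sprintf("segment %s: sequence contains non-ACGT characters", name))
  if (is.null(segment_type)) segment_type <- infer_segment_type(name)
  assert_that(segment_type %in% c("V", "D", "J", "C"),
              sprintf("segment %s: invalid type %s", name, segment_type))
  assert_that(reading_frame_offset %in% 0:2,
              sprintf("segment %s: reading frame offset must be 0..2", name))
  regions <- validate_regions(name, regions, nchar(sequence),
                              segment_type, reading_frame_offset)
  structure(
    list(name = name, segment_type = segment_type, sequence = sequence,
         regions = regions,
         reading_frame_offset = as.integer(reading_frame_offset)),
    class = "germline_segment"
  )
}

infer_segment_type <- function(name) {
  if (grepl("^IGHV", name)) return("V")
  if (grepl("^IGHJ", name)) return("J")
  if (grepl("^IGHD[0-9]", name)) return("D")
  if (grepl("^IGH[MDGAE]", name)) return("C")
  stop("cannot infer segment type for allele '", name, "'", call. = FALSE)
}

validate_regions <- function(name, regions, len, segment_type, frame) {
  if (length(regions) == 0L) return(list())
  starts <- vapply(regions, function(r) as.integer(r[1]), 1L)
  ends <- vapply(regions, function(r) as.integer(r[2]), 1L)
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  regions <- lapply(regions[ord], function(r) as.integer(r[1:2]))
  if (any(starts < 0L) || any(ends > len) || any(starts >= ends)) {
    stop("segment ", name, ": region interval outside [0, ", len, ")",
         call. = FALSE)
  }
  if (length(starts) > 1L && any(starts[-1L] < ends[-length(ends)])) {
    stop("segment ", name, ": overlapping region intervals", call. = FALSE)
  }
  if (segment_type == "V" && any((starts - frame) %% 3L != 0L)) {
    stop("segment ", name, ": V region start not in reading frame",
         call. = FALSE)
  }
  regions
}

#' @export
print.germline_segment <- function(x, ...) {
  cat(sprintf("<germline_segment> %s (%s, %d nt, %d region(s))\n",
              x$name, x$segment_type, nchar(x$sequence), length(x$regions)))
  invisible(x)
}

#' Read a germline region-boundary configuration
#'
#' The configuration is a YAML map from allele name to an entry with optional
#' `frame` (reading-frame offset, default 0) and `regions`, itself a map from
#' region name to a two-element `[start, end)` 0-based half-open interval.
#'
#' @param path YAML file path.
#' @return named list of entries, each `list(frame=, regions=)`.
#' @export
read_boundary_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  lapply(cfg, function(entry) {
    list(frame = as.integer(entry$frame %||% 0L),
         regions = lapply(entry$regions %||% list(), function(r) as.integer(r)))
  })
}

#' Read germline segments from FASTA
#'
#' Loads V/D/J/C segments from a FASTA file and attaches region boundaries
#' from a boundary configuration (see [read_boundary_config()]). V segments
#' without a boundary entry are loaded with empty regions and flagged in the
#' `missing_boundaries` attribute of the result.
#'
#' @param path FASTA file.
#' @param boundary_config a parsed configuration list, a YAML path, or `NULL`.
#' @return a `germline_set`: named list of [germline_segment()] objects, in
#'   file order.
#' @export
read_germline_fasta <- function(path, boundary_config = NULL) {
  if (is.character(boundary_config)) {
    boundary_config <- read_boundary_config(boundary_config)
  }
  boundary_config <- boundary_config %||% list()
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    warning("empty germline FASTA: ", path)
    return(structure(list(), class = "germline_set",
                     missing_boundaries = character()))
  }
  if (!startsWith(trimws(lines[nonblank[1L]]), ">")) {
    stop("malformed FASTA at line ", nonblank[1L],
         ": expected '>' header", call. = FALSE)
  }
  seqs <- Biostrings::readBStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  for (al in names(boundary_config)) {
    if (grepl("^IGHV", al) && !al %in% names(seqs)) {
      stop("boundary config names V allele '", al,
           "' absent from FASTA", call. = FALSE)
    }
  }
  segs <- vector("list", length(seqs))
  missing_b <- character()
  for (i in seq_along(seqs)) {
    nm <- names(seqs)[i]
    entry <- boundary_config[[nm]]
    seg <- germline_segment(
      name = nm, sequence = as.character(seqs[[i]]),
      regions = entry$regions %||% list(),
      reading_frame_offset = entry$frame %||% 0L
    )
    if (seg$segment_type == "V" && length(seg$regions) == 0L) {
      missing_b <- c(missing_b, nm)
    }
    segs[[i]] <- seg
  }
  names(segs) <- names(seqs)
  structure(segs, class = "germline_set", missing_boundaries = missing_b)
}

#' @export
print.germline_set <- function(x, ...) {
  types <- vapply(x, `[[`, "", "segment_type")
  cat(sprintf("<germline_set> %d segment(s): %s\n", length(x),
              paste(sprintf("%d %s", as.integer(table(types)[unique(types)]),
                            unique(types)), collapse = ", ")))
  invisible(x)
}

germline_of_type <- function(germline, type) {
  germline[vapply(germline, function(s) s$segment_type == type, TRUE)]
}

#' Bundled toy germline reference
#'
#' A small fully synthetic heavy-chain germline set (3 V, 2 D, 2 J, 2 C
#' segments) used by the simulator defaults, the bundled pipeline fixture and
#' the test-suite. V segments are 92 nt with FR1/CDR1/FR2/CDR2/FR3 boundaries,
#' a conserved Cys codon immediately after FR3 and an 8 nt 3' tail; J segments
#' are 30 nt with the conserved Trp codon ending at the FR4 start (position
#' 18). Framework regions contain canonical hotspot (WRCY/WA) and coldspot
#' (SYC) motifs so motif-biased hypermutation is exercised.
#'
#' @return a `germline_set`.
#' @export
toy_germline <- function() {
  v_regions <- list(FR1 = c(0L, 18L), CDR1 = c(18L, 30L), FR2 = c(30L, 48L),
                    CDR2 = c(48L, 60L), FR3 = c(60L, 81L))
  j_regions <- list(FR4 = c(18L, 30L))
  segs <- list(
    germline_segment("IGHV1-8*01", paste0(
      "GAGGTGCAGCTGTTGGAG", "AGCTACGCTATG", "TGGGTCCGCCAGGCTCCA",
      "ATTAGTGGTAGT", "TACTATGCAGACTCTGTGAAG", "TGT", "GCGAGAGA"),
      regions = v_regions),
    germline_segment("IGHV3-23*01", paste0(
      "CAGGTGCAGCTGGTGCAG", "GGCTACACCTTC", "TGGGTGCGACAGGCCCCT",
      "ATCAACCCTAGT", "TACGCACAGAAGTTTCAGGGC", "TGT", "GCGAGGGA"),
      regions = v_regions),
    germline_segment("IGHV4-59*01", paste0(
      "GAAGTGCAGCTGGTGGAG", "GGATTCACCTTT", "TGGGTCCGTCAGGCTCCG",
      "ATTAAGCAAGAT", "TATGTGGACTCTGTGAAGGGC", "TGT", "ACGAGAGA"),
      regions = v_regions),
    germline_segment("IGHD3-10*01", "GGTATAACTGGAACGAC"),
    germline_segment("IGHD2-2*01", "GTATTACGATTTTTGGAGTGGT"),
    germline_segment("IGHJ4*01",
      paste0("ACTACTTTGACTACT", "TGG", "GGCCAGGGAACC"), regions = j_regions),
    germline_segment("IGHJ6*01",
      paste0("CTTTGACTACTACTA", "TGG", "GGTCAAGGAACT"), regions = j_regions),
    germline_segment("IGHM*01", "GGGAGTGCATCCGCCCCAACC"),
    germline_segment("IGHG1*01", "GCCTCCACCAAGGGCCCATCG")
  )
  names(segs) <- vapply(segs, `[[`, "", "name")
  structure(segs, class = "germline_set", missing_boundaries = character())
}

#' Write a germline set to FASTA plus boundary YAML
#'
#' @param germline a `germline_set`.
#' @param fasta_path,boundary_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_germline <- function(germline, fasta_path, boundary_path) {
  lines <- unlist(lapply(germline, function(s) c(paste0(">", s$name),
                                                 s$sequence)))
  writeLines(lines, fasta_path)
  cfg <- lapply(germline, function(s) {
    list(frame = s$reading_frame_offset,
         regions = lapply(s$regions, as.integer))
  })
  names(cfg) <- vapply(germline, `[[`, "", "name")
  yaml::write_yaml(cfg, boundary_path)
  invisible(c(fasta = fasta_path, boundaries = boundary_path))
}
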