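#' Simulation parameters for synthetic heavy-chain repertoires
#'
#' Bundles and validates the generative model's parameters. The model:
#' V/D/J segments are sampled from usage vectors; exonucleolytic trimming at
#' the four junction sites and non-templated insertion lengths at the two
#' junctions follow truncated geometric distributions; the CDR3 runs from
#' the conserved Cys codon (at the V FR3 end) to the conserved Trp codon
#' (ending at the J FR4 start); per-read point mutations are i.i.d. over V
#' positions with the base rate scaled up at hotspot-tagged and down at
#' coldspot-tagged positions; clone abundances follow a rank-based power
#' law; isotypes are sampled from a six-category probability vector.
#'
#' @param germline a `germline_set` (default [toy_germline()]).
#' @param v_usage,d_usage,j_usage named probability vectors over segment
#'   allele names (default uniform).
#' @param trim_prob,trim_max truncated-geometric success probability and
#'   maximum per site V3/D5/D3/J5.
#' @param ins_prob,ins_max same per junction VD/DJ.
#' @param base_mutation_rate per-base per-read mutation probability.
#' @param hotspot_multiplier,coldspot_multiplier rate multipliers at
#'   motif-tagged positions (hotspot tags win when a position carries both).
#' @param n_clones number of clones to simulate.
#' @param abundance_exponent power-law exponent a: clone abundance is
#'   proportional to rank^-a (0 = even repertoire), normalised to
#'   `total_reads` and floored at 1 read.
#' @param total_reads target total read count distributed over the clones
#'   (default `20 * n_clones`).
#' @param reads_extra_mean Poisson mean of additional (beyond 1)
#'   non-redundant reads per clone.
#' @param isotype_probs 6-vector of probabilities over
#'   IGHM/IGHD/IGHG/IGHA/IGHE/`NA`.
#' @param seed integer RNG seed.
#' @return validated `simulation_params` list.
#' @export
simulation_params <- function(germline = toy_germline(),
                              v_usage = NULL, d_usage = NULL, j_usage = NULL,
                              trim_prob = c(V3 = 0.35, D5 = 0.4, D3 = 0.4,
                                            J5 = 0.35),
                              trim_max = c(V3 = 6, D5 = 4, D3 = 4, J5 = 6),
                              ins_prob = c(VD = 0.2, DJ = 0.2),
                              ins_max = c(VD = 12, DJ = 12),
                              base_mutation_rate = 0.02,
                              hotspot_multiplier = 3,
                              coldspot_multiplier = 0.3,
                              n_clones = 1000L,
                              abundance_exponent = 1.5,
                              total_reads = NULL,
                              reads_extra_mean = 1,
                              isotype_probs = c(IGHM = 0.25, IGHD = 0,
                                                IGHG = 0.5, IGHA = 0,
                                                IGHE = 0, "NA" = 0.25),
                              seed = 1L) {
  uniform_over <- function(type) {
    segs <- germline_of_type(germline, type)
    assert_that(length(segs) > 0L, paste("germline has no", type, "segment"))
    setNames(rep(1 / length(segs), length(segs)), names(segs))
  }
  v_usage <- v_usage %||% uniform_over("V")
  d_usage <- d_usage %||% uniform_over("D")
  j_usage <- j_usage %||% uniform_over("J")
  for (u in list(v_usage, d_usage, j_usage, isotype_probs)) {
    assert_that(all(u >= 0) && abs(sum(u) - 1) <= 1e-9,
                "usage/probability vectors must be non-negative and sum to 1")
  }
  assert_that(all(names(v_usage) %in% names(germline)) &&
                all(names(d_usage) %in% names(germline)) &&
                all(names(j_usage) %in% names(germline)),
              "usage vectors name alleles absent from the germline")
  assert_that(setequal(names(isotype_probs), ISOTYPE_LEVELS),
              "isotype_probs must cover the six isotype categories")
  assert_that(all(c("V3", "D5", "D3", "J5") %in% names(trim_prob)) &&
                all(c("V3", "D5", "D3", "J5") %in% names(trim_max)),
              "trim parameters must name sites V3, D5, D3, J5")
  assert_that(all(c("VD", "DJ") %in% names(ins_prob)) &&
                all(c("VD", "DJ") %in% names(ins_max)),
              "insertion parameters must name junctions VD, DJ")
  assert_that(all(trim_prob > 0 & trim_prob <= 1) &&
                all(ins_prob > 0 & ins_prob <= 1),
              "geometric probabilities must be in (0, 1]")
  assert_that(base_mutation_rate >= 0 && base_mutation_rate <= 1,
              "base_mutation_rate must be in [0, 1]")
  assert_that(hotspot_multiplier > 0 && coldspot_multiplier > 0,
              "motif multipliers must be positive")
  assert_that(n_clones >= 1L, "n_clones must be >= 1")
  assert_that(abundance_exponent >= 0, "abundance_exponent must be >= 0")
  total_reads <- total_reads %||% (20L * as.integer(n_clones))
  assert_that(total_reads >= n_clones,
              "total_reads must be at least n_clones")
  assert_that(reads_extra_mean >= 0, "reads_extra_mean must be >= 0")
  structure(list(
    germline = germline, v_usage = v_usage, d_usage = d_usage,
    j_usage = j_usage, trim_prob = trim_prob,
    trim_max = vapply(trim_max, as.integer, 1L),
    ins_prob = ins_prob, ins_max = vapply(ins_max, as.integer, 1L),
    base_mutation_rate = base_mutation_rate,
    hotspot_multiplier = hotspot_multiplier,
    coldspot_multiplier = coldspot_multiplier,
    n_clones = as.integer(n_clones),
    abundance_exponent = abundance_exponent,
    total_reads = as.integer(total_reads),
    reads_extra_mean = reads_extra_mean,
    isotype_probs = isotype_probs[ISOTYPE_LEVELS],
    seed = as.integer(seed)
  ), class = "simulation_params")
}

# per-position mutation rate vector for one V segment
mutation_rate_vector <- function(segment, params) {
  len <- nchar(segment$sequence)
  mult <- rep(1, len)
  motifs <- annotate_motifs(segment)
  cold <- motifs$position[motifs$tag == "coldspot_SYC_GRS"]
  hot <- motifs$position[motifs$tag != "coldspot_SYC_GRS"]
  mult[cold + 1L] <- params$coldspot_multiplier
  mult[hot + 1L] <- params$hotspot_multiplier  # hotspot wins on overlap
  pmin(1, params$base_mutation_rate * mult)
}

isotype_c_allele <- function(germline, isotype_probs) {
  c_segs <- germline_of_type(germline, "C")
  map <- setNames(rep(NA_character_, 6L), ISOTYPE_LEVELS)
  for (nm in names(c_segs)) {
    iso <- assign_isotype(nm)
    if (is.na(map[[iso]])) map[[iso]] <- nm
  }
  missing <- names(isotype_probs)[isotype_probs > 0 &
                                    names(isotype_probs) != "NA" &
                                    is.na(map[names(isotype_probs)])]
  assert_that(length(missing) == 0L,
              paste("no germline C segment for isotype(s):",
                    paste(missing, collapse = ", ")))
  map
}

#' Simulate one heavy-chain repertoire with ground truth
#'
#' Deterministic for a fixed seed. See [simulation_params()] for the model.
#'
#' @param params a `simulation_params` object.
#' @param sample_id sample identifier.
#' @param metadata metadata list attached to the repertoire.
#' @return list with `repertoire` (clustered clones), `records` (the
#'   aligned-record table the native writer emits) and `truth`, a list with
#'   the per-clone generative variables (`clones` data.frame: genes, trims,
#'   insertion lengths and nucleotides, abundance, read count),
#'   `read_mutations` (per-clone list of per-read mutation strings) and the
#'   scalar parameters.
#' @export
simulate_repertoire <- function(params, sample_id = "sim",
                                metadata = list()) {
  assert_that(inherits(params, "simulation_params"),
              "params must come from simulation_params()")
  set.seed(params$seed)
  g <- params$germline
  n <- params$n_clones
  v_alleles <- sample(names(params$v_usage), n, replace = TRUE,
                      prob = params$v_usage)
  d_alleles <- sample(names(params$d_usage), n, replace = TRUE,
                      prob = params$d_usage)
  j_alleles <- sample(names(params$j_usage), n, replace = TRUE,
                      prob = params$j_usage)

  seg_info <- function(al) g[[al]]
  v_len <- vapply(v_alleles, function(a) nchar(g[[a]]$sequence), 1L)
  d_len <- vapply(d_alleles, function(a) nchar(g[[a]]$sequence), 1L)
  fr3_end <- vapply(v_alleles, function(a) g[[a]]$regions$FR3[2L], 1L)
  fr4_start <- vapply(j_alleles, function(a) {
    assert_that("FR4" %in% names(g[[a]]$regions),
                paste("J segment", a, "lacks an FR4 boundary"))
    g[[a]]$regions$FR4[1L]
  }, 1L)

  v_del3 <- pmin(rtgeom(n, params$trim_prob[["V3"]], params$trim_max[["V3"]]),
                 v_len - (fr3_end + 3L))
  d_del5 <- pmin(rtgeom(n, params$trim_prob[["D5"]], params$trim_max[["D5"]]),
                 d_len)
  d_del3 <- pmin(rtgeom(n, params$trim_prob[["D3"]], params$trim_max[["D3"]]),
                 d_len - d_del5)
  j_del5 <- pmin(rtgeom(n, params$trim_prob[["J5"]], params$trim_max[["J5"]]),
                 fr4_start - 3L)
  ins_vd <- rtgeom(n, params$ins_prob[["VD"]], params$ins_max[["VD"]])
  ins_dj <- rtgeom(n, params$ins_prob[["DJ"]], params$ins_max[["DJ"]])
  rand_nt <- function(lens) {
    vapply(lens, function(l) {
      if (l == 0L) "" else paste(sample(DNA_BASES, l, replace = TRUE),
                                 collapse = "")
    }, "")
  }
  ins_vd_nt <- rand_nt(ins_vd)
  ins_dj_nt <- rand_nt(ins_dj)

  v_seq <- vapply(v_alleles, function(a) g[[a]]$sequence, "")
  d_seq <- vapply(d_alleles, function(a) g[[a]]$sequence, "")
  j_seq <- vapply(j_alleles, function(a) g[[a]]$sequence, "")
  v_part <- substr(v_seq, fr3_end + 1L, v_len - v_del3)
  d_part <- substr(d_seq, d_del5 + 1L, d_len - d_del3)
  j_part <- substr(j_seq, j_del5 + 1L, fr4_start)
  cdr3_nt <- paste0(v_part, ins_vd_nt, d_part, ins_dj_nt, j_part)

  iso_map <- isotype_c_allele(g, params$isotype_probs)
  isotype <- sample(ISOTYPE_LEVELS, n, replace = TRUE,
                    prob = params$isotype_probs)
  c_call <- unname(iso_map[isotype])

  rank <- sample.int(n)
  w <- rank^(-params$abundance_exponent)
  abundance <- pmax(1L, as.integer(round(params$total_reads * w / sum(w))))
  n_reads <- pmin(abundance, 1L + rpois(n, params$reads_extra_mean))

  read_mutations <- simulate_mutations(v_alleles, n_reads, params)

  clone_of_read <- rep.int(seq_len(n), n_reads)
  first_read <- !duplicated(clone_of_read)
  dup <- rep(1L, length(clone_of_read))
  dup[first_read] <- abundance - (n_reads - 1L)
  read_in_clone <- sequence(n_reads)

  records <- empty_records()[seq_along(clone_of_read), , drop = FALSE]
  records$record_id <- sprintf("c%06d_r%d", clone_of_read, read_in_clone)
  records$v_call <- v_alleles[clone_of_read]
  records$d_call <- d_alleles[clone_of_read]
  records$j_call <- j_alleles[clone_of_read]
  records$c_call <- c_call[clone_of_read]
  records$cdr3_nt <- cdr3_nt[clone_of_read]
  records$cdr3_aa <- translate_nt(records$cdr3_nt)
  records$duplicate_count <- dup
  records$v_del3 <- v_del3[clone_of_read]
  records$d_del5 <- d_del5[clone_of_read]
  records$d_del3 <- d_del3[clone_of_read]
  records$j_del5 <- j_del5[clone_of_read]
  records$ins_vd <- ins_vd[clone_of_read]
  records$ins_dj <- ins_dj[clone_of_read]
  records$mutations <- unlist(lapply(read_mutations, identity),
                              use.names = FALSE)
  rownames(records) <- NULL

  truth_clones <- data.frame(
    v_call = v_alleles, d_call = d_alleles, j_call = j_alleles,
    c_call = c_call, isotype = isotype, cdr3_nt = cdr3_nt,
    cdr3_aa = translate_nt(cdr3_nt),
    v_del3 = v_del3, d_del5 = d_del5, d_del3 = d_del3, j_del5 = j_del5,
    ins_vd = ins_vd, ins_dj = ins_dj,
    ins_vd_nt = ins_vd_nt, ins_dj_nt = ins_dj_nt,
    abundance = abundance, n_reads = n_reads, stringsAsFactors = FALSE
  )
  rownames(truth_clones) <- NULL
  truth <- list(
    sample_id = sample_id, seed = params$seed,
    n_clones = n, clones = truth_clones, read_mutations = read_mutations,
    base_mutation_rate = params$base_mutation_rate,
    hotspot_multiplier = params$hotspot_multiplier,
    coldspot_multiplier = params$coldspot_multiplier,
    abundance_exponent = params$abundance_exponent
  )
  rep <- cluster_clones(records, sample_id = sample_id, use_c_gene = TRUE,
                        metadata = metadata)
  list(repertoire = rep, records = records, truth = truth)
}

# per-clone list of per-read mutation strings, vectorised by V allele
simulate_mutations <- function(v_alleles, n_reads, params) {
  g <- params$germline
  n <- length(v_alleles)
  clone_of_read <- rep.int(seq_len(n), n_reads)
  read_allele <- v_alleles[clone_of_read]
  total_reads <- length(clone_of_read)
  read_strings <- character(total_reads)
  if (params$base_mutation_rate > 0) {
    for (al in unique(v_alleles)) {
      seg <- g[[al]]
      rates <- mutation_rate_vector(seg, params)
      len <- length(rates)
      rows <- which(read_allele == al)
      if (length(rows) == 0L) next
      u <- matrix(runif(length(rows) * len), nrow = length(rows))
      hit <- which(u < matrix(rates, nrow = length(rows), ncol = len,
                              byrow = TRUE), arr.ind = TRUE)
      if (nrow(hit) > 0L) {
        bases <- strsplit(seg$sequence, "")[[1]]
        pos0 <- hit[, 2L] - 1L
        from <- bases[hit[, 2L]]
        # uniform choice among the three alternative bases
        alt_idx <- sample.int(3L, nrow(hit), replace = TRUE)
        alt_mat <- vapply(DNA_BASES, function(b) setdiff(DNA_BASES, b),
                          character(3L))
        to <- alt_mat[cbind(alt_idx, match(from, DNA_BASES))]
        item <- sprintf("%d:%s>%s", pos0, from, to)
        ord <- order(hit[, 1L], pos0)
        per_read <- vapply(
          split(item[ord], factor(hit[ord, 1L],
                                  levels = seq_along(rows))),
          paste, "", collapse = ",")
        read_strings[rows] <- unname(per_read)
      }
    }
  }
  split(read_strings, factor(clone_of_read, levels = seq_len(n)))
}

# fixed reverse codon table: lexicographically first codon per amino acid
aa_to_nt <- function(aa) {
  code <- get_gencode()
  rev_map <- vapply(AA_STANDARD, function(a) {
    sort(names(code)[code == a])[1L]
  }, "")
  letters_ <- strsplit(aa, "")[[1]]
  bad <- !letters_ %in% AA_STANDARD
  if (any(bad)) {
    stop("CDR3aa '", aa, "' contains non-standard letter(s): ",
         paste(unique(letters_[bad]), collapse = ", "), call. = FALSE)
  }
  paste(rev_map[letters_], collapse = "")
}

#' Simulate a group of repertoires with planted public clones
#'
#' Runs independent per-sample simulations with per-sample seeds derived
#' from the master seed, then injects each planted CDR3 amino-acid key as a
#' clone into exactly the listed samples (junction synthesised with a fixed
#' codon table, first V/J alleles, IGHG isotype when available).
#'
#' @param params a `simulation_params`; its `seed` is the master seed.
#' @param n_samples number of samples.
#' @param planted_keys list of `list(cdr3_aa =, samples =)` with 1-based
#'   sample indices.
#' @param label group label.
#' @param sample_prefix prefix for sample ids.
#' @param metadata either a single metadata list shared by all samples or a
#'   list of per-sample metadata lists.
#' @return list with `group` (a `sample_group`) and `truth` (per-sample
#'   truths plus the planted-key table).
#' @export
simulate_group <- function(params, n_samples, planted_keys = list(),
                           label = "experimental", sample_prefix = "S",
                           metadata = list()) {
  assert_that(n_samples >= 1L, "n_samples must be >= 1")
  for (pk in planted_keys) {
    assert_that(all(pk$samples >= 1L & pk$samples <= n_samples),
                "planted sample index out of range")
  }
  set.seed(params$seed)
  seeds <- sample.int(.Machine$integer.max, n_samples)
  per_sample_meta <- function(i) {
    if (length(metadata) == 0L) return(list())
    if (!is.null(names(metadata))) return(metadata)
    metadata[[i]]
  }
  g <- params$germline
  v1 <- names(germline_of_type(g, "V"))[1L]
  j1 <- names(germline_of_type(g, "J"))[1L]
  iso_map <- isotype_c_allele(g, params$isotype_probs)
  plant_c <- if (!is.na(iso_map[["IGHG"]])) iso_map[["IGHG"]] else NA_character_
  reps <- vector("list", n_samples)
  truths <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    p_i <- params
    p_i$seed <- seeds[i]
    sim <- simulate_repertoire(p_i, sample_id = sprintf("%s%02d",
                                                        sample_prefix, i),
                               metadata = per_sample_meta(i))
    recs <- sim$records
    for (pk in planted_keys) {
      if (!i %in% pk$samples) next
      nt <- aa_to_nt(pk$cdr3_aa)
      extra <- empty_records()[1L, , drop = FALSE]
      extra$record_id <- paste0("plant_", pk$cdr3_aa)
      extra$v_call <- v1; extra$j_call <- j1; extra$c_call <- plant_c
      extra$cdr3_nt <- nt; extra$cdr3_aa <- pk$cdr3_aa
      extra$duplicate_count <- 5L
      extra$mutations <- ""
      recs <- rbind(recs, extra)
    }
    reps[[i]] <- cluster_clones(recs, sample_id = sim$repertoire$sample_id,
                                use_c_gene = TRUE,
                                metadata = per_sample_meta(i))
    sim$truth$records <- NULL
    truths[[i]] <- sim$truth
  }
  planted_df <- if (length(planted_keys) > 0L) {
    data.frame(
      cdr3_aa = vapply(planted_keys, `[[`, "", "cdr3_aa"),
      samples = I(lapply(planted_keys, function(pk) {
        sprintf("%s%02d", sample_prefix, sort(pk$samples))
      })), stringsAsFactors = FALSE)
  } else {
    data.frame(cdr3_aa = character(), samples = I(list()))
  }
  list(group = sample_group(reps, label),
       truth = list(samples = truths, planted = planted_df,
                    master_seed = params$seed, sample_seeds = seeds))
}

#' Serialise / load a simulation ground truth
#'
#' @param truth the `truth` element of [simulate_repertoire()].
#' @param path JSON file path.
#' @return `write_ground_truth` returns `path` invisibly;
#'   `read_ground_truth` the truth list.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$clones <- as.data.frame(x$clones, stringsAsFactors = FALSE)
  x$read_mutations <- lapply(x$read_mutations, as.character)
  x
}
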