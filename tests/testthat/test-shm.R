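# independent genetic-code oracle for locus classification
oracle_classify <- function(codon, offset) {
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  aa0 <- code[[codon]]
  syn <- 0L
  for (b in setdiff(bases, substr(codon, offset, offset))) {
    alt <- codon
    substr(alt, offset, offset) <- b
    if (code[[alt]] == aa0 && code[[alt]] != "*") syn <- syn + 1L
  }
  if (syn == 3L) "silent" else if (syn == 0L) "replacement" else "composite"
}

# build a minimal V segment carrying an arbitrary in-frame FR1..FR3 core
core_v <- function(core_nt, name = "IGHV9-1*01") {
  len <- nchar(core_nt)
  stopifnot(len %% 3 == 0)
  third <- len %/% 3 %/% 3 * 3
  germline_segment(name, core_nt,
                   regions = list(FR1 = c(0L, third),
                                  FR3 = c(len - third, len)))
}

test_that("locus classification matches the genetic-code enumeration", {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  # spot-check the worked codon examples
  seg <- core_v("CTGAAAATTCTGAAAATTCTGAAAATT")
  cls <- classify_loci(seg)
  expect_equal(cls$class[cls$position == 2], "silent")       # CTG pos 3
  expect_equal(cls$class[cls$position == 3], "replacement")  # AAA pos 1
  expect_equal(cls$class[cls$position == 8], "composite")    # ATT pos 3
  # full 64 x 3 agreement, via segments of 9 identical codons
  for (codon in codons) {
    seg <- core_v(paste(rep(codon, 9), collapse = ""))
    got <- classify_loci(seg)
    for (off in 1:3) {
      expect_equal(got$class[got$position == (off - 1)],
                   oracle_classify(codon, off),
                   info = paste(codon, off))
    }
  }
})

test_that("motif annotation tags the mutable base of each IUPAC motif", {
  seg <- germline_segment("IGHD9-9*01", "TACT")
  m <- annotate_motifs(seg)
  expect_true(any(m$position == 2 & m$tag == "hotspot_WRCY_RGYW"))

  m2 <- annotate_motifs(germline_segment("IGHD9-9*01", "GTC"))
  expect_equal(m2[m2$tag == "coldspot_SYC_GRS", "position"], 2L)

  # GGG is itself a GRS coldspot instance (R=G, S=G)
  m3 <- annotate_motifs(germline_segment("IGHD9-9*01", "GGGG"))
  expect_equal(unique(m3$tag), "coldspot_SYC_GRS")
  expect_equal(nrow(annotate_motifs(germline_segment("IGHD9-9*01", "CACA"))),
               0L)

  # independent regex oracle over random sequences
  expand <- list(W = c("A", "T"), R = c("A", "G"), Y = c("C", "T"),
                 S = c("C", "G"))
  oracle_positions <- function(x, motif, offset) {
    chars <- strsplit(x, "")[[1]]
    mot <- strsplit(motif, "")[[1]]
    hits <- integer()
    for (s in seq_len(nchar(x) - length(mot) + 1)) {
      ok <- all(vapply(seq_along(mot), function(j) {
        allowed <- expand[[mot[j]]] %||% mot[j]
        chars[s + j - 1] %in% allowed
      }, TRUE))
      if (ok) hits <- c(hits, s - 1L + offset)
    }
    hits
  }
  set.seed(31)
  for (i in 1:10) {
    x <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
    m <- annotate_motifs(germline_segment("IGHD9-9*01", x))
    want_hot1 <- sort(unique(c(oracle_positions(x, "WRCY", 2L),
                               oracle_positions(x, "RGYW", 1L))))
    want_cold <- sort(unique(c(oracle_positions(x, "SYC", 2L),
                               oracle_positions(x, "GRS", 0L))))
    expect_equal(m$position[m$tag == "hotspot_WRCY_RGYW"], want_hot1)
    expect_equal(m$position[m$tag == "coldspot_SYC_GRS"], want_cold)
  }
})

test_that("clone position frequencies average over supporting reads", {
  seg <- toy[["IGHV1-8*01"]]
  clone <- list(read_mutations = c("10:A>G", ""))
  cpf <- clone_position_frequencies(clone, seg)
  expect_equal(cpf$freq[["10"]], 0.5)

  # at most three event types per position, frequencies add up
  clone2 <- list(read_mutations = c("7:G>A", "7:G>A", "7:G>C", ""))
  cpf2 <- clone_position_frequencies(clone2, seg)
  expect_equal(cpf2$freq[["7"]], 0.75)
  expect_equal(cpf2$events$freq[cpf2$events$to == "A"], 0.5)
  expect_equal(cpf2$events$freq[cpf2$events$to == "C"], 0.25)

  # unmutated clone: all-zero map over the FR1-FR3 span
  cpf3 <- clone_position_frequencies(list(read_mutations = c("", "")), seg)
  expect_true(all(cpf3$freq == 0))
  expect_equal(names(cpf3$freq), as.character(0:80))

  # event beyond the segment errors
  expect_error(
    clone_position_frequencies(list(read_mutations = "99:A>G"), seg),
    "beyond segment")
})

test_that("repertoire profile averages clones as units, per isotype", {
  recs <- make_records(
    list(id = "a", c = "IGHG1*01", cdr3 = "TGTAAATGG",
         mut = "10:A>G", n = 1),
    list(id = "a2", c = "IGHG1*01", cdr3 = "TGTAAATGG", mut = "", n = 1),
    list(id = "b", c = "IGHG1*01", cdr3 = "TGTCCCTGG", mut = "", n = 1),
    list(id = "m", c = "IGHM*01", cdr3 = "TGTGGGTGG",
         mut = "10:A>G", n = 1)
  )
  rep <- cluster_clones(recs, "s")
  pr <- repertoire_shm_profile(rep, toy, "IGHG")
  expect_equal(pr$n_clones, 2L)
  pf <- pr$position_freq
  # clone a: freq 0.5 at position 10; clone b: 0 -> mean 0.25
  expect_equal(pf$freq[pf$position == 10], 0.25)
  # IGHM clone ignored here, counted in its own profile
  prm <- repertoire_shm_profile(rep, toy, "IGHM")
  expect_equal(prm$n_clones, 1L)
  expect_equal(prm$position_freq$freq[prm$position_freq$position == 10], 1.0)
  expect_warning(pre <- repertoire_shm_profile(rep, toy, "IGHE"),
                 "no usable clone")
  expect_equal(pre$n_clones, 0L)

  # all clones unmutated -> all rates and transitions zero
  recs0 <- make_records(list(id = "a", c = "IGHG1*01"))
  pr0 <- repertoire_shm_profile(cluster_clones(recs0, "s"), toy, "IGHG")
  expect_true(all(pr0$region_rate == 0))
  expect_true(all(pr0$transition == 0))
})

test_that("profile invariants hold on simulated repertoires", {
  sim <- simulate_repertoire(simulation_params(n_clones = 300, seed = 17))
  pr <- repertoire_shm_profile(sim$repertoire, toy, "IGHG")
  pf <- pr$position_freq

  # FR1-FR3 restriction: nothing at or beyond each gene's FR3 end
  for (g in unique(pf$v_gene)) {
    fr3_end <- toy[[paste0(g, "*01")]]$regions$FR3[2]
    expect_true(all(pf$position[pf$v_gene == g] < fr3_end))
  }

  # region rate equals the arithmetic mean of its positions' frequencies
  for (rn in c("FR1", "CDR1", "FR2", "CDR2", "FR3")) {
    vals <- unlist(lapply(unique(pf$v_gene), function(g) {
      iv <- toy[[paste0(g, "*01")]]$regions[[rn]]
      pf$freq[pf$v_gene == g & pf$position >= iv[1] & pf$position < iv[2]]
    }))
    expect_equal(pr$region_rate[[rn]], mean(vals), tolerance = 1e-12)
  }

  # transition rows sum to the mean mutation frequency of that base
  for (b in c("A", "C", "G", "T")) {
    expect_equal(sum(pr$transition[b, ]),
                 mean(pf$freq[pf$germline_base == b]), tolerance = 1e-12)
    expect_equal(pr$transition[b, b], 0)
  }

  # profile equals the mean of the exported per-clone operation
  cl <- sim$repertoire$clones
  cl <- cl[cl$isotype == "IGHG" & cl$v_gene == "IGHV1-8", , drop = FALSE]
  seg <- toy[["IGHV1-8*01"]]
  manual <- Reduce(`+`, lapply(seq_len(nrow(cl)), function(i) {
    clone_position_frequencies(cl[i, ], seg)$freq
  })) / nrow(cl)
  got <- pf$freq[pf$v_gene == "IGHV1-8"]
  names(got) <- pf$position[pf$v_gene == "IGHV1-8"]
  expect_equal(got, manual, tolerance = 1e-12)
})

test_that("motif-biased simulation elevates hotspot mutation rates", {
  ratios <- vapply(1:5, function(s) {
    sim <- simulate_repertoire(simulation_params(
      n_clones = 800, hotspot_multiplier = 5, seed = 1000 + s))
    pr <- repertoire_shm_profile(sim$repertoire, toy, "IGHG")
    hotspot_to_untagged_ratio(pr, toy)
  }, 0)
  expect_true(all(ratios > 1))
})
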