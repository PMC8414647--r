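test_that("simulation is deterministic and parameters are validated", {
  p <- simulation_params(n_clones = 40, seed = 42)
  t1 <- withr::local_tempfile(fileext = ".tsv")
  t2 <- withr::local_tempfile(fileext = ".tsv")
  write_clone_table(simulate_repertoire(p)$records, t1)
  write_clone_table(simulate_repertoire(p)$records, t2)
  expect_identical(readLines(t1), readLines(t2))

  expect_error(simulation_params(v_usage = c(`IGHV1-8*01` = 0.5)),
               "sum to 1")
  expect_error(simulation_params(hotspot_multiplier = 0), "positive")
  expect_error(simulation_params(n_clones = 0), "n_clones")
  expect_error(simulation_params(isotype_probs = c(IGHM = 1)),
               "six isotype")
})

test_that("degenerate parameters give exact recovery", {
  # zero mutation rate: no mutation events anywhere
  p0 <- simulation_params(n_clones = 50, base_mutation_rate = 0, seed = 3)
  sim0 <- simulate_repertoire(p0)
  expect_true(all(sim0$records$mutations == ""))
  pr <- suppressWarnings(
    repertoire_shm_profile(sim0$repertoire, p0$germline, "IGHG"))
  if (pr$n_clones > 0) expect_true(all(pr$position_freq$freq == 0))

  # one-hot V usage
  p1 <- simulation_params(
    v_usage = c(`IGHV3-23*01` = 1, `IGHV1-8*01` = 0, `IGHV4-59*01` = 0),
    n_clones = 30, seed = 4)
  sim1 <- simulate_repertoire(p1)
  expect_equal(gene_usage(sim1$repertoire, "V"), c(`IGHV3-23` = 1.0))
})

test_that("ground truth is sufficient to reproduce the emitted features", {
  p <- simulation_params(n_clones = 150, seed = 29)
  sim <- simulate_repertoire(p)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_clone_table(sim$records, tsv)
  rep_tsv <- cluster_clones(read_clone_table(tsv, "native"), "sim")

  # rebuild records purely from the truth object
  tr <- sim$truth
  recs <- do.call(make_records, lapply(seq_len(nrow(tr$clones)), function(i) {
    cl <- tr$clones[i, ]
    list(id = sprintf("t%05d", i), v = cl$v_call, d = cl$d_call,
         j = cl$j_call, c = cl$c_call, cdr3 = cl$cdr3_nt, n = cl$abundance,
         v_del3 = cl$v_del3, d_del5 = cl$d_del5, d_del3 = cl$d_del3,
         j_del5 = cl$j_del5, ins_vd = cl$ins_vd, ins_dj = cl$ins_dj)
  }))
  rep_truth <- cluster_clones(recs, "sim")
  expect_equal(gene_usage(rep_tsv, "V"), gene_usage(rep_truth, "V"),
               tolerance = 1e-9)
  expect_equal(cdr3_length_distribution(rep_tsv, "nt"),
               cdr3_length_distribution(rep_truth, "nt"), tolerance = 1e-9)
  expect_equal(diversity_indices(rep_tsv), diversity_indices(rep_truth),
               tolerance = 1e-9)
  jp1 <- junction_profile(rep_tsv); jp2 <- junction_profile(rep_truth)
  expect_equal(jp1$deletion_freq, jp2$deletion_freq, tolerance = 1e-9)
  expect_equal(jp1$insertion_freq, jp2$insertion_freq, tolerance = 1e-9)

  # truth JSON round-trips
  js <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(tr, js)
  back <- read_ground_truth(js)
  expect_equal(back$clones$cdr3_nt, tr$clones$cdr3_nt)
  expect_equal(back$clones$abundance, tr$clones$abundance)
  expect_equal(unname(back$read_mutations), unname(tr$read_mutations))
})

test_that("junction trim and insertion lengths follow the model", {
  p <- simulation_params(n_clones = 4000, base_mutation_rate = 0, seed = 55)
  sim <- simulate_repertoire(p)
  tr <- sim$truth$clones
  # insertions are untruncated by construction: mean within 3 SE
  m <- repscope:::tgeom_mean(p$ins_prob[["VD"]], p$ins_max[["VD"]])
  v <- repscope:::tgeom_var(p$ins_prob[["VD"]], p$ins_max[["VD"]])
  se <- sqrt(v / nrow(tr))
  expect_lt(abs(mean(tr$ins_vd) - m), 3 * se)
  # all lengths within configured bounds
  expect_true(all(tr$ins_vd <= p$ins_max[["VD"]]))
  expect_true(all(tr$v_del3 <= p$trim_max[["V3"]]))
  # CDR3 assembles from the recorded parts
  i <- which(tr$ins_vd > 0)[1]
  expect_true(grepl(tr$ins_vd_nt[i], tr$cdr3_nt[i], fixed = TRUE))
  # conserved anchors: CDR3 starts at the Cys codon, ends at the Trp codon
  inframe <- !is.na(tr$cdr3_aa)
  expect_true(all(substr(tr$cdr3_aa[inframe], 1, 1) == "C" |
                    grepl("^TG", substr(tr$cdr3_nt[inframe], 1, 2))))
  expect_true(all(substr(tr$cdr3_nt, nchar(tr$cdr3_nt) - 2,
                         nchar(tr$cdr3_nt)) == "TGG"))
})

test_that("clonal expansion strengthens with the abundance exponent", {
  tf <- vapply(c(1.0, 1.5, 2.0), function(a) {
    mean(vapply(1:5, function(s) {
      sim <- simulate_repertoire(simulation_params(
        n_clones = 1500, abundance_exponent = a, base_mutation_rate = 0,
        seed = 700 + s))
      top_clone_fraction(sim$repertoire)
    }, 0))
  }, 0)
  expect_true(all(diff(tf) > 0))
})

test_that("grouped simulation derives per-sample seeds and plants keys", {
  p <- simulation_params(n_clones = 40, seed = 6)
  g1 <- simulate_group(p, 3, planted_keys = list(
    list(cdr3_aa = "CARNWFDPW", samples = c(1, 3))))
  g2 <- simulate_group(p, 3, planted_keys = list(
    list(cdr3_aa = "CARNWFDPW", samples = c(1, 3))))
  # deterministic across runs
  expect_equal(g1$group$repertoires[[2]]$clones$cdr3_nt,
               g2$group$repertoires[[2]]$clones$cdr3_nt)
  # samples differ from each other
  expect_false(identical(g1$group$repertoires[[1]]$clones$cdr3_nt,
                         g1$group$repertoires[[2]]$clones$cdr3_nt))
  # planted key present exactly in the listed samples
  has_key <- vapply(g1$group$repertoires, function(r) {
    "CARNWFDPW" %in% r$clones$cdr3_aa
  }, TRUE)
  expect_equal(has_key, c(TRUE, FALSE, TRUE))
  expect_error(simulate_group(p, 2, planted_keys = list(
    list(cdr3_aa = "CARBADW", samples = 1))), "non-standard")
  expect_error(simulate_group(p, 2, planted_keys = list(
    list(cdr3_aa = "CARW", samples = 5))), "out of range")
})

test_that("unplanted long CDR3s almost never collide across samples", {
  # junction randomness makes cross-sample identity of long CDR3s rare;
  # restrict to CDR3s longer than 20 nt and expect no sharing
  p <- simulation_params(n_clones = 150, seed = 91,
                         ins_prob = c(VD = 0.12, DJ = 0.12))
  g <- simulate_group(p, 4)
  long_keys <- lapply(g$group$repertoires, function(r) {
    unique(r$clones$cdr3_nt[nchar(r$clones$cdr3_nt) > 40])
  })
  names(long_keys) <- vapply(g$group$repertoires, `[[`, "", "sample_id")
  shared <- oracle_public(long_keys, list(), 2L)
  expect_length(shared, 0L)
})
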