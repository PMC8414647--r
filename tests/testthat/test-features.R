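test_that("gene usage counts clones, not reads", {
  recs <- make_records(
    list(id = "a", v = "IGHV1-8*01", cdr3 = "TGTAAATGG", n = 100),
    list(id = "b", v = "IGHV1-8*01", cdr3 = "TGTCCCTGG", n = 1),
    list(id = "c", v = "IGHV3-23*01", cdr3 = "TGTGGGTGG", n = 1)
  )
  rep <- cluster_clones(recs, "s")
  u <- gene_usage(rep, "V")
  expect_equal(u[["IGHV1-8"]], 2 / 3)
  expect_equal(u[["IGHV3-23"]], 1 / 3)
  expect_equal(sum(u), 1, tolerance = 1e-12)
  expect_warning(d <- gene_usage(rep, "D"), "no clone")
  expect_length(d, 0L)

  # single clone
  rep1 <- make_repertoire(5)
  expect_equal(unname(gene_usage(rep1, "V")), 1.0)
})

test_that("planted V usage is recovered within binomial sampling error", {
  vu <- c("IGHV1-8*01" = 0.6, "IGHV3-23*01" = 0.3, "IGHV4-59*01" = 0.1)
  sim <- simulate_repertoire(simulation_params(
    v_usage = vu, n_clones = 10000, base_mutation_rate = 0, seed = 99))
  u <- gene_usage(sim$repertoire, "V")
  n <- nrow(sim$repertoire$clones)
  for (al in names(vu)) {
    se <- sqrt(vu[[al]] * (1 - vu[[al]]) / n)
    expect_lt(abs(u[[gene_from_allele(al)]] - vu[[al]]), 3 * se)
  }
})

test_that("CDR3 length distribution counts clones in nt and aa units", {
  recs <- make_records(
    list(id = "a", cdr3 = "TGTAAATGG", n = 10),
    list(id = "b", cdr3 = "TGTCCCTGG", n = 1),
    list(id = "c", cdr3 = "TGTGGGCCCTGG", n = 1)
  )
  rep <- cluster_clones(recs, "s")
  expect_equal(cdr3_length_distribution(rep, "nt"),
               c(`9` = 2 / 3, `12` = 1 / 3))
  expect_equal(cdr3_length_distribution(rep, "aa"),
               c(`3` = 2 / 3, `4` = 1 / 3))
  one <- make_repertoire(c(4, 4))
  ld <- cdr3_length_distribution(make_repertoire(7), "nt")
  expect_equal(unname(ld), 1.0)
})

test_that("insertions and deletions at a junction are mutually exclusive", {
  mk_rep <- function(...) cluster_clones(make_records(...), "s")
  # insertion present: deletion tallies record 0, insertion tally records 0
  # because a deletion is present too
  rep <- mk_rep(list(id = "a", d = "IGHD3-10*01", v_del3 = 2L, d_del5 = 0L,
                     d_del3 = 0L, j_del5 = 0L, ins_vd = 3L, ins_dj = 0L))
  jp <- junction_profile(rep)
  expect_equal(jp$deletion_freq$V3, c(`0` = 1))
  expect_equal(jp$deletion_freq$D5, c(`0` = 1))
  expect_equal(jp$insertion_freq$VD, c(`0` = 1))

  # pure per-site application
  rep2 <- mk_rep(list(id = "a", d = "IGHD3-10*01", v_del3 = 2L, d_del5 = 1L,
                      d_del3 = 0L, j_del5 = 0L, ins_vd = 0L, ins_dj = 4L))
  jp2 <- junction_profile(rep2)
  expect_equal(jp2$deletion_freq$V3, c(`2` = 1))
  expect_equal(jp2$deletion_freq$D5, c(`1` = 1))
  expect_equal(jp2$deletion_freq$D3, c(`0` = 1))
  expect_equal(jp2$deletion_freq$J5, c(`0` = 1))
  expect_equal(jp2$insertion_freq$VD, c(`0` = 1))
  expect_equal(jp2$insertion_freq$DJ, c(`4` = 1))

  # global exclusivity zeroes the other junction too
  jp2g <- junction_profile(rep2, exclusivity = "global")
  expect_equal(jp2g$deletion_freq$V3, c(`0` = 1))

  # clones without a D call are excluded
  rep3 <- mk_rep(
    list(id = "a", d = "IGHD3-10*01", v_del3 = 0L, d_del5 = 0L, d_del3 = 0L,
         j_del5 = 0L, ins_vd = 0L, ins_dj = 0L),
    list(id = "b", cdr3 = "TGTCCCTGG")
  )
  expect_equal(junction_profile(rep3)$n_clones_used, 1L)
  expect_warning(junction_profile(cluster_clones(
    make_records(list(id = "b")), "s")), "no clone")
})

test_that("diversity indices match closed forms", {
  expect_equal(shannon_index(c(0.5, 0.5)), log(2), tolerance = 1e-12)
  expect_equal(shannon_index(1.0), 0)
  expect_equal(shannon_index(rep(1 / 100, 100)), log(100), tolerance = 1e-12)
  expect_equal(simpson_index(c(0.5, 0.5)), 0.5)
  expect_equal(simpson_index(1.0), 1.0)
  expect_equal(simpson_index(rep(1 / 64, 64)), 1 / 64, tolerance = 1e-12)
  expect_equal(d50(c(0.5, 0.3, 0.15, 0.05)), 25.0)
  expect_equal(d50(rep(0.1, 10)), 50.0)
  expect_equal(d50(1.0), 100.0)
  expect_error(shannon_index(c(0.5, 0.4)), "sum to 1")
  expect_error(simpson_index(c(0.7, 0.4)), "sum to 1")
})

test_that("diversity bounds hold with equality iff uniform", {
  set.seed(42)
  for (i in 1:25) {
    r <- sample(2:200, 1)
    w <- rgamma(r, shape = sample(c(0.2, 1, 5), 1))
    p <- w / sum(w)
    expect_lte(shannon_index(p), log(r) + 1e-9)
    expect_gte(simpson_index(p), 1 / r - 1e-9)
  }
  u <- rep(1 / 50, 50)
  expect_equal(shannon_index(u), log(50), tolerance = 1e-9)
  expect_equal(simpson_index(u), 1 / 50, tolerance = 1e-9)
})

test_that("moving reads into the largest clone cannot raise D50", {
  set.seed(7)
  for (i in 1:10) {
    counts <- sample(1:50, 20, replace = TRUE)
    p <- counts / sum(counts)
    d0 <- d50(p)
    # move mass from the smallest to the largest clone
    j <- which.min(p); k <- which.max(p)
    delta <- p[j] / 2
    p2 <- p; p2[j] <- p2[j] - delta; p2[k] <- p2[k] + delta
    expect_lte(d50(p2), d0 + 1e-9)
  }
})

test_that("top-clone fraction sums the largest frequencies", {
  expect_equal(top_clone_fraction(make_repertoire(c(1, 2, 3))), 1.0)
  rep <- make_repertoire(c(40, 30, 20, 10))
  expect_equal(top_clone_fraction(rep, top_n = 2), 0.7)

  # clonal expansion concentrates the top of the repertoire
  uni <- simulate_repertoire(simulation_params(
    n_clones = 3000, abundance_exponent = 0, base_mutation_rate = 0,
    seed = 13))
  pow <- simulate_repertoire(simulation_params(
    n_clones = 3000, abundance_exponent = 2, base_mutation_rate = 0,
    seed = 13))
  expect_gt(top_clone_fraction(pow$repertoire),
            top_clone_fraction(uni$repertoire))
})

test_that("distribution outputs are normalised on simulated data", {
  sim <- simulate_repertoire(simulation_params(n_clones = 400, seed = 3))
  rep <- sim$repertoire
  expect_equal(sum(gene_usage(rep, "V")), 1, tolerance = 1e-9)
  expect_equal(sum(gene_usage(rep, "J")), 1, tolerance = 1e-9)
  expect_equal(sum(cdr3_length_distribution(rep, "nt")), 1, tolerance = 1e-9)
  jp <- junction_profile(rep)
  for (f in c(jp$deletion_freq, jp$insertion_freq)) {
    expect_equal(sum(f), 1, tolerance = 1e-9)
  }
})
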