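catalog5 <- function() {
  meta <- list(
    list(health_condition = "Healthy", tissue = "PBMC"),
    list(health_condition = "Healthy", tissue = "PBMC"),
    list(health_condition = "Healthy", tissue = "Spleen"),
    list(health_condition = "COVID-19", tissue = "PBMC"),
    list(health_condition = "COVID-19", tissue = "PBMC")
  )
  lapply(1:5, function(i) {
    make_repertoire(c(3, 2, 1) + i, sample_id = sprintf("R%02d", i),
                    metadata = meta[[i]])
  })
}

test_that("reference selection filters by exact metadata match", {
  cat5 <- catalog5()
  g <- select_reference(cat5, list(health_condition = "Healthy",
                                   tissue = "PBMC"))
  expect_equal(group_ids <- vapply(g$repertoires, `[[`, "", "sample_id"),
               c("R01", "R02"))
  expect_length(select_reference(cat5, list())$repertoires, 5L)
  expect_error(select_reference(cat5, list(read_length = "2x300")),
               "relax")
})

test_that("feature comparison summarises the reference with type-7 quantiles", {
  # three reference samples engineered to give V-usage 0.1/0.2/0.3 impossible
  # directly; instead verify against an independent quantile computation
  exp_g <- sample_group(list(make_repertoire(c(9, 1), "E1")), "experimental")
  ref_g <- sample_group(lapply(1:3, function(i) {
    make_repertoire(rep(1, i + 1), sprintf("R%d", i))
  }), "reference")
  cmp <- compare_feature(exp_g, ref_g, "d50")
  vals <- vapply(ref_g$repertoires,
                 function(r) unname(diversity_indices(r)["d50"]), 0)
  want <- unname(quantile(vals, c(0, 0.25, 0.5, 0.75, 1), type = 7))
  expect_equal(unlist(cmp$reference_summary[1, c("min", "q1", "median",
                                                 "q3", "max")],
                      use.names = FALSE), want, tolerance = 1e-12)
  expect_equal(cmp$reference_summary$n, 3L)

  # worked three-point case
  expect_equal(unname(quantile(c(0.1, 0.2, 0.3), c(0.25, 0.5, 0.75),
                               type = 7)), c(0.15, 0.2, 0.25))
})

test_that("feature comparison densifies categories with zeros", {
  exp_g <- sample_group(list(cluster_clones(make_records(
    list(id = "a", v = "IGHV4-59*01")), "E1")), "experimental")
  ref_g <- sample_group(list(cluster_clones(make_records(
    list(id = "b", v = "IGHV1-8*01")), "R1"),
    cluster_clones(make_records(
      list(id = "c", v = "IGHV1-8*01")), "R2")), "reference")
  cmp <- compare_feature(exp_g, ref_g, "v_usage")
  expect_setequal(cmp$categories, c("IGHV1-8", "IGHV4-59"))
  rs <- cmp$reference_summary
  # gene present only in the experimental group: all-zero reference summary
  expect_true(all(rs[rs$category == "IGHV4-59",
                     c("min", "q1", "median", "q3", "max")] == 0))
  expect_equal(rs$n, c(2L, 2L))
  # experimental value passes through unclipped
  expect_equal(cmp$experimental_points["IGHV4-59", "E1"], 1.0)
})

test_that("public clone detection classifies intra- and intergroup sharing", {
  mk <- function(id, cdr3s) {
    cluster_clones(do.call(make_records, lapply(seq_along(cdr3s), function(i) {
      list(id = sprintf("%s_%d", id, i), cdr3 = cdr3s[i])
    })), id)
  }
  # keys a,b,c,d encoded as distinct CDR3s
  key <- c(a = "TGTGCTAAATGG", b = "TGTGCTCCCTGG", c = "TGTGCTGGGTGG",
           d = "TGTGCTTTTTGG")
  exp_g <- sample_group(list(mk("S1", key[c("a", "b")]),
                             mk("S2", key[c("b", "c")])), "experimental")
  ref_g <- sample_group(list(mk("R1", key[c("c", "d")])), "reference")
  pub <- detect_public_clones(exp_g, ref_g, "cdr3nt", min_share = 2)
  expect_setequal(pub$key, unname(key[c("b", "c")]))
  b_row <- pub[pub$key == key[["b"]], ]
  expect_equal(b_row$class, "intragroup")
  expect_equal(b_row$exp_samples[[1]], c("S1", "S2"))
  c_row <- pub[pub$key == key[["c"]], ]
  expect_equal(c_row$class, "intergroup")
  expect_equal(c_row$exp_samples[[1]], "S2")
  expect_equal(c_row$ref_samples[[1]], "R1")
  expect_error(detect_public_clones(exp_g, ref_g, min_share = 1), ">= 2")
})

test_that("public clone detection matches the brute-force oracle", {
  set.seed(2024)
  pool <- replicate(300, paste0("TGT", paste(
    sample(c("GCA", "CGT", "TAC", "GGA", "TTC"), 4, replace = TRUE),
    collapse = ""), "TGG"))
  mk <- function(id) {
    cdr3s <- sample(pool, 40)
    cluster_clones(do.call(make_records, lapply(seq_along(cdr3s), function(i) {
      list(id = sprintf("%s_%d", id, i), cdr3 = cdr3s[i],
           v = sample(c("IGHV1-8*01", "IGHV3-23*01"), 1))
    })), id)
  }
  exp_g <- sample_group(lapply(sprintf("S%02d", 1:6), mk), "experimental")
  ref_g <- sample_group(lapply(sprintf("R%02d", 1:4), mk), "reference")
  for (sk in c("cdr3aa", "cdr3nt", "vj_cdr3nt")) {
    got <- detect_public_clones(exp_g, ref_g, sk, min_share = 2)
    keyfun <- function(rep) {
      cl <- rep$clones
      switch(sk, cdr3aa = unique(cl$cdr3_aa),
             cdr3nt = unique(cl$cdr3_nt),
             vj_cdr3nt = unique(paste(cl$v_gene, cl$j_gene, cl$cdr3_nt,
                                      sep = "|")))
    }
    ek <- lapply(exp_g$repertoires, keyfun)
    names(ek) <- vapply(exp_g$repertoires, `[[`, "", "sample_id")
    rk <- lapply(ref_g$repertoires, keyfun)
    names(rk) <- vapply(ref_g$repertoires, `[[`, "", "sample_id")
    want <- oracle_public(ek, rk, 2L)
    expect_setequal(got$key, names(want))
    for (i in seq_len(nrow(got))) {
      w <- want[[got$key[i]]]
      expect_equal(got$exp_samples[[i]], w$exp)
      expect_equal(got$ref_samples[[i]], w$ref)
      expect_equal(got$class[i], w$class)
    }
  }
})

test_that("planted public keys are recovered with their exact sample sets", {
  p <- simulation_params(n_clones = 60, seed = 88)
  grp <- simulate_group(p, 3, planted_keys = list(
    list(cdr3_aa = "CARWDYSNAFDVW", samples = c(1, 2))))
  pub <- detect_public_clones(grp$group, NULL, "cdr3aa")
  row <- pub[pub$key == "CARWDYSNAFDVW", ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$class, "intragroup")
  expect_equal(row$exp_samples[[1]], c("S01", "S02"))

  # the 5 exp + 10 ref planted-sharing shape
  pe <- simulation_params(n_clones = 30, seed = 12)
  eg <- simulate_group(pe, 5, planted_keys = list(
    list(cdr3_aa = "CARGFDYW", samples = 1:5)), sample_prefix = "E")
  pr <- simulation_params(n_clones = 30, seed = 13)
  rg <- simulate_group(pr, 12, planted_keys = list(
    list(cdr3_aa = "CARGFDYW", samples = 1:10)), sample_prefix = "Q",
    label = "reference")
  pub2 <- detect_public_clones(eg$group, rg$group, "cdr3aa")
  row2 <- pub2[pub2$key == "CARGFDYW", ]
  expect_equal(row2$class, "intergroup")
  expect_equal(row2$n_exp, 5L)
  expect_equal(row2$n_ref, 10L)
})
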