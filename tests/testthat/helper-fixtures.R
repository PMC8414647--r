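# shared fixtures and independent oracles used across test files

toy <- toy_germline()

# build a native-layout record data.frame from compact per-row lists
make_records <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(
      record_id = r$id %||% sprintf("r%02d", i),
      v_call = r$v %||% "IGHV1-8*01",
      d_call = r$d %||% NA_character_,
      j_call = r$j %||% "IGHJ4*01",
      c_call = r[["c"]] %||% NA_character_,
      cdr3_nt = r$cdr3 %||% "TGTGCTTGG",
      cdr3_aa = NA_character_,
      duplicate_count = as.integer(r$n %||% 1L),
      v_del3 = r$v_del3 %||% NA_integer_,
      d_del5 = r$d_del5 %||% NA_integer_,
      d_del3 = r$d_del3 %||% NA_integer_,
      j_del5 = r$j_del5 %||% NA_integer_,
      ins_vd = r$ins_vd %||% NA_integer_,
      ins_dj = r$ins_dj %||% NA_integer_,
      mutations = r$mut %||% "",
      stringsAsFactors = FALSE
    )
  }))
  df$cdr3_aa <- translate_nt(df$cdr3_nt)
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a small repertoire with chosen clone read counts (distinct CDR3s)
make_repertoire <- function(counts, sample_id = "S", metadata = list()) {
  cdr3s <- vapply(seq_along(counts), function(i) {
    paste0("TGTGCT", paste(rep(c("AAA", "CCC", "GGG", "TTT"),
                               length.out = i), collapse = ""), "TGG")
  }, "")
  recs <- do.call(make_records, lapply(seq_along(counts), function(i) {
    list(id = sprintf("r%02d", i), cdr3 = cdr3s[i], n = counts[i])
  }))
  cluster_clones(recs, sample_id = sample_id, metadata = metadata)
}

# brute-force public-clone oracle: key -> sample set, filter by min_share
oracle_public <- function(exp_keys, ref_keys, min_share = 2L) {
  all_keys <- unique(c(unlist(exp_keys), unlist(ref_keys)))
  out <- list()
  for (k in sort(all_keys)) {
    es <- sort(names(exp_keys)[vapply(exp_keys, function(s) k %in% s, TRUE)])
    rs <- if (length(ref_keys) > 0) {
      sort(names(ref_keys)[vapply(ref_keys, function(s) k %in% s, TRUE)])
    } else character()
    if (length(es) >= 1L && length(es) + length(rs) >= min_share) {
      out[[k]] <- list(exp = es, ref = rs,
                       class = if (length(rs) == 0L) "intragroup" else "intergroup")
    }
  }
  out
}

# exhaustive hypergeometric upper tail via binomial coefficients
oracle_hyper <- function(k, n, K, N) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# hand step-up Benjamini-Hochberg
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}
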